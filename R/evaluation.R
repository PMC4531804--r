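#' Pairwise co-membership confusion counts
#'
#' Counts, over all unordered gene pairs within the evaluation universe, the
#' pairs co-membered in both partitions (TP), in the prediction only (FP) and
#' in the reference only (FN). The universe defaults to the genes assigned to
#' a reference orthogroup, since benchmark references curate only a subset of
#' genes and true negatives are unknowable outside it. Genes unassigned in
#' the prediction co-member with nothing.
#'
#' With `unit = "gene"` an alternative gene-level counter is used: each
#' reference group is matched to its best-overlapping predicted group and TP /
#' FN / FP count member genes in the intersection, missing from it, and extra
#' (universe) genes in it.
#'
#' @param predicted,reference Partition tibbles.
#' @param universe Optional integer vector of gene ids to evaluate over.
#' @param unit `"pair"` (default) or `"gene"`.
#' @return One-row tibble with columns `tp`, `fp`, `fn`.
#' @export
pairwise_confusion <- function(predicted, reference, universe = NULL,
                               unit = c("pair", "gene")) {
  unit <- match.arg(unit)
  if (all(is.na(reference$orthogroup))) {
    stop("empty reference: no orthogroups to evaluate against")
  }
  if (is.null(universe)) {
    universe <- reference$gene_id[!is.na(reference$orthogroup)]
  }
  pred <- predicted$orthogroup[match(universe, predicted$gene_id)]
  ref <- reference$orthogroup[match(universe, reference$gene_id)]
  if (unit == "gene") {
    return(gene_level_confusion(pred, ref))
  }
  co_pairs <- function(labels) {
    sizes <- table(labels[!is.na(labels)])
    sum(choose(as.numeric(sizes), 2))
  }
  # pairs co-membered in both = sum over contingency cells of C(n_ij, 2)
  both <- !is.na(pred) & !is.na(ref)
  cell_sizes <- as.numeric(table(paste(pred[both], ref[both])))
  tp <- sum(choose(cell_sizes, 2))
  fp <- co_pairs(pred) - tp
  fn <- co_pairs(ref) - tp
  tibble::tibble(tp = tp, fp = fp, fn = fn)
}

gene_level_confusion <- function(pred, ref) {
  tp <- 0
  fp <- 0
  fn <- 0
  for (rg in sort(unique(ref[!is.na(ref)]))) {
    in_ref <- which(ref == rg)
    pred_labels <- pred[in_ref]
    if (all(is.na(pred_labels))) {
      fn <- fn + length(in_ref)
      next
    }
    counts <- table(pred_labels[!is.na(pred_labels)])
    best <- names(counts)[order(-counts, as.numeric(names(counts)))][1]
    in_best <- which(!is.na(pred) & pred == as.numeric(best))
    tp <- tp + length(intersect(in_best, in_ref))
    fn <- fn + length(setdiff(in_ref, in_best))
    fp <- fp + length(setdiff(in_best, in_ref))
  }
  tibble::tibble(tp = tp, fp = fp, fn = fn)
}

#' Precision, recall and F-score from confusion counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN); the F-score is their harmonic
#' mean. Zero-denominator conventions: precision 0 if TP+FP = 0, recall 0 if
#' TP+FN = 0, F 0 if precision + recall = 0.
#'
#' @param counts One-row tibble (or list) with `tp`, `fp`, `fn`.
#' @return One-row tibble with `precision`, `recall`, `fscore`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  fscore <- ifelse(precision + recall > 0,
    2 * precision * recall / (precision + recall), 0
  )
  tibble::tibble(precision = precision, recall = recall, fscore = fscore)
}

#' Evaluate a predicted partition against a reference
#'
#' Convenience wrapper: confusion counts plus metrics in one row.
#'
#' @inheritParams pairwise_confusion
#' @return One-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `fscore`.
#' @export
evaluate_partition <- function(predicted, reference, universe = NULL,
                               unit = c("pair", "gene")) {
  counts <- pairwise_confusion(predicted, reference, universe, unit)
  dplyr::bind_cols(counts, metrics_from_counts(counts))
}

#' Length-binned accuracy
#'
#' Reference genes are sorted by protein length and split into `n_bins`
#' equal-count bins (remainders go to the earliest bins). For each bin,
#' confusion is counted over the gene pairs with at least one member in the
#' bin, so a pair contributes to each member's bin; short genes' missing
#' partners therefore depress the short bin's recall.
#'
#' @param predicted,reference Partition tibbles.
#' @param catalog Sequence catalogue (lengths).
#' @param n_bins Number of equal-count bins (default 4).
#' @return Tibble with one row per bin: `bin`, `n_genes`, `min_length`,
#'   `max_length`, `geomean_length`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `fscore`.
#' @export
length_binned_metrics <- function(predicted, reference, catalog, n_bins = 4) {
  universe <- sort(reference$gene_id[!is.na(reference$orthogroup)])
  n <- length(universe)
  if (n < n_bins) {
    stop(sprintf("fewer reference genes (%d) than bins (%d)", n, n_bins))
  }
  len <- catalog$length_aa[match(universe, catalog$gene_id)]
  if (anyNA(len)) {
    stop("length missing for reference gene(s)")
  }
  ord <- order(len, universe)
  universe <- universe[ord]
  len <- len[ord]
  base <- n %/% n_bins
  extra <- n %% n_bins
  bin_sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin_of <- rep(seq_len(n_bins), bin_sizes)

  pred <- predicted$orthogroup[match(universe, predicted$gene_id)]
  ref <- reference$orthogroup[match(universe, reference$gene_id)]
  ij <- utils::combn(n, 2)
  i <- ij[1, ]
  j <- ij[2, ]
  co_pred <- !is.na(pred[i]) & !is.na(pred[j]) & pred[i] == pred[j]
  co_ref <- !is.na(ref[i]) & !is.na(ref[j]) & ref[i] == ref[j]
  purrr::map_dfr(seq_len(n_bins), function(b) {
    sel <- bin_of[i] == b | bin_of[j] == b
    counts <- tibble::tibble(
      tp = sum(co_pred & co_ref & sel),
      fp = sum(co_pred & !co_ref & sel),
      fn = sum(!co_pred & co_ref & sel)
    )
    in_bin <- bin_of == b
    dplyr::bind_cols(
      tibble::tibble(
        bin = b,
        n_genes = sum(in_bin),
        min_length = min(len[in_bin]),
        max_length = max(len[in_bin]),
        geomean_length = exp(mean(log(len[in_bin])))
      ),
      counts,
      metrics_from_counts(counts)
    )
  })
}

#' Per-reference-orthogroup error report
#'
#' Each reference orthogroup is matched to the predicted group with the
#' largest overlap (ties to the larger predicted group, then the lowest
#' index). Reported per group: genes missing from that predicted group,
#' erroneously included (universe) genes, and fragmentation (reference genes
#' spread over several predicted groups) / fusion (the matched predicted
#' group overlapping several reference groups) flags.
#'
#' @param predicted,reference Partition tibbles.
#' @return Tibble with one row per reference orthogroup: `ref_group`,
#'   `n_ref`, `matched_group`, `n_missing`, `n_erroneous`, `fragmented`,
#'   `fused`, `error_free`. Share of error-free groups via
#'   [orthogroup_error_summary()].
#' @export
per_orthogroup_errors <- function(predicted, reference) {
  universe <- reference$gene_id[!is.na(reference$orthogroup)]
  ref_groups <- partition_groups(reference)$groups
  pred_groups <- partition_groups(predicted)$groups
  pred_sizes <- lengths(pred_groups)
  rows <- purrr::map_dfr(seq_along(ref_groups), function(rk) {
    ref_genes <- ref_groups[[rk]]
    overlaps <- vapply(pred_groups, function(pg) length(intersect(pg, ref_genes)), integer(1))
    if (length(overlaps) == 0 || max(overlaps) == 0) {
      return(tibble::tibble(
        ref_group = rk, n_ref = length(ref_genes), matched_group = NA_integer_,
        n_missing = length(ref_genes), n_erroneous = 0L,
        fragmented = FALSE, fused = FALSE, error_free = FALSE
      ))
    }
    best <- order(-overlaps, -pred_sizes, seq_along(overlaps))[1]
    matched <- pred_groups[[best]]
    missing <- setdiff(ref_genes, matched)
    erroneous <- setdiff(intersect(matched, universe), ref_genes)
    pred_of_ref <- predicted$orthogroup[match(ref_genes, predicted$gene_id)]
    fragmented <- length(unique(pred_of_ref[!is.na(pred_of_ref)])) > 1
    ref_of_matched <- reference$orthogroup[match(matched, reference$gene_id)]
    fused <- length(unique(ref_of_matched[!is.na(ref_of_matched)])) > 1
    tibble::tibble(
      ref_group = rk, n_ref = length(ref_genes), matched_group = best,
      n_missing = length(missing), n_erroneous = length(erroneous),
      fragmented = fragmented, fused = fused,
      error_free = length(missing) == 0 && length(erroneous) == 0
    )
  })
  rows
}

#' Summary of a per-orthogroup error report
#'
#' @param errors Output of [per_orthogroup_errors()].
#' @return One-row tibble: `n_groups`, `pct_error_free`, `total_missing`,
#'   `total_erroneous`, `n_fragmented`, `n_fused`.
#' @export
orthogroup_error_summary <- function(errors) {
  tibble::tibble(
    n_groups = nrow(errors),
    pct_error_free = 100 * mean(errors$error_free),
    total_missing = sum(errors$n_missing),
    total_erroneous = sum(errors$n_erroneous),
    n_fragmented = sum(errors$fragmented),
    n_fused = sum(errors$fused)
  )
}

#' Robustness of inference to random gene deletion
#'
#' Emulates incomplete assemblies: for each deletion fraction, that share of
#' catalogue genes is removed uniformly at random (together with all their
#' hits), the pipeline is rerun on the remainder, and the result is scored
#' against the reference restricted to surviving genes. A single random
#' permutation of the catalogue is drawn and each fraction deletes its prefix,
#' so deleted sets are nested across fractions: every set is still uniform at
#' random, but the curve is not jittered by independent redraws.
#'
#' @param hits Full hit tibble.
#' @param catalog Full sequence catalogue.
#' @param reference Reference partition over the full catalogue.
#' @param fractions Deletion fractions in `[0, 1)` (default 0.05 to 0.60 in
#'   steps of 0.05).
#' @param seed Integer seed for the deletion draws.
#' @param pipeline Function `(hits, catalog) -> partition` (defaults to
#'   [orthogroup_pipeline()] returning its partition).
#' @return Tibble with one row per fraction: `fraction`, `n_genes`, counts
#'   and metrics.
#' @export
deletion_robustness <- function(hits, catalog, reference,
                                fractions = seq(0.05, 0.60, by = 0.05),
                                seed = 1L, pipeline = NULL) {
  if (any(fractions < 0 | fractions >= 1)) {
    stop("deletion fractions must lie in [0, 1)")
  }
  if (is.null(pipeline)) {
    pipeline <- function(h, cat) orthogroup_pipeline(h, cat)$partition
  }
  set.seed(seed)
  perm <- sample(catalog$gene_id)
  purrr::map_dfr(fractions, function(f) {
    n_del <- round(f * nrow(catalog))
    deleted <- perm[seq_len(n_del)]
    cat_f <- catalog[!(catalog$gene_id %in% deleted), ]
    hits_f <- hits[!(hits$query %in% deleted) & !(hits$subject %in% deleted), ]
    pred <- pipeline(hits_f, cat_f)
    ref_f <- reference[reference$gene_id %in% cat_f$gene_id, ]
    dplyr::bind_cols(
      tibble::tibble(fraction = f, n_genes = nrow(cat_f)),
      evaluate_partition(pred, ref_f)
    )
  })
}

#' Plot length-binned accuracy
#'
#' Precision, recall and F-score against the geometric-mean length of each
#' bin, with horizontal bars marking the bin's length range.
#'
#' @param binned Output of [length_binned_metrics()].
#' @return A ggplot object.
#' @export
plot_length_bins <- function(binned) {
  long <- tidyr::pivot_longer(
    binned, c("precision", "recall", "fscore"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$geomean_length, y = .data$value, colour = .data$metric
  )) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$min_length, xmax = .data$max_length),
      height = 0.01, alpha = 0.4
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "geometric mean protein length (aa)", y = "score",
      title = "Accuracy by protein length bin"
    )
}
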