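#' Run the in-memory orthogroup inference pipeline
#'
#' Executes the core method on a hit table: per-species-pair length/distance
#' normalisation of bit scores, reciprocal best normalised hit (RBNH)
#' identification, per-gene inclusion thresholds, weighted gene graph
#' assembly, and Markov clustering into orthogroups.
#'
#' @param hits Hit tibble (deduplicated internally).
#' @param catalog Sequence catalogue.
#' @param top_fraction Fraction of hits per length bin used for fitting
#'   (default 0.05).
#' @param min_fit_points Minimum fit points before single-bin fallback.
#' @param inflation MCL inflation parameter (default 1.5).
#' @param include_within_species Whether same-species hits may satisfy the
#'   threshold clause (default TRUE).
#' @param self_loop,prune_threshold,max_iter MCL engine settings.
#' @param fits Optional cached per-pair fit coefficients (skips fitting).
#' @return Object of class `orthokit_result`: list with `partition`, `graph`,
#'   `fits`, `rbnhs`, `thresholds` and a one-row `stats` tibble.
#' @export
orthogroup_pipeline <- function(hits, catalog, top_fraction = 0.05,
                                min_fit_points = 10, inflation = 1.5,
                                include_within_species = TRUE,
                                self_loop = 1, prune_threshold = 1e-5,
                                max_iter = 100, fits = NULL) {
  hits <- dedupe_hits(hits)
  norm <- normalize_all_pairs(hits, catalog,
    top_fraction = top_fraction,
    min_fit_points = min_fit_points, fits = fits
  )
  rbnhs <- find_rbnhs(norm$hits)
  thresholds <- compute_thresholds(rbnhs)
  graph <- build_graph(norm$hits, thresholds, rbnhs,
    include_within_species = include_within_species
  )
  partition <- mcl_cluster(graph, catalog,
    inflation = inflation, self_loop = self_loop,
    prune_threshold = prune_threshold, max_iter = max_iter
  )
  pg <- partition_groups(partition)
  structure(
    list(
      partition = partition, graph = graph, fits = norm$fits,
      rbnhs = rbnhs, thresholds = thresholds,
      stats = tibble::tibble(
        n_genes = nrow(catalog), n_hits = nrow(hits),
        n_rbnh_pairs = nrow(rbnhs) / 2, n_edges = nrow(graph),
        n_orthogroups = length(pg$groups), n_unassigned = length(pg$unassigned)
      )
    ),
    class = "orthokit_result"
  )
}

#' @export
print.orthokit_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "orthogroup inference result: %d genes -> %d orthogroups (+%d unassigned), %d edges\n",
    s$n_genes, s$n_orthogroups, s$n_unassigned, s$n_edges
  ))
  invisible(x)
}

#' @method tidy orthokit_result
#' @export
tidy.orthokit_result <- function(x, ...) x$partition

#' @method glance orthokit_result
#' @export
glance.orthokit_result <- function(x, ...) x$stats

#' Orthogroup size distribution plot
#'
#' @param object An `orthokit_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot orthokit_result
#' @export
autoplot.orthokit_result <- function(object, ...) {
  pg <- partition_groups(object$partition)
  sizes <- tibble::tibble(size = c(lengths(pg$groups), rep(1L, length(pg$unassigned))))
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = "orthogroup size (genes)", y = "count",
      title = "Orthogroup size distribution (size 1 = unassigned)"
    )
}

#' Run the full pipeline on an input directory
#'
#' The directory must contain one protein FASTA file per species (`.fa`,
#' `.faa` or `.fasta`; species ids follow the sorted file names) and one
#' pre-computed BLAST tabular file `Blast<i>_<j>.txt` per ordered species
#' pair. Writes the id maps, per-pair fit coefficients, the graph in MCL abc
#' format, orthogroups as plain text and OrthoXML, the unassigned-gene list,
#' and a log of parameters and per-stage counts.
#'
#' Rerunning into the same output directory reuses the cached fit
#' coefficients (`fit_models.tsv`) when present, so deleting only the
#' clustering outputs and rerunning reproduces identical final files without
#' refitting.
#'
#' @param input_dir Input directory.
#' @param output_dir Output directory (created; default
#'   `file.path(input_dir, "orthokit_results")`).
#' @param evalue_max E-value cutoff applied when reading BLAST results
#'   (default 1e-3).
#' @param mcl_engine `"builtin"` or `"external"` (requires an `mcl`
#'   executable on the PATH).
#' @param ... Passed to [orthogroup_pipeline()].
#' @return The `orthokit_result`, invisibly.
#' @export
run_pipeline <- function(input_dir, output_dir = file.path(input_dir, "orthokit_results"),
                         evalue_max = 1e-3, mcl_engine = c("builtin", "external"),
                         ...) {
  mcl_engine <- match.arg(mcl_engine)
  fasta_paths <- sort(list.files(input_dir, "\\.(fa|faa|fasta)$", full.names = TRUE))
  if (length(fasta_paths) < 2) {
    stop(sprintf("input directory must contain at least 2 FASTA files, found %d", length(fasta_paths)))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- read_fasta_lengths(fasta_paths)
  write_id_maps(catalog, output_dir)
  hits <- read_blast_dir(input_dir, catalog, evalue_max = evalue_max)

  fits_path <- file.path(output_dir, "fit_models.tsv")
  cached_fits <- NULL
  if (file.exists(fits_path)) {
    cached_fits <- utils::read.delim(fits_path)
  }
  result <- orthogroup_pipeline(hits, catalog, fits = cached_fits, ...)

  if (mcl_engine == "external") {
    abc_path <- file.path(output_dir, "graph.abc")
    write_graph(result$graph, abc_path)
    result$partition <- run_external_mcl(abc_path, catalog)
  }

  utils::write.table(result$fits, fits_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_graph(result$graph, file.path(output_dir, "graph.abc"))
  write_plain_text(result$partition, catalog,
    file.path(output_dir, "orthogroups.txt"),
    unassigned_path = file.path(output_dir, "unassigned.txt")
  )
  write_orthoxml(result$partition, catalog, file.path(output_dir, "orthogroups.orthoxml"))

  opts <- list(...)
  s <- result$stats
  log_lines <- c(
    sprintf("orthokit %s", as.character(utils::packageVersion("orthokit"))),
    sprintf("input_dir: %s", input_dir),
    sprintf("evalue_max: %g", evalue_max),
    sprintf("mcl_engine: %s", mcl_engine),
    sprintf(
      "inflation: %g", if (!is.null(opts$inflation)) opts$inflation else 1.5
    ),
    sprintf(
      "top_fraction: %g", if (!is.null(opts$top_fraction)) opts$top_fraction else 0.05
    ),
    "bin_size rule: 1000 (or 200 when a pair has < 5000 hits)",
    sprintf("fits_cached: %s", !is.null(cached_fits)),
    "per-pair fit coefficients:",
    sprintf(
      "  %d vs %d: a = %.6f, b = %.6f (n = %d)",
      result$fits$qspecies, result$fits$sspecies,
      result$fits$a, result$fits$b, result$fits$n_hits_fit
    ),
    sprintf("genes: %d", s$n_genes),
    sprintf("hits after filtering/dedup: %d", s$n_hits),
    sprintf("RBNH pairs: %d", s$n_rbnh_pairs),
    sprintf("graph edges: %d", s$n_edges),
    sprintf("orthogroups: %d (+%d unassigned)", s$n_orthogroups, s$n_unassigned)
  )
  writeLines(log_lines, file.path(output_dir, "log.txt"))
  invisible(result)
}

#' Evaluate a predicted orthogroup file against a reference file
#'
#' Reads both files through [read_partition()], checks the gene universes
#' overlap, and reports global metrics, length-binned metrics, and the
#' per-orthogroup error table; optionally written as TSVs plus a summary.
#'
#' @param predicted_path,reference_path Plain-text orthogroup files.
#' @param catalog Sequence catalogue.
#' @param out_dir Optional directory for TSV reports.
#' @param n_bins Bins for the length-stratified report (default 4).
#' @return List with `global`, `by_length_bin`, `per_orthogroup`, `summary`.
#' @export
run_evaluation <- function(predicted_path, reference_path, catalog,
                           out_dir = NULL, n_bins = 4) {
  predicted <- read_partition(predicted_path, catalog)
  reference <- read_partition(reference_path, catalog)
  pred_genes <- predicted$gene_id[!is.na(predicted$orthogroup)]
  ref_genes <- reference$gene_id[!is.na(reference$orthogroup)]
  if (length(intersect(pred_genes, ref_genes)) == 0) {
    stop("predicted and reference orthogroups cover disjoint gene sets")
  }
  global <- evaluate_partition(predicted, reference)
  binned <- length_binned_metrics(predicted, reference, catalog, n_bins = n_bins)
  per_og <- per_orthogroup_errors(predicted, reference)
  summary <- orthogroup_error_summary(per_og)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(global, file.path(out_dir, "metrics_global.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(binned, file.path(out_dir, "metrics_by_length_bin.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(per_og, file.path(out_dir, "per_orthogroup_errors.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    writeLines(
      c(
        sprintf(
          "precision %.4f  recall %.4f  F-score %.4f",
          global$precision, global$recall, global$fscore
        ),
        sprintf(
          "%d reference orthogroups, %.1f%% error-free, %d missing genes, %d erroneous genes",
          summary$n_groups, summary$pct_error_free,
          summary$total_missing, summary$total_erroneous
        )
      ),
      file.path(out_dir, "summary.txt")
    )
  }
  list(
    global = global, by_length_bin = binned,
    per_orthogroup = per_og, summary = summary
  )
}

#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL
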