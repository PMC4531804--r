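#' Identify reciprocal best normalised hits (RBNHs)
#'
#' For each gene and each *other* species, the gene's best hit(s) by
#' normalised score are found; a pair (q, h) is an RBNH when each gene is
#' among the other's best hits in the reciprocal direction. Exact ties at the
#' maximum all count as best, so a gene can have several RBNHs in one
#' species. Reciprocal best is a between-species concept: same-species hits
#' never form RBNHs.
#'
#' @param normalized Normalised hit tibble (needs `query`, `subject`,
#'   `qspecies`, `sspecies`, `norm_score`), e.g. `normalize_all_pairs()$hits`.
#' @return Tibble of RBNH pairs with both directions present: columns
#'   `query`, `subject`, `qspecies`, `sspecies`, `norm_score` (the score in
#'   the query -> subject direction).
#' @export
find_rbnhs <- function(normalized) {
  between <- dplyr::filter(normalized, .data$qspecies != .data$sspecies)
  if (nrow(between) == 0) {
    return(between[, c("query", "subject", "qspecies", "sspecies", "norm_score")])
  }
  best <- between |>
    dplyr::group_by(.data$query, .data$sspecies) |>
    dplyr::filter(.data$norm_score == max(.data$norm_score)) |>
    dplyr::ungroup() |>
    dplyr::select("query", "subject", "qspecies", "sspecies", "norm_score")
  reciprocal <- dplyr::semi_join(
    best,
    dplyr::select(best, rq = "subject", rs = "query"),
    by = c(query = "rq", subject = "rs")
  )
  dplyr::arrange(reciprocal, .data$query, .data$subject)
}

#' Per-gene inclusion thresholds from RBNH scores
#'
#' A gene's inclusion threshold is the normalised score of its lowest-scoring
#' RBNH, irrespective of species. Genes with no RBNH get no threshold (they
#' can still enter the graph through other genes' thresholds).
#'
#' @param rbnhs RBNH tibble from [find_rbnhs()].
#' @return Tibble with columns `gene_id`, `threshold`.
#' @export
compute_thresholds <- function(rbnhs) {
  if (nrow(rbnhs) == 0) {
    return(tibble::tibble(gene_id = integer(), threshold = numeric()))
  }
  rbnhs |>
    dplyr::group_by(gene_id = .data$query) |>
    dplyr::summarise(threshold = min(.data$norm_score), .groups = "drop")
}

#' Build the weighted orthogroup graph
#'
#' Two genes are connected when their pair is an RBNH, or either directed hit
#' scores at or above the other end's inclusion threshold: edge (q, h) exists
#' iff (q, h) is an RBNH, or \eqn{B'_{qh} \ge threshold(q)}, or
#' \eqn{B'_{hq} \ge threshold(h)}. Same-species hits participate via the
#' threshold clauses (controlled by `include_within_species`). The edge
#' weight is the larger of the two directional normalised scores.
#'
#' @param normalized Normalised hit tibble.
#' @param thresholds Threshold tibble from [compute_thresholds()].
#' @param rbnhs RBNH tibble from [find_rbnhs()].
#' @param include_within_species Whether same-species hits may satisfy the
#'   threshold clause (default TRUE).
#' @param rbnh_only If TRUE, keep only RBNH edges (plain reciprocal-best
#'   graph; used to demonstrate what the threshold clause adds).
#' @return Edge tibble with columns `gene1 < gene2` and `weight`, sorted by
#'   (`gene1`, `gene2`).
#' @export
build_graph <- function(normalized, thresholds, rbnhs,
                        include_within_species = TRUE, rbnh_only = FALSE) {
  hits <- normalized
  thr <- thresholds$threshold[match(hits$query, thresholds$gene_id)]
  pass <- !is.na(thr) & hits$norm_score >= thr
  if (!include_within_species) {
    pass <- pass & (hits$qspecies != hits$sspecies)
  }
  is_rbnh <- paste(hits$query, hits$subject) %in% paste(rbnhs$query, rbnhs$subject)
  keep <- if (rbnh_only) is_rbnh else (pass | is_rbnh)
  edges <- tibble::tibble(
    gene1 = pmin(hits$query, hits$subject),
    gene2 = pmax(hits$query, hits$subject),
    weight = hits$norm_score,
    keep = keep
  ) |>
    dplyr::group_by(.data$gene1, .data$gene2) |>
    dplyr::summarise(
      weight = max(.data$weight),
      keep = any(.data$keep),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$keep, .data$gene1 != .data$gene2) |>
    dplyr::select("gene1", "gene2", "weight") |>
    dplyr::arrange(.data$gene1, .data$gene2)
  edges
}

#' Write the orthogroup graph in MCL label ("abc") format
#'
#' One `gene1<TAB>gene2<TAB>weight` line per edge, deterministically sorted
#' by (gene1, gene2); weights printed with 6 significant digits. A companion
#' label index file mapping gene ids to external names can be written with
#' [write_id_maps()].
#'
#' @param graph Edge tibble from [build_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  graph <- dplyr::arrange(graph, .data$gene1, .data$gene2)
  lines <- sprintf("%d\t%d\t%.6g", graph$gene1, graph$gene2, graph$weight)
  writeLines(lines, path)
  invisible(path)
}

#' Read a graph written by [write_graph()]
#'
#' @param path Path to an abc-format edge list.
#' @return Edge tibble with columns `gene1`, `gene2`, `weight`.
#' @export
read_graph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(gene1 = integer(), gene2 = integer(), weight = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    gene1 = as.integer(vapply(fields, `[[`, character(1), 1L)),
    gene2 = as.integer(vapply(fields, `[[`, character(1), 2L)),
    weight = as.numeric(vapply(fields, `[[`, character(1), 3L))
  ) |>
    dplyr::arrange(.data$gene1, .data$gene2)
}
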