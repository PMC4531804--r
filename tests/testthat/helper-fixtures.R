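# Fixture builders and brute-force oracles shared across the suite.

make_catalog <- function(lengths_by_species) {
  rows <- list()
  gid <- 0L
  for (sp in seq_along(lengths_by_species)) {
    lens <- lengths_by_species[[sp]]
    for (l in lens) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_id = gid, species_id = sp - 1L,
        external_name = sprintf("sp%d_g%d", sp - 1L, gid),
        full_header = sprintf("sp%d_g%d", sp - 1L, gid),
        length_aa = as.integer(l),
        species_name = paste0("sp", sp - 1L)
      )
      gid <- gid + 1L
    }
  }
  dplyr::bind_rows(rows)
}

# Normalised hit table with random scores over a random subset of directed
# gene pairs; used to exercise the RBNH / threshold / graph logic directly.
random_norm_instance <- function(seed, n_species = NULL, genes_per_species = NULL,
                                 hit_prob = 0.3) {
  set.seed(seed)
  if (is.null(n_species)) n_species <- sample(3:5, 1)
  if (is.null(genes_per_species)) genes_per_species <- sample(4:12, n_species, replace = TRUE)
  catalog <- make_catalog(lapply(genes_per_species, function(k) sample(50:900, k, replace = TRUE)))
  g <- catalog$gene_id
  pairs <- expand.grid(query = g, subject = g)
  pairs <- pairs[pairs$query != pairs$subject, ]
  keep <- runif(nrow(pairs)) < hit_prob
  hits <- tibble::tibble(
    query = as.integer(pairs$query[keep]),
    subject = as.integer(pairs$subject[keep]),
    qspecies = catalog$species_id[match(pairs$query[keep], catalog$gene_id)],
    sspecies = catalog$species_id[match(pairs$subject[keep], catalog$gene_id)],
    norm_score = round(runif(sum(keep), 0.01, 2), 3)
  )
  list(catalog = catalog, hits = hits)
}

# Brute-force RBNH scan: double maximum over every gene x other-species.
brute_rbnhs <- function(hits) {
  best <- list()
  key <- function(q, s) paste(q, s)
  between <- hits[hits$qspecies != hits$sspecies, ]
  for (r in seq_len(nrow(between))) {
    k <- key(between$query[r], between$sspecies[r])
    cur <- best[[k]]
    if (is.null(cur) || between$norm_score[r] > cur$score) {
      best[[k]] <- list(score = between$norm_score[r], subjects = between$subject[r])
    } else if (between$norm_score[r] == cur$score) {
      best[[k]]$subjects <- c(cur$subjects, between$subject[r])
    }
  }
  out <- between[0, c("query", "subject", "qspecies", "sspecies", "norm_score")]
  for (r in seq_len(nrow(between))) {
    q <- between$query[r]
    h <- between$subject[r]
    bq <- best[[key(q, between$sspecies[r])]]
    bh <- best[[key(h, between$qspecies[r])]]
    if (!is.null(bq) && !is.null(bh) && h %in% bq$subjects && q %in% bh$subjects) {
      out <- rbind(out, between[r, c("query", "subject", "qspecies", "sspecies", "norm_score")])
    }
  }
  dplyr::arrange(tibble::as_tibble(out), query, subject)
}

brute_thresholds <- function(rbnhs) {
  qs <- sort(unique(rbnhs$query))
  tibble::tibble(
    gene_id = qs,
    threshold = vapply(qs, function(q) min(rbnhs$norm_score[rbnhs$query == q]), numeric(1))
  )
}

# Brute-force three-clause edge rule: RBNH, or B'_qh >= thr(q), or
# B'_hq >= thr(h); weight = max over the available directions.
brute_edges <- function(hits, thresholds, rbnhs, include_within_species = TRUE) {
  thr <- function(g) {
    v <- thresholds$threshold[thresholds$gene_id == g]
    if (length(v)) v else Inf
  }
  score <- function(q, h) {
    v <- hits$norm_score[hits$query == q & hits$subject == h]
    if (length(v)) max(v) else NA_real_
  }
  is_rbnh <- function(q, h) any(rbnhs$query == q & rbnhs$subject == h)
  cand <- unique(tibble::tibble(
    gene1 = pmin(hits$query, hits$subject),
    gene2 = pmax(hits$query, hits$subject)
  ))
  keep <- logical(nrow(cand))
  weight <- numeric(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    a <- cand$gene1[r]
    b <- cand$gene2[r]
    s_ab <- score(a, b)
    s_ba <- score(b, a)
    sp_a <- c(hits$qspecies[hits$query == a], hits$sspecies[hits$subject == a])[1]
    sp_b <- c(hits$qspecies[hits$query == b], hits$sspecies[hits$subject == b])[1]
    within <- identical(sp_a, sp_b)
    clause_thr_a <- !is.na(s_ab) && s_ab >= thr(a) && (include_within_species || !within)
    clause_thr_b <- !is.na(s_ba) && s_ba >= thr(b) && (include_within_species || !within)
    keep[r] <- is_rbnh(a, b) || clause_thr_a || clause_thr_b
    weight[r] <- max(s_ab, s_ba, na.rm = TRUE)
  }
  out <- tibble::tibble(gene1 = cand$gene1[keep], gene2 = cand$gene2[keep], weight = weight[keep])
  dplyr::arrange(out, gene1, gene2)
}

# Random partition over a catalogue: k groups of size >= 2 plus leftovers.
random_partition <- function(catalog, seed) {
  set.seed(seed)
  ids <- sample(catalog$gene_id)
  clusters <- list(ids[1:2])
  ids <- ids[-(1:2)]
  while (length(ids) >= 2 && runif(1) < 0.9) {
    k <- min(length(ids), sample(2:6, 1))
    clusters[[length(clusters) + 1L]] <- ids[seq_len(k)]
    ids <- ids[-seq_len(k)]
  }
  new_partition(clusters, catalog)
}

# Random weighted graph over n nodes (gene ids 0..n-1).
random_graph <- function(seed, n = 30, edge_prob = 0.12) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < edge_prob
  tibble::tibble(
    gene1 = as.integer(pairs[keep, 1] - 1L),
    gene2 = as.integer(pairs[keep, 2] - 1L),
    weight = round(runif(sum(keep), 0.1, 5), 3)
  )
}

write_temp_fasta <- function(records, dir, file) {
  lines <- unlist(purrr::imap(records, function(seq, name) c(paste0(">", name), seq)))
  path <- file.path(dir, file)
  writeLines(lines, path)
  path
}
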