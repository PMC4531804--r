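#' Configuration for the synthetic orthology benchmark generator
#'
#' Bundles all parameters of the generative model: gene families arise from a
#' single ancestral gene per family and evolve along an ultrametric species
#' tree under a Poisson duplication/loss process; bit scores for within-family
#' gene pairs follow a multiplicative model of a length power law, exponential
#' decay with gene-tree distance, and log-normal noise; a small fraction of
#' random between-family pairs receive suppressed background scores.
#'
#' @param n_species Number of species (>= 2; default 5).
#' @param n_families Number of ancestral gene families (default 200).
#' @param duplication_rate,loss_rate Events per unit branch length (defaults
#'   0.2 and 0.1).
#' @param decay Score multiplier per unit gene-tree distance, in (0, 1]
#'   (default 0.7).
#' @param noise_sigma SD of the log10 score noise (default 0.1).
#' @param background_fraction Fraction of ordered between-family gene pairs
#'   receiving a background hit (default 0.001).
#' @param background_scale Extra suppression of background scores below the
#'   maximum-distance within-family level (default 0.5).
#' @param min_bitscore Hits below this raw score are dropped, emulating the
#'   weak hits lost to the similarity-search e-value cutoff (default 50).
#' @param length_meanlog,length_sdlog Log-normal parameters of the family
#'   base protein length in amino acids (defaults log(350) and 0.5).
#' @param a_true,b_true True slope and intercept of the log-log score/length
#'   model (defaults 0.38 and 1.2).
#' @param decay_jitter SD of a per-species-pair log-normal jitter on the decay
#'   constant, emulating pair-specific score behaviour (default 0 = off).
#' @param species_tree Optional `ape::phylo` ultrametric tree; generated from
#'   the seed (coalescent, scaled to depth 1) when NULL.
#' @param seed Integer seed; all generation is reproducible from the config.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_species = 5, n_families = 200,
                              duplication_rate = 0.2, loss_rate = 0.1,
                              decay = 0.7, noise_sigma = 0.1,
                              background_fraction = 0.001,
                              background_scale = 0.5, min_bitscore = 50,
                              length_meanlog = log(350), length_sdlog = 0.5,
                              a_true = 0.38, b_true = 1.2,
                              decay_jitter = 0, species_tree = NULL,
                              seed = 1L) {
  stopifnot(
    n_species >= 2, n_families >= 1,
    duplication_rate >= 0, loss_rate >= 0,
    decay > 0, decay <= 1, noise_sigma >= 0,
    background_fraction >= 0, background_fraction < 1
  )
  structure(
    list(
      n_species = as.integer(n_species), n_families = as.integer(n_families),
      duplication_rate = duplication_rate, loss_rate = loss_rate,
      decay = decay, noise_sigma = noise_sigma,
      background_fraction = background_fraction,
      background_scale = background_scale, min_bitscore = min_bitscore,
      length_meanlog = length_meanlog, length_sdlog = length_sdlog,
      a_true = a_true, b_true = b_true, decay_jitter = decay_jitter,
      species_tree = species_tree, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

default_species_tree <- function(n_species) {
  tree <- ape::rcoal(n_species, tip.label = paste0("sp", seq_len(n_species) - 1L))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Simulate gene families by duplication and loss along a species tree
#'
#' Each family starts as one gene at the species-tree root. Along every
#' branch, each gene lineage experiences duplication and loss events as a
#' Poisson process; at speciation nodes every surviving lineage is inherited
#' by both descendant branches. Surviving leaf lineages become the genes of
#' the corresponding species; each family's surviving genes form one true
#' orthogroup. Protein lengths are log-normal per family with a +/-10% member
#' jitter, so length is family-correlated as in real orthogroups.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_truth`: `catalog` (sequence catalogue
#'   with an extra `family` column), `partition` (true orthogroups),
#'   `distances` (within-family gene-tree distances, one row per unordered
#'   pair), `species_tree`, and `config`.
#' @export
simulate_families <- function(config) {
  set.seed(config$seed)
  tree <- config$species_tree
  if (is.null(tree)) {
    tree <- default_species_tree(config$n_species)
  }
  n_sp <- length(tree$tip.label)
  root <- n_sp + 1L
  children_of <- function(node) which(tree$edge[, 1] == node)

  dup <- config$duplication_rate
  loss <- config$loss_rate
  total_rate <- dup + loss

  # Simulate the fate of one gene lineage entering the branch that ends at
  # `node`, with `t_remaining` branch length left, at time `depth` from the
  # family root. Returns NULL (extinct) or list(species, depth, pairs) where
  # pairs is a data frame of local leaf index pairs and gene-tree distances.
  sim_from <- function(node, t_remaining, depth) {
    wait <- if (total_rate > 0) stats::rexp(1, total_rate) else Inf
    if (wait < t_remaining) {
      at <- depth + wait
      if (stats::runif(1) < dup / total_rate) {
        kids <- list(
          sim_from(node, t_remaining - wait, at),
          sim_from(node, t_remaining - wait, at)
        )
        return(combine_subtrees(kids, at))
      }
      return(NULL)
    }
    at <- depth + t_remaining
    if (node <= n_sp) {
      return(list(
        species = node - 1L, depth = at,
        pairs = data.frame(i = integer(), j = integer(), d = numeric())
      ))
    }
    kid_edges <- children_of(node)
    kids <- lapply(kid_edges, function(e) {
      sim_from(tree$edge[e, 2], tree$edge.length[e], at)
    })
    combine_subtrees(kids, at)
  }

  families <- vector("list", config$n_families)
  for (f in seq_len(config$n_families)) {
    kid_edges <- children_of(root)
    kids <- lapply(kid_edges, function(e) {
      sim_from(tree$edge[e, 2], tree$edge.length[e], 0)
    })
    families[[f]] <- combine_subtrees(kids, 0)
  }
  alive <- !vapply(families, is.null, logical(1))
  if (!any(alive)) {
    stop("all gene families went extinct; lower loss_rate")
  }

  gene_rows <- purrr::map_dfr(which(alive), function(f) {
    fam <- families[[f]]
    tibble::tibble(
      family = f, local_id = seq_along(fam$species),
      species_id = fam$species
    )
  })
  gene_rows <- dplyr::arrange(gene_rows, .data$species_id, .data$family, .data$local_id)
  gene_rows$gene_id <- seq_len(nrow(gene_rows)) - 1L

  base_len <- stats::rlnorm(config$n_families, config$length_meanlog, config$length_sdlog)
  jitter <- stats::runif(nrow(gene_rows), 0.9, 1.1)
  gene_rows$length_aa <- pmax(1L, as.integer(round(base_len[gene_rows$family] * jitter)))

  catalog <- tibble::tibble(
    gene_id = gene_rows$gene_id,
    species_id = gene_rows$species_id,
    external_name = sprintf("sp%d_g%06d", gene_rows$species_id, gene_rows$gene_id),
    full_header = sprintf(
      "sp%d_g%06d family=%d", gene_rows$species_id, gene_rows$gene_id, gene_rows$family
    ),
    length_aa = gene_rows$length_aa,
    species_name = paste0("sp", gene_rows$species_id),
    family = gene_rows$family
  ) |>
    dplyr::arrange(.data$gene_id)

  id_lookup <- gene_rows |>
    dplyr::select("family", "local_id", "gene_id")
  distances <- purrr::map_dfr(which(alive), function(f) {
    p <- families[[f]]$pairs
    if (nrow(p) == 0) {
      return(tibble::tibble(gene1 = integer(), gene2 = integer(), distance = numeric()))
    }
    lk <- id_lookup[id_lookup$family == f, ]
    g_i <- lk$gene_id[match(p$i, lk$local_id)]
    g_j <- lk$gene_id[match(p$j, lk$local_id)]
    tibble::tibble(
      gene1 = pmin(g_i, g_j), gene2 = pmax(g_i, g_j), distance = p$d
    )
  })

  clusters <- split(catalog$gene_id, catalog$family)
  partition <- new_partition(unname(clusters), catalog)

  structure(
    list(
      catalog = catalog, partition = partition, distances = distances,
      species_tree = tree, config = config
    ),
    class = "synthetic_truth"
  )
}

# Merge child subtrees at an internal node at time D from the family root:
# concatenates leaves (re-indexing child-local leaf ids) and adds cross-child
# leaf pair distances depth_i + depth_j - 2D.
combine_subtrees <- function(kids, D) {
  kids <- kids[!vapply(kids, is.null, logical(1))]
  if (length(kids) == 0) {
    return(NULL)
  }
  if (length(kids) == 1) {
    return(kids[[1]])
  }
  species <- integer(0)
  depth <- numeric(0)
  pairs <- list()
  offset <- 0L
  for (k in kids) {
    nk <- length(k$species)
    if (nrow(k$pairs) > 0) {
      p <- k$pairs
      p$i <- p$i + offset
      p$j <- p$j + offset
      pairs[[length(pairs) + 1L]] <- p
    }
    # cross pairs with everything accumulated so far
    if (offset > 0 && nk > 0) {
      cross <- expand.grid(i = seq_len(offset), j = offset + seq_len(nk))
      cross$d <- depth[cross$i] + k$depth[cross$j - offset] - 2 * D
      pairs[[length(pairs) + 1L]] <- cross
    }
    species <- c(species, k$species)
    depth <- c(depth, k$depth)
    offset <- offset + nk
  }
  list(
    species = species, depth = depth,
    pairs = if (length(pairs)) do.call(rbind, pairs) else data.frame(i = integer(), j = integer(), d = numeric())
  )
}

#' Simulate all-vs-all similarity hits for a synthetic truth
#'
#' Within-family ordered gene pairs (q, h) receive
#' \eqn{B = 10^{b} L_{qh}^{a} \cdot decay^{d(q,h)} \cdot 10^{\epsilon}} with
#' \eqn{\epsilon \sim N(0, \sigma)} and d the gene-tree distance. A
#' `background_fraction` of random between-family ordered pairs receive hits
#' suppressed below the maximum-distance within-family level. Hits with raw
#' score below `min_bitscore` are dropped.
#'
#' @param truth A `synthetic_truth` from [simulate_families()].
#' @param config Configuration; defaults to the truth's own config.
#' @return A hit tibble (query, subject, bitscore, evalue, qspecies,
#'   sspecies) covering all ordered species pairs with surviving hits.
#' @export
simulate_hits <- function(truth, config = truth$config) {
  set.seed(config$seed + 1L)
  catalog <- truth$catalog
  d <- truth$distances
  directed <- tibble::tibble(
    query = c(d$gene1, d$gene2),
    subject = c(d$gene2, d$gene1),
    distance = c(d$distance, d$distance)
  )
  directed <- add_length_product(directed, catalog)
  qsp <- catalog$species_id[match(directed$query, catalog$gene_id)]
  ssp <- catalog$species_id[match(directed$subject, catalog$gene_id)]

  log10_decay <- log10(config$decay)
  if (config$decay_jitter > 0) {
    n_sp <- length(unique(catalog$species_id))
    jit <- matrix(
      exp(stats::rnorm(n_sp^2, 0, config$decay_jitter)),
      n_sp, n_sp
    )
    pair_log_decay <- log10_decay * jit[cbind(qsp + 1L, ssp + 1L)]
  } else {
    pair_log_decay <- rep(log10_decay, nrow(directed))
  }
  eps <- stats::rnorm(nrow(directed), 0, config$noise_sigma)
  log10_b <- config$b_true + config$a_true * log10(directed$l_qh) +
    pair_log_decay * directed$distance + eps
  within <- tibble::tibble(
    query = directed$query, subject = directed$subject,
    bitscore = 10^log10_b, qspecies = qsp, sspecies = ssp
  )

  max_d <- if (nrow(d) > 0) max(d$distance) else 2
  n_genes <- nrow(catalog)
  n_bg <- round(config$background_fraction * n_genes * (n_genes - 1))
  bg <- NULL
  if (n_bg > 0) {
    q <- sample(catalog$gene_id, n_bg, replace = TRUE)
    h <- sample(catalog$gene_id, n_bg, replace = TRUE)
    keep <- q != h &
      catalog$family[match(q, catalog$gene_id)] != catalog$family[match(h, catalog$gene_id)]
    q <- q[keep]
    h <- h[keep]
    if (length(q) > 0) {
      bg <- tibble::tibble(query = q, subject = h)
      bg <- dplyr::distinct(bg, .data$query, .data$subject)
      bg <- add_length_product(bg, catalog)
      eps_b <- stats::rnorm(nrow(bg), 0, config$noise_sigma)
      log10_bg <- config$b_true + config$a_true * log10(bg$l_qh) +
        log10_decay * max_d + log10(config$background_scale) + eps_b
      bg <- tibble::tibble(
        query = bg$query, subject = bg$subject, bitscore = 10^log10_bg,
        qspecies = catalog$species_id[match(bg$query, catalog$gene_id)],
        sspecies = catalog$species_id[match(bg$subject, catalog$gene_id)]
      )
    }
  }
  hits <- dplyr::bind_rows(within, bg)
  hits <- hits[hits$bitscore >= config$min_bitscore, ]
  hits$evalue <- pmax(10^(-hits$bitscore / 10), 1e-180)
  hits <- dplyr::select(
    hits, "query", "subject", "bitscore", "evalue", "qspecies", "sspecies"
  )
  dplyr::arrange(hits, .data$query, .data$subject)
}

#' Write a complete fake input directory for the pipeline
#'
#' Emits one FASTA file per species ('X'-padded dummy sequences of the
#' correct lengths, labelled synthetic), one `Blast<i>_<j>.txt` tabular file
#' per ordered species pair (empty when the pair has no hits), and the true
#' orthogroups in the plain-text dialect (`truth_orthogroups.txt`).
#'
#' @param truth A `synthetic_truth`.
#' @param hits Hit tibble from [simulate_hits()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(truth, hits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- truth$catalog
  species <- sort(unique(catalog$species_id))
  for (sp in species) {
    sub <- catalog[catalog$species_id == sp, ]
    lines <- character(0)
    for (r in seq_len(nrow(sub))) {
      lines <- c(
        lines,
        paste0(">", sub$external_name[r], " synthetic"),
        strrep("X", sub$length_aa[r])
      )
    }
    writeLines(lines, file.path(dir, sprintf("sp%d.fa", sp)))
  }
  for (qs in species) {
    for (ss in species) {
      sub <- hits[hits$qspecies == qs & hits$sspecies == ss, ]
      write_hit_table(sub, catalog, file.path(dir, sprintf("Blast%d_%d.txt", qs, ss)))
    }
  }
  write_plain_text(truth$partition, catalog, file.path(dir, "truth_orthogroups.txt"))
  invisible(dir)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  pg <- partition_groups(x$partition)
  cat(sprintf(
    "synthetic truth: %d genes, %d species, %d orthogroups (+%d singletons)\n",
    nrow(x$catalog), length(unique(x$catalog$species_id)),
    length(pg$groups), length(pg$unassigned)
  ))
  invisible(x)
}
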