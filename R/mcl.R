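#' Build the column-stochastic flow matrix of a graph
#'
#' Symmetric adjacency from the edge list, plus `self_loop` times the
#' identity, column-normalised. Node order is sorted gene id; dimnames carry
#' the gene ids.
#'
#' @param graph Edge tibble (`gene1`, `gene2`, `weight`).
#' @param self_loop Self-loop weight added before normalisation (default 1).
#' @param nodes Optional integer vector of node gene ids; defaults to the
#'   genes present in the graph. Isolated nodes get a pure self-loop column.
#' @return A sparse `dgCMatrix`, every column summing to 1.
#' @export
build_flow_matrix <- function(graph, self_loop = 1, nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- sort(unique(c(graph$gene1, graph$gene2)))
  } else {
    nodes <- sort(unique(as.integer(nodes)))
  }
  n <- length(nodes)
  if (n == 0) {
    stop("graph has no nodes")
  }
  i <- match(graph$gene1, nodes)
  j <- match(graph$gene2, nodes)
  m <- Matrix::sparseMatrix(
    i = c(i, j, seq_len(n)),
    j = c(j, i, seq_len(n)),
    x = c(graph$weight, graph$weight, rep(self_loop, n)),
    dims = c(n, n),
    dimnames = list(as.character(nodes), as.character(nodes))
  )
  normalize_columns(m)
}

normalize_columns <- function(m) {
  dn <- dimnames(m)
  sums <- Matrix::colSums(m)
  sums[sums == 0] <- 1
  out <- m %*% Matrix::Diagonal(x = 1 / sums)
  dimnames(out) <- dn
  out
}

#' Markov clustering iteration (expand / inflate / prune)
#'
#' Alternates expansion (matrix squaring) and inflation (entrywise power
#' `inflation` followed by column renormalisation), pruning entries below
#' `prune_threshold` (the per-column maximum is always retained), until the
#' maximum entrywise change falls below `tol` or `max_iter` is reached.
#'
#' @param m Column-stochastic sparse matrix from [build_flow_matrix()].
#' @param inflation Inflation exponent, > 1 (default 1.5).
#' @param prune_threshold Entries below this are dropped each round
#'   (default 1e-5).
#' @param max_iter Maximum number of expand/inflate rounds (default 100).
#' @param tol Convergence tolerance on the max entry change (default 1e-6).
#' @return The converged column-stochastic matrix.
#' @export
mcl_iterate <- function(m, inflation = 1.5, prune_threshold = 1e-5,
                        max_iter = 100, tol = 1e-6) {
  if (inflation <= 1) {
    stop("inflation must be > 1")
  }
  m <- methods::as(m, "CsparseMatrix")
  for (iter in seq_len(max_iter)) {
    m2 <- m %*% m
    m2 <- methods::as(m2, "CsparseMatrix")
    m2@x <- m2@x^inflation
    m2 <- prune_matrix(m2, prune_threshold)
    m2 <- normalize_columns(m2)
    m2 <- methods::as(m2, "CsparseMatrix")
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) {
      return(m)
    }
  }
  warning(sprintf("MCL did not converge in %d iterations (last change %.2e)", max_iter, delta))
  m
}

# Drop entries below the threshold but never empty a column: the column
# maximum is always kept so the matrix stays stochastic after renormalisation.
prune_matrix <- function(m, threshold) {
  if (length(m@x) == 0) {
    return(m)
  }
  n <- ncol(m)
  col_of <- rep.int(seq_len(n), diff(m@p))
  colmax <- vapply(split(m@x, factor(col_of, levels = seq_len(n))), function(v) {
    if (length(v)) max(v) else 0
  }, numeric(1))
  keepmask <- m@x >= pmin(threshold, colmax[col_of])
  m@x[!keepmask] <- 0
  Matrix::drop0(m)
}

#' Extract clusters from a converged MCL matrix
#'
#' Clusters are the connected components of the symmetrised support of the
#' converged matrix, found by union-find. Self-loop-only nodes come out as
#' singletons. When the input graph is supplied, each cluster is additionally
#' split into its connected components within that graph: pruning can leave a
#' node attached to a distant attractor whose connecting path was assigned
#' elsewhere, and a cluster must induce a connected subgraph of the input.
#'
#' @param m Converged matrix from [mcl_iterate()] (dimnames = gene ids).
#' @param graph Optional edge tibble of the input graph used to enforce
#'   within-cluster connectivity.
#' @return List of integer vectors of gene ids, one per cluster (including
#'   singletons), each sorted; list ordered by decreasing size then smallest
#'   member.
#' @export
extract_clusters <- function(m, graph = NULL) {
  nodes <- as.integer(rownames(m))
  n <- length(nodes)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  s <- Matrix::summary(methods::as(m, "CsparseMatrix"))
  off <- s[s$i != s$j & s$x > 0, , drop = FALSE]
  for (k in seq_len(nrow(off))) {
    ri <- find(off$i[k])
    rj <- find(off$j[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(nodes, roots)
  groups <- lapply(unname(groups), sort)
  if (!is.null(graph)) {
    groups <- unlist(
      lapply(groups, split_by_graph_components, graph = graph),
      recursive = FALSE
    )
  }
  order_clusters(groups)
}

# Connected components of the induced subgraph of `members` in `graph`.
split_by_graph_components <- function(members, graph) {
  n <- length(members)
  if (n <= 1) {
    return(list(members))
  }
  e <- graph[graph$gene1 %in% members & graph$gene2 %in% members, ]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  i <- match(e$gene1, members)
  j <- match(e$gene2, members)
  for (k in seq_along(i)) {
    ri <- find(i[k])
    rj <- find(j[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unname(split(members, roots)), sort)
}

order_clusters <- function(groups) {
  if (length(groups) == 0) {
    return(groups)
  }
  sizes <- lengths(groups)
  mins <- vapply(groups, min, numeric(1))
  groups[order(-sizes, mins)]
}

#' Assemble a partition from clusters and the catalogue
#'
#' Clusters of size >= 2 become orthogroups, numbered 1..K in decreasing size
#' order (ties by smallest contained gene id); size-1 clusters and catalogue
#' genes absent from any cluster are unassigned (`orthogroup = NA`).
#'
#' @param clusters List of integer gene-id vectors.
#' @param catalog Sequence catalogue (defines the gene universe).
#' @return A partition tibble: columns `gene_id`, `orthogroup` (integer or
#'   NA), one row per catalogue gene.
#' @export
new_partition <- function(clusters, catalog) {
  clusters <- order_clusters(lapply(clusters, function(g) sort(as.integer(g))))
  clusters <- clusters[lengths(clusters) >= 2]
  part <- tibble::tibble(gene_id = sort(catalog$gene_id), orthogroup = NA_integer_)
  for (k in seq_along(clusters)) {
    idx <- match(clusters[[k]], part$gene_id)
    if (anyNA(idx)) {
      stop("cluster contains gene(s) absent from the catalogue")
    }
    if (any(!is.na(part$orthogroup[idx]))) {
      stop("clusters overlap: a gene appears in more than one orthogroup")
    }
    part$orthogroup[idx] <- k
  }
  part
}

#' Split a partition tibble into a list of gene-id vectors
#'
#' @param partition Partition tibble (`gene_id`, `orthogroup`).
#' @return Named list: `groups` (list of sorted gene-id vectors in orthogroup
#'   order) and `unassigned` (sorted gene ids with `orthogroup = NA`).
#' @export
partition_groups <- function(partition) {
  assigned <- partition[!is.na(partition$orthogroup), ]
  groups <- split(assigned$gene_id, assigned$orthogroup)
  groups <- lapply(unname(groups[as.character(sort(unique(assigned$orthogroup)))]), sort)
  list(groups = groups, unassigned = sort(partition$gene_id[is.na(partition$orthogroup)]))
}

#' Cluster an orthogroup graph with the built-in MCL engine
#'
#' @param graph Edge tibble from [build_graph()].
#' @param catalog Sequence catalogue.
#' @param inflation Inflation parameter (default 1.5, the method default).
#' @param self_loop,prune_threshold,max_iter,tol Passed to
#'   [build_flow_matrix()] / [mcl_iterate()].
#' @return Partition tibble over all catalogue genes.
#' @export
mcl_cluster <- function(graph, catalog, inflation = 1.5, self_loop = 1,
                        prune_threshold = 1e-5, max_iter = 100, tol = 1e-6) {
  if (nrow(graph) == 0) {
    return(new_partition(list(), catalog))
  }
  m <- build_flow_matrix(graph, self_loop = self_loop)
  conv <- mcl_iterate(m,
    inflation = inflation, prune_threshold = prune_threshold,
    max_iter = max_iter, tol = tol
  )
  new_partition(extract_clusters(conv, graph = graph), catalog)
}

#' Cluster a graph file with an external `mcl` executable
#'
#' Invokes `mcl <abc_path> --abc -I <inflation>` and parses its cluster
#' output (one cluster per line, tab-separated labels) into a partition with
#' the same ordering rules as the built-in engine.
#'
#' @param abc_path Path to an abc-format edge list (see [write_graph()]).
#' @param catalog Sequence catalogue.
#' @param inflation Inflation parameter.
#' @param mcl_bin Name or path of the mcl executable.
#' @return Partition tibble.
#' @export
run_external_mcl <- function(abc_path, catalog, inflation = 1.5, mcl_bin = "mcl") {
  exe <- Sys.which(mcl_bin)
  if (!nzchar(exe)) {
    stop(sprintf(
      "external mcl executable '%s' not found on PATH; use the built-in engine (mcl_cluster)",
      mcl_bin
    ))
  }
  if (length(readLines(abc_path)) == 0) {
    return(new_partition(list(), catalog))
  }
  out_path <- tempfile("mcl_out_")
  err_path <- tempfile("mcl_err_")
  status <- system2(exe, c(abc_path, "--abc", "-I", format(inflation), "-o", out_path),
    stdout = NULL, stderr = err_path
  )
  if (status != 0) {
    stop(sprintf(
      "mcl exited with status %d: %s", status,
      paste(readLines(err_path, warn = FALSE), collapse = "\n")
    ))
  }
  lines <- readLines(out_path)
  clusters <- lapply(strsplit(lines[nzchar(lines)], "\t", fixed = TRUE), as.integer)
  new_partition(clusters, catalog)
}
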