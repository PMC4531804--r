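part_from <- function(catalog, groups) new_partition(groups, catalog)

test_that("the worked confusion example gives precision 1/3, recall 1/2, F 0.4", {
  catalog <- make_catalog(list(c(100, 100), c(100, 100)))
  # genes: A=0 B=1 C=2 D=3
  predicted <- part_from(catalog, list(c(0L, 1L, 2L)))
  reference <- part_from(catalog, list(c(0L, 1L), c(2L, 3L)))
  counts <- pairwise_confusion(predicted, reference)
  expect_equal(counts$tp, 1)
  expect_equal(counts$fp, 2)
  expect_equal(counts$fn, 1)
  m <- metrics_from_counts(counts)
  expect_equal(m$precision, 1 / 3)
  expect_equal(m$recall, 1 / 2)
  expect_equal(m$fscore, 0.4)
})

test_that("identical partitions score perfectly; all-singleton predictions have zero recall", {
  catalog <- make_catalog(list(rep(100L, 5), rep(100L, 5)))
  ref <- part_from(catalog, list(c(0L, 5L), c(1L, 2L, 6L)))
  same <- evaluate_partition(ref, ref)
  expect_equal(same$fp, 0)
  expect_equal(same$fn, 0)
  expect_equal(same$fscore, 1)

  none <- part_from(catalog, list())
  m <- evaluate_partition(none, ref)
  expect_equal(m$tp, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$fscore, 0)

  expect_error(pairwise_confusion(ref, none), "empty reference")
})

test_that("metric conventions and harmonic-mean identity hold for random counts", {
  m0 <- metrics_from_counts(tibble::tibble(tp = 0, fp = 0, fn = 5))
  expect_equal(unlist(m0), c(precision = 0, recall = 0, fscore = 0))
  m1 <- metrics_from_counts(tibble::tibble(tp = 8, fp = 2, fn = 2))
  expect_equal(m1$precision, 0.8)
  expect_equal(m1$recall, 0.8)
  expect_equal(m1$fscore, 0.8)
  set.seed(99)
  for (i in 1:200) {
    counts <- tibble::tibble(
      tp = sample(0:50, 1), fp = sample(0:50, 1), fn = sample(0:50, 1)
    )
    m <- metrics_from_counts(counts)
    p <- if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp) else 0
    r <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else 0
    f <- if (p + r > 0) 2 / (1 / p + 1 / r) else 0 # harmonic mean, independent form
    expect_equal(m$fscore, f)
    # scale invariance
    m10 <- metrics_from_counts(dplyr::mutate(counts, tp = tp * 10, fp = fp * 10, fn = fn * 10))
    expect_equal(m10, m)
  }
})

test_that("swapping predicted and reference swaps precision and recall", {
  catalog <- make_catalog(list(rep(100L, 6), rep(100L, 6)))
  a <- part_from(catalog, list(c(0L, 1L, 6L), c(2L, 7L)))
  b <- part_from(catalog, list(c(0L, 6L), c(1L, 2L, 7L, 8L)))
  u <- catalog$gene_id
  mab <- metrics_from_counts(pairwise_confusion(a, b, universe = u))
  mba <- metrics_from_counts(pairwise_confusion(b, a, universe = u))
  expect_equal(mab$precision, mba$recall)
  expect_equal(mab$recall, mba$precision)
  expect_equal(mab$fscore, mba$fscore)
})

test_that("pair counting matches exhaustive enumeration on random partitions", {
  for (seed in 1:10) {
    catalog <- make_catalog(list(
      sample(50:500, 8, replace = TRUE), sample(50:500, 8, replace = TRUE)
    ))
    pred <- random_partition(catalog, seed)
    ref <- random_partition(catalog, seed + 100)
    u <- ref$gene_id[!is.na(ref$orthogroup)]
    counts <- pairwise_confusion(pred, ref)
    # brute force over all unordered pairs in the universe
    tp <- fp <- fn <- 0
    for (i in seq_along(u)) {
      for (j in seq_len(i - 1)) {
        pi <- pred$orthogroup[pred$gene_id == u[i]]
        pj <- pred$orthogroup[pred$gene_id == u[j]]
        ri <- ref$orthogroup[ref$gene_id == u[i]]
        rj <- ref$orthogroup[ref$gene_id == u[j]]
        cp <- !is.na(pi) && !is.na(pj) && pi == pj
        cr <- !is.na(ri) && !is.na(rj) && ri == rj
        tp <- tp + (cp && cr)
        fp <- fp + (cp && !cr)
        fn <- fn + (!cp && cr)
      }
    }
    expect_equal(unlist(counts), c(tp = tp, fp = fp, fn = fn))
  }
})

test_that("length bins are equal-count with geometric mean lengths reported", {
  catalog <- make_catalog(list(c(100L, 200L, 300L, 400L), c(150L, 250L, 350L, 450L)))
  ref <- part_from(catalog, list(c(0L, 4L), c(1L, 5L), c(2L, 6L), c(3L, 7L)))
  res <- length_binned_metrics(ref, ref, catalog, n_bins = 4)
  expect_equal(nrow(res), 4)
  expect_equal(res$n_genes, rep(2L, 4))
  expect_equal(res$geomean_length[1], sqrt(100 * 150))
  expect_equal(res$fscore, rep(1, 4))
  expect_error(length_binned_metrics(ref, ref, catalog, n_bins = 10), "fewer")
})

test_that("errors confined to long genes depress only the top bin's precision", {
  lens <- c(100L, 110L, 120L, 130L, 500L, 510L, 520L, 530L)
  catalog <- make_catalog(list(lens, lens + 5L))
  ref <- part_from(catalog, list(
    c(0L, 8L), c(1L, 9L), c(2L, 10L), c(3L, 11L),
    c(4L, 12L), c(5L, 13L), c(6L, 14L), c(7L, 15L)
  ))
  # prediction fuses the two longest reference groups
  pred <- part_from(catalog, list(
    c(0L, 8L), c(1L, 9L), c(2L, 10L), c(3L, 11L),
    c(4L, 12L), c(5L, 13L), c(6L, 7L, 14L, 15L)
  ))
  res <- length_binned_metrics(pred, ref, catalog, n_bins = 4)
  expect_equal(res$precision[1:3], rep(1, 3))
  expect_lt(res$precision[4], 1)
})

test_that("per-bin counts match a brute-force per-pair tabulation", {
  catalog <- make_catalog(list(
    sample(50:900, 10, replace = TRUE), sample(50:900, 10, replace = TRUE)
  ))
  pred <- random_partition(catalog, 7)
  ref <- NULL
  for (s in 8:30) { # first seed whose reference assigns enough genes to bin
    ref <- random_partition(catalog, s)
    if (sum(!is.na(ref$orthogroup)) >= 8) break
  }
  res <- length_binned_metrics(pred, ref, catalog, n_bins = 4)
  u <- sort(ref$gene_id[!is.na(ref$orthogroup)])
  len <- catalog$length_aa[match(u, catalog$gene_id)]
  u <- u[order(len, u)]
  n <- length(u)
  base <- n %/% 4
  extra <- n %% 4
  bin_of <- rep(1:4, rep(base, 4) + c(rep(1L, extra), rep(0L, 4 - extra)))
  for (b in 1:4) {
    tp <- fp <- fn <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1)) {
        if (bin_of[i] != b && bin_of[j] != b) next
        pi <- pred$orthogroup[pred$gene_id == u[i]]
        pj <- pred$orthogroup[pred$gene_id == u[j]]
        ri <- ref$orthogroup[ref$gene_id == u[i]]
        rj <- ref$orthogroup[ref$gene_id == u[j]]
        cp <- !is.na(pi) && !is.na(pj) && pi == pj
        cr <- !is.na(ri) && !is.na(rj) && ri == rj
        tp <- tp + (cp && cr)
        fp <- fp + (cp && !cr)
        fn <- fn + (!cp && cr)
      }
    }
    expect_equal(res$tp[b], tp)
    expect_equal(res$fp[b], fp)
    expect_equal(res$fn[b], fn)
  }
  # aggregation consistency: summed per-bin TP >= global TP (pairs count in <= 2 bins)
  global <- pairwise_confusion(pred, ref)
  expect_gte(sum(res$tp), global$tp)
  expect_lte(sum(res$tp), 2 * global$tp)
})

test_that("per-orthogroup error report flags splits and fusions", {
  catalog <- make_catalog(list(rep(100L, 6), rep(100L, 6)))
  ref <- part_from(catalog, list(c(0L, 1L, 6L, 7L), c(2L, 3L, 8L)))
  exact <- per_orthogroup_errors(ref, ref)
  expect_true(all(exact$error_free))
  expect_equal(orthogroup_error_summary(exact)$pct_error_free, 100)

  # first reference group split into two predicted halves
  split_pred <- part_from(catalog, list(c(0L, 1L), c(6L, 7L), c(2L, 3L, 8L)))
  rep_split <- per_orthogroup_errors(split_pred, ref)
  row1 <- rep_split[rep_split$ref_group == 1, ]
  expect_true(row1$fragmented)
  expect_equal(row1$n_missing, 2) # the smaller half
  expect_false(row1$error_free)

  # fusion: both reference groups merged into one predicted group
  fused_pred <- part_from(catalog, list(c(0L, 1L, 2L, 3L, 6L, 7L, 8L)))
  rep_fused <- per_orthogroup_errors(fused_pred, ref)
  expect_true(all(rep_fused$fused))
  expect_true(all(rep_fused$n_erroneous > 0))
})

test_that("deletion robustness: fraction 0 is a no-op and fractions count genes exactly", {
  catalog <- make_catalog(list(rep(100L, 50), rep(100L, 50)))
  ref <- part_from(catalog, lapply(0:24, function(k) c(k, k + 50L)))
  fake_pipeline <- function(h, cat) ref[ref$gene_id %in% cat$gene_id, ]
  hits <- tibble::tibble(
    query = integer(), subject = integer(), bitscore = numeric(),
    evalue = numeric(), qspecies = integer(), sspecies = integer()
  )
  res <- deletion_robustness(hits, catalog, ref,
    fractions = c(0, 0.5), seed = 3,
    pipeline = fake_pipeline
  )
  expect_equal(res$n_genes, c(100L, 50L))
  base <- evaluate_partition(ref, ref)
  expect_equal(res$fscore[1], base$fscore)
  expect_error(deletion_robustness(hits, catalog, ref, fractions = 1), "fractions")
})

test_that("gene-level counting unit is available behind the flag", {
  catalog <- make_catalog(list(rep(100L, 4), rep(100L, 4)))
  ref <- part_from(catalog, list(c(0L, 1L, 4L), c(2L, 5L)))
  pred <- part_from(catalog, list(c(0L, 1L), c(2L, 5L, 6L)))
  g <- pairwise_confusion(pred, ref, unit = "gene")
  # group1: best match {0,1}: tp 2, fn 1; group2: best {2,5,6}: tp 2, fp 0 (6 outside universe)
  expect_equal(g$tp, 4)
  expect_equal(g$fn, 1)
  expect_equal(g$fp, 0)
})
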