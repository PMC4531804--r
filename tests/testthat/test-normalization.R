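# helpers: synthetic hit tables with a known score/length law

law_hits <- function(n, a, b, seed = 1, noise_sigma = 0, l_range = c(50, 1000)) {
  set.seed(seed)
  lq <- sample(l_range[1]:l_range[2], n, replace = TRUE)
  lh <- sample(l_range[1]:l_range[2], n, replace = TRUE)
  catalog <- make_catalog(list(lq, lh))
  hits <- tibble::tibble(
    query = 0:(n - 1), subject = n:(2 * n - 1),
    qspecies = 0L, sspecies = 1L,
    evalue = 1e-20
  )
  l_qh <- as.numeric(lq) * as.numeric(lh)
  hits$bitscore <- 10^(b + a * log10(l_qh) + rnorm(n, 0, noise_sigma))
  list(catalog = catalog, hits = hits)
}

test_that("bin_hits follows the 1000/200 bin-size rule with merged remainder", {
  x <- law_hits(10000, 0.4, 1.2)
  b <- bin_hits(x$hits, x$catalog)
  expect_equal(as.integer(table(b$bin)), rep(1000L, 10))
  expect_false(is.unsorted(b$l_qh))

  x <- law_hits(4999, 0.4, 1.2)
  b <- bin_hits(x$hits, x$catalog)
  tab <- as.integer(table(b$bin))
  expect_equal(length(tab), 24)
  expect_equal(tab, c(rep(200L, 23), 399L))

  x <- law_hits(150, 0.4, 1.2)
  b <- bin_hits(x$hits, x$catalog)
  expect_equal(unique(b$bin), 1L)

  expect_error(bin_hits(x$hits[0, ], x$catalog), "no hits")
})

test_that("select_top_fraction keeps the ceiling of the top scorers per bin", {
  x <- law_hits(1000, 0.4, 1.2, noise_sigma = 0.3)
  b <- bin_hits(x$hits, x$catalog)
  sel <- select_top_fraction(b, 0.05)
  expect_equal(nrow(sel), 50) # 5 bins of 200, ceiling(0.05 * 200) = 10 each
  for (bb in unique(b$bin)) {
    sel_b <- sel$bitscore[sel$bin == bb]
    excl_b <- b$bitscore[b$bin == bb & !(paste(b$query, b$subject) %in% paste(sel$query, sel$subject))]
    expect_equal(length(sel_b), 10)
    expect_gte(min(sel_b), max(excl_b))
  }

  # ceiling guard: 10 hits at 5% still yields one
  x10 <- law_hits(10, 0.4, 1.2)
  sel10 <- select_top_fraction(bin_hits(x10$hits, x10$catalog), 0.05)
  expect_equal(nrow(sel10), 1)
  expect_equal(sel10$bitscore, max(x10$hits$bitscore))
})

test_that("bitscore ties are broken by smaller length product (sort oracle)", {
  set.seed(7)
  n <- 40
  lq <- sample(50:500, n, replace = TRUE)
  catalog <- make_catalog(list(lq, rep(100L, n)))
  hits <- tibble::tibble(
    query = 0:(n - 1), subject = n:(2 * n - 1),
    bitscore = 100, evalue = 1e-10, qspecies = 0L, sspecies = 1L
  )
  b <- bin_hits(hits, catalog)
  sel <- select_top_fraction(b, 0.1)
  k <- ceiling(0.1 * n)
  oracle <- sort(b$l_qh)[seq_len(k)]
  expect_equal(sort(sel$l_qh), oracle)
})

test_that("fit_loglog recovers exact coefficients and matches the closed form", {
  x <- law_hits(500, 0.5, 1.0, seed = 3)
  lq <- x$catalog$length_aa[match(x$hits$query, x$catalog$gene_id)]
  lh <- x$catalog$length_aa[match(x$hits$subject, x$catalog$gene_id)]
  x$hits$l_qh <- as.numeric(lq) * as.numeric(lh)
  fit <- fit_loglog(x$hits)
  expect_equal(fit$a, 0.5, tolerance = 1e-9)
  expect_equal(fit$b, 1.0, tolerance = 1e-9)

  # three-point case against the normal equations solved independently
  pts <- tibble::tibble(l_qh = c(10, 100, 1000), bitscore = c(10, 20, 40))
  fit3 <- fit_loglog(pts)
  X <- cbind(1, log10(pts$l_qh))
  beta <- solve(t(X) %*% X, t(X) %*% log10(pts$bitscore))
  expect_equal(fit3$b, beta[1], tolerance = 1e-12)
  expect_equal(fit3$a, beta[2], tolerance = 1e-12)

  # constant factor c on B shifts b by log10(c), leaves a unchanged
  pts2 <- dplyr::mutate(pts, bitscore = bitscore * 7)
  fit7 <- fit_loglog(pts2)
  expect_equal(fit7$a, fit3$a, tolerance = 1e-12)
  expect_equal(fit7$b, fit3$b + log10(7), tolerance = 1e-12)

  expect_error(fit_loglog(tibble::tibble(l_qh = c(10, 10), bitscore = c(5, 6))), "degenerate")
})

test_that("tidy and glance expose the fit coefficients", {
  pts <- tibble::tibble(l_qh = c(10, 100, 1000), bitscore = c(10, 20, 40))
  fit <- fit_loglog(pts)
  td <- tidy(fit)
  expect_equal(td$term, c("log10_length_product", "intercept"))
  expect_equal(glance(fit)$n_hits_fit, 3)
})

test_that("normalize_scores divides by the expected best-hit score", {
  catalog <- make_catalog(list(c(350L), c(400L)))
  model <- structure(list(a = 0.3785, b = 1.241, n_hits_fit = 10), class = "loglog_fit")
  hits <- tibble::tibble(
    query = 0L, subject = 1L, bitscore = 416, evalue = 1e-30,
    qspecies = 0L, sspecies = 1L
  )
  out <- normalize_scores(hits, model, catalog)
  expect_equal(out$norm_score, 416 / (10^1.241 * (350 * 400)^0.3785), tolerance = 1e-12)

  # a hit exactly on the line scores 1; double the score gives 2
  on_line <- hits
  on_line$bitscore <- 10^1.241 * (350 * 400)^0.3785
  expect_equal(normalize_scores(on_line, model, catalog)$norm_score, 1.0, tolerance = 1e-12)
  on_line$bitscore <- 2 * on_line$bitscore
  expect_equal(normalize_scores(on_line, model, catalog)$norm_score, 2.0, tolerance = 1e-12)
})

test_that("normalize_all_pairs fits every ordered species pair independently", {
  set.seed(11)
  catalogs <- make_catalog(lapply(1:3, function(i) sample(100:600, 30, replace = TRUE)))
  hits <- list()
  for (qs in 0:2) {
    for (ss in 0:2) {
      qg <- catalogs$gene_id[catalogs$species_id == qs]
      sg <- catalogs$gene_id[catalogs$species_id == ss]
      pr <- expand.grid(query = qg, subject = sg)
      pr <- pr[pr$query != pr$subject, ]
      lq <- catalogs$length_aa[match(pr$query, catalogs$gene_id)]
      lh <- catalogs$length_aa[match(pr$subject, catalogs$gene_id)]
      hits[[length(hits) + 1]] <- tibble::tibble(
        query = as.integer(pr$query), subject = as.integer(pr$subject),
        bitscore = 10^(1 + (0.1 * qs) + 0.4 * log10(as.numeric(lq) * lh) + rnorm(nrow(pr), 0, 0.05)),
        evalue = 1e-20, qspecies = qs, sspecies = ss
      )
    }
  }
  hits <- dplyr::bind_rows(hits)
  norm <- normalize_all_pairs(hits, catalogs)
  expect_equal(nrow(norm$fits), 9)
  expect_equal(nrow(norm$hits), nrow(hits))
  # same length structure, scores shifted by a constant factor per qs: same a, different b
  f <- norm$fits
  expect_true(diff(range(f$a)) < 0.1)
  expect_gt(mean(f$b[f$qspecies == 2]), mean(f$b[f$qspecies == 0]))
})

test_that("top-fraction mean normalised score is ~1 for every pair (distance claim)", {
  # two species pairs whose true scores differ by a factor of 5
  mk <- function(factor, seed) {
    x <- law_hits(6000, 0.4, 1.2, seed = seed, noise_sigma = 0.1)
    x$hits$bitscore <- x$hits$bitscore * factor
    x
  }
  xa <- mk(1, 21)
  xb <- mk(5, 22)
  top_mean <- function(x) {
    norm <- suppressWarnings(normalize_all_pairs(x$hits, x$catalog))
    sel <- select_top_fraction(bin_hits(x$hits, x$catalog), 0.05)
    m <- dplyr::semi_join(norm$hits, sel, by = c("query", "subject"))
    mean(m$norm_score)
  }
  ma <- top_mean(xa)
  mb <- top_mean(xb)
  expect_equal(ma, 1, tolerance = 0.02)
  expect_equal(mb, 1, tolerance = 0.02)
  expect_lt(abs(ma - mb) / ma, 0.01)
})

test_that("scale equivariance: multiplying a pair's bitscores leaves norm scores unchanged", {
  x <- law_hits(2000, 0.4, 1.2, seed = 5, noise_sigma = 0.15)
  n1 <- suppressWarnings(normalize_all_pairs(x$hits, x$catalog))
  x2 <- x
  x2$hits$bitscore <- x2$hits$bitscore * 3.7
  n2 <- suppressWarnings(normalize_all_pairs(x2$hits, x2$catalog))
  expect_equal(n1$hits$norm_score, n2$hits$norm_score, tolerance = 1e-9)
})

test_that("normalisation preserves rank order among hits of equal length product", {
  catalog <- make_catalog(list(rep(200L, 5), rep(300L, 5)))
  set.seed(9)
  hits <- tibble::tibble(
    query = 0:4, subject = 5:9,
    bitscore = runif(5, 50, 500), evalue = 1e-20,
    qspecies = 0L, sspecies = 1L
  )
  model <- structure(list(a = 0.4, b = 1.2, n_hits_fit = 5), class = "loglog_fit")
  out <- normalize_scores(hits, model, catalog)
  expect_equal(order(out$norm_score), order(hits$bitscore))
})

test_that("length bias is removed: norm score of top hits uncorrelated with length", {
  x <- law_hits(20000, 0.45, 1.1, seed = 13, noise_sigma = 0.1)
  norm <- suppressWarnings(normalize_all_pairs(x$hits, x$catalog))
  sel <- select_top_fraction(bin_hits(x$hits, x$catalog), 0.05)
  pre <- cor(sel$bitscore, sel$l_qh, method = "spearman")
  m <- dplyr::semi_join(norm$hits, sel, by = c("query", "subject"))
  post <- cor(m$norm_score, m$l_qh, method = "spearman")
  expect_gt(abs(pre), 0.9)
  expect_lt(abs(post), 0.05)
})

test_that("small pairs fall back to a single fitting bin", {
  x <- law_hits(30, 0.4, 1.2, seed = 2, noise_sigma = 0.05)
  norm <- expect_no_error(suppressWarnings(normalize_all_pairs(x$hits, x$catalog)))
  expect_equal(nrow(norm$fits), 1)
  expect_true(all(is.finite(norm$hits$norm_score)))
})

test_that("cached fits reproduce the same normalised scores", {
  x <- law_hits(3000, 0.4, 1.2, seed = 8, noise_sigma = 0.1)
  n1 <- suppressWarnings(normalize_all_pairs(x$hits, x$catalog))
  n2 <- suppressWarnings(normalize_all_pairs(x$hits, x$catalog, fits = n1$fits))
  expect_equal(
    dplyr::arrange(n1$hits, query, subject)$norm_score,
    dplyr::arrange(n2$hits, query, subject)$norm_score
  )
})
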