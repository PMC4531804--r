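#' Assign hits of one species pair to equal-count length bins
#'
#' Hits are sorted by the length product \eqn{L_{qh} = L_q L_h} (query length
#' times hit length, amino acids squared) and split into consecutive bins of
#' 1,000 hits, or bins of 200 when fewer than 5,000 hits are present. A final
#' partial bin is merged into the preceding full bin; if there are fewer hits
#' than one bin size, a single bin holds everything.
#'
#' @param hits Hit tibble for a single ordered species pair.
#' @param catalog Sequence catalogue supplying gene lengths.
#' @return The hits sorted ascending by `l_qh`, with added columns `l_qh` and
#'   `bin` (1-based bin index).
#' @export
bin_hits <- function(hits, catalog) {
  if (nrow(hits) == 0) {
    stop("no hits for species pair")
  }
  hits <- add_length_product(hits, catalog)
  hits <- dplyr::arrange(hits, .data$l_qh)
  n <- nrow(hits)
  bin_size <- if (n >= 5000) 1000L else 200L
  if (n < bin_size) {
    hits$bin <- 1L
  } else {
    n_full <- n %/% bin_size
    hits$bin <- pmin((seq_len(n) - 1L) %/% bin_size + 1L, n_full)
  }
  hits
}

add_length_product <- function(hits, catalog) {
  lq <- catalog$length_aa[match(hits$query, catalog$gene_id)]
  lh <- catalog$length_aa[match(hits$subject, catalog$gene_id)]
  if (anyNA(lq) || anyNA(lh)) {
    stop("hit references gene absent from the catalogue")
  }
  hits$l_qh <- as.numeric(lq) * as.numeric(lh)
  hits
}

#' Select the top fraction of hits per bin by bit score
#'
#' Within each bin, the \eqn{\lceil fraction \times n \rceil} highest-scoring
#' hits are selected (the ceiling guarantees at least one hit per bin). Ties
#' at the cut are broken by lower length product first, then stable input
#' order.
#'
#' @param binned Output of [bin_hits()] (must contain `bin` and `l_qh`).
#' @param fraction Fraction of hits to keep per bin (default 0.05).
#' @return The selected hits (all bins combined), retaining all columns.
#' @export
select_top_fraction <- function(binned, fraction = 0.05) {
  binned |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$bin) |>
    dplyr::arrange(dplyr::desc(.data$bitscore), .data$l_qh, .data$.row, .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() <= ceiling(fraction * dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
}

#' Fit the log-log model of bit score against length product
#'
#' Ordinary least squares fit of \eqn{\log_{10} B_{qh} = a \log_{10} L_{qh} + b}
#' over the selected top-scoring hits: the line describing the bit score
#' expected for the best hits between sequences of a given length.
#'
#' @param selected Hits with `bitscore` and `l_qh` columns (typically from
#'   [select_top_fraction()]).
#' @return An object of class `loglog_fit`: list with slope `a`, intercept
#'   `b`, and `n_hits_fit`.
#' @export
fit_loglog <- function(selected) {
  if (length(unique(selected$l_qh)) < 2) {
    stop("degenerate fit; widen bins (all length products identical)")
  }
  fit <- stats::lm(log10(bitscore) ~ log10(l_qh), data = selected)
  coefs <- stats::coef(fit)
  a <- unname(coefs[2])
  b <- unname(coefs[1])
  if (!is.finite(a) || !is.finite(b)) {
    stop("non-finite fit coefficients")
  }
  structure(
    list(a = a, b = b, n_hits_fit = nrow(selected)),
    class = "loglog_fit"
  )
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "log-log bit score fit: log10(B) = %.4f * log10(L_qh) + %.4f  (n = %d)\n",
    x$a, x$b, x$n_hits_fit
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy loglog_fit
#' @export
tidy.loglog_fit <- function(x, ...) {
  tibble::tibble(
    term = c("log10_length_product", "intercept"),
    estimate = c(x$a, x$b)
  )
}

#' @method glance loglog_fit
#' @export
glance.loglog_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, n_hits_fit = x$n_hits_fit)
}

#' Normalise bit scores with a fitted length model
#'
#' Every hit (not only the fitted top fraction) is annotated with
#' \eqn{B'_{qh} = B_{qh} / (10^b L_{qh}^a)}: the observed bit score divided by
#' the score expected for the best hits between sequences of that length.
#'
#' @param hits Hit tibble for the species pair the model was fitted on.
#' @param model A `loglog_fit`.
#' @param catalog Sequence catalogue.
#' @return The hits with added columns `l_qh` and `norm_score`.
#' @export
normalize_scores <- function(hits, model, catalog) {
  if (!("l_qh" %in% names(hits))) {
    hits <- add_length_product(hits, catalog)
  }
  hits$norm_score <- hits$bitscore / (10^model$b * hits$l_qh^model$a)
  bad <- !is.finite(hits$norm_score) | hits$norm_score <= 0
  if (any(bad)) {
    stop(sprintf(
      "non-finite or non-positive normalised score for hit(s): %s",
      paste(sprintf("%d->%d", hits$query[bad], hits$subject[bad])[seq_len(min(5, sum(bad)))],
        collapse = ", "
      )
    ))
  }
  hits
}

#' Normalise all species pairs independently
#'
#' Applies the bin / top-fraction / log-log fit / transform procedure to each
#' ordered species pair (same-species pairs included) independently, so that
#' the best hits of every pair score about 1 regardless of gene length or
#' phylogenetic distance. If a pair yields fewer than `min_fit_points`
#' selected hits, a single global bin is used for that pair instead.
#'
#' @param hits Hit tibble covering any number of ordered species pairs (needs
#'   `qspecies` / `sspecies`).
#' @param catalog Sequence catalogue.
#' @param top_fraction Fraction of hits per bin used for fitting.
#' @param min_fit_points Minimum selected points required before falling back
#'   to a single bin (default 10).
#' @param fits Optional pre-computed fit tibble (columns `qspecies`,
#'   `sspecies`, `a`, `b`, `n_hits_fit`), e.g. cached from an earlier run;
#'   when given, fitting is skipped and these coefficients are applied.
#' @return Object of class `norm_result`: list with `hits` (all input hits
#'   plus `l_qh`, `norm_score`) and `fits` (one row per ordered species pair).
#' @export
normalize_all_pairs <- function(hits, catalog, top_fraction = 0.05,
                                min_fit_points = 10, fits = NULL) {
  species <- sort(unique(catalog$species_id))
  seen <- dplyr::distinct(hits, .data$qspecies, .data$sspecies)
  all_pairs <- expand.grid(qspecies = species, sspecies = species)
  absent <- dplyr::anti_join(all_pairs, seen, by = c("qspecies", "sspecies"))
  if (nrow(absent) > 0) {
    warning(sprintf(
      "species pair(s) with zero hits skipped: %s",
      paste(sprintf("%d vs %d", absent$qspecies, absent$sspecies), collapse = "; ")
    ))
  }
  groups <- hits |>
    dplyr::group_by(.data$qspecies, .data$sspecies) |>
    dplyr::group_split()
  out <- purrr::map(groups, function(g) {
    qs <- g$qspecies[1]
    ss <- g$sspecies[1]
    if (!is.null(fits)) {
      row <- fits[fits$qspecies == qs & fits$sspecies == ss, ]
      if (nrow(row) != 1) {
        stop(sprintf("no cached fit for species pair %d vs %d", qs, ss))
      }
      model <- structure(
        list(a = row$a, b = row$b, n_hits_fit = row$n_hits_fit),
        class = "loglog_fit"
      )
      g <- add_length_product(g, catalog)
    } else {
      binned <- bin_hits(g, catalog)
      selected <- select_top_fraction(binned, top_fraction)
      if (nrow(selected) < min_fit_points) {
        # sparse pair: re-select from a single global bin, taking at least
        # min_fit_points top hits so the fit stays stable
        binned$bin <- 1L
        frac <- min(1, min_fit_points / nrow(binned))
        selected <- select_top_fraction(binned, max(top_fraction, frac))
      }
      constant_model <- function() {
        # degenerate pair (no usable length spread): normalise against the
        # mean of the top-fraction scores instead of a fitted line
        pts <- select_top_fraction(binned, top_fraction)
        structure(
          list(a = 0, b = mean(log10(pts$bitscore)), n_hits_fit = nrow(pts)),
          class = "loglog_fit"
        )
      }
      if (nrow(selected) < 2 || length(unique(selected$l_qh)) < 2) {
        if (length(unique(binned$l_qh)) >= 2) {
          # widen to the whole pair so the slope stays estimable
          model <- fit_loglog(binned)
          model$n_hits_fit <- nrow(binned)
        } else {
          model <- constant_model()
        }
      } else {
        model <- fit_loglog(selected)
      }
      # a near-degenerate fit (few points, tiny length spread) can produce an
      # extreme slope whose expected score over- or underflows; fall back
      expected <- 10^model$b * binned$l_qh^model$a
      if (!all(is.finite(expected)) || any(expected <= 0)) {
        model <- constant_model()
      }
      g <- binned
    }
    list(
      hits = normalize_scores(dplyr::select(g, -dplyr::any_of("bin")), model, catalog),
      fit = tibble::tibble(
        qspecies = qs, sspecies = ss,
        a = model$a, b = model$b, n_hits_fit = model$n_hits_fit
      )
    )
  })
  structure(
    list(
      hits = dplyr::bind_rows(purrr::map(out, "hits")),
      fits = dplyr::bind_rows(purrr::map(out, "fit"))
    ),
    class = "norm_result"
  )
}

#' @export
print.norm_result <- function(x, ...) {
  cat(sprintf(
    "normalised hit table: %d hits, %d species-pair fits\n",
    nrow(x$hits), nrow(x$fits)
  ))
  print(x$fits)
  invisible(x)
}

#' @method tidy norm_result
#' @export
tidy.norm_result <- function(x, ...) x$fits

#' @method glance norm_result
#' @export
glance.norm_result <- function(x, ...) {
  tibble::tibble(
    n_hits = nrow(x$hits),
    n_pairs = nrow(x$fits),
    mean_a = mean(x$fits$a),
    mean_b = mean(x$fits$b)
  )
}

#' Diagnostic plot of raw scores and per-pair fits
#'
#' Log-log scatter of bit score against length product, with the fitted line
#' per ordered species pair.
#'
#' @param object A `norm_result`.
#' @param max_points Hits subsampled per pair for plotting (default 2000).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot norm_result
#' @export
autoplot.norm_result <- function(object, max_points = 2000, ...) {
  hits <- object$hits |>
    dplyr::group_by(.data$qspecies, .data$sspecies) |>
    dplyr::slice_sample(n = max_points) |>
    dplyr::ungroup() |>
    dplyr::mutate(pair = sprintf("%d vs %d", .data$qspecies, .data$sspecies))
  fits <- dplyr::mutate(object$fits, pair = sprintf("%d vs %d", .data$qspecies, .data$sspecies))
  ggplot2::ggplot(hits, ggplot2::aes(x = log10(.data$l_qh), y = log10(.data$bitscore))) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(slope = .data$a, intercept = .data$b),
      colour = "red"
    ) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(
      x = "log10 length product (aa^2)", y = "log10 bit score",
      title = "Per-species-pair length model"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
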