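#' Decile prediction grid for one interactive species
#'
#' Builds the 11 x 11 grid of warming and conversion values over the
#' species' observed squares — minimum, the nine deciles (10th...90th
#' percentile, linear interpolation), and maximum for each predictor — and
#' the paired persistence predictions from the interactive (full) and
#' additive fits, with all control variables held at their observed
#' medians. 121 paired points per species.
#'
#' @param fit_full formulation-5 `persist_fit`.
#' @param fit_additive formulation-4 `persist_fit` on the same data.
#' @param data the species' observed data (defaults to the full fit's).
#' @return A `prediction_grid` tibble: `dT`, `L`, `dT_level`, `L_level`
#'   (1-11), `p_full`, `p_additive`, `diff`.
#' @export
build_grid <- function(fit_full, fit_additive, data = NULL) {
  if (is.null(data)) data <- fit_full$data
  grid_values <- function(v) {
    if (stats::sd(data[[v]]) == 0) {
      stop("degenerate predictor '", v, "': constant over observed squares")
    }
    unname(c(min(data[[v]]),
             stats::quantile(data[[v]], probs = seq(0.1, 0.9, by = 0.1),
                             type = 7),
             max(data[[v]])))
  }
  gT <- grid_values("dT")
  gL <- grid_values("L")
  controls <- setdiff(fit_full$terms, c("L", "dT", "L:dT"))
  nd <- tidyr::expand_grid(dT_level = 1:11, L_level = 1:11)
  nd$dT <- gT[nd$dT_level]
  nd$L <- gL[nd$L_level]
  for (v in controls) nd[[v]] <- stats::median(data[[v]])
  nd$p_full <- predict.persist_fit(fit_full, nd)
  nd$p_additive <- predict.persist_fit(fit_additive, nd)
  nd$diff <- nd$p_full - nd$p_additive
  class(nd) <- c("prediction_grid", class(nd))
  nd
}

#' Bonferroni per-test threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of tests in the family.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Paired comparison of interactive vs additive predictions
#'
#' One paired t-test per species over its grid's 121 prediction
#' differences, against the Bonferroni-corrected threshold `alpha / m`
#' (m = number of species in the family). Zero-variance differences are
#' degenerate: all-zero differences give p = 1 (not significant), constant
#' nonzero differences give p = 0 (counted significant); both are flagged.
#'
#' @param grids named list of `prediction_grid`s (one per species).
#' @param alpha family-wise level (default 0.05).
#' @return Tibble `species_id`, `n_pairs`, `mean_diff`, `t`, `df`, `p`,
#'   `significant`, `degenerate`; the per-test threshold in attribute
#'   `"threshold"`.
#' @export
paired_comparison <- function(grids, alpha = 0.05) {
  m <- length(grids)
  stopifnot(m >= 1)
  thr <- bonferroni_threshold(alpha, m)
  ids <- names(grids) %||% as.character(seq_len(m))
  rows <- lapply(seq_len(m), function(i) {
    d <- grids[[i]]$diff[is.finite(grids[[i]]$diff)]
    n <- length(d)
    md <- mean(d)
    s <- stats::sd(d)
    if (s == 0) {
      p <- if (md == 0) 1 else 0
      tv <- if (md == 0) 0 else sign(md) * Inf
      degen <- TRUE
    } else {
      tv <- md / (s / sqrt(n))
      p <- 2 * stats::pt(-abs(tv), df = n - 1)
      degen <- FALSE
    }
    tibble::tibble(species_id = ids[i], n_pairs = n, mean_diff = md,
                   t = tv, df = n - 1L, p = p,
                   significant = p < thr, degenerate = degen)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "threshold") <- thr
  out
}

#' Decile-by-size table of prediction differences
#'
#' For each decile row of one predictor, each species contributes its
#' maximum absolute interactive-vs-additive prediction difference across
#' the other predictor's 11 grid values; species are counted into size
#' bins. Every row sums to the number of species.
#'
#' @param grids named list of `prediction_grid`s.
#' @param by predictor defining the rows, `"dT"` or `"L"`.
#' @param bin_edges difference size bin edges on \[0, 1\] (default 0, .1,
#'   .2, .3, .4, 1).
#' @param statistic per-row species statistic: `"max"` (default) or
#'   `"mean"` absolute difference across the other predictor's values.
#' @return Tibble with `level` (1-11), one count column per bin, and
#'   `n_species`.
#' @export
difference_table <- function(grids, by = c("dT", "L"),
                             bin_edges = c(0, 0.1, 0.2, 0.3, 0.4, 1),
                             statistic = c("max", "mean")) {
  by <- match.arg(by)
  statistic <- match.arg(statistic)
  stopifnot(length(grids) >= 1)
  level_col <- paste0(by, "_level")
  stat_fun <- if (statistic == "max") max else mean
  labels <- paste0("(", utils::head(bin_edges, -1) * 100, "%, ",
                   utils::tail(bin_edges, -1) * 100, "%]")
  rows <- lapply(1:11, function(lev) {
    stat <- vapply(grids, function(g) {
      stat_fun(abs(g$diff[g[[level_col]] == lev]))
    }, numeric(1))
    bins <- cut(stat, breaks = bin_edges, labels = labels,
                include.lowest = TRUE)
    counts <- table(bins)
    out <- tibble::as_tibble(as.list(counts))
    out$level <- lev
    out$n_species <- length(grids)
    out
  })
  dplyr::relocate(dplyr::bind_rows(rows), "level")
}
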