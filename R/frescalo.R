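#' Frescalo neighbourhood weights
#'
#' For every target square, take the `n_candidates` geographically nearest
#' squares (the target itself included, at distance rank 1), rank them by
#' Sorensen similarity of their recorded species composition, keep the
#' `n_neighbours` most similar and weight them
#' `w = (1 - (r_sim - 1)/K)^4 * (1 - (r_dist - 1)/G)^4`,
#' so the target itself always gets weight 1 and weights decrease in both
#' ranks. These weighted neighbourhoods are the frequency-scaling basis of
#' the recorder-effort correction.
#'
#' @param centroids data frame with `x`, `y` (one row per square, in the
#'   row order of `presence`).
#' @param presence binary squares-by-species matrix (pooled periods).
#' @param n_candidates geographic candidate pool size G (default 200).
#' @param n_neighbours neighbours kept K (default 100, the method default).
#' @return Tibble `target`, `neighbour` (row indices), `r_dist`, `r_sim`,
#'   `w`.
#' @export
neighbourhood_weights <- function(centroids, presence,
                                  n_candidates = 200, n_neighbours = 100) {
  n <- nrow(presence)
  if (nrow(centroids) != n) stop("centroids and presence disagree on squares")
  if (n < n_neighbours) {
    stop("need at least n_neighbours = ", n_neighbours, " squares, have ", n)
  }
  G <- min(n_candidates, n)
  K <- n_neighbours
  if (K > G) stop("n_neighbours must not exceed n_candidates")
  d <- as.matrix(stats::dist(centroids[, c("x", "y")]))
  inter <- tcrossprod(presence)           # shared species counts
  rich <- rowSums(presence)
  sim <- 2 * inter / outer(rich, rich, "+")
  sim[!is.finite(sim)] <- 0
  diag(sim) <- 1
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- order(d[i, ])[seq_len(G)]     # self first (distance 0)
    sel <- order(-sim[i, cand], seq_len(G))[seq_len(K)]
    r_dist_sel <- sel                      # distance rank within the pool
    r_sim_sel <- seq_len(K)
    out[[i]] <- tibble::tibble(
      target = i,
      neighbour = cand[sel],
      r_dist = r_dist_sel,
      r_sim = r_sim_sel,
      w = (1 - (r_sim_sel - 1) / K)^4 * (1 - (r_dist_sel - 1) / G)^4
    )
  }
  dplyr::bind_rows(out)
}

#' Weighted local species frequencies
#'
#' `f_ij = sum_k w_ik x_kj / sum_k w_ik`: the weighted frequency of species
#' j in the neighbourhood of square i, in \[0, 1\].
#'
#' @param presence binary squares-by-species matrix.
#' @param weights tibble from [neighbourhood_weights()].
#' @return Numeric squares-by-species matrix of local frequencies.
#' @export
local_frequencies <- function(presence, weights) {
  n <- nrow(presence)
  W <- matrix(0, n, n)
  W[cbind(weights$target, weights$neighbour)] <- weights$w
  f <- (W %*% presence) / rowSums(W)
  f <- pmin(pmax(f, 0), 1)   # guard against floating-point overshoot
  dimnames(f) <- dimnames(presence)
  f
}

#' Per-square effort multiplier
#'
#' Solves, for each square, `mean_benchmark(1 - (1 - f_ij)^alpha_i) = phi`
#' where the benchmark set is the top `benchmark_fraction` of the expected
#' local richness `R_i = sum_j f_ij`, species ranked by local frequency
#' (ranking by raw and by rescaled frequency coincide, so the definition is
#' not circular). `alpha_i` is the sampling-effort multiplier: it exceeds 1
#' where neighbourhood frequencies fall short of the taxon's standard
#' frequency `phi` (i.e. under-recorded squares), and the recorder-effort
#' covariate is its reciprocal `1/alpha_i`. The monotone scalar equation is
#' solved to |residual| < 1e-8.
#'
#' @param f local frequency matrix from [local_frequencies()].
#' @param phi standard neighbourhood frequency target in (0, 1); taxon
#'   defaults used in this pipeline: birds .92, butterflies .86, macromoths
#'   .67, plants .75.
#' @param benchmark_fraction benchmark share of expected richness (default
#'   0.27).
#' @return Tibble `square`, `alpha`, `effort`, `flagged` (no finite
#'   solution).
#' @export
effort_multiplier <- function(f, phi, benchmark_fraction = 0.27) {
  stopifnot(phi > 0, phi < 1)
  n <- nrow(f)
  alpha <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    fi <- f[i, ]
    R <- sum(fi)
    nb <- max(1L, ceiling(benchmark_fraction * R))
    bench <- fi[order(-fi)[seq_len(min(nb, sum(fi > 0)))]]
    if (length(bench) == 0 || all(bench %in% c(0, 1))) {
      flagged[i] <- TRUE
      next
    }
    target <- function(a) mean(1 - (1 - bench)^a) - phi
    if (target(Inf) <= 0) {  # even infinite effort cannot reach phi
      flagged[i] <- TRUE
      next
    }
    hi <- 1
    while (target(hi) < 0) hi <- hi * 2
    alpha[i] <- stats::uniroot(target, c(0, hi), tol = 1e-12)$root
  }
  tibble::tibble(square = seq_len(n), alpha = alpha, effort = 1 / alpha,
                 flagged = flagged)
}

# solve sum_i (1 - (1 - fstar_i)^TF) = n_obs for TF >= 0
solve_time_factor <- function(fstar_visited, n_obs, tf_max = 99) {
  if (n_obs <= 0) return(list(tf = 0, capped = FALSE))
  g <- function(tf) sum(1 - (1 - fstar_visited)^tf) - n_obs
  if (g(tf_max) < 0) return(list(tf = tf_max, capped = TRUE))
  list(tf = stats::uniroot(g, c(0, tf_max), tol = 1e-12)$root, capped = FALSE)
}

#' Fit the Frescalo effort and trend model
#'
#' Runs the full chain for one taxon: neighbourhood weights on the pooled
#' two-period presence, local frequencies, per-square effort multipliers
#' standardised to `phi`, rescaled frequencies
#' `f*_ij = 1 - (1 - f_ij)^alpha_i`, and per-species per-period time
#' factors: `TF_jt` solves
#' `sum_{i visited in t} (1 - (1 - f*_ij)^TF) = n_jt`,
#' the observed number of squares recording species j in period t ("visited"
#' means any species of the taxon was recorded there in t). The decadal
#' distribution trend is `(TF_2 - TF_1) / (midpoint interval / 10)`.
#'
#' @param p1,p2 per-period presence matrices (same squares/species).
#' @param centroids data frame with `x`, `y` per square (row order of `p1`).
#' @param phi standard neighbourhood frequency for the taxon.
#' @param period_years list of two `(start, end)` year pairs, used for the
#'   midpoint interval; default gives an interval of 6.25 decades.
#' @param n_candidates,n_neighbours,benchmark_fraction see
#'   [neighbourhood_weights()] and [effort_multiplier()].
#' @param tf_max cap for time factors when the scalar equation has no finite
#'   root (observed count equals the number of visited squares).
#' @return A `frescalo_fit` with `squares` (effort tibble), `species`
#'   (`TF1`, `TF2`, `trend`, cap flags), and the `f`, `fstar` matrices.
#' @export
frescalo <- function(p1, p2, centroids, phi,
                     period_years = list(c(1930, 1960), c(2000, 2015)),
                     n_candidates = 200, n_neighbours = 100,
                     benchmark_fraction = 0.27, tf_max = 99) {
  stopifnot(identical(dim(p1), dim(p2)))
  pooled <- pmax(p1, p2)
  wts <- neighbourhood_weights(centroids, pooled, n_candidates, n_neighbours)
  f <- local_frequencies(pooled, wts)
  eff <- effort_multiplier(f, phi, benchmark_fraction)
  fstar <- 1 - (1 - f)^matrix(eff$alpha, nrow(f), ncol(f))
  dimnames(fstar) <- dimnames(f)

  mids <- vapply(period_years, mean, numeric(1))
  interval_decades <- (mids[2] - mids[1]) / 10
  visited <- list(rowSums(p1) > 0, rowSums(p2) > 0)
  n_sp <- ncol(p1)
  res <- vector("list", 2)
  for (t in 1:2) {
    p_t <- if (t == 1) p1 else p2
    rows <- visited[[t]] & !eff$flagged  # flagged squares have no f*
    counts <- colSums(p_t[rows, , drop = FALSE])
    sol <- lapply(seq_len(n_sp), function(j) {
      solve_time_factor(fstar[rows, j], counts[j], tf_max)
    })
    res[[t]] <- tibble::tibble(
      tf = vapply(sol, `[[`, numeric(1), "tf"),
      capped = vapply(sol, `[[`, logical(1), "capped")
    )
  }
  species <- tibble::tibble(
    species_id = colnames(p1) %||% as.character(seq_len(n_sp)),
    TF1 = res[[1]]$tf, TF2 = res[[2]]$tf,
    capped = res[[1]]$capped | res[[2]]$capped,
    trend = (res[[2]]$tf - res[[1]]$tf) / interval_decades
  )
  structure(
    list(squares = eff, species = species, f = f, fstar = fstar,
         phi = phi, weights = wts, interval_decades = interval_decades),
    class = "frescalo_fit"
  )
}

#' @export
print.frescalo_fit <- function(x, ...) {
  cat("<frescalo_fit> ", nrow(x$squares), " squares, ", nrow(x$species),
      " species, phi = ", x$phi, "\n", sep = "")
  cat("  effort multiplier alpha: median ",
      signif(stats::median(x$squares$alpha, na.rm = TRUE), 3),
      ", flagged ", sum(x$squares$flagged), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname frescalo
#' @param x a `frescalo_fit`.
#' @param ... unused.
#' @method tidy frescalo_fit
#' @export
tidy.frescalo_fit <- function(x, ...) x$species

#' @rdname frescalo
#' @method glance frescalo_fit
#' @export
glance.frescalo_fit <- function(x, ...) {
  tibble::tibble(
    n_squares = nrow(x$squares),
    n_species = nrow(x$species),
    phi = x$phi,
    median_alpha = stats::median(x$squares$alpha, na.rm = TRUE),
    effort_cv = stats::sd(x$squares$effort[!x$squares$flagged]) /
      mean(x$squares$effort[!x$squares$flagged]),
    n_flagged = sum(x$squares$flagged),
    n_capped = sum(x$species$capped)
  )
}

#' Telfer index of relative distribution change
#'
#' Regresses each species' second-period logit range proportion on its
#' first-period logit proportion across species, weighting inversely to the
#' binomial sampling variance of the logit (`w = N2 p2 (1 - p2)`), and
#' returns the standardized weighted residual: positive values mean the
#' species gained range relative to other species. Species with proportions
#' of exactly 0 or 1 in either period are excluded and flagged.
#'
#' @param n1,n2 per-species occupied square counts in periods 1 and 2.
#' @param N1,N2 total surveyed squares per period.
#' @param species_id optional ids.
#' @return Tibble `species_id`, `p1`, `p2`, `residual`, `index`, `excluded`;
#'   regression coefficients in attribute `"coefficients"`.
#' @export
telfer_index <- function(n1, n2, N1, N2, species_id = NULL) {
  if (is.null(species_id)) species_id <- as.character(seq_along(n1))
  p1 <- n1 / N1; p2 <- n2 / N2
  ok <- p1 > 0 & p1 < 1 & p2 > 0 & p2 < 1
  if (sum(ok) < 3) stop("need at least 3 species with proportions in (0, 1)")
  x <- stats::qlogis(p1[ok]); y <- stats::qlogis(p2[ok])
  w <- N2 * p2[ok] * (1 - p2[ok])
  fit <- stats::lm(y ~ x, weights = w)
  r <- stats::residuals(fit)
  sr <- r * sqrt(w)
  index <- sr / sqrt(sum(w * r^2) / (sum(ok) - 2))
  out <- tibble::tibble(species_id = species_id, p1 = p1, p2 = p2,
                        residual = NA_real_, index = NA_real_,
                        excluded = !ok)
  out$residual[ok] <- r
  out$index[ok] <- index
  attr(out, "coefficients") <- stats::coef(fit)
  attr(out, "weights") <- w
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
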