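# Frescalo effort/trend estimator and the Telfer cross-check.

# small deterministic presence set: 6 squares on a line, 4 species
line_presence <- function() {
  m <- rbind(
    c(1L, 1L, 1L, 0L),
    c(1L, 1L, 0L, 0L),
    c(1L, 0L, 1L, 1L),
    c(1L, 1L, 1L, 0L),
    c(0L, 1L, 1L, 1L),
    c(1L, 1L, 0L, 1L)
  )
  dimnames(m) <- list(as.character(1:6), paste0("sp", 1:4))
  m
}
line_centroids <- function() data.frame(x = 1:6 * 10, y = 0)

test_that("neighbourhood weights follow the rank formula", {
  pres <- line_presence()
  cent <- line_centroids()
  wts <- neighbourhood_weights(cent, pres, n_candidates = 6, n_neighbours = 3)
  # the target square has both ranks 1 and weight exactly 1
  self <- wts[wts$target == wts$neighbour, ]
  expect_identical(nrow(self), 6L)
  expect_true(all(self$w == 1))
  expect_true(all(self$r_sim == 1 & self$r_dist == 1))
  # the worst kept neighbour always weighs less than the target itself
  for (i in 1:6) {
    wi <- wts[wts$target == i, ]
    expect_lt(wi$w[wi$r_sim == 3], wi$w[wi$r_sim == 1])
    expect_true(all(wi$w > 0 & wi$w <= 1))
  }
  # hand evaluation for target square 1 (G = 6, K = 3):
  # Sorensen similarities to square 1, hand-computed from the matrix
  sor <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  sims <- apply(pres, 1, sor, b = pres[1, ])
  ord <- order(-sims, seq_len(6))[1:3]
  w1 <- wts[wts$target == 1, ]
  expect_identical(w1$neighbour, ord)
  expect_equal(w1$w,
               (1 - (1:3 - 1) / 3)^4 * (1 - (ord - 1) / 6)^4)
  # fewer squares than K is an error
  expect_error(neighbourhood_weights(cent[1:2, ], pres[1:2, ],
                                     n_neighbours = 3),
               "at least")
})

test_that("local frequencies are the weighted neighbourhood means", {
  pres <- matrix(c(1L, 0L, 1L, 1L), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  wts <- tibble::tibble(target = c(1, 1, 2, 2), neighbour = c(1, 2, 2, 1),
                        r_dist = c(1, 2, 1, 2), r_sim = c(1, 2, 1, 2),
                        w = c(1, 0.5, 1, 0.5))
  f <- local_frequencies(pres, wts)
  # species s1: target a sees (1 * 1 + 0.5 * 0) / 1.5 = 2/3
  expect_equal(f["a", "s1"], 2 / 3)
  # species present everywhere -> f = 1; absent everywhere -> f = 0
  pres2 <- cbind(all = c(1L, 1L), none = c(0L, 0L))
  f2 <- local_frequencies(pres2, wts)
  expect_equal(unname(f2[, "all"]), c(1, 1))
  expect_equal(unname(f2[, "none"]), c(0, 0))
})

test_that("effort multiplier solves the phi standardisation equation", {
  # closed form: all benchmark frequencies 0.5, phi 0.75 -> alpha = 2
  f <- matrix(0.5, 1, 10)
  eff <- effort_multiplier(f, phi = 0.75, benchmark_fraction = 1)
  expect_equal(eff$alpha, 2, tolerance = 1e-8)
  expect_equal(eff$effort, 0.5, tolerance = 1e-8)
  # benchmark mean already at phi -> alpha = 1
  f2 <- matrix(0.6, 1, 10)
  expect_equal(effort_multiplier(f2, phi = 0.6, benchmark_fraction = 1)$alpha,
               1, tolerance = 1e-8)
  # raising phi strictly raises alpha on the same input
  a1 <- effort_multiplier(f, phi = 0.6, benchmark_fraction = 1)$alpha
  a2 <- effort_multiplier(f, phi = 0.9, benchmark_fraction = 1)$alpha
  expect_gt(a2, a1)
  # residual below 1e-8
  bench <- rep(0.5, 10)
  expect_lt(abs(mean(1 - (1 - bench)^eff$alpha) - 0.75), 1e-8)
  # degenerate frequencies flagged
  f3 <- matrix(c(0, 1, 1, 0), 1, 4)
  expect_true(effort_multiplier(f3, phi = 0.75)$flagged)
})

test_that("time factors solve the visited-square equation", {
  pres <- line_presence()
  cent <- line_centroids()
  fr_same <- frescalo(pres, pres, cent, phi = 0.7, n_candidates = 6,
                      n_neighbours = 3, benchmark_fraction = 0.8)
  # identical presence and visitation in both periods -> zero trend
  expect_equal(fr_same$species$trend, rep(0, 4), tolerance = 1e-8)
  # strictly more occupied squares in period 2 -> positive trend
  p2 <- pres
  p2[2, "sp4"] <- 1L
  p2[1, "sp4"] <- 1L
  fr_up <- frescalo(pres, p2, cent, phi = 0.7, n_candidates = 6,
                    n_neighbours = 3, benchmark_fraction = 0.8)
  expect_gt(fr_up$species$trend[4], 0)
  # no finite root: observed count equals visited squares -> capped
  sol <- solve_time_factor(c(0.5), n_obs = 1, tf_max = 50)
  expect_true(sol$capped)
  expect_equal(sol$tf, 50)
})

test_that("thinning one square's records lowers its effort estimate", {
  w <- trend_world()
  pm <- world_presence(w)
  fr <- frescalo(pm$p1, pm$p2, w$square_table[, c("x", "y")], phi = 0.75)
  k <- 50
  p1t <- pm$p1; p2t <- pm$p2
  pres1 <- which(p1t[k, ] == 1)
  p1t[k, pres1[seq(1, length(pres1), by = 2)]] <- 0L
  pres2 <- which(p2t[k, ] == 1)
  p2t[k, pres2[seq(1, length(pres2), by = 2)]] <- 0L
  frt <- frescalo(p1t, p2t, w$square_table[, c("x", "y")], phi = 0.75)
  expect_gt(frt$squares$alpha[k], fr$squares$alpha[k])
  expect_lt(frt$squares$effort[k], fr$squares$effort[k])
})

test_that("uniform true effort yields a narrow effort distribution", {
  w <- generate_world(synth_config(
    seed = 11, n_squares_x = 20, n_squares_y = 20, fine_per_square = 4,
    species_spec = list(taxon_spec("plants", n = 80)),
    effort_spec = list(meanlog = log(2.5), sdlog = 0)
  ))
  pm <- world_presence(w)
  fr <- frescalo(pm$p1, pm$p2, w$square_table[, c("x", "y")], phi = 0.75)
  ok <- !fr$squares$flagged
  cv <- sd(fr$squares$effort[ok]) / mean(fr$squares$effort[ok])
  expect_lt(cv, 0.10)
})

test_that("Telfer index matches a hand weighted regression", {
  n1 <- c(50, 100, 150, 200, 10)
  n2 <- c(60, 90, 170, 180, 0)   # last species drops to 0 -> excluded
  N1 <- 400; N2 <- 400
  tel <- telfer_index(n1, n2, N1, N2)
  expect_true(tel$excluded[5])
  ok <- !tel$excluded
  # hand WLS oracle
  p1 <- n1[ok] / N1; p2 <- n2[ok] / N2
  x <- qlogis(p1); y <- qlogis(p2)
  wt <- N2 * p2 * (1 - p2)
  xb <- sum(wt * x) / sum(wt); yb <- sum(wt * y) / sum(wt)
  slope <- sum(wt * (x - xb) * (y - yb)) / sum(wt * (x - xb)^2)
  icpt <- yb - slope * xb
  res <- y - icpt - slope * x
  expect_equal(tel$residual[ok], res, tolerance = 1e-10)
  # weighted mean of residuals is zero
  expect_lt(abs(sum(wt * tel$residual[ok])), 1e-9)
  # standardized: unit weighted scale
  expect_equal(tel$index[ok], res * sqrt(wt) / sqrt(sum(wt * res^2) / 2),
               tolerance = 1e-10)
  expect_error(telfer_index(c(0, 1), c(1, 1), 2, 2), "at least 3")
})

test_that("Frescalo trend sign agrees with the Telfer index", {
  pooled_n <- 0; pooled_ok <- 0
  for (seed in 11:13) {
    w <- trend_world(seed)
    pm <- world_presence(w)
    fr <- frescalo(pm$p1, pm$p2, w$square_table[, c("x", "y")], phi = 0.75)
    tel <- telfer_index(colSums(pm$p1), colSums(pm$p2),
                        nrow(pm$p1), nrow(pm$p2),
                        species_id = colnames(pm$p1))
    occ_change <- (colSums(w$truth$occ2) - colSums(w$truth$occ1)) /
      nrow(w$square_table)
    j <- dplyr::inner_join(fr$species, tel, by = "species_id")
    j$occ_change <- occ_change[j$species_id]
    big <- j[abs(j$occ_change) > 0.10 & !j$excluded & !j$capped, ]
    pooled_n <- pooled_n + nrow(big)
    pooled_ok <- pooled_ok + sum(sign(big$trend) == sign(big$index))
  }
  expect_gt(pooled_n, 50)
  expect_gte(pooled_ok / pooled_n, 0.9)
})
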