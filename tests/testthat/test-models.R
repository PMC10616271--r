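# Model suite: PCNM controls, logistic fits vs independent oracles, AIC
# selection, marginal effects, bootstrap, mixed models, collinearity.

test_that("PCNM axes match a dense PCoA oracle and are orthogonal", {
  xy <- data.frame(x = seq(0, 120, by = 10), y = 0)
  ax <- pcnm_axes(xy)
  expect_lt(abs(sum(ax$pcnm1 * ax$pcnm2)), 1e-10)
  oracle <- pcnm_oracle(xy)
  expect_equal(ax$pcnm1, oracle[, 1], tolerance = 1e-8)
  expect_equal(ax$pcnm2, oracle[, 2], tolerance = 1e-8)
  # translation and rotation leave the axes unchanged (up to sign fix)
  th <- 0.7
  rot <- cbind(x = xy$x * cos(th) - xy$y * sin(th) + 5,
               y = xy$x * sin(th) + xy$y * cos(th) - 3)
  ax2 <- pcnm_axes(as.data.frame(rot))
  expect_equal(abs(ax$pcnm1), abs(ax2$pcnm1), tolerance = 1e-8)
  # 2-D grid case agrees with the oracle too
  g <- expand.grid(x = 1:6, y = 1:5)
  axg <- pcnm_axes(g)
  og <- pcnm_oracle(g)
  expect_equal(abs(axg$pcnm1), abs(og[, 1]), tolerance = 1e-6)
})

test_that("logistic MLE matches closed forms and a grid-search oracle", {
  # balanced intercept-only fit
  d <- tibble::tibble(y = c(0, 1, 0, 1, 0, 1))
  f0 <- fit_logistic(d, 1, controls = character())
  expect_lt(abs(f0$coefficients[["(Intercept)"]]), 1e-8)
  # 3 of 4 ones -> logit(0.75)
  d2 <- tibble::tibble(y = c(1, 1, 1, 0))
  f2 <- fit_logistic(d2, 1, controls = character())
  expect_equal(unname(f2$coefficients[["(Intercept)"]]), qlogis(0.75),
               tolerance = 1e-8)
  # 6-point toy with one covariate: staged likelihood grid-search oracle
  d6 <- tibble::tibble(y = c(0, 0, 1, 0, 1, 1), M = c(-2, -1, 0, 1, 2, 3))
  f6 <- fit_logistic(d6, 1, controls = "M")
  ll_grid <- function(b0s, b1s) {
    g <- expand.grid(b0 = b0s, b1 = b1s)
    eta <- cbind(1, d6$M) %*% rbind(g$b0, g$b1)   # 6 x npoints
    lls <- colSums(dbinom(d6$y, 1, plogis(eta), log = TRUE))
    list(best = g[which.max(lls), ], ll = max(lls))
  }
  centre <- c(0, 0); width <- 4; best_ll <- -Inf
  for (stage in 1:4) {                            # refine 100-fold each stage
    gr <- ll_grid(seq(centre[1] - width, centre[1] + width, length.out = 161),
                  seq(centre[2] - width, centre[2] + width, length.out = 161))
    centre <- as.numeric(gr$best); best_ll <- gr$ll
    width <- width / 40
  }
  expect_lt(abs(best_ll - f6$logLik), 1e-6)
  expect_gte(f6$logLik, best_ll - 1e-8)           # MLE at least as good
  expect_lt(f6$gradient_norm, 1e-8)
  # raw-scale coefficients equal an unstandardized glm fit
  w <- test_world()
  dd <- species_data(w, "sp001")
  f5 <- fit_logistic(dd, 5)
  g <- glm(y ~ L * dT + E + M + pcnm1 + pcnm2, binomial, data = dd,
           control = glm.control(epsilon = 1e-13, maxit = 100))
  nm <- names(f5$coefficients)
  expect_equal(unname(f5$coefficients[nm]), unname(coef(g)[nm]),
               tolerance = 1e-6)
  expect_equal(f5$logLik, as.numeric(logLik(g)), tolerance = 1e-8)
})

test_that("log-likelihood is invariant to affine covariate rescaling", {
  w <- test_world()
  d <- species_data(w, "sp002")
  f <- fit_logistic(d, 4)
  d2 <- dplyr::mutate(d, L = 100 * L - 7, dT = 0.01 * dT + 3)
  f2 <- fit_logistic(d2, 4)
  expect_lt(abs(f$logLik - f2$logLik), 1e-8)
  expect_equal(f$aic, f2$aic, tolerance = 1e-8)
})

test_that("AIC selection prefers fewer parameters on ties", {
  mk <- function(form, k, ll, conv = TRUE) {
    tibble::tibble(formulation = form, k = k, logLik = ll,
                   AIC = 2 * k - 2 * ll, converged = conv,
                   fit = list(structure(list(formulation = form, k = k,
                                             aic = 2 * k - 2 * ll),
                                        class = "persist_fit")))
  }
  fits <- dplyr::bind_rows(mk(4, 4, -10), mk(5, 5, -10))
  best <- select_best(fits)
  expect_identical(best$formulation, 4)
  da <- attr(best, "delta_aic")
  expect_equal(da$delta_aic, c(0, 2))
  # non-converged fits are excluded with a warning
  fits2 <- dplyr::bind_rows(mk(4, 4, -10), mk(5, 5, -20, conv = FALSE))
  expect_warning(best2 <- select_best(fits2), "non-converged")
  expect_identical(best2$formulation, 4)
  expect_error(select_best(fits2[2, ]), "no converged")
})

test_that("AME follows the logistic chain rule and a finite-difference oracle", {
  # single observation at p = 0.5 with slope 1: AME = 0.25 * unit
  fake <- structure(list(
    formulation = 3, terms = c("dT"),
    coefficients = c(`(Intercept)` = 0, dT = 1),
    data = tibble::tibble(y = 1L, dT = 0)
  ), class = "persist_fit")
  expect_equal(average_marginal_effect(fake, "dT", 0.1)$ame, 0.025)
  # zero coefficient -> zero AME
  fake0 <- fake; fake0$coefficients["dT"] <- 0
  expect_equal(average_marginal_effect(fake0, "dT", 0.1)$ame, 0)
  # central finite differences on a real interactive fit
  w <- test_world()
  d <- species_data(w, "sp003")
  f5 <- fit_logistic(d, 5)
  for (v in c("dT", "L")) {
    unit <- 0.1
    h <- 1e-6 * unit
    up <- d; up[[v]] <- up[[v]] + h
    dn <- d; dn[[v]] <- dn[[v]] - h
    fd <- unit * mean((predict(f5, up) - predict(f5, dn)) / (2 * h))
    expect_lt(abs(average_marginal_effect(f5, v, unit)$ame - fd), 1e-6)
  }
  # a variable absent from the model errors, never silently zero
  f1 <- fit_logistic(d, 1)
  expect_error(average_marginal_effect(f1, "L"), "not in the fitted model")
  expect_error(average_marginal_effect(f1, "dT"), "not in the fitted model")
})

test_that("parametric bootstrap intervals are seeded and reproducible", {
  w <- test_world()
  d <- species_data(w, "sp004")
  f <- fit_logistic(d, 4)
  ci1 <- bootstrap_ci(f, n_sim = 30, seed = 7)
  ci2 <- bootstrap_ci(f, n_sim = 30, seed = 7)
  expect_equal(ci1, ci2)
  ci3 <- bootstrap_ci(f, n_sim = 30, seed = 8)
  expect_false(isTRUE(all.equal(ci1$lower, ci3$lower)))
  expect_true(all(ci1$lower <= ci1$upper))
  # AME bootstrap columns appear when requested
  ciA <- bootstrap_ci(f, n_sim = 10, seed = 1, ame_variables = "dT")
  expect_true("AME_dT" %in% ciA$term)
})

test_that("mixed fit reduces to the pooled fit without species variance", {
  w <- test_world()
  d <- species_data(w, "sp005")
  # one species duplicated under two labels: no between-species variance
  d2 <- dplyr::bind_rows(dplyr::mutate(d, species_id = "a"),
                         dplyr::mutate(d, species_id = "b"))
  mf <- fit_mixed_logistic(d2, 4)
  expect_lt(mf$sigma2_u, 1e-4)
  pooled <- fit_logistic(d2, 4)
  expect_lt(max(abs(mf$coefficients - pooled$coefficients[names(mf$coefficients)])),
            1e-4)
})

test_that("mixed fit recovers a known species intercept variance", {
  # species intercepts drawn N(0, 1): sigma2_u estimate in [0.5, 1.6]
  set.seed(31)
  n_sp <- 50; n_per <- 500
  u <- rnorm(n_sp, 0, 1)
  d <- tibble::tibble(
    species_id = rep(sprintf("s%02d", 1:n_sp), each = n_per),
    dT = rnorm(n_sp * n_per, 0.25, 0.1),
    E = rlnorm(n_sp * n_per, 0, 0.5),
    M = rnorm(n_sp * n_per)
  )
  eta <- 0.5 + rep(u, each = n_per) + 2 * (d$dT - 0.25) + 0.1 * d$M
  d$y <- rbinom(nrow(d), 1, plogis(eta))
  mf <- fit_mixed_logistic(d, 3, controls = c("E", "M"))
  expect_gt(mf$sigma2_u, 0.5)
  expect_lt(mf$sigma2_u, 1.6)
  r2 <- r2_mixed(mf)
  expect_gt(r2$r2_conditional, r2$r2_marginal)
})

test_that("latent-scale R-squared matches closed forms", {
  expect_equal(unlist(r2_mixed(0, 0)), c(r2_marginal = 0, r2_conditional = 0))
  expect_equal(unlist(r2_mixed(0, pi^2 / 3)),
               c(r2_marginal = 0, r2_conditional = 0.5))
  expect_equal(unlist(r2_mixed(pi^2 / 3, pi^2 / 3)),
               c(r2_marginal = 1 / 3, r2_conditional = 2 / 3))
})

test_that("collinearity report matches cor.test", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y <- c(0.7, 2.9, 1.5, 4.2, 4.4)
  rep1 <- collinearity_report(data.frame(a = x, b = y))
  ct <- cor.test(x, y)
  expect_equal(rep1$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(rep1$df, unname(ct$parameter))
  expect_equal(rep1$p, ct$p.value, tolerance = 1e-12)
  # identical vectors -> r = 1; orthogonal mean-centred vectors -> r = 0
  rep2 <- collinearity_report(data.frame(a = x, b = x))
  expect_equal(rep2$r, 1)
  o <- data.frame(a = c(-1, 0, 1, 0), b = c(0, -1, 0, 1))
  expect_equal(collinearity_report(o)$r, 0)
  # constant vector flagged as undefined
  k <- data.frame(a = x, b = rep(2, 5))
  expect_true(is.na(collinearity_report(k)$r))
})
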