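#' Spatial eigenvector (PCNM) axes
#'
#' Principal coordinates of a truncated neighbour matrix of square
#' centroids: Euclidean distances are truncated at the longest edge of the
#' minimum spanning tree (larger distances replaced by four times the
#' threshold), the matrix is double-centred and eigen-decomposed, and the
#' eigenvectors of the two largest positive eigenvalues are returned as
#' spatial autocorrelation controls. Delegates to `vegan::pcnm` and then
#' unit-normalises each axis and fixes its sign so the first nonzero
#' loading is positive.
#'
#' @param centroids data frame or matrix with columns `x`, `y` (at least 3
#'   non-collinear points).
#' @return Tibble `pcnm1`, `pcnm2` (one row per centroid), eigenvalues in
#'   attribute `"eigenvalues"`.
#' @export
pcnm_axes <- function(centroids) {
  xy <- as.matrix(as.data.frame(centroids)[, c("x", "y")])
  if (nrow(xy) < 3) stop("need at least 3 centroids")
  pc <- vegan::pcnm(stats::dist(xy))
  if (sum(pc$values > 0) < 2) stop("fewer than 2 positive PCNM eigenvalues")
  v <- pc$vectors[, 1:2, drop = FALSE]
  v <- apply(v, 2, function(col) {
    col <- col / sqrt(sum(col^2))
    nz <- which(abs(col) > 1e-12)[1]
    if (!is.na(nz) && col[nz] < 0) col <- -col
    col
  })
  out <- tibble::tibble(pcnm1 = unname(v[, 1]), pcnm2 = unname(v[, 2]))
  attr(out, "eigenvalues") <- pc$values[1:2]
  out
}

#' Model formulations of the persistence suite
#'
#' The five formulations span a complexity gradient over the two
#' environmental change variables, always on top of the control set
#' (recorder effort, microclimate, two PCNM axes):
#' 1 controls only; 2 + land conversion; 3 + temperature change;
#' 4 additive; 5 interactive (conversion x warming).
#'
#' @param formulation integer 1-5.
#' @param controls control variable names.
#' @return Character vector of term names (`"L:dT"` for the interaction).
#' @export
formulation_terms <- function(formulation,
                              controls = c("E", "M", "pcnm1", "pcnm2")) {
  env <- switch(as.character(formulation),
    "1" = character(),
    "2" = "L",
    "3" = "dT",
    "4" = c("L", "dT"),
    "5" = c("L", "dT", "L:dT"),
    stop("formulation must be 1-5")
  )
  c(env, controls)
}

# standardized design matrix for a term set; returns X, scales, term names
build_design <- function(data, terms) {
  plain <- setdiff(terms, "L:dT")
  missing <- setdiff(plain, names(data))
  if (length(missing) > 0) {
    stop("missing model variables: ", paste(missing, collapse = ", "))
  }
  sc <- lapply(data[plain], function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("constant covariate in design")
    c(mean = mean(v), sd = s)
  })
  z <- matrix(0, nrow(data), length(plain), dimnames = list(NULL, plain))
  for (v in plain) z[, v] <- (data[[v]] - sc[[v]]["mean"]) / sc[[v]]["sd"]
  X <- cbind(`(Intercept)` = rep(1, nrow(data)), z)
  if ("L:dT" %in% terms) {
    X <- cbind(X, `L:dT` = z[, "L"] * z[, "dT"])
  }
  list(X = X, scales = sc)
}

# z-scale coefficients -> raw covariate scale
unstandardize_coefs <- function(bz, scales) {
  b <- bz
  nm <- names(bz)
  for (v in names(scales)) {
    if (v %in% nm) b[v] <- bz[v] / scales[[v]]["sd"]
  }
  if ("L:dT" %in% nm) {
    sL <- scales[["L"]]["sd"]; mL <- scales[["L"]]["mean"]
    sT <- scales[["dT"]]["sd"]; mT <- scales[["dT"]]["mean"]
    b["L:dT"] <- bz["L:dT"] / (sL * sT)
    b["L"] <- b["L"] - bz["L:dT"] * mT / (sL * sT)
    b["dT"] <- b["dT"] - bz["L:dT"] * mL / (sL * sT)
  }
  b0 <- bz["(Intercept)"]
  for (v in names(scales)) {
    if (v %in% nm) b0 <- b0 - bz[v] * scales[[v]]["mean"] / scales[[v]]["sd"]
  }
  if ("L:dT" %in% nm) {
    b0 <- b0 + bz["L:dT"] *
      (scales[["L"]]["mean"] * scales[["dT"]]["mean"]) /
      (scales[["L"]]["sd"] * scales[["dT"]]["sd"])
  }
  b["(Intercept)"] <- b0
  b
}

#' Fit one logistic persistence model
#'
#' Maximum-likelihood logistic regression of persistence (1) /
#' extirpation (0) on the formulation's terms. Covariates are z-scored
#' internally for IRLS conditioning; the fit is polished by Newton steps to
#' a score-vector norm below `tol`, and coefficients are reported
#' back-transformed to the raw covariate scale (the two parameterisations
#' have identical likelihood).
#'
#' @param data tibble with outcome `y` and the model variables.
#' @param formulation integer 1-5 (see [formulation_terms()]).
#' @param controls control variable names.
#' @param tol score-norm convergence tolerance (default 1e-8).
#' @param max_iter Newton iteration cap (default 100).
#' @return A `persist_fit`: coefficients on both scales, log-likelihood,
#'   AIC, convergence diagnostics, and the data needed for prediction.
#' @export
fit_logistic <- function(data, formulation = 5,
                         controls = c("E", "M", "pcnm1", "pcnm2"),
                         tol = 1e-8, max_iter = 100) {
  terms <- formulation_terms(formulation, controls)
  des <- build_design(data, terms)
  X <- des$X
  y <- data$y
  stopifnot(all(y %in% c(0, 1)))
  if (nrow(X) <= ncol(X)) stop("need n > number of parameters")

  fit0 <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = max_iter))
  )
  beta <- fit0$coefficients
  converged <- fit0$converged && all(is.finite(beta))
  grad_norm <- Inf
  if (converged) {
    for (it in seq_len(25)) {  # Newton polish to score norm < tol
      p <- stats::plogis(drop(X %*% beta))
      g <- drop(crossprod(X, y - p))
      grad_norm <- sqrt(sum(g^2))
      if (grad_norm < tol) break
      W <- p * (1 - p)
      H <- crossprod(X, X * W)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) { converged <- FALSE; break }
      beta <- beta + step
    }
    if (!is.finite(grad_norm) || grad_norm >= tol) converged <- FALSE
  }
  p <- stats::plogis(drop(X %*% beta))
  ll <- sum(stats::dbinom(y, 1, p, log = TRUE))
  k <- ncol(X)
  structure(list(
    formulation = formulation,
    terms = terms,
    coefficients_z = beta,
    coefficients = unstandardize_coefs(beta, des$scales),
    scales = des$scales,
    logLik = ll,
    aic = 2 * k - 2 * ll,
    k = k,
    n = nrow(X),
    converged = converged,
    gradient_norm = grad_norm,
    data = data[, c("y", setdiff(terms, "L:dT")), drop = FALSE]
  ), class = "persist_fit")
}

#' @export
print.persist_fit <- function(x, ...) {
  cat("<persist_fit> formulation ", x$formulation, ", n = ", x$n,
      ", AIC = ", round(x$aic, 2),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted persistence probability
#'
#' @param object a `persist_fit`.
#' @param newdata data frame with the fit's variables (defaults to the
#'   training data).
#' @param ... unused.
#' @export
predict.persist_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  plain <- setdiff(object$terms, "L:dT")
  b <- object$coefficients
  eta <- rep(b["(Intercept)"], nrow(newdata))
  for (v in plain) eta <- eta + b[v] * newdata[[v]]
  if ("L:dT" %in% object$terms) {
    eta <- eta + b["L:dT"] * newdata$L * newdata$dT
  }
  stats::plogis(unname(eta))
}

#' @rdname fit_logistic
#' @param x a `persist_fit`.
#' @param ... unused.
#' @method tidy persist_fit
#' @export
tidy.persist_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 estimate_std = unname(x$coefficients_z))
}

#' @rdname fit_logistic
#' @method glance persist_fit
#' @export
glance.persist_fit <- function(x, ...) {
  tibble::tibble(formulation = x$formulation, n = x$n, k = x$k,
                 logLik = x$logLik, AIC = x$aic, converged = x$converged)
}

#' Fit all five formulations for one unit
#'
#' @inheritParams fit_logistic
#' @param formulations which formulations to fit (default 1:5).
#' @return Tibble `formulation`, `fit` (list column), `k`, `logLik`, `AIC`,
#'   `converged`.
#' @export
fit_formulations <- function(data, formulations = 1:5,
                             controls = c("E", "M", "pcnm1", "pcnm2")) {
  rows <- lapply(formulations, function(f) {
    fit <- tryCatch(fit_logistic(data, f, controls), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(formulation = f, fit = list(NULL), k = NA_integer_,
                            logLik = NA_real_, AIC = NA_real_,
                            converged = FALSE))
    }
    tibble::tibble(formulation = f, k = fit$k, logLik = fit$logLik,
                   AIC = fit$aic, converged = fit$converged,
                   fit = list(fit))
  })
  dplyr::bind_rows(rows)
}

#' AIC model selection
#'
#' Picks the converged fit with minimum AIC; exact ties go to the fit with
#' fewer parameters. Non-converged formulations are excluded with a
#' warning; if none converged the unit is excluded (error).
#'
#' @param fits tibble from [fit_formulations()].
#' @return The winning `persist_fit`, with `delta_aic` (tibble of all
#'   formulations' AIC minus the best) attached as attribute.
#' @export
select_best <- function(fits) {
  ok <- fits[fits$converged & is.finite(fits$AIC), ]
  if (nrow(ok) == 0) stop("no converged fits to select from")
  if (nrow(ok) < nrow(fits)) {
    warning(nrow(fits) - nrow(ok), " non-converged fit(s) excluded")
  }
  best_i <- order(ok$AIC, ok$k)[1]
  best <- ok$fit[[best_i]]
  attr(best, "delta_aic") <- tibble::tibble(
    formulation = fits$formulation,
    delta_aic = fits$AIC - ok$AIC[best_i]
  )
  best
}

#' Average marginal effect of a predictor
#'
#' `AME = unit * mean_i (dp_i/dv)` over the observed squares, with the
#' logistic chain rule `dp/dv = (b_v + b_int * w_i) * p_i (1 - p_i)` (w is
#' the interaction partner where the fit includes one). The conventional
#' units are 0.1 degrees C/decade for warming and 0.1 (ten percentage
#' points) for land conversion, so the AME reads as the change in
#' persistence probability per that increment. Requesting a variable the
#' fit does not contain is an error, never a silent zero.
#'
#' @param fit a `persist_fit`.
#' @param variable variable name (e.g. `"dT"` or `"L"`).
#' @param unit increment in raw variable units (default 0.1).
#' @param data evaluation data (defaults to training data).
#' @return Tibble `variable`, `unit`, `ame`.
#' @export
average_marginal_effect <- function(fit, variable, unit = 0.1, data = NULL) {
  if (!variable %in% fit$terms) {
    stop("variable '", variable, "' is not in the fitted model")
  }
  if (is.null(data)) data <- fit$data
  b <- fit$coefficients
  p <- predict.persist_fit(fit, data)
  slope <- rep(b[variable], nrow(data))
  if ("L:dT" %in% fit$terms && variable %in% c("L", "dT")) {
    partner <- if (variable == "L") "dT" else "L"
    slope <- slope + b["L:dT"] * data[[partner]]
  }
  tibble::tibble(variable = variable, unit = unit,
                 ame = unit * mean(slope * p * (1 - p)))
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates outcomes from the fitted persistence probabilities, refits the
#' same formulation, and returns percentile intervals for the raw-scale
#' coefficients (and the AME of any requested variables). Seeded and
#' reproducible; refit failures are dropped and counted.
#'
#' @param fit a `persist_fit`.
#' @param n_sim bootstrap replicates (default 100).
#' @param level interval level (default 0.95).
#' @param seed RNG seed.
#' @param ame_variables variables whose AME to bootstrap too.
#' @param ame_unit unit for bootstrapped AMEs.
#' @return Tibble `term`, `estimate`, `lower`, `upper` with attribute
#'   `"n_failed"`.
#' @export
bootstrap_ci <- function(fit, n_sim = 100, level = 0.95, seed = 1,
                         ame_variables = character(), ame_unit = 0.1) {
  set.seed(seed)
  p_hat <- predict.persist_fit(fit)
  data <- fit$data
  draws <- vector("list", n_sim)
  n_failed <- 0
  for (s in seq_len(n_sim)) {
    db <- data
    db$y <- stats::rbinom(nrow(data), 1, p_hat)
    refit <- tryCatch(
      fit_logistic(db, fit$formulation,
                   controls = intersect(fit$terms, c("E", "M", "pcnm1", "pcnm2"))),
      error = function(e) NULL
    )
    if (is.null(refit) || !refit$converged) { n_failed <- n_failed + 1; next }
    vals <- refit$coefficients
    for (v in ame_variables) {
      vals[paste0("AME_", v)] <-
        average_marginal_effect(refit, v, ame_unit)$ame
    }
    draws[[s]] <- vals
  }
  draws <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  if (is.null(draws) || nrow(draws) == 0) stop("all bootstrap refits failed")
  a <- (1 - level) / 2
  est <- fit$coefficients
  for (v in ame_variables) {
    est[paste0("AME_", v)] <- average_marginal_effect(fit, v, ame_unit)$ame
  }
  out <- tibble::tibble(
    term = colnames(draws),
    estimate = unname(est[colnames(draws)]),
    lower = apply(draws, 2, stats::quantile, probs = a),
    upper = apply(draws, 2, stats::quantile, probs = 1 - a)
  )
  attr(out, "n_failed") <- n_failed
  out
}

#' Taxon-level mixed logistic model
#'
#' The formulation's fixed effects plus a species random intercept, fitted
#' with `lme4::glmer` (logit link). Covariates are z-scored internally;
#' fixed effects are reported back-transformed to the raw scale. A singular
#' fit (variance estimated at the boundary) is reported, not hidden.
#'
#' @param data tibble with `y`, `species_id` and the model variables.
#' @param formulation integer 1-5.
#' @param controls control variable names.
#' @return A `persist_mixed_fit` with coefficients, `sigma2_u`, AIC,
#'   log-likelihood, the fixed-effect linear predictor variance and flags.
#' @export
fit_mixed_logistic <- function(data, formulation = 5,
                               controls = c("E", "M", "pcnm1", "pcnm2")) {
  if (length(unique(data$species_id)) < 2) stop("need at least 2 species")
  terms <- formulation_terms(formulation, controls)
  des <- build_design(data, terms)
  zd <- as.data.frame(des$X[, -1, drop = FALSE])
  names(zd) <- make.names(colnames(des$X)[-1])
  zd$y <- data$y
  zd$species_id <- data$species_id
  rhs <- paste(c(names(zd)[!names(zd) %in% c("y", "species_id")],
                 "(1 | species_id)"), collapse = " + ")
  fml <- stats::as.formula(paste("y ~", rhs))
  fit <- lme4::glmer(fml, data = zd, family = stats::binomial())
  vc <- lme4::VarCorr(fit)
  sigma2_u <- as.numeric(vc$species_id[1, 1])
  fe <- lme4::fixef(fit)
  names(fe) <- c("(Intercept)", colnames(des$X)[-1])
  eta_fixed <- drop(des$X %*% fe)
  structure(list(
    formulation = formulation,
    terms = terms,
    coefficients_z = fe,
    coefficients = unstandardize_coefs(fe, des$scales),
    sigma2_u = sigma2_u,
    var_fixed = stats::var(eta_fixed),
    logLik = as.numeric(stats::logLik(fit)),
    aic = stats::AIC(fit),
    k = length(fe) + 1,
    n = nrow(zd),
    singular = lme4::isSingular(fit),
    converged = length(fit@optinfo$conv$lme4$messages) == 0,
    model = fit
  ), class = "persist_mixed_fit")
}

#' @export
print.persist_mixed_fit <- function(x, ...) {
  cat("<persist_mixed_fit> formulation ", x$formulation, ", n = ", x$n,
      ", AIC = ", round(x$aic, 2), ", sigma2_u = ", signif(x$sigma2_u, 3),
      if (x$singular) " (singular)", "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_mixed_logistic
#' @param x a `persist_mixed_fit`.
#' @param ... unused.
#' @method tidy persist_mixed_fit
#' @export
tidy.persist_mixed_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 estimate_std = unname(x$coefficients_z))
}

#' @rdname fit_mixed_logistic
#' @method glance persist_mixed_fit
#' @export
glance.persist_mixed_fit <- function(x, ...) {
  r2 <- r2_mixed(x)
  tibble::tibble(formulation = x$formulation, n = x$n, k = x$k,
                 logLik = x$logLik, AIC = x$aic, sigma2_u = x$sigma2_u,
                 r2_marginal = r2$r2_marginal,
                 r2_conditional = r2$r2_conditional,
                 singular = x$singular, converged = x$converged)
}

#' Latent-scale R-squared for mixed logistic models
#'
#' The logistic latent-residual convention: with fixed-effect linear
#' predictor variance `s2_f` and random-intercept variance `s2_u`,
#' `R2_marginal = s2_f / (s2_f + s2_u + pi^2/3)` and
#' `R2_conditional = (s2_f + s2_u) / (s2_f + s2_u + pi^2/3)`.
#'
#' @param fit a `persist_mixed_fit`, or a number (`s2_f`) together with
#'   `sigma2_u`.
#' @param sigma2_u random-intercept variance when `fit` is numeric.
#' @return Tibble `r2_marginal`, `r2_conditional`.
#' @export
r2_mixed <- function(fit, sigma2_u = NULL) {
  if (inherits(fit, "persist_mixed_fit")) {
    s2f <- fit$var_fixed; s2u <- fit$sigma2_u
  } else {
    s2f <- fit; s2u <- sigma2_u
  }
  denom <- s2f + s2u + pi^2 / 3
  tibble::tibble(r2_marginal = s2f / denom,
                 r2_conditional = (s2f + s2u) / denom)
}

#' Pairwise Pearson collinearity report
#'
#' Pearson r, degrees of freedom (n - 2) and a two-sided p-value from
#' `t = r sqrt(d.f.) / sqrt(1 - r^2)` for every pair of the named columns —
#' the standard pre-modelling collinearity screen.
#'
#' @param data data frame of complete cases over `vars`.
#' @param vars column names to correlate (default all numeric columns).
#' @return Tibble `var1`, `var2`, `n`, `r`, `df`, `p`.
#' @export
collinearity_report <- function(data, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  df <- data[stats::complete.cases(data[, vars]), vars]
  if (nrow(df) < 3) stop("need at least 3 complete rows")
  pairs <- utils::combn(vars, 2)
  rows <- apply(pairs, 2, function(pr) {
    x <- df[[pr[1]]]; y <- df[[pr[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(var1 = pr[1], var2 = pr[2], n = length(x),
                            r = NA_real_, df = length(x) - 2, p = NA_real_))
    }
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    dfree <- length(x) - 2
    tt <- r * sqrt(dfree) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    tibble::tibble(var1 = pr[1], var2 = pr[2], n = length(x),
                   r = r, df = dfree, p = 2 * stats::pt(-abs(tt), dfree))
  })
  dplyr::bind_rows(rows)
}
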