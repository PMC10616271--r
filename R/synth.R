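#' Configuration for the synthetic world generator
#'
#' Bundles every knob of the synthetic landscape: grid dimensions, the
#' historical land-cover composition, the per-square conversion intensity
#' distribution, the warming surface, the conversion-warming correlation,
#' per-taxon species coefficient distributions, and recording effort. The
#' defaults emulate the study design the package targets: ~10 km coarse
#' squares subdivided into fine pixels, six harmonized land categories with
#' semi-natural grassland dominant historically (65%), a smooth warming
#' surface of ~0.25 degrees C/decade correlated with conversion at Pearson
#' r = 0.5 (the reported per-taxon range is 0.38-0.58), and two recording
#' periods with effort-biased detection.
#'
#' @param seed integer RNG seed; the whole world is a deterministic function
#'   of the config including this seed.
#' @param n_squares_x,n_squares_y coarse squares along each axis.
#' @param fine_per_square fine pixels per coarse-square edge.
#' @param n_categories number of harmonized land categories.
#' @param historical_proportions category fractions of the historical
#'   landscape, summing to 1. Default: urban .04, semi-natural grassland .65,
#'   arable .22, woodland .06, water .03, improved grassland 0.
#' @param conversion_beta_params shape1/shape2 of the Beta distribution of
#'   per-square conversion intensity L.
#' @param conversion_weights relative propensity of each category's pixels
#'   to be the ones converted within a square.
#' @param transition_kernel 6x6 row-stochastic destination kernel for
#'   converted pixels (zero diagonal); the default sends converted grassland
#'   mostly to improved grassland and arable.
#' @param climate_mean_trend,climate_sd mean and SD of the warming surface,
#'   degrees C per decade.
#' @param rho_LT target Pearson correlation between land conversion and
#'   warming across squares, |rho_LT| < 1.
#' @param field_bandwidth_fine,field_bandwidth_coarse Gaussian smoothing
#'   bandwidths (pixels / squares) of the latent fields.
#' @param species_spec list of per-taxon specs from [taxon_spec()].
#' @param effort_spec list with `meanlog`, `sdlog` of the lognormal
#'   square-by-period recording effort (use `sdlog = 0` for uniform effort).
#' @param period_years list of two `(start, end)` year pairs.
#' @param climate_noise_sd SD of interannual noise around the linear
#'   temperature trend in the emitted climate series.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_squares_x = 16L, n_squares_y = 16L,
                         fine_per_square = 10L,
                         n_categories = 6L,
                         historical_proportions =
                           c(urban = 0.04, grassland = 0.65, arable = 0.22,
                             woodland = 0.06, water = 0.03, improved = 0.00),
                         conversion_beta_params = c(2, 3),
                         conversion_weights =
                           c(0.25, 1.6, 0.8, 0.6, 0.15, 0.8),
                         transition_kernel = default_transition_kernel(),
                         climate_mean_trend = 0.25, climate_sd = 0.08,
                         rho_LT = 0.5,
                         field_bandwidth_fine = 3,
                         field_bandwidth_coarse = 1.5,
                         species_spec = list(
                           taxon_spec("plants", n = 40),
                           taxon_spec("birds", n = 20)
                         ),
                         effort_spec = list(meanlog = log(2), sdlog = 0.5),
                         period_years = list(c(1930, 1960), c(2000, 2015)),
                         climate_noise_sd = 0.25) {
  stopifnot(n_squares_x > 0, n_squares_y > 0, fine_per_square > 0,
            n_categories > 0)
  if (abs(sum(historical_proportions) - 1) > 1e-9) {
    stop("historical_proportions must sum to 1")
  }
  if (length(historical_proportions) != n_categories) {
    stop("historical_proportions length must equal n_categories")
  }
  if (abs(rho_LT) >= 1) stop("|rho_LT| must be < 1")
  if (any(conversion_beta_params <= 0)) {
    stop("conversion_beta_params must be positive")
  }
  k <- transition_kernel
  if (!all(abs(rowSums(k) - 1) < 1e-9) || any(diag(k) != 0)) {
    stop("transition_kernel must be row-stochastic with zero diagonal")
  }
  structure(as.list(environment()), class = "synth_config")
}

#' @rdname synth_config
#' @param taxon taxon label.
#' @param n number of species.
#' @param formulation generating model per species: an integer 1-5, a vector
#'   recycled over species, or `"mix"` to sample formulations uniformly.
#'   1 = controls only, 2 = +conversion, 3 = +warming, 4 = additive,
#'   5 = interactive.
#' @param b0 mean/SD of the persistence intercept (logit scale).
#' @param bmag range of |effect| for warming/conversion terms, on the
#'   standardized-covariate (per-SD) scale; signs are drawn at random.
#' @param bint_mag range of |interaction| for formulation-5 species.
#' @param p_positive probability a drawn main effect is positive.
#' @param bE,bM mean/SD of the effort and microclimate control effects.
#' @param occ_logit mean/SD of the period-1 occupancy logit.
#' @param col_logit colonisation logit (period-2 gains in unoccupied squares).
#' @param detect range of per-species detectability q.
#' @export
taxon_spec <- function(taxon, n = 30L, formulation = "mix",
                       b0 = c(1.2, 0.4),
                       bmag = c(0.5, 1.2), bint_mag = c(0.5, 1.0),
                       p_positive = 0.6,
                       bE = c(0.2, 0.05), bM = c(0.15, 0.05),
                       occ_logit = c(0.4, 0.5), col_logit = -2.5,
                       detect = c(0.25, 0.6)) {
  stopifnot(n > 0)
  as.list(environment())
}

#' @rdname synth_config
#' @export
default_transition_kernel <- function() {
  k <- rbind(
    c(0.00, 0.10, 0.30, 0.20, 0.10, 0.30),  # urban
    c(0.12, 0.00, 0.28, 0.08, 0.02, 0.50),  # grassland
    c(0.15, 0.05, 0.00, 0.10, 0.02, 0.68),  # arable
    c(0.10, 0.15, 0.25, 0.00, 0.02, 0.48),  # woodland
    c(0.20, 0.20, 0.20, 0.20, 0.00, 0.20),  # water
    c(0.25, 0.10, 0.45, 0.15, 0.05, 0.00)   # improved
  )
  dimnames(k) <- NULL
  k
}

# Smooth standard-normal random field: iid N(0,1) circularly convolved with
# a Gaussian kernel whose weights are normalized so sum(w^2) = 1, keeping
# the pointwise marginal exactly N(0,1) while inducing spatial correlation.
smooth_field <- function(n_row, n_col, bandwidth) {
  z <- matrix(stats::rnorm(n_row * n_col), n_row, n_col)
  if (bandwidth <= 0) return(z)
  dr <- pmin(0:(n_row - 1), n_row - 0:(n_row - 1))
  dc <- pmin(0:(n_col - 1), n_col - 0:(n_col - 1))
  k <- exp(-outer(dr^2, dc^2, "+") / (2 * bandwidth^2))
  k <- k / sqrt(sum(k^2))
  out <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
    (n_row * n_col)
  out
}

derive_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 7919 + 104729 * k) %%
               (.Machine$integer.max - 1)) + 1L
}

#' Generate a complete synthetic world
#'
#' Builds, from one seeded configuration: a historical categorical raster
#' (smoothed latent Gaussian field thresholded at empirical quantiles so the
#' realized composition matches `historical_proportions`), a modern raster
#' obtained by converting a Beta-distributed fraction of each square's
#' pixels through the transition kernel, a spatially smooth warming surface
#' whose realized correlation with land conversion equals `rho_LT` (the
#' latent mixing weight is solved numerically on the realized fields; an
#' unattainable `rho_LT` is an explicit error), a microclimate surface,
#' lognormal recording effort, species with known logit-linear persistence
#' models, period-1/2 true occupancy, and effort-biased detection records.
#'
#' @param config a [synth_config()].
#' @return A `synthetic_world` list with elements `config`, `raster_hist`,
#'   `raster_mod`, `square_table`, `records`, `climate_series`, and `truth`
#'   (species coefficients on both the standardized and raw covariate
#'   scales, occupancy/survival matrices, and the solved mixing weight).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nx <- config$n_squares_x; ny <- config$n_squares_y
  fps <- config$fine_per_square
  n_sq <- nx * ny
  npx <- nx * fps; npy <- ny * fps

  # --- historical raster: rank-thresholded smooth field -------------------
  fine <- smooth_field(npy, npx, config$field_bandwidth_fine)
  props <- config$historical_proportions
  n_pix <- npx * npy
  counts <- floor(props * n_pix)
  rem <- n_pix - sum(counts)
  if (rem > 0) {  # distribute rounding remainder to largest fractions
    extra <- order(props * n_pix - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  cat_of_rank <- rep.int(seq_along(props), counts)
  hist_vals <- matrix(0L, npy, npx)
  hist_vals[order(fine)] <- cat_of_rank
  raster_hist <- cat_raster(hist_vals, resolution = 1, origin = c(0, 0),
                            categories = seq_len(config$n_categories))

  # --- latent coarse fields, empirically orthonormalized ------------------
  z1 <- as.vector(smooth_field(ny, nx, config$field_bandwidth_coarse))
  z2 <- as.vector(smooth_field(ny, nx, config$field_bandwidth_coarse))
  z1 <- (z1 - mean(z1)) / stats::sd(z1)
  z2 <- stats::residuals(stats::lm(z2 ~ z1))
  z2 <- (z2 - mean(z2)) / stats::sd(z2)

  dT <- config$climate_mean_trend + config$climate_sd * z1

  a <- config$conversion_beta_params[1]; b <- config$conversion_beta_params[2]
  L_of <- function(r) stats::qbeta(stats::pnorm(r * z1 + sqrt(1 - r^2) * z2),
                                   a, b)
  gap <- function(r) stats::cor(L_of(r), dT) - config$rho_LT
  lo <- gap(-0.999); hi <- gap(0.999)
  if (is.na(lo) || is.na(hi) || lo * hi > 0) {
    stop("target rho_LT = ", config$rho_LT,
         " is unattainable with the configured smoothness/Beta settings")
  }
  mix <- stats::uniroot(gap, c(-0.999, 0.999), tol = 1e-9)$root
  L_target <- L_of(mix)

  # --- modern raster: per-square pixel conversion via kernel --------------
  mod_vals <- hist_vals
  sq_idx <- square_index(raster_hist, fps)
  w_cat <- config$conversion_weights
  for (i in seq_len(n_sq)) {
    pix <- which(sq_idx == i)
    n_conv <- round(L_target[i] * length(pix))
    if (n_conv == 0) next
    cats <- hist_vals[pix]
    sel <- sample(pix, n_conv, prob = w_cat[cats])
    from <- hist_vals[sel]
    for (cc in unique(from)) {
      ii <- sel[from == cc]
      mod_vals[ii] <- sample.int(config$n_categories, length(ii),
                                 replace = TRUE,
                                 prob = config$transition_kernel[cc, ])
    }
  }
  raster_mod <- cat_raster(mod_vals, resolution = 1, origin = c(0, 0),
                           categories = seq_len(config$n_categories))

  # --- covariate table ----------------------------------------------------
  cent <- square_centroids(raster_hist, fps)
  M <- as.vector(smooth_field(ny, nx, config$field_bandwidth_coarse))
  E1 <- stats::rlnorm(n_sq, config$effort_spec$meanlog, config$effort_spec$sdlog)
  E2 <- stats::rlnorm(n_sq, config$effort_spec$meanlog, config$effort_spec$sdlog)
  L_real <- land_conversion(raster_hist, raster_mod, fps)$L
  pc <- pcnm_axes(cent[, c("x", "y")])
  square_table <- dplyr::mutate(cent, L = L_real, dT = dT, M = M,
                                E1 = E1, E2 = E2,
                                pcnm1 = pc$pcnm1, pcnm2 = pc$pcnm2)

  zs <- function(v) (v - mean(v)) / stats::sd(v)
  Z <- list(L = zs(L_real), dT = zs(dT), E = zs(E1), M = zs(M))
  scales <- tibble::tibble(
    variable = c("L", "dT", "E", "M"),
    mean = c(mean(L_real), mean(dT), mean(E1), mean(M)),
    sd = c(stats::sd(L_real), stats::sd(dT), stats::sd(E1), stats::sd(M))
  )

  # --- species ------------------------------------------------------------
  species <- draw_species(config$species_spec)
  species <- add_raw_betas(species, scales)
  n_species <- nrow(species)

  eta <- outer(rep(1, n_sq), species$b0) +
    outer(Z$dT, species$bT) + outer(Z$L, species$bL) +
    outer(Z$dT * Z$L, species$bint) +
    outer(Z$E, species$bE) + outer(Z$M, species$bM)
  surv_prob <- stats::plogis(eta)

  occ1 <- matrix(stats::runif(n_sq * n_species), n_sq, n_species) <
    stats::plogis(outer(rep(1, n_sq), species$occ_logit))
  survived <- matrix(stats::runif(n_sq * n_species), n_sq, n_species) < surv_prob
  # colonisation is dispersal-limited: per-square gain probability scales
  # with the species' period-1 prevalence
  col_prob <- stats::plogis(species$col_logit) * colMeans(occ1)
  colonised <- matrix(stats::runif(n_sq * n_species), n_sq, n_species) <
    outer(rep(1, n_sq), col_prob)
  occ2 <- (occ1 & survived) | (!occ1 & colonised)
  dimnames(occ1) <- dimnames(occ2) <- dimnames(surv_prob) <-
    dimnames(survived) <- list(NULL, species$species_id)

  # --- climate series consistent with dT ----------------------------------
  years <- seq(config$period_years[[1]][1], config$period_years[[2]][2])
  climate_series <- tibble::tibble(
    square_id = rep(seq_len(n_sq), each = length(years)),
    year = rep(years, times = n_sq),
    temp = 8 + rep(dT / 10, each = length(years)) *
      (rep(years, times = n_sq) - mean(years)) +
      stats::rnorm(n_sq * length(years), sd = config$climate_noise_sd)
  )

  world <- structure(list(
    config = config,
    raster_hist = raster_hist, raster_mod = raster_mod,
    square_table = square_table,
    climate_series = climate_series,
    truth = list(species = species, occ1 = occ1, occ2 = occ2,
                 survived = survived, surv_prob = surv_prob,
                 z = Z, scales = scales, mixing_weight = mix)
  ), class = "synthetic_world")
  world$records <- generate_records(world)
  world
}

draw_species <- function(species_spec) {
  sp_list <- lapply(species_spec, function(ts) {
    n <- ts$n
    form <- ts$formulation
    if (identical(form, "mix")) {
      form <- sample(1:5, n, replace = TRUE)
    } else {
      form <- rep_len(as.integer(form), n)
    }
    draw_mag <- function(rng) stats::runif(n, rng[1], rng[2])
    sgn <- function() ifelse(stats::runif(n) < ts$p_positive, 1, -1)
    bT <- ifelse(form %in% c(3, 4, 5), sgn() * draw_mag(ts$bmag), 0)
    bL <- ifelse(form %in% c(2, 4, 5), sgn() * draw_mag(ts$bmag), 0)
    bint <- ifelse(form == 5, sgn() * draw_mag(ts$bint_mag), 0)
    tibble::tibble(
      taxon = ts$taxon,
      formulation = form,
      b0 = stats::rnorm(n, ts$b0[1], ts$b0[2]),
      bT = bT, bL = bL, bint = bint,
      bE = stats::rnorm(n, ts$bE[1], ts$bE[2]),
      bM = stats::rnorm(n, ts$bM[1], ts$bM[2]),
      occ_logit = stats::rnorm(n, ts$occ_logit[1], ts$occ_logit[2]),
      col_logit = ts$col_logit,
      q = stats::runif(n, ts$detect[1], ts$detect[2])
    )
  })
  species <- dplyr::bind_rows(sp_list)
  species$species_id <- sprintf("sp%03d", seq_len(nrow(species)))
  dplyr::relocate(species, "species_id")
}

# convert standardized-scale coefficients to the raw covariate scale
add_raw_betas <- function(species, scales) {
  s <- stats::setNames(scales$sd, scales$variable)
  m <- stats::setNames(scales$mean, scales$variable)
  dplyr::mutate(
    species,
    bint_raw = .data$bint / (s["L"] * s["dT"]),
    bT_raw = .data$bT / s["dT"] - .data$bint * m["L"] / (s["dT"] * s["L"]),
    bL_raw = .data$bL / s["L"] - .data$bint * m["dT"] / (s["L"] * s["dT"]),
    bE_raw = .data$bE / s["E"],
    bM_raw = .data$bM / s["M"],
    b0_raw = .data$b0 - .data$bT * m["dT"] / s["dT"] -
      .data$bL * m["L"] / s["L"] - .data$bE * m["E"] / s["E"] -
      .data$bM * m["M"] / s["M"] +
      .data$bint * m["dT"] * m["L"] / (s["dT"] * s["L"])
  )
}

#' Generate detection records from a synthetic world
#'
#' Detection of an occupied square-period follows
#' `P(detect) = 1 - (1 - q_j)^E_it` with per-species detectability `q_j` and
#' square-by-period effort `E_it`; zero effort yields no records. Seeded
#' deterministically from the world's config.
#'
#' @param world a `synthetic_world`.
#' @param effort override tibble with `square_id`, `E1`, `E2` (defaults to
#'   the world's effort columns).
#' @return Tibble `species_id`, `taxon`, `square_id`, `period`, `year`.
#' @export
generate_records <- function(world, effort = NULL) {
  st <- world$square_table
  if (!is.null(effort)) {
    st <- dplyr::left_join(dplyr::select(st, -"E1", -"E2"), effort,
                           by = "square_id")
  }
  if (any(st$E1 < 0 | st$E2 < 0)) stop("effort must be non-negative")
  set.seed(derive_seed(world$config$seed, 2L))
  sp <- world$truth$species
  py <- world$config$period_years
  recs <- list()
  occ <- list(world$truth$occ1, world$truth$occ2)
  eff <- list(st$E1, st$E2)
  for (t in 1:2) {
    p_det <- 1 - t(outer(1 - sp$q, eff[[t]], function(q1, e) q1^e))
    det <- occ[[t]] & (matrix(stats::runif(length(p_det)), nrow(p_det)) < p_det)
    det[eff[[t]] == 0, ] <- FALSE
    hit <- which(det, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      recs[[t]] <- tibble::tibble(
        species_id = sp$species_id[hit[, 2]],
        taxon = sp$taxon[hit[, 2]],
        square_id = st$square_id[hit[, 1]],
        period = t,
        year = sample(seq(py[[t]][1], py[[t]][2]), nrow(hit), replace = TRUE)
      )
    }
  }
  out <- dplyr::bind_rows(recs)
  dplyr::arrange(out, .data$period, .data$species_id, .data$square_id)
}

#' True persistence outcomes of a synthetic world
#'
#' Persistence (1) / extirpation (0) of every occupied period-1 square,
#' straight from the generating truth (no detection noise) — the input for
#' parameter-recovery checks of the model suite.
#'
#' @param world a `synthetic_world`.
#' @return Tibble `species_id`, `taxon`, `square_id`, `y`.
#' @export
truth_outcomes <- function(world) {
  occ1 <- world$truth$occ1
  surv <- world$truth$survived
  sp <- world$truth$species
  hit <- which(occ1, arr.ind = TRUE)
  tibble::tibble(
    species_id = sp$species_id[hit[, 2]],
    taxon = sp$taxon[hit[, 2]],
    square_id = world$square_table$square_id[hit[, 1]],
    y = as.integer(surv[cbind(hit[, 1], hit[, 2])])
  )
}

#' Write / read a synthetic world fixture
#'
#' Persists the world as plain-text files: two ASCII-grid rasters, records
#' and square-covariate CSVs, a climate-series CSV, and a truth JSON
#' (species coefficients and the solved mixing weight). `read_fixture()`
#' round-trips them.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `write_fixture()` returns the file paths invisibly;
#'   `read_fixture()` returns a list of the re-read components.
#' @export
write_fixture <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    hist = file.path(dir, "landuse_hist.asc"),
    mod = file.path(dir, "landuse_mod.asc"),
    records = file.path(dir, "records.csv"),
    squares = file.path(dir, "squares.csv"),
    climate = file.path(dir, "climate.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_asc(world$raster_hist, paths$hist)
  write_asc(world$raster_mod, paths$mod)
  utils::write.csv(world$records, paths$records, row.names = FALSE)
  utils::write.csv(world$square_table, paths$squares, row.names = FALSE)
  utils::write.csv(world$climate_series, paths$climate, row.names = FALSE)
  jsonlite::write_json(
    list(species = world$truth$species,
         scales = world$truth$scales,
         mixing_weight = world$truth$mixing_weight,
         seed = world$config$seed),
    paths$truth, digits = NA, auto_unbox = TRUE
  )
  invisible(paths)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  list(
    raster_hist = read_asc(file.path(dir, "landuse_hist.asc")),
    raster_mod = read_asc(file.path(dir, "landuse_mod.asc")),
    records = tibble::as_tibble(
      utils::read.csv(file.path(dir, "records.csv"))),
    square_table = tibble::as_tibble(
      utils::read.csv(file.path(dir, "squares.csv"))),
    climate_series = tibble::as_tibble(
      utils::read.csv(file.path(dir, "climate.csv"))),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", x$config$n_squares_x, "x", x$config$n_squares_y,
      " squares, ", nrow(x$truth$species), " species, ",
      nrow(x$records), " records (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}
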