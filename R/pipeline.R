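#' Pipeline run configuration
#'
#' Collects every stage's settings: either a synthetic-world config or
#' paths to input files, the per-taxon standard neighbourhood frequencies,
#' thresholds, and the seed. Defaults mirror the analysis constants this
#' pipeline standardises on: 100 Frescalo neighbours, taxon-specific phi,
#' a 100-square range filter (exclusive), family-wise alpha 0.05, 100
#' bootstrap simulations.
#'
#' @param synth a [synth_config()] (or `NULL` when file inputs are given).
#' @param inputs named list of file paths (`hist`, `mod`, `records`,
#'   `squares`, `climate`) when not generating synthetically.
#' @param phi named vector of standard neighbourhood frequencies per taxon
#'   (defaults: birds .92, butterflies .86, macromoths .67, plants .75).
#' @param min_squares exclusive period-1 range-size threshold (default 100).
#' @param alpha family-wise level for the interaction assessment.
#' @param n_boot bootstrap simulations for AME intervals (0 disables).
#' @param n_neighbours,n_candidates Frescalo neighbourhood sizes.
#' @param climate_window optional `(start, end)` years for the temperature
#'   trend (defaults to all years present).
#' @param seed integer seed for the stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(synth = synth_config(),
                       inputs = NULL,
                       phi = c(birds = 0.92, butterflies = 0.86,
                               macromoths = 0.67, plants = 0.75),
                       min_squares = 100, alpha = 0.05, n_boot = 100,
                       n_neighbours = 100, n_candidates = 200,
                       climate_window = NULL,
                       seed = 1L) {
  stopifnot(all(phi > 0 & phi < 1))
  if (is.null(synth) && is.null(inputs)) {
    stop("either a synth config or input paths must be provided")
  }
  if (!is.null(inputs)) {
    missing <- names(inputs)[!vapply(inputs, file.exists, logical(1))]
    if (length(missing) > 0) {
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    }
  }
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with fields matching the `run_config()` arguments;
#'   a `synth:` section is passed to [synth_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) {
    y$synth <- do.call(synth_config, y$synth)
  }
  if (!is.null(y$phi)) y$phi <- unlist(y$phi)
  do.call(run_config, y)
}

#' Run the full persistence pipeline
#'
#' Executes land-use change, climate trend, outcome construction, Frescalo
#' effort/trend, the model suite with separation screening and AIC
#' selection, the interaction assessment, and cohort reporting, persisting
#' every stage's output as plain files in `out_dir`. Reruns with the same
#' config are byte-identical for the deterministic stages.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return A list with the run artefacts (invisible copies of what was
#'   written): `square_table`, `outcomes`, `frescalo` (per taxon),
#'   `model_results`, `interaction`, `assignments`, `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$synth)) {
    world <- stage("synth", {
      cfg <- config$synth
      cfg$seed <- config$seed
      generate_world(cfg)
    })
    hist <- world$raster_hist; mod <- world$raster_mod
    records <- world$records
    climate <- world$climate_series
    square_size <- config$synth$fine_per_square * hist$resolution
    micro <- dplyr::select(world$square_table, "square_id", "M")
    write_fixture(world, file.path(out_dir, "input"))
  } else {
    world <- NULL
    hist <- read_asc(config$inputs$hist)
    mod <- read_asc(config$inputs$mod)
    records <- tibble::as_tibble(utils::read.csv(config$inputs$records))
    climate <- tibble::as_tibble(utils::read.csv(config$inputs$climate))
    sq_in <- tibble::as_tibble(utils::read.csv(config$inputs$squares))
    micro <- dplyr::select(sq_in, "square_id", "M")
    square_size <- config$square_size %||%
      stop("square_size required with file inputs")
  }

  taxa <- sort(unique(records$taxon))
  no_phi <- setdiff(taxa, names(config$phi))
  if (length(no_phi) > 0) {
    stop("no phi configured for taxon/taxa: ", paste(no_phi, collapse = ", "))
  }

  # --- land-use change ----------------------------------------------------
  landuse <- stage("landuse", {
    fh <- category_fractions(hist, square_size)
    fm <- category_fractions(mod, square_size)
    change <- fractional_change(fh, fm)
    conv <- land_conversion(hist, mod, square_size)
    list(change = change, conversion = conv)
  })
  utils::write.csv(landuse$change, file.path(out_dir, "fractional_change.csv"),
                   row.names = FALSE)
  utils::write.csv(landuse$conversion, file.path(out_dir, "land_conversion.csv"),
                   row.names = FALSE)

  # --- climate ------------------------------------------------------------
  trend <- stage("climate", temperature_trend(climate, config$climate_window))
  utils::write.csv(trend, file.path(out_dir, "temperature_trend.csv"),
                   row.names = FALSE)

  # --- covariate table ----------------------------------------------------
  cent <- square_centroids(hist, square_size)
  pc <- stage("pcnm", pcnm_axes(cent))
  square_table <- cent |>
    dplyr::left_join(landuse$conversion[, c("square_id", "L")], by = "square_id") |>
    dplyr::left_join(trend[, c("square_id", "temp_trend")], by = "square_id") |>
    dplyr::rename(dT = "temp_trend") |>
    dplyr::left_join(micro, by = "square_id") |>
    dplyr::mutate(pcnm1 = pc$pcnm1, pcnm2 = pc$pcnm2)

  # --- outcomes -----------------------------------------------------------
  outcomes <- stage("outcomes",
                    outcomes_from_records(records, config$min_squares))
  utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"),
                   row.names = FALSE)

  # --- frescalo per taxon -------------------------------------------------
  fres <- stage("frescalo", {
    res <- list()
    for (tx in taxa) {
      rec_tx <- dplyr::filter(records, .data$taxon == tx)
      sq <- as.character(square_table$square_id)
      sp <- sort(unique(rec_tx$species_id))
      p1 <- presence_matrix(rec_tx, 1, squares = sq, species = sp)
      p2 <- presence_matrix(rec_tx, 2, squares = sq, species = sp)
      res[[tx]] <- frescalo(
        p1, p2, square_table[, c("x", "y")], phi = config$phi[[tx]],
        n_candidates = config$n_candidates,
        n_neighbours = config$n_neighbours
      )
    }
    res
  })
  effort_tbl <- dplyr::bind_rows(lapply(names(fres), function(tx) {
    dplyr::mutate(fres[[tx]]$squares, taxon = tx,
                  square_id = square_table$square_id[.data$square])
  }))
  trends_tbl <- dplyr::bind_rows(lapply(names(fres), function(tx) {
    dplyr::mutate(fres[[tx]]$species, taxon = tx)
  }))
  utils::write.csv(effort_tbl, file.path(out_dir, "frescalo_effort.csv"),
                   row.names = FALSE)
  utils::write.csv(trends_tbl, file.path(out_dir, "frescalo_trends.csv"),
                   row.names = FALSE)

  # --- model suite per species --------------------------------------------
  models <- stage("model_suite", {
    sep <- character(); rows <- list()
    for (tx in taxa) {
      eff_tx <- dplyr::select(
        dplyr::filter(effort_tbl, .data$taxon == tx), "square_id", "effort")
      covars <- dplyr::inner_join(
        dplyr::select(square_table, "square_id", "L", "dT", "M",
                      "pcnm1", "pcnm2"),
        eff_tx, by = "square_id")
      covars <- dplyr::rename(covars, E = "effort")
      out_tx <- dplyr::filter(outcomes, .data$taxon == tx)
      for (sp in unique(out_tx$species_id)) {
        d <- dplyr::inner_join(
          dplyr::filter(out_tx, .data$species_id == sp),
          covars, by = "square_id"
        )
        d <- d[stats::complete.cases(d[, c("y", "L", "dT", "E", "M",
                                           "pcnm1", "pcnm2")]), ]
        if (nrow(d) < 20) next
        flag <- detect_separation(d$y, d[, c("L", "dT", "E", "M",
                                             "pcnm1", "pcnm2")])
        if (flag$separated) { sep <- c(sep, sp); next }
        fits <- fit_formulations(d)
        best <- tryCatch(select_best(fits), error = function(e) NULL)
        if (is.null(best)) { sep <- c(sep, sp); next }
        rows[[sp]] <- tibble::tibble(
          species_id = sp, taxon = tx,
          formulation = best$formulation,
          fit = list(best), fits = list(fits), data = list(d)
        )
      }
    }
    list(results = dplyr::bind_rows(rows), separated = sep)
  })
  model_results <- models$results
  if (nrow(model_results) > 0) {
    flat <- dplyr::bind_rows(lapply(seq_len(nrow(model_results)), function(i) {
      dplyr::mutate(tidy(model_results$fit[[i]]),
                    species_id = model_results$species_id[i],
                    formulation = model_results$formulation[i])
    }))
    utils::write.csv(flat, file.path(out_dir, "model_coefficients.csv"),
                     row.names = FALSE)
  }

  # --- interaction assessment ---------------------------------------------
  interaction <- stage("interaction", {
    idx <- which(model_results$formulation == 5)
    if (length(idx) == 0) return(NULL)
    grids <- list()
    for (i in idx) {
      fits <- model_results$fits[[i]]
      f5 <- fits$fit[[5]]; f4 <- fits$fit[[4]]
      if (is.null(f4) || !fits$converged[4]) next
      g <- tryCatch(build_grid(f5, f4, model_results$data[[i]]),
                    error = function(e) NULL)
      if (!is.null(g)) grids[[model_results$species_id[i]]] <- g
    }
    if (length(grids) == 0) return(NULL)
    tests <- paired_comparison(grids, alpha = config$alpha)
    list(grids = grids, tests = tests,
         table_dT = difference_table(grids, "dT"),
         table_L = difference_table(grids, "L"))
  })
  if (!is.null(interaction)) {
    utils::write.csv(interaction$tests,
                     file.path(out_dir, "interaction_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(interaction$table_dT,
                     file.path(out_dir, "interaction_table_dT.csv"),
                     row.names = FALSE)
  }

  # --- reporting ----------------------------------------------------------
  assignments <- NULL; ctest <- NULL
  if (nrow(model_results) > 0) {
    assignments <- stage("cohorts", classify_cohort(model_results))
    trends_join <- dplyr::select(trends_tbl, "species_id", "trend")
    ctest <- tryCatch(
      suppressWarnings(cohort_trend_test(assignments, trends_join)),
      error = function(e) NULL
    )
    utils::write.csv(assignments, file.path(out_dir, "cohorts.csv"),
                     row.names = FALSE)
  }
  summary <- summarize_run(
    model_results[, c("species_id", "taxon", "fit")],
    separated = models$separated,
    interaction_tests = interaction$tests,
    cohort_test = ctest,
    assignments = assignments
  )
  write_run_summary(summary, file.path(out_dir, "report.json"))

  invisible(list(
    world = world, square_table = square_table, outcomes = outcomes,
    frescalo = fres, model_results = model_results,
    separated = models$separated, interaction = interaction,
    assignments = assignments, cohort_test = ctest, summary = summary
  ))
}
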