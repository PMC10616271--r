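#' Classify species into response cohorts
#'
#' Species whose best model is conversion-only, warming-only, or additive
#' are sorted into eight cohorts by the sign of the included environmental
#' coefficients: `T+`, `T-` (warming-only), `L+`, `L-` (conversion-only),
#' and `++`, `+-`, `-+`, `--` for additive species (warming sign first).
#' Controls-only and interactive species are excluded with a reason, as are
#' species with an exactly-zero coefficient (unclassifiable).
#'
#' @param best_fits tibble with `species_id` and `fit` (list of
#'   `persist_fit`, each the species' AIC-best model).
#' @return Tibble `species_id`, `formulation`, `cohort`, `excluded`,
#'   `reason`.
#' @export
classify_cohort <- function(best_fits) {
  rows <- lapply(seq_len(nrow(best_fits)), function(i) {
    fit <- best_fits$fit[[i]]
    id <- best_fits$species_id[i]
    f <- fit$formulation
    b <- fit$coefficients
    base <- tibble::tibble(species_id = id, formulation = f,
                           cohort = NA_character_, excluded = TRUE,
                           reason = NA_character_)
    if (f == 1) { base$reason <- "controls-only best model"; return(base) }
    if (f == 5) { base$reason <- "interactive best model"; return(base) }
    sgn <- function(v) {
      if (b[v] == 0) NA_character_ else if (b[v] > 0) "+" else "-"
    }
    cohort <- switch(as.character(f),
      "2" = { s <- sgn("L"); if (is.na(s)) NA else paste0("L", s) },
      "3" = { s <- sgn("dT"); if (is.na(s)) NA else paste0("T", s) },
      "4" = {
        st <- sgn("dT"); sl <- sgn("L")
        if (is.na(st) || is.na(sl)) NA else paste0(st, sl)
      }
    )
    if (is.na(cohort)) { base$reason <- "exactly zero coefficient"; return(base) }
    base$cohort <- cohort; base$excluded <- FALSE
    base
  })
  dplyr::bind_rows(rows)
}

#' Cohort vs distribution-trend association test
#'
#' Pearson chi-square on the 8 x 2 table of response cohort against the
#' sign of the Frescalo distribution trend. Zero-trend species are dropped
#' (and counted); empty cohort rows are dropped and the reduced degrees of
#' freedom reported.
#'
#' @param assignments tibble from [classify_cohort()] (non-excluded rows
#'   are used).
#' @param trends tibble with `species_id`, `trend`.
#' @return Tibble `chi_square`, `df`, `p`, `n_species`, `n_zero_trend`;
#'   the observed table in attribute `"table"`.
#' @export
cohort_trend_test <- function(assignments, trends) {
  dat <- dplyr::inner_join(
    dplyr::filter(assignments, !.data$excluded),
    trends, by = "species_id"
  )
  n_zero <- sum(dat$trend == 0)
  dat <- dplyr::filter(dat, .data$trend != 0)
  cohorts <- c("T+", "T-", "L+", "L-", "++", "+-", "-+", "--")
  tab <- table(
    cohort = factor(dat$cohort, levels = cohorts),
    trend = factor(ifelse(dat$trend > 0, "positive", "negative"),
                   levels = c("positive", "negative"))
  )
  keep <- rowSums(tab) > 0
  if (sum(keep) < nrow(tab)) {
    warning(nrow(tab) - sum(keep), " empty cohort row(s) dropped; d.f. reduced")
  }
  tab2 <- tab[keep, , drop = FALSE]
  O <- as.matrix(tab2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  nonzero <- E > 0
  chi2 <- sum((O[nonzero] - E[nonzero])^2 / E[nonzero])
  dfree <- (nrow(O) - 1) * (ncol(O) - 1)
  out <- tibble::tibble(
    chi_square = chi2, df = dfree,
    p = stats::pchisq(chi2, dfree, lower.tail = FALSE),
    n_species = nrow(dat), n_zero_trend = n_zero
  )
  attr(out, "table") <- tab
  out
}

#' Summarise a full persistence-modelling run
#'
#' Collects the run's headline numbers: per-taxon species counts,
#' best-formulation tallies, median AMEs per conventional unit (0.1 degrees
#' C/decade warming; 10 percentage points conversion) over species whose
#' best model includes the variable non-interactively, interaction
#' significance counts, the cohort table, and exclusion bookkeeping. All
#' counts satisfy the conservation identity: cohorts + controls-only +
#' interactive + unclassifiable + separated = analysed species.
#'
#' @param model_results tibble with `species_id`, `taxon`, `fit` (best
#'   `persist_fit` per species).
#' @param separated character vector of species removed by the separation
#'   screen.
#' @param interaction_tests optional tibble from [paired_comparison()].
#' @param cohort_test optional tibble from [cohort_trend_test()].
#' @param assignments optional tibble from [classify_cohort()].
#' @return A `run_summary` list, JSON-serialisable.
#' @export
summarize_run <- function(model_results, separated = character(),
                          interaction_tests = NULL, cohort_test = NULL,
                          assignments = NULL) {
  if (nrow(model_results) == 0) {
    return(structure(list(n_species = 0, n_separated = length(separated)),
                     class = "run_summary"))
  }
  best_form <- vapply(model_results$fit, function(f) f$formulation, numeric(1))
  tally <- as.list(table(factor(best_form, levels = 1:5)))
  names(tally) <- paste0("formulation_", 1:5)

  ame_for <- function(var, forms) {
    sel <- which(best_form %in% forms)
    if (length(sel) == 0) return(NA_real_)
    stats::median(vapply(sel, function(i) {
      average_marginal_effect(model_results$fit[[i]], var, 0.1)$ame
    }, numeric(1)))
  }
  summary <- list(
    n_species = nrow(model_results),
    n_separated = length(separated),
    by_taxon = as.list(table(model_results$taxon)),
    best_model_tally = tally,
    median_ame_dT_per_0.1C = ame_for("dT", c(3, 4)),
    median_ame_L_per_10pct = ame_for("L", c(2, 4)),
    n_interactive = sum(best_form == 5),
    n_noninteractive_env = sum(best_form %in% 2:4),
    n_controls_only = sum(best_form == 1)
  )
  if (!is.null(interaction_tests)) {
    summary$interaction <- list(
      n_tested = nrow(interaction_tests),
      n_meaningful = sum(interaction_tests$significant),
      threshold = attr(interaction_tests, "threshold")
    )
  }
  if (!is.null(assignments)) {
    kept <- dplyr::filter(assignments, !.data$excluded)
    summary$cohorts <- as.list(table(kept$cohort))
  }
  if (!is.null(cohort_test)) {
    summary$cohort_trend_test <- as.list(cohort_test[1, ])
  }
  structure(summary, class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Write a run summary to JSON
#'
#' @param summary a `run_summary`.
#' @param path output file.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
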