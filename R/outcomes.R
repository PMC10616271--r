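#' Presence matrix for one recording period
#'
#' Collapses occurrence records to a binary squares-by-species matrix for a
#' period (an entry is 1 iff at least one record exists), plus per-square
#' taxon coverage: whether any species of each taxon was recorded there in
#' that period, the information the status-change acceptance rule needs.
#'
#' @param records tibble with `species_id`, `taxon`, `square_id`, `period`.
#' @param period period label to extract; must occur in the records.
#' @param squares optional vector of square ids fixing the row set (defaults
#'   to all squares present in `records` across periods).
#' @param species optional vector of species ids fixing the column set.
#' @return A binary matrix (squares x species) with a `"coverage"` attribute:
#'   a logical squares x taxa matrix.
#' @export
presence_matrix <- function(records, period, squares = NULL, species = NULL) {
  if (!period %in% unique(records$period)) {
    stop("unknown period label: ", period)
  }
  if (is.null(squares)) squares <- sort(unique(records$square_id))
  if (is.null(species)) species <- sort(unique(records$species_id))
  taxa <- sort(unique(records$taxon))
  per <- period
  rec <- dplyr::filter(records, .data$period == per,
                       .data$square_id %in% squares,
                       .data$species_id %in% species)
  m <- matrix(0L, length(squares), length(species),
              dimnames = list(squares, species))
  m[cbind(match(rec$square_id, squares), match(rec$species_id, species))] <- 1L
  cov <- matrix(FALSE, length(squares), length(taxa),
                dimnames = list(squares, taxa))
  cov[cbind(match(rec$square_id, squares), match(rec$taxon, taxa))] <- TRUE
  attr(m, "coverage") <- cov
  m
}

#' Persistence / extirpation outcomes from two presence matrices
#'
#' A species present in a square in both periods persisted (y = 1). A
#' species present in period 1 but absent in period 2 is only accepted as
#' extirpated (y = 0) if another species of the same taxon was recorded in
#' that square in period 2 (otherwise the square was plausibly unvisited and
#' the square-species pair is excluded). Colonisations (absent then present)
#' are returned separately under the symmetric period-1 coverage rule.
#'
#' @param p1,p2 presence matrices from [presence_matrix()] on identical
#'   square/species sets (with coverage attributes).
#' @param taxon_of named character vector mapping species_id to taxon.
#' @return Tibble `species_id`, `taxon`, `square_id`, `y`, with attributes
#'   `"colonisations"` (tibble) and `"n_excluded"` (count of unresolvable
#'   present-then-absent cases).
#' @export
build_outcomes <- function(p1, p2, taxon_of) {
  stopifnot(identical(dimnames(p1), dimnames(p2)))
  cov1 <- attr(p1, "coverage"); cov2 <- attr(p2, "coverage")
  squares <- rownames(p1); species <- colnames(p1)
  taxa <- taxon_of[species]
  cov2_sp <- cov2[, taxa, drop = FALSE]  # per-species period-2 coverage
  cov1_sp <- cov1[, taxa, drop = FALSE]

  persisted <- p1 == 1 & p2 == 1
  extirpated <- p1 == 1 & p2 == 0 & cov2_sp
  excluded <- p1 == 1 & p2 == 0 & !cov2_sp
  colonised <- p1 == 0 & p2 == 1 & cov1_sp

  to_tbl <- function(m, y) {
    hit <- which(m, arr.ind = TRUE)
    tibble::tibble(
      species_id = species[hit[, 2]],
      taxon = unname(taxa[hit[, 2]]),
      square_id = squares[hit[, 1]],
      y = y
    )
  }
  out <- dplyr::bind_rows(to_tbl(persisted, 1L), to_tbl(extirpated, 0L))
  out <- dplyr::arrange(out, .data$species_id, .data$square_id)
  if (is.numeric(utils::type.convert(squares, as.is = TRUE))) {
    out$square_id <- as.integer(out$square_id)
  }
  colo <- to_tbl(colonised, 1L)
  colo <- dplyr::select(dplyr::arrange(colo, .data$species_id, .data$square_id),
                        -"y")
  if (nrow(colo) > 0 && is.numeric(utils::type.convert(squares, as.is = TRUE))) {
    colo$square_id <- as.integer(colo$square_id)
  }
  attr(out, "colonisations") <- colo
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' Range-size filter
#'
#' Keeps species recorded in strictly more than `min_squares` unique squares
#' in the first period (the default reproduces the "100 squares or fewer"
#' exclusion: exactly 100 squares is excluded, 101 is kept).
#'
#' @param outcomes an outcome tibble from [build_outcomes()].
#' @param min_squares exclusive threshold (default 100).
#' @return The filtered tibble; removed species in attribute `"removed"`.
#' @export
filter_range_size <- function(outcomes, min_squares = 100) {
  n1 <- dplyr::summarise(dplyr::group_by(outcomes, .data$species_id),
                         n = dplyr::n_distinct(.data$square_id),
                         .groups = "drop")
  keep <- n1$species_id[n1$n > min_squares]
  out <- dplyr::filter(outcomes, .data$species_id %in% keep)
  attr(out, "removed") <- setdiff(n1$species_id, keep)
  out
}

#' Detect complete (or quasi-) separation for one species
#'
#' Flags a species when, for any predictor of the full formulation, the
#' observed predictor ranges under persistence and extirpation do not
#' overlap — the configuration under which the logistic MLE diverges. By
#' default ranges touching at a single value (quasi-separation) are also
#' flagged. Species with all-identical outcomes are flagged as degenerate.
#'
#' @param y binary outcome vector.
#' @param predictors data frame of predictor columns for the same rows.
#' @param quasi flag quasi-separation too (default TRUE).
#' @return Tibble with `separated` (logical) and `reason` (character).
#' @export
detect_separation <- function(y, predictors, quasi = TRUE) {
  stopifnot(ncol(predictors) >= 1)
  if (length(unique(y)) < 2) {
    return(tibble::tibble(separated = TRUE, reason = "degenerate outcome"))
  }
  for (v in names(predictors)) {
    x0 <- predictors[[v]][y == 0]
    x1 <- predictors[[v]][y == 1]
    if (max(x0) < min(x1) || max(x1) < min(x0)) {
      return(tibble::tibble(separated = TRUE,
                            reason = paste("complete separation on", v)))
    }
    if (quasi && (max(x0) == min(x1) || max(x1) == min(x0))) {
      return(tibble::tibble(separated = TRUE,
                            reason = paste("quasi-separation on", v)))
    }
  }
  tibble::tibble(separated = FALSE, reason = NA_character_)
}

#' Outcome construction straight from records
#'
#' Convenience wrapper: presence matrices for both periods, the coverage
#' rule, and the range-size filter in one call.
#'
#' @inheritParams presence_matrix
#' @param min_squares passed to [filter_range_size()]; `NULL` skips the
#'   filter.
#' @return Outcome tibble as from [build_outcomes()].
#' @export
outcomes_from_records <- function(records, min_squares = 100) {
  taxon_of <- records |>
    dplyr::distinct(.data$species_id, .data$taxon)
  taxon_lookup <- stats::setNames(taxon_of$taxon, taxon_of$species_id)
  p1 <- presence_matrix(records, 1)
  p2 <- presence_matrix(records, 2,
                        squares = rownames(p1), species = colnames(p1))
  out <- build_outcomes(p1, p2, taxon_lookup)
  if (!is.null(min_squares)) {
    colo <- attr(out, "colonisations"); nexc <- attr(out, "n_excluded")
    out <- filter_range_size(out, min_squares)
    attr(out, "colonisations") <- colo
    attr(out, "n_excluded") <- nexc
  }
  out
}
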