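# Shared fixtures, built once per test run.

.world_cache <- new.env(parent = emptyenv())

# default-sized world (16 x 16 squares, two taxa)
test_world <- function() {
  if (is.null(.world_cache$default)) {
    .world_cache$default <- generate_world(synth_config(seed = 42))
  }
  .world_cache$default
}

# large high-occupancy world for parameter recovery: 40 x 40 squares,
# ~1500 occupied squares per species, species stratified over formulations
recovery_world <- function(seed = 5) {
  key <- paste0("recovery", seed)
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_world(synth_config(
      seed = seed, n_squares_x = 40, n_squares_y = 40, fine_per_square = 4,
      species_spec = list(taxon_spec("plants", n = 50,
                                     formulation = rep(1:5, each = 10),
                                     b0 = c(1.2, 0.3),
                                     occ_logit = c(3.6, 0.2)))
    ))
  }
  .world_cache[[key]]
}

# range-shift world for trend estimators: balanced gains and losses,
# dispersal-limited colonisation, moderate effort bias
trend_world <- function(seed = 11) {
  key <- paste0("trend", seed)
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_world(synth_config(
      seed = seed, n_squares_x = 20, n_squares_y = 20, fine_per_square = 4,
      species_spec = list(taxon_spec("plants", n = 80, b0 = c(1.3, 1.3),
                                     col_logit = 0.4)),
      effort_spec = list(meanlog = log(2.5), sdlog = 0.4)
    ))
  }
  .world_cache[[key]]
}

# model covariates (true effort as the effort control)
model_covars <- function(world) {
  dplyr::select(dplyr::mutate(world$square_table, E = E1),
                square_id, L, dT, E, M, pcnm1, pcnm2)
}

# per-species model data from truth outcomes
species_data <- function(world, species_id) {
  to <- truth_outcomes(world)
  dplyr::inner_join(to[to$species_id == species_id, ],
                    model_covars(world), by = "square_id")
}

# presence matrices for one taxon of a world, all squares as rows
world_presence <- function(world, taxon = NULL) {
  rec <- world$records
  if (!is.null(taxon)) rec <- rec[rec$taxon == taxon, ]
  sq <- as.character(world$square_table$square_id)
  sp <- sort(unique(rec$species_id))
  list(
    p1 = presence_matrix(rec, 1, squares = sq, species = sp),
    p2 = presence_matrix(rec, 2, squares = sq, species = sp)
  )
}

# true average marginal effect of a variable for one species, over its
# occupied squares (generating-model probabilities)
true_ame <- function(world, i, variable, data, unit = 0.1) {
  sp <- world$truth$species
  ptrue <- stats::plogis(
    sp$b0_raw[i] + sp$bT_raw[i] * data$dT + sp$bL_raw[i] * data$L +
      sp$bint_raw[i] * data$dT * data$L +
      sp$bE_raw[i] * data$E + sp$bM_raw[i] * data$M
  )
  braw <- if (variable == "dT") sp$bT_raw[i] else sp$bL_raw[i]
  partner <- if (variable == "dT") data$L else data$dT
  slope <- braw + sp$bint_raw[i] * partner
  unit * mean(slope * ptrue * (1 - ptrue))
}
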