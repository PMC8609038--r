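#' Default per-channel log-normal parameters for simulated cytometry events
#'
#' Intensities on each channel are log-normal, the standard working model for
#' cytometry fluorescence.  FRET-positive (aggregate-bearing) cells raise the
#' FRET channel and lower the donor channel relative to FRET-negative cells
#' (sensitized emission with donor quenching); acceptor and viability-dye
#' channels are unchanged between the two subpopulations.  Dead cells take up
#' the viability dye and sit far above the live-cell band.
#'
#' @return nested list: `$negative` and `$positive`, each mapping channel name
#'   (`donor`, `acceptor`, `fret`, `viability`) to `c(meanlog, sdlog)`;
#'   `$dead_viability` holds the dead-cell viability-dye parameters.
#' @export
default_channel_params <- function() {
  list(
    negative = list(
      donor     = c(meanlog = log(2000), sdlog = 0.30),
      acceptor  = c(meanlog = log(1500), sdlog = 0.30),
      fret      = c(meanlog = log(100),  sdlog = 0.35),
      viability = c(meanlog = log(50),   sdlog = 0.30)
    ),
    positive = list(
      donor     = c(meanlog = log(1200), sdlog = 0.30),
      acceptor  = c(meanlog = log(1500), sdlog = 0.30),
      fret      = c(meanlog = log(1000), sdlog = 0.35),
      viability = c(meanlog = log(50),   sdlog = 0.30)
    ),
    dead_viability = c(meanlog = log(2000), sdlog = 0.30)
  )
}

#' Configuration for a simulated screening plate
#'
#' Describes one simulated high-throughput screen: reporter cells seeded in
#' multi-well plates, pre-treated with compounds at several concentration
#' tiers, aggregation induced in all but the negative-control wells, and each
#' well read out as a per-cell fluorescence event table.  Every well's true
#' fraction of aggregate-bearing (FRET-positive) cells is
#' `baseline_positive_fraction * effect(compound, tier)`, clamped to [0, 1];
#' vehicle wells sit at baseline and negative-control (no induction) wells at
#' zero.
#'
#' @param n_compounds number of screened compounds.
#' @param concentrations character vector of dose-tier labels (nominal only).
#' @param n_wells_per_compound replicate wells per compound and tier.
#' @param n_events_per_well acquired events (cells) per well; the default
#'   follows the screen design of 10,000 cells seeded per well.
#' @param baseline_positive_fraction fraction of aggregate-bearing cells in
#'   induced vehicle wells, in [0, 1].
#' @param compound_effects named list mapping compound id to a multiplicative
#'   effect on the positive fraction, either a single number or one value per
#'   tier (1 = inert, < 1 inhibitor, > 1 exacerbator).  Compounds not listed
#'   have effect 1 at every tier.
#' @param n_vehicle_wells,n_negative_wells number of vehicle (maximal
#'   induction) and negative-control (no induction) wells per replicate.
#' @param dead_fraction fraction of dead cells per well (removed by the
#'   viability gate downstream).
#' @param channel_params per-channel log-normal parameters, see
#'   [default_channel_params()].
#' @param n_replicates independent experimental repetitions of the screen.
#' @param compound_ids optional character vector of compound names.
#' @param seed top-level integer seed; streams are split per well with
#'   [split_seed()].
#' @return an object of class `plate_sim_config`.
#' @export
plate_sim_config <- function(n_compounds = 80,
                             concentrations = c("2uM", "4uM", "10uM"),
                             n_wells_per_compound = 1,
                             n_events_per_well = 10000,
                             baseline_positive_fraction = 0.30,
                             compound_effects = NULL,
                             n_vehicle_wells = 8,
                             n_negative_wells = 8,
                             dead_fraction = 0.02,
                             channel_params = default_channel_params(),
                             n_replicates = 1,
                             compound_ids = NULL,
                             seed = 1) {
  assert_that(n_compounds >= 1 && n_events_per_well >= 1,
              "n_compounds and n_events_per_well must be >= 1")
  assert_that(baseline_positive_fraction >= 0 && baseline_positive_fraction <= 1,
              "baseline_positive_fraction must lie in [0, 1]")
  assert_that(dead_fraction >= 0 && dead_fraction < 1,
              "dead_fraction must lie in [0, 1)")
  assert_that(length(concentrations) >= 1, "at least one concentration tier")
  if (is.null(compound_ids))
    compound_ids <- sprintf("C%03d", seq_len(n_compounds))
  assert_that(length(compound_ids) == n_compounds && !anyDuplicated(compound_ids),
              "compound_ids must be unique and match n_compounds")
  compound_effects <- compound_effects %||% list()
  n_tiers <- length(concentrations)
  for (nm in names(compound_effects)) {
    eff <- compound_effects[[nm]]
    assert_that(nm %in% compound_ids,
                sprintf("effect given for unknown compound '%s'", nm))
    assert_that(all(is.finite(eff)) && all(eff > 0),
                sprintf("effects for '%s' must be finite and > 0", nm))
    assert_that(length(eff) %in% c(1L, n_tiers),
                sprintf("effects for '%s' must have length 1 or %d", nm, n_tiers))
  }
  structure(list(
    n_compounds = n_compounds, concentrations = concentrations,
    n_wells_per_compound = n_wells_per_compound,
    n_events_per_well = n_events_per_well,
    baseline_positive_fraction = baseline_positive_fraction,
    compound_effects = compound_effects,
    n_vehicle_wells = n_vehicle_wells, n_negative_wells = n_negative_wells,
    dead_fraction = dead_fraction, channel_params = channel_params,
    n_replicates = n_replicates, compound_ids = compound_ids,
    seed = as.integer(seed)
  ), class = "plate_sim_config")
}

effect_at_tier <- function(config, compound, tier_index) {
  eff <- config$compound_effects[[compound]]
  if (is.null(eff)) return(1)
  if (length(eff) == 1L) eff else eff[tier_index]
}

# One well's event table: a two-component log-normal mixture with mixing
# weight p (the true positive fraction), plus a dead-cell contingent that the
# viability gate removes downstream.
simulate_well_events <- function(n, p, dead_fraction, cp, well_id, seed) {
  with_seed(seed, {
    is_pos  <- runif(n) < p
    is_dead <- runif(n) < dead_fraction
    draw <- function(channel) {
      par_n <- cp$negative[[channel]]; par_p <- cp$positive[[channel]]
      v <- rlnorm(n, par_n["meanlog"], par_n["sdlog"])
      if (any(is_pos))
        v[is_pos] <- rlnorm(sum(is_pos), par_p["meanlog"], par_p["sdlog"])
      v
    }
    ev <- data.frame(
      event_id  = sprintf("%s_e%05d", well_id, seq_len(n)),
      donor     = draw("donor"),
      acceptor  = draw("acceptor"),
      fret      = draw("fret"),
      viability = draw("viability"),
      stringsAsFactors = FALSE
    )
    if (any(is_dead))
      ev$viability[is_dead] <- rlnorm(sum(is_dead),
                                      cp$dead_viability["meanlog"],
                                      cp$dead_viability["sdlog"])
    ev
  })
}

#' Simulate a screening plate with known ground truth
#'
#' Generates one event table per well according to the plate design in
#' `config`: compound wells for every compound x tier x replicate-well,
#' plus vehicle and negative-control wells, repeated for each experimental
#' replicate.  Returns the tables, the plate layout, and the ground truth
#' (every well's planted positive fraction).
#'
#' @param config a [plate_sim_config()].
#' @return list with components `wells` (named list of event data frames),
#'   `layout` (data frame: well, compound, concentration, role, replicate)
#'   and `truth` (layout plus `true_fraction`).
#' @export
simulate_plate <- function(config) {
  stopifnot(inherits(config, "plate_sim_config"))
  rows <- list(); k <- 0L
  for (rep_i in seq_len(config$n_replicates)) {
    for (ci in seq_along(config$compound_ids)) {
      cmp <- config$compound_ids[ci]
      for (ti in seq_along(config$concentrations)) {
        p <- min(1, max(0, config$baseline_positive_fraction *
                             effect_at_tier(config, cmp, ti)))
        for (w in seq_len(config$n_wells_per_compound)) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            compound = cmp, concentration = config$concentrations[ti],
            role = "compound", replicate = rep_i, true_fraction = p,
            stringsAsFactors = FALSE)
        }
      }
    }
    for (w in seq_len(config$n_vehicle_wells)) {
      k <- k + 1L
      rows[[k]] <- data.frame(compound = "vehicle", concentration = NA_character_,
                              role = "vehicle", replicate = rep_i,
                              true_fraction = config$baseline_positive_fraction,
                              stringsAsFactors = FALSE)
    }
    for (w in seq_len(config$n_negative_wells)) {
      k <- k + 1L
      rows[[k]] <- data.frame(compound = "negative", concentration = NA_character_,
                              role = "negative-control", replicate = rep_i,
                              true_fraction = 0, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  truth$well <- sprintf("W%04d", seq_len(nrow(truth)))
  truth <- truth[, c("well", "compound", "concentration", "role",
                     "replicate", "true_fraction")]
  wells <- vector("list", nrow(truth))
  names(wells) <- truth$well
  for (i in seq_len(nrow(truth))) {
    wells[[i]] <- simulate_well_events(
      config$n_events_per_well, truth$true_fraction[i], config$dead_fraction,
      config$channel_params, truth$well[i], split_seed(config$seed, i))
  }
  layout <- truth[, c("well", "compound", "concentration", "role", "replicate")]
  list(wells = wells, layout = layout, truth = truth)
}
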