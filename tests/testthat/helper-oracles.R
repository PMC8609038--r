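# Brute-force Pearson correlation via the explicit summation formula:
#   r = (n*Sxy - Sx*Sy) / sqrt((n*Sxx - Sx^2) * (n*Syy - Sy^2))
# kept deliberately independent of stats::cor and of the package.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

binomial_se <- function(p, n) sqrt(p * (1 - p) / n)

# Small constructed event table with exact, countable gate outcomes.
make_event_table <- function(donor, acceptor, fret, viability) {
  n <- max(lengths(list(donor, acceptor, fret, viability)))
  data.frame(event_id = sprintf("e%03d", seq_len(n)),
             donor = rep_len(donor, n), acceptor = rep_len(acceptor, n),
             fret = rep_len(fret, n), viability = rep_len(viability, n),
             stringsAsFactors = FALSE)
}

withr_local_tempdir <- function() {
  d <- tempfile("agtest")
  dir.create(d)
  d
}

# A quick, small simulated plate shared across flow tests.
small_plate <- function(seed = 1, n_events = 2000, effects = NULL,
                        n_compounds = 6) {
  simulate_plate(plate_sim_config(
    n_compounds = n_compounds, n_events_per_well = n_events,
    compound_effects = effects, n_vehicle_wells = 4, n_negative_wells = 4,
    seed = seed))
}
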