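EVENT_COLUMNS <- c("donor", "acceptor", "fret", "viability")

check_event_table <- function(events, require_rows = TRUE) {
  missing <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing))
    stop_ag("event table is missing column(s): ", paste(missing, collapse = ", "))
  if (require_rows && nrow(events) == 0)
    stop_ag("event table is empty")
  invisible(TRUE)
}

#' Rectangular gate specification for event tables
#'
#' Gates are rectangular thresholds: a viability-dye cutoff (keep-below for
#' dyes that stain dead cells, e.g. Draq7; keep-above for live-cell dyes),
#' minimum donor and acceptor intensities selecting the double-positive
#' reporter population, and the FRET-positive threshold on the FRET channel.
#'
#' @param fret_threshold FRET-positive threshold (a.u.).
#' @param viability_cutoff viability-dye cutoff (a.u.); default `Inf` keeps
#'   everything.
#' @param viability_keep `"below"` (dead-cell dye) or `"above"`.
#' @param donor_min,acceptor_min double-positive thresholds (a.u.).
#' @return an object of class `gate_spec`.
#' @export
gate_spec <- function(fret_threshold,
                      viability_cutoff = Inf,
                      viability_keep = c("below", "above"),
                      donor_min = -Inf, acceptor_min = -Inf) {
  viability_keep <- match.arg(viability_keep)
  vals <- c(fret_threshold, viability_cutoff, donor_min, acceptor_min)
  assert_that(all(!is.na(vals)), "gate thresholds must not be NA")
  structure(list(fret_threshold = fret_threshold,
                 viability_cutoff = viability_cutoff,
                 viability_keep = viability_keep,
                 donor_min = donor_min, acceptor_min = acceptor_min),
            class = "gate_spec")
}

#' Derive a control-anchored gate from a simulated or loaded plate
#'
#' Sets the FRET-positive threshold at a high quantile of the pooled
#' negative-control wells (no induced aggregation), the standard
#' control-anchored way to place a positivity gate, and loose double-positive
#' thresholds at a low quantile of all pooled events.  The default quantile
#' 0.999 keeps gate leakage (negative events ending up above the gate) an
#' order of magnitude below the binomial sampling error of a 10,000-event
#' well, so recovered percent-positive values are essentially unbiased even
#' for strongly inhibited wells.
#'
#' @param plate list with `wells` and `layout` as returned by
#'   [simulate_plate()] or [load_plate()].
#' @param fret_quantile quantile of pooled negative-control FRET intensities
#'   used as the positivity threshold.
#' @param viability_cutoff,viability_keep viability gate; the default cutoff
#'   500 sits between the live and dead bands of the default simulator.
#' @return a [gate_spec()].
#' @export
auto_gate <- function(plate, fret_quantile = 0.999,
                      viability_cutoff = 500, viability_keep = "below") {
  neg_wells <- plate$layout$well[plate$layout$role == "negative-control"]
  assert_that(length(neg_wells) > 0,
              "auto_gate needs at least one negative-control well")
  neg_fret <- unlist(lapply(plate$wells[neg_wells], function(w) w$fret),
                     use.names = FALSE)
  pooled <- do.call(rbind, plate$wells)
  gate_spec(
    fret_threshold = as.numeric(quantile(neg_fret, fret_quantile)),
    viability_cutoff = viability_cutoff, viability_keep = viability_keep,
    donor_min = as.numeric(quantile(pooled$donor, 0.001)),
    acceptor_min = as.numeric(quantile(pooled$acceptor, 0.001))
  )
}

#' Gate an event table
#'
#' Keeps events passing the viability gate and the donor/acceptor
#' double-positive thresholds, in their original order.  The FRET-positive
#' threshold is not applied here: it defines the positive subpopulation
#' inside the gated events (see [fret_positive_fraction()]).
#'
#' @param events event data frame with columns donor, acceptor, fret,
#'   viability.
#' @param gates a [gate_spec()].
#' @return the gated event table.
#' @export
gate_events <- function(events, gates) {
  stopifnot(inherits(gates, "gate_spec"))
  check_event_table(events, require_rows = FALSE)
  if (nrow(events) == 0) {
    warning("gating an empty event table", call. = FALSE)
    return(events)
  }
  viable <- if (gates$viability_keep == "below")
    events$viability <= gates$viability_cutoff
  else events$viability >= gates$viability_cutoff
  keep <- viable & events$donor >= gates$donor_min &
    events$acceptor >= gates$acceptor_min
  events[keep, , drop = FALSE]
}

#' Percent FRET-positive cells in a well
#'
#' Fraction (on the 0-100 scale) of gated events at or above the
#' FRET-positive threshold.
#'
#' @inheritParams gate_events
#' @param gated set `TRUE` if `events` has already been through
#'   [gate_events()].
#' @return percent in [0, 100].
#' @export
fret_positive_fraction <- function(events, gates, gated = FALSE) {
  check_event_table(events)
  if (!gated) events <- gate_events(events, gates)
  if (nrow(events) == 0)
    stop_ag("no events left after gating; percent FRET-positive is undefined")
  100 * mean(events$fret >= gates$fret_threshold)
}

#' FRET MFI of a well
#'
#' Median (default) or mean fluorescence intensity of the FRET channel.  The
#' default scope is the FRET-positive subpopulation; `scope = "gated"`
#' computes it over all gated events instead (both conventions are in use for
#' "MFI"; the product with percent-positive is compared only after z-scoring,
#' where the choice is immaterial in practice).
#'
#' @inheritParams fret_positive_fraction
#' @param stat `"median"` or `"mean"`.
#' @param scope `"positive"` (FRET-positive events only) or `"gated"`.
#' @return intensity (a.u.); 0 with attribute `no_positive_events = TRUE`
#'   when the scoped population is empty, so wells without aggregation score
#'   0 rather than erroring.
#' @export
fret_mfi <- function(events, gates, stat = c("median", "mean"),
                     scope = c("positive", "gated"), gated = FALSE) {
  stat <- match.arg(stat); scope <- match.arg(scope)
  check_event_table(events)
  if (!gated) events <- gate_events(events, gates)
  pop <- if (scope == "positive")
    events$fret[events$fret >= gates$fret_threshold] else events$fret
  if (length(pop) == 0)
    return(structure(0, no_positive_events = TRUE))
  if (stat == "median") median(pop) else mean(pop)
}

#' Normalized FRET score
#'
#' The per-well screening score: percent FRET-positive multiplied by the
#' FRET MFI.
#'
#' @param percent_fret_positive percent in [0, 100].
#' @param mfi FRET MFI (a.u., >= 0).
#' @return the product score (a.u.).
#' @export
normalized_fret <- function(percent_fret_positive, mfi) {
  assert_that(all(percent_fret_positive >= 0 & percent_fret_positive <= 100),
              "percent_fret_positive must lie in [0, 100]")
  assert_that(all(mfi >= 0), "mfi must be >= 0")
  percent_fret_positive * mfi
}

#' Summarize one well
#'
#' @inheritParams fret_mfi
#' @return one-row data frame: percent_fret_positive, fret_mfi,
#'   normalized_fret, n_events_gated.
#' @export
summarize_well <- function(events, gates, stat = "median", scope = "positive") {
  check_event_table(events)
  g <- gate_events(events, gates)
  n <- nrow(g)
  if (n == 0) {
    return(data.frame(percent_fret_positive = NA_real_, fret_mfi = NA_real_,
                      normalized_fret = NA_real_, n_events_gated = 0L))
  }
  pct <- fret_positive_fraction(g, gates, gated = TRUE)
  mfi <- fret_mfi(g, gates, stat = stat, scope = scope, gated = TRUE)
  data.frame(percent_fret_positive = pct, fret_mfi = as.numeric(mfi),
             normalized_fret = normalized_fret(pct, as.numeric(mfi)),
             n_events_gated = n)
}

#' Summarize every well of a plate
#'
#' @param plate list with `wells` (named list of event tables).
#' @inheritParams summarize_well
#' @param gates a [gate_spec()], or `NULL` to derive one with [auto_gate()].
#' @return data frame with one row per well (column `well` first).
#' @export
summarize_plate <- function(plate, gates = NULL, stat = "median",
                            scope = "positive") {
  gates <- gates %||% auto_gate(plate)
  out <- do.call(rbind, lapply(plate$wells, summarize_well, gates = gates,
                               stat = stat, scope = scope))
  cbind(data.frame(well = names(plate$wells), stringsAsFactors = FALSE),
        out, row.names = NULL)
}

#' Fold change of a channel's MFI between two event tables
#'
#' Generic per-channel readout used for Lysotracker and FITC-dextran style
#' comparisons: the ratio of the treated to control channel MFI.
#'
#' @param treated,control event data frames.
#' @param channel column name present in both tables.
#' @param stat `"median"` or `"mean"`.
#' @return the fold change (treated / control).
#' @export
mfi_fold_change <- function(treated, control, channel,
                            stat = c("median", "mean")) {
  stat <- match.arg(stat)
  for (tb in list(treated, control))
    if (nrow(tb) == 0) stop_ag("event tables must be non-empty")
  for (tb in list(treated, control))
    if (!channel %in% names(tb))
      stop_ag(sprintf("channel '%s' not present in both tables", channel))
  f <- if (stat == "median") median else mean
  denom <- f(control[[channel]])
  if (denom == 0) stop_ag("control MFI is zero; fold change undefined")
  f(treated[[channel]]) / denom
}
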