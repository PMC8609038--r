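#' Fit a FRET aggregation screen
#'
#' The central analysis of the package: takes a plate of per-cell event
#' tables plus its layout, gates the events, computes each well's normalized
#' FRET score (percent FRET-positive x FRET MFI), standardizes compound
#' scores to z-scores per concentration tier, calls inhibitor/exacerbator
#' hits at a two-sided threshold, and summarizes assay quality (Z'-factor
#' between vehicle and negative-control wells, control z-score band).
#'
#' @param plate list with `wells` (named list of event tables) and `layout`
#'   (well, compound, concentration, role, optionally replicate), as from
#'   [simulate_plate()] or [load_plate()].
#' @param gates a [gate_spec()], or `NULL` to derive one with [auto_gate()].
#' @param threshold two-sided hit threshold on z.
#' @param tiers hit criterion: `"all"` tiers (default), `"any"`, or a tier
#'   label (e.g. only the highest concentration).
#' @param mfi_stat,mfi_scope conventions for the FRET MFI, see [fret_mfi()].
#' @param replicates replicate handling, see [build_screen_table()].
#' @return an object of class `fret_screen` with components `summaries`,
#'   `screen` (per-well [build_screen_table()] result), `compound_z`
#'   (compound x tier z matrix), `hits` ([call_hits()] result), `controls`
#'   (control z summary), `qc` (Z' per replicate) and `gates`.
#' @seealso [print.fret_screen()], [summary.fret_screen()],
#'   [coef.fret_screen()], [plot.fret_screen()]
#' @export
fret_screen <- function(plate, gates = NULL, threshold = 1.5, tiers = "all",
                        mfi_stat = "median", mfi_scope = "positive",
                        replicates = "average") {
  assert_that(all(c("wells", "layout") %in% names(plate)),
              "plate must have components wells and layout")
  gates <- gates %||% auto_gate(plate)
  summaries <- summarize_plate(plate, gates, stat = mfi_stat, scope = mfi_scope)
  screen <- build_screen_table(summaries, plate$layout, replicates = replicates)
  hits <- call_hits(screen, threshold = threshold, tiers = tiers)
  ctrl <- screen[screen$role != "compound", , drop = FALSE]
  controls <- if (nrow(ctrl)) {
    agg <- tapply(ctrl$z, ctrl$role, function(z)
      c(mean_z = mean(z), sd_z = sd(z), n = length(z)))
    do.call(rbind, lapply(names(agg), function(r)
      data.frame(role = r, t(agg[[r]]), stringsAsFactors = FALSE)))
  } else NULL
  qc <- screen_z_prime(screen)
  structure(list(summaries = summaries, screen = screen,
                 compound_z = attr(screen, "compound_z"), hits = hits,
                 controls = controls, qc = qc, gates = gates,
                 threshold = threshold, tiers = tiers,
                 call = match.call()),
            class = "fret_screen")
}

# Z' per replicate from normalized FRET scores: vehicle wells are the
# maximal-induction band, negative-control wells the no-induction band.
screen_z_prime <- function(screen) {
  reps <- unique(screen$replicate)
  out <- data.frame(replicate = reps, z_prime = NA_real_)
  for (i in seq_along(reps)) {
    s <- screen[screen$replicate == reps[i], ]
    pos <- s$score[s$role %in% c("vehicle", "positive-control")]
    neg <- s$score[s$role == "negative-control"]
    if (length(pos) >= 2 && length(neg) >= 2)
      out$z_prime[i] <- z_prime(mean(pos), sd(pos), mean(neg), sd(neg))
  }
  out
}

#' @export
print.fret_screen <- function(x, ...) {
  m <- x$compound_z
  cat("FRET aggregation screen\n")
  cat(sprintf("  %d compounds x %d concentration tiers, %d wells\n",
              nrow(m), ncol(m), nrow(x$screen)))
  cat(sprintf("  hit threshold |z| >= %.2f at %s tier(s)\n",
              x$threshold, x$tiers))
  nh <- table(factor(x$hits$direction, c("inhibitor", "exacerbator", "none")))
  cat(sprintf("  hits: %d inhibitor(s), %d exacerbator(s)\n",
              nh[["inhibitor"]], nh[["exacerbator"]]))
  zp <- x$qc$z_prime[!is.na(x$qc$z_prime)]
  if (length(zp))
    cat(sprintf("  Z'-factor: %s\n", paste(sprintf("%.2f", zp), collapse = ", ")))
  invisible(x)
}

#' @export
summary.fret_screen <- function(object, ...) {
  hits <- object$hits[object$hits$hit, , drop = FALSE]
  structure(list(hits = hits, controls = object$controls, qc = object$qc,
                 n_compounds = nrow(object$compound_z),
                 threshold = object$threshold, tiers = object$tiers),
            class = "summary.fret_screen")
}

#' @export
print.summary.fret_screen <- function(x, ...) {
  cat(sprintf("Screen of %d compounds; hits at |z| >= %.2f (%s tiers):\n",
              x$n_compounds, x$threshold, x$tiers))
  if (nrow(x$hits)) print.data.frame(x$hits, row.names = FALSE)
  else cat("  (no hits)\n")
  if (!is.null(x$controls)) {
    cat("Control wells (z against the compound sample):\n")
    print.data.frame(x$controls, row.names = FALSE)
  }
  cat("Assay quality (Z'-factor, vehicle vs negative control):\n")
  print.data.frame(x$qc, row.names = FALSE)
  invisible(x)
}

#' Per-compound z-score matrix of a fitted screen
#'
#' @param object a [fret_screen()] object.
#' @param ... unused.
#' @return numeric compound x tier matrix of z-scores.
#' @export
coef.fret_screen <- function(object, ...) object$compound_z

#' Waterfall plot of a fitted screen
#'
#' Compounds ranked by z at one tier; the hit threshold is drawn as
#' horizontal lines and hits are highlighted.
#'
#' @param x a [fret_screen()] object.
#' @param tier tier to rank by (default the highest).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the ranked data frame from [rank_waterfall()].
#' @export
plot.fret_screen <- function(x, tier = NULL, ...) {
  wf <- rank_waterfall(x$compound_z, tier)
  is_hit <- wf$compound %in% x$hits$compound[x$hits$hit]
  graphics::plot(wf$rank, wf$z, pch = 19,
                 col = ifelse(is_hit, "firebrick", "grey40"),
                 xlab = "compound rank", ylab = "z-score", ...)
  graphics::abline(h = c(-x$threshold, x$threshold), lty = 2, col = "grey60")
  invisible(wf)
}
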