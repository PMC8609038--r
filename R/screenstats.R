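#' Z-scores of compound screening scores
#'
#' Standardizes each observed score x against the sample of screened
#' compounds: z = (x - mean) / sd.  The sample standard deviation (ddof = 1)
#' is used by default.
#'
#' @param x numeric scores (n >= 2).
#' @param ddof delta degrees of freedom for the SD (1 = sample SD).
#' @return numeric z-scores, same length as `x`.
#' @export
zscores <- function(x, ddof = 1) {
  st <- sample_stats(x, ddof)
  (x - st$mean) / st$sd
}

#' Mean/SD summary of a score sample
#'
#' @inheritParams zscores
#' @return list with `mean`, `sd`, `n`.
#' @export
sample_stats <- function(x, ddof = 1) {
  x <- x[is.finite(x)]
  n <- length(x)
  assert_that(n >= 2, "need at least 2 finite scores")
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / (n - ddof))
  if (s == 0) stop_ag("scores are constant; z-scores are undefined")
  list(mean = m, sd = s, n = n)
}

#' Score values against a fixed sample distribution
#'
#' Standardizes control-well scores (or any external values) against the
#' compound-sample mean and SD without letting them perturb that sample.
#' Wells with no induced aggregation land well below zero this way, which is
#' what anchors the inhibitor threshold.
#'
#' @param values numeric values to standardize.
#' @param stats a list with `mean` and `sd` as from [sample_stats()].
#' @return numeric z-scores.
#' @export
score_against <- function(values, stats) {
  assert_that(is.finite(stats$mean) && is.finite(stats$sd) && stats$sd > 0,
              "stats must carry a finite mean and positive sd")
  (values - stats$mean) / stats$sd
}

#' Per-compound z-scores from well summaries and a plate layout
#'
#' For each concentration tier (and each experimental replicate when the
#' layout has one), the sample distribution is formed from the compound
#' wells only; compound wells are z-scored within it and control wells are
#' scored against it with [score_against()].  With `replicates = "average"`
#' per-compound z-scores are computed per replicate and then averaged;
#' `"pool"` pools the wells of all replicates into one sample first.
#'
#' @param summaries data frame with columns `well` and `normalized_fret`
#'   (from [summarize_plate()]).
#' @param layout data frame with columns well, compound, concentration, role
#'   (optionally replicate).
#' @param ddof SD convention, see [zscores()].
#' @param replicates `"average"` or `"pool"`.
#' @return an object of class `screen_table`: a data frame of per-well rows
#'   (well, compound, concentration, role, replicate, score, z) with the
#'   per-compound z matrix in `attr(, "compound_z")` (compound x tier, z
#'   averaged over replicates) and per-tier sample stats in
#'   `attr(, "tier_stats")`.
#' @export
build_screen_table <- function(summaries, layout, ddof = 1,
                               replicates = c("average", "pool")) {
  replicates <- match.arg(replicates)
  need <- c("well", "compound", "concentration", "role")
  assert_that(all(need %in% names(layout)),
              paste("layout must have columns:", paste(need, collapse = ", ")))
  assert_that(all(c("well", "normalized_fret") %in% names(summaries)),
              "summaries must have columns well and normalized_fret")
  if (!"replicate" %in% names(layout)) layout$replicate <- 1L
  df <- merge(layout, summaries[, c("well", "normalized_fret")], by = "well")
  assert_that(nrow(df) == nrow(layout), "every layout well needs a summary row")
  names(df)[names(df) == "normalized_fret"] <- "score"
  df$z <- NA_real_
  tiers <- unique(df$concentration[df$role == "compound"])
  blocks <- if (replicates == "average") unique(df$replicate) else "all"
  tier_stats <- list()
  for (tier in tiers) {
    for (b in blocks) {
      in_block <- if (identical(b, "all")) rep(TRUE, nrow(df)) else df$replicate == b
      samp <- df$role == "compound" & df$concentration == tier & in_block
      st <- sample_stats(df$score[samp], ddof)
      df$z[samp] <- score_against(df$score[samp], st)
      ctrl <- df$role != "compound" & in_block
      # controls have no tier of their own; score them against each tier's
      # sample and keep the per-tier values in tier_stats for reporting
      tier_stats[[paste(tier, b, sep = "/")]] <-
        c(st, list(tier = tier, block = b,
                   control_z = stats::setNames(
                     score_against(df$score[ctrl], st), df$well[ctrl])))
    }
  }
  # control wells: z against the sample of the highest tier by convention is
  # ambiguous; report their z against each tier via tier_stats, and leave the
  # per-well z as the average over tiers within their block
  for (i in which(df$role != "compound")) {
    zs <- vapply(tier_stats, function(ts) {
      if (!identical(ts$block, "all") && ts$block != df$replicate[i]) return(NA_real_)
      ts$control_z[[df$well[i]]] %||% NA_real_
    }, numeric(1))
    df$z[i] <- mean(zs, na.rm = TRUE)
  }
  cz <- compound_z_matrix(df, tiers)
  structure(df, class = c("screen_table", "data.frame"),
            compound_z = cz, tier_stats = tier_stats)
}

compound_z_matrix <- function(df, tiers) {
  cmp <- sort(unique(df$compound[df$role == "compound"]))
  m <- matrix(NA_real_, length(cmp), length(tiers),
              dimnames = list(cmp, tiers))
  for (ti in seq_along(tiers)) {
    sub <- df[df$role == "compound" & df$concentration == tiers[ti], ]
    agg <- tapply(sub$z, sub$compound, mean)
    m[names(agg), ti] <- agg
  }
  m
}

#' Call screening hits from per-compound z-scores
#'
#' Inhibitor hits must reach z <= -threshold, exacerbators z >= +threshold.
#' With `tiers = "all"` (default) the criterion must hold at every
#' concentration tier; `tiers = "any"` accepts a single tier; a tier label
#' restricts the test to that tier only.
#'
#' @param screen a `screen_table` from [build_screen_table()], or a numeric
#'   compound x tier z matrix.
#' @param threshold two-sided hit threshold on z (default 1.5).
#' @param tiers `"all"`, `"any"`, or one tier label.
#' @return an object of class `hit_table`: data frame with compound, per-tier
#'   z columns (`z_<tier>`), per-tier pass flags, `direction`
#'   (inhibitor/exacerbator/none) and logical `hit`.
#' @export
call_hits <- function(screen, threshold = 1.5, tiers = "all") {
  m <- if (is.matrix(screen)) screen else attr(screen, "compound_z")
  assert_that(is.matrix(m) && !is.null(colnames(m)),
              "screen must be a screen_table or a compound x tier z matrix")
  if (anyNA(m)) {
    bad <- rownames(m)[apply(m, 1, anyNA)]
    stop_ag("incomplete dose series (missing tier z) for: ",
            paste(bad, collapse = ", "))
  }
  tier_names <- colnames(m)
  use <- if (tiers %in% c("all", "any")) tier_names else {
    assert_that(tiers %in% tier_names,
                sprintf("unknown tier '%s'", tiers))
    tiers
  }
  conj <- if (identical(tiers, "any")) function(x) any(x) else function(x) all(x)
  pass_inh <- m[, use, drop = FALSE] <= -threshold
  pass_exa <- m[, use, drop = FALSE] >= threshold
  inh <- apply(pass_inh, 1, conj)
  exa <- apply(pass_exa, 1, conj)
  out <- data.frame(compound = rownames(m), stringsAsFactors = FALSE)
  for (t in tier_names) out[[paste0("z_", t)]] <- m[, t]
  for (t in use) out[[paste0("pass_", t)]] <- pass_inh[, t] | pass_exa[, t]
  out$direction <- ifelse(inh, "inhibitor", ifelse(exa, "exacerbator", "none"))
  out$hit <- inh | exa
  structure(out, class = c("hit_table", "data.frame"),
            threshold = threshold, tiers = tiers)
}

#' Z'-factor assay-quality metric
#'
#' The standard high-throughput-screening separation statistic between the
#' maximal-induction (positive) and no-induction (negative) control bands:
#' Z' = 1 - 3 (sd_p + sd_n) / |mean_p - mean_n|.  Z' = 1 only for
#' zero-variance controls; values above ~0.5 indicate an assay well suited
#' to screening; values <= 0 indicate overlapping bands.
#'
#' @param mu_p,sd_p mean and SD of the positive (maximal induction) control.
#' @param mu_n,sd_n mean and SD of the negative (no induction) control.
#' @return the Z'-factor (<= 1).
#' @export
z_prime <- function(mu_p, sd_p, mu_n, sd_n) {
  assert_that(sd_p >= 0 && sd_n >= 0, "control SDs must be >= 0")
  if (mu_p == mu_n) stop_ag("control means are equal; Z'-factor undefined")
  1 - 3 * (sd_p + sd_n) / abs(mu_p - mu_n)
}

#' Waterfall ranking of a screen
#'
#' Compounds sorted ascending by z at one tier (the strongest inhibitors
#' first); ties broken alphabetically by compound id.
#'
#' @inheritParams call_hits
#' @param tier tier label to rank by; default the last (highest) tier.
#' @return data frame (compound, z, rank) in waterfall order.
#' @export
rank_waterfall <- function(screen, tier = NULL) {
  m <- if (is.matrix(screen)) screen else attr(screen, "compound_z")
  tier <- tier %||% colnames(m)[ncol(m)]
  assert_that(tier %in% colnames(m), sprintf("unknown tier '%s'", tier))
  z <- m[, tier]
  ord <- order(z, rownames(m))
  data.frame(compound = rownames(m)[ord], z = unname(z[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
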