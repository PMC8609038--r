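#' Planted altered-feature sets with a controlled pairwise overlap
#'
#' Helper for building `planted_sets` with a chosen Venn-style overlap
#' (intersection over union) between consecutive treatments.
#'
#' @param n_features number of features in the universe.
#' @param set_size features altered per treatment.
#' @param treatments character vector of treatment names (>= 1).
#' @param jaccard target pairwise intersection/union between consecutive
#'   treatment sets, in [0, 1].
#' @return named list of integer feature-index vectors.
#' @export
planted_overlap_sets <- function(n_features, set_size, treatments,
                                 jaccard = 0.5) {
  assert_that(jaccard >= 0 && jaccard <= 1, "jaccard must lie in [0, 1]")
  n_shared <- round(jaccard * 2 * set_size / (1 + jaccard))
  need <- set_size + (length(treatments) - 1) * (set_size - n_shared)
  assert_that(need <= n_features,
              "n_features too small for the requested sets and overlap")
  sets <- list()
  nxt <- 1L
  for (i in seq_along(treatments)) {
    if (i == 1) {
      sets[[treatments[i]]] <- seq.int(nxt, nxt + set_size - 1L)
    } else {
      prev <- sets[[treatments[i - 1]]]
      fresh <- seq.int(nxt, nxt + (set_size - n_shared) - 1L)
      sets[[treatments[i]]] <- c(utils::tail(prev, n_shared), fresh)
    }
    nxt <- max(unlist(sets)) + 1L
  }
  sets
}

#' Configuration for a simulated omics intensity matrix
#'
#' Emulates a label-free proteomics (or phospho-proteomics) experiment:
#' features x samples raw intensities whose log2 values are a per-feature
#' baseline plus i.i.d. Gaussian noise, with planted features carrying a
#' group-specific log2 shift in the non-control treatments.  Shared planted
#' features shift in the same direction across treatments, so related
#' treatments produce correlated fold-change profiles.
#'
#' @param n_features number of features (proteins / phospho-epitopes).
#' @param groups named list or vector mapping treatment name to replicate
#'   count (>= 2 each); the first group is the control unless one is named
#'   `"vehicle"`.
#' @param effect_size magnitude of the planted log2 shift.
#' @param noise_sd residual log2 SD per observation.
#' @param planted_sets named list of integer feature indices per non-control
#'   treatment; defaults to sets of 100 with 50% pairwise overlap via
#'   [planted_overlap_sets()].
#' @param baseline_mean,baseline_sd per-feature baseline log2 intensity
#'   distribution.
#' @param seed integer seed.
#' @return an object of class `omics_sim_config`.
#' @export
omics_sim_config <- function(n_features = 2000,
                             groups = c(vehicle = 3, drugA = 3, drugB = 3),
                             effect_size = 1,
                             noise_sd = 0.3,
                             planted_sets = NULL,
                             baseline_mean = 20, baseline_sd = 2,
                             seed = 1) {
  groups <- unlist(groups)
  assert_that(length(groups) >= 1 && !is.null(names(groups)) &&
                all(nzchar(names(groups))), "groups must be named")
  assert_that(!anyDuplicated(names(groups)), "duplicate group labels")
  assert_that(all(groups >= 2), "every group needs >= 2 replicates")
  control <- if ("vehicle" %in% names(groups)) "vehicle" else names(groups)[1]
  trts <- setdiff(names(groups), control)
  if (is.null(planted_sets) && length(trts) > 0)
    planted_sets <- planted_overlap_sets(n_features,
                                         set_size = min(100, n_features %/% 4),
                                         treatments = trts, jaccard = 0.5)
  for (nm in names(planted_sets)) {
    assert_that(nm %in% trts, sprintf("planted set for unknown treatment '%s'", nm))
    assert_that(all(planted_sets[[nm]] >= 1 & planted_sets[[nm]] <= n_features),
                "planted sets must index existing features")
  }
  structure(list(
    n_features = n_features, groups = groups, control = control,
    effect_size = effect_size, noise_sd = noise_sd,
    planted_sets = planted_sets, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, seed = as.integer(seed)
  ), class = "omics_sim_config")
}

#' Simulate an omics matrix with planted differential features
#'
#' @param config an [omics_sim_config()].
#' @return list with `matrix` (raw intensities, features x samples, ready for
#'   [normalize_lfq()]), `annotations` (sample, treatment, replicate) and
#'   `truth` (planted sets, signed per-feature effects, control name).
#' @export
simulate_omics <- function(config) {
  stopifnot(inherits(config, "omics_sim_config"))
  with_seed(config$seed, {
    nf <- config$n_features
    baseline <- rnorm(nf, config$baseline_mean, config$baseline_sd)
    feat_sign <- sample(c(-1, 1), nf, replace = TRUE)  # shared across treatments
    samples <- character(0); trt_of <- character(0); rep_of <- integer(0)
    for (g in names(config$groups)) {
      r <- config$groups[[g]]
      samples <- c(samples, sprintf("%s_r%d", g, seq_len(r)))
      trt_of <- c(trt_of, rep(g, r)); rep_of <- c(rep_of, seq_len(r))
    }
    effects <- matrix(0, nf, length(config$groups),
                      dimnames = list(NULL, names(config$groups)))
    for (g in names(config$planted_sets)) {
      idx <- config$planted_sets[[g]]
      effects[idx, g] <- feat_sign[idx] * config$effect_size
    }
    log2m <- matrix(baseline, nf, length(samples)) +
      effects[, trt_of, drop = FALSE] +
      matrix(rnorm(nf * length(samples), 0, config$noise_sd), nf)
    dimnames(log2m) <- list(sprintf("F%05d", seq_len(nf)), samples)
    ann <- data.frame(sample = samples, treatment = trt_of,
                      replicate = rep_of, stringsAsFactors = FALSE)
    truth <- list(planted_sets = lapply(config$planted_sets,
                                        function(i) rownames(log2m)[i]),
                  effects = effects, control = config$control)
    list(matrix = 2^log2m, annotations = ann, truth = truth)
  })
}
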