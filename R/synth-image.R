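#' Configuration for a simulated multichannel microscopy image
#'
#' Describes a 2-D field of view containing disk-shaped nuclei, punctate
#' aggregates, a channel constructed to a target pixelwise Pearson
#' correlation with the aggregate channel, and a transcription-factor-like
#' channel with a planted nuclear:cytosolic intensity ratio.
#'
#' @param shape image dimensions `c(rows, cols)` in pixels.
#' @param n_nuclei number of non-overlapping disk nuclei.
#' @param nucleus_radius_px nucleus radius (px).
#' @param n_aggregates number of punctate spots in the aggregate channel.
#' @param aggregate_sigma_px Gaussian spot width (px); for `spot_shape =
#'   "disk"` the disk radius is `spot_radius_px`.
#' @param aggregate_amplitude peak spot intensity above background (a.u.).
#' @param spot_shape `"gaussian"` (diffraction-limited-like spots) or
#'   `"disk"` (hard disks with exact pixel areas, useful when area ground
#'   truth must be exact).
#' @param spot_radius_px disk radius when `spot_shape = "disk"`.
#' @param background constant background level (a.u.).
#' @param background_noise_sd Gaussian pixel noise SD (a.u.).
#' @param coloc_rho target pixelwise Pearson correlation, in [-1, 1], of the
#'   constructed colocalization channel with the aggregate channel.
#' @param nc_ratio target nuclear:cytosolic mean-intensity ratio (> 0) of the
#'   TFEB-like channel.
#' @param cytosol_level cytosolic intensity of the TFEB-like channel (a.u.).
#' @param tfeb_noise_sd pixel noise SD of the TFEB-like channel (a.u.).
#' @param min_separation_px minimum centre-to-centre spot separation;
#'   defaults to `4 * aggregate_sigma_px` (or `4 * spot_radius_px` for disks)
#'   so spots stay resolvable.
#' @param seed integer seed.
#' @return an object of class `image_sim_config`.
#' @export
image_sim_config <- function(shape = c(128, 128),
                             n_nuclei = 5, nucleus_radius_px = 10,
                             n_aggregates = 8,
                             aggregate_sigma_px = 2,
                             aggregate_amplitude = 1000,
                             spot_shape = c("gaussian", "disk"),
                             spot_radius_px = 3,
                             background = 100,
                             background_noise_sd = 20,
                             coloc_rho = 0.8,
                             nc_ratio = 2,
                             cytosol_level = 200,
                             tfeb_noise_sd = 2,
                             min_separation_px = NULL,
                             seed = 1) {
  spot_shape <- match.arg(spot_shape)
  assert_that(length(shape) == 2 && all(shape > 0), "shape must be two positive sizes")
  assert_that(n_nuclei >= 0 && n_aggregates >= 0, "counts must be >= 0")
  assert_that(abs(coloc_rho) <= 1, "coloc_rho must lie in [-1, 1]")
  assert_that(nc_ratio > 0, "nc_ratio must be > 0")
  assert_that(aggregate_sigma_px > 0 && spot_radius_px > 0, "spot sizes must be > 0")
  if (is.null(min_separation_px))
    min_separation_px <- 4 * if (spot_shape == "disk") spot_radius_px else aggregate_sigma_px
  structure(list(
    shape = as.integer(shape), n_nuclei = n_nuclei,
    nucleus_radius_px = nucleus_radius_px, n_aggregates = n_aggregates,
    aggregate_sigma_px = aggregate_sigma_px,
    aggregate_amplitude = aggregate_amplitude, spot_shape = spot_shape,
    spot_radius_px = spot_radius_px, background = background,
    background_noise_sd = background_noise_sd, coloc_rho = coloc_rho,
    nc_ratio = nc_ratio, cytosol_level = cytosol_level,
    tfeb_noise_sd = tfeb_noise_sd, min_separation_px = min_separation_px,
    seed = as.integer(seed)
  ), class = "image_sim_config")
}

# Rejection-sample n centres (1-based row/col) with pairwise separation
# >= min_sep and a margin from the frame edge; errors after max_tries.
place_centers <- function(n, shape, margin, min_sep, max_tries = 1000) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  lo <- c(1 + margin, 1 + margin); hi <- shape - margin
  if (any(hi < lo)) stop_ag("objects cannot fit the frame with the requested margin")
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
      if (i == 1 ||
          all(sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                            matrix(cand, i - 1, 2, byrow = TRUE))^2)) >= min_sep)) {
        centers[i, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) stop_ag(sprintf(
      "could not place object %d after %d retries; frame too crowded", i, max_tries))
  }
  centers
}

disk_mask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

gaussian_spot <- function(shape, center, sigma, amplitude) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  amplitude * exp(-((r - center[1])^2 + (c - center[2])^2) / (2 * sigma^2))
}

#' Simulate a multichannel microscopy image with ground truth
#'
#' Builds four registered channels: `nuclei` (bright non-overlapping disks,
#' DAPI-like), `aggregates` (punctate spots plus Gaussian noise), `coloc`
#' (constructed so its pixelwise Pearson correlation with the aggregate
#' channel equals `coloc_rho`: the noise component is orthogonalized against
#' the standardized aggregate channel, so the sample correlation matches the
#' target up to floating point), and `tfeb` (cytosolic level everywhere,
#' nuclear pixels at `nc_ratio` times that level, plus noise).
#'
#' @param config an [image_sim_config()].
#' @return list with `channels` (named list of numeric matrices) and `truth`
#'   (spot centres as 0-based (row, col), per-spot pixel areas, nuclei
#'   centres/radius, and the planted `coloc_rho` and `nc_ratio`).
#' @export
simulate_image <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  sh <- config$shape
  with_seed(config$seed, {
    nuc_centers <- place_centers(config$n_nuclei, sh,
                                 margin = config$nucleus_radius_px + 2,
                                 min_sep = 2 * config$nucleus_radius_px + 4)
    nuc_mask <- matrix(FALSE, sh[1], sh[2])
    for (i in seq_len(config$n_nuclei))
      nuc_mask <- nuc_mask | disk_mask(sh, nuc_centers[i, ], config$nucleus_radius_px)

    spot_margin <- if (config$spot_shape == "disk")
      config$spot_radius_px + 2 else 3 * config$aggregate_sigma_px
    agg_centers <- place_centers(config$n_aggregates, sh,
                                 margin = spot_margin,
                                 min_sep = config$min_separation_px)

    agg <- matrix(config$background, sh[1], sh[2])
    spot_areas <- numeric(config$n_aggregates)
    for (i in seq_len(config$n_aggregates)) {
      if (config$spot_shape == "disk") {
        m <- disk_mask(sh, agg_centers[i, ], config$spot_radius_px)
        agg[m] <- agg[m] + config$aggregate_amplitude
        spot_areas[i] <- sum(m)
      } else {
        agg <- agg + gaussian_spot(sh, agg_centers[i, ],
                                   config$aggregate_sigma_px,
                                   config$aggregate_amplitude)
        spot_areas[i] <- sum(disk_mask(sh, agg_centers[i, ],
                                       2 * config$aggregate_sigma_px))
      }
    }
    if (config$background_noise_sd > 0)
      agg <- agg + matrix(rnorm(prod(sh), 0, config$background_noise_sd),
                          sh[1], sh[2])
    agg <- pmax(agg, 0)

    nuclei <- matrix(config$background, sh[1], sh[2])
    nuclei[nuc_mask] <- nuclei[nuc_mask] + 1000
    if (config$background_noise_sd > 0)
      nuclei <- pmax(nuclei + matrix(rnorm(prod(sh), 0, config$background_noise_sd),
                                     sh[1], sh[2]), 0)

    # coloc channel: rho * z(agg) + sqrt(1-rho^2) * e_perp, with e_perp a
    # standardized noise field orthogonalized against z(agg); rescaled to
    # positive intensities without clipping so the correlation is exact.
    rho <- config$coloc_rho
    degenerate <- sd(as.vector(agg)) == 0
    z1 <- if (degenerate) rep(0, prod(sh)) else as.vector(scale(as.vector(agg)))
    if (degenerate) {
      # no structure to correlate with; emit a plain noise channel
      cvec <- as.vector(scale(rnorm(prod(sh))))
    } else if (abs(rho) < 1) {
      e <- rnorm(prod(sh))
      e <- e - z1 * (sum(e * z1) / sum(z1 * z1))
      e <- as.vector(scale(e))
      cvec <- rho * z1 + sqrt(1 - rho^2) * e
    } else {
      cvec <- sign(rho) * z1
    }
    coloc <- matrix(1000 + 100 * cvec, sh[1], sh[2])
    if (min(coloc) < 0) coloc <- coloc - min(coloc)  # affine shift preserves r

    tfeb <- matrix(config$cytosol_level, sh[1], sh[2])
    tfeb[nuc_mask] <- config$nc_ratio * config$cytosol_level
    if (config$tfeb_noise_sd > 0)
      tfeb <- pmax(tfeb + matrix(rnorm(prod(sh), 0, config$tfeb_noise_sd),
                                 sh[1], sh[2]), 0)

    truth <- list(
      spot_centers = agg_centers - 1,  # 0-based (row, col)
      spot_areas = spot_areas,
      n_aggregates = config$n_aggregates,
      nuclei_centers = nuc_centers - 1,
      nucleus_radius_px = config$nucleus_radius_px,
      nucleus_mask = nuc_mask,
      coloc_rho = rho, nc_ratio = config$nc_ratio
    )
    list(channels = list(nuclei = nuclei, aggregates = agg,
                         coloc = coloc, tfeb = tfeb),
         truth = truth)
  })
}
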