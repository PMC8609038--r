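test_that("pixelwise PCC matches trivial and closed-form cases", {
  a <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(pixel_pcc(a, a)$r, 1)
  expect_equal(pixel_pcc(a, -a + 10)$r, -1)
  expect_equal(pixel_pcc(a, -a + 10)$r_squared, 1)

  b <- matrix(c(2, 4, 6, 9), 2, 2)
  expect_equal(pixel_pcc(a, b)$r, pearson_oracle(as.vector(a), as.vector(b)),
               tolerance = 1e-14)

  expect_error(pixel_pcc(a, matrix(5, 2, 2)), "constant")
  expect_error(pixel_pcc(a, matrix(1, 3, 3)), "shapes differ")
})

test_that("pixelwise PCC equals the summation oracle on random images", {
  set.seed(10)
  for (i in 1:100) {
    a <- matrix(runif(64, 0, 10), 8, 8)
    b <- matrix(runif(64, 0, 10), 8, 8)
    res <- pixel_pcc(a, b)
    expect_lt(abs(res$r - pearson_oracle(as.vector(a), as.vector(b))), 1e-12)
    expect_equal(res$r_squared, res$r^2)
  }
})

test_that("pixelwise PCC is symmetric, bounded and affine-invariant", {
  set.seed(11)
  a <- matrix(runif(100), 10); b <- matrix(runif(100), 10)
  r <- pixel_pcc(a, b)$r
  expect_equal(pixel_pcc(b, a)$r, r)
  expect_lte(abs(r), 1)
  expect_equal(pixel_pcc(3 * a + 7, b)$r, r, tolerance = 1e-12)
  # mask restricts the pixel set
  m <- matrix(FALSE, 10, 10); m[1:5, ] <- TRUE
  res <- pixel_pcc(a, b, mask = m)
  expect_equal(res$n_pixels_used, 50)
  expect_equal(res$r, pearson_oracle(a[m], b[m]), tolerance = 1e-12)
})

test_that("aggregate detection finds planted spots and respects area bounds", {
  im <- simulate_image(image_sim_config(shape = c(128, 128), n_nuclei = 0,
                                        n_aggregates = 5, seed = 12))
  obj <- detect_aggregates(im$channels$aggregates)
  expect_equal(nrow(obj), 5)
  # each detection sits near a planted centre (0-based truth)
  d <- as.matrix(dist(rbind(as.matrix(obj[, c("centroid_row", "centroid_col")]),
                            im$truth$spot_centers)))[1:5, 6:10]
  expect_lt(max(apply(d, 1, min)), 2)

  # raising min_area above the largest spot suppresses everything
  none <- detect_aggregates(im$channels$aggregates,
                            min_area = max(obj$area) + 1)
  expect_equal(nrow(none), 0)

  blank <- matrix(100, 64, 64)
  expect_equal(nrow(detect_aggregates(blank)), 0)
  expect_error(detect_aggregates(blank, sigma = 0), "sigma")
  expect_error(detect_aggregates(blank, tophat_radius = -1), "tophat_radius")
})

test_that("detection is deterministic and offset-invariant", {
  im <- simulate_image(image_sim_config(shape = c(96, 96), n_nuclei = 0,
                                        n_aggregates = 6, seed = 13))
  x <- im$channels$aggregates
  expect_identical(detect_aggregates(x), detect_aggregates(x))
  # mean + k*SD thresholding adapts to a global additive offset
  shifted <- detect_aggregates(x + 500)
  expect_equal(nrow(shifted), nrow(detect_aggregates(x)))
})

test_that("detected count equals truth on >= 95% of well-separated images", {
  ok <- 0; n_img <- 50
  for (s in 1:n_img) {
    im <- simulate_image(image_sim_config(
      shape = c(128, 128), n_nuclei = 0, n_aggregates = 5 + s %% 4,
      aggregate_amplitude = 1000, background_noise_sd = 20,  # SNR 50
      seed = 1000 + s))
    n <- nrow(detect_aggregates(im$channels$aggregates))
    ok <- ok + (n == im$truth$n_aggregates)
  }
  expect_gte(ok / n_img, 0.95)
})

test_that("timecourse counts are per-frame and permutation-equivariant", {
  mk <- function(n, s) simulate_image(image_sim_config(
    shape = c(96, 96), n_nuclei = 0, n_aggregates = n,
    seed = s))$channels$aggregates
  stack <- list(matrix(100, 96, 96), mk(5, 21), mk(10, 22))
  counts <- aggregate_timecourse(stack)
  expect_equal(counts, c(0L, 5L, 10L))
  expect_equal(aggregate_timecourse(stack[c(3, 1, 2)]), counts[c(3, 1, 2)])
  expect_equal(aggregate_timecourse(list(matrix(1, 8, 8), matrix(1, 8, 8))),
               c(0L, 0L))
  expect_error(aggregate_timecourse(list()), "non-empty")
})

test_that("TFEB translocation recovers a planted nuclear:cytosolic ratio", {
  im <- simulate_image(image_sim_config(shape = c(160, 160), n_nuclei = 4,
                                        nucleus_radius_px = 10,
                                        n_aggregates = 0, nc_ratio = 2,
                                        seed = 14))
  res <- tfeb_translocation(im$channels$nuclei, im$channels$tfeb)
  expect_equal(nrow(res$cells), 4)
  expect_equal(res$mean_ratio, 2, tolerance = 0.05)

  # uniform TFEB channel: every ratio is 1
  uni <- matrix(300, 160, 160)
  res1 <- tfeb_translocation(im$channels$nuclei, uni)
  expect_equal(res1$cells$ratio, rep(1, nrow(res1$cells)), tolerance = 1e-12)

  # ratio grows monotonically with the nuclear amplitude
  nuc_mask <- im$truth$nucleus_mask
  ratios <- sapply(c(2, 5, 20), function(amp) {
    tf <- matrix(10, 160, 160); tf[nuc_mask] <- amp * 10
    tfeb_translocation(im$channels$nuclei, tf)$mean_ratio
  })
  expect_true(all(diff(ratios) > 0))

  expect_warning(res0 <- tfeb_translocation(matrix(0, 32, 32), matrix(1, 32, 32)),
                 "no nuclei")
  expect_equal(nrow(res0$cells), 0)
})

test_that("puncta area fraction recovers planted disk areas", {
  im <- simulate_image(image_sim_config(
    shape = c(128, 128), n_nuclei = 0, n_aggregates = 6,
    spot_shape = "disk", spot_radius_px = 3, aggregate_amplitude = 2000,
    background_noise_sd = 10, seed = 15))
  mask <- matrix(TRUE, 128, 128)
  frac <- puncta_area_fraction(im$channels$aggregates, mask,
                               sigma = 0.5, threshold_k = 5)
  truth_frac <- sum(im$truth$spot_areas) / sum(mask)
  # tolerance: one boundary-pixel ring per object
  per_obj_perim <- 2 * pi * (3 + 1)
  tol <- 6 * per_obj_perim / sum(mask)
  expect_lt(abs(frac - truth_frac), tol)

  # no puncta -> 0
  expect_equal(as.numeric(puncta_area_fraction(matrix(5, 64, 64),
                                               matrix(TRUE, 64, 64))), 0)
  # mask equal to the detected puncta -> exactly 1
  obj <- detect_aggregates(im$channels$aggregates, sigma = 0.5, threshold_k = 5)
  pm <- attr(obj, "labels") > 0
  expect_equal(as.numeric(puncta_area_fraction(
    im$channels$aggregates, pm, sigma = 0.5, threshold_k = 5)), 1)
  expect_error(puncta_area_fraction(matrix(1, 8, 8), matrix(FALSE, 8, 8)),
               "empty")
})
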