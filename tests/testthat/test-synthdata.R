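test_that("all generators are deterministic under a fixed seed", {
  cfg <- plate_sim_config(n_compounds = 3, n_events_per_well = 500, seed = 11)
  expect_identical(simulate_plate(cfg), simulate_plate(cfg))

  ic <- image_sim_config(shape = c(64, 64), n_nuclei = 2, n_aggregates = 4,
                         seed = 11)
  expect_identical(simulate_image(ic), simulate_image(ic))

  oc <- omics_sim_config(n_features = 200, seed = 11)
  expect_identical(simulate_omics(oc), simulate_omics(oc))
})

test_that("plate config validation rejects bad fractions and effects", {
  expect_error(plate_sim_config(baseline_positive_fraction = 1.2), "\\[0, 1\\]")
  expect_error(plate_sim_config(compound_effects = list(C001 = -1)), "> 0")
  expect_error(plate_sim_config(compound_effects = list(NOPE = 1)), "unknown compound")
  expect_error(plate_sim_config(n_events_per_well = 0), ">= 1")
})

test_that("an inert compound is statistically indistinguishable from vehicle", {
  # oracle: two-sample binomial comparison of gated positive counts; an
  # effect of exactly 1.0 means both wells share the same mixture weight
  pl <- simulate_plate(plate_sim_config(
    n_compounds = 2, n_events_per_well = 10000,
    compound_effects = list(C001 = c(1, 1, 1)), seed = 21))
  gates <- auto_gate(pl)
  layout <- pl$layout
  cmp_wells <- layout$well[layout$compound == "C001"]
  veh_wells <- layout$well[layout$role == "vehicle"]
  p_cmp <- mean(sapply(cmp_wells, function(w)
    fret_positive_fraction(pl$wells[[w]], gates))) / 100
  p_veh <- mean(sapply(veh_wells, function(w)
    fret_positive_fraction(pl$wells[[w]], gates))) / 100
  n_c <- length(cmp_wells) * 10000; n_v <- length(veh_wells) * 10000
  se <- sqrt(p_veh * (1 - p_veh) * (1 / n_c + 1 / n_v))
  expect_lt(abs(p_cmp - p_veh), 3 * se + 1e-12)
})

test_that("negative-control wells show only gate leakage", {
  cfg <- plate_sim_config(n_compounds = 2, n_events_per_well = 10000, seed = 31)
  pl <- simulate_plate(cfg)
  gates <- auto_gate(pl, fret_quantile = 0.999)
  # oracle: expected leakage is the upper tail of the stated negative
  # log-normal above the (fixed) gate threshold
  par_n <- cfg$channel_params$negative$fret
  p_leak <- plnorm(gates$fret_threshold, par_n["meanlog"], par_n["sdlog"],
                   lower.tail = FALSE)
  neg_wells <- pl$layout$well[pl$layout$role == "negative-control"]
  for (w in neg_wells) {
    pct <- fret_positive_fraction(pl$wells[[w]], gates)
    expect_lt(pct / 100, p_leak + 3 * binomial_se(p_leak, 10000))
  }
})

test_that("mixture weight calibration follows binomial sampling at n = 1e5", {
  p_true <- 0.3
  pl <- simulate_plate(plate_sim_config(
    n_compounds = 1, n_events_per_well = 1e5, dead_fraction = 0,
    n_vehicle_wells = 1, n_negative_wells = 1, seed = 41))
  gates <- auto_gate(pl)
  w <- pl$layout$well[pl$layout$role == "compound"][1]
  phat <- fret_positive_fraction(pl$wells[[w]], gates) / 100
  expect_lt(abs(phat - p_true), 3 * binomial_se(p_true, 1e5) + 1e-3)
})

test_that("image ground truth is internally consistent", {
  ic <- image_sim_config(shape = c(96, 96), n_nuclei = 3, n_aggregates = 7,
                         seed = 5)
  im <- simulate_image(ic)
  expect_equal(nrow(im$truth$spot_centers), 7)
  expect_equal(im$truth$n_aggregates, 7)
  expect_true(all(im$truth$spot_centers >= 0))
  expect_true(all(im$truth$spot_centers[, 1] < 96 &
                    im$truth$spot_centers[, 2] < 96))
  expect_equal(length(im$truth$spot_areas), 7)
})

test_that("degenerate image settings produce the expected channels", {
  ic0 <- image_sim_config(shape = c(48, 48), n_nuclei = 0, n_aggregates = 0,
                          background_noise_sd = 0, tfeb_noise_sd = 0, seed = 1)
  im0 <- simulate_image(ic0)
  expect_equal(max(im0$channels$aggregates), min(im0$channels$aggregates))

  # rho = 1: the coloc channel is an affine copy, measured r exactly 1
  ic1 <- image_sim_config(shape = c(48, 48), n_nuclei = 1, n_aggregates = 3,
                          coloc_rho = 1, seed = 2)
  im1 <- simulate_image(ic1)
  r <- pixel_pcc(im1$channels$aggregates, im1$channels$coloc)$r
  expect_equal(r, 1, tolerance = 1e-12)
})

test_that("constructed coloc channel hits the target correlation", {
  for (rho in c(-0.6, 0, 0.5, 0.9)) {
    im <- simulate_image(image_sim_config(shape = c(64, 64), n_nuclei = 1,
                                          n_aggregates = 4, coloc_rho = rho,
                                          seed = 3))
    r <- pixel_pcc(im$channels$aggregates, im$channels$coloc)$r
    expect_equal(r, rho, tolerance = 1e-8)
  }
})

test_that("spot placement fails informatively when the frame is too crowded", {
  expect_error(simulate_image(image_sim_config(
    shape = c(32, 32), n_nuclei = 0, n_aggregates = 200, seed = 1)),
    "retries|fit the frame")
})

test_that("omics generator: planted shifts, overlap control, null tail rate", {
  # effect 0: |log2FC| >= 0.5 exceedances follow the Gaussian difference tail
  oc0 <- omics_sim_config(n_features = 4000, effect_size = 0, noise_sd = 0.3,
                          groups = c(vehicle = 3, drugA = 3), seed = 7)
  om0 <- simulate_omics(oc0)
  fc0 <- log2fc(normalize_lfq(om0$matrix), om0$annotations, "drugA", "vehicle")
  # oracle: fc is N(0, noise_sd * sqrt(2/3)); tail prob of |fc| >= 0.5
  se_fc <- 0.3 * sqrt(2 / 3)
  p_tail <- 2 * pnorm(0.5 / se_fc, lower.tail = FALSE)
  rate <- mean(abs(fc0) >= 0.5)
  expect_lt(abs(rate - p_tail), 3 * binomial_se(p_tail, 4000) + 1e-4)

  # planted 50% pairwise overlap is recovered from the truth sets
  oc <- omics_sim_config(n_features = 1000, effect_size = 3, seed = 8)
  om <- simulate_omics(oc)
  ov <- overlap_percent(om$truth$planted_sets$drugA, om$truth$planted_sets$drugB)
  expect_equal(as.numeric(ov), 50, tolerance = 1)
})

test_that("omics config validation", {
  expect_error(omics_sim_config(groups = c(vehicle = 1, drugA = 3)), ">= 2")
  expect_error(omics_sim_config(groups = c(3, 3)), "named")
  expect_error(omics_sim_config(n_features = 50,
                                planted_sets = list(drugA = 40:60)),
               "index existing features")
})
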