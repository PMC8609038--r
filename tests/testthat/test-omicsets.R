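test_that("median normalization: worked example, zero medians, idempotence", {
  # hand oracle: log2 of [[2,8],[8,2],[32,8]] is [[1,3],[3,1],[5,3]];
  # column medians are 3 and 3, so centred values are known exactly
  m <- matrix(c(2, 8, 32, 8, 2, 8), 3, 2,
              dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
  nm <- normalize_lfq(m)
  expect_equal(unname(nm), cbind(c(-2, 0, 2), c(0, -2, 0)))

  # constant column collapses to zero
  cc <- matrix(c(4, 4, 4, 1, 2, 8), 3, 2,
               dimnames = list(NULL, c("s1", "s2")))
  expect_equal(unname(normalize_lfq(cc)[, 1]), c(0, 0, 0))

  set.seed(20)
  big <- matrix(2^rnorm(600, 20, 2), 100, 6,
                dimnames = list(sprintf("f%d", 1:100), sprintf("s%d", 1:6)))
  big[sample(600, 40)] <- NA
  nb <- normalize_lfq(big)
  expect_lt(max(abs(apply(nb, 2, median, na.rm = TRUE))), 1e-12)
  # idempotence on already-normalized data
  expect_lt(max(abs(normalize_lfq(nb, log2 = FALSE) - nb), na.rm = TRUE), 1e-12)

  bad <- matrix(c(NA, NA, 3, 1, 2, 3), 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(normalize_lfq(bad), "fewer than 2")
  expect_error(normalize_lfq(matrix(c(-1, 2, 2, 2), 2)), "> 0")
})

test_that("log2 fold changes: trivial identities and planted recovery", {
  ann <- data.frame(sample = c("v1", "v2", "t1", "t2"),
                    treatment = c("veh", "veh", "trt", "trt"))
  m <- matrix(2^c(10, 10, 10, 10, 11, 11, 12, 12), 2, 4, byrow = FALSE,
              dimnames = list(c("fA", "fB"), ann$sample))
  # fA: identical means -> 0; fB: treatment = 2x control -> log2FC = 1
  m["fA", ] <- 2^c(10, 10, 10, 10)
  m["fB", ] <- 2^c(10, 10, 11, 11)
  raw_fc <- log2fc(log2(m), ann, "trt", "veh")  # already-log2 path
  expect_equal(unname(as.numeric(raw_fc)), c(0, 1))

  oc <- omics_sim_config(n_features = 800, effect_size = 0.8, noise_sd = 0.3,
                         groups = c(vehicle = 4, drugA = 4),
                         planted_sets = list(drugA = 1:150), seed = 30)
  om <- simulate_omics(oc)
  fc <- log2fc(normalize_lfq(om$matrix), om$annotations, "drugA", "vehicle")
  se <- 0.3 * sqrt(2 / 4)  # SE of a difference of two 4-replicate means
  planted <- om$truth$planted_sets$drugA
  signs <- sign(om$truth$effects[1:150, "drugA"])
  recovered <- fc[planted] * signs
  expect_gt(mean(abs(recovered - 0.8) < 3 * se), 0.95)

  # under-observation flags
  m2 <- m; m2["fB", c("t1", "t2")] <- NA
  fc2 <- log2fc(log2(m2), ann, "trt", "veh")
  expect_true(is.na(fc2["fB"]))
  expect_equal(attr(fc2, "underobserved"), "fB")
})

test_that("altered sets honour flags, the inclusive boundary, and monotonicity", {
  ann <- data.frame(sample = sprintf("s%d", 1:6),
                    treatment = rep(c("veh", "trt"), each = 3))
  set.seed(31)
  nm <- matrix(rnorm(60, 0, 0.05), 10, 6,
               dimnames = list(sprintf("f%d", 1:10), ann$sample))
  nm[1, 4:6] <- nm[1, 4:6] + 0.5   # exactly at the boundary in expectation
  nm[1, ] <- c(0, 0, 0, 0.5, 0.5, 0.5)  # make it exact
  nm[2, ] <- c(0, 0, 0, 2, 2, 2)
  flags <- setNames(rep(TRUE, 10), rownames(nm))

  s <- altered_set(nm, ann, "trt", "veh", flags = flags, min_abs_log2fc = 0.5)
  expect_true(all(c("f1", "f2") %in% s$features))  # boundary inclusive

  expect_error(altered_set(nm, ann, "trt", "veh"), "auto_flags")

  # all-zero fold changes -> empty set
  nz <- matrix(1, 5, 6, dimnames = list(sprintf("g%d", 1:5), ann$sample))
  nz <- nz + matrix(rep(rnorm(5, 0, 0.01), 6), 5, 6)  # constant per feature
  s0 <- altered_set(nz, ann, "trt", "veh",
                    flags = setNames(rep(TRUE, 5), rownames(nz)))
  expect_length(s0$features, 0)

  # set size is non-increasing in the cutoff
  sizes <- sapply(c(0, 0.25, 0.5, 1, 2), function(k)
    length(altered_set(nm, ann, "trt", "veh", flags = flags,
                       min_abs_log2fc = k)$features))
  expect_true(all(diff(sizes) <= 0))
})

test_that("high-effect synthetic runs recover the planted altered set", {
  oc <- omics_sim_config(n_features = 600, effect_size = 3, noise_sd = 0.15,
                         groups = c(vehicle = 3, drugA = 3),
                         planted_sets = list(drugA = 1:80), seed = 32)
  om <- simulate_omics(oc)
  nm <- normalize_lfq(om$matrix)
  s <- altered_set(nm, om$annotations, "drugA", "vehicle", auto_flags = TRUE)
  expect_setequal(s$features, om$truth$planted_sets$drugA)
})

test_that("overlap percent implements Venn set arithmetic", {
  expect_equal(as.numeric(overlap_percent(c("a", "b"), c("a", "b"))), 100)
  expect_equal(as.numeric(overlap_percent(c("a", "b"), c("c", "d"))), 0)
  ov <- overlap_percent(c("1", "2"), c("2", "3"))
  expect_equal(as.numeric(ov), 100 / 3, tolerance = 1e-12)
  expect_equal(attr(ov, "pct_of_a"), 50)
  # symmetry; 100 iff equal
  expect_equal(as.numeric(overlap_percent(c("x", "y"), c("y"))),
               as.numeric(overlap_percent(c("y"), c("x", "y"))))
  expect_lt(as.numeric(overlap_percent(c("x", "y"), c("y"))), 100)
  expect_error(overlap_percent(character(0), character(0)), "empty")
})

test_that("replicate correlation matches the oracle and is PSD", {
  set.seed(33)
  m <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, sprintf("s%d", 1:5)))
  cc <- replicate_correlation(m)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(cc[i, j], pearson_oracle(m[, i], m[, j]), tolerance = 1e-12)
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 5))
  expect_gte(min(eigen(cc, symmetric = TRUE)$values), -1e-10)

  dup <- cbind(m, s6 = m[, 1])
  expect_equal(replicate_correlation(dup)["s1", "s6"], 1)
  neg <- cbind(m, s6 = -m[, 1])
  expect_equal(replicate_correlation(neg)["s1", "s6"], -1)

  # sparse pair flagged missing
  sp <- m; sp[3:40, 4] <- NA; sp[1:2, 5] <- NA
  expect_true(is.na(replicate_correlation(sp, min_shared = 3)[4, 5]))
})

test_that("clustering groups planted treatments and ignores input order", {
  # two identical profiles merge first at height 0
  p <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  p[, 2] <- p[, 1]
  hc <- cluster_samples(p)
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("a", "b"))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)

  hits <- 0
  for (s in 1:20) {
    oc <- omics_sim_config(
      n_features = 400, effect_size = 2, noise_sd = 0.4,
      groups = c(vehicle = 3, drugA = 3, drugB = 3),
      planted_sets = list(drugA = 1:60, drugB = 61:120), seed = 200 + s)
    om <- simulate_omics(oc)
    nm <- normalize_lfq(om$matrix)
    ann <- om$annotations
    prof <- sapply(ann$sample[ann$treatment != "vehicle"], function(smp) {
      nm[, smp] - rowMeans(nm[, ann$sample[ann$treatment == "vehicle"]])
    })
    hc <- cluster_samples(prof)
    grp <- cutree(hc, 2)
    lab <- sub("_r\\d+$", "", names(grp))
    hits <- hits + (length(unique(tapply(grp, lab, function(g)
      paste(sort(unique(g)), collapse = "")))) == 2 &&
        all(tapply(grp, lab, function(g) length(unique(g))) == 1))
  }
  expect_gte(hits, 19)

  # permutation of columns yields the same merge partitions
  set.seed(34)
  q <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, letters[1:5]))
  h1 <- cluster_samples(q)
  h2 <- cluster_samples(q[, c(3, 1, 5, 2, 4)])
  canonical <- function(h, k) {
    grp <- split(names(cutree(h, k)), unname(cutree(h, k)))
    grp <- lapply(grp, sort)
    unname(grp[order(vapply(grp, `[`, "", 1))])
  }
  for (k in 2:4) expect_equal(canonical(h1, k), canonical(h2, k))

  expect_error(cluster_samples(q[, 1:2]), "3 profiles")
})
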