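#' Median-normalize a label-free quantification matrix
#'
#' Log2-transforms raw intensities and centres each sample (column) on its
#' median computed over observed values, so every sample's median becomes 0.
#' Missing values (NA) are carried through untouched.
#'
#' @param mat numeric matrix, features x samples; raw positive intensities
#'   when `log2 = TRUE`, already-log2 values when `log2 = FALSE`.
#' @param log2 apply the log2 transform first.
#' @return matrix of normalized log2 intensities.
#' @export
normalize_lfq <- function(mat, log2 = TRUE) {
  assert_that(is.matrix(mat) && is.numeric(mat), "mat must be a numeric matrix")
  if (log2) {
    assert_that(all(mat > 0, na.rm = TRUE),
                "raw intensities must be > 0 for the log2 transform")
    mat <- base::log2(mat)
  }
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs < 2))
    stop_ag("sample(s) with fewer than 2 observed values: ",
            paste(colnames(mat)[n_obs < 2], collapse = ", "))
  meds <- apply(mat, 2, median, na.rm = TRUE)
  sweep(mat, 2, meds, "-")
}

group_columns <- function(mat, annotations, group) {
  assert_that(all(c("sample", "treatment") %in% names(annotations)),
              "annotations must have columns sample and treatment")
  smp <- annotations$sample[annotations$treatment == group]
  assert_that(length(smp) >= 2,
              sprintf("group '%s' needs >= 2 replicates", group))
  assert_that(all(smp %in% colnames(mat)),
              sprintf("samples of group '%s' missing from the matrix", group))
  smp
}

#' Per-feature log2 fold changes between two treatment groups
#'
#' Mean normalized log2 intensity in the treatment group minus the control
#' group, per feature.  Features observed in fewer than 2 replicates of
#' either group are returned as NA and flagged.
#'
#' @param norm_mat normalized log2 matrix from [normalize_lfq()].
#' @param annotations data frame with columns sample and treatment.
#' @param treatment,control treatment labels.
#' @return named numeric vector of log2 fold changes (NA where
#'   under-observed), with the flagged feature names in
#'   `attr(, "underobserved")`.
#' @export
log2fc <- function(norm_mat, annotations, treatment, control) {
  tcols <- group_columns(norm_mat, annotations, treatment)
  ccols <- group_columns(norm_mat, annotations, control)
  tm <- norm_mat[, tcols, drop = FALSE]
  cm <- norm_mat[, ccols, drop = FALSE]
  ok <- rowSums(!is.na(tm)) >= 2 & rowSums(!is.na(cm)) >= 2
  fc <- rowMeans(tm, na.rm = TRUE) - rowMeans(cm, na.rm = TRUE)
  fc[!ok] <- NA_real_
  structure(fc, underobserved = rownames(norm_mat)[!ok])
}

#' Internal significance stand-in: Welch test with BH adjustment
#'
#' Per-feature Welch two-sample t-test between the groups with
#' Benjamini-Hochberg adjustment.  This is a stand-in for an externally
#' supplied significance column, intended for synthetic data; analyses of
#' real experiments should pass their own flags to [altered_set()].
#'
#' @inheritParams log2fc
#' @param alpha BH-adjusted significance level.
#' @return named logical vector of per-feature flags (NA-safe: FALSE where
#'   the test is not computable).
#' @export
significance_flags <- function(norm_mat, annotations, treatment, control,
                               alpha = 0.05) {
  tcols <- group_columns(norm_mat, annotations, treatment)
  ccols <- group_columns(norm_mat, annotations, control)
  p <- apply(norm_mat, 1, function(row) {
    x <- row[tcols]; y <- row[ccols]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (sd(x) == 0 && sd(y) == 0) return(1)
    tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
  })
  padj <- p.adjust(p, method = "BH")
  flags <- !is.na(padj) & padj <= alpha
  names(flags) <- rownames(norm_mat)
  flags
}

#' Significantly altered feature set of a treatment
#'
#' Features that are flagged significant AND have |log2FC| at or above the
#' cutoff (boundary inclusive).
#'
#' @inheritParams log2fc
#' @param flags named logical per-feature significance vector; when `NULL`,
#'   `auto_flags = TRUE` computes the internal Welch/BH stand-in (see
#'   [significance_flags()]), otherwise an error directs the user to supply
#'   flags.
#' @param min_abs_log2fc minimum absolute log2 fold change.
#' @param auto_flags allow the internal stand-in test.
#' @return an object of class `altered_set`: list with `treatment`,
#'   `features` (character vector), `cutoff` and `log2fc` (of the members).
#' @export
altered_set <- function(norm_mat, annotations, treatment, control,
                        flags = NULL, min_abs_log2fc = 0.5,
                        auto_flags = FALSE) {
  if (is.null(flags)) {
    if (!auto_flags)
      stop_ag("no significance flags supplied; pass `flags` or set ",
              "`auto_flags = TRUE` to use the internal Welch/BH stand-in test")
    flags <- significance_flags(norm_mat, annotations, treatment, control)
  }
  assert_that(is.logical(flags) && length(flags) == nrow(norm_mat),
              "flags must be one logical per matrix feature")
  fc <- log2fc(norm_mat, annotations, treatment, control)
  sel <- !is.na(fc) & flags & abs(fc) >= min_abs_log2fc
  structure(list(treatment = treatment,
                 features = rownames(norm_mat)[sel],
                 cutoff = min_abs_log2fc,
                 log2fc = fc[sel]),
            class = "altered_set")
}

#' @export
print.altered_set <- function(x, ...) {
  cat(sprintf("altered set '%s': %d feature(s) at |log2FC| >= %.2f\n",
              x$treatment, length(x$features), x$cutoff))
  invisible(x)
}

as_feature_set <- function(x) {
  if (inherits(x, "altered_set")) x$features else as.character(x)
}

#' Venn-style overlap between two altered sets
#'
#' 100 x |intersection| / |union| of the two feature sets.  Per-set shared
#' fractions (|intersection| / |A| and / |B|) are attached as attributes
#' since both conventions appear in practice.
#'
#' @param a,b `altered_set` objects or character vectors of feature ids.
#' @return percent in [0, 100], with attributes `pct_of_a` and `pct_of_b`.
#' @export
overlap_percent <- function(a, b) {
  a <- unique(as_feature_set(a)); b <- unique(as_feature_set(b))
  if (length(a) == 0 && length(b) == 0)
    stop_ag("both sets are empty; overlap undefined")
  inter <- length(intersect(a, b))
  structure(100 * inter / length(union(a, b)),
            pct_of_a = if (length(a)) 100 * inter / length(a) else NA_real_,
            pct_of_b = if (length(b)) 100 * inter / length(b) else NA_real_)
}

#' Sample-by-sample replicate correlation matrix
#'
#' Pearson correlation between every pair of samples over the features
#' observed in both; pairs sharing fewer than `min_shared` features are
#' flagged missing (NA).  The diagonal is exactly 1.
#'
#' @param mat numeric matrix, features x samples (normalized or raw log2).
#' @param min_shared minimum number of pairwise-complete features.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
replicate_correlation <- function(mat, min_shared = 3) {
  assert_that(is.matrix(mat) && ncol(mat) >= 2, "need >= 2 samples")
  obs <- !is.na(mat)
  shared <- crossprod(obs)
  cc <- suppressWarnings(cor(mat, use = "pairwise.complete.obs"))
  cc[shared < min_shared] <- NA_real_
  diag(cc) <- 1
  cc
}

#' Agglomerative clustering of fold-change profiles
#'
#' Average-linkage hierarchical clustering on correlation distance
#' (1 - Pearson) between per-sample (or per-treatment) log2 fold-change
#' profiles — the unsupervised grouping used to check that treatments with
#' shared molecular targets cluster together.
#'
#' @param profiles numeric matrix, features x profiles (>= 3 columns).
#' @param method linkage passed to [stats::hclust()].
#' @return an object of class [stats::hclust].
#' @export
cluster_samples <- function(profiles, method = "average") {
  assert_that(is.matrix(profiles) && ncol(profiles) >= 3,
              "need at least 3 profiles to cluster")
  cc <- suppressWarnings(cor(profiles, use = "pairwise.complete.obs"))
  d <- as.dist(1 - cc)
  assert_that(all(is.finite(d)), "correlation distance has missing entries")
  hclust(d, method = method)
}
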