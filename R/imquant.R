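check_channel <- function(img, name = "image") {
  assert_that(is.matrix(img) && is.numeric(img),
              sprintf("%s must be a numeric matrix", name))
  assert_that(all(is.finite(img)), sprintf("%s has non-finite pixels", name))
  invisible(TRUE)
}

#' Pixelwise Pearson colocalization between two channels
#'
#' Computes the Pearson correlation coefficient over the (optionally masked)
#' pixels of two registered channels, the standard intensity-based
#' colocalization measure.  Both r and r^2 are returned; the squared value is
#' the conventional headline number for antibody co-staining.
#'
#' @param a,b numeric matrices of identical shape.
#' @param mask optional logical matrix of the same shape; `NULL` uses all
#'   pixels.
#' @return an object of class `coloc_result`: list with `r`, `r_squared`,
#'   `n_pixels_used` and `mask` (`"all"` or `"custom"`).
#' @export
pixel_pcc <- function(a, b, mask = NULL) {
  check_channel(a, "a"); check_channel(b, "b")
  assert_that(all(dim(a) == dim(b)), "channel shapes differ")
  if (is.null(mask)) {
    x <- as.vector(a); y <- as.vector(b); mlab <- "all"
  } else {
    assert_that(is.logical(mask) && all(dim(mask) == dim(a)),
                "mask must be a logical matrix matching the channels")
    x <- a[mask]; y <- b[mask]; mlab <- "custom"
  }
  assert_that(length(x) >= 2, "need at least 2 pixels")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop_ag("a channel is constant within the mask; correlation undefined")
  r <- cor(x, y)
  structure(list(r = r, r_squared = r^2, n_pixels_used = length(x),
                 mask = mlab), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("pixelwise PCC: r = %.4f (r^2 = %.4f) over %d pixels (%s)\n",
              x$r, x$r_squared, x$n_pixels_used, x$mask))
  invisible(x)
}

# 8-connectivity labeling: EBImage::bwlabel is 4-connected, so components
# touching only diagonally are merged afterwards with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n < 2) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nrow(lab), -ncol(lab)]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -ncol(lab)]), as.vector(lab[-nrow(lab), -1]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    while (parent[a] != a) a <- parent[a]
    while (parent[b] != b) b <- parent[b]
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), function(i) {
    while (parent[i] != i) i <- parent[i]; i
  }, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Detect punctate aggregates in a single channel
#'
#' The detection pipeline: Gaussian blur, white top-hat filtering with a disk
#' structuring element (which isolates bright structures smaller than the
#' disk), thresholding, 8-connectivity component labeling, and an area
#' filter.  The default threshold rule, mean + k SD of the filtered image, is
#' adaptive to global additive intensity offsets.  Spots whose thresholded
#' footprints touch are split on the distance transform by default
#' (`split_touching`), since nearby diffraction-limited puncta commonly
#' bridge at threshold even when their centres are several widths apart.
#'
#' @param img numeric matrix (single channel).
#' @param sigma Gaussian blur SD in px (> 0).
#' @param tophat_radius disk structuring-element radius in px (> 0).
#' @param threshold_k threshold rule multiplier: threshold = mean + k * SD of
#'   the filtered image.
#' @param threshold absolute threshold overriding the rule, or `NULL`.
#' @param min_area,max_area object area bounds in px^2 (inclusive).
#' @param split_touching split touching objects with a distance-transform
#'   watershed after thresholding.
#' @return an object of class `object_set`: data frame with one row per
#'   surviving object (label, area, centroid_row, centroid_col — 0-based —
#'   and mean_intensity of the original image), with the filtered label
#'   matrix in `attr(, "labels")` and the parameters in `attr(, "params")`.
#' @export
detect_aggregates <- function(img, sigma = 1, tophat_radius = 5,
                              threshold_k = 3, threshold = NULL,
                              min_area = 4, max_area = 10000,
                              split_touching = TRUE) {
  check_channel(img)
  assert_that(sigma > 0, "sigma must be > 0")
  assert_that(tophat_radius > 0, "tophat_radius must be > 0")
  blurred <- EBImage::gblur(img, sigma = sigma)
  brush <- EBImage::makeBrush(2 * round(tophat_radius) + 1, shape = "disc")
  filtered <- EBImage::whiteTopHat(blurred, brush)
  thr <- threshold %||% (mean(filtered) + threshold_k * sd(filtered))
  mask <- filtered > thr
  lab <- if (split_touching && any(mask)) {
    m <- matrix(as.integer(EBImage::watershed(EBImage::distmap(mask),
                                              tolerance = 1)),
                nrow(mask), ncol(mask))
    storage.mode(m) <- "integer"; m
  } else label_components8(mask)
  params <- list(sigma = sigma, tophat_radius = tophat_radius,
                 threshold_k = threshold_k, threshold = thr,
                 min_area = min_area, max_area = max_area)
  n <- max(lab)
  if (n == 0) {
    out <- data.frame(label = integer(0), area = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      mean_intensity = numeric(0))
    return(structure(out, class = c("object_set", "data.frame"),
                     labels = lab, params = params))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  area <- tabulate(l, n)
  cr <- tapply(idx[, 1], l, mean) - 1   # 0-based centroids
  cc <- tapply(idx[, 2], l, mean) - 1
  mi <- tapply(img[lab > 0], l, mean)
  keep <- which(area >= min_area & area <= max_area)
  labels_kept <- lab
  labels_kept[!(lab %in% keep)] <- 0L
  out <- data.frame(label = keep, area = area[keep],
                    centroid_row = unname(cr[as.character(keep)]),
                    centroid_col = unname(cc[as.character(keep)]),
                    mean_intensity = unname(mi[as.character(keep)]))
  structure(out[order(out$label), , drop = FALSE],
            class = c("object_set", "data.frame"),
            labels = labels_kept, params = params)
}

#' Aggregate counts along an image time course
#'
#' Runs [detect_aggregates()] with fixed parameters on every frame of a
#' live-cell series and returns the count per frame.
#'
#' @param stack list of numeric matrices of identical shape.
#' @param ... parameters passed to [detect_aggregates()].
#' @return integer vector of object counts, one per frame.
#' @export
aggregate_timecourse <- function(stack, ...) {
  assert_that(is.list(stack) && length(stack) >= 1, "stack must be a non-empty list")
  shp <- dim(stack[[1]])
  for (f in stack) {
    check_channel(f)
    assert_that(all(dim(f) == shp), "all frames must share one shape")
  }
  vapply(stack, function(f) nrow(detect_aggregates(f, ...)), integer(1))
}

#' Puncta area fraction within a cell mask
#'
#' The normalized area readout for galectin-3-type puncta: total pixel area
#' of detected objects lying inside the cell mask, divided by the mask area.
#'
#' @param img numeric matrix (puncta channel).
#' @param cell_mask logical matrix of the same shape; must be non-empty.
#' @param ... parameters passed to [detect_aggregates()].
#' @return fraction in [0, 1], with the underlying `object_set` in
#'   `attr(, "objects")`.
#' @export
puncta_area_fraction <- function(img, cell_mask, ...) {
  check_channel(img)
  assert_that(is.logical(cell_mask) && all(dim(cell_mask) == dim(img)),
              "cell_mask must be a logical matrix matching img")
  assert_that(sum(cell_mask) > 0, "cell mask is empty")
  objs <- detect_aggregates(img, ...)
  lab <- attr(objs, "labels")
  frac <- sum(lab > 0 & cell_mask) / sum(cell_mask)
  structure(frac, objects = objs)
}
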