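PLATE_ROLES <- c("compound", "vehicle", "negative-control", "positive-control")

#' Write a plate to disk (one event CSV per well plus a layout CSV)
#'
#' @param plate list with `wells` and `layout`.
#' @param dir output directory (created if needed).
#' @return invisibly, the layout file path.
#' @export
write_plate <- function(plate, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (w in names(plate$wells))
    write.csv(plate$wells[[w]], file.path(dir, paste0(w, ".csv")),
              row.names = FALSE)
  lp <- file.path(dir, "layout.csv")
  write.csv(plate$layout, lp, row.names = FALSE)
  invisible(lp)
}

#' Load and validate a plate from event CSVs and a layout CSV
#'
#' Every well in the layout must have an event file with the expected schema
#' (event_id, donor, acceptor, fret, viability); duplicate wells and unknown
#' role labels are rejected with descriptive errors.
#'
#' @param dir directory holding `<well>.csv` event files.
#' @param layout_path layout CSV (well, compound, concentration, role,
#'   optionally replicate); defaults to `layout.csv` inside `dir`.
#' @return list with `wells` and `layout`, the package's plate structure.
#' @export
load_plate <- function(dir, layout_path = file.path(dir, "layout.csv")) {
  assert_that(file.exists(layout_path),
              paste("layout file not found:", layout_path))
  layout <- read.csv(layout_path, stringsAsFactors = FALSE)
  need <- c("well", "compound", "concentration", "role")
  missing <- setdiff(need, names(layout))
  if (length(missing))
    stop_ag("layout is missing column(s): ", paste(missing, collapse = ", "))
  dup <- layout$well[duplicated(layout$well)]
  if (length(dup))
    stop_ag("duplicate well(s) in layout: ", paste(unique(dup), collapse = ", "))
  bad_role <- setdiff(unique(layout$role), PLATE_ROLES)
  if (length(bad_role))
    stop_ag("unknown role label(s): ", paste(bad_role, collapse = ", "),
            "; allowed roles are: ", paste(PLATE_ROLES, collapse = ", "))
  wells <- vector("list", nrow(layout))
  names(wells) <- layout$well
  for (w in layout$well) {
    f <- file.path(dir, paste0(w, ".csv"))
    if (!file.exists(f))
      stop_ag(sprintf("no event file for well '%s' (expected %s)", w, f))
    ev <- read.csv(f, stringsAsFactors = FALSE)
    check_event_table(ev, require_rows = FALSE)
    wells[[w]] <- ev
  }
  list(wells = wells, layout = layout)
}

#' Read or write a single image channel
#'
#' Images are stored as 16-bit grayscale TIFF: intensities are rounded to
#' the 0..65535 integer grid on write and restored to that scale on read
#' losslessly.  PNG is supported as an 8-bit convenience format (values are
#' quantized to 256 levels, i.e. to multiples of 257 on the 16-bit scale).
#'
#' @param img numeric matrix with values in [0, 65535].
#' @param path file path; format chosen by extension (.tif/.tiff/.png).
#' @return `read_channel_image` returns a numeric matrix on the 0..65535
#'   scale; `write_channel_image` returns the path invisibly.
#' @export
write_channel_image <- function(img, path) {
  check_channel(img)
  assert_that(max(img) <= 65535 && min(img) >= 0,
              "intensities must lie in [0, 65535] for 16-bit storage")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(round(img) / 65535, path, bits.per.sample = 16L)
  else if (ext == "png") png::writePNG(round(img / 257) / 255, path)
  else stop_ag("unsupported image extension: ", ext)
  invisible(path)
}

#' @rdname write_channel_image
#' @export
read_channel_image <- function(path) {
  assert_that(file.exists(path), paste("image not found:", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else if (ext == "png") png::readPNG(path)
  else stop_ag("unsupported image extension: ", ext)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  round(raw * 65535)
}

#' Write / read an omics matrix with its sample annotations
#'
#' @param mat numeric feature x sample matrix.
#' @param annotations data frame with columns sample, treatment, replicate.
#' @param dir output directory.
#' @return `write_omics` invisibly returns `dir`; `read_omics` returns a
#'   list with `matrix` and `annotations`.
#' @export
write_omics <- function(mat, annotations, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(data.frame(feature = rownames(mat), mat, check.names = FALSE),
              file.path(dir, "matrix.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(annotations, file.path(dir, "samples.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_omics
#' @export
read_omics <- function(dir) {
  m <- read.delim(file.path(dir, "matrix.tsv"), check.names = FALSE)
  ann <- read.delim(file.path(dir, "samples.tsv"))
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m[[1]]
  assert_that(!anyDuplicated(rownames(mat)), "duplicate feature ids")
  assert_that(all(colnames(mat) %in% ann$sample), "unannotated sample column")
  list(matrix = mat, annotations = ann)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; referenced paths must exist.
#'
#' @param path YAML file.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), paste("config not found:", path))
  cfg <- yaml::read_yaml(path)
  known <- c("plate_dir", "layout", "output_dir", "threshold", "tiers",
             "mfi_stat", "mfi_scope", "fret_quantile", "seed", "simulate")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop_ag("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in c("plate_dir", "layout"))
    if (!is.null(cfg[[key]]))
      assert_that(file.exists(cfg[[key]]),
                  sprintf("config path '%s' does not exist: %s", key, cfg[[key]]))
  structure(cfg, class = "run_config")
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end screen workflow
#'
#' Loads (or simulates) a plate, fits the screen with [fret_screen()], and
#' writes the stage outputs — well summaries, per-well screen table, hit
#' table and a QC JSON block — into the output directory.  The report is a
#' pure function of the inputs, configuration and seed.
#'
#' @param config a `run_config` list (see [read_run_config()]); recognised
#'   keys: `plate_dir`/`layout` (or `simulate: true` with `seed`),
#'   `output_dir`, `threshold`, `tiers`, `mfi_stat`, `mfi_scope`,
#'   `fret_quantile`, `seed`.
#' @return an object of class `run_report`: list with the fitted screen, the
#'   paths written, the configuration hash and the package version.
#' @export
run_screen <- function(config) {
  out_dir <- config$output_dir %||% stop_ag("config needs output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_ag(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  }
  plate <- stage("load", {
    if (isTRUE(config$simulate))
      simulate_plate(plate_sim_config(seed = config$seed %||% 1))
    else load_plate(config$plate_dir,
                    config$layout %||% file.path(config$plate_dir, "layout.csv"))
  })
  gates <- stage("gate", auto_gate(plate,
                                   fret_quantile = config$fret_quantile %||% 0.999))
  fit <- stage("screen", fret_screen(
    plate, gates = gates,
    threshold = config$threshold %||% 1.5,
    tiers = config$tiers %||% "all",
    mfi_stat = config$mfi_stat %||% "median",
    mfi_scope = config$mfi_scope %||% "positive"))
  paths <- list(
    summaries = file.path(out_dir, "well_summaries.tsv"),
    screen = file.path(out_dir, "screen_table.tsv"),
    hits = file.path(out_dir, "hit_table.tsv"),
    qc = file.path(out_dir, "qc.json"))
  stage("write", {
    write.table(fit$summaries, paths$summaries, sep = "\t", row.names = FALSE,
                quote = FALSE)
    write.table(as.data.frame(fit$screen), paths$screen, sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(as.data.frame(fit$hits), paths$hits, sep = "\t",
                row.names = FALSE, quote = FALSE)
    qc <- list(z_prime = fit$qc, controls = fit$controls,
               threshold = fit$threshold, tiers = fit$tiers,
               gates = unclass(fit$gates),
               version = as.character(packageVersion("aggrescreen")),
               config_hash = config_hash(unclass(config)))
    jsonlite::write_json(qc, paths$qc, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  })
  structure(list(fit = fit, paths = paths,
                 config_hash = config_hash(unclass(config)),
                 version = as.character(packageVersion("aggrescreen"))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("screen run report (config", substr(x$config_hash, 1, 8), ")\n")
  print(x$fit)
  cat("outputs:\n")
  for (p in x$paths) cat(" ", p, "\n")
  invisible(x)
}
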