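# Shared I/O: grayscale image and stack reading (TIFF/PNG), CSV and JSON
# writers, and the run configuration with validated defaults.

#' Read a grayscale image
#'
#' Reads TIFF or PNG; color images are converted to grayscale by averaging
#' the color channels. Values are returned on their stored scale (0-255 for
#' 8-bit, 0-65535 for 16-bit TIFF).
#'
#' @param path image file path.
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = {
      x <- tiff::readTIFF(path, as.is = TRUE)
      if (is.list(x)) x <- x[[1]]
      x
    },
    png = png::readPNG(path) * 255,
    io_error(sprintf("unsupported image format '%s' for %s (TIFF or PNG expected)",
                     ext, path)))
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3, dim(img)[3])),
                                               drop = FALSE], c(1, 2), mean)
  as.matrix(img)
}

#' Read a directory of TIFF slices as a 3D stack
#'
#' Slices are ordered by file name; all slices must share the same shape.
#'
#' @param directory directory containing `.tif`/`.tiff` slice files.
#' @return 3D array, slices along the third dimension.
#' @export
read_stack <- function(directory) {
  if (!dir.exists(directory)) io_error(sprintf("directory not found: %s", directory))
  files <- sort(list.files(directory, pattern = "\\.tiff?$", ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(files)) io_error(sprintf("no TIFF slices in %s", directory))
  slices <- lapply(files, read_image)
  d1 <- dim(slices[[1]])
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]]), d1))
      io_error(sprintf("slice %s has shape %s, expected %s",
                       basename(files[i]), paste(dim(slices[[i]]), collapse = "x"),
                       paste(d1, collapse = "x")))
  }
  array(unlist(slices), dim = c(d1, length(slices)))
}

#' Write a 3D array as a directory of 8-bit TIFF slices
#'
#' Counterpart of [read_stack()], mainly for synthetic end-to-end tests.
#'
#' @param stack 3D numeric array on a 0-255 scale.
#' @param directory output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_stack <- function(stack, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(stack)[3]
  paths <- character(nz)
  for (k in seq_len(nz)) {
    paths[k] <- file.path(directory, sprintf("slice_%04d.tif", k))
    tiff::writeTIFF(stack[, , k] / 255, paths[k], bits.per.sample = 8L)
  }
  invisible(paths)
}

#' Write detected ommatidia as CSV
#'
#' One row per ommatidium with columns `id`, `row_px`, `col_px`,
#' `diameter_px`, `diameter_um` (comma separator, '.' decimal, UTF-8,
#' header row).
#'
#' @param result an `ommatidia_set`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_ommatidia_csv <- function(result, path) {
  stopifnot(inherits(result, "ommatidia_set"))
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline summary as JSON
#'
#' @param summary named list (e.g. `run_oda3d(...)$summary`).
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

.config_defaults <- list(
  n_fundamentals = 3,
  cutoff_factor = 1.25,
  min_distance_factor = 0.25,
  k_mad = 5,
  window_deg = 90,
  neighborhood_radius = 5,
  section_width = 1,
  projection_radius_um = 1e5,
  lens_diameter_guess_um = NULL,
  voxel_size_um = 1,
  density_range = NULL,
  correct_clusters = TRUE,
  de_iter = 20,
  de_pop = 15,
  seed = 1
)

#' Run configuration
#'
#' All tunables of both pipelines with their defaults: `n_fundamentals` (3),
#' `cutoff_factor` (1.25), `min_distance_factor` (0.25), `k_mad` (5),
#' `window_deg` (90), `neighborhood_radius` (5 lens diameters),
#' `section_width` (1 lens diameter), `projection_radius_um` (1e5 um =
#' 10 cm), `lens_diameter_guess_um` (none), `voxel_size_um` (1),
#' `density_range` (none), `correct_clusters` (TRUE), `de_iter` / `de_pop`
#' (optimizer budget), `seed` (1). Unknown keys are rejected.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    config_error("config overrides must be named")
  unknown <- setdiff(names(over), names(.config_defaults))
  if (length(unknown))
    config_error(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(.config_defaults, over, keep.null = TRUE)
  structure(cfg, class = c("run_config", "list"))
}

#' Read a run configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file of config keys (see
#'   [run_config()]); unknown keys are rejected.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    io_error(sprintf("unsupported config format '%s'", ext)))
  do.call(run_config, as.list(vals))
}
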