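# TIFF dialect: one multi-page file per cell, page order dark-field,
# bright-field, autofluorescence; 16-bit unsigned with a fixed linear scale
# of .TIFF_COUNTS_PER_UNIT camera counts per intensity unit (so the
# representable range is [0, 65535 / scale] intensity units). The scale and
# channel order are also recorded in images_metadata.yaml next to the files.
.TIFF_COUNTS_PER_UNIT <- 1000

.quantize16 <- function(m) {
  counts <- round(pmin(pmax(m, 0), 65535 / .TIFF_COUNTS_PER_UNIT) *
                    .TIFF_COUNTS_PER_UNIT)
  counts / 65535
}

#' Write per-cell images as multi-page TIFF files
#'
#' One file per cell, named `{sample}_{cell_id}.tif`, pages ordered
#' dark-field, bright-field, autofluorescence, 16-bit unsigned at a fixed
#' intensity scale. A `images_metadata.yaml` sidecar documents the dialect.
#'
#' @param cells List of `cell_image` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cell_images <- function(cells, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    fn <- file.path(dir, sprintf("%s_%s.tif", cell$meta$sample,
                                 cell$meta$cell_id))
    pages <- lapply(list(cell$darkfield, cell$brightfield, cell$autofluor),
                    .quantize16)
    tiff::writeTIFF(pages, fn, bits.per.sample = 16L, compression = "none")
    paths[i] <- fn
  }
  yaml::write_yaml(list(channel_order = c("darkfield", "brightfield",
                                          "autofluorescence"),
                        bits_per_sample = 16L,
                        counts_per_intensity_unit = .TIFF_COUNTS_PER_UNIT),
                   file.path(dir, "images_metadata.yaml"))
  invisible(paths)
}

#' Read per-cell TIFF images
#'
#' Reads every `.tif`/`.tiff` file in `path` written in the package's
#' dialect (three pages: dark-field, bright-field, autofluorescence).
#' Sample label and cell id are parsed from the filename
#' `{sample}_{cell_id}.tif` (the cell id is the token after the final
#' underscore). Files with the wrong page count are skipped with a warning;
#' zero readable files is an error.
#'
#' @param path Directory of TIFF files.
#' @return List of `cell_image` objects (`mask` is `NULL`: segmentation is
#'   recomputed by the gating stage); attribute `"n_skipped"` counts
#'   skipped files.
#' @export
read_cell_images <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- list.files(path, pattern = "\\.tiff?$", full.names = TRUE)
  if (length(files) == 0L) stop("no TIFF files in ", path)
  cells <- list()
  skipped <- 0L
  for (fn in files) {
    pages <- tryCatch(tiff::readTIFF(fn, all = TRUE), error = function(e) NULL)
    if (is.null(pages) || length(pages) != 3L) {
      warning("skipping malformed TIFF (expected 3 pages): ", basename(fn))
      skipped <- skipped + 1L
      next
    }
    base <- tools::file_path_sans_ext(basename(fn))
    cell_id <- sub("^.*_", "", base)
    sample <- sub("_[^_]*$", "", base)
    unscale <- function(p) round(p * 65535) / .TIFF_COUNTS_PER_UNIT
    cells[[length(cells) + 1L]] <- structure(list(
      darkfield = unscale(pages[[1L]]),
      brightfield = unscale(pages[[2L]]),
      autofluor = unscale(pages[[3L]]),
      mask = NULL,
      meta = list(cell_id = cell_id, sample = sample, class = NA_character_,
                  activation = NA_real_)), class = "cell_image")
  }
  if (length(cells) == 0L) stop("no readable 3-page TIFF files in ", path)
  attr(cells, "n_skipped") <- skipped
  cells
}

#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end analysis, with the
#' defaults of the synthetic study design. The configuration round-trips
#' losslessly through YAML via [write_run_config()] / [read_run_config()].
#'
#' Exactly one input mode is active: simulate a cohort (`simulate = TRUE`),
#' read per-cell TIFFs (`image_dir`), or start from a precomputed feature
#' table (`feature_csv`, which skips the imaging stages).
#'
#' @param out_dir Output directory for stage CSVs and metadata.
#' @param seed Global seed (drives cohort simulation).
#' @param simulate Generate the synthetic cohort as input.
#' @param image_dir Optional directory of per-cell TIFFs to read instead.
#' @param feature_csv Optional precomputed feature table (columns
#'   `cell_id`, `sample`, then the feature columns).
#' @param write_images Also write the simulated cohort as TIFFs.
#' @param sim_params List of [cell_sim_params()] overrides.
#' @param cohort List of [cohort_config()] overrides (`samples` as a
#'   data.frame or list, `n_distractors`).
#' @param gate List of [gate_config()] overrides.
#' @param sigma Diffusion-map bandwidth (`"auto"` or positive number).
#' @param alpha Diffusion-map density-normalisation exponent.
#' @param path_degree Trajectory polynomial degree.
#' @param run_pca Also compute the 3-component PCA baseline.
#' @param embed_per_sample Must remain `FALSE`: the embedding is defined on
#'   the pooled multi-sample matrix (pooling maximises state-space
#'   occupancy and makes all cells directly comparable); requesting a
#'   per-sample embedding is refused.
#' @param control_label,high_label Sample labels used by the statistics
#'   stage and the index sign convention.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       simulate = TRUE,
                       image_dir = NULL,
                       feature_csv = NULL,
                       write_images = FALSE,
                       sim_params = list(),
                       cohort = list(),
                       gate = list(),
                       sigma = "auto",
                       alpha = 1,
                       path_degree = 2L,
                       run_pca = FALSE,
                       embed_per_sample = FALSE,
                       control_label = "control",
                       high_label = "eotaxin_5h") {
  if (isTRUE(embed_per_sample))
    stop("per-sample embedding is refused: the diffusion map must be fitted ",
         "on the pooled multi-sample feature matrix so that indices are ",
         "comparable across samples")
  if (!is.null(feature_csv) && !file.exists(feature_csv))
    stop("feature_csv does not exist: ", feature_csv)
  if (!is.null(image_dir) && !dir.exists(image_dir))
    stop("image_dir does not exist: ", image_dir)
  if (is.null(feature_csv) && is.null(image_dir) && !isTRUE(simulate))
    stop("no input: enable simulate or provide image_dir or feature_csv")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = isTRUE(simulate) && is.null(image_dir) &&
                   is.null(feature_csv),
                 image_dir = image_dir, feature_csv = feature_csv,
                 write_images = isTRUE(write_images),
                 sim_params = sim_params, cohort = cohort, gate = gate,
                 sigma = sigma, alpha = alpha,
                 path_degree = as.integer(path_degree),
                 run_pca = isTRUE(run_pca),
                 embed_per_sample = FALSE,
                 control_label = control_label, high_label = high_label),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$cohort <- lapply(x$cohort, function(v)
    if (is.data.frame(v)) as.list(v) else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$cohort$samples))
    x$cohort$samples <- as.data.frame(x$cohort$samples,
                                      stringsAsFactors = FALSE)
  x$simulate <- isTRUE(x$simulate)
  do.call(run_config, x)
}
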