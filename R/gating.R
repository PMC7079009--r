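#' Segment the cell from a dark-field image
#'
#' Threshold-based whole-cell segmentation of a single-cell dark-field
#' frame: Otsu threshold on the intensity-normalised image, morphological
#' closing with a radius-1 disk, retention of the largest connected
#' component, and hole filling. A constant (or otherwise unthresholdable)
#' image yields an empty mask, which downstream code treats as a failed
#' event rather than an error.
#'
#' Normalising to the image's own intensity range before thresholding makes
#' the segmentation invariant to global intensity scaling.
#'
#' @param darkfield Numeric matrix of non-negative intensities.
#' @return Logical matrix of the same dimensions (possibly all `FALSE`).
#' @export
segment_cell <- function(darkfield) {
  if (!is.matrix(darkfield) || length(darkfield) == 0L)
    stop("darkfield must be a non-empty numeric matrix")
  if (!all(is.finite(darkfield)) || any(darkfield < 0))
    stop("darkfield intensities must be finite and non-negative")
  rng <- range(darkfield)
  if (diff(rng) == 0)
    return(matrix(FALSE, nrow(darkfield), ncol(darkfield)))
  norm <- (darkfield - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256L)
  bw <- EBImage::Image(norm > thr)
  bw <- EBImage::closing(bw, EBImage::makeBrush(3L, "disc"))
  lab <- EBImage::bwlabel(bw)
  labs <- as.integer(lab)
  labs <- labs[labs > 0L]
  if (length(labs) == 0L)
    return(matrix(FALSE, nrow(darkfield), ncol(darkfield)))
  keep <- as.integer(names(which.max(table(labs))))
  comp <- EBImage::Image(ifelse(as.matrix(lab) == keep, 1, 0))
  filled <- EBImage::fillHull(comp)
  matrix(as.matrix(filled) > 0.5, nrow(darkfield), ncol(darkfield))
}

#' Integrate channel intensity over a mask
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix of the same dimensions, with at least one
#'   `TRUE` pixel.
#' @return Sum of the pixel intensities inside the mask.
#' @export
integrate_channel <- function(image, mask) {
  stopifnot(is.matrix(image), is.logical(mask),
            all(dim(image) == dim(mask)))
  if (!any(mask)) stop("mask is empty")
  sum(image[mask])
}

#' Quadrant gate configuration
#'
#' Thresholds for the eosinophil identification gate on integrated
#' autofluorescence and integrated side-scatter, plus a mask-area window
#' that stands in for singlet/debris selection. Events must exceed both
#' intensity thresholds *strictly* and have a mask area within
#' `[min_mask_area, max_mask_area]` to pass.
#'
#' Default thresholds sit between the synthetic eosinophil cluster
#' (granule-rich: high scatter, high autofluorescence) and the distractor
#' leukocyte cluster (dim, granule-free) of the default generator profile.
#'
#' @param autofluor_threshold,sidescatter_threshold Intensity-unit
#'   thresholds (strict lower bounds).
#' @param min_mask_area,max_mask_area Pixel-area window (inclusive).
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(autofluor_threshold = 15,
                        sidescatter_threshold = 80,
                        min_mask_area = 250,
                        max_mask_area = 1600) {
  stopifnot(autofluor_threshold >= 0, sidescatter_threshold >= 0,
            min_mask_area >= 0, min_mask_area < max_mask_area)
  structure(list(autofluor_threshold = autofluor_threshold,
                 sidescatter_threshold = sidescatter_threshold,
                 min_mask_area = min_mask_area,
                 max_mask_area = max_mask_area),
            class = "gate_config")
}

#' Whole-cell event table for a set of cells
#'
#' Segments each cell's dark-field image and integrates the dark-field
#' (side-scatter) and autofluorescence channels over the mask. Cells whose
#' segmentation yields an empty mask get `mask_area = 0` and `NA`
#' intensities, and can never pass the gate.
#'
#' @param cells List of `cell_image` objects (e.g. `cohort$cells`).
#' @return List with `events` (a `data.frame`: `cell_id`, `sample`,
#'   `integrated_sidescatter`, `integrated_autofluorescence`, `mask_area`,
#'   `gated` — initialised `FALSE`) and `masks` (named list of logical
#'   matrices, empty-mask cells omitted).
#' @export
whole_cell_events <- function(cells) {
  stopifnot(is.list(cells), length(cells) > 0L)
  masks <- list()
  rows <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    m <- segment_cell(cell$darkfield)
    area <- sum(m)
    if (area > 0L) {
      ssc <- integrate_channel(cell$darkfield, m)
      af <- integrate_channel(cell$autofluor, m)
      masks[[cell$meta$cell_id]] <- m
    } else {
      ssc <- NA_real_; af <- NA_real_
    }
    rows[[i]] <- data.frame(cell_id = cell$meta$cell_id,
                            sample = cell$meta$sample,
                            integrated_sidescatter = ssc,
                            integrated_autofluorescence = af,
                            mask_area = area,
                            gated = FALSE,
                            stringsAsFactors = FALSE)
  }
  list(events = do.call(rbind, rows), masks = masks)
}

#' Apply the quadrant gate
#'
#' Retains events whose integrated autofluorescence and side-scatter are
#' both strictly above their thresholds and whose mask area lies inside the
#' configured window. Row order is preserved; the `gated` flag is set on
#' the returned subset. Gating an already-gated table is a no-op.
#'
#' @param events `data.frame` as produced by [whole_cell_events()].
#' @param gate A [gate_config()] object.
#' @return The gated subset of `events` with `gated = TRUE`.
#' @export
quadrant_gate <- function(events, gate = gate_config()) {
  stopifnot(is.data.frame(events), inherits(gate, "gate_config"))
  needed <- c("integrated_sidescatter", "integrated_autofluorescence", "mask_area")
  stopifnot(all(needed %in% names(events)))
  keep <- !is.na(events$integrated_autofluorescence) &
    !is.na(events$integrated_sidescatter) &
    events$integrated_autofluorescence > gate$autofluor_threshold &
    events$integrated_sidescatter > gate$sidescatter_threshold &
    events$mask_area >= gate$min_mask_area &
    events$mask_area <= gate$max_mask_area
  out <- events[keep, , drop = FALSE]
  out$gated <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
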