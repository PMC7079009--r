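#' @title Spatial feature families for dark-field cell images
#' @description
#' The per-cell profile pools four families computed on the dark-field
#' channel inside the segmentation mask, totalling 85 values by default:
#' \itemize{
#'   \item intensity statistics (11),
#'   \item radial intensity distribution (3 measures x 2 annuli = 6),
#'   \item morphological granularity spectrum (16 sieving steps),
#'   \item Haralick texture (13 statistics x 4 pixel offsets = 52).
#' }
#' A cell for which any family is undefined (e.g. an empty radial annulus,
#' or a pixel offset with no co-occurring in-mask pairs) is dropped from the
#' pooled table rather than imputed, so the feature matrix handed to the
#' embedding is always complete.
#' @name features
NULL

.HARALICK_STATS <- c("ASM", "Contrast", "Correlation", "Variance", "IDM",
                     "SumAverage", "SumVariance", "SumEntropy", "Entropy",
                     "DiffVariance", "DiffEntropy", "IMC1", "IMC2")

#' Names of the default 85-feature profile, in extraction order
#'
#' @param offsets GLCM pixel offsets (default `c(1, 2, 3, 5)`).
#' @param n_radial_bins Number of concentric annuli (default 2).
#' @param n_gran_steps Number of granularity sieving steps (default 16).
#' @return Character vector of feature names (length 85 at the defaults).
#' @export
feature_names <- function(offsets = c(1L, 2L, 3L, 5L),
                          n_radial_bins = 2L,
                          n_gran_steps = 16L) {
  c("Int_Integrated", "Int_Mean", "Int_Median", "Int_StdDev", "Int_MAD",
    "Int_Min", "Int_Max", "Int_LowerQuartile", "Int_UpperQuartile",
    "Int_MassDisplacement", "Int_EdgeMean",
    as.vector(t(outer(c("Rad_FracAtD", "Rad_MeanFrac", "Rad_RadialCV"),
                      seq_len(n_radial_bins),
                      function(a, b) paste0(a, "_b", b)))),
    sprintf("Gran_%02d", seq_len(n_gran_steps)),
    as.vector(vapply(offsets, function(d)
      paste0("Tex_", .HARALICK_STATS, "_d", d),
      character(length(.HARALICK_STATS)))))
}

#' Intensity statistics of the masked dark-field image
#'
#' Eleven statistics of the in-mask pixel intensities: integrated intensity,
#' mean, median, standard deviation (n-1 denominator), median absolute
#' deviation (unscaled), min, max, lower and upper quartiles (type-7
#' interpolation), mass displacement (Euclidean distance between the binary
#' mask centroid and the intensity-weighted centroid, in pixels; 0 for a
#' zero-intensity mask), and the mean intensity over the mask's 1-pixel
#' inner boundary (4-connectivity; frame-edge pixels count as boundary).
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix, at least one `TRUE` pixel.
#' @return Named numeric vector of length 11.
#' @export
intensity_features <- function(image, mask) {
  stopifnot(is.matrix(image), is.logical(mask), all(dim(image) == dim(mask)))
  if (!any(mask)) stop("mask is empty")
  v <- image[mask]
  total <- sum(v)
  rows <- row(mask)[mask]; cols <- col(mask)[mask]
  c_geo <- c(mean(rows), mean(cols))
  if (total > 0) {
    c_int <- c(sum(rows * v), sum(cols * v)) / total
    disp <- sqrt(sum((c_geo - c_int)^2))
  } else disp <- 0
  edge <- mask & !(.erode_cross(mask * 1) > 0)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  out <- c(total, mean(v), q[2L],
           if (length(v) > 1L) stats::sd(v) else 0,
           stats::median(abs(v - q[2L])),
           min(v), max(v), q[1L], q[3L], disp,
           mean(image[edge]))
  names(out) <- feature_names()[1:11]
  out
}

#' Radial intensity distribution
#'
#' Distances of in-mask pixels from the intensity-weighted centroid are
#' normalised by their in-mask maximum and cut into `n_bins` equal-width
#' concentric annuli. Per annulus: `FracAtD` (fraction of total in-mask
#' intensity), `MeanFrac` (`FracAtD` divided by the annulus's fraction of
#' mask pixels), and `RadialCV` (population coefficient of variation of the
#' mean intensity over 8 equal angular wedges intersecting the annulus;
#' defined as 0 when the wedge means are all zero).
#'
#' @param image Numeric matrix with non-negative in-mask total intensity.
#' @param mask Logical matrix.
#' @param n_bins Number of annuli (default 2).
#' @return Named numeric vector of length `3 * n_bins`, ordered
#'   `FracAtD_b1..`, `MeanFrac_b1..`, `RadialCV_b1..` interleaved by bin as
#'   in [feature_names()].
#' @export
radial_distribution <- function(image, mask, n_bins = 2L) {
  stopifnot(is.matrix(image), is.logical(mask), all(dim(image) == dim(mask)),
            n_bins >= 1L)
  if (!any(mask)) stop("mask is empty")
  v <- image[mask]
  total <- sum(v)
  if (!is.finite(total) || total <= 0)
    stop("total in-mask intensity must be positive for radial features")
  rows <- row(mask)[mask]; cols <- col(mask)[mask]
  cy <- sum(rows * v) / total; cx <- sum(cols * v) / total
  d <- sqrt((rows - cy)^2 + (cols - cx)^2)
  dmax <- max(d)
  bin <- if (dmax > 0) pmin(floor(d / dmax * n_bins) + 1L, n_bins) else
    rep(1L, length(d))
  ang <- atan2(rows - cy, cols - cx)
  wedge <- pmin(floor((ang + pi) / (2 * pi) * 8) + 1L, 8L)

  frac <- meanfrac <- rcv <- numeric(n_bins)
  n_mask <- length(v)
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    nb <- sum(sel)
    if (nb == 0L)
      stop(sprintf("radial annulus %d contains no pixels", b))
    frac[b] <- sum(v[sel]) / total
    meanfrac[b] <- frac[b] / (nb / n_mask)
    wm <- tapply(v[sel], wedge[sel], mean)
    mu <- mean(wm)
    rcv[b] <- if (mu > 0) sqrt(mean((wm - mu)^2)) / mu else 0
  }
  out <- c(frac, meanfrac, rcv)
  names(out) <- as.vector(t(outer(c("Rad_FracAtD", "Rad_MeanFrac", "Rad_RadialCV"),
                                  seq_len(n_bins),
                                  function(a, b) paste0(a, "_b", b))))
  out
}

#' Morphological granularity spectrum
#'
#' Iterative grayscale sieving of the masked image: with `I_0` the image
#' zeroed outside the mask and `I_k` its opening by the digital disc of
#' radius `k` (erosion by the 4-connected unit cross iterated `k` times,
#' followed by `k` dilations), step `k` reports
#' `G_k = 100 * (sum(I_{k-1}) - sum(I_k)) / sum(I_0)` — the percentage of
#' total intensity carried by structures erased between scales `k-1` and
#' `k`. Because the disc openings form a granulometry every `G_k >= 0` and
#' the spectrum sums to at most 100.
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param mask Logical matrix.
#' @param n_steps Number of sieving steps (default 16).
#' @return Named numeric vector `Gran_01..Gran_<n_steps>`; all zeros for a
#'   zero in-mask image.
#' @export
granularity_spectrum <- function(image, mask, n_steps = 16L) {
  stopifnot(is.matrix(image), is.logical(mask), all(dim(image) == dim(mask)),
            n_steps >= 1L)
  if (!any(mask)) stop("mask is empty")
  img <- image
  img[!mask] <- 0
  total <- sum(img)
  out <- numeric(n_steps)
  names(out) <- sprintf("Gran_%02d", seq_len(n_steps))
  if (total <= 0) return(out)
  prev_sum <- total
  ero <- img
  for (k in seq_len(n_steps)) {
    ero <- .erode_cross(ero)
    opened <- ero
    for (j in seq_len(k)) opened <- .dilate_cross(opened)
    cur_sum <- sum(opened)
    out[k] <- 100 * (prev_sum - cur_sum) / total
    prev_sum <- cur_sum
  }
  out
}

# quantize in-mask intensities to n_levels equal-width bins over the
# in-mask range; constant images map to level 1 everywhere
.glcm_quantize <- function(image, mask, n_levels = 8L) {
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  v <- image[mask]
  lo <- min(v); hi <- max(v)
  if (hi > lo)
    q[mask] <- pmin(floor((image[mask] - lo) / (hi - lo) * n_levels) + 1L,
                    n_levels)
  else q[mask] <- 1L
  q
}

# symmetric co-occurrence count matrix for one (dr, dc) offset
.glcm_counts <- function(q, dr, dc, n_levels = 8L) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r1) == 0L || length(c1) == 0L)
    return(matrix(0, n_levels, n_levels))
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, n_levels, n_levels))
  tt <- table(factor(a[ok], levels = seq_len(n_levels)),
              factor(b[ok], levels = seq_len(n_levels)))
  m <- matrix(as.numeric(tt), n_levels, n_levels)
  m + t(m)
}

# the 13 classic texture statistics of a normalised symmetric GLCM.
# Conventions: natural logarithms; 0*log(0) = 0; Correlation and IMC1 are 0
# for a degenerate (single-level) matrix; SumVariance is taken about the
# sum average; Variance is about the marginal mean.
.haralick_stats <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mx <- sum(seq_len(ng) * px); my <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - my)^2 * py))
  xlog <- function(p) ifelse(p > 0, log(p), 0)

  p_sum <- vapply(2:(2 * ng), function(k) sum(P[i + j == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_diff <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_diff <- 0:(ng - 1)

  asm <- sum(P^2)
  contrast <- sum(k_diff^2 * p_diff)
  correlation <- if (sx > 0 && sy > 0)
    (sum(i * j * P) - mx * my) / (sx * sy) else 0
  variance <- sum((i - mx)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_avg <- sum(k_sum * p_sum)
  sum_var <- sum((k_sum - sum_avg)^2 * p_sum)
  sum_ent <- -sum(p_sum * xlog(p_sum))
  entropy <- -sum(P * xlog(P))
  diff_avg <- sum(k_diff * p_diff)
  diff_var <- sum((k_diff - diff_avg)^2 * p_diff)
  diff_ent <- -sum(p_diff * xlog(p_diff))
  hx <- -sum(px * xlog(px)); hy <- -sum(py * xlog(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * xlog(pxy))
  hxy2 <- -sum(pxy * xlog(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))

  stats::setNames(c(asm, contrast, correlation, variance, idm, sum_avg,
                    sum_var, sum_ent, entropy, diff_var, diff_ent,
                    imc1, imc2), .HARALICK_STATS)
}

#' Haralick texture statistics of the masked image
#'
#' In-mask intensities are quantised to `n_levels` equal-width gray levels
#' over the in-mask range. For each offset distance `d`, symmetric gray-level
#' co-occurrence matrices are accumulated along the four directions 0, 45,
#' 90 and 135 degrees (pairs with either pixel outside the mask are
#' discarded), each direction's matrix is normalised to sum 1, and the four
#' are averaged. Thirteen classic texture statistics are computed per
#' offset.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix.
#' @param offsets Integer vector of pixel offset distances.
#' @param n_levels Number of gray levels (default 8).
#' @return Named numeric vector of length `13 * length(offsets)`.
#' @export
haralick_texture <- function(image, mask, offsets = c(1L, 2L, 3L, 5L),
                             n_levels = 8L) {
  stopifnot(is.matrix(image), is.logical(mask), all(dim(image) == dim(mask)),
            length(offsets) >= 1L, all(offsets >= 1L))
  if (!any(mask)) stop("mask is empty")
  q <- .glcm_quantize(image, mask, n_levels)
  out <- numeric(0)
  for (d in offsets) {
    dirs <- list(c(0L, d), c(d, 0L), c(d, d), c(d, -d))
    acc <- matrix(0, n_levels, n_levels)
    for (dd in dirs) {
      cnt <- .glcm_counts(q, dd[1L], dd[2L], n_levels)
      tot <- sum(cnt)
      if (tot < 2)
        stop(sprintf("offset %d: fewer than 2 in-mask co-occurring pairs", d))
      acc <- acc + cnt / tot
    }
    P <- acc / 4
    st <- .haralick_stats(P)
    names(st) <- paste0("Tex_", .HARALICK_STATS, "_d", d)
    out <- c(out, st)
  }
  out
}

#' Extract the full spatial feature profile of one cell
#'
#' Concatenates the four feature families computed on the dark-field
#' channel inside the given mask, in the fixed order of [feature_names()].
#' Any family failure (empty annulus, unpaired texture offset, zero-signal
#' mask) propagates as an error; callers that pool cells catch it and drop
#' the cell with a logged reason.
#'
#' @param image Dark-field numeric matrix (or a `cell_image` object, in
#'   which case its dark-field channel and stored mask are used unless
#'   `mask` is supplied).
#' @param mask Logical matrix.
#' @param offsets,n_radial_bins,n_gran_steps,n_levels Family settings; the
#'   defaults give the 85-feature profile.
#' @return Named numeric vector (length 85 at the defaults), all finite.
#' @export
extract_features <- function(image, mask = NULL,
                             offsets = c(1L, 2L, 3L, 5L),
                             n_radial_bins = 2L,
                             n_gran_steps = 16L,
                             n_levels = 8L) {
  if (inherits(image, "cell_image")) {
    if (is.null(mask)) mask <- image$mask
    image <- image$darkfield
  }
  stopifnot(is.matrix(image), is.logical(mask))
  out <- c(intensity_features(image, mask),
           radial_distribution(image, mask, n_radial_bins),
           granularity_spectrum(image, mask, n_gran_steps),
           haralick_texture(image, mask, offsets, n_levels))
  if (!all(is.finite(out)))
    stop("non-finite feature value: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Pool per-cell features into a complete table
#'
#' Runs [extract_features()] on every gated cell, using the segmentation
#' masks from the gating stage. Cells whose extraction fails are dropped
#' and recorded with their failure reason.
#'
#' @param cells List of `cell_image` objects (the full cohort; only cells
#'   present in `gated_events` are used).
#' @param gated_events Gated event `data.frame` from [quadrant_gate()].
#' @param masks Named list of masks from [whole_cell_events()].
#' @param ... Family settings forwarded to [extract_features()].
#' @return List with `table` (`data.frame`: `cell_id`, `sample`, then one
#'   column per feature) and `dropped` (`data.frame`: `cell_id`, `reason`).
#' @export
extract_feature_table <- function(cells, gated_events, masks, ...) {
  stopifnot(is.data.frame(gated_events), is.list(masks))
  by_id <- stats::setNames(cells, vapply(cells, function(x) x$meta$cell_id, ""))
  rows <- list(); drop_rows <- list()
  for (k in seq_len(nrow(gated_events))) {
    id <- gated_events$cell_id[k]
    fv <- tryCatch(
      extract_features(by_id[[id]]$darkfield, masks[[id]], ...),
      error = function(e) e)
    if (inherits(fv, "error")) {
      drop_rows[[length(drop_rows) + 1L]] <-
        data.frame(cell_id = id, reason = conditionMessage(fv),
                   stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = id, sample = gated_events$sample[k],
        as.list(fv), check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("feature extraction failed for every cell")
  list(table = do.call(rbind, rows),
       dropped = if (length(drop_rows)) do.call(rbind, drop_rows) else
         data.frame(cell_id = character(), reason = character()))
}
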