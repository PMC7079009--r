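#' Fit the diffusion path through a 2-D embedding
#'
#' Least-squares polynomial fit `DC2 = f(DC1)` of the stated degree over
#' the pooled cells, discretised to a polyline whose vertex grid spans the
#' data's DC1 range extended (if necessary) to include DC1 = 0. The "zero
#' point" from which activation indices are measured is the path point at
#' DC1 = 0; cumulative arc length along the polyline is accumulated by
#' chord summation.
#'
#' A degree-2 polynomial matches the single-bend trajectory the pooled
#' activation continuum produces; higher degrees are accepted.
#'
#' @param embedding A `diffusion_map` object or a 2-column coordinate
#'   matrix (DC1, DC2).
#' @param degree Polynomial degree (default 2).
#' @param n_vertices Number of polyline vertices before insertion of the
#'   DC1 = 0 vertex (default 512).
#' @return Object of class `trajectory_model`: list with `vertices`
#'   (matrix, columns `DC1`, `DC2`), `arc` (cumulative arc length),
#'   `zero_arc` (arc length at the zero point), `coefficients`, `degree`,
#'   `rmse` (fit residual RMS).
#' @export
fit_path <- function(embedding, degree = 2L, n_vertices = 512L) {
  pts <- if (inherits(embedding, "diffusion_map")) embedding$coords else
    as.matrix(embedding)
  stopifnot(ncol(pts) >= 2L, n_vertices >= 2L, degree >= 1L)
  if (nrow(pts) < 10L) stop("need at least 10 points to fit the path")
  x <- pts[, 1L]; y <- pts[, 2L]
  if (diff(range(x)) == 0) stop("all DC1 values identical: no path direction")
  X <- outer(x, 0:degree, `^`)
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  rmse <- sqrt(mean((y - drop(X %*% beta))^2))
  lo <- min(min(x), 0); hi <- max(max(x), 0)
  grid <- sort(unique(c(seq(lo, hi, length.out = n_vertices), 0)))
  fy <- drop(outer(grid, 0:degree, `^`) %*% beta)
  seg <- sqrt(diff(grid)^2 + diff(fy)^2)
  arc <- c(0, cumsum(seg))
  zero_idx <- which(grid == 0)[1L]
  structure(list(vertices = cbind(DC1 = grid, DC2 = fy),
                 arc = arc, zero_arc = arc[zero_idx],
                 coefficients = beta, degree = degree, rmse = rmse),
            class = "trajectory_model")
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf("Trajectory: degree-%d path, %d vertices, arc length %.4g, fit RMSE %.4g\n",
              x$degree, nrow(x$vertices), max(x$arc), x$rmse))
  invisible(x)
}

#' Score cells by signed arc length along the path
#'
#' Each point is orthogonally projected onto its nearest polyline segment
#' (ties broken toward the lower arc length); its activation index is the
#' signed arc-length distance of the projection from the zero point. The
#' distance from the point to its projection is reported alongside, as a
#' fit-quality diagnostic.
#'
#' @param model A [fit_path()] result.
#' @param points 2-column matrix of (DC1, DC2) coordinates, or a
#'   `diffusion_map` object.
#' @return `data.frame` with columns `activation_index` and
#'   `projection_distance`.
#' @export
activation_index <- function(model, points) {
  stopifnot(inherits(model, "trajectory_model"))
  pts <- if (inherits(points, "diffusion_map")) points$coords else
    as.matrix(points)
  stopifnot(ncol(pts) >= 2L)
  if (!all(is.finite(pts[, 1:2]))) stop("points contain non-finite coordinates")
  V <- model$vertices
  ax <- V[-nrow(V), 1L]; ay <- V[-nrow(V), 2L]
  bx <- V[-1L, 1L]; by <- V[-1L, 2L]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- .Machine$double.eps
  seg_arc <- model$arc[-length(model$arc)]
  seg_len <- sqrt(len2)

  n <- nrow(pts)
  idx_out <- numeric(n); dist_out <- numeric(n)
  for (i in seq_len(n)) {
    px <- pts[i, 1L]; py <- pts[i, 2L]
    t <- pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
    qx <- ax + t * dx; qy <- ay + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    j <- which.min(d2)                 # first minimum = lower arc length
    idx_out[i] <- seg_arc[j] + t[j] * seg_len[j] - model$zero_arc
    dist_out[i] <- sqrt(d2[j])
  }
  data.frame(activation_index = idx_out, projection_distance = dist_out)
}

#' Score a pooled embedding and orient the index by exposure
#'
#' Convenience wrapper: computes activation indices for every cell of the
#' embedding and fixes the sign convention so that the mean index of the
#' highest-exposure sample is positive (the reporting convention in
#' which activation increases along the path).
#'
#' @param model A [fit_path()] result.
#' @param embedding `diffusion_map` object or coordinate matrix.
#' @param samples Character vector of per-cell sample labels (same order
#'   as the embedding rows).
#' @param high_label Label of the highest-exposure sample used to orient
#'   the sign; `NULL` leaves the raw orientation.
#' @param cell_ids Optional per-cell identifiers carried into the result.
#' @return `data.frame`: `cell_id` (if given), `sample`,
#'   `activation_index`, `projection_distance`; attribute `"orientation"`
#'   records the applied sign.
#' @export
score_cells <- function(model, embedding, samples, high_label = NULL,
                        cell_ids = NULL) {
  sc <- activation_index(model, embedding)
  stopifnot(length(samples) == nrow(sc))
  orient <- 1
  if (!is.null(high_label)) {
    if (!high_label %in% samples)
      stop("high_label not present among samples")
    if (mean(sc$activation_index[samples == high_label]) < 0) orient <- -1
  }
  sc$activation_index <- orient * sc$activation_index
  out <- data.frame(sample = samples, sc, stringsAsFactors = FALSE)
  if (!is.null(cell_ids)) out <- data.frame(cell_id = cell_ids, out,
                                            stringsAsFactors = FALSE)
  attr(out, "orientation") <- orient
  out
}
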