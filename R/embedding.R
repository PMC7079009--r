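#' Standardize a pooled feature matrix
#'
#' Centers every feature column to mean 0 and scales it to unit standard
#' deviation (population convention, n denominator) over the pooled cell
#' set. Zero-variance columns carry no information for the embedding and
#' are dropped with a warning.
#'
#' @param x Numeric matrix (cells x features), at least 2 rows.
#' @return List with `x` (standardized matrix, possibly fewer columns),
#'   `center` and `scale` (named vectors for the kept columns), and
#'   `dropped` (names of zero-variance columns).
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to standardize")
  if (!all(is.finite(x))) stop("feature matrix contains non-finite values")
  ctr <- colMeans(x)
  sc <- sqrt(colMeans(sweep(x, 2L, ctr)^2))
  drop <- sc == 0
  if (any(drop))
    warning("dropping zero-variance feature column(s): ",
            paste(colnames(x)[drop], collapse = ", "))
  keep <- which(!drop)
  z <- sweep(sweep(x[, keep, drop = FALSE], 2L, ctr[keep]), 2L, sc[keep], "/")
  list(x = z, center = ctr[keep], scale = sc[keep],
       dropped = colnames(x)[drop])
}

#' Diffusion-map embedding
#'
#' Nonlinear dimensionality reduction in which Euclidean feature-space
#' distances are converted into transition probabilities of a Markov chain
#' whose leading non-trivial eigenvectors coordinate the embedding:
#' \deqn{K_{ij} = \exp(-\|x_i - x_j\|^2 / 2\sigma^2)}
#' with density normalisation \eqn{\tilde K = K_{ij}/(d_i d_j)^\alpha},
#' \eqn{d_i = \sum_j K_{ij}} (default \eqn{\alpha = 1}, which removes
#' sampling-density bias so pooling samples of different sizes does not
#' distort the geometry), followed by row normalisation to a stochastic
#' matrix `P`. Coordinates are \eqn{\lambda_k \psi_k} for the top
#' `n_components` non-trivial right eigenvectors (diffusion time 1).
#' Eigenvectors are normalised to unit norm under the chain's stationary
#' distribution — which makes the embedding exactly invariant to point
#' duplication at \eqn{\alpha = 1} — and signed so that each one's
#' largest-magnitude entry is positive.
#'
#' @param x Numeric matrix (cells x features), typically standardized.
#' @param sigma Kernel bandwidth; `"auto"` (default) uses the median
#'   pairwise Euclidean distance.
#' @param n_components Number of diffusion coordinates (default 2).
#' @param alpha Density-normalisation exponent, 1 (default) or 0.
#' @param return_operator Keep the Markov matrix `P` in the result (for
#'   diagnostics; memory scales as n^2).
#' @return Object of class `diffusion_map`: list with `coords` (n x
#'   `n_components` matrix, columns `DC1..`), `eigenvalues` (non-trivial,
#'   descending), `sigma`, `alpha`, `n`, and optionally `P`.
#' @export
diffusion_map <- function(x, sigma = "auto", n_components = 2L, alpha = 1,
                          return_operator = FALSE) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("input matrix contains non-finite values")
  n <- nrow(x)
  if (n < n_components + 1L) stop("too few rows for the requested components")
  D <- as.matrix(stats::dist(x))
  if (identical(sigma, "auto")) {
    sigma <- stats::median(D[upper.tri(D)])
    if (!is.finite(sigma) || sigma <= 0)
      stop("auto bandwidth failed: median pairwise distance is not positive")
  }
  stopifnot(is.numeric(sigma), sigma > 0)
  K <- exp(-D^2 / (2 * sigma^2))
  d <- rowSums(K)
  # off-diagonal connectivity: a row whose kernel mass is only its own
  # diagonal entry is numerically disconnected
  bad <- which(d - 1 < .Machine$double.xmin * n)
  if (length(bad))
    stop("numerically disconnected cells at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  Kt <- if (alpha == 0) K else K / outer(d, d)^alpha
  dt <- rowSums(Kt)
  # symmetric conjugate of the Markov matrix P = Dt^-1 Kt
  S <- Kt / sqrt(outer(dt, dt))
  eig <- eigen(S, symmetric = TRUE)
  psi <- eig$vectors / sqrt(dt)           # right eigenvectors of P
  pi_st <- dt / sum(dt)                   # stationary distribution
  idx <- 1L + seq_len(n_components)
  lambda <- eig$values[idx]
  coords <- matrix(NA_real_, n, n_components,
                   dimnames = list(NULL, paste0("DC", seq_len(n_components))))
  for (k in seq_len(n_components)) {
    v <- psi[, idx[k]]
    v <- v / sqrt(sum(pi_st * v^2))
    v <- v * sign(v[which.max(abs(v))])
    coords[, k] <- lambda[k] * v
  }
  out <- list(coords = coords, eigenvalues = lambda,
              sigma = sigma, alpha = alpha, n = n,
              trivial_eigenvalue = eig$values[1L],
              trivial_vector_cv = stats::sd(psi[, 1L]) / abs(mean(psi[, 1L])))
  if (return_operator) out$P <- Kt / dt
  structure(out, class = "diffusion_map")
}

#' @export
print.diffusion_map <- function(x, ...) {
  cat(sprintf("Diffusion map: %d cells, %d components, sigma = %.4g, alpha = %g\n",
              x$n, ncol(x$coords), x$sigma, x$alpha))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' PCA baseline embedding
#'
#' Linear projection of the (standardized) feature matrix onto its top
#' principal axes, with the same deterministic sign convention as the
#' diffusion map (each score column's largest-magnitude entry positive).
#' If the matrix rank is below `n_components`, only the informative
#' components are returned, with a warning.
#'
#' @param x Numeric matrix (cells x features).
#' @param n_components Number of components (default 3).
#' @return Object of class `pca_embedding`: list with `coords` (columns
#'   `PC1..`) and `explained_variance` (fractions, non-increasing).
#' @export
pca_embed <- function(x, n_components = 3L) {
  x <- as.matrix(x)
  if (nrow(x) < n_components) stop("need at least n_components rows")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  k <- min(n_components, rank)
  if (k < n_components)
    warning(sprintf("rank %d < %d requested components; returning %d",
                    rank, n_components, k))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k))
    coords[, j] <- coords[, j] * sign(coords[which.max(abs(coords[, j])), j])
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coords = coords, explained_variance = evf[seq_len(k)]),
            class = "pca_embedding")
}
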