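#' Simulation parameters for synthetic eosinophil images
#'
#' Bundles every knob of the per-cell image generator. The generator draws a
#' circular cell body and populates it with Gaussian "granule" spots whose
#' number, width, placement radius and brightness depend on a latent
#' activation level in \[0, 1\]. Activation is encoded primarily as granule
#' *redistribution* (wider placement, slightly smaller and more numerous
#' spots) with only a modest gain in total intensity, so that integrated
#' side-scatter intensity rises by roughly 10\% between resting and fully
#' activated cells while texture and radial-distribution features change
#' much more strongly.
#'
#' @param image_size Frame side length in pixels.
#' @param cell_radius_mean,cell_radius_sd Cell-disk radius distribution
#'   (pixels); radii are redrawn until the cell fits the frame.
#' @param body_intensity Dark-field intensity of the cell body (arbitrary
#'   units; granule spots add on top of this baseline).
#' @param granule_count_mean Expected granule count for a cell of mean radius
#'   at activation 0; actual counts are Poisson and scale with the cell's
#'   cross-sectional area.
#' @param granule_count_gain Fractional increase of the expected granule
#'   count at activation 1 (activation fragments granules into more, smaller
#'   scattering centres).
#' @param granule_sigma Gaussian width of a granule spot in pixels
#'   (diffraction-blurred, isotropic).
#' @param granule_sigma_shrink Fractional shrinkage of `granule_sigma` at
#'   activation 1.
#' @param granule_amplitude Peak dark-field intensity of one granule spot at
#'   activation 0 (before per-granule jitter).
#' @param amplitude_gain Fractional increase of granule amplitude at
#'   activation 1. The default is calibrated so that the mean integrated
#'   dark-field intensity of fully activated cells is ~1.10 times the
#'   resting mean.
#' @param amplitude_jitter Half-width of the uniform multiplicative jitter
#'   applied independently to each granule's amplitude.
#' @param dispersion_base,dispersion_gain Granule placement radius as a
#'   fraction of the cell radius: centres are uniform over a disk of radius
#'   `(dispersion_base + dispersion_gain * activation) * cell_radius`.
#'   Their sum must lie in \[0, 1\].
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise
#'   (all channels); negative pixels are clipped to zero.
#' @param autofluor_scale Autofluorescence intensity per unit of granule
#'   dark-field signal (the two channels share the granule spot map, which
#'   is what couples integrated autofluorescence to integrated scatter).
#' @param seed Optional integer seed stored with the parameters; cohort
#'   generation uses the cohort seed instead.
#'
#' @return An object of class `cell_sim_params` (a named list).
#' @seealso [simulate_cell()], [simulate_cohort()]
#' @export
cell_sim_params <- function(image_size = 64L,
                            cell_radius_mean = 14,
                            cell_radius_sd = 1.2,
                            body_intensity = 0.4,
                            granule_count_mean = 25,
                            granule_count_gain = 0.4,
                            granule_sigma = 1.4,
                            granule_sigma_shrink = 0.12,
                            granule_amplitude = 0.25,
                            amplitude_gain = 0.3,
                            amplitude_jitter = 0.15,
                            dispersion_base = 0.35,
                            dispersion_gain = 0.45,
                            noise_sd = 0.02,
                            autofluor_scale = 0.8,
                            seed = NULL) {
  p <- list(image_size = as.integer(image_size),
            cell_radius_mean = cell_radius_mean,
            cell_radius_sd = cell_radius_sd,
            body_intensity = body_intensity,
            granule_count_mean = granule_count_mean,
            granule_count_gain = granule_count_gain,
            granule_sigma = granule_sigma,
            granule_sigma_shrink = granule_sigma_shrink,
            granule_amplitude = granule_amplitude,
            amplitude_gain = amplitude_gain,
            amplitude_jitter = amplitude_jitter,
            dispersion_base = dispersion_base,
            dispersion_gain = dispersion_gain,
            noise_sd = noise_sd,
            autofluor_scale = autofluor_scale,
            seed = seed)
  stopifnot(p$image_size >= 8,
            p$cell_radius_mean > 0, p$cell_radius_sd >= 0,
            p$granule_sigma > 0, p$granule_count_mean >= 0,
            p$granule_amplitude >= 0, p$amplitude_gain >= 0,
            p$noise_sd >= 0, p$autofluor_scale >= 0,
            p$dispersion_base >= 0, p$dispersion_gain >= 0)
  if (p$dispersion_base + p$dispersion_gain > 1)
    stop("dispersion_base + dispersion_gain must be <= 1 (granules inside the cell)")
  class(p) <- "cell_sim_params"
  p
}

#' @export
print.cell_sim_params <- function(x, ...) {
  cat("Synthetic cell simulation parameters:\n")
  for (nm in setdiff(names(x), "seed"))
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# squared-distance grid from (cx, cy); rows are y, cols are x
.dist2_grid <- function(n, cx, cy) {
  dx <- outer(rep(1, n), seq_len(n) - cx)
  dy <- outer(seq_len(n) - cy, rep(1, n))
  dx * dx + dy * dy
}

#' Simulate one multichannel cell image
#'
#' Renders a single cell at the given activation level. Three channels are
#' produced on a common pixel grid: dark-field (cell-body baseline plus
#' granule spots plus noise), bright-field (bright disk with dark dips at
#' granule positions), and autofluorescence (proportional to the granule
#' spot map plus noise, with no cell-body term). The true cell-disk mask and
#' the generating ground truth (granule centres, count, noiseless integrated
#' dark-field intensity) are stored in the object.
#'
#' @param params A [cell_sim_params()] object.
#' @param activation Latent activation level in \[0, 1\].
#' @param seed Optional integer; when supplied the cell is generated under
#'   its own temporary RNG state so repeated calls are bit-identical.
#' @param class Event class label, `"eosinophil"` (default) or
#'   `"distractor"`. Distractors model other leukocytes: smaller, dimmer,
#'   granule-free disks with negligible autofluorescence, present so the
#'   quadrant gate has something to exclude.
#'
#' @return An object of class `cell_image`: list with matrices `darkfield`,
#'   `brightfield`, `autofluor`, logical `mask`, and a `meta` list.
#' @export
simulate_cell <- function(params, activation, seed = NULL,
                          class = c("eosinophil", "distractor")) {
  class <- match.arg(class)
  if (!is.numeric(activation) || length(activation) != 1L ||
      is.na(activation) || activation < 0 || activation > 1)
    stop("activation must be a single value in [0, 1]")
  if (!is.null(seed))
    return(withr::with_seed(seed,
      simulate_cell(params, activation, seed = NULL, class = class)))

  n <- params$image_size
  r_mean <- if (class == "distractor") 0.62 * params$cell_radius_mean
            else params$cell_radius_mean
  r_sd <- params$cell_radius_sd
  body <- if (class == "distractor") 0.2 * params$body_intensity
          else params$body_intensity

  # cell must fit the frame with a small margin; bounded redraws
  r <- NA_real_
  for (i in seq_len(100L)) {
    cand <- stats::rnorm(1L, r_mean, r_sd)
    if (cand >= 3 && cand + 3 <= n / 2) { r <- cand; break }
  }
  if (is.na(r)) stop("could not draw a positive cell radius that fits the frame")
  ctr <- (n + 1) / 2 + stats::runif(2L, -2, 2)
  cx <- ctr[1L]; cy <- ctr[2L]

  d2 <- .dist2_grid(n, cx, cy)
  mask <- d2 <= r * r

  a <- activation
  spots <- matrix(0, n, n)
  gx <- gy <- numeric(0)
  n_gran <- 0L
  if (class == "eosinophil" && params$granule_count_mean > 0) {
    lambda <- params$granule_count_mean *
      (1 + params$granule_count_gain * a) * (r / params$cell_radius_mean)^2
    n_gran <- stats::rpois(1L, lambda)
    if (n_gran > 0L) {
      r_max <- (params$dispersion_base + params$dispersion_gain * a) * r
      theta <- stats::runif(n_gran, 0, 2 * pi)
      rad <- r_max * sqrt(stats::runif(n_gran))
      gx <- cx + rad * cos(theta)
      gy <- cy + rad * sin(theta)
      sig <- params$granule_sigma * (1 - params$granule_sigma_shrink * a)
      amp <- params$granule_amplitude * (1 + params$amplitude_gain * a) *
        stats::runif(n_gran, 1 - params$amplitude_jitter,
                     1 + params$amplitude_jitter)
      for (g in seq_len(n_gran))
        spots <- spots + amp[g] * exp(-.dist2_grid(n, gx[g], gy[g]) / (2 * sig^2))
    }
  }

  clean_df <- body * mask + spots
  noise <- function() if (params$noise_sd > 0)
    matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n) else 0
  darkfield <- pmax(clean_df + noise(), 0)
  brightfield <- pmax(1 - 0.2 * mask - spots + noise(), 0)
  autofluor <- pmax(params$autofluor_scale * spots + noise(), 0)

  structure(list(
    darkfield = darkfield,
    brightfield = brightfield,
    autofluor = autofluor,
    mask = mask,
    meta = list(cell_id = NA_character_, sample = NA_character_,
                class = class, activation = a,
                radius = r, center = c(cx, cy),
                granules = cbind(x = gx, y = gy),
                granule_count = n_gran,
                true_integrated = sum(clean_df[mask]))
  ), class = "cell_image")
}

#' Cohort layout for synthetic samples
#'
#' Defines the pooled multi-sample design: each sample has a label, a fixed
#' latent activation level shared by all its cells, and a cell count. The
#' default mirrors the study design the analysis targets: an exogenous
#' exposure arm (untreated control plus two stimulation durations) and an
#' endogenous "donor" arm with elevated eosinophil counts, five samples of
#' 215-302 cells each, pooled into a single feature matrix downstream.
#'
#' @param samples `data.frame` with columns `label` (character),
#'   `activation` (in \[0, 1\]) and `n_cells` (positive integer).
#' @param n_distractors Number of non-eosinophil events mixed into the
#'   cohort (spread uniformly over the samples).
#' @param seed Integer seed; cohort generation is a pure function of
#'   (config, params, seed).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(samples = data.frame(
                            label = c("control", "eotaxin_2h", "eotaxin_5h",
                                      "donor_3.1pct", "donor_9.0pct"),
                            activation = c(0, 0.3, 0.6, 0.2, 0.5),
                            n_cells = c(248L, 265L, 232L, 287L, 224L),
                            stringsAsFactors = FALSE),
                          n_distractors = 300L,
                          seed = 1L) {
  if (!is.data.frame(samples) || nrow(samples) == 0L)
    stop("samples must be a non-empty data.frame")
  stopifnot(all(c("label", "activation", "n_cells") %in% names(samples)),
            all(samples$activation >= 0 & samples$activation <= 1),
            all(samples$n_cells >= 1), n_distractors >= 0)
  if (anyDuplicated(samples$label)) stop("sample labels must be unique")
  structure(list(samples = samples,
                 n_distractors = as.integer(n_distractors),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a pooled multi-sample cohort
#'
#' Generates every cell of the configured samples (at each sample's
#' activation level) plus the distractor events, under a single RNG stream
#' seeded from `config$seed`. The ground-truth table has one row per
#' generated eosinophil; distractors are identifiable by their `meta$class`.
#'
#' @param config A [cohort_config()] object.
#' @param params A [cell_sim_params()] object.
#' @return A list of class `cohort` with elements `cells` (list of
#'   `cell_image`) and `truth` (`data.frame` with columns `cell_id`,
#'   `sample`, `activation_level`, `true_granule_count`,
#'   `true_integrated_intensity`).
#' @export
simulate_cohort <- function(config, params = cell_sim_params()) {
  stopifnot(inherits(config, "cohort_config"), inherits(params, "cell_sim_params"))
  withr::with_seed(config$seed, {
    cells <- list()
    rows <- list()
    idx <- 0L
    for (s in seq_len(nrow(config$samples))) {
      lab <- config$samples$label[s]
      act <- config$samples$activation[s]
      for (i in seq_len(config$samples$n_cells[s])) {
        idx <- idx + 1L
        cell <- simulate_cell(params, act)
        cell$meta$cell_id <- sprintf("c%05d", idx)
        cell$meta$sample <- lab
        cells[[idx]] <- cell
        rows[[idx]] <- data.frame(
          cell_id = cell$meta$cell_id, sample = lab, activation_level = act,
          true_granule_count = cell$meta$granule_count,
          true_integrated_intensity = cell$meta$true_integrated,
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
    # distractor events assigned round-robin to samples
    if (config$n_distractors > 0L) {
      labs <- rep_len(config$samples$label, config$n_distractors)
      for (i in seq_len(config$n_distractors)) {
        idx <- idx + 1L
        cell <- simulate_cell(params, 0, class = "distractor")
        cell$meta$cell_id <- sprintf("c%05d", idx)
        cell$meta$sample <- labs[i]
        cells[[idx]] <- cell
      }
    }
    structure(list(cells = cells, truth = truth), class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  n_eos <- nrow(x$truth)
  cat(sprintf("Synthetic cohort: %d cells (%d eosinophils, %d distractors), %d samples\n",
              length(x$cells), n_eos, length(x$cells) - n_eos,
              length(unique(x$truth$sample))))
  invisible(x)
}
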