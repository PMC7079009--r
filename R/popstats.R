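#' Fisher discriminant ratio of two groups
#'
#' Two-class separability of a 1-D metric:
#' \deqn{r_d = (\bar a - \bar b)^2 / (s_a^2 + s_b^2)}
#' with unbiased (n-1) sample variances. Symmetric in its arguments,
#' invariant to a common shift and to a common rescaling.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return The ratio `r_d` (non-negative scalar).
#' @export
fisher_ratio <- function(group_a, group_b) {
  stopifnot(is.numeric(group_a), is.numeric(group_b),
            length(group_a) >= 2L, length(group_b) >= 2L)
  v <- stats::var(group_a) + stats::var(group_b)
  if (v == 0) stop("both groups are constant: Fisher ratio undefined")
  (mean(group_a) - mean(group_b))^2 / v
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs. The default
#' p-value comes from the asymptotic Kolmogorov distribution with the
#' standard two-sample effective size `n1 n2 / (n1 + n2)`; a seeded
#' permutation alternative is available for small samples.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Number of permutations for the permutation method.
#' @param seed Seed for the permutation method.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(a, b, method = c("asymptotic", "permutation"),
                          n_perm = 2000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  D <- unname(kt$statistic)
  if (method == "asymptotic") return(list(D = D, p = kt$p.value))
  pooled <- c(a, b)
  na <- length(a)
  withr::with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pooled), na)
      Dp <- suppressWarnings(
        stats::ks.test(pooled[idx], pooled[-idx], exact = FALSE)$statistic)
      if (Dp >= D - 1e-12) hits <- hits + 1L
    }
    list(D = D, p = (hits + 1) / (n_perm + 1))
  })
}

#' Pearson correlation of paired values
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Sample Pearson correlation coefficient.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: Pearson correlation undefined")
  stats::cor(x, y)
}

#' Gaussian fit to a histogram
#'
#' Bins the values and fits `A * exp(-(x - mu)^2 / (2 sigma^2))` to the
#' (bin centre, bin count) pairs by Levenberg-Marquardt nonlinear least
#' squares, initialised at (max count, sample mean, sample sd). The
#' relative residual (RMSE / maximum bin count) flags distributions the
#' single Gaussian cannot describe (e.g. bimodal input).
#'
#' @param values Numeric vector, length >= 20.
#' @param n_bins Number of equal-width bins; `NULL` (default) uses the
#'   Freedman-Diaconis rule.
#' @param misfit_threshold Relative-residual level above which `misfit` is
#'   flagged (default 0.1).
#' @return List with `amplitude`, `mu`, `sigma` (> 0), `rmse`,
#'   `relative_rmse`, `misfit` (logical), `n_bins`.
#' @export
gaussian_fit_histogram <- function(values, n_bins = NULL,
                                   misfit_threshold = 0.1) {
  stopifnot(is.numeric(values))
  if (length(values) < 20L) stop("need at least 20 values")
  if (is.null(n_bins)) n_bins <- max(grDevices::nclass.FD(values), 5L)
  rng <- range(values)
  if (diff(rng) == 0) stop("constant input: fewer than 5 nonempty bins")
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  if (sum(h$counts > 0) < 5L) stop("fewer than 5 nonempty bins")
  df <- data.frame(x = h$mids, y = h$counts)
  start <- list(A = max(h$counts), mu = mean(values), sigma = stats::sd(values))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-8, ptol = 1e-8, maxiter = 200L)),
    error = function(e)
      stop(sprintf("Gaussian fit did not converge (start: A=%.4g, mu=%.4g, sigma=%.4g): %s",
                   start$A, start$mu, start$sigma, conditionMessage(e))))
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::resid(fit)^2))
  amp <- abs(unname(cf["A"]))
  rel <- rmse / max(h$counts)
  list(amplitude = amp, mu = unname(cf["mu"]), sigma = abs(unname(cf["sigma"])),
       rmse = rmse, relative_rmse = rel,
       misfit = rel > misfit_threshold, n_bins = n_bins)
}

#' Control-normalized group means with s.e.m.
#'
#' Each group's mean is divided by the control group's mean; the standard
#' error of the mean (sd / sqrt(n)) is scaled by the same factor, so the
#' control group reports mean 1.
#'
#' @param values Numeric vector of per-cell measurements.
#' @param groups Group label per value.
#' @param control_label Label of the control group (nonzero mean required).
#' @return `data.frame`: `group`, `n`, `mean`, `sem`, `normalized_mean`,
#'   `normalized_sem`.
#' @export
normalized_group_means <- function(values, groups, control_label) {
  stopifnot(length(values) == length(groups))
  if (!control_label %in% groups) stop("control group not present")
  groups <- as.character(groups)
  labs <- unique(groups)
  mu <- tapply(values, groups, mean)
  if (mu[[control_label]] == 0) stop("control mean is zero: cannot normalize")
  n <- tapply(values, groups, length)
  sem <- tapply(values, groups, stats::sd) / sqrt(n)
  data.frame(group = labs, n = as.integer(n[labs]),
             mean = as.numeric(mu[labs]), sem = as.numeric(sem[labs]),
             normalized_mean = as.numeric(mu[labs] / mu[[control_label]]),
             normalized_sem = as.numeric(sem[labs] / mu[[control_label]]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Population-level comparison of activation measures
#'
#' Composes the group-level statistics the analysis reports: per-sample
#' activation-index means with s.e.m. and Gaussian histogram fits,
#' control-normalized integrated side-scatter means, pairwise KS tests of
#' the index between the control and every other sample, Fisher
#' discriminant ratios (control vs the highest-exposure sample) for both
#' the multivariate index and the integrated side-scatter intensity, and
#' the per-sample Pearson correlation between the two measures.
#'
#' @param scores `data.frame` with columns `sample`, `activation_index`,
#'   `integrated_sidescatter`.
#' @param control_label,high_label Sample labels of the untreated control
#'   and the highest-exposure sample.
#' @return List of class `population_stats`.
#' @export
population_stats <- function(scores, control_label = "control",
                             high_label = "eotaxin_5h") {
  stopifnot(all(c("sample", "activation_index", "integrated_sidescatter")
                %in% names(scores)),
            control_label %in% scores$sample,
            high_label %in% scores$sample)
  by_sample <- split(scores, scores$sample)
  labs <- unique(scores$sample)

  index_means <- normalized_group_means(scores$activation_index + 0,
                                        scores$sample, control_label)
  # index means are reported raw (the index is already on a common scale
  # with a meaningful zero); drop the normalized columns
  index_means <- index_means[, c("group", "n", "mean", "sem")]
  ssc_means <- normalized_group_means(scores$integrated_sidescatter,
                                      scores$sample, control_label)

  ks <- lapply(setdiff(labs, control_label), function(l)
    c(list(sample = l),
      ks_two_sample(by_sample[[control_label]]$activation_index,
                    by_sample[[l]]$activation_index)))
  names(ks) <- setdiff(labs, control_label)

  rd_index <- fisher_ratio(by_sample[[control_label]]$activation_index,
                           by_sample[[high_label]]$activation_index)
  rd_ssc <- fisher_ratio(by_sample[[control_label]]$integrated_sidescatter,
                         by_sample[[high_label]]$integrated_sidescatter)

  rp <- vapply(labs, function(l)
    pearson_cor(by_sample[[l]]$integrated_sidescatter,
                by_sample[[l]]$activation_index), numeric(1))

  gauss <- lapply(labs, function(l)
    tryCatch(gaussian_fit_histogram(by_sample[[l]]$activation_index),
             error = function(e) list(error = conditionMessage(e))))
  names(gauss) <- labs

  structure(list(index_means = index_means,
                 sidescatter_means = ssc_means,
                 ks_vs_control = ks,
                 fisher_index = rd_index,
                 fisher_sidescatter = rd_ssc,
                 pearson_by_sample = rp,
                 gaussian_fits = gauss,
                 control_label = control_label,
                 high_label = high_label),
            class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat("Population statistics\n")
  cat(sprintf("  Fisher ratio (activation index, %s vs %s): %.3f\n",
              x$control_label, x$high_label, x$fisher_index))
  cat(sprintf("  Fisher ratio (integrated side-scatter):     %.3f\n",
              x$fisher_sidescatter))
  cat("  Pearson r (side-scatter vs index) by sample:\n")
  for (l in names(x$pearson_by_sample))
    cat(sprintf("    %-14s %.3f\n", l, x$pearson_by_sample[[l]]))
  cat("  KS vs control (activation index):\n")
  for (l in names(x$ks_vs_control))
    cat(sprintf("    %-14s D = %.3f, p = %.3g\n", l,
                x$ks_vs_control[[l]]$D, x$ks_vs_control[[l]]$p))
  invisible(x)
}

#' Write the statistics report
#'
#' Emits a machine-readable CSV (one row per statistic) and a
#' human-readable text rendering of a [population_stats()] result.
#'
#' @param stats A `population_stats` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_stats_report <- function(stats, dir) {
  stopifnot(inherits(stats, "population_stats"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  add <- function(stat, sample, value)
    rows[[length(rows) + 1L]] <<- data.frame(statistic = stat, sample = sample,
                                             value = value,
                                             stringsAsFactors = FALSE)
  for (k in seq_len(nrow(stats$index_means))) {
    g <- stats$index_means$group[k]
    add("index_mean", g, stats$index_means$mean[k])
    add("index_sem", g, stats$index_means$sem[k])
  }
  for (k in seq_len(nrow(stats$sidescatter_means))) {
    g <- stats$sidescatter_means$group[k]
    add("sidescatter_normalized_mean", g,
        stats$sidescatter_means$normalized_mean[k])
    add("sidescatter_normalized_sem", g,
        stats$sidescatter_means$normalized_sem[k])
  }
  for (l in names(stats$ks_vs_control)) {
    add("ks_D_vs_control", l, stats$ks_vs_control[[l]]$D)
    add("ks_p_vs_control", l, stats$ks_vs_control[[l]]$p)
  }
  add("fisher_ratio_index", paste(stats$control_label, "vs", stats$high_label),
      stats$fisher_index)
  add("fisher_ratio_sidescatter",
      paste(stats$control_label, "vs", stats$high_label),
      stats$fisher_sidescatter)
  for (l in names(stats$pearson_by_sample))
    add("pearson_r", l, stats$pearson_by_sample[[l]])
  for (l in names(stats$gaussian_fits)) {
    gf <- stats$gaussian_fits[[l]]
    if (is.null(gf$error)) {
      add("gauss_amplitude", l, gf$amplitude)
      add("gauss_mu", l, gf$mu)
      add("gauss_sigma", l, gf$sigma)
    }
  }
  csv <- file.path(dir, "stats_report.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  txt <- file.path(dir, "stats_report.txt")
  con <- file(txt, open = "wt")
  sink(con); on.exit({ sink(); close(con) })
  print(stats)
  invisible(c(csv = csv, txt = txt))
}
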