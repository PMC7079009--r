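# Independent brute-force oracles: every function here recomputes a feature
# family by direct per-pixel enumeration, sharing no code with the package
# implementations they check.

oracle_intensity <- function(image, mask) {
  v <- c()
  rs <- c(); cs <- c()
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image)))
    if (mask[i, j]) { v <- c(v, image[i, j]); rs <- c(rs, i); cs <- c(cs, j) }
  med <- stats::median(v)
  tot <- sum(v)
  if (tot > 0) {
    ci <- c(sum(rs * v) / tot, sum(cs * v) / tot)
    disp <- sqrt(sum((c(mean(rs), mean(cs)) - ci)^2))
  } else disp <- 0
  edge_vals <- c()
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    if (!mask[i, j]) next
    nb <- c(if (i > 1) mask[i - 1, j] else FALSE,
            if (i < nrow(image)) mask[i + 1, j] else FALSE,
            if (j > 1) mask[i, j - 1] else FALSE,
            if (j < ncol(image)) mask[i, j + 1] else FALSE)
    if (any(!nb)) edge_vals <- c(edge_vals, image[i, j])
  }
  c(tot, mean(v), med, stats::sd(v), stats::median(abs(v - med)),
    min(v), max(v),
    stats::quantile(v, 0.25, names = FALSE), stats::quantile(v, 0.75, names = FALSE),
    disp, mean(edge_vals))
}

oracle_radial <- function(image, mask, n_bins = 2L) {
  v <- image[mask]
  tot <- sum(v)
  rs <- row(mask)[mask]; cs <- col(mask)[mask]
  cy <- sum(rs * v) / tot; cx <- sum(cs * v) / tot
  d <- sqrt((rs - cy)^2 + (cs - cx)^2)
  dmax <- max(d)
  frac <- meanfrac <- rcv <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins * dmax; hi <- b / n_bins * dmax
    sel <- if (b < n_bins) d >= lo & d < hi else d >= lo
    frac[b] <- sum(v[sel]) / tot
    meanfrac[b] <- frac[b] / (sum(sel) / length(v))
    ang <- atan2(rs[sel] - cy, cs[sel] - cx)
    w <- pmin(floor((ang + pi) / (2 * pi) * 8) + 1L, 8L)
    wm <- sapply(sort(unique(w)), function(k) mean(v[sel][w == k]))
    mu <- mean(wm)
    rcv[b] <- if (mu > 0) sqrt(mean((wm - mu)^2)) / mu else 0
  }
  c(frac, meanfrac, rcv)
}

# erosion/dilation by per-pixel neighbourhood scan (out-of-frame = 0)
.oracle_morph <- function(m, op) {
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    nb <- c(m[i, j],
            if (i > 1) m[i - 1, j] else 0,
            if (i < nrow(m)) m[i + 1, j] else 0,
            if (j > 1) m[i, j - 1] else 0,
            if (j < ncol(m)) m[i, j + 1] else 0)
    out[i, j] <- op(nb)
  }
  out
}

oracle_granularity <- function(image, mask, n_steps = 16L) {
  img <- image; img[!mask] <- 0
  tot <- sum(img)
  if (tot <= 0) return(numeric(n_steps))
  G <- numeric(n_steps)
  prev <- tot
  for (k in seq_len(n_steps)) {
    ero <- img
    for (s in seq_len(k)) ero <- .oracle_morph(ero, min)
    opened <- ero
    for (s in seq_len(k)) opened <- .oracle_morph(opened, max)
    G[k] <- 100 * (prev - sum(opened)) / tot
    prev <- sum(opened)
  }
  G
}

oracle_haralick <- function(image, mask, offsets = c(1L, 2L, 3L, 5L),
                            n_levels = 8L) {
  v <- image[mask]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image)))
    if (mask[i, j])
      q[i, j] <- if (hi > lo)
        min(floor((image[i, j] - lo) / (hi - lo) * n_levels) + 1, n_levels)
      else 1L
  out <- c()
  for (d in offsets) {
    dirs <- list(c(0, d), c(d, 0), c(d, d), c(d, -d))
    P <- matrix(0, n_levels, n_levels)
    for (dd in dirs) {
      cnt <- matrix(0, n_levels, n_levels)
      for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
        i2 <- i + dd[1]; j2 <- j + dd[2]
        if (i2 < 1 || i2 > nrow(q) || j2 < 1 || j2 > ncol(q)) next
        if (is.na(q[i, j]) || is.na(q[i2, j2])) next
        cnt[q[i, j], q[i2, j2]] <- cnt[q[i, j], q[i2, j2]] + 1
        cnt[q[i2, j2], q[i, j]] <- cnt[q[i2, j2], q[i, j]] + 1
      }
      P <- P + cnt / sum(cnt)
    }
    P <- P / 4
    out <- c(out, oracle_haralick_stats(P))
  }
  out
}

oracle_haralick_stats <- function(P) {
  ng <- nrow(P)
  xlog <- function(p) if (p > 0) log(p) else 0
  px <- rowSums(P); py <- colSums(P)
  mx <- sum((1:ng) * px); my <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mx)^2 * px)); sy <- sqrt(sum(((1:ng) - my)^2 * py))
  asm <- contrast <- corr_num <- variance <- idm <- entropy <- 0
  hxy1 <- hxy2 <- 0
  psum <- rep(0, 2 * ng); pdiff <- rep(0, ng)   # psum[k] = p_{x+y}(k), k=2..2ng
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    asm <- asm + p^2
    corr_num <- corr_num + i * j * p
    variance <- variance + (i - mx)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    entropy <- entropy - p * xlog(p)
    hxy1 <- hxy1 - p * xlog(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * xlog(px[i] * py[j])
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
  }
  ks <- 2:(2 * ng); kd <- 0:(ng - 1)
  psum <- psum[ks]
  sum_avg <- sum(ks * psum)
  sum_var <- sum((ks - sum_avg)^2 * psum)
  sum_ent <- -sum(sapply(seq_along(psum), function(k) psum[k] * xlog(psum[k])))
  contrast <- sum(kd^2 * pdiff)
  diff_avg <- sum(kd * pdiff)
  diff_var <- sum((kd - diff_avg)^2 * pdiff)
  diff_ent <- -sum(sapply(seq_along(pdiff), function(k) pdiff[k] * xlog(pdiff[k])))
  hx <- -sum(sapply(1:ng, function(i) px[i] * xlog(px[i])))
  hy <- -sum(sapply(1:ng, function(i) py[i] * xlog(py[i])))
  corr <- if (sx > 0 && sy > 0) (corr_num - mx * my) / (sx * sy) else 0
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - entropy)), 0))
  c(asm, contrast, corr, variance, idm, sum_avg, sum_var, sum_ent,
    entropy, diff_var, diff_ent, imc1, imc2)
}

# exhaustive nearest-segment projection with signed arc length
oracle_projection <- function(model, p) {
  V <- model$vertices
  best_d <- Inf; best_s <- NA
  for (j in seq_len(nrow(V) - 1)) {
    a <- V[j, ]; b <- V[j + 1, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- max(0, min(1, t))
    qp <- a + t * ab
    d <- sqrt(sum((p - qp)^2))
    if (d < best_d - 1e-15) {
      best_d <- d
      best_s <- model$arc[j] + t * sqrt(sum(ab^2))
    }
  }
  c(index = best_s - model$zero_arc, dist = best_d)
}

# small deterministic fixtures
disk_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

random_cell_fixture <- function(seed, n = 16L) {
  withr::with_seed(seed, {
    img <- matrix(runif(n * n), n, n)
    list(image = img, mask = disk_mask(n, n / 2 - 1))
  })
}
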