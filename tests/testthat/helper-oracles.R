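# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the ODE oracle integrates the model's printed
# right-hand side numerically, and the texture oracle recomputes the
# co-occurrence statistics with explicit loops.

ode_traj <- function(kf_d, kr, times, mode = "dissociation", C0 = 1,
                     L_T = 0, c_init = 0) {
  rhs <- if (mode == "dissociation") {
    function(t, y, parms) list(kf_d * (C0 - y) - kr * y)
  } else {
    function(t, y, parms) list(kf_d * L_T - kr * y)
  }
  y0 <- if (mode == "dissociation") C0 else c_init
  out <- deSolve::lsoda(y = c(C = y0), times = times, func = rhs,
                        rtol = 1e-11, atol = 1e-13)
  as.numeric(out[, "C"])
}

# Symmetric normalized co-occurrence matrix by explicit pair enumeration.
brute_glcm <- function(lev, n_levels, dr, dc) {
  P <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(lev))) for (c in seq_len(ncol(lev))) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nrow(lev) || c2 < 1 || c2 > ncol(lev)) next
    a <- lev[r, c]; b <- lev[r2, c2]
    if (is.na(a) || is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P / sum(P)
}

# The 13 co-occurrence statistics, loop-based, straight from the
# definitions (natural log, 0 log 0 = 0, sum-variance centered on
# sum-average, correlation 0 for zero marginal variance).
brute_haralick <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j]
  }
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  psum <- numeric(2 * ng); pdiff <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  lg <- function(p) if (p > 0) log(p) else 0
  asm <- 0; contrast <- 0; corr_num <- 0; variance <- 0; idm <- 0
  entropy <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    asm <- asm + P[i, j]^2
    contrast <- contrast + (i - j)^2 * P[i, j]
    corr_num <- corr_num + i * j * P[i, j]
    variance <- variance + (i - mux)^2 * P[i, j]
    idm <- idm + P[i, j] / (1 + (i - j)^2)
    entropy <- entropy - P[i, j] * lg(P[i, j])
    if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  sum_average <- 0
  for (k in 2:(2 * ng)) sum_average <- sum_average + k * psum[k]
  sum_variance <- 0; sum_entropy <- 0
  for (k in 2:(2 * ng)) {
    sum_variance <- sum_variance + (k - sum_average)^2 * psum[k]
    sum_entropy <- sum_entropy - psum[k] * lg(psum[k])
  }
  dmean <- 0
  for (k in 0:(ng - 1)) dmean <- dmean + k * pdiff[k + 1]
  diff_variance <- 0; diff_entropy <- 0
  for (k in 0:(ng - 1)) {
    diff_variance <- diff_variance + (k - dmean)^2 * pdiff[k + 1]
    diff_entropy <- diff_entropy - pdiff[k + 1] * lg(pdiff[k + 1])
  }
  hx <- -sum(sapply(px, function(p) p * lg(p)))
  hy <- -sum(sapply(py, function(p) p * lg(p)))
  c(asm = asm, contrast = contrast,
    correlation = if (sx * sy > 0) (corr_num - mux * muy) / (sx * sy) else 0,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, diff_variance = diff_variance,
    diff_entropy = diff_entropy,
    imc1 = if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0,
    imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy)))))
}

# A tiny dual-channel image with hand-placed elliptical cells, for
# segmentation and feature tests that need exact ground truth.
toy_cell_image <- function(centers, radii = 10, size = 96, ratio = 0.6) {
  sa <- matrix(0.005, size, size); nuc <- matrix(0.002, size, size)
  radii <- rep_len(radii, nrow(centers))
  for (i in seq_len(nrow(centers))) {
    rr <- outer((1:size) - centers[i, 1], rep(1, size))
    cc <- outer(rep(1, size), (1:size) - centers[i, 2])
    d2 <- (rr / radii[i])^2 + (cc / (radii[i] * ratio))^2
    sa[d2 <= 1] <- sa[d2 <= 1] + 0.6
    dn <- (rr / (radii[i] * 0.35))^2 + (cc / (radii[i] * 0.35))^2
    nuc[dn <= 1] <- nuc[dn <= 1] + 0.8
  }
  dual_channel_image(sa, sa * 0.8, nuc)
}
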