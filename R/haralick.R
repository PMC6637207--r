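#' @name haralick
#' @title Gray-level co-occurrence texture statistics
#'
#' @description
#' The 13 classic co-occurrence (Haralick) texture statistics used in the
#' single-cell descriptor set. Intensities within the analysed region are
#' min-max quantized to a fixed number of gray levels; the co-occurrence
#' matrix is accumulated at distance 1 over the four standard directions
#' (0, 45, 90, 135 degrees), symmetrized and normalized per direction; and
#' the statistics are averaged over directions.
#'
#' Conventions (recorded here because the literature varies): logarithms
#' are natural, `0 log 0 = 0`; the sum-variance statistic is centered on
#' the sum-average; correlation and both information measures of
#' correlation are defined as 0 when the relevant marginal variance or
#' entropy vanishes (e.g. on a constant patch).
NULL

#' Names of the 13 co-occurrence statistics
#' @return Character vector of length 13.
#' @export
haralick_names <- function() {
  c("asm", "contrast", "correlation", "variance", "idm",
    "sum_average", "sum_variance", "sum_entropy", "entropy",
    "diff_variance", "diff_entropy", "imc1", "imc2")
}

#' Quantize intensities to discrete gray levels
#'
#' Min-max scales the masked intensities and bins them into `n_levels`
#' equal-width levels (1-based). A constant region maps entirely to
#' level 1.
#'
#' @param x Numeric matrix of intensities.
#' @param mask Logical matrix; pixels outside are returned as `NA`.
#' @param n_levels Number of gray levels (default 8).
#' @return Integer matrix of levels with `NA` outside the mask.
#' @export
quantize_gray <- function(x, mask = NULL, n_levels = 8) {
  stopifnot(is.matrix(x), n_levels >= 2)
  if (is.null(mask)) mask <- array(TRUE, dim(x))
  v <- x[mask]
  out <- matrix(NA_integer_, nrow(x), ncol(x))
  if (!length(v)) return(out)
  rng <- range(v)
  lev <- if (rng[2] > rng[1]) {
    pmin(as.integer(floor((v - rng[1]) / (rng[2] - rng[1]) * n_levels)) + 1L,
         as.integer(n_levels))
  } else rep(1L, length(v))
  out[mask] <- lev
  out
}

# Accumulate one symmetric, normalized GLCM for offset (dr, dc).
glcm_offset <- function(levels, n_levels, dr, dc) {
  nr <- nrow(levels); nc <- ncol(levels)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- levels[r1, c1, drop = FALSE]
  b <- levels[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  P <- matrix(0, n_levels, n_levels)
  tab <- table(factor(a[ok], levels = seq_len(n_levels)),
               factor(b[ok], levels = seq_len(n_levels)))
  P <- unclass(tab) + t(unclass(tab))
  P / sum(P)
}

#' Co-occurrence matrices of a quantized patch
#'
#' @param levels Integer level matrix (`NA` = outside region), e.g. from
#'   [quantize_gray()].
#' @param n_levels Number of gray levels.
#' @param distance Pixel offset distance (default 1).
#' @return A list of up to 4 symmetric normalized co-occurrence matrices,
#'   one per direction with at least one valid pixel pair.
#' @export
glcm_matrices <- function(levels, n_levels = 8, distance = 1) {
  offs <- list(c(0, distance), c(distance, distance),
               c(distance, 0), c(distance, -distance))
  out <- lapply(offs, function(o) glcm_offset(levels, n_levels, o[1], o[2]))
  Filter(Negate(is.null), out)
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' The 13 texture statistics of one co-occurrence matrix
#'
#' @param P A symmetric, normalized co-occurrence matrix.
#' @return Named numeric vector of the 13 statistics (see
#'   [haralick_names()]).
#' @export
haralick_from_glcm <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))

  # marginal distributions of i + j and |i - j|
  psum <- vapply(2:(2 * ng), function(k) sum(P[i + j == k]), numeric(1))
  ks <- 2:(2 * ng)
  pdiff <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  kd <- 0:(ng - 1)

  asm <- sum(P^2)
  contrast <- sum(kd^2 * pdiff)
  correlation <- if (sx * sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  variance <- sum((i - mux)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(xlogx(psum))
  entropy <- -sum(xlogx(P))
  dmean <- sum(kd * pdiff)
  diff_variance <- sum((kd - dmean)^2 * pdiff)
  diff_entropy <- -sum(xlogx(pdiff))

  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pp <- outer(px, py)
  nz <- P > 0 & pp > 0
  hxy1 <- -sum(P[nz] * log(pp[nz]))
  hxy2 <- -sum(xlogx(pp))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))

  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, diff_variance = diff_variance,
    diff_entropy = diff_entropy, imc1 = imc1, imc2 = imc2)
}

#' Haralick texture features of a masked intensity patch
#'
#' Quantizes the masked intensities, accumulates the four distance-1
#' co-occurrence matrices, and averages the 13 statistics over directions.
#'
#' @param x Numeric intensity matrix.
#' @param mask Logical matrix selecting the region (default: all pixels).
#' @param n_levels Gray levels for quantization (default 8).
#' @param distance Co-occurrence distance in pixels (default 1).
#' @return Named numeric vector of the 13 direction-averaged statistics,
#'   or all-`NA` when no direction has a valid pixel pair (degenerate
#'   region).
#' @examples
#' haralick_features(matrix(runif(64), 8, 8))
#' @export
haralick_features <- function(x, mask = NULL, n_levels = 8, distance = 1) {
  lev <- quantize_gray(x, mask, n_levels)
  Ps <- glcm_matrices(lev, n_levels, distance)
  if (!length(Ps)) {
    out <- rep(NA_real_, 13)
    names(out) <- haralick_names()
    return(out)
  }
  feats <- vapply(Ps, haralick_from_glcm, numeric(13))
  rowMeans(feats)
}
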