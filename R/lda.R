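#' Canonical linear discriminant analysis of cell features
#'
#' Fits the supervised projection that maximizes between-group relative
#' to within-group scatter. Features are z-scored on the training data by
#' default (heterogeneous units — areas vs texture statistics — otherwise
#' dominate the scatter matrices). Canonical coefficients are scaled so
#' the pooled within-group covariance of the canonical scores is the
#' identity; components are ordered by decreasing eigenvalue of
#' `Sw^-1 Sb` (scatter matrices). A numerically singular pooled scatter
#' triggers a small ridge regularization, flagged on the model.
#'
#' @param X Numeric matrix (cells x features) or data frame of numeric
#'   columns.
#' @param y Group labels, one per row; >= 2 groups, each with >= 2 cells.
#' @param standardize Z-score the features first? Default `TRUE`.
#' @return An `lda_model`: list with `coef` (features x components),
#'   `eigenvalues`, `group_means` (canonical space), `center`, `scale`,
#'   `within_cov` (pooled, standardized features), `levels`,
#'   `regularized`.
#' @export
fit_lda <- function(X, y, standardize = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X); p <- ncol(X); k <- nlevels(y)
  if (k < 2) stop("need at least 2 groups")
  if (any(table(y) < 2)) stop("every group needs more than 1 cell")
  stopifnot(length(y) == n)

  center <- colMeans(X)
  scl <- if (standardize) apply(X, 2, stats::sd) else rep(1, p)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scl, "/")

  Ms <- rowsum(Z, y) / as.vector(table(y))      # group means, k x p
  ng <- as.vector(table(y))
  Sw <- matrix(0, p, p)
  for (g in seq_len(k)) {
    D <- sweep(Z[y == levels(y)[g], , drop = FALSE], 2, Ms[g, ])
    Sw <- Sw + crossprod(D)
  }
  gm <- colMeans(Z)
  Dm <- sweep(Ms, 2, gm)
  Sb <- crossprod(Dm * sqrt(ng))

  ew <- eigen(Sw, symmetric = TRUE)
  tol <- 1e-10 * max(ew$values, 1)
  regularized <- any(ew$values < tol)
  if (regularized) {
    warning("singular pooled within-group scatter; ridge-regularized")
    ridge <- 1e-6 * mean(diag(Sw)) + 1e-12
    Sw <- Sw + diag(ridge, p)
    ew <- eigen(Sw, symmetric = TRUE)
  }
  Wi2 <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))  # Sw^{-1/2}
  M <- t(Wi2) %*% Sb %*% Wi2
  M <- (M + t(M)) / 2
  eb <- eigen(M, symmetric = TRUE)

  ncomp <- min(k - 1, p)
  # scores get identity *pooled within covariance*: A' (Sw/(n-k)) A = I
  A <- Wi2 %*% eb$vectors[, seq_len(ncomp), drop = FALSE] * sqrt(n - k)
  rownames(A) <- colnames(X)
  colnames(A) <- paste0("canonical", seq_len(ncomp))
  gmeans <- Dm %*% A
  rownames(gmeans) <- levels(y)

  structure(list(coef = A, eigenvalues = eb$values[seq_len(ncomp)],
                 group_means = gmeans, center = center, scale = scl,
                 grand_mean = gm, within_cov = Sw / (n - k),
                 levels = levels(y), n = n, regularized = regularized),
            class = "lda_model")
}

#' Canonical scores of cells under a fitted model
#'
#' @param model An `lda_model`.
#' @param X Feature matrix with the model's columns.
#' @return Matrix of canonical scores (cells x components).
#' @export
canonical_scores <- function(model, X) {
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  sweep(Z, 2, model$grand_mean) %*% model$coef
}

#' Classify cells and report accuracy
#'
#' Assigns each cell to the group with the nearest canonical mean
#' (Euclidean distance in canonical space — the Mahalanobis rule under
#' the pooled covariance — with equal priors; equidistant ties go to the
#' lowest group index). By default this is resubstitution on the supplied
#' set; see [cv_accuracy()] for a cross-validated variant.
#'
#' @param model An `lda_model`.
#' @param X Feature matrix.
#' @param y True group labels (must all be levels of the model).
#' @return A `classification_report`: `confusion` (true x predicted),
#'   `percent_correct`, `per_group_percent`, `predicted`.
#' @export
classify <- function(model, X, y) {
  y <- factor(y, levels = model$levels)
  if (anyNA(y)) stop("labels contain groups unseen by the model")
  S <- canonical_scores(model, X)
  D <- outer(rowSums(S^2), rowSums(model$group_means^2), "+") -
    2 * S %*% t(model$group_means)
  pred <- factor(model$levels[apply(D, 1, which.min)], levels = model$levels)
  confusion <- table(true = y, predicted = pred)
  pc <- 100 * sum(diag(confusion)) / length(y)
  pg <- 100 * diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion, percent_correct = pc,
                 per_group_percent = pg, predicted = pred),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("%.1f%% correctly classified\n", x$percent_correct))
  print(x$confusion)
  invisible(x)
}

#' Cross-validated classification accuracy
#'
#' Refits the canonical discriminant model on each training fold and
#' classifies the held-out cells.
#'
#' @inheritParams fit_lda
#' @param folds Number of folds (default 5).
#' @param seed Seed controlling the fold assignment.
#' @return Percent of cells correctly classified out-of-fold.
#' @export
cv_accuracy <- function(X, y, folds = 5, seed = 1, standardize = TRUE) {
  X <- as.matrix(X); y <- factor(y)
  n <- nrow(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  correct <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < nlevels(y)) next
    m <- fit_lda(X[tr, , drop = FALSE], y[tr], standardize = standardize)
    te <- which(!tr & y %in% m$levels)
    if (!length(te)) next
    rep <- classify(m, X[te, , drop = FALSE], droplevels(y[te]))
    correct <- correct + sum(diag(rep$confusion))
  }
  100 * correct / n
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Wilks' lambda test of equal multivariate group means
#'
#' `lambda = det(Sw) / det(St)` on the feature scatter matrices, with
#' Rao's approximate F transformation and its p-value (the `p_F` reported
#' alongside canonical plots).
#'
#' @inheritParams fit_lda
#' @return A `wilks_result`: `lambda`, `F`, `df1`, `df2`, `p_F`.
#' @export
wilks_test <- function(X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X); p <- ncol(X); g <- nlevels(y)
  if (n - g <= p)
    stop("too few observations for ", p,
         " features; reduce the feature set (need n - groups > features)")
  Ms <- rowsum(X, y) / as.vector(table(y))
  Sw <- matrix(0, p, p)
  for (i in seq_len(g)) {
    D <- sweep(X[y == levels(y)[i], , drop = FALSE], 2, Ms[i, ])
    Sw <- Sw + crossprod(D)
  }
  Dt <- sweep(X, 2, colMeans(X))
  St <- crossprod(Dt)
  ldt <- determinant(St, logarithm = TRUE)
  if (!is.finite(ldt$modulus) || ldt$sign <= 0)
    stop("singular total scatter matrix; reduce or decorrelate the features")
  ldw <- determinant(Sw, logarithm = TRUE)
  lambda <- exp(as.numeric(ldw$modulus - ldt$modulus))
  lambda <- min(1, max(0, lambda))

  tden <- p^2 + (g - 1)^2 - 5
  tt <- if (tden > 0) sqrt((p^2 * (g - 1)^2 - 4) / tden) else 1
  w <- n - 1 - (p + g) / 2
  df1 <- p * (g - 1)
  df2 <- w * tt - (df1 - 2) / 2
  lam_t <- lambda^(1 / tt)
  Fstat <- if (lam_t > 0) (1 - lam_t) / lam_t * df2 / df1 else Inf
  pF <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  structure(list(lambda = lambda, F = Fstat, df1 = df1, df2 = df2, p_F = pF),
            class = "wilks_result")
}

#' @export
print.wilks_result <- function(x, ...) {
  cat(sprintf("Wilks' lambda = %.4f, F(%g, %.1f) = %.3f, p_F = %.4g\n",
              x$lambda, x$df1, x$df2, x$F, x$p_F))
  invisible(x)
}

#' Coverage contour ellipse of a group in canonical space
#'
#' Fits a bivariate normal to a group's first two canonical scores and
#' returns the covariance ellipse scaled to enclose the requested
#' probability mass (via the chi-square(2) quantile); with the default
#' `coverage = 0.5` this is the "contains roughly half the cells" contour
#' of a canonical plot, centered on the group's mean canonical values.
#'
#' @param model An `lda_model` with >= 2 components.
#' @param scores Canonical score matrix of all cells.
#' @param y Group labels for the rows of `scores`.
#' @param group The group to contour (>= 3 cells).
#' @param coverage Probability mass inside the ellipse, in (0, 1).
#' @return List with `center`, `radii` (semi-axes), `angle` (radians of
#'   the major axis), `cov`, and `coverage`.
#' @export
canonical_contour <- function(model, scores, y, group, coverage = 0.5) {
  if (coverage <= 0 || coverage >= 1) stop("coverage must be inside (0, 1)")
  if (ncol(scores) < 2) stop("need at least 2 canonical components")
  S <- scores[y == group, 1:2, drop = FALSE]
  if (nrow(S) < 3) stop("need at least 3 cells in group ", group)
  ctr <- colMeans(S)
  V <- stats::cov(S)
  ev <- eigen(V, symmetric = TRUE)
  r <- sqrt(pmax(ev$values, 0) * stats::qchisq(coverage, df = 2))
  list(center = ctr, radii = r,
       angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
       cov = V, coverage = coverage)
}

#' Is a point inside a coverage ellipse?
#' @param contour A contour from [canonical_contour()].
#' @param pts Matrix of points (n x 2).
#' @return Logical vector.
#' @export
in_contour <- function(contour, pts) {
  d <- sweep(as.matrix(pts), 2, contour$center)
  md <- rowSums((d %*% solve(contour$cov)) * d)
  md <= stats::qchisq(contour$coverage, df = 2)
}

#' Rank predictors by bootstrap-forest importance
#'
#' Screens the feature set with an ensemble of bootstrap-resampled
#' decision trees (a bootstrap forest): per-feature impurity decrease is
#' summed within each tree and averaged over the ensemble. Deterministic
#' given `seed`. Constant features receive importance 0.
#'
#' @inheritParams fit_lda
#' @param n_boot Number of bootstrap trees (>= 50; default 200).
#' @param seed Integer seed for the resampling.
#' @return A `predictor_ranking` data frame (`feature`, `importance`) in
#'   decreasing importance.
#' @export
rank_predictors <- function(X, y, n_boot = 200, seed = 1) {
  if (n_boot < 50) stop("n_boot must be at least 50")
  d <- as.data.frame(X)
  d$.group <- factor(y)
  if (nlevels(d$.group) < 2) stop("need at least 2 groups")
  fit <- ranger::ranger(dependent.variable.name = ".group", data = d,
                        num.trees = n_boot, importance = "impurity",
                        replace = TRUE, seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  out <- data.frame(feature = names(imp), importance = as.numeric(imp))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  class(out) <- c("predictor_ranking", "data.frame")
  out
}
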