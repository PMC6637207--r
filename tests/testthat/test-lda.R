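gauss_groups <- function(n, means, sd = 1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_along(means), function(g)
    matrix(rnorm(n * length(means[[g]]), sd = sd), n,
           byrow = TRUE) + rep(means[[g]], each = n)))
  list(X = X, y = factor(rep(seq_along(means), each = n)))
}

test_that("two 1D groups separate by their Mahalanobis distance", {
  set.seed(1)
  x <- c(rnorm(300, 0), rnorm(300, 1))
  y <- rep(c("a", "b"), each = 300)
  m <- fit_lda(matrix(x, ncol = 1), y, standardize = FALSE)
  sep <- unname(abs(diff(m$group_means[, 1])))
  # canonical scores have unit pooled within-group sd, so the separation
  # approximates the Mahalanobis distance between the population means
  pooled_sd <- sqrt(((300 - 1) * var(x[1:300]) +
                     (300 - 1) * var(x[301:600])) / (600 - 2))
  expect_equal(sep, abs(mean(x[301:600]) - mean(x[1:300])) / pooled_sd,
               tolerance = 1e-10)
  expect_equal(sep, 1, tolerance = 0.2)
})

test_that("canonical eigenvalues solve the generalized eigenproblem", {
  d <- gauss_groups(40, list(c(0, 0), c(2, 0), c(1, 3)), seed = 7)
  m <- fit_lda(d$X, d$y, standardize = FALSE)

  # dense oracle: eigenvalues of solve(Sw) %*% Sb on raw scatter matrices
  Ms <- rowsum(d$X, d$y) / as.vector(table(d$y))
  Sw <- matrix(0, 2, 2)
  for (g in levels(d$y)) {
    D <- sweep(d$X[d$y == g, ], 2, Ms[g, ])
    Sw <- Sw + crossprod(D)
  }
  Dm <- sweep(Ms, 2, colMeans(d$X))
  Sb <- crossprod(Dm * sqrt(as.vector(table(d$y))))
  oracle <- sort(Re(eigen(solve(Sw) %*% Sb)$values), decreasing = TRUE)
  expect_lt(max(abs(m$eigenvalues - oracle[1:2])), 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
})

test_that("canonical scores have identity pooled within-group covariance", {
  d <- gauss_groups(50, list(c(0, 0, 0), c(1, 2, 0), c(0, 1, 2)), seed = 8)
  m <- fit_lda(d$X, d$y)
  S <- canonical_scores(m, d$X)
  k <- nlevels(d$y); n <- nrow(S)
  Sw <- matrix(0, ncol(S), ncol(S))
  for (g in levels(d$y)) {
    D <- sweep(S[d$y == g, ], 2, colMeans(S[d$y == g, , drop = FALSE]))
    Sw <- Sw + crossprod(D)
  }
  expect_lt(max(abs(Sw / (n - k) - diag(ncol(S)))), 1e-10)
})

test_that("classification agrees with an independent LDA on clear data", {
  d <- gauss_groups(60, list(c(0, 0), c(4, 0), c(0, 4), c(4, 4)), seed = 9)
  m <- fit_lda(d$X, d$y, standardize = FALSE)
  rep <- classify(m, d$X, d$y)
  ref <- MASS::lda(d$X, d$y, prior = rep(1 / 4, 4))
  agree <- mean(predict(ref)$class == rep$predicted)
  expect_gte(agree, 0.99)
  expect_equal(sum(rep$confusion), 240)
})

test_that("permuted labels collapse the leading eigenvalue", {
  d <- gauss_groups(60, list(c(0, 0), c(3, 0), c(0, 3)), seed = 10)
  m_true <- fit_lda(d$X, d$y, standardize = FALSE)
  set.seed(11)
  lead_perm <- replicate(20, {
    fit_lda(d$X, sample(d$y), standardize = FALSE)$eigenvalues[1]
  })
  expect_gt(m_true$eigenvalues[1], 10 * median(lead_perm))
})

test_that("perfect separation classifies at 100%, identity at chance", {
  d <- gauss_groups(50, list(c(0, 0), c(50, 0)), sd = 0.5, seed = 12)
  m <- fit_lda(d$X, d$y)
  expect_equal(classify(m, d$X, d$y)$percent_correct, 100)

  d0 <- gauss_groups(400, list(c(0, 0), c(0, 0), c(0, 0), c(0, 0)), seed = 13)
  m0 <- fit_lda(d0$X, d0$y)
  pc <- classify(m0, d0$X, d0$y)$percent_correct
  expect_lt(abs(pc - 25), 6)
  expect_error(classify(m0, d0$X, factor(rep("zz", 1600))), "unseen")
})

test_that("resubstitution accuracy is at least cross-validated accuracy", {
  accs <- sapply(1:5, function(s) {
    d <- gauss_groups(40, list(c(0, 0, 0), c(1, 0.5, 0), c(0, 1, 0.5)),
                      seed = 100 + s)
    m <- fit_lda(d$X, d$y)
    c(classify(m, d$X, d$y)$percent_correct,
      cv_accuracy(d$X, d$y, folds = 5, seed = s))
  })
  expect_gte(mean(accs[1, ] - accs[2, ]), 0)
})

test_that("Wilks lambda matches manova and the 1-feature ANOVA F", {
  # duplicated identical groups: no between-group scatter at all
  set.seed(14)
  X <- matrix(rnorm(60), 30, 2)
  dup <- rbind(X, X)
  y <- rep(c("a", "b"), each = 30)
  w <- wilks_test(dup, y)
  expect_equal(w$lambda, 1)
  expect_equal(w$p_F, 1)

  # 1 feature, 2 groups: F equals the one-way ANOVA F exactly
  x1 <- matrix(c(rnorm(20), rnorm(20, 0.8)), ncol = 1)
  y1 <- rep(c("a", "b"), each = 20)
  w1 <- wilks_test(x1, y1)
  a1 <- anova(lm(x1 ~ y1))
  expect_equal(w1$F, a1$`F value`[1], tolerance = 1e-10)
  expect_equal(w1$p_F, a1$`Pr(>F)`[1], tolerance = 1e-10)

  # multi-feature, multi-group: agree with stats::manova
  d <- gauss_groups(30, list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), seed = 15)
  w3 <- wilks_test(d$X, d$y)
  mv <- summary(manova(d$X ~ d$y), test = "Wilks")$stats
  expect_equal(w3$lambda, mv[1, "Wilks"], tolerance = 1e-10)
  expect_equal(w3$F, mv[1, "approx F"], tolerance = 1e-8)
  expect_equal(w3$p_F, mv[1, "Pr(>F)"], tolerance = 1e-10)

  expect_error(wilks_test(matrix(rnorm(80), 10, 8), rep(1:5, 2)), "features")
})

test_that("coverage contours have the closed-form isotropic radius", {
  set.seed(16)
  n <- 20000
  S <- matrix(rnorm(2 * n), n, 2)
  y <- rep("g", n)
  model <- list(levels = "g")  # only scores are used
  ct <- canonical_contour(model, S, y, "g", coverage = 0.5)
  r_expect <- sqrt(qchisq(0.5, 2))  # ~1.1774 for unit isotropic scores
  expect_equal(unname(ct$radii[1]), r_expect, tolerance = 0.03)
  expect_equal(unname(ct$radii[2]), r_expect, tolerance = 0.03)
  # empirical containment ~ 50%
  expect_equal(mean(in_contour(ct, S)), 0.5, tolerance = 0.02)
  # near-total coverage contains almost everything
  ct99 <- canonical_contour(model, S, y, "g", coverage = 0.999)
  expect_gt(mean(in_contour(ct99, S)), 0.99)
  expect_error(canonical_contour(model, S, y, "g", coverage = 1.2), "coverage")
})

test_that("bootstrap-forest ranking finds a planted predictor", {
  set.seed(17)
  n <- 120
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c("a", "b"), each = n / 2)
  X[, 3] <- ifelse(y == "a", 0, 4) + rnorm(n, sd = 0.3)
  X[, 5] <- 7  # constant
  rk <- rank_predictors(X, y, n_boot = 200, seed = 3)
  expect_equal(rk$feature[1], "f3")
  expect_lt(rk$importance[rk$feature == "f5"], 1e-12)
  rk2 <- rank_predictors(X, y, n_boot = 200, seed = 3)
  expect_identical(rk, rk2)
  expect_error(rank_predictors(X, y, n_boot = 10), "50")
})

test_that("pure-noise features show no dominant predictor", {
  set.seed(18)
  X <- matrix(rnorm(200 * 6), 200, 6)
  y <- rep(c("a", "b"), each = 100)
  rk <- rank_predictors(X, y, n_boot = 300, seed = 4)
  expect_lt(max(rk$importance) / sum(rk$importance), 0.5)
})
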