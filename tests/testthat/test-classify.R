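# Literal sample-by-sample implementation of the analytic shrinkage
# estimator (diagonal-variance target), kept as the independent oracle.
brute_shrinkage <- function(xc) {
  n <- nrow(xc); p <- ncol(xc)
  wbar <- matrix(0, p, p)
  for (k in seq_len(n)) wbar <- wbar + tcrossprod(xc[k, ])
  wbar <- wbar / n
  s <- n / (n - 1) * wbar
  vs <- matrix(0, p, p)
  for (k in seq_len(n)) vs <- vs + (tcrossprod(xc[k, ]) - wbar)^2
  vs <- n / (n - 1)^3 * vs
  off <- !diag(p)
  min(1, max(0, sum(vs[off]) / sum(s[off]^2)))
}

test_that("shrinkage intensity and discriminants match the brute-force oracle", {
  set.seed(20)
  x <- matrix(stats::rnorm(20 * 5), 20, 5) %*%
    matrix(stats::runif(25, -1, 1), 5, 5)
  xc <- scale(x, center = TRUE, scale = FALSE)
  lam_brute <- brute_shrinkage(xc)
  expect_equal(twitchbci:::shrinkage_intensity(xc), lam_brute,
               tolerance = 1e-10)
  # discriminant direction: shrunk solve vs explicit covariance solve
  d <- stats::rnorm(5)
  S <- crossprod(xc) / (nrow(xc) - 1)
  sigma <- (1 - lam_brute) * S + lam_brute * diag(diag(S))
  expect_equal(twitchbci:::shrunk_solve(xc, lam_brute, d),
               solve(sigma, d), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("shrinkage limits recover ordinary and diagonal LDA", {
  set.seed(21)
  n <- 60
  x <- rbind(matrix(stats::rnorm(n * 4), n), matrix(stats::rnorm(n * 4) + 1, n))
  y <- rep(c("a", "b"), each = n)
  m0 <- fit_shrinkage_lda(x, y, lambda = 0)
  # closed-form ordinary LDA
  mu1 <- colMeans(x[y == "a", ]); mu0 <- colMeans(x[y == "b", ])
  xc <- x
  xc[y == "a", ] <- sweep(x[y == "a", ], 2, mu1)
  xc[y == "b", ] <- sweep(x[y == "b", ], 2, mu0)
  S <- crossprod(xc) / (nrow(x) - 1)
  expect_equal(m0$W[, "a"], solve(S, mu1 - mu0), tolerance = 1e-6,
               ignore_attr = TRUE)
  # lambda = 1: covariance collapses to the diagonal target
  m1 <- fit_shrinkage_lda(x, y, lambda = 1)
  expect_equal(m1$W[, "a"], (mu1 - mu0) / diag(S), tolerance = 1e-10,
               ignore_attr = TRUE)
  # estimated intensity always lies in [0, 1]
  for (i in 1:5) {
    xi <- matrix(stats::rnorm(40 * 30), 40)
    yi <- rep(c("a", "b"), each = 20)
    expect_true(all(fit_shrinkage_lda(xi, yi)$lambda >= 0 &
                      fit_shrinkage_lda(xi, yi)$lambda <= 1))
  }
  expect_error(fit_shrinkage_lda(x[1:3, ], c("a", "a", "b")), "2 samples")
})

test_that("the Woodbury path equals the direct solve for p > n", {
  set.seed(22)
  xc <- scale(matrix(stats::rnorm(30 * 400), 30, 400), scale = FALSE)
  d <- stats::rnorm(400)
  S <- crossprod(xc) / (nrow(xc) - 1)
  lam <- 0.3
  sigma <- (1 - lam) * S + lam * diag(diag(S))
  direct <- solve(sigma, d)
  wood <- twitchbci:::shrunk_solve(xc, lam, d)
  expect_equal(wood, direct, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("probability mapping preserves score ranking", {
  set.seed(23)
  x <- matrix(stats::rnorm(90 * 6), 90)
  y <- rep(c("focus_left", "focus_right", "idle"), each = 30)
  m <- fit_shrinkage_lda(x, y)
  s <- predict(m, x, type = "score")
  p <- predict_proba(m, x)
  expect_equal(rowSums(p), rep(1, 90))
  expect_equal(max.col(s), max.col(p))
  # equal scores -> uniform probabilities
  m_eq <- m
  m_eq$W[] <- 0; m_eq$b[] <- 0
  expect_equal(unname(predict_proba(m_eq, x[1, , drop = FALSE])[1, ]),
               rep(1 / 3, 3))
})

test_that("decision fusion follows the probability-threshold rule", {
  cls <- c("focus_left", "focus_right", "idle")
  pa <- matrix(c(0.8, 0.1, 0.1), 1, dimnames = list(NULL, cls))
  pb <- matrix(c(0.2, 0.6, 0.2), 1, dimnames = list(NULL, cls))
  expect_equal(fuse_decisions(pa, pb), "focus_left")
  pa2 <- matrix(c(0.45, 0.3, 0.25), 1, dimnames = list(NULL, cls))
  pb2 <- matrix(c(0.3, 0.3, 0.4), 1, dimnames = list(NULL, cls))
  expect_equal(fuse_decisions(pa2, pb2), "no_decision")
  # exact tie between different classes: first classifier wins
  pt1 <- matrix(c(0.7, 0.2, 0.1), 1, dimnames = list(NULL, cls))
  pt2 <- matrix(c(0.1, 0.7, 0.2), 1, dimnames = list(NULL, cls))
  expect_equal(fuse_decisions(pt1, pt2), "focus_left")
  # never outputs a class whose winning probability is below the threshold
  set.seed(24)
  for (i in 1:50) {
    ra <- matrix(stats::runif(3), 1, dimnames = list(NULL, cls))
    ra <- ra / sum(ra)
    rb <- matrix(stats::runif(3), 1, dimnames = list(NULL, cls))
    rb <- rb / sum(rb)
    out <- fuse_decisions(ra, rb)
    if (out != "no_decision") {
      expect_gte(max(ra, rb), 0.5)
    } else {
      expect_lt(max(ra), 0.5); expect_lt(max(rb), 0.5)
    }
  }
})

test_that("cross-validation is stratified, deterministic, and consistent", {
  set.seed(25)
  # perfectly separable three-class data
  x <- rbind(matrix(stats::rnorm(30 * 4), 30),
             matrix(stats::rnorm(30 * 4) + 8, 30),
             matrix(stats::rnorm(30 * 4) - 8, 30))
  y <- rep(c("focus_left", "focus_right", "idle"), each = 30)
  cv <- cross_validate(x, y, n_repeats = 2, n_folds = 5, seed = 10)
  expect_equal(cv$accuracy, 100)
  cv2 <- cross_validate(x, y, n_repeats = 2, n_folds = 5, seed = 10)
  expect_identical(cv$fold_accuracy, cv2$fold_accuracy)
  idx <- c(1:5, 31:35, 61:65)                    # 5 trials per class
  expect_error(cross_validate(x[idx, ], y[idx], n_folds = 10), "n_folds")
})

test_that("the exact binomial chance level reproduces known values", {
  # manual tail-sum oracle
  brute_chance <- function(n, K, alpha) {
    p <- 1 / K
    probs <- stats::dbinom(0:n, n, p)
    for (k in 0:n) {
      if (sum(probs[(k + 1):(n + 1)]) < alpha) return(100 * k / n)
    }
  }
  expect_equal(round(chance_level(240, 3, 0.01), 1), 40.8)
  expect_equal(chance_level(240, 3, 0.01), brute_chance(240, 3, 0.01))
  expect_equal(chance_level(240, 3, 0.5), brute_chance(240, 3, 0.5))
  expect_gt(chance_level(240, 3, 0.5), 100 / 3)   # just above the null median
  expect_lt(chance_level(240, 3, 0.5), 35)
  # large-n limit approaches 1/3 from above (normal approximation oracle)
  big <- chance_level(1e6, 3, 0.01)
  approx <- 100 * (1 / 3 + stats::qnorm(0.99) * sqrt(2 / 9 / 1e6))
  expect_equal(big, approx, tolerance = 0.001)
  expect_gt(big, 100 / 3)
})
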