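#' Multi-class shrinkage LDA (one-vs-all)
#'
#' Fits one binary linear discriminant per class (class vs rest).  The pooled
#' within-group covariance of each discriminant is shrunk toward its own
#' diagonal, `(1 - lambda) S + lambda diag(S)`, with the shrinkage intensity
#' estimated analytically (Schaefer-Strimmer, diagonal-variance target) and
#' clipped to [0, 1].  For feature dimensions exceeding the sample count the
#' shrunk system is solved exactly through the Woodbury identity, which keeps
#' high-dimensional fits (e.g. 960 P300 features) inexpensive.
#'
#' @param x feature matrix (trials x features) or a `bci_features` object.
#' @param y class labels (factor); taken from the features object when
#'   omitted.
#' @param lambda fixed shrinkage intensity in [0, 1], or `NULL` to estimate
#'   it analytically per discriminant.
#' @return object of class `shrinkage_lda`: weights `W` (features x classes),
#'   biases `b`, per-class `lambda`, `classes`.
#' @export
fit_shrinkage_lda <- function(x, y = NULL, lambda = NULL) {
  if (inherits(x, "bci_features")) {
    y <- y %||% x$labels
    x <- x$x
  }
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  if (length(classes) < 2) stopf("need at least two classes")
  if (any(table(y) < 2)) stopf("every class needs at least 2 samples")
  p <- ncol(x)
  W <- matrix(0, p, length(classes),
              dimnames = list(colnames(x), classes))
  b <- stats::setNames(numeric(length(classes)), classes)
  lam <- stats::setNames(numeric(length(classes)), classes)
  for (k in seq_along(classes)) {
    g <- y == classes[k]
    mu1 <- colMeans(x[g, , drop = FALSE])
    mu0 <- colMeans(x[!g, , drop = FALSE])
    xc <- x
    xc[g, ] <- sweep(x[g, , drop = FALSE], 2, mu1)
    xc[!g, ] <- sweep(x[!g, , drop = FALSE], 2, mu0)
    l <- lambda %||% shrinkage_intensity(xc)
    w <- shrunk_solve(xc, l, mu1 - mu0)
    W[, k] <- w
    b[k] <- -0.5 * sum((mu1 + mu0) * w)
    lam[k] <- l
  }
  structure(list(W = W, b = b, lambda = lam, classes = classes),
            class = "shrinkage_lda")
}

# Analytic shrinkage intensity toward the diagonal-variance target,
# computed from the group-centered data matrix xc (n x p) in O(n^2 p):
#   lambda* = sum_{i != j} Var(s_ij) / sum_{i != j} s_ij^2
# with s = (n/(n-1)) * mean_k(x_ki x_kj) and
# Var(s_ij) = n/(n-1)^3 * sum_k (x_ki x_kj - mean_k)^2.
shrinkage_intensity <- function(xc) {
  n <- nrow(xc)
  xx <- tcrossprod(xc)                       # n x n
  frob_wbar2 <- sum(xx^2) / n^2              # ||mean_k w_k||_F^2
  d2 <- colSums(xc^2) / n                    # diag of mean_k w_k
  sum_wk2 <- sum(rowSums(xc^2)^2)            # sum_k sum_ij w_kij^2
  sum_wk2_diag <- sum(xc^4)
  var_all <- n / (n - 1)^3 * (sum_wk2 - n * frob_wbar2)
  var_diag <- n / (n - 1)^3 * (sum_wk2_diag - n * sum(d2^2))
  s2_all <- (n / (n - 1))^2 * frob_wbar2
  s2_diag <- (n / (n - 1))^2 * sum(d2^2)
  denom <- s2_all - s2_diag
  if (denom <= 0) return(1)
  min(1, max(0, (var_all - var_diag) / denom))
}

# Solve ((1-lambda) S + lambda diag(S)) w = d with S = crossprod(xc)/(n-1),
# exactly; uses the Woodbury identity when p > n.
shrunk_solve <- function(xc, lambda, d) {
  n <- nrow(xc); p <- ncol(xc)
  dS <- colSums(xc^2) / (n - 1)
  dS <- pmax(dS, max(dS, 1e-300) * 1e-12)
  if (lambda >= 1) return(d / dS)
  if (p <= n || p <= 200) {
    S <- crossprod(xc) / (n - 1)
    sigma <- (1 - lambda) * S
    diag(sigma) <- diag(sigma) + lambda * dS
    return(solve(sigma, d))
  }
  if (lambda <= 0) {
    stopf("p > n with zero shrinkage: covariance is singular")
  }
  # (D + c X'X)^-1 = D^-1 - D^-1 X' (I/c + X D^-1 X')^-1 X D^-1,  D = lambda dS
  cc <- (1 - lambda) / (n - 1)
  Dv <- lambda * dS
  z <- d / Dv
  xdi <- sweep(xc, 2, Dv, "/")               # X D^-1
  K <- diag(n) / cc + tcrossprod(xdi, xc)    # I/c + X D^-1 X'
  z - crossprod(xdi, solve(K, xc %*% z))[, 1]
}

#' @export
predict.shrinkage_lda <- function(object, newdata,
                                  type = c("class", "prob", "score"), ...) {
  if (inherits(newdata, "bci_features")) newdata <- newdata$x
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  scores <- sweep(newdata %*% object$W, 2, object$b, "+")
  switch(match.arg(type),
         score = scores,
         prob = softmax_rows(scores),
         class = factor(object$classes[max.col(scores, "first")],
                        levels = object$classes))
}

#' Class probabilities from one-vs-all scores
#'
#' Maps the linear one-vs-all scores to class probabilities by a softmax
#' (monotone in each score; rows sum to 1).
#'
#' @param model a fitted [fit_shrinkage_lda()] model.
#' @param newdata feature matrix or `bci_features`.
#' @return matrix of probabilities (trials x classes).
#' @export
predict_proba <- function(model, newdata) {
  predict(model, newdata, type = "prob")
}

softmax_rows <- function(s) {
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}

#' Fuse two classifiers' probability outputs
#'
#' Each classifier contributes its most probable class and that class's
#' probability; the final decision is the class from the classifier with the
#' higher probability, provided it reaches the threshold -- otherwise no
#' decision is made.  Exact ties go to the first classifier.
#'
#' @param proba_a,proba_b probability matrices (trials x classes, identical
#'   column sets) or single probability vectors.
#' @param threshold minimum winning probability.
#' @return character vector of class names, `"no_decision"` where neither
#'   classifier reaches the threshold.
#' @export
fuse_decisions <- function(proba_a, proba_b, threshold = 0.5) {
  as_mat <- function(p) if (is.null(dim(p))) matrix(p, nrow = 1) else p
  pa <- as_mat(proba_a); pb <- as_mat(proba_b)
  stopifnot(identical(colnames(pa), colnames(pb)), nrow(pa) == nrow(pb))
  out <- character(nrow(pa))
  for (i in seq_len(nrow(pa))) {
    ia <- which.max(pa[i, ]); ib <- which.max(pb[i, ])
    va <- pa[i, ia]; vb <- pb[i, ib]
    win <- if (va >= vb) c(ia, va) else c(ib, vb)   # tie -> first classifier
    out[i] <- if (win[2] >= threshold) colnames(pa)[win[1]] else "no_decision"
  }
  out
}

#' Repeated stratified cross-validation
#'
#' `n_repeats` x `n_folds` cross-validation with class-stratified folds; the
#' model is refit on every training split and the accuracy averaged over all
#' repeat x fold test sets.
#'
#' @param x feature matrix or `bci_features`.
#' @param y labels (taken from the features object when omitted).
#' @param n_repeats,n_folds layout (default 10 x 10).
#' @param seed RNG seed; the fold assignment is fully determined by it.
#' @param lambda passed to [fit_shrinkage_lda()].
#' @return object of class `cv_result`: `accuracy` (%), `fold_accuracy`
#'   (repeats x folds, %), `confusion` (true x predicted counts).
#' @export
cross_validate <- function(x, y = NULL, n_repeats = 10, n_folds = 10,
                           seed = 1, lambda = NULL) {
  if (inherits(x, "bci_features")) {
    y <- y %||% x$labels
    x <- x$x
  }
  y <- droplevels(as.factor(y))
  if (any(table(y) < n_folds)) {
    stopf("every class needs at least n_folds = %d samples", n_folds)
  }
  classes <- levels(y)
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  fold_acc <- matrix(NA_real_, n_repeats, n_folds)
  for (r in seq_len(n_repeats)) {
    folds <- with_seed(derive_seed(seed, r), {
      f <- integer(length(y))
      for (cl in classes) {
        idx <- sample(which(y == cl))
        f[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      f
    })
    for (k in seq_len(n_folds)) {
      test <- folds == k
      model <- fit_shrinkage_lda(x[!test, , drop = FALSE], y[!test],
                                 lambda = lambda)
      pred <- predict(model, x[test, , drop = FALSE])
      fold_acc[r, k] <- 100 * mean(pred == y[test])
      tab <- table(factor(y[test], classes), factor(pred, classes))
      conf <- conf + as.matrix(tab)
    }
  }
  structure(list(accuracy = mean(fold_acc), fold_accuracy = fold_acc,
                 confusion = conf, n = length(y)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> accuracy %.1f%% (%d x %d CV, n = %d)\n",
              x$accuracy, nrow(x$fold_accuracy), ncol(x$fold_accuracy), x$n))
  invisible(x)
}

#' Exact binomial chance level
#'
#' The smallest accuracy (in %) that a random classifier guessing uniformly
#' among `n_classes` exceeds with probability below `alpha`: the minimal k/n
#' with `P(Binomial(n, 1/n_classes) >= k) < alpha`, computed by exact
#' binomial tail summation.  Classification accuracies above this level are
#' significantly better than random at level `alpha`.
#'
#' @param n_trials_total total number of trials n.
#' @param n_classes number of classes.
#' @param alpha significance level.
#' @return accuracy threshold in percent.
#' @export
chance_level <- function(n_trials_total, n_classes = 3, alpha = 0.01) {
  if (n_trials_total < 1) stopf("need at least one trial")
  p <- 1 / n_classes
  for (k in 0:n_trials_total) {
    tail <- stats::pbinom(k - 1, n_trials_total, p, lower.tail = FALSE)
    if (tail < alpha) return(100 * k / n_trials_total)
  }
  stopf("no attainable threshold at alpha = %g", alpha)
}
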