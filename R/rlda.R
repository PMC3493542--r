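#' Shrinkage-regularized linear discriminant analysis
#'
#' Fits an LDA classifier whose pooled within-class covariance is shrunk
#' toward a scaled identity, `S(lambda) = (1 - lambda) * S +
#' lambda * (tr(S)/d) * I`, `lambda` in `[0, 1]`. The identity target keeps
#' the estimate invertible when the feature dimension approaches or exceeds
#' the trial count — the regime of multi-channel single-trial decoding —
#' while leaving the class means untouched. `lambda = 0` is plain LDA;
#' `lambda = 1` discards all covariance structure and reduces to a
#' nearest-class-mean rule.
#'
#' With `lambda = "auto"` the shrinkage is selected on the training data
#' alone by stratified inner cross-validation over a fixed grid, so no
#' information from held-out trials reaches the hyperparameter.
#'
#' @param x trials x features numeric matrix.
#' @param y class labels (coerced to character), >= 2 classes with >= 2
#'   trials each.
#' @param lambda shrinkage in `[0, 1]`, or `"auto"`.
#' @param priors named class priors (default: empirical frequencies).
#' @param grid candidate grid for `lambda = "auto"`.
#' @param inner_folds folds of the inner selection CV.
#' @return object of class `rlda`: list with `means` (d x K), `cov_eig`
#'   (eigendecomposition of the pooled covariance), `lambda`, `priors`,
#'   `levels`, `W`/`b` (per-class linear scores: `score = x W + b`).
#' @seealso [predict.rlda()], [cross_validated_da()]
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' y <- rep(c("a", "b"), each = 20)
#' fit <- rlda(x, y, lambda = 0.1)
#' mean(predict(fit, x) == y)
rlda <- function(x, y, lambda = "auto", priors = NULL,
                 grid = c(0, 0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 1),
                 inner_folds = 5) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stopf("x has %d rows but y has %d labels",
                                  nrow(x), length(y))
  lev <- sort(unique(y))
  if (length(lev) < 2) stopf("need >= 2 classes")
  cnt <- table(factor(y, lev))
  if (any(cnt < 2)) stopf("every class needs >= 2 trials (got %s)",
                          paste(cnt, collapse = ", "))
  if (identical(lambda, "auto")) {
    lambda <- select_lambda(x, y, grid, inner_folds)
  }
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    stopf("lambda must lie in [0, 1] or be \"auto\"")
  }
  fit <- rlda_core(x, y, lev, priors)
  finish_rlda(fit, lambda)
}

# pooled moments + eigendecomposition, shared by fitting and fast CV paths
rlda_core <- function(x, y, lev, priors = NULL) {
  d <- ncol(x)
  K <- length(lev)
  n <- nrow(x)
  M <- matrix(0, d, K, dimnames = list(colnames(x), lev))
  S <- matrix(0, d, d)
  for (j in seq_len(K)) {
    xi <- x[y == lev[j], , drop = FALSE]
    M[, j] <- colMeans(xi)
    cx <- sweep(xi, 2, M[, j])
    S <- S + crossprod(cx)
  }
  S <- S / max(n - K, 1)
  eig <- eigen(S, symmetric = TRUE)
  nu <- mean(diag(S))
  # zero residual variance (e.g. one trial per class): the shrinkage
  # target degenerates; an isotropic unit target preserves the
  # nearest-class-mean geometry instead of failing
  if (nu <= 0) nu <- 1
  if (is.null(priors)) {
    priors <- as.numeric(table(factor(y, lev))) / n
  } else {
    priors <- priors[lev] / sum(priors[lev])
  }
  list(means = M, cov_eig = eig, nu = nu, priors = priors,
       levels = lev, d = d)
}

# turn the shared moments into per-class linear score functions for a
# given shrinkage; the shrunk inverse reuses the eigenbasis:
# S(l)^-1 = U diag(1 / ((1-l) e + l nu)) U'
finish_rlda <- function(fit, lambda) {
  e <- fit$cov_eig$values
  nu <- fit$nu
  shrunk <- (1 - lambda) * e + lambda * nu
  if (min(shrunk) <= max(shrunk) * 1e-12) {
    stopf(paste("pooled covariance is singular at lambda = %g;",
                "use lambda > 0 (or \"auto\")"), lambda)
  }
  U <- fit$cov_eig$vectors
  W <- U %*% ((1 / shrunk) * crossprod(U, fit$means))   # d x K
  b <- -0.5 * colSums(fit$means * W) + log(fit$priors)
  structure(c(fit, list(lambda = lambda, W = W, b = b)), class = "rlda")
}

# inner-CV shrinkage selection on training data only; first grid value
# attaining the best accuracy wins (smallest lambda on ties)
select_lambda <- function(x, y, grid, inner_folds) {
  folds <- stratified_folds(y, inner_folds)
  acc <- numeric(length(grid))
  lev <- sort(unique(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < length(lev)) next
    core <- rlda_core(x[tr, , drop = FALSE], y[tr], lev)
    for (g in seq_along(grid)) {
      m <- try(finish_rlda(core, grid[g]), silent = TRUE)
      if (inherits(m, "try-error")) { acc[g] <- -Inf; next }
      pr <- predict(m, x[!tr, , drop = FALSE])
      acc[g] <- acc[g] + sum(pr == y[!tr])
    }
  }
  grid[which.max(acc)]
}

#' Predict classes or discriminant scores from an RLDA fit
#'
#' Assigns each row the class with the highest linear discriminant score;
#' exact ties go to the lexicographically smallest label, so prediction is
#' deterministic.
#'
#' @param object an [rlda()] fit.
#' @param newdata trials x features matrix (same feature dimension as
#'   training).
#' @param type `"class"` (default) or `"score"` (trials x classes matrix of
#'   discriminant scores).
#' @param ... unused.
#' @export
predict.rlda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d) {
    stopf("feature dimension %d does not match the fit's %d",
          ncol(newdata), object$d)
  }
  sc <- sweep(newdata %*% object$W, 2, object$b, `+`)
  colnames(sc) <- object$levels
  if (type == "score") return(sc)
  # ties resolved toward the first (lexicographically smallest) level
  object$levels[apply(sc, 1, which.max)]
}

#' @export
print.rlda <- function(x, ...) {
  cat(sprintf("<rlda> %d classes (%s), %d features, lambda = %g\n",
              length(x$levels), paste(x$levels, collapse = ", "),
              x$d, x$lambda))
  invisible(x)
}

#' @export
#' @describeIn rlda discriminant weight vector(s): for two classes the
#'   single vector `S(lambda)^-1 (mu_1 - mu_2)`; for more, the per-class
#'   score weights.
coef.rlda <- function(object, ...) {
  if (length(object$levels) == 2) {
    drop(object$W[, 1] - object$W[, 2])
  } else {
    object$W
  }
}

# balanced label-stratified fold assignment drawn from the current RNG
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
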