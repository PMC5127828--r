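#' Analytic shrinkage estimate of a covariance matrix
#'
#' Ledoit-Wolf well-conditioned estimator: the convex combination
#' `Sigma = (1 - lambda) S + lambda nu I` of the empirical covariance `S`
#' (computed with `1/n` scaling from rows already centered, e.g. within
#' class) and the spherical target `nu I` with `nu = trace(S) / p`. The
#' shrinkage intensity is the closed form
#' `lambda = min(b2, d2) / d2` with
#' `d2 = ||S - nu I||_F^2` and
#' `b2 = (1/n^2) sum_t ||x_t x_t' - S||_F^2`
#' (the estimated variance of the entries of `S`), clipped to \[0, 1\].
#' Shrinkage compresses the eigenvalue spectrum toward `nu`: every
#' eigenvalue of the result lies between the corresponding eigenvalue of
#' `S` and `nu`, so the estimate is positive definite whenever `nu > 0`,
#' even when `S` is rank-deficient (`p > n`).
#'
#' @param X n x p matrix of centered observations (rows).
#' @return List with `sigma` (p x p shrunk covariance), `lambda`, `nu`,
#'   and `s` (the empirical covariance).
#' @export
shrinkage_covariance <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) stop("need at least 2 rows")
  S <- crossprod(X) / n
  nu <- sum(diag(S)) / p
  if (nu <= 0) stop("degenerate input: zero covariance (nu = 0)")
  d2 <- sum((S - diag(nu, p))^2)
  # sum_t ||x_t x_t' - S||^2 = sum_t (x_t'x_t)^2 - n ||S||^2
  b2 <- (sum(rowSums(X^2)^2) / n - sum(S^2)) / n
  lambda <- if (d2 == 0) 1 else min(max(b2, 0), d2) / d2
  sigma <- (1 - lambda) * S + diag(lambda * nu, p)
  list(sigma = sigma, lambda = lambda, nu = nu, s = S)
}

#' Fit a regularized binary linear discriminant
#'
#' Binary LDA with the pooled within-class covariance replaced by its
#' analytic shrinkage estimate: class means are computed per class, rows
#' are centered by their own class mean, the pooled centered sample is
#' shrunk once via [shrinkage_covariance()], and the discriminant weight
#' vector is obtained from the linear solve
#' `w = Sigma^{-1} (mu1 - mu0)` (no explicit inverse). The decision
#' threshold is the midpoint `b = w' (mu0 + mu1) / 2`, i.e. equal class
#' priors, appropriate for balanced designs.
#'
#' @param X n x p numeric matrix of (transformed, screened) predictors.
#' @param y binary labels; the second factor level (or the larger of two
#'   numeric values) is the positive class.
#' @param lambda optional fixed shrinkage intensity overriding the
#'   analytic estimate (`lambda = 0` gives classical pooled-covariance
#'   LDA).
#' @return An `rlda` object: list with `mu0`, `mu1`, `sigma`, `lambda`,
#'   `nu`, `w`, `bias`, `levels`, `columns`.
#' @export
fit_rlda <- function(X, y, lambda = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite predictor values")
  f <- as.factor(y)
  if (nlevels(f) != 2) stop("labels must contain exactly two classes")
  i1 <- f == levels(f)[2]
  mu0 <- colMeans(X[!i1, , drop = FALSE])
  mu1 <- colMeans(X[i1, , drop = FALSE])
  Xc <- X
  Xc[!i1, ] <- sweep(X[!i1, , drop = FALSE], 2, mu0)
  Xc[i1, ] <- sweep(X[i1, , drop = FALSE], 2, mu1)
  shr <- shrinkage_covariance(Xc)
  if (!is.null(lambda)) {
    stopifnot(lambda >= 0, lambda <= 1)
    shr$lambda <- lambda
    shr$sigma <- (1 - lambda) * shr$s + diag(lambda * shr$nu, ncol(X))
  }
  w <- drop(solve(shr$sigma, mu1 - mu0))
  structure(list(mu0 = mu0, mu1 = mu1, sigma = shr$sigma,
                 lambda = shr$lambda, nu = shr$nu, w = w,
                 bias = sum(w * (mu0 + mu1)) / 2, levels = levels(f),
                 columns = colnames(X)),
            class = "rlda")
}

#' Decision scores of a fitted discriminant
#'
#' Signed distance to the decision boundary: `score = w' x - bias`;
#' positive scores predict the positive class.
#'
#' @param model an `rlda` fit.
#' @param X matrix of observations with the model's columns.
#' @return Numeric score vector.
#' @export
decision_scores <- function(model, X) {
  stopifnot(inherits(model, "rlda"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$w)) {
    stop("dimension mismatch: model has ", length(model$w), " columns")
  }
  drop(X %*% model$w) - model$bias
}

#' @export
predict.rlda <- function(object, newdata, type = c("class", "score"), ...) {
  sc <- decision_scores(object, newdata)
  if (match.arg(type) == "score") return(sc)
  factor(object$levels[(sc > 0) + 1L], levels = object$levels)
}

#' Serialize / restore an RLDA model as JSON
#'
#' @param model an `rlda` fit.
#' @param path file path to write to.
#' @return `rlda_write` returns `path` invisibly; `rlda_read` the model.
#' @export
rlda_write <- function(model, path) {
  stopifnot(inherits(model, "rlda"))
  obj <- model
  obj$sigma <- as.data.frame(obj$sigma)
  class(obj) <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname rlda_write
#' @export
rlda_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sigma <- as.matrix(obj$sigma)
  dimnames(obj$sigma) <- NULL
  obj$mu0 <- unlist(obj$mu0)
  obj$mu1 <- unlist(obj$mu1)
  obj$w <- unlist(obj$w)
  if (!is.null(obj$columns)) {
    names(obj$mu0) <- names(obj$mu1) <- names(obj$w) <- obj$columns
  }
  structure(obj, class = "rlda")
}
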