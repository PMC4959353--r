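#' Closed-form ridge regression with unpenalized intercept
#'
#' Minimizes `sum((y - b0 - X b)^2) + lambda * sum(b^2)` with the
#' intercept handled by centering `y` and the columns of `X` (never
#' penalized).  This unscaled penalty convention is the one under which
#' rrBLUP's shrinkage weight is the variance ratio `sigma_e^2 /
#' sigma_beta^2`; see [fit_rrblup()].
#'
#' @param X numeric matrix (samples x features).
#' @param y numeric response, `length(y) == nrow(X)`.
#' @param lambda nonnegative ridge weight.  `lambda = 0` requires
#'   full-rank centered `X` and gives ordinary least squares.
#' @return A list with `beta0` (intercept) and `beta` (named effects).
#' @examples
#' fit <- ridge_solve(cbind(x = c(1, 2, 3)), c(2, 4, 6), 0)
#' fit$beta   # 2
#' @export
ridge_solve <- function(X, y, lambda) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), length(lambda) == 1L, lambda >= 0)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - mean(y)
  m <- ncol(X)
  A <- crossprod(Xc) + diag(lambda, m)
  if (lambda == 0) {
    r <- qr(Xc)$rank
    if (r < m) stop("lambda = 0 with rank-deficient design: system is singular",
                    call. = FALSE)
  }
  beta <- drop(solve(A, crossprod(Xc, yc)))
  names(beta) <- colnames(X)
  list(beta0 = mean(y) - sum(xbar * beta), beta = beta)
}

#' Fit rrBLUP by REML
#'
#' @description
#' Fits the mixed model `y = 1 b0 + X b + e` with marker effects
#' `b ~ N(0, sigma_beta^2 I)` and residuals `e ~ N(0, sigma_e^2 I)`.
#' The variance components are estimated by restricted maximum
#' likelihood: after absorbing the intercept by centering, the
#' `n x n` kernel `Xc Xc'` is eigendecomposed once, the REML
#' log-likelihood becomes a cheap function of the variance ratio
#' `lambda = sigma_e^2 / sigma_beta^2`, and a bounded one-dimensional
#' search over `log10(lambda)` in [-8, 8] (relative tolerance 1e-6)
#' locates the optimum.  The marker effects are then the best linear
#' unbiased predictions, identical to the closed-form ridge solution at
#' the estimated `lambda` under the unscaled penalty convention of
#' [ridge_solve()].
#'
#' @param X numeric matrix (samples x features), at least 3 rows.
#' @param y numeric response; must not be constant.
#' @return An object of class `rrblup` with elements `beta0`, `beta`
#'   (named effects), `lambda`, `sigma_beta_sq`, `sigma_e_sq`,
#'   `feature_ids`, and `boundary` (`TRUE` when the optimizer stopped at
#'   a bound of the search interval).
#' @seealso [ridge_solve()], [predict.rrblup()]
#' @export
fit_rrblup <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n == length(y), ncol(X) >= 1L)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(y) == 0) stop("trait is constant; variance components are undefined",
                              call. = FALSE)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - mean(y)

  # One spectral decomposition; every REML evaluation reuses it.
  K <- tcrossprod(Xc)
  eig <- eigen(K, symmetric = TRUE)
  theta_all <- pmax(eig$values, 0)
  U <- eig$vectors
  # Centering projects out the intercept: drop the eigenvector spanning
  # the constant direction (its eigenvalue is 0 because 1'Xc = 0).
  const_dir <- which.max(abs(colMeans(U)))
  keep <- setdiff(seq_len(n), const_dir)
  theta <- theta_all[keep]
  eta <- drop(crossprod(U[, keep, drop = FALSE], yc))

  neg_restricted_ll <- function(log10_lambda) {
    lam <- 10^log10_lambda
    d <- theta + lam
    (n - 1) * log(sum(eta^2 / d)) + sum(log(d))
  }
  lo <- -8; hi <- 8
  opt <- stats::optimize(neg_restricted_ll, interval = c(lo, hi), tol = 1e-6)
  log_lam <- opt$minimum
  boundary <- (log_lam - lo) < 1e-3 || (hi - log_lam) < 1e-3
  lambda <- 10^log_lam
  sigma_beta_sq <- sum(eta^2 / (theta + lambda)) / (n - 1)
  sigma_e_sq <- lambda * sigma_beta_sq

  # BLUP effects via the dual ridge form, reusing the decomposition:
  # beta = Xc' (K + lambda I)^{-1} yc
  w <- drop(crossprod(U, yc)) / (theta_all + lambda)
  beta <- drop(crossprod(Xc, U %*% w))
  names(beta) <- colnames(X)
  structure(list(beta0 = mean(y) - sum(xbar * beta), beta = beta,
                 lambda = lambda, sigma_beta_sq = sigma_beta_sq,
                 sigma_e_sq = sigma_e_sq,
                 feature_ids = colnames(X), boundary = boundary),
            class = "rrblup")
}

#' Predict from a fitted rrBLUP model
#'
#' @param object an `rrblup` model.
#' @param X numeric matrix whose columns match the fit-time features in
#'   order.
#' @param ... unused.
#' @return Numeric vector `beta0 + X beta`.
#' @export
predict.rrblup <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$beta)) {
    stop("feature count does not match the fitted model", call. = FALSE)
  }
  if (!is.null(colnames(X)) && !is.null(object$feature_ids) &&
      !identical(colnames(X), object$feature_ids)) {
    stop("feature ids do not match the fitted model", call. = FALSE)
  }
  drop(object$beta0 + X %*% object$beta)
}

#' @export
print.rrblup <- function(x, ...) {
  cat(sprintf("<rrblup> %d effects, lambda = %.4g (sigma_beta^2 = %.4g, sigma_e^2 = %.4g)%s\n",
              length(x$beta), x$lambda, x$sigma_beta_sq, x$sigma_e_sq,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Support vector regression configuration
#'
#' Hyperparameters for the epsilon-insensitive SVR predictor.  Defaults:
#' sigmoid kernel, `C = 1`, `epsilon = 0.1`, `gamma = 1/m` (set at fit
#' time when `NULL`), `coef0 = 0`, `degree = 3`.
#'
#' @param kernel one of `"linear"`, `"polynomial"`, `"radial"`,
#'   `"sigmoid"`.
#' @param C positive cost of constraint violation.
#' @param epsilon nonnegative width of the insensitive tube.
#' @param gamma positive kernel coefficient, or `NULL` for `1/m`.
#' @param coef0 kernel offset (polynomial/sigmoid).
#' @param degree positive integer polynomial degree.
#' @return A list of class `svr_config`.
#' @export
svr_config <- function(kernel = c("sigmoid", "linear", "polynomial", "radial"),
                       C = 1, epsilon = 0.1, gamma = NULL, coef0 = 0,
                       degree = 3L) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0, epsilon >= 0, is.null(gamma) || gamma > 0, degree >= 1)
  structure(list(kernel = kernel, C = C, epsilon = epsilon, gamma = gamma,
                 coef0 = coef0, degree = as.integer(degree)),
            class = "svr_config")
}

#' Fit an epsilon-SVR on standardized features
#'
#' Thin wrapper around [e1071::svm()].  Features are standardized to
#' zero mean and unit variance on the training data (a zero-variance
#' feature keeps scale 1) and the same standardization is replayed at
#' prediction time.
#'
#' @param X numeric training matrix.
#' @param y numeric response.
#' @param cfg an [svr_config()].
#' @return An object of class `svr_gp` wrapping the fitted machine and
#'   the standardization.
#' @export
fit_svr <- function(X, y, cfg = svr_config()) {
  stopifnot(inherits(cfg, "svr_config"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0] <- 1
  Xs <- scale(X, center = center, scale = scale)
  gamma <- cfg$gamma %||% (1 / ncol(X))
  fit <- e1071::svm(x = Xs, y = y, type = "eps-regression",
                    kernel = cfg$kernel, cost = cfg$C, epsilon = cfg$epsilon,
                    gamma = gamma, coef0 = cfg$coef0, degree = cfg$degree,
                    scale = FALSE, fitted = FALSE)
  structure(list(fit = fit, center = center, scale = scale, cfg = cfg),
            class = "svr_gp")
}

#' @export
predict.svr_gp <- function(object, X, ...) {
  X <- as.matrix(X)
  if (object$fit$tot.nSV == 0L) {
    # every training point sat inside the epsilon tube: the machine is the
    # constant -rho (libsvm's decision value with no support vectors)
    return(rep(-object$fit$rho, nrow(X)))
  }
  Xs <- scale(X, center = object$center, scale = object$scale)
  unname(stats::predict(object$fit, Xs))
}
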