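# DACE-style kriging: constant trend, exponential auto-correlation
# R(d) = exp(-sum_k theta_k |d_k|), hyperparameters by profile-likelihood
# maximum likelihood with a multi-start bounded search.

krig_corr <- function(X1, X2, theta) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  R <- matrix(0, n1, n2)
  for (k in seq_len(ncol(X1))) {
    R <- R + theta[k] * abs(outer(X1[, k], X2[, k], `-`))
  }
  exp(-R)
}

krig_nll <- function(log_theta, X, y, nugget) {
  theta <- exp(log_theta)
  n <- nrow(X)
  R <- krig_corr(X, X, theta) + diag(nugget, n)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  ones <- rep(1, n)
  Ri_y <- backsolve(ch, forwardsolve(t(ch), y))
  Ri_1 <- backsolve(ch, forwardsolve(t(ch), ones))
  beta <- sum(Ri_y) / sum(Ri_1)
  res <- y - beta
  Ri_res <- backsolve(ch, forwardsolve(t(ch), res))
  sigma2 <- max(sum(res * Ri_res) / n, 1e-300)
  n / 2 * log(sigma2) + sum(log(diag(ch)))
}

#' Fit a kriging surrogate
#'
#' Interpolating Gaussian-process model with constant trend and exponential
#' correlation over the unit-cube-normalized inputs. Correlation lengths are
#' fitted by maximum likelihood (multi-start L-BFGS-B over log theta in
#' `[0.01, 20]`); a small nugget keeps the correlation matrix positive
#' definite while preserving interpolation to ~1e-6.
#'
#' @param samples A data frame / tibble with design columns (all but the
#'   last-named `objective` column) and an `objective` column, or a list with
#'   `X` (matrix) and `y`.
#' @param bounds List with `lower` and `upper` used for input normalization;
#'   defaults to [design_bounds()] for 3-column designs, else the data range.
#' @param n_starts Multi-start count for the likelihood search.
#' @param nugget Diagonal regularization of the correlation matrix.
#' @return An object of class `kriging_model`.
#' @export
fit_kriging <- function(samples, bounds = NULL, n_starts = 8, nugget = 1e-8) {
  if (is.data.frame(samples)) {
    y <- samples$objective
    X <- as.matrix(samples[setdiff(names(samples),
                                   c("objective", "provenance", "call",
                                     "seed"))])
  } else {
    X <- as.matrix(samples$X); y <- samples$y
  }
  stopifnot(is.numeric(y), all(is.finite(y)), all(is.finite(X)))
  d <- ncol(X)
  if (nrow(X) < d + 2) stop("need at least d + 2 samples", call. = FALSE)
  dup <- duplicated(round(X, 9))
  if (any(dup)) {
    X <- X[!dup, , drop = FALSE]; y <- y[!dup]
  }
  if (is.null(bounds)) {
    bounds <- if (d == 3) design_bounds()
    else list(lower = apply(X, 2, min), upper = apply(X, 2, max))
  }
  rng <- pmax(bounds$upper - bounds$lower, 1e-12)
  Xn <- sweep(sweep(X, 2, bounds$lower), 2, rng, `/`)
  if (any(apply(Xn, 2, stats::sd) < 1e-12) && nrow(Xn) > 1) {
    stop("degenerate sample spread: a design dimension is constant",
         call. = FALSE)
  }
  # constant response: shortcut (likelihood is flat in theta)
  if (stats::sd(y) < 1e-14) {
    theta <- rep(1, d)
  } else {
    lb <- log(1e-2); ub <- log(20)
    starts <- matrix(stats::runif(n_starts * d, lb, ub), n_starts, d)
    starts[1, ] <- rep(log(1), d)
    best <- NULL
    for (s in seq_len(n_starts)) {
      fit <- tryCatch(
        stats::optim(starts[s, ], krig_nll, X = Xn, y = y, nugget = nugget,
                     method = "L-BFGS-B", lower = lb, upper = ub),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("kriging hyperparameter search failed", call. = FALSE)
    theta <- exp(best$par)
  }
  n <- nrow(Xn)
  R <- krig_corr(Xn, Xn, theta) + diag(nugget, n)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  tries <- 0
  while (is.null(ch) && tries < 6) {
    nugget <- max(nugget * 10, 1e-12)
    if (nugget > 1e-8 * 100) break
    ch <- tryCatch(chol(R + diag(nugget, n)), error = function(e) NULL)
    tries <- tries + 1
  }
  if (is.null(ch)) stop("correlation matrix is rank deficient", call. = FALSE)
  ones <- rep(1, n)
  Ri_y <- backsolve(ch, forwardsolve(t(ch), y))
  Ri_1 <- backsolve(ch, forwardsolve(t(ch), ones))
  beta <- sum(Ri_y) / sum(Ri_1)
  res <- y - beta
  Ri_res <- backsolve(ch, forwardsolve(t(ch), res))
  sigma2 <- sum(res * Ri_res) / n
  structure(list(X = X, Xn = Xn, y = y, bounds = bounds, theta = theta,
                 beta = beta, sigma2 = sigma2, chol = ch,
                 Ri_res = Ri_res, Ri_1 = Ri_1, nugget = nugget),
            class = "kriging_model")
}

#' Predict from a kriging surrogate
#'
#' Kriging mean and mean-squared-error estimate; the uncertainty is zero (up
#' to the nugget) at training points.
#'
#' @param object A `kriging_model`.
#' @param newdata Matrix or data frame of designs (columns as in training).
#' @param check_bounds Reject out-of-bounds designs.
#' @param ... Unused.
#' @return Tibble with columns `mean` and `se`.
#' @export
predict.kriging_model <- function(object, newdata, check_bounds = TRUE, ...) {
  X <- as.matrix(newdata)
  if (check_bounds) {
    ok <- sweep(X, 2, object$bounds$lower - 1e-9, `>=`) &
      sweep(X, 2, object$bounds$upper + 1e-9, `<=`)
    if (!all(ok)) stop("design outside bounds", call. = FALSE)
  }
  rng <- pmax(object$bounds$upper - object$bounds$lower, 1e-12)
  Xn <- sweep(sweep(X, 2, object$bounds$lower), 2, rng, `/`)
  r <- krig_corr(Xn, object$Xn, object$theta)       # m x n
  mean <- object$beta + as.numeric(r %*% object$Ri_res)
  # MSE via the universal-kriging formula with constant trend
  ch <- object$chol
  Ri_r <- backsolve(ch, forwardsolve(t(ch), t(r)))  # n x m
  rRr <- colSums(t(r) * Ri_r)
  one_Ri_r <- as.numeric(crossprod(object$Ri_1, t(r)))
  s2 <- object$sigma2 * pmax(0, 1 - rRr + (1 - one_Ri_r)^2 / sum(object$Ri_1))
  tibble::tibble(mean = mean, se = sqrt(s2))
}

#' @export
print.kriging_model <- function(x, ...) {
  cat(sprintf("<kriging_model> n = %d, d = %d\n  theta: %s\n  beta = %.4g, sigma2 = %.4g\n",
              nrow(x$X), ncol(x$X), paste(signif(x$theta, 4), collapse = ", "),
              x$beta, x$sigma2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kriging model
#'
#' @param x A `kriging_model`.
#' @param ... Unused.
#' @return A tibble with one row per correlation length plus the trend and
#'   process-variance terms.
#' @export
tidy.kriging_model <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("theta_", seq_along(x$theta)), "beta", "sigma2"),
    estimate = c(x$theta, x$beta, x$sigma2))
}

#' @rdname tidy.kriging_model
#' @return `glance()`: a one-row tibble with sample size, dimension and
#'   nugget.
#' @export
glance.kriging_model <- function(x, ...) {
  tibble::tibble(n = nrow(x$X), d = ncol(x$X), nugget = x$nugget,
                 sigma2 = x$sigma2)
}

#' Leave-one-out RMSE of a kriging model
#'
#' Refits the model without each training point in turn (hyperparameters
#' included) and measures the prediction error at the held-out point.
#'
#' @param samples As in [fit_kriging()].
#' @param ... Passed to [fit_kriging()].
#' @return The leave-one-out root-mean-square error.
#' @export
kriging_loo_rmse <- function(samples, ...) {
  if (is.data.frame(samples)) {
    y <- samples$objective
    X <- as.matrix(samples[setdiff(names(samples), "objective")])
  } else {
    X <- as.matrix(samples$X); y <- samples$y
  }
  err <- vapply(seq_along(y), function(i) {
    m <- fit_kriging(list(X = X[-i, , drop = FALSE], y = y[-i]), ...)
    predict(m, X[i, , drop = FALSE], check_bounds = FALSE)$mean - y[i]
  }, numeric(1))
  sqrt(mean(err^2))
}
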