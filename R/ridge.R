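#' Fit a kernel ridge regression interpolant
#'
#' Solves the regularized least squares problem whose loss is
#' \deqn{\sum_i (g(t_i) - y_i)^2 + \lambda\, b^T K b, \qquad
#'       g(t) = \sum_i b_i k(t, t_i),}
#' with the closed-form solution \eqn{b = (K + \lambda I)^{-1} y}. A diagonal
#' jitter (default `1e-8`) is added before factorization to guard against
#' ill-conditioning at small length scales; with `lambda = 0` and distinct
#' times the fit interpolates the data to within that jitter.
#'
#' @param times numeric vector of training abscissa values (length >= 2).
#' @param y numeric vector of observations, same length as `times`.
#' @param kernel a [kernel_spec()].
#' @param lambda nonnegative regularization parameter \eqn{\lambda}.
#' @param jitter nonnegative diagonal jitter added before factorization.
#' @return an object of class `rkhs_interpolant` with fields `kernel`,
#'   `train_times`, `coef`, `lambda`.
#' @examples
#' t <- seq(0, 2 * pi, length.out = 15)
#' g <- fit_ridge(t, sin(t), kernel_spec("rbf"), lambda = 1e-6)
#' predict(g, pi / 2)
#' @export
fit_ridge <- function(times, y, kernel, lambda, jitter = 1e-8) {
  assert_finite(times, "times"); assert_finite(y, "y")
  if (length(times) != length(y)) stop_warpgm("length(times) != length(y)")
  if (length(times) < 2) stop_warpgm("need at least 2 observations")
  if (!is.finite(lambda) || lambda < 0) stop_warpgm("lambda must be >= 0")
  K <- gram_matrix(kernel, times)
  A <- K + diag(lambda + jitter, length(times))
  coef <- tryCatch(
    solve(A, y),
    error = function(e) stop_warpgm(
      "singular ridge system (", conditionMessage(e),
      "); increase lambda or jitter", class = "warpgm_singular")
  )
  structure(list(kernel = kernel, train_times = times, coef = as.numeric(coef),
                 lambda = lambda, jitter = jitter, gram = K),
            class = "rkhs_interpolant")
}

#' @export
print.rkhs_interpolant <- function(x, ...) {
  cat("<rkhs_interpolant>", length(x$train_times), "basis functions,",
      x$kernel$family, "kernel, lambda =", format(x$lambda), "\n")
  invisible(x)
}

#' Predict from an interpolant, with derivatives
#'
#' `predict()` evaluates \eqn{g(t) = \sum_i b_i k(t, t_i)};
#' `predict_dt()` and `predict_d2t()` evaluate the first and second time
#' derivatives through the analytic kernel derivatives. The derivative
#' generics dispatch on the class of `object`, so test fixtures with known
#' closed-form derivatives can provide their own methods.
#'
#' @param object an `rkhs_interpolant` (or any object with methods).
#' @param t numeric vector of evaluation points.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.rkhs_interpolant <- function(object, t, ...) {
  as.numeric(kernel_cross(object$kernel, t, object$train_times, 0L) %*%
               object$coef)
}

#' @rdname predict.rkhs_interpolant
#' @export
predict_dt <- function(object, t) UseMethod("predict_dt")

#' @rdname predict.rkhs_interpolant
#' @export
predict_dt.rkhs_interpolant <- function(object, t) {
  as.numeric(kernel_cross(object$kernel, t, object$train_times, 1L) %*%
               object$coef)
}

#' @rdname predict.rkhs_interpolant
#' @export
predict_d2t <- function(object, t) UseMethod("predict_d2t")

#' @rdname predict.rkhs_interpolant
#' @export
predict_d2t.rkhs_interpolant <- function(object, t) {
  as.numeric(kernel_cross(object$kernel, t, object$train_times, 2L) %*%
               object$coef)
}

# Ridge training loss (data term + lambda * b' K b) of an interpolant.
ridge_loss <- function(interp, y) {
  g <- predict(interp, interp$train_times)
  sum((g - y)^2) +
    interp$lambda * sum(interp$coef * (interp$gram %*% interp$coef))
}

cv_folds <- function(n, folds, scheme = c("blocks", "random"), seed = NULL) {
  scheme <- match.arg(scheme)
  if (folds < 2 || folds > n) stop_warpgm("folds must be in [2, n]")
  idx <- if (scheme == "blocks") seq_len(n) else with_seed(seed, sample.int(n))
  split(idx, cut(seq_len(n), folds, labels = FALSE))
}

cv_error <- function(times, y, kernel, lambda, folds_list, jitter = 1e-8) {
  err <- 0
  for (f in folds_list) {
    tr <- setdiff(seq_along(times), f)
    fit <- fit_ridge(times[tr], y[tr], kernel, lambda, jitter)
    err <- err + sum((predict(fit, times[f]) - y[f])^2)
  }
  err / length(times)
}

# Closed-form leave-one-out squared error of kernel ridge regression:
# e_i = (y_i - g(t_i)) / (1 - H_ii), H = K (K + (lambda + jitter) I)^{-1}.
# Equals the exhaustive n-refit computation exactly.
loo_error <- function(times, y, kernel, lambda, jitter = 1e-8) {
  n <- length(times)
  K <- gram_matrix(kernel, times)
  H <- K %*% solve(K + diag(lambda + jitter, n))
  h <- pmin(diag(H), 1 - 1e-12)
  r <- (y - as.numeric(H %*% y)) / (1 - h)
  mean(r^2)
}

#' Select the ridge regularization parameter by cross validation
#'
#' Scans a grid of \eqn{\lambda} values and returns the one minimizing the
#' mean held-out squared error. Folds are contiguous time blocks by default
#' (avoiding optimistic leakage between neighbouring time points); a
#' seed-controlled random assignment is available. `folds = length(times)`
#' gives exact leave-one-out CV.
#'
#' @param times,y,kernel as in [fit_ridge()].
#' @param lambda_grid numeric vector of candidate \eqn{\lambda} values;
#'   default 12 points log-spaced in `[1e-6, 1e2]`.
#' @param folds number of folds (default 10, capped at `length(times)`).
#' @param scheme `"blocks"` (contiguous, default) or `"random"`.
#' @param seed fold seed for `scheme = "random"`.
#' @return the selected `lambda` (a single number).
#' @export
select_lambda_cv <- function(times, y, kernel,
                             lambda_grid = log_spaced(1e-6, 1e2, 12),
                             folds = 10, scheme = "blocks", seed = NULL) {
  if (length(lambda_grid) == 0) stop_warpgm("lambda_grid must be nonempty")
  n <- length(times)
  if (n < folds) stop_warpgm("fewer observations than folds")
  if (length(lambda_grid) == 1) return(lambda_grid)
  if (folds == n) {
    errs <- vapply(lambda_grid, function(l) loo_error(times, y, kernel, l),
                   numeric(1))
  } else {
    fl <- cv_folds(n, folds, scheme, seed)
    errs <- vapply(lambda_grid, function(l)
      cv_error(times, y, kernel, l, fl), numeric(1))
  }
  lambda_grid[which.min(errs)]
}

#' Optimize kernel hyperparameters against held-out error
#'
#' Multi-start bounded quasi-Newton optimization of the kernel
#' hyperparameters on the log scale (ensuring positivity without a
#' constrained optimizer). The objective is the cross-validated held-out
#' squared error at fixed \eqn{\lambda}, using the same fold scheme as
#' [select_lambda_cv()]. The first start is a data-driven heuristic (length
#' scale from the median knot spacing, amplitude from the data variance);
#' the remaining starts are drawn log-uniformly inside the bounds.
#'
#' @param times,y as in [fit_ridge()].
#' @param family kernel family (`"rbf"` or `"mlp"`).
#' @param lambda fixed ridge penalty used while scoring hyperparameters.
#' @param bounds named list of `c(lower, upper)` per hyperparameter
#'   (positive, finite); defaults cover the data scale.
#' @param n_starts number of multi-starts (>= 1, default 5).
#' @param folds,scheme fold settings, see [select_lambda_cv()].
#' @param seed seed controlling the random starts.
#' @return a list with the optimized `kernel`, the attained `objective`, a
#'   `trace` data frame of all starts, and a `converged` flag (`FALSE` means
#'   the best iterate is returned with a warning).
#' @export
optimize_kernel_hyperparams <- function(times, y, family = "rbf", lambda,
                                        bounds = NULL, n_starts = 5,
                                        folds = 10, scheme = "blocks",
                                        seed = NULL) {
  n <- length(times)
  span <- diff(range(times))
  if (is.null(bounds)) {
    bounds <- switch(family,
      rbf = list(lengthscale = c(span / (2 * n), span),
                 amplitude = c(1e-6, 1e4) * max(stats::var(y), 1e-12)),
      mlp = list(weight_var = c(1e-3, 1e3), bias_var = c(1e-3, 1e3)),
      stop_warpgm("no default bounds for family ", family))
  }
  bl <- log(vapply(bounds, `[`, numeric(1), 1))
  bu <- log(vapply(bounds, `[`, numeric(1), 2))
  if (any(!is.finite(c(bl, bu)))) stop_warpgm("bounds must be positive finite")
  make_spec <- function(logp) {
    p <- as.list(exp(logp)); names(p) <- names(bounds)
    do.call(kernel_spec, c(list(family = family), p))
  }
  use_loo <- folds >= n
  fl <- if (use_loo) NULL else cv_folds(n, folds, scheme, seed)
  obj <- function(logp) {
    sp <- make_spec(logp)
    e <- tryCatch(
      if (use_loo) loo_error(times, y, sp, lambda)
      else cv_error(times, y, sp, lambda, fl),
      error = function(e) NA_real_)
    if (!is.finite(e)) 1e12 else e
  }
  heur <- switch(family,
    rbf = log(c(max(min(2 * stats::median(diff(sort(times)))), exp(bl[1])),
                max(stats::var(y), 1e-12))),
    mlp = log(c(1, 1)))
  heur <- pmin(pmax(heur, bl), bu)
  starts <- list(heur)
  if (n_starts > 1) {
    extra <- with_seed(seed, lapply(seq_len(n_starts - 1), function(i) {
      bl + stats::runif(length(bl)) * (bu - bl)
    }))
    starts <- c(starts, extra)
  }
  trace <- data.frame()
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = bl, upper = bu,
                   control = list(maxit = 100)),
      error = function(e) list(par = s, value = obj(s), convergence = 1L))
    any_conv <- any_conv || identical(res$convergence, 0L)
    trace <- rbind(trace, data.frame(start = I(list(exp(s))),
                                     value = res$value))
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!any_conv) warning("hyperparameter optimizer did not converge; ",
                         "returning best iterate")
  list(kernel = make_spec(best$par), objective = best$value, trace = trace,
       converged = any_conv)
}

# One state's interpolant selection: alternate lambda grid-CV and
# hyperparameter optimization (2 rounds), then fit.
select_interpolant <- function(times, y, family = "rbf",
                               lambda_grid = log_spaced(1e-6, 1e2, 12),
                               folds = 10, scheme = "blocks",
                               n_starts = 5, seed = NULL, rounds = 2) {
  folds <- min(folds, length(times))
  kern <- NULL
  lambda <- stats::median(lambda_grid)
  for (r in seq_len(rounds)) {
    hp <- optimize_kernel_hyperparams(times, y, family, lambda,
                                      n_starts = n_starts, folds = folds,
                                      scheme = scheme, seed = seed)
    kern <- hp$kernel
    lambda <- select_lambda_cv(times, y, kern, lambda_grid, folds, scheme,
                               seed)
  }
  fit <- fit_ridge(times, y, kern, lambda)
  fit$cv_objective <- hp$objective
  fit
}
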