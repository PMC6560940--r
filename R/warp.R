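#' Sum-of-sigmoids time warp
#'
#' The stage-1 warp is a strictly increasing bijection of the abscissa,
#' \deqn{w(t) = \sum_j \exp(b_j^w)\, S(t - t_j, l^w), \qquad
#'       S(z, l^w) = 1 / (1 + e^{-l^w z}),}
#' a sum of logistic sigmoids centred at the observation times with positive
#' weights \eqn{\exp(b_j^w)}. Strict monotonicity holds for arbitrary
#' parameter values because every summand is increasing; the range is
#' bounded by \eqn{\sum_j \exp(b_j^w)}.
#'
#' @param log_weights numeric vector \eqn{b^w} (log weights).
#' @param steepness positive sigmoid steepness \eqn{l^w}.
#' @param centers numeric vector of sigmoid centres, same length as
#'   `log_weights`.
#' @return an object of class `sigmoid_warp`.
#' @export
sigmoid_warp <- function(log_weights, steepness, centers) {
  assert_finite(log_weights, "log_weights"); assert_finite(centers, "centers")
  if (!is.finite(steepness) || steepness <= 0) {
    stop_warpgm("steepness must be positive")
  }
  if (length(log_weights) != length(centers)) {
    stop_warpgm("log_weights and centers must have equal length")
  }
  structure(list(log_weights = log_weights, steepness = steepness,
                 centers = centers),
            class = "sigmoid_warp")
}

#' MLP-kernel smoothed warp
#'
#' The stage-2 warp \eqn{\hat w(t) = \sum_j b_j^{\hat w} k_{mlp}(t, t_j)} is
#' a kernel ridge regression of the stage-1 warped knots on the original
#' times, giving a smooth monotone reparameterization over the whole
#' window. Monotonicity is not structural here, so it is validated
#' numerically on a dense grid when the object is built by [smooth_warp()].
#'
#' @param coef regression coefficients \eqn{b^{\hat w}}.
#' @param mlp_kernel an mlp [kernel_spec()].
#' @param lambda ridge penalty \eqn{\lambda^{\hat w}} used in the fit.
#' @param train_times knot locations.
#' @return an object of class `smoothed_warp`.
#' @export
smoothed_warp <- function(coef, mlp_kernel, lambda, train_times) {
  structure(list(coef = coef, mlp_kernel = mlp_kernel, lambda = lambda,
                 train_times = train_times),
            class = "smoothed_warp")
}

#' Evaluate a warp and its derivative
#'
#' `warp_eval()` maps original to warped time; `warp_derivative()` returns
#' \eqn{w'(t)}, analytic for both warp classes. For a [sigmoid_warp()] the
#' derivative is positive by construction; for a [smoothed_warp()] a
#' non-positive derivative at a requested point signals a monotonicity
#' violation and raises an error.
#'
#' @param warp a `sigmoid_warp` or `smoothed_warp`.
#' @param t numeric vector of original times.
#' @return numeric vector of warped times / derivative values.
#' @export
warp_eval <- function(warp, t) UseMethod("warp_eval")

#' @export
warp_eval.sigmoid_warp <- function(warp, t) {
  S <- kernel_cross(kernel_spec("sigmoid_basis", steepness = warp$steepness),
                    t, warp$centers, 0L)
  as.numeric(S %*% exp(warp$log_weights))
}

#' @export
warp_eval.smoothed_warp <- function(warp, t) {
  as.numeric(kernel_cross(warp$mlp_kernel, t, warp$train_times, 0L) %*%
               warp$coef)
}

#' @rdname warp_eval
#' @export
warp_derivative <- function(warp, t) UseMethod("warp_derivative")

#' @export
warp_derivative.sigmoid_warp <- function(warp, t) {
  S <- kernel_cross(kernel_spec("sigmoid_basis", steepness = warp$steepness),
                    t, warp$centers, 1L)
  as.numeric(S %*% exp(warp$log_weights))
}

#' @export
warp_derivative.smoothed_warp <- function(warp, t) {
  d <- as.numeric(kernel_cross(warp$mlp_kernel, t, warp$train_times, 1L) %*%
                    warp$coef)
  if (any(d <= 0)) {
    stop_warpgm("smoothed warp is non-monotone at a requested point",
                class = "warpgm_warp_monotonicity")
  }
  d
}

warp_second_derivative <- function(warp, t) UseMethod("warp_second_derivative")

#' @export
warp_second_derivative.sigmoid_warp <- function(warp, t) {
  S <- kernel_cross(kernel_spec("sigmoid_basis", steepness = warp$steepness),
                    t, warp$centers, 2L)
  as.numeric(S %*% exp(warp$log_weights))
}

#' @export
warp_second_derivative.smoothed_warp <- function(warp, t) {
  as.numeric(kernel_cross(warp$mlp_kernel, t, warp$train_times, 2L) %*%
               warp$coef)
}

#' Warp objective configuration
#'
#' Bundles the tunables of the warp loss: the admissible range of the
#' angular frequency \eqn{\lambda^w} (encoding prior knowledge of typical
#' periods), the endpoint penalty weight \eqn{\lambda_t} that anchors
#' \eqn{w(T_0) \approx T_0} and \eqn{w(T_1) \approx T_1} against degenerate
#' range drift, and the window endpoints. Defaults: `lambda_w_bounds`
#' spans one oscillation period per window up to a Nyquist-like limit of
#' `n/2` periods, and `lambda_t` should be large relative to the squared
#' data scale (the fitting front ends use `1e3 * var(y)`).
#'
#' @param T0,T1 window endpoints in original time.
#' @param lambda_w_bounds length-2 positive vector, `lambda_w` range.
#' @param lambda_t positive endpoint penalty weight.
#' @param n number of observations (used only for the default bounds).
#' @return an object of class `warp_config`.
#' @export
warp_config <- function(T0, T1, lambda_w_bounds = NULL, lambda_t = 1e3,
                        n = NULL) {
  if (is.null(lambda_w_bounds)) {
    if (is.null(n)) stop_warpgm("need n to build default lambda_w bounds")
    lambda_w_bounds <- c(2 * pi / (T1 - T0), pi * n / (T1 - T0))
  }
  if (lambda_w_bounds[1] >= lambda_w_bounds[2] ||
      any(lambda_w_bounds <= 0)) {
    stop_warpgm("need 0 < lambda_w_min < lambda_w_max")
  }
  if (!is.finite(lambda_t) || lambda_t <= 0) {
    stop_warpgm("lambda_t must be positive")
  }
  structure(list(T0 = T0, T1 = T1, lambda_w_bounds = lambda_w_bounds,
                 lambda_t = lambda_t),
            class = "warp_config")
}

#' Curvature of the warped-domain interpolant at the knots
#'
#' Given the fixed original-domain interpolant \eqn{g} and a warp \eqn{w},
#' the warped-domain function \eqn{q = g \circ w^{-1}} has derivatives that
#' follow from inverting the chain rule:
#' \deqn{q'(\tilde t_i) = \dot g(t_i) / w'(t_i), \qquad
#'       \ddot q(\tilde t_i) = (\ddot g(t_i) - q'(\tilde t_i) w''(t_i)) /
#'       w'(t_i)^2.}
#' No finite differencing is involved; all derivatives are analytic.
#'
#' @param g an interpolant with [predict_dt()] and [predict_d2t()] methods.
#' @param warp a warp object.
#' @param times knot locations \eqn{t_i}.
#' @return numeric vector \eqn{\ddot q(\tilde t_i)}.
#' @export
q_curvature_at_knots <- function(g, warp, times) {
  wp <- warp_derivative(warp, times)
  if (any(wp < 1e-10)) {
    stop_warpgm("degenerate warp: w'(t) below 1e-10 at a knot",
                class = "warpgm_degenerate_warp")
  }
  wpp <- warp_second_derivative(warp, times)
  gd <- predict_dt(g, times)
  gdd <- predict_d2t(g, times)
  qp <- gd / wp
  (gdd - qp * wpp) / wp^2
}

#' Warp loss function
#'
#' The stage-1 warp is scored by how far the warped-domain signal is from a
#' regular oscillation with angular frequency \eqn{\lambda^w}:
#' \deqn{L_w = \sum_i \big( \ddot q(\tilde t_i) +
#'       [\lambda^w]^2 (q(\tilde t_i) - c) \big)^2 +
#'       \lambda_t \big( (w(T_1) - T_1)^2 + (w(T_0) - T_0)^2 \big),}
#' with \eqn{q(\tilde t_i) = g(t_i)} fixed by the bijection and
#' \eqn{\ddot q} from [q_curvature_at_knots()]. The first term vanishes iff
#' the warped signal is a phase-shifted sinusoid of frequency
#' \eqn{\lambda^w} about the centre `c` (default 0; the fitting front end
#' passes the signal mean, since the benchmark signals oscillate about a
#' positive level). The second term pins the warped window to the original
#' one, ruling out flat or runaway warps.
#'
#' @param g interpolant (see [q_curvature_at_knots()]).
#' @param warp a warp object.
#' @param lambda_w angular frequency \eqn{\lambda^w > 0}.
#' @param cfg a [warp_config()].
#' @param times knot locations.
#' @param center oscillation centre `c` subtracted from `q` in the first
#'   term.
#' @return nonnegative loss value.
#' @export
warp_objective <- function(g, warp, lambda_w, cfg, times, center = 0) {
  qdd <- q_curvature_at_knots(g, warp, times)
  qv <- predict(g, times)
  ends <- warp_eval(warp, c(cfg$T0, cfg$T1))
  sum((qdd + lambda_w^2 * (qv - center))^2) +
    cfg$lambda_t * ((ends[2] - cfg$T1)^2 + (ends[1] - cfg$T0)^2)
}

# Fast internal evaluator used inside the optimization loop: precomputes
# everything that does not depend on the warp parameters.
warp_objective_fast <- function(par, Z, gv, gd, gdd, lam_bounds, lambda_t,
                                T0, T1, center, n) {
  lw <- exp(par[n + 1])
  u <- par[n + 2]
  lambda_w <- lam_bounds[1] +
    (lam_bounds[2] - lam_bounds[1]) * stats::plogis(u)
  ew <- exp(par[seq_len(n)])
  S <- stats::plogis(lw * Z)              # (n+2) x n, rows: knots, T0, T1
  SP <- S * (1 - S)
  w_ends <- as.numeric(S[n + 1:2, , drop = FALSE] %*% ew)
  wp <- as.numeric((lw * SP[seq_len(n), , drop = FALSE]) %*% ew)
  if (any(wp < 1e-10)) return(1e12)
  wpp <- as.numeric((lw^2 * SP[seq_len(n), , drop = FALSE] *
                       (1 - 2 * S[seq_len(n), , drop = FALSE])) %*% ew)
  qp <- gd / wp
  qdd <- (gdd - qp * wpp) / wp^2
  r <- qdd + lambda_w^2 * (gv - center)
  sum(r^2) + lambda_t * ((w_ends[1] - T0)^2 + (w_ends[2] - T1)^2)
}

# Plain gradient descent with backtracking (Armijo) line search and
# central-difference gradients. Deliberately local: the warp loss has
# degenerate global minima (see the vignette), and descent from the
# near-identity initialization converges to the benign one.
gradient_descent <- function(fn, par, maxit = 150, tol = 1e-9, fd_h = 1e-6) {
  f <- fn(par)
  step <- 0.1
  m <- length(par)
  for (it in seq_len(maxit)) {
    g <- vapply(seq_len(m), function(j) {
      e <- numeric(m); e[j] <- fd_h
      (fn(par + e) - fn(par - e)) / (2 * fd_h)
    }, numeric(1))
    gn <- sqrt(sum(g^2))
    if (!is.finite(gn) || gn < 1e-12) break
    d <- -g / gn
    st <- step; ok <- FALSE
    for (k in 1:30) {
      fn_new <- fn(par + st * d)
      if (is.finite(fn_new) && fn_new < f - 1e-4 * st * gn) {
        ok <- TRUE; break
      }
      st <- st / 2
    }
    if (!ok) break
    par <- par + st * d
    improved <- f - fn_new
    f <- fn_new
    step <- min(st * 2, 1)
    if (improved < tol * (1 + abs(f))) break
  }
  list(par = par, value = f, iterations = it)
}

#' Fit the stage-1 time warp
#'
#' Minimizes the warp loss over the sigmoid log-weights \eqn{b^w}, the
#' steepness \eqn{l^w} and the angular frequency \eqn{\lambda^w} (the
#' latter kept inside its bounds through a rescaled sigmoid
#' reparameterization). Optimization is plain gradient descent with a
#' backtracking line search, run from a near-identity initialization
#' (\eqn{b_j^w = \log((T_1 - T_0)/n)}, moderate steepness) plus seeded
#' perturbed restarts; the returned solution never scores worse than the
#' initialization. See the vignette for why a local optimizer is a
#' deliberate part of the estimator.
#'
#' @param g the fixed stage-1 interpolant for this state.
#' @param times observation times (also the sigmoid centres).
#' @param cfg a [warp_config()].
#' @param seed integer seed for the restarts.
#' @param n_starts number of restarts (first one unperturbed).
#' @param maxit gradient-descent iteration cap per restart.
#' @param center oscillation centre passed to the loss (the fitting front
#'   end uses the per-state signal mean).
#' @return a list with `warp` (a [sigmoid_warp()]), `lambda_w`,
#'   `objective`, `initial_objective` and a per-restart `trace`.
#' @export
fit_warp <- function(g, times, cfg, seed = NULL, n_starts = 5, maxit = 150,
                     center = 0) {
  n <- length(times)
  gv <- predict(g, times)
  gd <- predict_dt(g, times)
  gdd <- predict_d2t(g, times)
  Z <- outer(c(times, cfg$T0, cfg$T1), times, "-")
  fn <- function(par) {
    warp_objective_fast(par, Z, gv, gd, gdd, cfg$lambda_w_bounds,
                        cfg$lambda_t, cfg$T0, cfg$T1, center, n)
  }
  l0 <- log(2 / stats::median(diff(sort(times))))
  p0 <- c(rep(log((cfg$T1 - cfg$T0) / n), n), l0, 0)
  f0 <- fn(p0)
  starts <- list(p0)
  if (n_starts > 1) {
    starts <- c(starts, with_seed(seed, lapply(seq_len(n_starts - 1),
      function(i) p0 + stats::rnorm(n + 2) * c(rep(0.1, n), 0.1, 0.5))))
  }
  best <- NULL
  trace <- numeric(0)
  for (s in starts) {
    res <- gradient_descent(fn, s, maxit = maxit)
    trace <- c(trace, res$value)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!is.finite(best$value) || best$value >= 1e12) {
    stop_warpgm("all warp optimizer restarts diverged (best objective ",
                format(best$value), ")", class = "warpgm_warp_failure")
  }
  par <- best$par
  lambda_w <- cfg$lambda_w_bounds[1] +
    diff(cfg$lambda_w_bounds) * stats::plogis(par[n + 2])
  list(warp = sigmoid_warp(par[seq_len(n)], exp(par[n + 1]), times),
       lambda_w = lambda_w, objective = best$value,
       initial_objective = f0, trace = trace)
}

#' Smooth a fitted warp with MLP-kernel ridge regression
#'
#' The stage-1 warp is only constrained at the knots; stage 2 regresses the
#' warped knots \eqn{\tilde t_i} on the original times with an MLP kernel,
#' controlling the smoothness of the bijection over the whole window. The
#' ridge penalty \eqn{\lambda^{\hat w}} is chosen by exact leave-one-out
#' cross validation (closed form); the MLP hyperparameters are scanned over
#' a small grid. Candidates whose derivative is not strictly positive on a
#' dense grid are rejected; if every candidate is non-monotone an error
#' suggests enlarging the penalty grid.
#'
#' @param times original observation times (strictly increasing).
#' @param warped_times stage-1 warped knots (strictly increasing).
#' @param mlp_grid list with numeric vectors `weight_var` and `bias_var`
#'   scanned for the MLP kernel.
#' @param lambda_grid penalty grid for \eqn{\lambda^{\hat w}}.
#' @param grid_n size of the dense monotonicity-check grid.
#' @return a [smoothed_warp()] with attributes recording the selection.
#' @export
smooth_warp <- function(times, warped_times,
                        mlp_grid = list(weight_var = c(0.1, 1, 10),
                                        bias_var = c(0.1, 1, 10)),
                        lambda_grid = log_spaced(1e-9, 1e-1, 9),
                        grid_n = 1000) {
  if (any(diff(warped_times) <= 0)) {
    stop_warpgm("warped_times must be strictly increasing")
  }
  n <- length(times)
  cand <- expand.grid(weight_var = mlp_grid$weight_var,
                      bias_var = mlp_grid$bias_var,
                      lambda = lambda_grid)
  loo <- vapply(seq_len(nrow(cand)), function(i) {
    k <- kernel_spec("mlp", weight_var = cand$weight_var[i],
                     bias_var = cand$bias_var[i])
    tryCatch(loo_error(times, warped_times, k, cand$lambda[i]),
             error = function(e) Inf)
  }, numeric(1))
  dense <- seq(min(times), max(times), length.out = grid_n)
  for (i in order(loo)) {
    if (!is.finite(loo[i])) break
    k <- kernel_spec("mlp", weight_var = cand$weight_var[i],
                     bias_var = cand$bias_var[i])
    fit <- fit_ridge(times, warped_times, k, cand$lambda[i])
    w <- smoothed_warp(fit$coef, k, cand$lambda[i], times)
    dp <- as.numeric(kernel_cross(k, dense, times, 1L) %*% fit$coef)
    if (all(dp > 0)) {
      attr(w, "loo_error") <- loo[i]
      attr(w, "selection") <- cand[i, ]
      return(w)
    }
  }
  stop_warpgm("no monotone smoothed warp found on the candidate grid; ",
              "enlarge lambda_grid toward stronger smoothing",
              class = "warpgm_warp_monotonicity")
}
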