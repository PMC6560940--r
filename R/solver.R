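#' Solve an ODE model with an adaptive RK2(3) method
#'
#' Integrates \eqn{\dot x = f(x, \theta)} with the Bogacki--Shampine
#' embedded Runge--Kutta 2(3) pair (the classic low-order method with
#' automatic step-size adjustment). Dense output at user-requested times is
#' obtained by cubic Hermite interpolation on the accepted steps, which
#' matches the order of the integrator.
#'
#' @param model an [ode_model()].
#' @param theta named (or positional) parameter vector.
#' @param x0 initial state vector, length `model$dim`.
#' @param span length-2 numeric, integration window `c(t0, t1)`.
#' @param t_eval optional vector of output times inside `span`; if `NULL`
#'   the solver-chosen accepted steps are returned.
#' @param rtol,atol relative and absolute local error tolerances.
#' @param max_steps step budget before an integration-failure error.
#' @return an object of class `ode_trajectory`: list with `times`, `states`
#'   (matrix, one column per state), `steps` (number of accepted steps).
#' @examples
#' m <- lotka_volterra_model()
#' tr <- solve_ode(m, c(alpha = 1, beta = 1, gamma = 4, delta = 1),
#'                 c(0.5, 1), c(0, 5))
#' @export
solve_ode <- function(model, theta, x0, span, t_eval = NULL,
                      rtol = 1e-6, atol = 1e-8, max_steps = 100000L) {
  stopifnot(inherits(model, "ode_model"))
  x0 <- as.numeric(x0)
  if (length(x0) != model$dim) stop_warpgm("x0 has wrong length")
  t0 <- span[1]; t1 <- span[2]
  if (!is.finite(t0) || !is.finite(t1) || t1 <= t0) {
    stop_warpgm("span must be finite with span[2] > span[1]")
  }
  f <- function(t, x) {
    v <- model$rhs(x, t, theta)
    if (length(v) != model$dim) stop_warpgm("rhs returned wrong dimension")
    as.numeric(v)
  }
  k1 <- f(t0, x0)
  if (any(!is.finite(k1))) {
    stop_warpgm("rhs not finite at the initial condition",
                class = "warpgm_integration_failure")
  }

  ts <- numeric(512); n_acc <- 1L
  ys <- matrix(0, 512, model$dim); fs <- matrix(0, 512, model$dim)
  ts[1] <- t0; ys[1, ] <- x0; fs[1, ] <- k1

  t <- t0; y <- x0
  h <- (t1 - t0) / 100
  steps <- 0L
  while (t < t1) {
    steps <- steps + 1L
    if (steps > max_steps) {
      stop_warpgm("step budget exceeded at t = ", format(t),
                  class = "warpgm_integration_failure")
    }
    h <- min(h, t1 - t)
    if (h < .Machine$double.eps * max(1, abs(t)) * 4) {
      stop_warpgm("step size underflow at t = ", format(t),
                  "; last good state recorded",
                  class = "warpgm_integration_failure")
    }
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + 3 * h / 4, y + 3 * h / 4 * k2)
    ynew <- y + h * (2 * k1 + 3 * k2 + 4 * k3) / 9
    k4 <- f(t + h, ynew)
    bad <- any(!is.finite(c(k2, k3, k4, ynew)))
    if (!bad) {
      errv <- h * (-5 * k1 / 72 + k2 / 12 + k3 / 9 - k4 / 8)
      sc <- atol + rtol * pmax(abs(y), abs(ynew))
      errnorm <- sqrt(mean((errv / sc)^2))
    } else errnorm <- Inf
    if (errnorm <= 1) {
      t <- t + h; y <- ynew; k1 <- k4       # FSAL
      n_acc <- n_acc + 1L
      if (n_acc > nrow(ys)) {
        ys <- rbind(ys, matrix(0, nrow(ys), model$dim))
        fs <- rbind(fs, matrix(0, nrow(fs), model$dim))
        ts <- c(ts, numeric(length(ts)))
      }
      ts[n_acc] <- t; ys[n_acc, ] <- y; fs[n_acc, ] <- k1
      fac <- if (errnorm == 0) 5 else min(5, max(0.2, 0.9 * errnorm^(-1 / 3)))
      h <- h * fac
    } else {
      h <- h * max(0.2, 0.9 * errnorm^(-1 / 3))
    }
  }
  ts <- ts[seq_len(n_acc)]
  ys <- ys[seq_len(n_acc), , drop = FALSE]
  fs <- fs[seq_len(n_acc), , drop = FALSE]

  if (!is.null(t_eval)) {
    if (any(t_eval < t0 - 1e-12) || any(t_eval > t1 + 1e-12)) {
      stop_warpgm("t_eval outside span")
    }
    out <- hermite_eval(ts, ys, fs, pmin(pmax(t_eval, t0), t1))
    times <- as.numeric(t_eval); states <- out
  } else {
    times <- ts; states <- ys
  }
  colnames(states) <- model$state_names
  structure(list(times = times, states = states, steps = n_acc - 1L,
                 model_name = model$name),
            class = "ode_trajectory")
}

# Cubic Hermite interpolation on solver steps (times, states, derivatives).
hermite_eval <- function(ts, ys, fs, tq) {
  idx <- findInterval(tq, ts, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(ts) - 1L)
  h <- ts[idx + 1L] - ts[idx]
  s <- (tq - ts[idx]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  out <- matrix(0, length(tq), ncol(ys))
  for (j in seq_len(ncol(ys))) {
    out[, j] <- h00 * ys[idx, j] + h10 * h * fs[idx, j] +
      h01 * ys[idx + 1L, j] + h11 * h * fs[idx + 1L, j]
  }
  out
}

#' @export
print.ode_trajectory <- function(x, ...) {
  cat("<ode_trajectory>", x$model_name, "-", length(x$times), "points in [",
      format(min(x$times)), ",", format(max(x$times)), "]\n")
  invisible(x)
}
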