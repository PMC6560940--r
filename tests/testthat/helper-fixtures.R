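# Shared fixtures and oracles for the test suite. Fixtures are built in
# code; nothing is read from disk.

# Central finite differences used as independent derivative oracles.
fd1 <- function(f, t, h = 1e-5) (f(t + h) - f(t - h)) / (2 * h)
fd2 <- function(f, t, h = 1e-4) (f(t + h) - 2 * f(t) + f(t - h)) / h^2

# An "interpolant" whose value and derivatives are closed-form functions.
# predict/predict_dt/predict_d2t dispatch lets warp machinery consume it.
analytic_fun <- function(f, df, d2f) {
  structure(list(f = f, df = df, d2f = d2f), class = "analytic_fun")
}
predict.analytic_fun <- function(object, t, ...) object$f(t)
predict_dt.analytic_fun <- function(object, t) object$df(t)
predict_d2t.analytic_fun <- function(object, t) object$d2f(t)
registerS3method("predict", "analytic_fun", predict.analytic_fun,
                 envir = asNamespace("stats"))
registerS3method("predict_dt", "analytic_fun", predict_dt.analytic_fun,
                 envir = asNamespace("warpgm"))
registerS3method("predict_d2t", "analytic_fun", predict_d2t.analytic_fun,
                 envir = asNamespace("warpgm"))

# Sinusoid composed with a warp: g(t) = A sin(lw * w(t)) + c. Its chain-rule
# derivatives make the warp-objective residual exactly zero at frequency lw.
warped_sinusoid <- function(warp, lw, A = 1, offset = 0) {
  analytic_fun(
    f = function(t) A * sin(lw * warp_eval(warp, t)) + offset,
    df = function(t) {
      A * lw * cos(lw * warp_eval(warp, t)) * warp_derivative(warp, t)
    },
    d2f = function(t) {
      w <- warp_eval(warp, t)
      wp <- warp_derivative(warp, t)
      wpp <- warpgm:::warp_second_derivative(warp, t)
      -A * lw^2 * sin(lw * w) * wp^2 + A * lw * cos(lw * w) * wpp
    })
}

# Two-regime chirp: angular frequency om1 on the first half of the window,
# om2 on the second, with continuous phase.
chirp_fun <- function(om1, om2, t_mid) {
  phase <- function(t) {
    ifelse(t <= t_mid, om1 * t, om1 * t_mid + om2 * (t - t_mid))
  }
  function(t) sin(phase(t))
}

# Small deterministic LV fixture shared by the slower pipeline tests.
lv_fixture <- function(snr_db = 40, seed = 11, n_obs = 28) {
  tr <- default_truth("lotka_volterra")
  generate_dataset("lotka_volterra", tr$theta, tr$x0, tr$span, snr_db,
                   seed = seed, n_obs = n_obs)
}

# Independent reimplementation of the arcsine MLP kernel (scalar, written
# from the formula, no shared code with the package internals).
mlp_kernel_oracle <- function(t, tp, sw, sb) {
  num <- 2 * (sw * t * tp + sb)
  den <- sqrt((1 + 2 * (sw * t^2 + sb)) * (1 + 2 * (sw * tp^2 + sb)))
  2 / pi * asin(num / den)
}

expect_close <- function(object, expected, tol = 1e-8) {
  expect_lt(max(abs(object - expected)), tol)
}
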