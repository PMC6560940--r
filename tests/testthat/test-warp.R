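# affine test warp w(t) = a + c t, used as the identity-like reference
affine_warp <- function(a = 0, c = 1) {
  structure(list(a = a, c = c), class = c("affine_warp"))
}
warp_eval.affine_warp <- function(warp, t) warp$a + warp$c * t
warp_derivative.affine_warp <- function(warp, t) rep(warp$c, length(t))
warp_second_derivative.affine_warp <- function(warp, t) rep(0, length(t))
registerS3method("warp_eval", "affine_warp", warp_eval.affine_warp,
                 envir = asNamespace("warpgm"))
registerS3method("warp_derivative", "affine_warp",
                 warp_derivative.affine_warp, envir = asNamespace("warpgm"))
registerS3method("warp_second_derivative", "affine_warp",
                 warp_second_derivative.affine_warp,
                 envir = asNamespace("warpgm"))

test_that("sigmoid warp evaluation matches its definition", {
  # single steep sigmoid at 0 with unit weight approaches a unit step
  w <- sigmoid_warp(0, steepness = 500, centers = 0)
  expect_equal(warp_eval(w, 1), 1, tolerance = 1e-10)
  expect_equal(warp_eval(w, -1), 0, tolerance = 1e-10)
  # at its own centre each basis contributes exp(b_j)/2
  w2 <- sigmoid_warp(c(log(2), -1), steepness = 3, centers = c(1, 7))
  far <- exp(-1) * plogis(3 * (1 - 7))     # basis 2's residual at t = 1
  expect_equal(warp_eval(w2, 1), 2 / 2 + far, tolerance = 1e-12)
  # range bound: 0 < w < sum(exp(b))
  tt <- seq(-50, 50, length.out = 101)
  v <- warp_eval(w2, tt)
  expect_true(all(v > 0 & v <= exp(log(2)) + exp(-1) + 1e-12))
})

test_that("sigmoid warps are strictly increasing for arbitrary parameters", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(2:15, 1)
    w <- sigmoid_warp(rnorm(n, sd = 2), steepness = exp(rnorm(1)),
                      centers = sort(runif(n, 0, 10)))
    t1 <- sort(runif(2, -5, 15))
    expect_lt(warp_eval(w, t1[1]), warp_eval(w, t1[2]))
    expect_gt(warp_derivative(w, runif(1, -5, 15)), 0)
  }
})

test_that("warp derivatives match finite differences and limits", {
  w <- sigmoid_warp(c(0.3, -0.5, 1), steepness = 2, centers = c(0, 1, 3))
  set.seed(4)
  for (tq in runif(6, -1, 4)) {
    expect_equal(warp_derivative(w, tq),
                 fd1(function(x) warp_eval(w, x), tq), tolerance = 1e-6)
    expect_equal(warpgm:::warp_second_derivative(w, tq),
                 fd2(function(x) warp_eval(w, x), tq), tolerance = 1e-4)
  }
  # steepness -> 0: the warp flattens, derivative vanishes everywhere
  w0 <- sigmoid_warp(c(0.3, -0.5, 1), steepness = 1e-9,
                     centers = c(0, 1, 3))
  expect_lt(max(warp_derivative(w0, seq(-1, 4, 0.5))), 1e-8)
})

test_that("q curvature inverts the chain rule", {
  g_sin <- analytic_fun(sin, cos, function(t) -sin(t))
  times <- seq(0.2, 5.8, length.out = 12)
  # constant-derivative warp: qdd = gdd / c^2
  aw <- affine_warp(a = 0.4, c = 1.7)
  expect_close(q_curvature_at_knots(g_sin, aw, times),
               -sin(times) / 1.7^2, tol = 1e-12)
  # constant g has zero curvature under any warp
  g_const <- analytic_fun(function(t) rep(2, length(t)),
                          function(t) rep(0, length(t)),
                          function(t) rep(0, length(t)))
  w <- sigmoid_warp(rep(log(0.5), 8), steepness = 2,
                    centers = seq(0, 6, length.out = 8))
  expect_equal(q_curvature_at_knots(g_const, w, times), rep(0, 12))
  # dense-grid oracle: q rebuilt by numerically inverting the warp
  qdd <- q_curvature_at_knots(g_sin, w, times)
  tg <- seq(-2, 8, length.out = 20001)
  wg <- warp_eval(w, tg)
  qfun <- function(tt) sin(approx(wg, tg, xout = tt)$y)  # q = g o w^{-1}
  wt <- warp_eval(w, times)
  oracle <- vapply(wt, function(tt) fd2(qfun, tt, h = 1e-3), numeric(1))
  expect_close(qdd, oracle, tol = 1e-2 * max(abs(qdd)))
  # degenerate flat warp is rejected
  w0 <- sigmoid_warp(rep(0, 3), steepness = 1e-12, centers = c(0, 3, 6))
  expect_error(q_curvature_at_knots(g_sin, w0, times),
               class = "warpgm_degenerate_warp")
})

test_that("warp objective vanishes on a matched sinusoid and splits into
           curvature and endpoint terms", {
  lw <- 1.3
  times <- seq(0, 6, length.out = 15)
  w <- sigmoid_warp(rep(log(6 / 15), 15), steepness = 4, centers = times)
  cfg <- warp_config(0, 6, lambda_w_bounds = c(0.5, 5), lambda_t = 1e4)
  g <- warped_sinusoid(w, lw)          # g = sin(lw * w(t)) by construction
  ends <- warp_eval(w, c(0, 6))
  expected_pen <- 1e4 * ((ends[2] - 6)^2 + (ends[1] - 0)^2)
  obj <- warp_objective(g, w, lw, cfg, times)
  expect_equal(obj, expected_pen, tolerance = 1e-10)  # first term == 0
  # identity warp with matching frequency: total objective exactly zero
  aw <- affine_warp(0, 1)
  g2 <- analytic_fun(function(t) sin(lw * t),
                     function(t) lw * cos(lw * t),
                     function(t) -lw^2 * sin(lw * t))
  expect_lt(warp_objective(g2, aw, lw, cfg, times), 1e-20)
  # mismatched frequency scores strictly worse
  expect_gt(warp_objective(g2, aw, 2 * lw, cfg, times), 1)
})

test_that("knot sum approximates the integral form of the warp loss", {
  # identity warp, uniform knots: sum * dt ~ integral of the residual
  lw <- 2; om <- 1.4
  n <- 200
  times <- seq(0, 10, length.out = n)
  g <- analytic_fun(function(t) sin(om * t),
                    function(t) om * cos(om * t),
                    function(t) -om^2 * sin(om * t))
  aw <- affine_warp(0, 1)
  cfg <- warp_config(0, 10, lambda_w_bounds = c(0.5, 5), lambda_t = 1e-30)
  knot_sum <- warp_objective(g, aw, lw, cfg, times) * (10 / (n - 1))
  quad <- integrate(function(t) (-om^2 * sin(om * t) +
                                   lw^2 * sin(om * t))^2, 0, 10,
                    subdivisions = 1000)$value
  expect_lt(abs(knot_sum - quad) / quad, 0.05)
})

test_that("fit_warp descends and stays near-affine on a regular sinusoid", {
  om <- 2
  times <- seq(0, 3 * pi, length.out = 24)
  g <- analytic_fun(function(t) sin(om * t),
                    function(t) om * cos(om * t),
                    function(t) -om^2 * sin(om * t))
  cfg <- warp_config(0, 3 * pi, lambda_t = 1e3, n = 24)
  wf <- fit_warp(g, times, cfg, seed = 1, n_starts = 3)
  expect_lte(wf$objective, wf$initial_objective)
  # near-affine away from the anchored endpoints: the sigmoid basis cannot
  # represent an exactly affine map at the boundary knots, so those two are
  # excluded from the coefficient-of-variation check
  wp <- warp_derivative(wf$warp, times[2:23])
  expect_lt(sd(wp) / mean(wp), 0.1)
})

test_that("fit_warp equalizes the periods of a two-regime chirp", {
  om1 <- 1.5; om2 <- 3; t_mid <- 6
  phase <- function(t) ifelse(t <= t_mid, om1 * t,
                              om1 * t_mid + om2 * (t - t_mid))
  omt <- function(t) ifelse(t <= t_mid, om1, om2)
  g <- analytic_fun(function(t) sin(phase(t)),
                    function(t) omt(t) * cos(phase(t)),
                    function(t) -omt(t)^2 * sin(phase(t)))
  times <- seq(0, 12, length.out = 30)
  cfg <- warp_config(0, 12, lambda_t = 1e3, n = 30)
  wf <- fit_warp(g, times, cfg, seed = 2, n_starts = 5)
  wp <- warp_derivative(wf$warp, times)
  ratio <- mean(wp[times > t_mid + 0.5]) / mean(wp[times < t_mid - 0.5])
  expect_gt(ratio, (om2 / om1) * 0.7)
  expect_lt(ratio, (om2 / om1) * 1.3)
})

test_that("smooth_warp reproduces, selects by exact LOO, stays monotone", {
  times <- seq(0, 5, length.out = 20)
  # identity warp comes back within 1e-3
  sw <- smooth_warp(times, times)
  expect_lt(max(abs(warp_eval(sw, times) - times)), 1e-3)
  # exact-LOO selection equals the exhaustive n-refit oracle
  set.seed(6)
  wt <- sort(times + rnorm(20, sd = 0.08)); wt <- cumsum(c(wt[1],
    pmax(diff(wt), 0.01)))
  grid <- list(weight_var = 1, bias_var = 1)
  lams <- log_spaced(1e-6, 1e-1, 6)
  sw2 <- smooth_warp(times, wt, mlp_grid = grid, lambda_grid = lams)
  k <- sw2$mlp_kernel
  exhaustive <- vapply(lams, function(l) {
    mean(vapply(seq_along(times), function(i) {
      f <- fit_ridge(times[-i], wt[-i], k, l)
      (predict(f, times[i]) - wt[i])^2
    }, numeric(1)))
  }, numeric(1))
  expect_equal(sw2$lambda, lams[which.min(exhaustive)])
  # chirp-style uneven warp: strictly increasing on a dense grid
  wt3 <- c(seq(0, 1, length.out = 10), seq(1.3, 5, length.out = 10))
  sw3 <- smooth_warp(times, wt3)
  dense <- seq(0, 5, length.out = 1000)
  v <- warp_eval(sw3, dense)
  expect_true(all(diff(v) > 0))
  expect_true(all(warp_derivative(sw3, dense) > 0))
  # non-monotone input is rejected
  expect_error(smooth_warp(times, rev(wt)), "strictly increasing")
})

test_that("a full warp pass does not hurt a homogeneous sinusoid", {
  # mean interpolation RMSE over seeded noise draws: the warp layer may
  # not degrade a constant-frequency signal by more than 10%
  om <- 2.5
  times <- seq(0, 3 * 2 * pi / om, length.out = 26)
  dense <- seq(min(times), max(times), length.out = 400)
  rmse_g <- rmse_q <- numeric(0)
  for (seed in 1:6) {
    set.seed(seed)
    y <- sin(om * times) + rnorm(26, sd = 0.05)
    g <- warpgm:::select_interpolant(times, y, "rbf", seed = 1)
    rmse_g <- c(rmse_g, sqrt(mean((predict(g, dense) -
                                     sin(om * dense))^2)))
    cfg <- warp_config(min(times), max(times), lambda_t = 1e3 * var(y),
                       n = 26)
    wf <- fit_warp(g, times, cfg, seed = 3, center = mean(y))
    sw <- smooth_warp(times, warp_eval(wf$warp, times))
    q <- warpgm:::select_interpolant(warp_eval(sw, times), y, "rbf",
                                     seed = 1)
    rmse_q <- c(rmse_q, sqrt(mean((predict(q, warp_eval(sw, dense)) -
                                     sin(om * dense))^2)))
  }
  expect_lt(mean(rmse_q), mean(rmse_g) * 1.1)
})
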