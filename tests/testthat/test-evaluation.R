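test_that("parameter errors are plain absolute differences with ratio
           substitution for weakly identifiable pairs", {
  th <- c(a = 1.1, b = 2.2); tt <- c(a = 1, b = 2)
  expect_equal(parameter_errors(th, tt), c(a = 0.1, b = 0.2),
               tolerance = 1e-12)
  expect_equal(parameter_errors(tt, tt), c(a = 0, b = 0))
  # ratio pair: k5/k6 identical ratios give zero error
  h <- c(k5 = 0.1, k6 = 0.2, k1 = 1)
  t2 <- c(k5 = 0.2, k6 = 0.4, k1 = 1.5)
  pe <- parameter_errors(h, t2, ratio_pairs = list(c("k5", "k6")))
  expect_equal(pe[["k5/k6"]], 0)
  expect_equal(pe[["k1"]], 0.5)
  expect_false(any(c("k5", "k6") %in% names(pe)))
  # random vectors match direct arithmetic
  set.seed(77)
  for (i in 1:10) {
    a <- runif(4, 0.1, 3); b <- runif(4, 0.1, 3)
    names(a) <- names(b) <- paste0("p", 1:4)
    expect_equal(parameter_errors(a, b), abs(a - b))
  }
  expect_error(parameter_errors(c(k5 = 1, k6 = 0), c(k5 = 1, k6 = 1),
                                ratio_pairs = list(c("k5", "k6"))),
               "denominator")
  expect_error(parameter_errors(c(x = 1), c(y = 1)), "align")
})

test_that("function-space error matches the closed form for decay", {
  decay <- ode_model("decay_fs", "x", "theta",
                     function(x, t, th) -th[1] * x)
  register_ode_model(decay)
  grid <- c(0.3, 0.9, 1.7)   # x0 applies at the grid start, t = 0.3
  fe <- function_space_error(decay, 1.4, 1.0, 1, grid = grid,
                             rtol = 1e-12, atol = 1e-14)
  closed <- sqrt(mean((exp(-1.4 * (grid - 0.3)) -
                         exp(-1.0 * (grid - 0.3)))^2))
  expect_equal(fe, closed, tolerance = 1e-10)
  # identical parameters give zero
  expect_equal(function_space_error(decay, 1, 1, 1, grid = grid), 0)
  # permutation invariance of the grid
  expect_equal(function_space_error(decay, 1.4, 1, 1, grid = rev(grid),
                                    rtol = 1e-12, atol = 1e-14), fe,
               tolerance = 1e-12)
  # divergent estimate counts as maximal error with a flag
  blow <- ode_model("blow_fs", "x", "theta",
                    function(x, t, th) th[1] * x^2)
  register_ode_model(blow)
  fe2 <- function_space_error(blow, 10, 0.1, 1,
                              grid = seq(0, 5, length.out = 10))
  expect_identical(unclass(fe2)[1], Inf)
  expect_true(attr(fe2, "solve_failed"))
})

test_that("paired Wilcoxon matches exact combinatorics", {
  # constant shift, n = 6, no ties: two-sided p = 2/2^6
  a <- c(1.2, 3.4, 2.2, 5.1, 0.7, 2.9)
  res <- paired_wilcoxon(a + 0.5, a)
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, 2 / 64)
  # single differing pair: statistic is that one rank
  b <- a; b[3] <- b[3] + 1
  res1 <- paired_wilcoxon(b, a)
  expect_equal(res1$statistic, 1)
  expect_equal(res1$n_used, 1)
  expect_equal(res1$p_value, 1)
  expect_equal(res1$method, "exact_enumeration")
  expect_error(paired_wilcoxon(a, a), class = "warpgm_degenerate_test")
  expect_error(paired_wilcoxon(a, a[1:3]), "equal length")
})

test_that("exact p-values agree across the two exact routes", {
  enumerate_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.numeric(signs %*% r)
    p_le <- mean(Vs <= V); p_ge <- mean(Vs >= V)
    min(1, 2 * min(p_le, p_ge))
  }
  # n = 8: the implementation enumerates; the signed-rank distribution
  # function is the independent closed-form oracle
  set.seed(123)
  for (i in 1:6) {
    d <- round(rnorm(8), 3)
    while (any(d == 0) || any(duplicated(abs(d)))) d <- round(rnorm(8), 3)
    res <- paired_wilcoxon(d + 5, rep(5, 8))   # differences are exactly d
    V <- res$statistic
    p_or <- min(1, 2 * min(psignrank(V, 8),
                           psignrank(V - 1, 8, lower.tail = FALSE)))
    expect_equal(res$p_value, p_or, tolerance = 1e-12)
    expect_equal(res$p_value, enumerate_p(d), tolerance = 1e-12)
    expect_equal(res$method, "exact_enumeration")
  }
  # n = 16: the implementation uses the signed-rank distribution; full
  # enumeration is the oracle
  for (i in 1:3) {
    d <- round(rnorm(16), 3)
    while (any(d == 0) || any(duplicated(abs(d)))) d <- round(rnorm(16), 3)
    res <- paired_wilcoxon(d + 5, rep(5, 16))
    expect_equal(res$p_value, enumerate_p(d), tolerance = 1e-12)
    expect_equal(res$method, "exact")
  }
})

test_that("compare_methods preserves pairing and flags improvements", {
  tr <- default_truth("lotka_volterra")
  suite <- generate_replicate_suite("lotka_volterra", tr$theta, tr$x0,
                                    tr$span, snr_list = 40, n_reps = 12,
                                    base_seed = 8, n_obs = 12)
  # stub methods: deterministic estimates with replicate-dependent jitter
  stub <- function(offset) {
    function(dataset, model, cfg) {
      jit <- 1e-3 * (dataset$seed %% 7)
      structure(list(theta_hat = dataset$truth$theta + offset + jit,
                     method = "stub"), class = "ode_fit")
    }
  }
  rep_worse <- compare_methods(suite,
                               list(base = stub(0.3), cand = stub(0.1)),
                               cfg = fit_config(), fs_grid_n = 40)
  comp <- rep_worse$comparisons
  param_rows <- comp[comp$parameter %in% names(tr$theta), ]
  expect_true(all(param_rows$median_improvement > 0.15))
  expect_true(all(param_rows$significant))
  expect_true(all(rep_worse$errors$error[rep_worse$errors$method ==
                                           "base" &
                    rep_worse$errors$parameter == "alpha"] > 0.29))
  # self comparison: zero differences everywhere, nothing significant
  rep_self <- compare_methods(suite[1:4],
                              list(m1 = stub(0.2), m2 = stub(0.2)),
                              cfg = fit_config(), fs_grid_n = 40)
  expect_true(all(rep_self$comparisons$median_improvement == 0))
  expect_false(any(rep_self$comparisons$significant %in% TRUE))
  # pairing: identical reordering of the suite leaves comparisons intact
  perm <- c(3, 1, 2, 4)
  rep_perm <- compare_methods(suite[1:4][perm],
                              list(base = stub(0.3), cand = stub(0.1)),
                              cfg = fit_config(), fs_grid_n = 40)
  rep_orig <- compare_methods(suite[1:4],
                              list(base = stub(0.3), cand = stub(0.1)),
                              cfg = fit_config(), fs_grid_n = 40)
  expect_equal(rep_perm$comparisons$median_improvement,
               rep_orig$comparisons$median_improvement)
  expect_equal(rep_perm$comparisons$p_value, rep_orig$comparisons$p_value)
  # too few replicates: flagged, not crashed
  rep_small <- compare_methods(suite[1:2],
                               list(m1 = stub(0.2), m2 = stub(0.1)),
                               cfg = fit_config(), fs_grid_n = 40)
  expect_true(all(rep_small$comparisons$insufficient_data))
})

test_that("reports serialize to CSV and JSON", {
  tr <- default_truth("lotka_volterra")
  suite <- generate_replicate_suite("lotka_volterra", tr$theta, tr$x0,
                                    tr$span, snr_list = 40, n_reps = 3,
                                    base_seed = 9, n_obs = 10)
  stub <- function(dataset, model, cfg) {
    structure(list(theta_hat = dataset$truth$theta + 0.05),
              class = "ode_fit")
  }
  rep <- compare_methods(suite, list(a = stub, b = stub),
                         cfg = fit_config(), fs_grid_n = 30)
  cp <- file.path(tempdir(), "rep.csv"); jp <- file.path(tempdir(),
                                                         "rep.json")
  write_report(rep, cp, jp)
  expect_true(all(c("model", "snr_db", "replicate", "method", "parameter",
                    "error") %in% names(read.csv(cp))))
  j <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(j$metadata$baseline, "a")
  file.remove(cp, jp)
})
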