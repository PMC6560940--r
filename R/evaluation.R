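#' Per-parameter absolute estimation errors
#'
#' Returns \eqn{|\hat\theta_j - \theta^*_j|} per parameter. For parameter
#' pairs that are only weakly identifiable individually (the
#' Michaelis--Menten pair \eqn{k_5, k_6} of the biopathway model), accuracy
#' is assessed on their ratio instead: each declared pair `(num, den)`
#' replaces its two entries with a single
#' \eqn{|\hat\theta_{num}/\hat\theta_{den} -
#' \theta^*_{num}/\theta^*_{den}|} entry named `"num/den"`.
#'
#' @param theta_hat,theta_true named parameter vectors with equal names.
#' @param ratio_pairs list of character pairs `c(numerator, denominator)`.
#' @return named nonnegative vector of errors.
#' @examples
#' parameter_errors(c(a = 1.1, b = 2), c(a = 1, b = 2))
#' @export
parameter_errors <- function(theta_hat, theta_true, ratio_pairs = NULL) {
  if (is.null(names(theta_hat))) names(theta_hat) <- names(theta_true)
  if (!setequal(names(theta_hat), names(theta_true))) {
    stop_warpgm("parameter names do not align")
  }
  theta_hat <- theta_hat[names(theta_true)]
  err <- abs(theta_hat - theta_true)
  for (pr in ratio_pairs) {
    if (theta_hat[pr[2]] == 0 || theta_true[pr[2]] == 0) {
      stop_warpgm("zero denominator in ratio pair ", pr[2])
    }
    rerr <- abs(theta_hat[pr[1]] / theta_hat[pr[2]] -
                  theta_true[pr[1]] / theta_true[pr[2]])
    err <- err[!names(err) %in% pr]
    err[paste(pr[1], pr[2], sep = "/")] <- rerr
  }
  err
}

#' Function-space error of an estimate
#'
#' Reinserts the estimated parameters into the differential equations,
#' solves numerically, and returns the RMS difference to the solution at
#' the true parameters over the grid (pooled across states). If the solve
#' at the estimate fails or diverges, `Inf` is returned with attribute
#' `solve_failed = TRUE` -- divergent dynamics count as maximal error.
#'
#' @param model an [ode_model()] or name.
#' @param theta_hat,theta_true parameter vectors.
#' @param x0 initial state.
#' @param grid evaluation abscissa grid (default 200 equidistant points
#'   need `span`).
#' @param span window used when `grid` is `NULL`.
#' @param rtol,atol solver tolerances for both solves.
#' @return nonnegative RMS error.
#' @export
function_space_error <- function(model, theta_hat, theta_true, x0,
                                 grid = NULL, span = NULL,
                                 rtol = 1e-8, atol = 1e-10) {
  if (is.character(model)) model <- get_ode_model(model)
  if (is.null(grid)) {
    if (is.null(span)) stop_warpgm("need grid or span")
    grid <- seq(span[1], span[2], length.out = 200)
  }
  sp <- range(grid)
  ref <- solve_ode(model, theta_true, x0, sp, t_eval = grid,
                   rtol = rtol, atol = atol)
  est <- tryCatch(solve_ode(model, theta_hat, x0, sp, t_eval = grid,
                            rtol = rtol, atol = atol),
                  error = function(e) NULL)
  if (is.null(est) || any(!is.finite(est$states))) {
    out <- Inf
    attr(out, "solve_failed") <- TRUE
    return(out)
  }
  sqrt(mean((est$states - ref$states)^2))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the paired differences `errors_A -
#' errors_B`. Zero differences are dropped (the standard convention). With
#' at most 14 nonzero pairs the p-value is computed by exhaustive
#' enumeration of all sign assignments (exact, and valid under tied
#' absolute differences); with 15--25 untied pairs the exact signed-rank
#' distribution is used; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param errors_A,errors_B equal-length numeric vectors, paired by
#'   replicate.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `statistic` (positive-rank sum V), `p_value`,
#'   `n_used`, `method`.
#' @export
paired_wilcoxon <- function(errors_A, errors_B,
                            alternative = c("two.sided", "greater",
                                            "less")) {
  alternative <- match.arg(alternative)
  if (length(errors_A) != length(errors_B)) {
    stop_warpgm("paired vectors must have equal length")
  }
  d <- errors_A - errors_B
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop_warpgm("all paired differences are zero; test degenerate",
                class = "warpgm_degenerate_test")
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 14) {
    # exact by full enumeration of sign assignments; valid under ties
    # because the (average) ranks are held fixed
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.numeric(signs %*% r)
    p_le <- mean(Vs <= V); p_ge <- mean(Vs >= V)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      greater = p_ge,
      less = p_le)
    method <- "exact_enumeration"
  } else if (n <= 25 && !ties) {
    p <- switch(alternative,
      two.sided = min(1, 2 * min(stats::psignrank(V, n),
                                 stats::psignrank(V - 1, n,
                                                  lower.tail = FALSE))),
      greater = stats::psignrank(V - 1, n, lower.tail = FALSE),
      less = stats::psignrank(V, n))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    z <- V - mu
    cc <- 0.5
    p <- switch(alternative,
      two.sided = {
        zc <- (z - sign(z) * cc) / sqrt(sig2)
        min(1, 2 * stats::pnorm(-abs(zc)))
      },
      greater = stats::pnorm((z - cc) / sqrt(sig2), lower.tail = FALSE),
      less = stats::pnorm((z + cc) / sqrt(sig2)))
    method <- "normal_approx"
  }
  list(statistic = V, p_value = p, n_used = n, method = method)
}

#' Compare estimation methods over a replicate suite
#'
#' Runs each method on every dataset of the suite and assembles, per SNR
#' level and parameter (and for the trajectory RMS error as a whole), the
#' paired distribution of `|error(baseline)| - |error(candidate)|`
#' (positive values mean the candidate improves on the first, baseline,
#' method), with a two-sided paired Wilcoxon p-value and a 5% significance
#' flag. Pairing by replicate is preserved throughout.
#'
#' @param suite list of datasets from [generate_replicate_suite()].
#' @param methods named list; each element is either a method name
#'   (`"rkg"`, `"rkgw"`) or a function `(dataset, model, cfg) -> ode_fit`.
#'   The first element is the baseline.
#' @param cfg a [fit_config()].
#' @param ratio_pairs passed to [parameter_errors()].
#' @param fs_grid_n grid size for the function-space error.
#' @param alpha significance level for the flags.
#' @return an object of class `evaluation_report` with data frames
#'   `errors` (long format) and `comparisons`, plus `metadata`.
#' @export
compare_methods <- function(suite, methods, cfg = fit_config(),
                            ratio_pairs = NULL, fs_grid_n = 200,
                            alpha = 0.05) {
  if (length(methods) < 2) stop_warpgm("need at least two methods")
  if (is.null(names(methods)) || any(names(methods) == "")) {
    stop_warpgm("methods must be named")
  }
  model <- get_ode_model(suite[[1]]$model_name)
  runner <- function(m) {
    if (is.function(m)) return(m)
    switch(m, rkg = rkg_fit, rkgw = rkgw_fit,
           stop_warpgm("unknown method ", m))
  }
  errors <- data.frame()
  for (i in seq_along(suite)) {
    ds <- suite[[i]]
    truth <- ds$truth$theta
    grid <- seq(ds$truth$span[1], ds$truth$span[2],
                length.out = fs_grid_n)
    for (mn in names(methods)) {
      fit <- tryCatch(runner(methods[[mn]])(ds, model, cfg),
                      error = function(e) NULL)
      if (is.null(fit)) {
        errors <- rbind(errors, data.frame(
          model = ds$model_name, snr_db = ds$snr_db, replicate = i,
          method = mn, parameter = "FIT_FAILED", error = NA_real_))
        next
      }
      pe <- parameter_errors(fit$theta_hat, truth, ratio_pairs)
      fe <- function_space_error(model, fit$theta_hat, truth,
                                 ds$truth$x0, grid = grid)
      errors <- rbind(errors, data.frame(
        model = ds$model_name, snr_db = ds$snr_db, replicate = i,
        method = mn, parameter = c(names(pe), "function_space"),
        error = c(unname(pe), unname(fe))))
    }
  }
  baseline <- names(methods)[1]
  comparisons <- data.frame()
  for (cand in names(methods)[-1]) {
    for (snr in unique(errors$snr_db)) {
      for (par in setdiff(unique(errors$parameter), "FIT_FAILED")) {
        eb <- errors[errors$method == baseline & errors$snr_db == snr &
                       errors$parameter == par, ]
        ec <- errors[errors$method == cand & errors$snr_db == snr &
                       errors$parameter == par, ]
        shared <- intersect(eb$replicate[is.finite(eb$error)],
                            ec$replicate[is.finite(ec$error)])
        if (length(shared) < 3) {
          comparisons <- rbind(comparisons, data.frame(
            baseline = baseline, candidate = cand, snr_db = snr,
            parameter = par, n = length(shared),
            median_improvement = NA_real_, p_value = NA_real_,
            significant = NA, insufficient_data = TRUE))
          next
        }
        db <- eb$error[match(shared, eb$replicate)]
        dc <- ec$error[match(shared, ec$replicate)]
        diffs <- abs(db) - abs(dc)
        wt <- tryCatch(paired_wilcoxon(abs(db), abs(dc)),
                       error = function(e) list(p_value = NA_real_))
        comparisons <- rbind(comparisons, data.frame(
          baseline = baseline, candidate = cand, snr_db = snr,
          parameter = par, n = length(shared),
          median_improvement = stats::median(diffs),
          p_value = wt$p_value,
          significant = isTRUE(wt$p_value < alpha),
          insufficient_data = FALSE))
      }
    }
  }
  structure(list(errors = errors, comparisons = comparisons,
                 metadata = list(model = model$name,
                                 n_datasets = length(suite),
                                 baseline = baseline, alpha = alpha)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$metadata$model, "-",
      x$metadata$n_datasets, "datasets, baseline", x$metadata$baseline,
      "\n")
  print(x$comparisons, digits = 3)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Long-format errors as CSV and the comparison table plus metadata as
#' JSON.
#'
#' @param report an `evaluation_report`.
#' @param csv_path,json_path output paths.
#' @export
write_report <- function(report, csv_path, json_path) {
  utils::write.csv(report$errors, csv_path, row.names = FALSE)
  jsonlite::write_json(list(metadata = report$metadata,
                            comparisons = report$comparisons),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
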