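#' Construct a kernel specification
#'
#' A kernel specification bundles a kernel family with its hyperparameters.
#' Three families are supported:
#' \describe{
#'   \item{`rbf`}{squared-exponential
#'     \eqn{k(t,t') = a\,\exp(-(t-t')^2 / (2\ell^2))} with `lengthscale`
#'     \eqn{\ell > 0} and `amplitude` \eqn{a > 0};}
#'   \item{`mlp`}{the arcsine neural-network kernel
#'     \eqn{k(t,t') = (2/\pi) \arcsin\!\big(2(\sigma_w^2 t t' + \sigma_b^2) /
#'     \sqrt{(1+2(\sigma_w^2 t^2+\sigma_b^2))(1+2(\sigma_w^2 t'^2+\sigma_b^2))}\big)}
#'     with `weight_var` \eqn{\sigma_w^2} and `bias_var` \eqn{\sigma_b^2};}
#'   \item{`sigmoid_basis`}{the asymmetric basis
#'     \eqn{k(t,t_j) = 1/(1+\exp(-l^w (t - t_j)))} with `steepness`
#'     \eqn{l^w > 0}, used as the building block of monotone time warps.
#'     This family is not symmetric in its arguments and is not meant for
#'     Gram-matrix regression.}
#' }
#' All families expose analytic first and second derivatives with respect to
#' the first argument; no finite differencing is used in the production path.
#'
#' @param family one of `"rbf"`, `"mlp"`, `"sigmoid_basis"`.
#' @param lengthscale,amplitude rbf hyperparameters.
#' @param weight_var,bias_var mlp hyperparameters.
#' @param steepness sigmoid-basis hyperparameter.
#' @return an object of class `kernel_spec`.
#' @examples
#' k <- kernel_spec("rbf", lengthscale = 1, amplitude = 1)
#' eval_kernel(k, 0, 0)
#' @export
kernel_spec <- function(family = c("rbf", "mlp", "sigmoid_basis"),
                        lengthscale = 1, amplitude = 1,
                        weight_var = 1, bias_var = 1,
                        steepness = 1) {
  family <- match.arg(family)
  params <- switch(family,
    rbf = c(lengthscale = lengthscale, amplitude = amplitude),
    mlp = c(weight_var = weight_var, bias_var = bias_var),
    sigmoid_basis = c(steepness = steepness)
  )
  if (anyNA(params) || any(!is.finite(params)) || any(params <= 0)) {
    stop_warpgm("kernel hyperparameters must be strictly positive and finite",
                class = "warpgm_bad_hyperparams")
  }
  structure(list(family = family, params = as.list(params)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec> family =", x$family, "|",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

check_kernel_inputs <- function(spec, t, tprime) {
  if (!inherits(spec, "kernel_spec")) {
    stop_warpgm("spec must be a kernel_spec", class = "warpgm_bad_spec")
  }
  assert_finite(t, "t")
  assert_finite(tprime, "t'")
}

# Cross-kernel matrix k^(deriv)(t_i, t'_j) with derivatives taken in the
# first argument. Returns length(t) x length(tprime).
kernel_cross <- function(spec, t, tprime, deriv = 0L) {
  check_kernel_inputs(spec, t, tprime)
  p <- spec$params
  switch(spec$family,
    rbf = {
      D <- outer(t, tprime, "-")
      l2 <- p$lengthscale^2
      E <- p$amplitude * exp(-D^2 / (2 * l2))
      if (deriv == 0L) E
      else if (deriv == 1L) -D / l2 * E
      else if (deriv == 2L) (D^2 / l2^2 - 1 / l2) * E
      else stop_warpgm("deriv must be 0, 1 or 2")
    },
    mlp = {
      sw <- p$weight_var; sb <- p$bias_var
      u <- 2 * (sw * outer(t, tprime) + sb)
      v <- 1 + 2 * (sw * t^2 + sb)          # depends on first argument
      vp <- 1 + 2 * (sw * tprime^2 + sb)
      z <- u / sqrt(outer(v, vp))
      z <- pmin(pmax(z, -1 + 1e-15), 1 - 1e-15)
      if (deriv == 0L) return(2 / pi * asin(z))
      ut <- matrix(2 * sw * tprime, length(t), length(tprime), byrow = TRUE)
      vt <- matrix(4 * sw * t, length(t), length(tprime))
      vv <- matrix(v, length(t), length(tprime))
      cc <- matrix(1 / sqrt(vp), length(t), length(tprime), byrow = TRUE)
      zt <- ut * vv^-0.5 * cc - 0.5 * u * vv^-1.5 * vt * cc
      if (deriv == 1L) return(2 / pi * zt / sqrt(1 - z^2))
      if (deriv != 2L) stop_warpgm("deriv must be 0, 1 or 2")
      ztt <- cc * (-ut * vv^-1.5 * vt + 0.75 * u * vv^-2.5 * vt^2 -
                     0.5 * u * vv^-1.5 * (4 * sw))
      2 / pi * (ztt / sqrt(1 - z^2) + zt^2 * z * (1 - z^2)^-1.5)
    },
    sigmoid_basis = {
      lw <- p$steepness
      Z <- outer(t, tprime, "-")
      S <- stats::plogis(lw * Z)
      if (deriv == 0L) S
      else if (deriv == 1L) lw * S * (1 - S)
      else if (deriv == 2L) lw^2 * S * (1 - S) * (1 - 2 * S)
      else stop_warpgm("deriv must be 0, 1 or 2")
    }
  )
}

#' Evaluate a kernel and its time derivatives
#'
#' `eval_kernel()` returns \eqn{k(t, t')}; `eval_kernel_dt()` and
#' `eval_kernel_d2t()` return the analytic first and second partial
#' derivatives with respect to the first argument. Inputs are recycled
#' elementwise; non-finite inputs are rejected.
#'
#' @param spec a [kernel_spec()].
#' @param t,tprime numeric vectors of abscissa values.
#' @return numeric vector of kernel (derivative) values.
#' @examples
#' k <- kernel_spec("rbf")
#' eval_kernel(k, 0, sqrt(2 * log(2)))  # = 1/2
#' eval_kernel_dt(k, 1, 0)              # = -exp(-1/2)
#' @export
eval_kernel <- function(spec, t, tprime) {
  n <- max(length(t), length(tprime))
  t <- rep_len(t, n); tprime <- rep_len(tprime, n)
  vapply(seq_len(n), function(i) {
    kernel_cross(spec, t[i], tprime[i], 0L)[1, 1]
  }, numeric(1))
}

#' @rdname eval_kernel
#' @export
eval_kernel_dt <- function(spec, t, tprime) {
  n <- max(length(t), length(tprime))
  t <- rep_len(t, n); tprime <- rep_len(tprime, n)
  vapply(seq_len(n), function(i) {
    kernel_cross(spec, t[i], tprime[i], 1L)[1, 1]
  }, numeric(1))
}

#' @rdname eval_kernel
#' @export
eval_kernel_d2t <- function(spec, t, tprime) {
  n <- max(length(t), length(tprime))
  t <- rep_len(t, n); tprime <- rep_len(tprime, n)
  vapply(seq_len(n), function(i) {
    kernel_cross(spec, t[i], tprime[i], 2L)[1, 1]
  }, numeric(1))
}

#' Gram matrix of a kernel on a set of points
#'
#' For the symmetric families (rbf, mlp) the result is symmetric positive
#' semi-definite up to floating point error; a small jitter is added to the
#' diagonal before any factorization elsewhere in the package.
#'
#' @param spec a [kernel_spec()].
#' @param times numeric vector of abscissa values.
#' @return a `length(times)` square matrix with entries \eqn{k(t_i, t_j)}.
#' @export
gram_matrix <- function(spec, times) {
  K <- kernel_cross(spec, times, times, 0L)
  if (spec$family != "sigmoid_basis") K <- (K + t(K)) / 2
  K
}
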