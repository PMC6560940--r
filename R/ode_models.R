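#' Define an ODE model
#'
#' An `ode_model` couples a named right-hand side \eqn{f(x, \theta)} with its
#' state and parameter names and optional parameter bounds. The abscissa is
#' time for dynamical systems; the soft-tissue model uses radius instead, so
#' the right-hand side also receives the abscissa value.
#'
#' @param name model identifier (used by the registry and the CLI).
#' @param state_names character vector of state names (length = dimension).
#' @param param_names character vector of parameter names.
#' @param rhs function `(x, t, theta) -> numeric(dim)`.
#' @param param_bounds matrix with columns `lower`, `upper` and one row per
#'   parameter, or `NULL` for the default `[1e-3, 1e2]`.
#' @param abscissa label of the abscissa, `"time"` or `"radius"`.
#' @return an object of class `ode_model`.
#' @export
ode_model <- function(name, state_names, param_names, rhs,
                      param_bounds = NULL, abscissa = "time") {
  if (is.null(param_bounds)) {
    param_bounds <- matrix(rep(c(1e-3, 1e2), each = length(param_names)),
                           ncol = 2,
                           dimnames = list(param_names, c("lower", "upper")))
  }
  structure(list(name = name, state_names = state_names,
                 param_names = param_names, dim = length(state_names),
                 rhs = rhs, param_bounds = param_bounds,
                 abscissa = abscissa),
            class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model>", x$name, "-", x$dim, "states (",
      paste(x$state_names, collapse = ", "), "),",
      length(x$param_names), "parameters (",
      paste(x$param_names, collapse = ", "), ")\n")
  invisible(x)
}

#' Benchmark right-hand sides
#'
#' Plain-function right-hand sides of the four benchmark systems.
#' `lotka_volterra_rhs()` is the predator--prey system
#' \eqn{\dot x_1 = \alpha x_1 - \beta x_1 x_2},
#' \eqn{\dot x_2 = -\gamma x_2 + \delta x_1 x_2}.
#' `fitzhugh_nagumo_rhs()` is the spike-generation model
#' \eqn{\dot x_1 = c (x_1 - x_1^3/3 + x_2)},
#' \eqn{\dot x_2 = -c^{-1} (x_1 - a + b x_2)}.
#' `biopathway_rhs()` is a five-species signal transduction pathway
#' (states S, dS, R, RS, Rpp) mixing mass action and Michaelis--Menten
#' kinetics with parameters \eqn{k_1, \ldots, k_6}; the R-moiety
#' \eqn{R + RS + Rpp} is conserved by construction.
#' `soft_tissue_rhs()` is the radial strain equation of a thick-walled
#' artery model with material parameters \eqn{a, b, a_f, b_f}; the
#' anisotropic fibre term is active only where the fibre invariant
#' \eqn{I_4 > 1}.
#'
#' @param x state vector (length 2, 2, 5; scalar strain for soft tissue).
#' @param theta parameter vector: `(alpha, beta, gamma, delta)`,
#'   `(a, b, c)`, `(k1..k6)`, `(a, b, a_f, b_f)` respectively.
#' @param r radius (soft tissue abscissa).
#' @param consts a [soft_tissue_constants()] object.
#' @return the derivative vector.
#' @examples
#' lotka_volterra_rhs(c(0.5, 1), c(1, 1, 4, 1))
#' @export
lotka_volterra_rhs <- function(x, theta) {
  c(theta[1] * x[1] - theta[2] * x[1] * x[2],
    -theta[3] * x[2] + theta[4] * x[1] * x[2])
}

#' @rdname lotka_volterra_rhs
#' @export
fitzhugh_nagumo_rhs <- function(x, theta) {
  a <- theta[1]; b <- theta[2]; cc <- theta[3]
  c(cc * (x[1] - x[1]^3 / 3 + x[2]),
    -(x[1] - a + b * x[2]) / cc)
}

#' @rdname lotka_volterra_rhs
#' @export
biopathway_rhs <- function(x, theta) {
  S <- x[1]; dS <- x[2]; R <- x[3]; RS <- x[4]; Rpp <- x[5]
  k <- theta
  if (k[6] + Rpp <= 0) {
    stop_warpgm("Michaelis-Menten denominator k6 + Rpp must be positive",
                class = "warpgm_domain_error")
  }
  mm <- k[5] * Rpp / (k[6] + Rpp)
  c(-k[1] * S - k[2] * S * R + k[3] * RS,
    k[1] * S,
    -k[2] * S * R + k[3] * RS + mm,
    k[2] * S * R - k[3] * RS - k[4] * RS,
    k[4] * RS - mm)
}

#' Physiological constants of the soft-tissue model
#'
#' The radial strain model needs five predefined physiological constants:
#' the axial stretch `lambda_z`, the reference inner and outer radii `R_i`
#' and `R_0` (with `R_0 > R_i`), the opening-angle parameter `k`, and the
#' deformed inner radius `r_i`. The defaults are synthetic placeholders of
#' plausible magnitude for an arterial segment; they are configuration
#' values, not literature measurements, and should be replaced with
#' patient-specific values in any real application.
#'
#' @param lambda_z,R_i,R_0,k,r_i positive reals, `R_0 > R_i`.
#' @return an object of class `soft_tissue_constants`.
#' @export
soft_tissue_constants <- function(lambda_z = 1.2, R_i = 0.71, R_0 = 1.1,
                                  k = 1.0, r_i = 0.65) {
  v <- c(lambda_z = lambda_z, R_i = R_i, R_0 = R_0, k = k, r_i = r_i)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop_warpgm("soft tissue constants must be positive")
  }
  if (R_0 <= R_i) stop_warpgm("R_0 must exceed R_i")
  structure(as.list(v), class = "soft_tissue_constants")
}

#' @rdname lotka_volterra_rhs
#' @export
soft_tissue_rhs <- function(x, r, theta, consts = soft_tissue_constants()) {
  stopifnot(inherits(consts, "soft_tissue_constants"))
  if (r <= 0) stop_warpgm("radius must be positive")
  a <- theta[[1]]; b <- theta[[2]]; af <- theta[[3]]; bf <- theta[[4]]
  lz <- consts$lambda_z; k <- consts$k
  arg <- (r^2 - consts$r_i^2) * k * lz + consts$r_i^2
  if (arg < 0) {
    stop_warpgm("negative argument in reference-radius square root",
                class = "warpgm_domain_error")
  }
  R <- sqrt(arg)
  l1 <- R / (r * k * lz)
  l2 <- k * r / R
  I1 <- l1^2 + l2^2 + lz^2
  gam <- 2 * pi / (3 * consts$R_0 - consts$R_i) * (R - consts$R_i) - pi / 3
  I4 <- l2^2 * (cos(gam)^2 + lz^2 * sin(gam)^2)
  H <- as.numeric(I4 > 1)
  (a * exp(b * (I1 - 3)) * (l2^2 - l1^2) +
      H * af * (I4 - 1) * exp(bf * (I4 - 1)^2)) / r
}

#' Built-in benchmark models
#'
#' Constructors for the four benchmark systems, returning [ode_model()]
#' objects ready for [solve_ode()], [generate_dataset()] and the fitting
#' front ends. `default_truth()` returns the generating parameters, initial
#' state and observation window used by the simulation protocol for each
#' model. The Lotka--Volterra values (`theta = (1, 1, 4, 1)`,
#' `x0 = (0.5, 1)`) are the protocol's printed ground truth; the
#' FitzHugh--Nagumo and biopathway values are conventional literature
#' choices (FHN: a = 0.2, b = 0.2, c = 3; biopathway: the Vyshemirsky &
#' Girolami model-1 kinetics), and the soft-tissue values are synthetic
#' placeholders -- all three are configuration defaults, not printed
#' protocol values.
#'
#' @param consts soft-tissue constants, see [soft_tissue_constants()].
#' @return an `ode_model`; for `default_truth()` a list with `theta`, `x0`,
#'   `span`, `n_obs`.
#' @export
lotka_volterra_model <- function() {
  ode_model("lotka_volterra", c("x1", "x2"),
            c("alpha", "beta", "gamma", "delta"),
            function(x, t, theta) lotka_volterra_rhs(x, theta))
}

#' @rdname lotka_volterra_model
#' @export
fitzhugh_nagumo_model <- function() {
  bounds <- matrix(c(1e-3, 1e2, 1e-3, 1e2, 1e-3, 1e2), ncol = 2,
                   byrow = TRUE, dimnames = list(c("a", "b", "c"),
                                                 c("lower", "upper")))
  ode_model("fitzhugh_nagumo", c("x1", "x2"), c("a", "b", "c"),
            function(x, t, theta) fitzhugh_nagumo_rhs(x, theta),
            param_bounds = bounds)
}

#' @rdname lotka_volterra_model
#' @export
biopathway_model <- function() {
  pn <- paste0("k", 1:6)
  bounds <- matrix(rep(c(1e-3, 1e2), each = 6), ncol = 2,
                   dimnames = list(pn, c("lower", "upper")))
  ode_model("biopathway", c("S", "dS", "R", "RS", "Rpp"), pn,
            function(x, t, theta) biopathway_rhs(x, theta),
            param_bounds = bounds)
}

#' @rdname lotka_volterra_model
#' @export
soft_tissue_model <- function(consts = soft_tissue_constants()) {
  m <- ode_model("soft_tissue", "sigma", c("a", "b", "a_f", "b_f"),
                 function(x, t, theta) soft_tissue_rhs(x, t, theta, consts),
                 abscissa = "radius")
  m$consts <- consts
  m
}

#' @rdname lotka_volterra_model
#' @param model_name one of the built-in model names.
#' @export
default_truth <- function(model_name) {
  switch(model_name,
    lotka_volterra = list(theta = c(alpha = 1, beta = 1, gamma = 4,
                                    delta = 1),
                          x0 = c(0.5, 1), span = c(0, 4.8), n_obs = 28),
    fitzhugh_nagumo = list(theta = c(a = 0.2, b = 0.2, c = 3),
                           x0 = c(-1, 1), span = c(0, 10), n_obs = 37),
    biopathway = list(theta = c(k1 = 0.07, k2 = 0.6, k3 = 0.05, k4 = 0.3,
                                k5 = 0.017, k6 = 0.3),
                      x0 = c(1, 0, 1, 0, 0), span = c(0, 100), n_obs = 17),
    soft_tissue = list(theta = c(a = 0.05, b = 1, a_f = 0.2, b_f = 1.5),
                       x0 = 0, span = c(0.65, 1.2), n_obs = 20),
    stop_warpgm("unknown model: ", model_name))
}

# ---- model registry ---------------------------------------------------

the_registry <- new.env(parent = emptyenv())

#' Model registry
#'
#' Models are addressable by name from the CLI and configuration files.
#' The four built-in models are pre-registered; `register_ode_model()` adds
#' a user-defined system.
#'
#' @param model an [ode_model()].
#' @param name model name to look up.
#' @return `get_ode_model()` returns the registered `ode_model`.
#' @export
register_ode_model <- function(model) {
  stopifnot(inherits(model, "ode_model"))
  assign(model$name, model, envir = the_registry)
  invisible(model)
}

#' @rdname register_ode_model
#' @export
get_ode_model <- function(name) {
  if (!exists(name, envir = the_registry, inherits = FALSE)) {
    builtin <- switch(name,
      lotka_volterra = lotka_volterra_model(),
      fitzhugh_nagumo = fitzhugh_nagumo_model(),
      biopathway = biopathway_model(),
      soft_tissue = soft_tissue_model(),
      NULL)
    if (is.null(builtin)) stop_warpgm("unknown model: ", name)
    register_ode_model(builtin)
  }
  get(name, envir = the_registry)
}
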