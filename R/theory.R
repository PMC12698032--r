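#' Non-spatial (CSR) carrying capacity
#'
#' Equilibrium density of the classic logistic model, `(b - d0) / gamma`,
#' floored at zero when the baseline death rate exceeds the birth rate.
#'
#' @param b Birth rate.
#' @param d0 Baseline death rate.
#' @param gamma Competition strength; must be positive.
#' @return Density (1/area).
#' @examples
#' n_csr(1.5, 0.1, 0.002)  # 700
#' @export
n_csr <- function(b, d0, gamma) {
  if (any(gamma <= 0)) stop("gamma must be positive")
  pmax((b - d0) / gamma, 0)
}

#' Logistic growth rate with crowding
#'
#' Right-hand side of the first-order mean-density equation
#' `dn/dt = b n - d0 n - gamma c n^2`, where the crowding index `c` carries
#' all the spatial information. With `c = 1` this is the classic Verhulst
#' equation.
#'
#' @param n Density, non-negative.
#' @param b,d0,gamma Demographic rates as in [demography_params()].
#' @param c Crowding index (dimensionless).
#' @return Rate of change of density.
#' @examples
#' logistic_rhs(350, 1.5, 0.1, 0.002, c = 2)  # 0: equilibrium at c = 2
#' @export
logistic_rhs <- function(n, b, d0, gamma, c = 1) {
  stopifnot(all(n >= 0))
  b * n - d0 * n - gamma * c * n^2
}

#' Integrate the mean-density dynamics
#'
#' Numerically solves `dn/dt = (b - d0) n - gamma c(t) n^2` with an adaptive
#' solver (`deSolve::ode`, lsoda). For a constant crowding index the solution
#' is the closed-form logistic curve.
#'
#' @param n0 Initial density, non-negative.
#' @param b,d0,gamma Demographic rates.
#' @param c_path Crowding index over time: a constant or a `function(t)`.
#' @param horizon Final time.
#' @param n_out Number of output times (including 0).
#' @return Data frame with columns `t` and `n`.
#' @examples
#' tr <- integrate_mean_dynamics(70, 1.5, 0.1, 0.002, c_path = 1, horizon = 10)
#' tail(tr, 1)  # approaches 700
#' @export
integrate_mean_dynamics <- function(n0, b, d0, gamma, c_path = 1, horizon,
                                    n_out = 201) {
  stopifnot(n0 >= 0, horizon > 0)
  cfun <- if (is.function(c_path)) c_path else function(t) c_path
  if (any(vapply(c(0, horizon / 2, horizon), cfun, numeric(1)) < 0))
    stop("c_path must be non-negative")
  rhs <- function(t, y, p) list(logistic_rhs(max(y[1], 0), b, d0, gamma, cfun(t)))
  times <- seq(0, horizon, length.out = n_out)
  sol <- deSolve::ode(y = c(n = n0), times = times, func = rhs, parms = NULL,
                      rtol = 1e-9, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed: istate = ", attr(sol, "istate")[1])
  data.frame(t = sol[, "time"], n = sol[, "n"])
}

#' Normalised carrying capacity
#'
#' Final abundance as a fraction of the homogeneous reference, corrected for
#' the interaction mass lost to kernel truncation:
#' `(N_final / A) / (n_csr / retained_mass)`. A homogeneously distributed
#' population therefore scores 1.
#'
#' @param N_final Final abundance (count).
#' @param domain A [torus_domain()].
#' @param b,d0,gamma Demographic rates.
#' @param retained_mass Kernel mass within the truncation radius, in (0, 1].
#' @return Dimensionless normalised carrying capacity.
#' @examples
#' normalized_carrying_capacity(700, torus_domain(1), 1.5, 0.1, 0.002, 0.95)
#' @export
normalized_carrying_capacity <- function(N_final, domain, b, d0, gamma,
                                         retained_mass = kernel_retained_mass(2.45)) {
  stopifnot(all(retained_mass > 0), all(retained_mass <= 1))
  (N_final / domain$A) / (n_csr(b, d0, gamma) / retained_mass)
}

#' Equilibrium prediction from a measured crowding index
#'
#' Carrying capacity of the first-order theory: `n* = n_csr / c*`, so that
#' `n* c* = n_csr` exactly. The inverse crowding index `1 / c*` is the
#' predicted normalised carrying capacity.
#'
#' @param b,d0,gamma Demographic rates.
#' @param c_star Equilibrium crowding index (scalar or vector), positive.
#' @return Data frame with `n_csr`, `c_star`, `n_star`, `predicted_K`
#'   (`= 1 / c_star`).
#' @examples
#' equilibrium_prediction(1.5, 0.1, 0.002, c_star = 2)
#' @export
equilibrium_prediction <- function(b, d0, gamma, c_star) {
  stopifnot(all(c_star > 0))
  ncsr <- n_csr(b, d0, gamma)
  data.frame(n_csr = ncsr, c_star = c_star, n_star = ncsr / c_star,
             predicted_K = 1 / c_star)
}

#' Goodness of fit of crowding-based predictions
#'
#' Ordinary-least-squares R-squared of measured normalised carrying
#' capacities against their predictions (`1 / c*`), with the fit both with an
#' intercept (the headline value) and through the origin (for comparison with
#' the 1-1 line).
#'
#' @param predicted Numeric vector of predicted values (`1 / c*`).
#' @param measured Numeric vector of measured normalised carrying capacities.
#' @return List with `r2`, `r2_through_origin`, `slope`, `intercept`, `n`.
#' @examples
#' predicted_vs_measured_r2(c(0.5, 1, 1.5), c(0.52, 0.98, 1.49))
#' @export
predicted_vs_measured_r2 <- function(predicted, measured) {
  ok <- is.finite(predicted) & is.finite(measured)
  predicted <- predicted[ok]; measured <- measured[ok]
  if (length(predicted) < 3) stop("need at least 3 finite pairs")
  if (stats::var(predicted) == 0)
    stop("degenerate predictor: no variance in predicted values")
  if (stats::var(measured) == 0)
    stop("degenerate response: no variance in measured values")
  fit <- stats::lm(measured ~ predicted)
  fit0 <- stats::lm(measured ~ predicted + 0)
  list(r2 = summary(fit)$r.squared,
       r2_through_origin = summary(fit0)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(predicted))
}
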