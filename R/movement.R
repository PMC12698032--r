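#' Movement model parameters
#'
#' Range-resident movement is an Ornstein-Uhlenbeck (OU) process: diffusive
#' motion plus linear reversion to a home-range centre with autocorrelation
#' time `tau` (the home-range crossing time) and stationary per-component
#' variance `sigma_r2` (the home-range spatial scale). Two limits are exposed
#' as their own modes: `"BM"`, uniform space use (`tau`, `sigma_r2` both
#' infinite at fixed diffusion `D = sigma_r2 / tau`), and `"SESSILE"`,
#' organisms that never move after settling (`D = 0`).
#'
#' For OU, any two of `tau`, `sigma_r2`, `D` determine the third; supplying
#' all three is accepted only if consistent.
#'
#' @param mode One of `"OU"`, `"BM"`, `"SESSILE"`.
#' @param tau Home-range crossing time (time units), positive (OU).
#' @param sigma_r2 Stationary positional variance per component (area), positive (OU).
#' @param D Diffusion coefficient (area/time); free parameter for BM,
#'   derived `sigma_r2 / tau` for OU, 0 for SESSILE.
#' @return An object of class `rrl_movement`.
#' @examples
#' movement_params("OU", tau = 0.1, sigma_r2 = 0.01)
#' movement_params("BM", D = 1)
#' movement_params("SESSILE")
#' @export
movement_params <- function(mode = c("OU", "BM", "SESSILE"),
                            tau = NULL, sigma_r2 = NULL, D = NULL) {
  mode <- match.arg(toupper(mode[1]), c("OU", "BM", "SESSILE"))
  if (mode == "OU") {
    given <- !c(is.null(tau), is.null(sigma_r2), is.null(D))
    if (sum(given) < 2L)
      stop("OU mode needs two of tau, sigma_r2, D")
    if (is.null(tau)) tau <- sigma_r2 / D
    if (is.null(sigma_r2)) sigma_r2 <- D * tau
    if (is.null(D)) D <- sigma_r2 / tau
    stopifnot(tau > 0, sigma_r2 > 0, D > 0)
    if (abs(D - sigma_r2 / tau) > 1e-9 * max(D, sigma_r2 / tau))
      stop("inconsistent OU parameters: D must equal sigma_r2 / tau")
    D <- sigma_r2 / tau
  } else if (mode == "BM") {
    if (is.null(D) || !is.finite(D) || D <= 0)
      stop("BM mode needs a finite positive diffusion coefficient D")
    tau <- Inf; sigma_r2 <- Inf
  } else {
    tau <- Inf; sigma_r2 <- 0; D <- 0
  }
  structure(list(mode = mode, tau = as.numeric(tau),
                 sigma_r2 = as.numeric(sigma_r2), D = as.numeric(D)),
            class = "rrl_movement")
}

#' @export
print.rrl_movement <- function(x, ...) {
  cat("Movement mode:", x$mode, "\n")
  if (x$mode == "OU")
    cat("  tau =", x$tau, " sigma_r2 =", x$sigma_r2, " D =", x$D, "\n")
  if (x$mode == "BM") cat("  D =", x$D, "\n")
  invisible(x)
}

#' Propagate positions between demographic events
#'
#' Advances organism positions over an interval `dt` using the exact
#' transition law of the movement process, so arbitrarily long or short
#' inter-event times are handled without discretisation error. For OU,
#' `x' = mu + (x - mu) e^{-dt/tau} + eps` with per-component
#' `eps ~ N(0, sigma_r2 (1 - e^{-2 dt/tau}))`; for BM,
#' `x' = x + N(0, 2 D dt)` per component; sessile organisms do not move.
#' Positions are returned unwrapped relative to the centre; wrapping happens
#' only when interactions are computed.
#'
#' @param position Numeric 2-vector or n-by-2 matrix of current positions.
#' @param centre Home-range centre(s), same shape as `position`.
#' @param dt Elapsed time, non-negative.
#' @param params A [movement_params()].
#' @return New position(s), same shape as `position`.
#' @examples
#' set.seed(1)
#' propagate(c(0.5, 0.5), c(0.4, 0.4), 0.2, movement_params("OU", 0.1, 0.01))
#' @export
propagate <- function(position, centre, dt, params) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("dt must be a non-negative finite scalar")
  x <- rbind2cols(position); mu <- rbind2cols(centre)
  stopifnot(nrow(x) == nrow(mu))
  if (dt == 0 || params$mode == "SESSILE") {
    out <- x
  } else if (params$mode == "OU") {
    f <- exp(-dt / params$tau)
    s <- sqrt(params$sigma_r2 * (1 - f^2))
    out <- mu + (x - mu) * f + matrix(stats::rnorm(2 * nrow(x), sd = s), ncol = 2)
  } else { # BM
    s <- sqrt(2 * params$D * dt)
    out <- x + matrix(stats::rnorm(2 * nrow(x), sd = s), ncol = 2)
  }
  if (is.null(dim(position))) drop(out) else out
}

#' Sample a stationary space-use position
#'
#' Draws a position from the long-run utilisation distribution of the
#' movement process: isotropic Gaussian `N(centre, sigma_r2 I)` for OU, the
#' centre itself for sessile organisms, and uniform over the domain for BM
#' (whose stationary use of a finite torus is flat).
#'
#' @param centre 2-vector or n-by-2 matrix of home-range centres.
#' @param params A [movement_params()].
#' @param domain A [torus_domain()] (needed for BM).
#' @return Position(s), same shape as `centre`.
#' @examples
#' set.seed(1)
#' sample_stationary_position(c(0.5, 0.5), movement_params("OU", 0.1, 0.01),
#'                            torus_domain(1))
#' @export
sample_stationary_position <- function(centre, params, domain) {
  mu <- rbind2cols(centre)
  n <- nrow(mu)
  out <- switch(params$mode,
    SESSILE = mu,
    OU = mu + matrix(stats::rnorm(2 * n, sd = sqrt(params$sigma_r2)), ncol = 2),
    BM = matrix(stats::runif(2 * n, 0, domain$L), ncol = 2))
  if (is.null(dim(centre))) drop(out) else out
}

#' Effective diffusion coefficient
#'
#' `sigma_r2 / tau` for OU, the free parameter `D` for BM, and 0 for sessile
#' organisms.
#'
#' @param params A [movement_params()].
#' @return Diffusion coefficient (area/time).
#' @examples
#' effective_diffusion(movement_params("OU", tau = 0.1, sigma_r2 = 0.01))
#' @export
effective_diffusion <- function(params) {
  switch(params$mode,
         OU = params$sigma_r2 / params$tau,
         BM = params$D,
         SESSILE = 0)
}

#' Gaussian home-range area
#'
#' Area of the circle containing a given fraction of an isotropic Gaussian
#' utilisation distribution with per-component variance `sigma_r2`:
#' `-2 pi sigma_r2 log(1 - coverage)` (the conventional 95% home range by
#' default). Reported alongside raw `sigma_r2` in sweep outputs.
#'
#' @param sigma_r2 Stationary positional variance (area units).
#' @param coverage Probability mass enclosed, in (0, 1).
#' @return Home-range area.
#' @examples
#' home_range_area(0.01)
#' @export
home_range_area <- function(sigma_r2, coverage = 0.95) {
  stopifnot(all(sigma_r2 >= 0), coverage > 0, coverage < 1)
  -2 * pi * sigma_r2 * log(1 - coverage)
}
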