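#' Crowding index from organism positions
#'
#' The crowding index is the competition-kernel-weighted integral of the pair
#' correlation function: it measures how crowded organisms are at the scales
#' where they actually compete, with `c = 1` the homogeneous (CSR) reference,
#' `c > 1` overcrowding and `c < 1` undercrowding. The estimator is the
#' ordered-pair sum
#' `c = A / (N (N-1)) * sum_{i != j} Kc~(min_image(x_i, x_j))`,
#' where `Kc~` is the truncated competition kernel renormalised by its
#' retained mass so that the CSR expectation is exactly 1 at finite `N`.
#'
#' @param snapshot An `rrl_population`, a data frame with `x`, `y` columns,
#'   or an n-by-2 matrix of positions.
#' @param spec A [kernel_spec()].
#' @param domain A [torus_domain()].
#' @return Object of class `rrl_crowding` with fields `value`, `estimator`,
#'   `n_points`, `sigma_q`, `sigma_r2`.
#' @examples
#' set.seed(1)
#' pop <- init_population(200, torus_domain(1), movement_params("SESSILE"))
#' crowding_from_positions(pop, kernel_spec(0.05), torus_domain(1))
#' @export
crowding_from_positions <- function(snapshot, spec, domain) {
  xy <- snapshot_coords(snapshot, c("x", "y"))
  n <- nrow(xy)
  if (n < 2) stop("crowding is undefined for fewer than 2 organisms")
  mass <- kernel_retained_mass(spec)
  s <- cpp_pair_kernel_sum(xy[, 1], xy[, 2], domain$L,
                           spec$sigma_q^2, spec$trunc_mult * spec$sigma_q)
  val <- domain$A / (n * (n - 1)) * s / mass
  structure(list(value = val, estimator = "positions", n_points = n,
                 sigma_q = spec$sigma_q, sigma_r2 = NA_real_),
            class = "rrl_crowding")
}

#' Home-range competition weighting function
#'
#' For two independent range residents whose positions have relaxed to their
#' stationary Gaussian space use, the displacement between the organisms is
#' the displacement between their home-range centres plus two independent
#' `N(0, sigma_r2 I)` deviations. Composing with the Gaussian competition
#' kernel yields an isotropic bivariate Gaussian with per-component variance
#' `sigma_q^2 + 2 sigma_r2`; with `sigma_r2 = 0` it reduces to the
#' (untruncated) competition kernel.
#'
#' @param u 2-vector or n-by-2 matrix of centre-to-centre displacements.
#' @param sigma_q Competition scale (length).
#' @param sigma_r2 Stationary positional variance (area).
#' @return Density value(s) (1/area).
#' @examples
#' khr_value(c(0, 0), sigma_q = 0.01, sigma_r2 = 0.005)
#' @export
khr_value <- function(u, sigma_q, sigma_r2) {
  stopifnot(sigma_q >= 0, sigma_r2 >= 0, sigma_q > 0 || sigma_r2 > 0)
  u <- rbind2cols(u)
  v <- sigma_q^2 + 2 * sigma_r2
  exp(-(u[, 1]^2 + u[, 2]^2) / (2 * v)) / (2 * pi * v)
}

#' Crowding index from home-range centres and sizes
#'
#' Estimates crowding from the point pattern of home-range centres, weighting
#' centre-to-centre displacements by the composed kernel [khr_value()] (which
#' accounts for both the competition scale and each organism's space use).
#' The composed Gaussian is evaluated out to 6 composite standard deviations
#' (a machine-negligible cut) and renormalised so the CSR-centres expectation
#' is exactly 1.
#'
#' @param centres An `rrl_population`, a data frame with `mu_x`, `mu_y`
#'   columns, or an n-by-2 matrix of centres.
#' @param sigma_r2 Stationary positional variance (area units).
#' @param spec A [kernel_spec()] giving the competition scale.
#' @param domain A [torus_domain()].
#' @return Object of class `rrl_crowding` (`estimator = "home_ranges"`).
#' @examples
#' set.seed(1)
#' pop <- init_population(200, torus_domain(1), movement_params("OU", 0.1, 0.001))
#' crowding_from_home_ranges(pop, 0.001, kernel_spec(0.05), torus_domain(1))
#' @export
crowding_from_home_ranges <- function(centres, sigma_r2, spec, domain) {
  xy <- snapshot_coords(centres, c("mu_x", "mu_y"))
  n <- nrow(xy)
  if (n < 2) stop("crowding is undefined for fewer than 2 organisms")
  stopifnot(sigma_r2 >= 0)
  v <- spec$sigma_q^2 + 2 * sigma_r2
  rtrunc <- 6 * sqrt(v)
  mass <- 1 - exp(-rtrunc^2 / (2 * v))  # 1 - exp(-18)
  s <- cpp_pair_kernel_sum(xy[, 1], xy[, 2], domain$L, v, rtrunc)
  val <- domain$A / (n * (n - 1)) * s / mass
  structure(list(value = val, estimator = "home_ranges", n_points = n,
                 sigma_q = spec$sigma_q, sigma_r2 = sigma_r2),
            class = "rrl_crowding")
}

#' @export
print.rrl_crowding <- function(x, ...) {
  cat("Crowding index (", x$estimator, "): c = ", signif(x$value, 6),
      "  [N = ", x$n_points, "]\n", sep = "")
  invisible(x)
}

#' Isotropic pair correlation function on the torus
#'
#' Ratio of the density of organism pairs at distance r to its value under
#' complete spatial randomness. The periodic estimator needs no edge
#' correction: `g2(bin) = A / (N (N-1)) * ordered-pair count in annulus /
#' annulus area`, with distances taken as minimum-image.
#'
#' @param snapshot Positions (as in [crowding_from_positions()]).
#' @param breaks Increasing vector of distance bin edges within `(0, L/2]`.
#' @param domain A [torus_domain()].
#' @return Data frame with `r_lo`, `r_hi`, `r_mid`, `npairs` (ordered pairs)
#'   and `g2` per bin.
#' @examples
#' set.seed(1)
#' pop <- init_population(300, torus_domain(1), movement_params("SESSILE"))
#' pair_correlation(pop, seq(0, 0.2, by = 0.02), torus_domain(1))
#' @export
pair_correlation <- function(snapshot, breaks, domain) {
  xy <- snapshot_coords(snapshot, c("x", "y"))
  n <- nrow(xy)
  if (n < 2) stop("pair correlation is undefined for fewer than 2 organisms")
  breaks <- sort(as.numeric(breaks))
  if (max(breaks) > domain$L / 2 + 1e-12)
    stop("bins must lie within (0, L/2]: beyond L/2 minimum-image distances do not exist")
  counts <- cpp_pair_dist_counts(xy[, 1], xy[, 2], domain$L, breaks)
  lo <- breaks[-length(breaks)]; hi <- breaks[-1]
  area <- pi * (hi^2 - lo^2)
  data.frame(r_lo = lo, r_hi = hi, r_mid = (lo + hi) / 2,
             npairs = counts,
             g2 = domain$A / (n * (n - 1)) * counts / area)
}

#' Covariance-form crowding
#'
#' Converts the pair-correlation-based crowding index `c` into the weighted
#' spatial-covariance convention: `ccov = n^2 (c - 1)`, which is 0 for a
#' homogeneous population.
#'
#' @param c Crowding index (dimensionless).
#' @param n Organism density (1/area).
#' @return Covariance-scale crowding value.
#' @examples
#' ccov_from_c(2, 700)
#' @export
ccov_from_c <- function(c, n) {
  stopifnot(all(n >= 0))
  n^2 * (c - 1)
}

# extract an n x 2 coordinate matrix from the accepted snapshot forms
snapshot_coords <- function(snapshot, cols) {
  if (is.matrix(snapshot)) {
    stopifnot(ncol(snapshot) == 2L)
    return(snapshot)
  }
  if (is.data.frame(snapshot)) {
    if (all(cols %in% names(snapshot)))
      return(cbind(snapshot[[cols[1]]], snapshot[[cols[2]]]))
    if (all(c("x", "y") %in% names(snapshot)))
      return(cbind(snapshot$x, snapshot$y))
    stop("snapshot lacks coordinate columns ", paste(cols, collapse = ", "))
  }
  stop("unsupported snapshot type")
}
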