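#' Generate test point patterns
#'
#' Point patterns on the torus with known statistics, used to validate the
#' crowding and pair-correlation estimators:
#' \describe{
#'   \item{csr}{`n` independent uniform points (complete spatial randomness).}
#'   \item{thomas}{Poisson cluster process: `Poisson(kappa * A)` uniform
#'     parents, each with `Poisson(mean_offspring)` offspring displaced by
#'     isotropic Gaussian `N(0, sigma_c^2 I)` and wrapped. Its pair
#'     correlation function is known in closed form,
#'     `g2(r) = 1 + exp(-r^2 / (4 sigma_c^2)) / (4 pi kappa sigma_c^2)`.}
#'   \item{lattice}{A regular `k` x `k` grid (`n = k^2`), maximally
#'     overdispersed.}
#'   \item{two_point}{Two points separated by `separation` along the x axis.}
#' }
#'
#' @param kind One of `"csr"`, `"thomas"`, `"lattice"`, `"two_point"`.
#' @param n Number of points (csr; rounded to a square for lattice).
#' @param domain A [torus_domain()].
#' @param kappa Thomas parent intensity (1/area).
#' @param sigma_c Thomas cluster spread (length).
#' @param mean_offspring Thomas mean offspring per parent.
#' @param separation two_point distance.
#' @return An `rrl_population` snapshot (centres equal to positions).
#' @examples
#' set.seed(1)
#' generate_fixture("thomas", domain = torus_domain(1))
#' @export
generate_fixture <- function(kind = c("csr", "thomas", "lattice", "two_point"),
                             n = 700, domain = torus_domain(1),
                             kappa = 25, sigma_c = 0.02, mean_offspring = 4,
                             separation = 0) {
  kind <- match.arg(kind)
  L <- domain$L
  xy <- switch(kind,
    csr = matrix(stats::runif(2 * n, 0, L), ncol = 2),
    thomas = {
      np <- stats::rpois(1, kappa * domain$A)
      parents <- matrix(stats::runif(2 * np, 0, L), ncol = 2)
      kids <- lapply(seq_len(np), function(i) {
        m <- stats::rpois(1, mean_offspring)
        if (m == 0) return(NULL)
        sweep(matrix(stats::rnorm(2 * m, sd = sigma_c), ncol = 2), 2,
              parents[i, ], "+")
      })
      pts <- do.call(rbind, kids)
      if (is.null(pts) || nrow(pts) < 2)
        pts <- matrix(stats::runif(4, 0, L), ncol = 2) # degenerate draw guard
      pts %% L
    },
    lattice = {
      k <- max(1L, round(sqrt(n)))
      g <- (seq_len(k) - 1) * L / k
      as.matrix(expand.grid(x = g, y = g))
    },
    two_point = rbind(c(L / 2, L / 2), c((L / 2 + separation) %% L, L / 2)))
  pop <- data.frame(id = seq_len(nrow(xy)),
                    mu_x = xy[, 1], mu_y = xy[, 2],
                    x = xy[, 1], y = xy[, 2])
  attr(pop, "t") <- 0
  attr(pop, "domain") <- domain
  attr(pop, "next_id") <- nrow(xy) + 1L
  class(pop) <- c("rrl_population", "data.frame")
  pop
}

#' Summarise replicate runs of one parameter cell
#'
#' Computes the statistics reported per sweep cell: median, mean and 5th/95th
#' percentiles (linear interpolation between order statistics, `quantile`
#' type 7) of the normalised carrying capacity, the extinction fraction, and
#' mean end-state crowding indices over surviving runs.
#'
#' @param runs List of `rrl_sim` objects from the same parameter cell.
#' @param params The cell's [demography_params()].
#' @param movement The cell's [movement_params()].
#' @param domain A [torus_domain()].
#' @return One-row data frame of summary statistics.
#' @export
summarize_runs <- function(runs, params, movement, domain) {
  stopifnot(length(runs) >= 1)
  mass <- kernel_retained_mass(params$kernel)
  Nf <- vapply(runs, function(r) nrow(r$snapshot), numeric(1))
  K <- normalized_carrying_capacity(Nf, domain, params$b, params$d0,
                                    params$gamma, mass)
  ext <- vapply(runs, function(r) isTRUE(r$extinct), logical(1))
  surv <- which(!ext & Nf >= 2)
  cpos <- chr <- NA_real_
  if (length(surv) > 0) {
    cpos <- mean(vapply(surv, function(i)
      crowding_from_positions(runs[[i]]$snapshot, params$kernel, domain)$value,
      numeric(1)))
    sr2 <- if (is.finite(movement$sigma_r2)) movement$sigma_r2 else NA_real_
    if (!is.na(sr2))
      chr <- mean(vapply(surv, function(i)
        crowding_from_home_ranges(runs[[i]]$snapshot, sr2, params$kernel,
                                  domain)$value, numeric(1)))
  }
  q <- stats::quantile(K, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  data.frame(n_reps = length(runs),
             K_median = q[2], K_mean = mean(K), K_q05 = q[1], K_q95 = q[3],
             extinction_fraction = mean(ext),
             c_pos = cpos, c_hr = chr)
}

#' Deterministic per-replicate seeds
#'
#' Splits a master seed into per-(cell, replicate) seeds with a fixed affine
#' scheme so any sweep cell can be re-run in isolation and reproduced
#' bit-exactly.
#'
#' @param master Master seed (integer).
#' @param cell Cell index (1-based).
#' @param rep Replicate index (1-based).
#' @return Integer seed below 2^31.
#' @export
sweep_seed <- function(master, cell, rep) {
  as.integer((as.numeric(master) + 7919 * cell + 104729 * rep) %% 2147483647)
}

#' Run a replicate sweep over movement/kernel parameter cells
#'
#' Runs the IBM for every row of `cells` (a data frame with columns `mode`,
#' `sigma_q`, `sigma_d`, and optionally `tau`, `sigma_r2`, `D`) with
#' `replicates` independent runs per cell, and returns per-cell summaries
#' plus per-run results. Seeds derive deterministically from `seed` via
#' [sweep_seed()], so the whole sweep reproduces bit-exactly. Sweeps over
#' home-range size at fixed diffusion (vary `tau`, derive
#' `sigma_r2 = D * tau`) can be expressed by supplying `tau` and `D` columns.
#'
#' @param cells Data frame of parameter cells.
#' @param replicates Runs per cell.
#' @param events Gillespie event budget per run.
#' @param n0 Initial abundance.
#' @param b,d0,gamma Demographic rates.
#' @param trunc_mult Kernel truncation multiplier.
#' @param dispersal_family Dispersal kernel family (see [dispersal_spec()]).
#' @param domain A [torus_domain()].
#' @param seed Master seed.
#' @param record_stride Abundance-series thinning for the per-run results.
#' @return List with `summary` (one row per cell: cell parameters,
#'   home-range area, K statistics, extinction fraction, crowding means) and
#'   `runs` (one row per run: cell, rep, seed, final N, normalised K,
#'   extinct, end-state crowding estimates).
#' @export
run_sweep <- function(cells, replicates = 5, events = 2e5, n0 = 700,
                      b = 1.5, d0 = 0.1, gamma = 0.002, trunc_mult = 2.45,
                      dispersal_family = "gaussian",
                      domain = torus_domain(1), seed = 1,
                      record_stride = 1000L) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1, replicates >= 1)
  summaries <- vector("list", nrow(cells))
  run_rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    mv <- cell_movement(cell)
    dem <- demography_params(b, d0, gamma,
                             kernel = kernel_spec(cell$sigma_q, trunc_mult),
                             dispersal = dispersal_spec(cell$sigma_d,
                                                        dispersal_family))
    runs <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      s <- sweep_seed(seed, ci, r)
      runs[[r]] <- tryCatch(
        simulate_rrl(n0, events, dem, mv, domain, seed = s,
                     record_stride = record_stride),
        error = function(e) e)
    }
    failed <- vapply(runs, inherits, logical(1), "error")
    if (any(failed)) {
      warning("cell ", ci, ": ", sum(failed), " replicate(s) failed: ",
              conditionMessage(runs[[which(failed)[1]]]))
      runs <- runs[!failed]
    }
    mass <- kernel_retained_mass(dem$kernel)
    for (r in seq_along(runs)) {
      rn <- runs[[r]]
      Nf <- nrow(rn$snapshot)
      cp <- if (Nf >= 2)
        crowding_from_positions(rn$snapshot, dem$kernel, domain)$value
      else NA_real_
      chr <- if (Nf >= 2 && is.finite(mv$sigma_r2))
        crowding_from_home_ranges(rn$snapshot, mv$sigma_r2, dem$kernel,
                                  domain)$value
      else NA_real_
      run_rows[[length(run_rows) + 1L]] <- data.frame(
        cell = ci, rep = r, seed = rn$seed, N_final = Nf,
        K = normalized_carrying_capacity(Nf, domain, b, d0, gamma, mass),
        extinct = rn$extinct, c_pos = cp, c_hr = chr)
    }
    summ <- if (length(runs) > 0)
      summarize_runs(runs, dem, mv, domain)
    else data.frame(n_reps = 0, K_median = NA, K_mean = NA, K_q05 = NA,
                    K_q95 = NA, extinction_fraction = NA,
                    c_pos = NA, c_hr = NA)
    hr <- if (is.finite(mv$sigma_r2)) home_range_area(mv$sigma_r2) else Inf
    summaries[[ci]] <- cbind(cell = ci, as.data.frame(cell),
                             sigma_r2_used = mv$sigma_r2,
                             hr_area_95 = hr, summ)
  }
  list(summary = do.call(rbind, summaries),
       runs = do.call(rbind, run_rows),
       seed = seed,
       percentile_convention = "linear interpolation (quantile type 7)")
}

# build movement_params from one sweep-cell row
cell_movement <- function(cell) {
  mode <- toupper(as.character(cell$mode))
  if (mode == "SESSILE") return(movement_params("SESSILE"))
  if (mode == "BM") return(movement_params("BM", D = cell$D))
  tau <- if ("tau" %in% names(cell) && is.finite(cell$tau)) cell$tau else NULL
  sr2 <- if ("sigma_r2" %in% names(cell) && is.finite(cell$sigma_r2))
    cell$sigma_r2 else NULL
  D <- if ("D" %in% names(cell) && is.finite(cell$D)) cell$D else NULL
  movement_params("OU", tau = tau, sigma_r2 = sr2, D = D)
}
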