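#' Demographic parameters
#'
#' Birth is density independent at rate `b`; death is density dependent:
#' organism `i` dies at rate `d0 + gamma * sum_j Kc(x_i - x_j)` where the sum
#' runs over all other organisms weighted by the competition kernel at the
#' minimum-image displacement.
#'
#' @param b Intrinsic birth rate (1/time), non-negative.
#' @param d0 Baseline death rate (1/time), non-negative.
#' @param gamma Competition strength (rate x area), non-negative.
#' @param kernel A [kernel_spec()].
#' @param dispersal A [dispersal_spec()].
#' @return Object of class `rrl_demography`.
#' @examples
#' demography_params(kernel = kernel_spec(0.01), dispersal = dispersal_spec(0.1))
#' @export
demography_params <- function(b = 1.5, d0 = 0.1, gamma = 0.002,
                              kernel, dispersal) {
  stopifnot(b >= 0, d0 >= 0, gamma >= 0,
            inherits(kernel, "rrl_kernel"),
            inherits(dispersal, "rrl_dispersal"))
  structure(list(b = as.numeric(b), d0 = as.numeric(d0),
                 gamma = as.numeric(gamma),
                 kernel = kernel, dispersal = dispersal),
            class = "rrl_demography")
}

#' Initialise a population
#'
#' Draws `n0` home-range centres independently and uniformly on the torus and
#' positions from each organism's stationary space-use rule (the centre for
#' sessile organisms, `N(mu, sigma_r2 I)` for OU, uniform for BM).
#'
#' @param n0 Initial number of organisms (non-negative integer).
#' @param domain A [torus_domain()].
#' @param movement A [movement_params()].
#' @return An `rrl_population`: a data frame with columns
#'   `id, mu_x, mu_y, x, y` plus attributes `t` (clock, 0) and `domain`.
#' @examples
#' set.seed(1)
#' pop <- init_population(10, torus_domain(1), movement_params("SESSILE"))
#' @export
init_population <- function(n0, domain, movement) {
  stopifnot(n0 >= 0, n0 == round(n0))
  mu <- matrix(stats::runif(2 * n0, 0, domain$L), ncol = 2)
  x <- if (n0 > 0) sample_stationary_position(mu, movement, domain)
       else matrix(numeric(0), ncol = 2)
  pop <- data.frame(id = seq_len(n0),
                    mu_x = mu[, 1], mu_y = mu[, 2],
                    x = x[, 1], y = x[, 2])
  attr(pop, "t") <- 0
  attr(pop, "domain") <- domain
  attr(pop, "next_id") <- n0 + 1L
  class(pop) <- c("rrl_population", "data.frame")
  pop
}

#' Per-organism death rates
#'
#' `d_i = d0 + gamma * sum_{j != i} Kc(min_image(x_i, x_j))`, with the sum
#' restricted to pairs inside the truncation radius. `method = "reference"`
#' is a vectorised all-pairs implementation in R kept as an independent check
#' of the compiled grid-hash path used by the simulation engine.
#'
#' @param pop An `rrl_population` (or data frame with `x`, `y` columns).
#' @param params A [demography_params()].
#' @param domain A [torus_domain()].
#' @param method `"grid"` (compiled, used by the engine) or `"reference"`.
#' @return Numeric vector of death rates, one per organism.
#' @examples
#' set.seed(1)
#' pop <- init_population(5, torus_domain(1), movement_params("SESSILE"))
#' dem <- demography_params(kernel = kernel_spec(0.01),
#'                          dispersal = dispersal_spec(0.1))
#' death_rates(pop, dem, torus_domain(1))
#' @export
death_rates <- function(pop, params, domain, method = c("grid", "reference")) {
  method <- match.arg(method)
  n <- nrow(pop)
  if (n == 0) return(numeric(0))
  if (method == "grid") {
    return(cpp_death_rates(pop$x, pop$y, domain$L, params$d0, params$gamma,
                           params$kernel$sigma_q, params$kernel$trunc_mult))
  }
  wx <- wrap_torus(pop$x, domain)
  wy <- wrap_torus(pop$y, domain)
  dx <- outer(wx, wx, function(a, b) min_image1_r(b - a, domain$L))
  dy <- outer(wy, wy, function(a, b) min_image1_r(b - a, domain$L))
  u <- cbind(as.vector(dx), as.vector(dy))
  kv <- matrix(kernel_value(u, params$kernel, domain), n, n)
  diag(kv) <- 0
  params$d0 + params$gamma * rowSums(kv)
}

# scalar/vector minimum-image for coordinate differences
min_image1_r <- function(d, L) {
  d <- d %% L
  d[d >= L] <- 0
  d - L * (d >= L / 2)
}

#' Advance the population by one Gillespie event
#'
#' One step of the event-driven dynamics: (1) per-capita rates are computed
#' from the current (pre-move) positions, total birth rate `B = b N` and
#' total death rate `Dtot = sum d_i`; (2) an exponential waiting time
#' `dt ~ Exp(B + Dtot)` is drawn; (3) every organism's position is advanced
#' by `dt` with [propagate()]; (4) a birth is selected with probability
#' `B / (B + Dtot)`, otherwise a death with per-organism probability
#' `d_i / Dtot` (rates frozen from step 1); (5) a birth adds an organism with
#' centre `wrap(parent centre + dispersal draw)` and a stationary-draw
#' position, a death removes the selected organism; (6) the clock advances.
#'
#' This pure-R step is the readable reference for the compiled engine used by
#' [simulate_rrl()]; both implement the same event algebra.
#'
#' @param pop An `rrl_population` with at least one organism.
#' @param params A [demography_params()].
#' @param movement A [movement_params()].
#' @param domain A [torus_domain()].
#' @return A list with elements `state` (the new population) and `event`
#'   (list: `type` "birth"/"death", `dt`, `t`, `id` of the organism added or
#'   removed).
#' @export
gillespie_step <- function(pop, params, movement, domain) {
  n <- nrow(pop)
  if (n == 0) stop("population is extinct; cannot step")
  dr <- death_rates(pop, params, domain)
  B <- params$b * n
  Dtot <- sum(dr)
  dt <- stats::rexp(1, rate = B + Dtot)
  xy <- propagate(cbind(pop$x, pop$y), cbind(pop$mu_x, pop$mu_y), dt, movement)
  pop$x <- xy[, 1]; pop$y <- xy[, 2]
  t_new <- attr(pop, "t") + dt
  if (stats::runif(1) * (B + Dtot) < B) {
    parent <- sample.int(n, 1)
    u <- sample_dispersal(params$dispersal, 1)
    mu_new <- wrap_torus(c(pop$mu_x[parent], pop$mu_y[parent]) + drop(u), domain)
    x_new <- sample_stationary_position(mu_new, movement, domain)
    new_id <- attr(pop, "next_id")
    row <- data.frame(id = new_id, mu_x = mu_new[1], mu_y = mu_new[2],
                      x = x_new[1], y = x_new[2])
    out <- rbind(as.data.frame(pop), row)
    attr(out, "next_id") <- new_id + 1L
    ev <- list(type = "birth", dt = dt, t = t_new, id = new_id)
  } else {
    victim <- sample.int(n, 1, prob = dr)
    ev <- list(type = "death", dt = dt, t = t_new, id = pop$id[victim])
    out <- as.data.frame(pop)[-victim, , drop = FALSE]
    attr(out, "next_id") <- attr(pop, "next_id")
  }
  attr(out, "t") <- t_new
  attr(out, "domain") <- domain
  class(out) <- c("rrl_population", "data.frame")
  list(state = out, event = ev)
}

#' Run the range-resident logistic IBM
#'
#' Event-driven simulation of the birth-dispersal-death dynamics with
#' movement, run until the event budget is exhausted or the population goes
#' extinct (an absorbing state, recorded explicitly). With `engine = "cpp"`
#' (default) the compiled core is used: death rates are maintained with a
#' grid-hash neighbour search and, for sessile populations, updated
#' incrementally after each event. `engine = "r"` loops [gillespie_step()]
#' and is intended for small runs and cross-checks.
#'
#' @param n0 Initial number of organisms (uniform centres; stationary positions).
#' @param events Event budget.
#' @param params A [demography_params()].
#' @param movement A [movement_params()].
#' @param domain A [torus_domain()].
#' @param seed Optional integer; if given, `set.seed(seed)` is called so the
#'   run is reproducible.
#' @param record_stride Record every `record_stride`-th event in the
#'   abundance series (1 = every event).
#' @param init Optional `rrl_population` to start from instead of drawing a
#'   fresh uniform population.
#' @param engine `"cpp"` or `"r"`.
#' @return An object of class `rrl_sim`: list with `abundance` (data frame
#'   `t`, `N`, `event` in \{"init", "birth", "death"\}), `snapshot` (final
#'   `rrl_population`), `t_final`, `events`, `births`, `deaths`, `extinct`,
#'   `seed`, and `config` (parameter echo).
#' @examples
#' dem <- demography_params(kernel = kernel_spec(0.01),
#'                          dispersal = dispersal_spec(0.1))
#' sim <- simulate_rrl(50, 200, dem, movement_params("SESSILE"),
#'                     torus_domain(1), seed = 1)
#' sim
#' @export
simulate_rrl <- function(n0, events, params, movement, domain = torus_domain(1),
                         seed = NULL, record_stride = 1L, init = NULL,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(events >= 0, record_stride >= 1)
  if (!is.null(seed)) set.seed(seed)
  pop <- if (is.null(init)) init_population(n0, domain, movement) else init
  cfg <- list(n0 = nrow(pop), events = events,
              b = params$b, d0 = params$d0, gamma = params$gamma,
              sigma_q = params$kernel$sigma_q,
              trunc_mult = params$kernel$trunc_mult,
              dispersal = params$dispersal[c("family", "sigma_d", "shape", "scale")],
              movement = unclass(movement), L = domain$L)

  if (engine == "cpp") {
    disp <- params$dispersal
    res <- cpp_simulate(pop$mu_x, pop$mu_y, pop$x, pop$y,
                        as.integer(pop$id), as.integer(attr(pop, "next_id")),
                        domain$L, params$b, params$d0, params$gamma,
                        params$kernel$sigma_q, params$kernel$trunc_mult,
                        if (disp$family == "gaussian") 0L else 1L,
                        disp$sigma_d,
                        ifelse(is.na(disp$shape), 1, disp$shape),
                        ifelse(is.na(disp$scale), 1, disp$scale),
                        switch(movement$mode, SESSILE = 0L, OU = 1L, BM = 2L),
                        ifelse(is.finite(movement$tau), movement$tau, 1),
                        ifelse(is.finite(movement$sigma_r2), movement$sigma_r2, 1),
                        movement$D,
                        as.integer(events), as.integer(record_stride))
    snap <- data.frame(id = res$id, mu_x = res$mu_x, mu_y = res$mu_y,
                       x = res$x, y = res$y)
    attr(snap, "t") <- res$t_final
    attr(snap, "domain") <- domain
    attr(snap, "next_id") <- res$next_id
    class(snap) <- c("rrl_population", "data.frame")
    ab <- data.frame(t = res$t, N = res$N,
                     event = c("init", "birth", "death")[res$event + 1L])
    out <- list(abundance = ab, snapshot = snap, t_final = res$t_final,
                events = res$events, births = res$births, deaths = res$deaths,
                extinct = res$extinct, seed = seed, config = cfg)
  } else {
    ab_t <- numeric(events + 1); ab_N <- integer(events + 1)
    ab_e <- character(events + 1)
    ab_t[1] <- attr(pop, "t"); ab_N[1] <- nrow(pop); ab_e[1] <- "init"
    births <- 0L; deaths <- 0L; extinct <- nrow(pop) == 0
    ev <- 0L
    while (ev < events && nrow(pop) > 0) {
      st <- gillespie_step(pop, params, movement, domain)
      pop <- st$state
      ev <- ev + 1L
      if (st$event$type == "birth") births <- births + 1L else deaths <- deaths + 1L
      ab_t[ev + 1] <- st$event$t; ab_N[ev + 1] <- nrow(pop)
      ab_e[ev + 1] <- st$event$type
    }
    extinct <- nrow(pop) == 0
    idx <- seq_len(ev)
    keep <- c(0L, idx[idx %% record_stride == 0 | idx == ev]) + 1L
    keep <- unique(keep)
    ab <- data.frame(t = ab_t[keep], N = ab_N[keep], event = ab_e[keep])
    out <- list(abundance = ab, snapshot = pop, t_final = attr(pop, "t"),
                events = ev, births = births, deaths = deaths,
                extinct = extinct, seed = seed, config = cfg)
  }
  class(out) <- "rrl_sim"
  out
}

#' @export
print.rrl_sim <- function(x, ...) {
  cat("Range-resident logistic IBM run\n")
  cat("  events:", x$events, " final N:", nrow(x$snapshot),
      " t_final:", signif(x$t_final, 5), "\n")
  cat("  births:", x$births, " deaths:", x$deaths,
      if (x$extinct) " (extinct)" else "", "\n")
  invisible(x)
}
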