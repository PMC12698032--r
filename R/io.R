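#' Read and write population snapshots
#'
#' Snapshots are plain-text CSV tables with header `id,mu_x,mu_y,x,y`, one
#' row per organism, coordinates in domain units: `mu_*` are home-range
#' centres and `x`, `y` current positions.
#'
#' @param path File path.
#' @param domain A [torus_domain()] attached to the population on read.
#' @return `read_snapshot` returns an `rrl_population`.
#' @export
read_snapshot <- function(path, domain = torus_domain(1)) {
  df <- utils::read.csv(path)
  need <- c("id", "mu_x", "mu_y", "x", "y")
  if (!all(need %in% names(df)))
    stop("snapshot must have columns ", paste(need, collapse = ","))
  df <- df[need]
  attr(df, "t") <- NA_real_
  attr(df, "domain") <- domain
  attr(df, "next_id") <- if (nrow(df)) max(df$id) + 1L else 1L
  class(df) <- c("rrl_population", "data.frame")
  df
}

#' @param pop An `rrl_population` (or data frame with the snapshot columns).
#' @rdname read_snapshot
#' @export
write_snapshot <- function(pop, path) {
  utils::write.csv(as.data.frame(pop)[c("id", "mu_x", "mu_y", "x", "y")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a simulation configuration file
#'
#' Configurations are YAML with sections `domain` (`L`), `kernel`
#' (`sigma_q`, `trunc_mult`), `dispersal` (`family`, `sigma_d`), `movement`
#' (`mode`, `tau`, `sigma_r2`, `D`), `demography` (`b`, `d0`, `gamma`) and
#' `sim` (`events`, `n0`, `replicates`, `seed`). Missing optional keys take
#' the documented defaults; unknown sections or keys are an error (strict
#' validation).
#'
#' @param path Path to a YAML configuration file.
#' @return A validated config list with components `domain`, `params`
#'   (demography), `movement`, and `sim`.
#' @export
read_rrl_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- list(
    domain = c("L"),
    kernel = c("sigma_q", "trunc_mult"),
    dispersal = c("family", "sigma_d", "shape", "scale"),
    movement = c("mode", "tau", "sigma_r2", "D"),
    demography = c("b", "d0", "gamma"),
    sim = c("events", "n0", "replicates", "seed", "record_stride"))
  bad <- setdiff(names(raw), names(known))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (s in names(raw)) {
    extra <- setdiff(names(raw[[s]]), known[[s]])
    if (length(extra))
      stop("unknown key(s) in [", s, "]: ", paste(extra, collapse = ", "))
  }
  g <- function(sec, key, default = NULL) {
    v <- raw[[sec]][[key]]
    if (is.null(v)) default else v
  }
  domain <- torus_domain(g("domain", "L", 1))
  kern <- kernel_spec(g("kernel", "sigma_q", 0.01),
                      g("kernel", "trunc_mult", 2.45))
  disp <- dispersal_spec(g("dispersal", "sigma_d", 0.1),
                         g("dispersal", "family", "gaussian"),
                         shape = g("dispersal", "shape", 3),
                         scale = g("dispersal", "scale", NULL))
  mv <- movement_params(g("movement", "mode", "OU"),
                        tau = g("movement", "tau", NULL),
                        sigma_r2 = g("movement", "sigma_r2", NULL),
                        D = g("movement", "D", NULL))
  params <- demography_params(g("demography", "b", 1.5),
                              g("demography", "d0", 0.1),
                              g("demography", "gamma", 0.002),
                              kernel = kern, dispersal = disp)
  sim <- list(events = g("sim", "events", 1e6),
              n0 = g("sim", "n0", 700),
              replicates = g("sim", "replicates", 1),
              seed = g("sim", "seed", NULL),
              record_stride = g("sim", "record_stride", 1L))
  list(domain = domain, params = params, movement = mv, sim = sim)
}

#' Run a simulation from a configuration
#'
#' Convenience wrapper: `run_simulation(read_rrl_config(path))` is the
#' programmatic equivalent of the command-line `simulate` subcommand.
#'
#' @param config A config list from [read_rrl_config()] (or built by hand
#'   with the same shape).
#' @param seed Optional override of `sim.seed`.
#' @return An `rrl_sim` (single replicate) or list of them
#'   (`sim.replicates > 1`, seeds split with [sweep_seed()]).
#' @export
run_simulation <- function(config, seed = NULL) {
  s <- if (!is.null(seed)) seed else config$sim$seed
  reps <- config$sim$replicates
  one <- function(si) simulate_rrl(config$sim$n0, config$sim$events,
                                   config$params, config$movement,
                                   config$domain, seed = si,
                                   record_stride = config$sim$record_stride)
  if (reps <= 1) return(one(s))
  lapply(seq_len(reps), function(r) one(sweep_seed(s, 1, r)))
}

#' Write run metadata as JSON
#'
#' @param sim An `rrl_sim`.
#' @param path Output path.
#' @export
write_meta <- function(sim, path) {
  meta <- list(config = sim$config, seed = sim$seed, events = sim$events,
               births = sim$births, deaths = sim$deaths,
               extinct = sim$extinct, t_final = sim$t_final,
               package_version = as.character(utils::packageVersion("rrlogistic")))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
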