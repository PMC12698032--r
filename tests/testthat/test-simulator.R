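dom <- torus_domain(1)
dem <- demography_params(b = 1.5, d0 = 0.1, gamma = 0.002,
                         kernel = kernel_spec(0.01),
                         dispersal = dispersal_spec(0.1))
ss <- movement_params("SESSILE")

make_pop <- function(x, y, mu_x = x, mu_y = y) {
  pop <- data.frame(id = seq_along(x), mu_x = mu_x, mu_y = mu_y, x = x, y = y)
  attr(pop, "t") <- 0; attr(pop, "domain") <- dom
  attr(pop, "next_id") <- length(x) + 1L
  class(pop) <- c("rrl_population", "data.frame")
  pop
}

test_that("death rates follow baseline-plus-kernel-sum arithmetic", {
  # isolated organisms: no neighbour within the truncation radius
  pop <- make_pop(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(death_rates(pop, dem, dom), rep(0.1, 3))
  # one coincident neighbour: d0 + gamma * Gaussian peak
  pop2 <- make_pop(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(death_rates(pop2, dem, dom),
               rep(0.1 + 0.002 / (2 * pi * 1e-4), 2))
  expect_equal(death_rates(pop2, dem, dom)[1], 3.2831, tolerance = 1e-4)
  # competition off
  dem0 <- demography_params(1.5, 0.1, 0, kernel = dem$kernel,
                            dispersal = dem$dispersal)
  set.seed(31)
  pop3 <- init_population(100, dom, ss)
  expect_equal(death_rates(pop3, dem0, dom), rep(0.1, 100))
})

test_that("grid-hash rates equal reference and brute-force oracles, including across the boundary", {
  set.seed(32)
  pop <- init_population(300, dom, ss)
  fast <- death_rates(pop, dem, dom, method = "grid")
  ref <- death_rates(pop, dem, dom, method = "reference")
  oracle <- brute_death_rates(pop$x, pop$y, 1, 0.1, 0.002, 0.01, 2.45)
  expect_equal(fast, ref, tolerance = 1e-12)
  expect_equal(fast, oracle, tolerance = 1e-12)
  # wide kernel exercises the periodic image-sum path
  demw <- demography_params(kernel = kernel_spec(0.3), dispersal = dem$dispersal)
  set.seed(33)
  popw <- init_population(60, dom, ss)
  expect_equal(death_rates(popw, demw, dom, method = "grid"),
               death_rates(popw, demw, dom, method = "reference"),
               tolerance = 1e-10)
})

test_that("initial populations are uniform with stationary positions", {
  set.seed(34)
  pop <- init_population(700, dom, ss)
  expect_equal(nrow(pop), 700)
  expect_true(all(pop$mu_x >= 0 & pop$mu_x < 1 & pop$mu_y >= 0 & pop$mu_y < 1))
  expect_identical(pop$x, pop$mu_x) # sessile positions are the centres
  expect_equal(nrow(init_population(0, dom, ss)), 0)
  # CSR chi-square on a 10x10 grid passes for nearly all seeds
  passes <- sum(vapply(1:100, function(s) {
    set.seed(1000 + s)
    p <- init_population(700, dom, ss)
    csr_grid_ok(p$mu_x, p$mu_y, 1)
  }, logical(1)))
  expect_gte(passes, 97)
})

test_that("waiting times are exponential with the total event rate", {
  # single organism: total rate b + d0, mean waiting time 1/(b + d0)
  set.seed(35)
  dts <- replicate(1e4, {
    pop <- make_pop(0.5, 0.5)
    gillespie_step(pop, dem, ss, dom)$event$dt
  })
  expect_equal(mean(dts), 1 / 1.6, tolerance = 4 / sqrt(1e4) / 1.6)
  expect_equal(1 / 1.6, 0.625)
})

test_that("event bookkeeping is exact: |dN| = 1, conservation, monotone without births", {
  set.seed(36)
  s <- simulate_rrl(80, 500, dem, ss, dom)
  dN <- diff(s$abundance$N)
  expect_true(all(abs(dN) == 1))
  expect_true(all(s$abundance$event[-1] %in% c("birth", "death")))
  expect_equal((dN == 1), (s$abundance$event[-1] == "birth"))
  expect_equal(s$births - s$deaths, nrow(s$snapshot) - 80)
  # no birth channel: abundance never increases, run ends at extinction or budget
  demb0 <- demography_params(0, 0.1, 0.002, kernel = dem$kernel,
                             dispersal = dem$dispersal)
  set.seed(37)
  s0 <- simulate_rrl(50, 500, demb0, ss, dom)
  expect_true(all(diff(s0$abundance$N) <= 0))
  expect_true(s0$extinct)
  expect_equal(s0$abundance$N[nrow(s0$abundance)], 0)
})

test_that("same seed reproduces the run bit-exactly; engines agree on event statistics", {
  a <- simulate_rrl(60, 400, dem, ss, dom, seed = 99)
  b <- simulate_rrl(60, 400, dem, ss, dom, seed = 99)
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$snapshot$x, b$snapshot$x)
  # R and compiled engines implement the same dynamics (statistical check)
  set.seed(40)
  nr <- replicate(6, nrow(simulate_rrl(60, 300, dem, ss, dom, engine = "r")$snapshot))
  set.seed(41)
  nc <- replicate(6, nrow(simulate_rrl(60, 300, dem, ss, dom, engine = "cpp")$snapshot))
  expect_lt(abs(mean(nr) - mean(nc)),
            4 * sqrt(var(nr) / 6 + var(nc) / 6) + 1e-9)
})

test_that("sessile organisms never move: positions are bit-identical to centres for life", {
  s <- simulate_rrl(120, 2000, dem, ss, dom, seed = 43)
  expect_identical(s$snapshot$x, s$snapshot$mu_x)
  expect_identical(s$snapshot$y, s$snapshot$mu_y)
})

test_that("OU and BM runs keep centres in the domain and stay consistent", {
  mv <- movement_params("OU", tau = 0.05, sigma_r2 = 1e-3)
  s <- simulate_rrl(100, 1500, dem, mv, dom, seed = 44)
  expect_true(all(s$snapshot$mu_x >= 0 & s$snapshot$mu_x < 1))
  expect_equal(s$births - s$deaths, nrow(s$snapshot) - 100)
  expect_false(identical(s$snapshot$x, s$snapshot$mu_x)) # OU positions wander
})

test_that("extinction terminates the run and is recorded", {
  # overwhelming competition: everyone coincident, tiny dispersal
  demx <- demography_params(b = 0.01, d0 = 2, gamma = 0.002,
                            kernel = dem$kernel, dispersal = dem$dispersal)
  set.seed(45)
  s <- simulate_rrl(10, 5000, demx, ss, dom)
  expect_true(s$extinct)
  expect_equal(nrow(s$snapshot), 0)
  expect_lt(s$events, 5000)
  expect_error(gillespie_step(s$snapshot, dem, ss, dom), "extinct")
})

test_that("a domain-wide flat kernel recovers the non-spatial logistic capacity", {
  demf <- demography_params(kernel = kernel_spec(1), dispersal = dem$dispersal)
  K <- vapply(1:3, function(s) {
    r <- simulate_rrl(700, 3e4, demf, ss, dom, seed = 500 + s,
                      record_stride = 10)
    ab <- r$abundance
    mean(ab$N[ab$t > max(ab$t) / 2]) /
      (700 / kernel_retained_mass(demf$kernel))
  }, numeric(1))
  se <- sd(K) / sqrt(3)
  expect_lt(abs(mean(K) - 1), 3 * se + 0.02)
})
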