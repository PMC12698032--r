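dom <- torus_domain(1)
ks <- kernel_spec(0.01)

test_that("CSR patterns have unit crowding on average (both estimators)", {
  vals <- t(vapply(1:100, function(s) {
    set.seed(2000 + s)
    pop <- generate_fixture("csr", n = 50, domain = dom)
    c(crowding_from_positions(pop, ks, dom)$value,
      crowding_from_home_ranges(pop, 0.002, ks, dom)$value)
  }, numeric(2)))
  for (k in 1:2) {
    se <- sd(vals[, k]) / sqrt(nrow(vals))
    expect_lt(abs(mean(vals[, k]) - 1), 4 * se)
  }
})

test_that("two coincident points give the renormalised kernel peak", {
  pop <- generate_fixture("two_point", domain = dom, separation = 0)
  got <- crowding_from_positions(pop, ks, dom)
  expect_equal(got$value,
               1 / (kernel_retained_mass(ks) * 2 * pi * ks$sigma_q^2))
  expect_equal(got$n_points, 2)
  # brute-force ordered-pair sum oracle
  brute <- dom$A / 2 * 2 * kernel_value(c(0, 0), ks) / kernel_retained_mass(ks)
  expect_equal(got$value, brute)
  expect_error(crowding_from_positions(pop[1, ], ks, dom), "fewer than 2")
})

test_that("patterns with all pairs beyond the truncation radius score zero", {
  pop <- generate_fixture("lattice", n = 100, domain = dom) # spacing 0.1
  expect_equal(crowding_from_positions(pop, ks, dom)$value, 0)
})

test_that("adding a coincident duplicate never decreases positional crowding", {
  set.seed(61)
  pop <- generate_fixture("csr", n = 60, domain = dom)
  c0 <- crowding_from_positions(pop, ks, dom)$value
  dup <- rbind(as.data.frame(pop), as.data.frame(pop)[1, ])
  c1 <- crowding_from_positions(dup, ks, dom)$value
  expect_gte(c1, c0)
})

test_that("composed home-range kernel matches its Monte-Carlo convolution oracle", {
  sq <- 0.01; s2 <- 5e-4
  # oracle: E[Kc(u + d2 - d1)] with d1, d2 ~ N(0, s2 I), untruncated Kc
  set.seed(62)
  n <- 1e6
  for (u in list(c(0, 0), c(0.02, 0.01), c(0.05, 0))) {
    delta <- matrix(rnorm(2 * n, sd = sqrt(s2)), ncol = 2) -
      matrix(rnorm(2 * n, sd = sqrt(s2)), ncol = 2)
    ux <- u[1] + delta[, 1]; uy <- u[2] + delta[, 2]
    kvals <- exp(-(ux^2 + uy^2) / (2 * sq^2)) / (2 * pi * sq^2)
    mc <- mean(kvals); se <- sd(kvals) / sqrt(n)
    expect_lt(abs(khr_value(u, sq, s2) - mc), 4 * se + 1e-12)
  }
  # sessile limit reduces to the untruncated competition kernel
  expect_equal(khr_value(c(0.005, 0.002), sq, 0),
               kernel_value(c(0.005, 0.002), kernel_spec(sq, trunc_mult = 50)))
  expect_equal(khr_value(c(0, 0), sq, s2), 1 / (2 * pi * (sq^2 + 2 * s2)))
})

test_that("home-range crowding reduces to positional crowding in the sessile limit", {
  set.seed(63)
  pop <- generate_fixture("thomas", domain = dom, kappa = 25, sigma_c = 0.02)
  cpos <- crowding_from_positions(pop, ks, dom)$value
  chr0 <- crowding_from_home_ranges(pop, 0, ks, dom)$value
  # same kernel scale; the estimators differ only in truncation handling
  expect_equal(chr0, cpos, tolerance = 0.02)
})

test_that("fast-movement OU snapshots give matching position and home-range crowding", {
  dem <- demography_params(kernel = kernel_spec(0.02),
                           dispersal = dispersal_spec(0.05))
  mv <- movement_params("OU", tau = 0.02, sigma_r2 = 2e-3) # tau*(b+d0) = 0.032
  reps <- lapply(1:3, function(s)
    simulate_rrl(400, 3e4, dem, mv, dom, seed = 700 + s, record_stride = 100))
  cp <- vapply(reps, function(r)
    crowding_from_positions(r$snapshot, dem$kernel, dom)$value, numeric(1))
  ch <- vapply(reps, function(r)
    crowding_from_home_ranges(r$snapshot, 2e-3, dem$kernel, dom)$value,
    numeric(1))
  se <- sqrt(var(cp) / 3 + var(ch) / 3)
  expect_lt(abs(mean(cp) - mean(ch)), 4 * se + 0.05 * mean(cp))
})

test_that("torus pair correlation is flat for CSR and matches the Thomas closed form", {
  set.seed(64)
  pop <- generate_fixture("csr", n = 700, domain = dom)
  breaks <- seq(0, 0.25, by = 0.025)
  g <- pair_correlation(pop, breaks, dom)
  # binomial error bands on ordered-pair counts
  expected <- 700 * 699 * pi * (g$r_hi^2 - g$r_lo^2)
  tolg <- 5 * sqrt(2 * expected) / expected
  expect_true(all(abs(g$g2 - 1) < tolg))
  expect_error(pair_correlation(pop, c(0, 0.6), dom), "L/2")

  # Thomas process: g2(r) = 1 + exp(-r^2/(4 sc^2)) / (4 pi kappa sc^2)
  kap <- 25; sc <- 0.02
  set.seed(65)
  pats <- lapply(1:40, function(i)
    generate_fixture("thomas", domain = dom, kappa = kap, sigma_c = sc,
                     mean_offspring = 6))
  breaks <- seq(0, 0.1, by = 0.01)
  gmat <- vapply(pats, function(p)
    pair_correlation(p, breaks, dom)$g2, numeric(10))
  gbar <- rowMeans(gmat)
  gse <- apply(gmat, 1, sd) / sqrt(ncol(gmat))
  # bin-averaged closed form (the pcf is steep at small r)
  gtheory <- vapply(seq_len(10), function(i) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    integrate(function(r)
      (1 + exp(-r^2 / (4 * sc^2)) / (4 * pi * kap * sc^2)) * 2 * r / (hi^2 - lo^2),
      lo, hi)$value
  }, numeric(1))
  expect_true(all(abs(gbar - gtheory) < 4 * gse + 0.02 * gtheory))
})

test_that("a hard-exclusion pattern is underdispersed at short range", {
  pop <- generate_fixture("lattice", n = 400, domain = dom) # spacing 0.05
  g <- pair_correlation(pop, c(0, 0.04, 0.08), dom)
  expect_equal(g$g2[1], 0)
  expect_gt(g$g2[2], 0)
})

test_that("Thomas-process crowding matches the truncation-corrected closed form", {
  kap <- 25; sc <- 0.02; sq <- 0.01
  kst <- kernel_spec(sq)
  # closed form: c = 1 + (1/kappa) * (trunc integral of Kc x N(0, 2 sc^2 I)) / mass
  rt <- 2.45 * sq
  integrand <- function(r)
    2 * pi * r * exp(-r^2 / (2 * sq^2)) / (2 * pi * sq^2) *
    exp(-r^2 / (4 * sc^2)) / (4 * pi * sc^2)
  I <- integrate(integrand, 0, rt, rel.tol = 1e-10)$value
  c_theory <- 1 + I / (kap * kernel_retained_mass(kst))
  # untruncated composition for reference: 1 + 1/(kappa 2 pi (sq^2 + 2 sc^2))
  expect_equal(1 + 1 / (kap * 2 * pi * (sq^2 + 2 * sc^2)),
               1 + integrate(integrand, 0, Inf, rel.tol = 1e-10)$value / kap,
               tolerance = 1e-6)
  set.seed(66)
  cvals <- vapply(1:60, function(i) {
    p <- generate_fixture("thomas", domain = dom, kappa = kap, sigma_c = sc,
                          mean_offspring = 6)
    crowding_from_positions(p, kst, dom)$value
  }, numeric(1))
  se <- sd(cvals) / sqrt(length(cvals))
  expect_lt(abs(mean(cvals) - c_theory), 4 * se)
})

test_that("positional crowding equals the kernel-weighted pcf integral", {
  set.seed(67)
  pop <- generate_fixture("thomas", domain = dom, kappa = 25, sigma_c = 0.02)
  sq <- 0.01
  kst <- kernel_spec(sq)
  rt <- 2.45 * sq
  breaks <- seq(0, rt, length.out = 200)
  g <- pair_correlation(pop, breaks, dom)
  quad <- sum(kernel_value(cbind(g$r_mid, 0), kst) * g$g2 *
                pi * (g$r_hi^2 - g$r_lo^2)) / kernel_retained_mass(kst)
  expect_equal(crowding_from_positions(pop, kst, dom)$value, quad,
               tolerance = 0.02)
})

test_that("covariance-form crowding is n^2 (c - 1)", {
  expect_equal(ccov_from_c(1, 123), 0)
  expect_equal(ccov_from_c(2, 700), 490000)
  expect_equal(ccov_from_c(5, 0), 0)
  expect_error(ccov_from_c(1, -1))
})
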