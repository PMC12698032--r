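# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force sums, naive integrators, closed forms.

# Euler-Maruyama integration of the OU Langevin equation (one component),
# n_paths independent paths over total time T with n_steps steps.
em_ou_paths <- function(x0, mu, tau, sigma_r2, T, n_steps, n_paths) {
  dt <- T / n_steps
  x <- rep(x0, n_paths)
  for (k in seq_len(n_steps)) {
    x <- x - (x - mu) * dt / tau +
      sqrt(2 * sigma_r2 / tau) * rnorm(n_paths, sd = sqrt(dt))
  }
  x
}

# 2-D quadrature of the truncated Gaussian kernel over the plane (midpoint
# rule on a fine grid); independent of the closed-form retained mass.
quad_kernel_mass <- function(sigma_q, trunc_mult, n = 801) {
  rt <- trunc_mult * sigma_q
  g <- seq(-rt, rt, length.out = n)
  h <- g[2] - g[1]
  xx <- outer(g, rep(1, n)); yy <- t(xx)
  r2 <- xx^2 + yy^2
  sum(exp(-r2 / (2 * sigma_q^2))[r2 <= rt^2]) / (2 * pi * sigma_q^2) * h^2
}

# chi-square CSR test on a k x k grid of counts; TRUE = consistent with CSR
csr_grid_ok <- function(x, y, L, k = 10, alpha = 0.01) {
  ix <- pmin(floor(x / L * k), k - 1)
  iy <- pmin(floor(y / L * k), k - 1)
  counts <- tabulate(1 + ix + k * iy, nbins = k * k)
  expected <- length(x) / (k * k)
  stat <- sum((counts - expected)^2 / expected)
  stat < qchisq(1 - alpha, df = k * k - 1)
}

# brute-force all-pairs death rates in plain R loops (no vectorised reuse of
# package helpers beyond arithmetic)
brute_death_rates <- function(x, y, L, d0, gamma, sigma_q, trunc_mult) {
  n <- length(x)
  rt2 <- (trunc_mult * sigma_q)^2
  out <- rep(d0, n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- x[j] - x[i]; dx <- dx - L * round(dx / L)
      dy <- y[j] - y[i]; dy <- dy - L * round(dy / L)
      r2 <- dx^2 + dy^2
      if (r2 <= rt2) s <- s + exp(-r2 / (2 * sigma_q^2)) / (2 * pi * sigma_q^2)
    }
    out[i] <- out[i] + gamma * s
  }
  out
}
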