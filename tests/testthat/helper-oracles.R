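# Independent oracles and fixture builders used across the suite.

# Classical fixed-step RK4 for dy/dt = f(t, y); independent of the package's
# analytic propagator.
rk4_integrate <- function(f, y0, t0, t1, dt = 0.01) {
  t <- t0
  y <- y0
  while (t < t1 - 1e-12) {
    h <- min(dt, t1 - t)
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# Two-compartment right-hand side with constant coefficients.
two_comp_rhs <- function(a, b, c, ksp) {
  function(t, y) c(a - b * y[1], ksp * y[1] - c * y[2])
}

# Brute-force OLS slope, written from the definition.
ols_slope_oracle <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# Build a single-trajectory timecourse from bare vectors.
make_tc <- function(time_min, value_fg, replicate = 1L, species = "spliced_mrna",
                    scenario = "test", condition = "mock", cell_line = "x") {
  timecourse(tibble::tibble(
    scenario = scenario, cell_line = cell_line, species = species,
    condition = condition, time_min = time_min,
    replicate = replicate, value_fg = value_fg))
}

# Replicated noisy timecourse around a mean trajectory (same noise model as
# the generator, applied independently here).
make_noisy_tc <- function(time_min, mean_fg, n_rep, cv, seed, ...) {
  set.seed(seed)
  sdlog <- sqrt(log1p(cv^2))
  n <- length(time_min) * n_rep
  fac <- if (cv > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
  make_tc(rep(time_min, n_rep), rep(mean_fg, n_rep) * fac,
          replicate = rep(seq_len(n_rep), each = length(time_min)), ...)
}

# Mass trajectory column of a simulation for a species.
sim_mass <- function(tr, species) {
  if (species == "pre_mrna") tr$P_mass_fg else tr$M_mass_fg
}
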