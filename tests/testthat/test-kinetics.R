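# Two-compartment model: exactness of the propagator, steady states,
# symmetry/monotonicity properties, parameter recovery.

test_that("no transcription and zero initial state stays identically zero", {
  p <- default_parameters("SOD_TO", k_tx = 0)
  tr <- simulate_minigene(p, experiment_design(seq(0, 300, 30)))
  expect_true(all(tr$P == 0) && all(tr$M == 0))
})

test_that("rho = 0 makes ASO treatment identical to mock", {
  des_aso <- experiment_design(seq(0, 360, 10), aso_add_min = 0)
  des_mock <- experiment_design(seq(0, 360, 10))
  p <- default_parameters("SOD_TO", rho = 0)
  tr_aso <- simulate_minigene(p, des_aso)
  tr_mock <- simulate_minigene(p, des_mock)
  expect_identical(tr_aso$P, tr_mock$P)
  expect_identical(tr_aso$M, tr_mock$M)
})

test_that("simulate matches an independent RK4 oracle on constant phases", {
  # induction phase, both species, no events inside the window
  p <- default_parameters("SOD_TO")
  grid <- seq(0, 100, 20)
  tr <- simulate_minigene(p, experiment_design(grid))
  f <- two_comp_rhs(a = p$k_tx * p$CN, b = p$k_sp + p$k_dn, c = p$k_dc,
                    ksp = p$k_sp)
  for (i in 2:length(grid)) {
    y <- rk4_integrate(f, c(0, 0), 0, grid[i], dt = 0.005)
    expect_equal(tr$P[i], y[1], tolerance = 1e-6)
    expect_equal(tr$M[i], y[2], tolerance = 1e-6)
  }
  # washout-with-cleavage phase from the steady state
  p2 <- default_parameters("SOD_TO", k1 = 0.03)
  ss <- steady_state(p2)
  kcl <- cleavage_constant(p2)
  tr2 <- simulate_minigene(
    p2, experiment_design(seq(0, 80, 20), tet_on_min = -Inf, tet_off_min = 0,
                          aso_add_min = 0, init_steady_state = TRUE))
  # cleavage switches on at tau_uptake+tau_scan+tau_recruit = 120 > 80,
  # so this phase has constant coefficients without cleavage
  f2 <- two_comp_rhs(a = 0, b = p2$k_sp + p2$k_dn, c = p2$k_dc, ksp = p2$k_sp)
  y <- rk4_integrate(f2, c(ss$P_ss, ss$M_ss), 0, 80, dt = 0.005)
  expect_equal(tr2$P[tr2$time_min == 80], y[1], tolerance = 1e-6)
  expect_equal(tr2$M[tr2$time_min == 80], y[2], tolerance = 1e-6)
})

test_that("splice-defective induction matches the scalar closed form", {
  p <- default_parameters("SOD187M_TO")  # k_sp = 0
  grid <- seq(0, 200, 10)
  tr <- simulate_minigene(p, experiment_design(grid))
  P_ss <- p$k_tx * p$CN / p$k_dn
  expect_equal(tr$P, P_ss * (1 - exp(-p$k_dn * grid)), tolerance = 1e-10)
  expect_true(all(tr$M == 0))
})

test_that("steady_state matches closed-form arithmetic and linearity", {
  p <- kinetic_parameters(k_tx = 10, CN = 6, k_sp = 0, k_dn = 0.01,
                          k_dc = 0.0069)
  expect_equal(steady_state(p)$P_ss, 6000)
  p2 <- kinetic_parameters(k_tx = 20, CN = 6, k_sp = 0, k_dn = 0.01,
                           k_dc = 0.0069)
  expect_equal(steady_state(p2)$P_ss, 2 * steady_state(p)$P_ss)
  pc <- default_parameters("SOD_TO")
  expect_equal(steady_state(default_parameters("SOD_TO", k_tx = 20))$M_ss,
               2 * steady_state(pc)$M_ss)
  expect_error(steady_state(kinetic_parameters(10, 6, 0, 0, 0.0069)),
               "no steady state")
})

test_that("long-time simulation converges to the closed-form steady state", {
  p <- default_parameters("SOD_TO")
  k_min <- min(p$k_sp + p$k_dn, p$k_dc)
  t_end <- 20 / k_min
  tr <- simulate_minigene(p, experiment_design(c(0, t_end / 2, t_end)))
  ss <- steady_state(p)
  expect_equal(tr$P[3], ss$P_ss, tolerance = 1e-3)
  expect_equal(tr$M[3], ss$M_ss, tolerance = 1e-3)
})

test_that("cleavage depends on (rho, n_sites, k1) only through the product", {
  des <- experiment_design(seq(0, 360, 10), aso_add_min = 0)
  tr_a <- simulate_minigene(default_parameters("SOD_TO", rho = 2, n_sites = 1),
                            des)
  tr_b <- simulate_minigene(default_parameters("SOD_TO", rho = 1, n_sites = 2),
                            des)
  expect_identical(tr_a$P, tr_b$P)
  expect_identical(tr_a$M, tr_b$M)
})

test_that("raising rho or n_sites never raises post-onset levels; delays never lower them", {
  des <- experiment_design(seq(0, 360, 10), tet_on_min = -Inf, tet_off_min = 0,
                           aso_add_min = 0, init_steady_state = TRUE)
  base <- simulate_minigene(default_parameters("SOD_TO", k1 = 0.02), des)
  hi_rho <- simulate_minigene(default_parameters("SOD_TO", k1 = 0.02, rho = 3),
                              des)
  hi_n <- simulate_minigene(default_parameters("SOD_TO", k1 = 0.02,
                                               n_sites = 4), des)
  expect_true(all(hi_rho$M <= base$M + 1e-12))
  expect_true(all(hi_n$M <= base$M + 1e-12))
  slow <- simulate_minigene(default_parameters("SOD_TO", k1 = 0.02,
                                               tau_recruit = 90), des)
  expect_true(all(slow$M >= base$M - 1e-12))
})

test_that("an ASO that doubles the loss constant doubles the early washout slope", {
  # calibrate cleavage to equal the endogenous cytoplasmic loss
  p_mock <- default_parameters("SOD_TO")
  p_aso <- default_parameters("SOD_TO", k1 = p_mock$k_dc,
                              tau_uptake = 0, tau_scan = 0, tau_recruit = 0)
  des_mock <- experiment_design(seq(0, 360, 10), tet_on_min = -Inf,
                                tet_off_min = 0, init_steady_state = TRUE)
  des_aso <- experiment_design(seq(0, 360, 10), tet_on_min = -Inf,
                               tet_off_min = 0, aso_add_min = 0,
                               init_steady_state = TRUE)
  tc_mock <- make_tc(seq(0, 360, 10),
                     sim_mass(simulate_minigene(p_mock, des_mock),
                              "spliced_mrna"))
  tc_aso <- make_tc(seq(0, 360, 10),
                    sim_mass(simulate_minigene(p_aso, des_aso),
                             "spliced_mrna"), condition = "aso")
  # early windows keep the initial-rate approximation honest
  s_mock <- windowed_slope(tc_mock, c(0, 60))$slope
  s_aso <- windowed_slope(tc_aso, c(0, 60))$slope
  expect_lt(abs(fold_change(s_aso, s_mock) - 2), 0.15 * 2)
})

test_that("compartment half-life ratio equals k_dn/k_dc exactly", {
  p <- default_parameters("SOD_TO")
  t <- seq(0, 300, 10)
  hl_n <- half_life(make_tc(t, 1000 * exp(-p$k_dn * t), species = "pre_mrna"))
  hl_c <- half_life(make_tc(t, 1000 * exp(-p$k_dc * t)))
  expect_equal(hl_c$t_half_min / hl_n$t_half_min, p$k_dn / p$k_dc,
               tolerance = 1e-12)
  expect_equal(p$k_dn / p$k_dc, 1.52, tolerance = 0.01)
})

test_that("slope_to_rate_constant bridges linear slopes to first-order decay", {
  k <- slope_to_rate_constant(6.9, 1000)
  expect_equal(k, 0.0069)
  expect_equal(log(2) / k, 100.5, tolerance = 1e-3)
  expect_equal(slope_to_rate_constant(0, 500), 0)
  expect_error(slope_to_rate_constant(5, 0), "positive")
  # round trip: early-window slope of a simulated pure decay recovers k
  # (splice-defective line so the pre-mRNA decays with k_dn and no inflow)
  p <- default_parameters("SOD187M_TO")
  des <- experiment_design(seq(0, 360, 5), tet_on_min = -Inf,
                           tet_off_min = 0, init_steady_state = TRUE)
  tr <- simulate_minigene(p, des)
  win_end <- 0.2 / p$k_dn  # window <= 0.2/k keeps the initial-rate reading
  est <- windowed_slope(make_tc(tr$time_min, tr$P_mass_fg,
                                species = "pre_mrna"), c(0, win_end))
  k_hat <- slope_to_rate_constant(est$slope, tr$P_mass_fg[1])
  expect_lt(abs(k_hat - p$k_dn) / p$k_dn, 0.10)
})

test_that("fit_parameters is self-consistent on noise-free data", {
  truth <- default_parameters("SOD187M_TO")
  des <- experiment_design(seq(0, 240, 10))
  tr <- simulate_minigene(truth, des)
  ds <- list(list(tc = make_tc(tr$time_min, tr$P_mass_fg,
                               species = "pre_mrna"), design = des))
  fit <- fit_parameters(ds, truth, free = c("k_tx", "k_dn"))
  expect_equal(unname(fit$estimates["k_tx"]), truth$k_tx, tolerance = 1e-6)
  expect_equal(unname(fit$estimates["k_dn"]), truth$k_dn, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-10)
})

test_that("fit_parameters warns when a free parameter is unidentifiable", {
  # cytoplasmic decay cannot be learned from splice-defective pre-mRNA data
  truth <- default_parameters("SOD187M_TO")
  des <- experiment_design(seq(0, 240, 20))
  tr <- simulate_minigene(truth, des)
  ds <- list(list(tc = make_tc(tr$time_min, tr$P_mass_fg,
                               species = "pre_mrna"), design = des))
  expect_warning(fit_parameters(ds, truth, free = c("k_tx", "k_dc")),
                 "unidentifiable")
})

test_that("joint fit of 1x vs 4x repeat-site designs recovers the site ratio", {
  # shared kinetics, n_sites 1 vs 4; fit k1 per dataset via rho trick:
  # fit k1 jointly with n_sites fixed at the design truth
  des <- experiment_design(seq(0, 300, 15), tet_on_min = -Inf,
                           tet_off_min = 0, aso_add_min = 0,
                           init_steady_state = TRUE)
  t1 <- default_parameters("SOD_TO", k1 = 0.012, n_sites = 1,
                           tau_uptake = 30, tau_scan = 15, tau_recruit = 15)
  t4 <- default_parameters("SOD_TO", k1 = 0.012, n_sites = 4,
                           tau_uptake = 30, tau_scan = 15, tau_recruit = 15)
  set.seed(99)
  fits <- lapply(list(t1, t4), function(tru) {
    tr <- simulate_minigene(tru, des)
    tc <- make_noisy_tc(tr$time_min, tr$M_mass_fg, 3, 0.10,
                        seed = sample.int(1e6, 1))
    init <- tru; init$k1 <- 0.03; class(init) <- "kinetic_parameters"
    fit_parameters(list(list(tc = tc, design = des)), init, free = "k1")
  })
  kcl1 <- fits[[1]]$estimates[["k1"]] * 1
  kcl4 <- fits[[2]]$estimates[["k1"]] * 4
  expect_lt(abs(kcl4 / kcl1 - 4) / 4, 0.20)
})

test_that("invalid parameters and designs are rejected", {
  expect_error(kinetic_parameters(-1, 6, 0, 0.01, 0.007), ">= 0")
  expect_error(kinetic_parameters(10, 0, 0, 0.01, 0.007), "CN")
  expect_error(experiment_design(c(0, 0, 10)), "ascending")
  expect_error(experiment_design(seq(0, 100, 10), aso_add_min = 500),
               "outside the sampling grid")
  expect_error(experiment_design(seq(0, 100, 10), preload = TRUE,
                                 tet_on_min = -Inf), "finite tet_on_min")
})

test_that("mass and molecule trajectories stay mutually consistent", {
  p <- default_parameters("SOD_TO")
  tr <- simulate_minigene(p, experiment_design(seq(0, 200, 20)))
  tx <- minigene_transcripts()
  f_pre <- tx$pre_mrna$mw_kda * 1000 * 1.66054e-24 / 1e-15 * 1000
  f_spl <- tx$spliced_mrna$mw_kda * 1000 * 1.66054e-24 / 1e-15 * 1000
  expect_equal(tr$P_mass_fg, tr$P * f_pre, tolerance = 1e-9)
  expect_equal(tr$M_mass_fg, tr$M * f_spl, tolerance = 1e-9)
  expect_true(all(tr$P >= 0) && all(tr$M >= 0))
})
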