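test_that("inflow profile integrates to the stroke volume and peaks at tau", {
  pars <- mean_hd_params()
  T_ms <- 60000 / pars$HR
  t <- seq(0, T_ms, length.out = 20001)
  q <- inflow_profile(t, pars)
  sv <- sum((q[-1] + q[-length(q)]) / 2 * diff(t)) / 1000 # cm^3
  expect_equal(sv, pars$SV, tolerance = 1e-6)
  expect_equal(pars$SV, 3.56 * 1000 / 60, tolerance = 1e-12) # 59.3 ml
  expect_true(all(q >= 0))
  ## diastole is exactly zero
  expect_equal(inflow_profile(pars$ED + 1, pars), 0)
  ## single interior maximum at tau (within one grid step)
  expect_lt(abs(t[which.max(q)] - pars$tau), diff(t)[1] + 1e-9)
  expect_equal(sum(diff(sign(diff(q[t < pars$ED]))) < 0), 1)
  ## tau >= ED is rejected
  expect_error(patient_parameters(k1 = 1e7, k3 = 1e6, CO = 4, tau = 400,
                                  S_R = 1, S_C = 10, HR = 60, ED = 300),
               "tau")
})

test_that("windkessel step follows the three-element closed form", {
  bc <- windkessel_bc(R1 = 1e3, R2 = 1e4, C = 1e-4, p_out_mmHg = 0)
  ## zero inflow decays to the venous pressure
  st <- list(p_c = 40)
  for (i in 1:4000) { r <- windkessel_step(st, 0, bc, 0.01); st <- r$state }
  expect_equal(r$p, 0, tolerance = 1e-3)
  ## steady state under constant inflow: p_out + q (R1 + R2)
  st <- list(p_c = 0)
  for (i in 1:6000) { r <- windkessel_step(st, 1, bc, 0.01); st <- r$state }
  expect_equal(r$p, 1.1e4 / 1333.22, tolerance = 1e-4) # 8.25 mmHg
  ## exponential relaxation: within 1% of steady state after 5 R2 C
  tau_s <- bc$R2 * bc$C
  st <- list(p_c = 0); nst <- ceiling(5 * tau_s / 1e-3)
  for (i in seq_len(nst)) { r <- windkessel_step(st, 1, bc, 1e-3); st <- r$state }
  p_ss <- 1.1e4 / 1333.22
  expect_lt(abs(r$p - p_ss) / p_ss, 0.01)
})

test_that("zero inflow from matched equilibrium stays constant", {
  tree <- toy_tree(L = 20, r_in = 1.0, r_out = 0.8) # tapering included
  pars <- patient_parameters(k1 = 0, k3 = 14.51e5, CO = 3.56, tau = 101,
                             S_R = 1, S_C = 1, HR = 60)
  sim <- simulate_cycle(tree, pars, numerics = numerics_config(
    dx_cm = 0.5, max_cycles = 2), inflow = function(t) 0 * t,
    p_init_mmHg = 5)
  drift <- max(abs(sim$fields[["1"]]$p - 5))
  expect_lt(drift, 0.05) # taper makes equilibrium approximate, not exact
  ## uniform vessel: equilibrium is exact to solver round-off
  sim_u <- simulate_cycle(toy_tree(), pars, numerics = numerics_config(
    dx_cm = 0.5, max_cycles = 2), inflow = function(t) 0 * t,
    p_init_mmHg = 5)
  expect_lt(max(abs(sim_u$fields[["1"]]$p - 5)), 1e-9)
})

test_that("a small pulse propagates at the linearised wave speed", {
  k3 <- 1.451e6
  tree <- toy_tree(L = 100, r_in = 0.5, R1 = 700, R2 = 4000, C = 3e-4,
                   pout = 97) # rest state = reference pressure
  pars <- patient_parameters(k1 = 0, k3 = k3, CO = 3.56, tau = 101,
                             S_R = 1, S_C = 1, HR = 60)
  c_theory <- sqrt((4 / 3) * k3 / (2 * 1.055))
  inflow <- function(t_ms) 4 * exp(-(t_ms - 30)^2 / (2 * 6^2))
  sim <- simulate_cycle(tree, pars,
                        numerics = numerics_config(dx_cm = 0.25, n_out = 512,
                                                   max_cycles = 1),
                        inflow = inflow, p_init_mmHg = 97)
  t1 <- foot_time(site_waveform(sim, "quarter"))
  t2 <- foot_time(site_waveform(sim, "threequarter"))
  c_meas <- 50 / ((t2 - t1) / 1000)
  expect_lt(abs(c_meas - c_theory) / c_theory, 0.05)
})

test_that("volume balance and junction conservation hold on a Y tree", {
  tree <- toy_y_tree()
  pars <- patient_parameters(k1 = 2e7, k3 = 1.4e6, CO = 3.56, tau = 101,
                             S_R = 1, S_C = 1, HR = 60)
  sim <- converge_to_periodic(tree, pars,
                              numerics = numerics_config(dx_cm = 0.5))
  expect_true(sim$converged)
  expect_lt(abs(sim$conservation$residual_fraction_of_SV), 0.005)
  ## parent outflow equals summed daughter inflows at every sampled time
  qp <- sim$fields[["1"]]$q[, ncol(sim$fields[["1"]]$q)]
  qa <- sim$fields[["2"]]$q[, 1]
  qb <- sim$fields[["3"]]$q[, 1]
  expect_lt(max(abs(qp - qa - qb)), 1e-8)
  ## junction pressure continuity to solver tolerance
  pp <- sim$fields[["1"]]$p[, ncol(sim$fields[["1"]]$p)]
  pa <- sim$fields[["2"]]$p[, 1]
  expect_lt(max(abs(pp - pa)), 1e-5)
})

test_that("periodic convergence is monotone in the tolerance", {
  tree <- toy_tree()
  pars <- patient_parameters(k1 = 0, k3 = 1.4e6, CO = 3.56, tau = 101,
                             S_R = 1, S_C = 1, HR = 60)
  loose <- converge_to_periodic(tree, pars,
                                numerics = numerics_config(dx_cm = 1),
                                tol_mmHg = 1)
  tight <- converge_to_periodic(tree, pars,
                                numerics = numerics_config(dx_cm = 1),
                                tol_mmHg = 0.25)
  expect_gte(tight$cycles, loose$cycles)
  expect_error(converge_to_periodic(tree, pars,
                                    numerics = numerics_config(dx_cm = 1),
                                    tol_mmHg = 1e-12, max_cycles = 3),
               "convergence")
})

test_that("grid refinement changes the radial waveform by under 1 mmHg", {
  tree <- nominal_tree()
  pars <- mean_hd_params()
  s1 <- simulate_cycle(tree, pars, numerics = numerics_config(dx_cm = 1))
  s2 <- simulate_cycle(tree, pars, numerics = numerics_config(dx_cm = 0.5))
  p1 <- site_waveform(s1, "radial_distal")$pressure_mmHg
  p2 <- site_waveform(s2, "radial_distal")$pressure_mmHg
  expect_lt(max(abs(p1 - p2)), 1)
})

test_that("stiffer trees transmit faster pulses (PWV monotonicity)", {
  tree <- nominal_tree()
  base <- mean_hd_params()
  stiff <- patient_parameters(k1 = 2 * base$k1, k3 = 2 * base$k3,
                              CO = base$CO, tau = base$tau, S_R = base$S_R,
                              S_C = base$S_C, HR = base$HR,
                              brachial_SP = 130, brachial_DP = 75)
  num <- numerics_config(dx_cm = 2)
  pwv1 <- pulse_wave_velocity(simulate_cycle(tree, base, numerics = num))
  pwv2 <- pulse_wave_velocity(simulate_cycle(tree, stiff, numerics = num))
  expect_gt(pwv2, pwv1)
})
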