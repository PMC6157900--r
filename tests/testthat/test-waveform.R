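test_that("brachial calibration is an exact affine map and idempotent", {
  t <- seq(0, 992, by = 8)
  raw <- pressure_waveform(t, 0.5 + 0.5 * sin(2 * pi * t / 1000))
  cal <- calibrate_waveform(raw, 120, 80)
  expect_equal(min(cal$pressure_mmHg), 80)
  expect_equal(max(cal$pressure_mmHg), 120)
  ## already spanning [DP, SP]: unchanged; re-calibration: idempotent
  expect_equal(calibrate_waveform(cal, 120, 80)$pressure_mmHg,
               cal$pressure_mmHg)
  ## normalized shape is preserved
  ns <- function(p) (p - min(p)) / (max(p) - min(p))
  expect_equal(ns(cal$pressure_mmHg), ns(raw$pressure_mmHg))
  flat <- pressure_waveform(t, rep(100, length(t)))
  expect_error(calibrate_waveform(flat, 120, 80), "flat")
  expect_error(calibrate_waveform(raw, 80, 120), "SP > DP|brachial")
})

test_that("waveform construction validates uniform sampling", {
  t <- seq(0, 992, by = 8)
  t2 <- t; t2[50] <- t2[50] + 3
  expect_error(pressure_waveform(t2, sin(t2)), "non-uniform")
  expect_error(pressure_waveform(t, c(NA, sin(t[-1]))), "finite")
})

test_that("landmark detection matches analytic features of constructions", {
  ## two-Gaussian wave: peak and (late-systolic) shoulder
  tg <- two_gaussian_waveform()
  lm <- detect_landmarks(tg$w)
  dt_s <- 1000 / tg$w$fs_hz
  t_peak_true <- dense_feature(tg$pfun, what = "peak")
  expect_lt(abs(lm$peak - t_peak_true), 2 * dt_s)
  ## the secondary hump produces a shoulder after the peak (type C here)
  expect_false(is.na(lm$shoulder))
  expect_gt(lm$shoulder, lm$peak)
  expect_lt(abs(lm$shoulder - 380), 6 * dt_s) # near the second Gaussian

  ## notched wave: end-systolic local minimum at the constructed notch
  nw <- notched_waveform()
  lm2 <- detect_landmarks(nw$w)
  expect_false(lm2$notch_fallback)
  ## the notch is a local minimum; search up to just past the dicrotic bump
  t_notch_true <- dense_feature(nw$pfun, what = "min",
                                interval = c(nw$t_peak + 50, nw$t_notch + 45))
  expect_lt(abs(lm2$notch - t_notch_true), 2 * dt_s)
  expect_lt(abs(lm2$peak - nw$t_peak), 2 * dt_s)
  ## foot of a clean upstroke sits near the start
  expect_lt(lm2$foot, 60)

  ## degenerate monotone ramp: no rising-edge/notch structure
  t <- seq(0, 992, by = 8)
  ramp <- pressure_waveform(t, 80 + 0.04 * t, calibrated = TRUE)
  res <- tryCatch(detect_landmarks(ramp), error = function(e) e)
  expect_true(inherits(res, "error") || res$notch_fallback)
})

test_that("augmentation index follows the printed formula", {
  expect_equal(augmentation_index(120, 80, 0), 100)
  expect_equal(augmentation_index(120, 80, 10), 400 / 3, tolerance = 1e-12)
  expect_equal(augmentation_index(120, 80, 20), 200)
  ## negative AP (early peak) gives AI below 100
  expect_lt(augmentation_index(120, 80, -10), 100)
  expect_error(augmentation_index(120, 80, 40), "pulse pressure")
  expect_error(augmentation_index(80, 120, 0), "SP > DP")
})

test_that("SEVR is the diastolic/systolic pressure-time integral ratio", {
  t <- seq(0, 992, by = 8)
  const <- pressure_waveform(t, rep(100, length(t)), calibrated = TRUE)
  expect_equal(sevr(const, 500), 100, tolerance = 1e-6)
  expect_equal(sevr(const, 300), (1000 - 300) / 300 * 100, tolerance = 1e-6)
  expect_lt(sevr(const, 990), 2)
  expect_error(sevr(const, 1200), "ED")
  ## monotone decreasing in ED on a realistic waveform
  nw <- notched_waveform()
  s1 <- sevr(nw$w, 300); s2 <- sevr(nw$w, 380)
  expect_gt(s1, s2)
})

test_that("AI is invariant under brachial calibration", {
  nw <- notched_waveform(bump = 10)
  ai1 <- pwa_indices(nw$w)$AI
  recal <- calibrate_waveform(nw$w, 180, 60)
  ai2 <- pwa_indices(recal)$AI
  expect_equal(ai1, ai2, tolerance = 1e-6)
})

test_that("pwa_indices satisfies the index identities", {
  nw <- notched_waveform()
  idx <- pwa_indices(nw$w)
  expect_equal(idx$PP, idx$SP - idx$DP)
  expect_gt(idx$PP, 0)
  expect_true(idx$ED > 0 && idx$ED < 1000)
  ## AI > 100 iff AP > 0 under the formula
  if (idx$AP > 0) expect_gt(idx$AI, 100) else expect_lte(idx$AI, 100)
})

test_that("pulse wave velocity requires distinct sites on one path", {
  tree <- nominal_tree()
  sim <- simulate_cycle(tree, mean_hd_params(),
                        numerics = numerics_config(dx_cm = 2))
  expect_error(pulse_wave_velocity(sim, "femoral", "femoral"),
               "zero distance")
  pwv <- pulse_wave_velocity(sim, "aortic_arch", "femoral")
  expect_true(is.finite(pwv) && pwv > 2 && pwv < 25)
})

test_that("PWV scales as the square root of wall stiffness", {
  mk <- function(k3) {
    tree <- toy_tree(L = 100, r_in = 0.5, R1 = 700, R2 = 4000, C = 3e-4,
                   pout = 97) # rest state = reference pressure
    pars <- patient_parameters(k1 = 0, k3 = k3, CO = 3.56, tau = 101,
                               S_R = 1, S_C = 1, HR = 60)
    inflow <- function(t_ms) 4 * exp(-(t_ms - 30)^2 / (2 * 6^2))
    sim <- simulate_cycle(tree, pars,
                          numerics = numerics_config(dx_cm = 0.25,
                                                     n_out = 512,
                                                     max_cycles = 1),
                          inflow = inflow, p_init_mmHg = 97)
    pulse_wave_velocity(sim, "quarter", "threequarter")
  }
  v1 <- mk(1.451e6); v4 <- mk(4 * 1.451e6)
  expect_lt(abs(v4 / v1 - 2), 0.1) # F x4 doubles the speed within 5% each
})

test_that("k3 and model PWV are positively rank-correlated across subjects", {
  tree <- nominal_tree()
  k3s <- c(6, 9, 13, 18, 24, 32) * 1e5
  pwv <- vapply(k3s, function(k3) {
    pars <- patient_parameters(k1 = 2.28e7, k3 = k3, CO = 3.56, tau = 101,
                               S_R = 1.34, S_C = 13.57, HR = 60,
                               brachial_SP = 130, brachial_DP = 75)
    pulse_wave_velocity(simulate_cycle(tree, pars,
                                       numerics = numerics_config(dx_cm = 2)))
  }, 1)
  expect_gt(cor(k3s, pwv, method = "spearman"), 0.9)
})
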