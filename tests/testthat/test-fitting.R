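# Small-budget fitting behaviour; the full-budget parameter-recovery
# experiment lives in the acceptance suite.

tiny_config <- function(seed = 1, particles = 5, iterations = 2,
                        refine_maxit = 0)
  fit_config(particles = particles, iterations = iterations,
             refine_maxit = refine_maxit, lm_maxit = 0, seed = seed)

fixture_waveform <- function(pars, tree, cfg) {
  sim <- simulate_cycle(tree, pars, numerics = cfg$numerics)
  site_waveform(sim, "radial_distal")
}

test_that("the objective is zero at truth and grows away from it", {
  tree <- scale_tree_to_height(nominal_tree(), 170)
  pars <- mean_hd_params(height_cm = 170)
  cfg <- fit_config()
  wm <- fixture_waveform(pars, tree, cfg)
  at_truth <- objective_error(pars, wm, tree, config = cfg)
  expect_lt(at_truth, 0.5) # self-consistency: discretisation only
  far <- patient_parameters(k1 = pars$k1, k3 = 100 * pars$k3, CO = pars$CO,
                            tau = pars$tau, S_R = pars$S_R, S_C = pars$S_C,
                            HR = 60, height_cm = 170, brachial_SP = 130,
                            brachial_DP = 75)
  expect_gt(objective_error(far, wm, tree, config = cfg), at_truth + 1)
})

test_that("the objective is invariant to a time shift of the recording", {
  tree <- scale_tree_to_height(nominal_tree(), 170)
  pars <- mean_hd_params(height_cm = 170)
  cfg <- fit_config()
  wm <- fixture_waveform(pars, tree, cfg)
  n <- length(wm$pressure_mmHg)
  for (k in c(11L, 64L)) {
    ws <- wm
    ws$pressure_mmHg <- wm$pressure_mmHg[((seq_len(n) - 1 + k) %% n) + 1]
    e0 <- objective_error(pars, wm, tree, config = cfg)
    es <- objective_error(pars, ws, tree, config = cfg)
    expect_lt(abs(es - e0), 0.35) # foot alignment absorbs the shift
  }
})

test_that("unstable parameter sets yield the finite sentinel, not an error", {
  tree <- scale_tree_to_height(nominal_tree(), 170)
  cfg <- fit_config()
  wm <- fixture_waveform(mean_hd_params(height_cm = 170), tree, cfg)
  crazy <- patient_parameters(k1 = 9e7, k3 = 5e6, CO = 6.7, tau = 20,
                              S_R = 0.2, S_C = 1, HR = 60, height_cm = 170)
  cfg2 <- cfg; cfg2$numerics$dt_s <- 5e-3 # deliberately CFL-unsafe
  val <- objective_error(crazy, wm, tree, config = cfg2)
  expect_true(is.finite(val))
  expect_equal(val, cfg2$sentinel)
})

test_that("each of the six parameters is individually visible (identifiability)", {
  tree <- scale_tree_to_height(nominal_tree(), 170)
  pars <- mean_hd_params(height_cm = 170)
  cfg <- fit_config()
  wm <- fixture_waveform(pars, tree, cfg)
  truth <- unlist(pars[c("k1", "k3", "CO", "tau", "S_R", "S_C")])
  floor_err <- objective_error(pars, wm, tree, config = cfg)
  for (nm in names(truth)) {
    v <- truth; v[[nm]] <- v[[nm]] * 1.2
    p2 <- pulsewave:::params_from_vector(v, list(HR = 60, height_cm = 170,
                                                 brachial_SP = 130,
                                                 brachial_DP = 75,
                                                 ED = pars$ED))
    e <- objective_error(p2, wm, tree, config = cfg)
    expect_gt(e, floor_err + 0.05) # perturbation visible above the floor
  }
})

test_that("fits are deterministic under the seed and improve with budget", {
  tree <- nominal_tree()
  pars <- mean_hd_params(height_cm = 170)
  cfg_small <- tiny_config(seed = 7)
  wm <- fixture_waveform(pars, scale_tree_to_height(tree, 170), cfg_small)
  meta <- list(HR = 60, height_cm = 170, brachial_SP = 130,
               brachial_DP = 75, ED = pars$ED)
  f1 <- fit_patient(wm, meta, tree = tree, config = cfg_small)
  f2 <- fit_patient(wm, meta, tree = tree, config = cfg_small)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$rel_error, f2$rel_error)
  expect_equal(f1$seed, 7L)
  expect_true(nzchar(f1$config_hash))

  ## doubling the iteration budget (same seed stream) is never worse
  f4 <- fit_patient(wm, meta, tree = tree,
                    config = tiny_config(seed = 7, iterations = 4))
  expect_lte(f4$rel_error, f1$rel_error + 1e-12)
  ## the gbest trace is monotone non-increasing
  expect_true(all(diff(f4$trace) <= 1e-12))
})

test_that("a zero-iteration budget starting at truth stays at truth", {
  tree <- nominal_tree()
  pars <- mean_hd_params(height_cm = 170)
  cfg <- fit_config(particles = 5, iterations = 0, refine_maxit = 0, seed = 3)
  wm <- fixture_waveform(pars, scale_tree_to_height(tree, 170), cfg)
  truth <- unlist(pars[c("k1", "k3", "CO", "tau", "S_R", "S_C")])
  f <- fit_patient(wm, list(HR = 60, height_cm = 170, brachial_SP = 130,
                            brachial_DP = 75, ED = pars$ED),
                   tree = tree, config = cfg, start = truth)
  expect_equal(unlist(f$estimates), truth, tolerance = 1e-8)
  expect_lt(f$rel_error, 0.3)
})
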