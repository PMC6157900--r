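# Fixtures built in code: toy trees, reference parameter sets, constructed
# waveforms with analytically known features.

## single uniform (or tapering) vessel with a terminal Windkessel
toy_tree <- function(L = 20, r_in = 1.0, r_out = r_in,
                     R1 = 200, R2 = 1500, C = 8.7e-4, pout = 5) {
  vs <- data.frame(id = 1L, name = "vessel", length_cm = L,
                   r_in_cm = r_in, r_out_cm = r_out,
                   d1 = NA_integer_, d2 = NA_integer_, terminal = TRUE)
  structure(list(
    vessels = vs,
    windkessel = data.frame(id = 1L, R1 = R1, R2 = R2, C = C,
                            p_out_mmHg = pout),
    named_sites = list(
      quarter = list(vessel = 1L, position = 0.25),
      threequarter = list(vessel = 1L, position = 0.75),
      inlet = list(vessel = 1L, position = 0.0),
      outlet = list(vessel = 1L, position = 1.0)),
    root = 1L, nominal_height_cm = 176, height_cm = 176,
    p_ref_mmHg = 97, name = "toy1"), class = "arterial_tree")
}

## symmetric Y: one parent bifurcating into two terminal daughters
toy_y_tree <- function() {
  vs <- data.frame(
    id = 1:3, name = c("parent", "d_a", "d_b"),
    length_cm = c(15, 12, 12), r_in_cm = c(1.0, 0.72, 0.72),
    r_out_cm = c(0.95, 0.65, 0.65),
    d1 = c(2L, NA, NA), d2 = c(3L, NA, NA),
    terminal = c(FALSE, TRUE, TRUE))
  structure(list(
    vessels = vs,
    windkessel = data.frame(id = 2:3, R1 = c(400, 400), R2 = c(3000, 3000),
                            C = c(4.4e-4, 4.4e-4), p_out_mmHg = c(5, 5)),
    named_sites = list(), root = 1L, nominal_height_cm = 176,
    height_cm = 176, p_ref_mmHg = 97, name = "toyY"),
    class = "arterial_tree")
}

## the printed haemodialysis cohort mean parameters
mean_hd_params <- function(HR = 60, height_cm = 176, ...) {
  patient_parameters(k1 = 2.28e7, k3 = 14.51e5, CO = 3.56, tau = 101.08,
                     S_R = 1.34, S_C = 13.57, HR = HR,
                     height_cm = height_cm, brachial_SP = 130,
                     brachial_DP = 75, ...)
}

## two-Gaussian systolic waveform; feature times found on the analytic curve
two_gaussian_waveform <- function(n = 256, T_ms = 1000, DP = 80,
                                  a1 = 40, t1 = 180, s1 = 60,
                                  a2 = 18, t2 = 380, s2 = 70) {
  pfun <- function(t) DP + a1 * exp(-(t - t1)^2 / (2 * s1^2)) +
    a2 * exp(-(t - t2)^2 / (2 * s2^2))
  t <- (seq_len(n) - 1) * T_ms / n
  list(w = pressure_waveform(t, pfun(t), HR = 60000 / T_ms,
                             calibrated = TRUE),
       pfun = pfun)
}

## half-sine systole falling to a dicrotic notch at t_notch, then a small
## dicrotic wave and exponential diastolic decay; the notch is a genuine
## local pressure minimum by construction
notched_waveform <- function(n = 256, T_ms = 1000, DP = 75, SP = 125,
                             t_peak = 160, t_notch = 340, bump = 8,
                             bump_w = 90, tau_d = 320) {
  p_n <- DP + 0.30 * (SP - DP)
  pfun <- function(t) {
    p <- numeric(length(t))
    i1 <- t <= t_peak
    p[i1] <- DP + (SP - DP) * sin(pi * t[i1] / (2 * t_peak))
    i2 <- t > t_peak & t <= t_notch
    p[i2] <- p_n + (SP - p_n) *
      cos(pi / 2 * (t[i2] - t_peak) / (t_notch - t_peak))
    i3 <- t > t_notch
    td <- t[i3] - t_notch
    p[i3] <- DP + (p_n - DP) * exp(-td / tau_d) +
      bump * sin(pmin(pi, pi * td / bump_w)) * exp(-td / bump_w)
    p
  }
  t <- (seq_len(n) - 1) * T_ms / n
  list(w = pressure_waveform(t, pfun(t), HR = 60000 / T_ms,
                             calibrated = TRUE),
       pfun = pfun, t_peak = t_peak, t_notch = t_notch)
}

## locate features of an analytic pressure function on a dense grid
dense_feature <- function(pfun, T_ms = 1000, what = c("peak", "min"),
                          interval = c(0, 1) * T_ms, n = 20000) {
  what <- match.arg(what)
  t <- seq(interval[1], interval[2], length.out = n)
  y <- pfun(t)
  t[if (what == "peak") which.max(y) else which.min(y)]
}

skip_slow <- function() invisible(TRUE) # all tests run everywhere
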