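#' Single-cycle pressure waveform
#'
#' A uniformly sampled pressure trace covering exactly one cardiac period
#' (the sample at `t = T` is not repeated).
#'
#' @param time_ms sample times, ms, uniformly spaced from 0.
#' @param pressure_mmHg pressures.
#' @param HR heart rate, beats/min; defaults to `60000 / (n * dt)`.
#' @param calibrated whether the trace is in true mmHg (as opposed to device
#'   units awaiting brachial calibration).
#' @return an object of class `pressure_waveform`.
#' @export
pressure_waveform <- function(time_ms, pressure_mmHg, HR = NULL,
                              calibrated = FALSE) {
  n <- length(time_ms)
  stopifnot(n == length(pressure_mmHg), n >= 8)
  if (any(!is.finite(pressure_mmHg))) stop("non-finite pressures")
  dt <- diff(time_ms)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    stop("non-uniform sampling at index ",
         which(abs(dt - dt[1]) > 1e-6 * dt[1])[1] + 1)
  if (is.null(HR)) HR <- 60000 / (n * dt[1])
  structure(list(time_ms = as.numeric(time_ms),
                 pressure_mmHg = as.numeric(pressure_mmHg),
                 fs_hz = 1000 / dt[1], HR = HR,
                 calibrated = isTRUE(calibrated)),
            class = "pressure_waveform")
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat("<pressure_waveform> ", length(x$time_ms), " samples @ ",
      signif(x$fs_hz, 4), " Hz, HR ", signif(x$HR, 4), ", range [",
      signif(min(x$pressure_mmHg), 4), ", ", signif(max(x$pressure_mmHg), 4),
      "] mmHg", if (x$calibrated) " (calibrated)", "\n", sep = "")
  invisible(x)
}

cycle_length_ms <- function(w) 60000 / w$HR

#' Calibrate a waveform to brachial pressures
#'
#' Affine rescaling so that the waveform minimum equals the brachial
#' diastolic and the maximum the brachial systolic pressure, the usual
#' calibration of tonometric radial recordings against an oscillometric
#' brachial cuff. The normalized shape is unchanged, so shape-derived indices
#' (e.g. the augmentation index) are invariant under calibration.
#'
#' @param w a `pressure_waveform`.
#' @param brachial_SP,brachial_DP cuff systolic/diastolic pressure, mmHg.
#' @return the calibrated `pressure_waveform`.
#' @export
calibrate_waveform <- function(w, brachial_SP, brachial_DP) {
  stopifnot(brachial_SP > brachial_DP, brachial_DP > 0)
  p <- w$pressure_mmHg
  rng <- range(p)
  if (diff(rng) <= 0) stop("flat waveform cannot be calibrated")
  w$pressure_mmHg <- brachial_DP +
    (p - rng[1]) / diff(rng) * (brachial_SP - brachial_DP)
  w$calibrated <- TRUE
  w
}

## smoothed derivatives via Savitzky-Golay; window = 5% of cycle (odd, >= 5)
sg_smooth <- function(p, fs_hz, deriv = 0, window_frac = 0.05) {
  n <- length(p)
  wl <- max(5L, as.integer(round(n * window_frac)))
  if (wl %% 2 == 0) wl <- wl + 1L
  if (wl >= n) wl <- if (n %% 2 == 0) n - 1L else n - 2L
  ## pad periodically for true cycles; replicate the edges when the trace is
  ## visibly non-periodic (e.g. a single transient pulse)
  pad <- wl
  periodic <- abs(p[n] - p[1]) <= 0.05 * (max(p) - min(p) + 1e-12)
  pp <- if (periodic) c(p[(n - pad + 1):n], p, p[1:pad])
  else c(rep(p[1], pad), p, rep(p[n], pad))
  sm <- signal::sgolayfilt(pp, p = min(4, wl - 2), n = wl, m = deriv,
                           ts = 1 / fs_hz)
  sm[(pad + 1):(pad + n)]
}

#' Detect characteristic landmarks of a pressure waveform
#'
#' Finds the foot (intersecting-tangent point), the systolic peak, the
#' systolic inflection/shoulder (zero crossing of the fourth derivative of
#' the smoothed waveform nearest the peak) and the end-systolic dicrotic
#' notch (local pressure minimum after the peak). If no notch is detectable
#' the ejection duration falls back to a third of the cycle and the result is
#' flagged.
#'
#' @param w a calibrated single-cycle `pressure_waveform`.
#' @param window_frac smoothing window as a fraction of the cycle.
#' @return list with times in ms (`foot`, `peak`, `shoulder`, `notch`),
#'   the pressures at those points, the waveform type (`"A"` when the
#'   shoulder precedes the peak, `"C"` otherwise) and `notch_fallback`.
#' @export
detect_landmarks <- function(w, window_frac = 0.05) {
  p <- w$pressure_mmHg; t <- w$time_ms; n <- length(p)
  fs <- w$fs_hz
  sm <- sg_smooth(p, fs, 0, window_frac)
  d1 <- sg_smooth(p, fs, 1, window_frac)
  if (max(p) - min(p) < 1e-9) stop("flat waveform: no landmarks")

  i_peak <- which.max(sm)
  i_min <- which.min(sm)

  ## foot: intersecting tangent — the tangent at the point of maximal
  ## upstroke intersected with the end-diastolic baseline (the minimum over
  ## the 30% of the cycle preceding the upstroke, circularly)
  up <- if (i_peak > 1) 1:i_peak else 1:n
  i_up <- up[which.max(d1[up])]
  slope <- d1[i_up] # mmHg/s
  if (slope <= 0) stop("degenerate waveform: no rising edge")
  eps <- 1e-4 * (max(sm) - min(sm))
  j <- i_up
  for (s in seq_len(max(2L, as.integer(0.5 * n)))) {
    jm <- if (j == 1L) n else j - 1L
    if (sm[jm] < sm[j] - eps) j <- jm else break
  }
  p_base <- sm[j]
  t_foot <- t[i_up] - (sm[i_up] - p_base) / slope * 1000

  sep <- max(2L, as.integer(0.02 * n))

  ## dicrotic notch: first local minimum of the smoothed wave after the peak
  notch_fallback <- FALSE
  lo <- i_peak + sep
  hi <- min(n - 1, i_peak + as.integer(0.55 * n))
  i_notch <- NA_integer_
  if (lo < hi) {
    seg <- sm[lo:hi]
    loc <- which(diff(sign(diff(seg))) > 0) + 1 # interior local minima
    if (length(loc)) i_notch <- lo + loc[1] - 1
  }
  if (is.na(i_notch)) {
    notch_fallback <- TRUE
    t_notch <- t_foot + cycle_length_ms(w) / 3
  } else t_notch <- t[i_notch]

  ## shoulder: a secondary systolic local maximum (zero crossing of the
  ## first derivative away from the peak, before the notch) when one
  ## exists, else the 4th-derivative zero crossing nearest the peak
  sys_end <- min(n - 1, i_peak + as.integer(0.3 * n))
  sys_beg <- max(1, i_up)
  i_shoulder <- NA_integer_
  if (sys_beg < sys_end) {
    idx <- sys_beg:(sys_end - 1)
    z1 <- idx[d1[idx] > 0 & d1[idx + 1] < 0] # local maxima only
    z1 <- z1[abs(z1 - i_peak) >= sep]
    if (length(z1)) {
      i_shoulder <- z1[which.min(abs(z1 - i_peak))]
    } else {
      d4 <- sg_smooth(p, fs, 4, window_frac)
      zc <- idx[d4[idx] * d4[idx + 1] < 0]
      zc <- zc[abs(zc - i_peak) >= sep]
      if (length(zc)) i_shoulder <- zc[which.min(abs(zc - i_peak))]
    }
  }

  list(
    foot = t_foot, peak = t[i_peak],
    shoulder = if (is.na(i_shoulder)) NA_real_ else t[i_shoulder],
    notch = t_notch,
    p_foot = p_base, p_peak = sm[i_peak],
    p_shoulder = if (is.na(i_shoulder)) NA_real_ else sm[i_shoulder],
    p_min = min(p), p_max = max(p),
    type = if (!is.na(i_shoulder) && i_shoulder < i_peak) "A" else "C",
    notch_fallback = notch_fallback, i_min = i_min
  )
}

#' Augmentation index
#'
#' `AI = (SP - DP) / (SP - DP - AP) * 100` (percent). `AP` is the augmented
#' pressure added by the reflected wave; `AI = 100` exactly when `AP = 0`,
#' and `AI > 100` whenever `AP > 0`.
#'
#' @param SP,DP systolic and diastolic pressure, mmHg.
#' @param AP augmented pressure, mmHg (negative for early-peak waveforms).
#' @return AI in percent.
#' @export
augmentation_index <- function(SP, DP, AP) {
  if (any(SP <= DP)) stop("need SP > DP")
  if (any(AP >= SP - DP)) stop("AP must be below the pulse pressure")
  (SP - DP) / (SP - DP - AP) * 100
}

#' Sub-endocardial viability ratio
#'
#' The ratio of the diastolic to the systolic pressure-time integral,
#' `SEVR = DPTI / SPTI * 100` (percent), a proxy for the adequacy of
#' myocardial perfusion. Systole is `[foot, foot + ED)`; the waveform is
#' treated as periodic.
#'
#' @param w a `pressure_waveform`.
#' @param ED ejection duration, ms.
#' @param t0 start of systole (foot time), ms; default 0.
#' @return SEVR in percent.
#' @export
sevr <- function(w, ED, t0 = 0) {
  T_ms <- cycle_length_ms(w)
  if (!(ED > 0 && ED < T_ms)) stop("ED outside cycle")
  ## integrate on a dense periodic interpolation so arbitrary ED values work
  p_fun <- function(tt) {
    tt <- (tt - w$time_ms[1]) %% T_ms + w$time_ms[1]
    approx(c(w$time_ms, w$time_ms[1] + T_ms),
           c(w$pressure_mmHg, w$pressure_mmHg[1]), xout = tt)$y
  }
  nsub <- 40L
  grid_int <- function(a, b) {
    m <- max(16L, as.integer((b - a) / T_ms * length(w$time_ms) * 4), nsub)
    xs <- seq(a, b, length.out = m)
    sum((p_fun(xs)[-1] + p_fun(xs)[-m]) / 2 * diff(xs))
  }
  spti <- grid_int(t0, t0 + ED)
  dpti <- grid_int(t0 + ED, t0 + T_ms)
  dpti / spti * 100
}

#' Full pulse-wave-analysis index set
#'
#' Computes SP, DP, PP, AP, AI, ED and SEVR from one calibrated waveform.
#' AP is the pressure difference between the systolic peak and the shoulder
#' (positive for late-peak, type A waveforms; negative for early-peak ones);
#' ED is the foot-to-notch interval.
#'
#' @param w a calibrated `pressure_waveform`.
#' @return list of class `pwa_indices`.
#' @export
pwa_indices <- function(w) {
  lm <- detect_landmarks(w)
  SP <- lm$p_max; DP <- lm$p_min
  AP <- if (is.na(lm$p_shoulder)) 0 else
    if (lm$type == "A") lm$p_peak - lm$p_shoulder else
      lm$p_shoulder - lm$p_peak # negative by construction for type C
  ED <- (lm$notch - lm$foot) %% cycle_length_ms(w)
  structure(list(
    SP = SP, DP = DP, PP = SP - DP, AP = AP,
    AI = augmentation_index(SP, DP, AP),
    ED = ED, SEVR = sevr(w, ED, t0 = lm$foot),
    type = lm$type, notch_fallback = lm$notch_fallback
  ), class = "pwa_indices")
}

#' @export
print.pwa_indices <- function(x, ...) {
  cat(sprintf(paste0("<pwa_indices> SP %.1f DP %.1f PP %.1f AP %.2f mmHg | ",
                     "AI %.1f%% | ED %.0f ms | SEVR %.1f%% (type %s%s)\n"),
              x$SP, x$DP, x$PP, x$AP, x$AI, x$ED, x$SEVR, x$type,
              if (x$notch_fallback) ", ED fallback" else ""))
  invisible(x)
}

## foot time (ms) of a waveform by the intersecting-tangent method
foot_time <- function(w, window_frac = 0.05) {
  detect_landmarks(w, window_frac)$foot
}

#' Model-predicted pulse wave velocity between two sites
#'
#' `PWV = path length / transit time`, with the transit time measured
#' between the waveform feet detected by the intersecting-tangent method at
#' the two sites. Both sites must lie on a common root-to-leaf path; the
#' headline path of the framework runs from the aortic arch to the femoral
#' artery.
#'
#' @param sim a `sim_result`.
#' @param site_a,site_b proximal and distal site (names or
#'   `list(vessel=, position=)`).
#' @return PWV in m/s.
#' @export
pulse_wave_velocity <- function(sim, site_a = "aortic_arch",
                                site_b = "femoral") {
  d_cm <- site_distance(sim$tree, site_a, site_b)
  wa <- site_waveform(sim, site_a)
  wb <- site_waveform(sim, site_b)
  ta <- foot_time(wa); tb <- foot_time(wb)
  T_ms <- cycle_length_ms(wa)
  dt_ms <- (tb - ta) %% T_ms
  if (dt_ms > T_ms / 2) dt_ms <- dt_ms - T_ms # wrong wrap direction
  one_sample <- 1000 / wa$fs_hz
  if (abs(dt_ms) < one_sample)
    stop("transit time below one sample; increase resolution or separation")
  (d_cm / 100) / (dt_ms / 1000)
}
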