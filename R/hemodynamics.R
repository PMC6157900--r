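#' Fixed haemodynamic constants
#'
#' Blood density and viscosity and the boundary-layer thickness used by the
#' friction term of the momentum equation. When `delta_cm` is `NULL` it is
#' computed per run as `sqrt(nu * T / (2 pi))` with `T` the cardiac period.
#'
#' @param rho blood density, g/cm^3.
#' @param mu blood viscosity, g/(cm s).
#' @param delta_cm boundary-layer thickness, cm, or `NULL` to derive from the
#'   cardiac period.
#' @export
hemo_constants <- function(rho = 1.055, mu = 0.049, delta_cm = NULL) {
  stopifnot(rho > 0, mu > 0, is.null(delta_cm) || delta_cm > 0)
  structure(list(rho = rho, mu = mu, delta_cm = delta_cm),
            class = "hemo_constants")
}

#' Patient-specific model parameters
#'
#' The six estimated quantities — `k1`, `k3` (small/large artery stiffness,
#' g/(s^2 cm)), `CO` (cardiac output, l/min), `tau` (heart ejection peak
#' time, ms), `S_R` and `S_C` (dimensionless scalings of the nominal terminal
#' Windkessel resistances and compliances) — plus the fixed per-subject
#' covariates (heart rate, ejection duration, height, brachial pressures).
#' The stroke volume is `SV = CO/HR`.
#'
#' @param k1,k3 stiffness coefficients, g/(s^2 cm).
#' @param CO cardiac output, l/min.
#' @param tau heart ejection peak time, ms.
#' @param S_R,S_C Windkessel resistance/compliance scalings.
#' @param HR heart rate, beats/min.
#' @param ED ejection duration, ms; defaults to a third of the cardiac cycle.
#' @param height_cm subject height.
#' @param brachial_SP,brachial_DP brachial systolic/diastolic pressure, mmHg.
#' @return an object of class `patient_parameters`.
#' @export
patient_parameters <- function(k1, k3, CO, tau, S_R, S_C, HR = 60,
                               ED = NULL, height_cm = 176,
                               brachial_SP = 120, brachial_DP = 80) {
  T_ms <- 60000 / HR
  if (is.null(ED)) ED <- T_ms / 3
  vals <- c(k1 = k1, k3 = k3, CO = CO, tau = tau, S_R = S_R, S_C = S_C,
            HR = HR, ED = ED, height_cm = height_cm)
  if (any(!is.finite(vals)) || any(vals[-1] <= 0) || k1 < 0)
    stop("patient parameters must be positive (k1 may be zero)")
  if (!(tau < ED && ED < T_ms))
    stop("need tau < ED < cycle length (tau=", tau, ", ED=", ED,
         ", T=", round(T_ms, 1), " ms)")
  if (!(brachial_SP > brachial_DP && brachial_DP > 0))
    stop("need brachial_SP > brachial_DP > 0")
  structure(list(k1 = k1, k3 = k3, CO = CO, tau = tau, S_R = S_R, S_C = S_C,
                 HR = HR, ED = ED, height_cm = height_cm,
                 brachial_SP = brachial_SP, brachial_DP = brachial_DP,
                 SV = CO * 1000 / HR),
            class = "patient_parameters")
}

#' Heart ejection inflow profile
#'
#' Smooth single-peaked ejection pulse at the aortic root: a quarter-sine
#' rise to the peak at `t = tau` followed by a quarter-cosine fall to zero at
#' the end of systole (`t = ED`), zero in diastole. The pulse is scaled so
#' its integral over one cycle equals the stroke volume `SV = CO/HR`.
#'
#' @param t_ms time within the cycle, ms (vectorised).
#' @param params a `patient_parameters` object.
#' @return flow in cm^3/s.
#' @export
inflow_profile <- function(t_ms, params) {
  T_ms <- 60000 / params$HR
  if (any(t_ms < 0 | t_ms >= T_ms + 1e-9)) {
    if (all(t_ms >= 0) && max(t_ms) <= T_ms + 1e-6) {
      # allow the cycle endpoint itself
    } else stop("t outside cycle [0, T)")
  }
  tau <- params$tau; ED <- params$ED
  if (tau >= ED) stop("tau must be below ED")
  # integral of the unit-peak shape is 2*ED/pi (in ms)
  peak <- params$SV / (2 * ED / pi) * 1000  # cm^3/s
  g <- numeric(length(t_ms))
  sys1 <- t_ms <= tau
  sys2 <- t_ms > tau & t_ms < ED
  g[sys1] <- sin(pi * t_ms[sys1] / (2 * tau))
  g[sys2] <- cos(pi * (t_ms[sys2] - tau) / (2 * (ED - tau)))
  peak * g
}

#' Three-element Windkessel boundary condition
#'
#' @param R1 proximal resistance, dyn s/cm^5.
#' @param R2 distal resistance, dyn s/cm^5.
#' @param C compliance, cm^5/dyn.
#' @param p_out_mmHg venous (outflow) pressure.
#' @export
windkessel_bc <- function(R1, R2, C, p_out_mmHg = 5) {
  stopifnot(R1 > 0, R2 > 0, C > 0)
  structure(list(R1 = R1, R2 = R2, C = C, p_out_mmHg = p_out_mmHg),
            class = "windkessel_bc")
}

#' Advance a three-element Windkessel by one time step
#'
#' For a constant inflow over the step the capacitor pressure is updated by
#' its exact exponential solution (time constant `R2*C`); the terminal
#' pressure is `p = q*R1 + p_c`. With constant `q_in`, `p` relaxes to
#' `p_out + q_in*(R1+R2)`.
#'
#' @param state list with element `p_c` (capacitor pressure, mmHg); use
#'   `list(p_c = p_out)` to start at rest.
#' @param q_in inflow, cm^3/s.
#' @param bc a `windkessel_bc`.
#' @param dt_s time step, s.
#' @return list with `p` (terminal pressure, mmHg) and the updated `state`.
#' @export
windkessel_step <- function(state, q_in, bc, dt_s) {
  stopifnot(dt_s > 0)
  p_c <- mmHg_to_dyn(state$p_c)
  p_out <- mmHg_to_dyn(bc$p_out_mmHg)
  p_ss <- p_out + q_in * bc$R2
  p_c_new <- p_ss + (p_c - p_ss) * exp(-dt_s / (bc$R2 * bc$C))
  list(p = dyn_to_mmHg(q_in * bc$R1 + p_c_new),
       state = list(p_c = dyn_to_mmHg(p_c_new)))
}

#' Numerical configuration for the network solver
#'
#' @param dx_cm target spatial step (each vessel keeps at least 3 nodes).
#' @param cfl CFL number relative to the estimated maximal characteristic
#'   speed.
#' @param tol_mmHg periodic-convergence tolerance on the cycle-to-cycle root
#'   pressure difference (max norm).
#' @param max_cycles maximum number of cardiac cycles to run.
#' @param junction_mode `"pressure"` (static pressure continuity, default) or
#'   `"total_pressure"`.
#' @param n_out output samples per cycle.
#' @param u_margin_cm_s velocity safety margin added to the wave speed when
#'   choosing the time step.
#' @param fixed_cycles run exactly this many cycles instead of stopping at
#'   `tol_mmHg` (used by the fitting objective, where a varying cycle count
#'   would make the objective discontinuous in the parameters).
#' @param dt_s explicit time step override in seconds (the default derives
#'   it from the CFL condition; an override keeps the discretisation
#'   identical across parameter sets during optimisation).
#' @export
numerics_config <- function(dx_cm = 0.25, cfl = 0.9, tol_mmHg = 0.5,
                            max_cycles = 25,
                            junction_mode = c("pressure", "total_pressure"),
                            n_out = 256, u_margin_cm_s = 400,
                            fixed_cycles = NULL, dt_s = NULL) {
  junction_mode <- match.arg(junction_mode)
  stopifnot(dx_cm > 0, cfl > 0, cfl <= 1, tol_mmHg > 0, max_cycles >= 1)
  structure(list(dx_cm = dx_cm, cfl = cfl, tol_mmHg = tol_mmHg,
                 max_cycles = max_cycles, junction_mode = junction_mode,
                 n_out = n_out, u_margin_cm_s = u_margin_cm_s,
                 fixed_cycles = fixed_cycles, dt_s = dt_s),
            class = "numerics_config")
}

## coarse preset used for optimisation loops
coarse_numerics <- function(...) numerics_config(dx_cm = 1.0, ...)

## Build the per-vessel discrete arrays the C++ core consumes.
## Returns list(vessels=..., idx (id -> 0-based index), meta)
discretize_tree <- function(tree, wall, params, numerics) {
  vs <- tree$vessels
  wk <- tree$windkessel
  n <- nrow(vs)
  idx0 <- seq_len(n) - 1L
  names(idx0) <- as.character(vs$id)
  fist <- attr(tree, "fistula_cpp") # set by add_fistula(); NULL otherwise
  out <- vector("list", n)
  for (i in seq_len(n)) {
    L <- vs$length_cm[i]
    N <- max(3L, as.integer(round(L / numerics$dx_cm)) + 1L)
    dx <- L / (N - 1)
    x <- seq(0, L, length.out = N)
    r0 <- vs$r_in_cm[i] + (vs$r_out_cm[i] - vs$r_in_cm[i]) * x / L
    xh <- (x[-1] + x[-N]) / 2
    r0h <- vs$r_in_cm[i] + (vs$r_out_cm[i] - vs$r_in_cm[i]) * xh / L
    rec <- list(
      N = N, dx = dx,
      dr0dx = (vs$r_out_cm[i] - vs$r_in_cm[i]) / L,
      f = wall_stiffness(r0, wall), dfdr = wall_stiffness_deriv(r0, wall),
      r0 = r0, A0 = pi * r0^2,
      fh = wall_stiffness(r0h, wall),
      dfdrh = wall_stiffness_deriv(r0h, wall),
      r0h = r0h, A0h = pi * r0h^2,
      d1 = if (is.na(vs$d1[i])) -1L else idx0[[as.character(vs$d1[i])]],
      d2 = if (is.na(vs$d2[i])) -1L else idx0[[as.character(vs$d2[i])]]
    )
    if (vs$terminal[i]) {
      w <- wk[wk$id == vs$id[i], ]
      rec$wk <- c(w$R1 * params$S_R, w$R2 * params$S_R, w$C * params$S_C,
                  mmHg_to_dyn(w$p_out_mmHg))
    }
    if (!is.null(fist) && fist$vessel_id == vs$id[i]) {
      rec$fist <- c(fist$Rf, fist$R1v, fist$R2v, fist$Cv,
                    mmHg_to_dyn(fist$p_out_mmHg))
    }
    out[[i]] <- rec
  }
  list(vessels = out, idx0 = idx0)
}

#' Simulate the arterial tree to a periodic cycle
#'
#' Runs the 1D network solver cycle after cycle until the root pressure trace
#' repeats to within `numerics$tol_mmHg` (max norm) or `max_cycles` is
#' reached. The returned object carries the space-time pressure/flow/area
#' fields of the final cycle for every vessel, the convergence metadata and a
#' volume-conservation audit.
#'
#' @param tree an `arterial_tree` (already height-scaled if desired).
#' @param params a `patient_parameters` object.
#' @param constants a `hemo_constants` object.
#' @param numerics a `numerics_config` object.
#' @param inflow optional replacement inflow: a function of time in ms
#'   returning cm^3/s, overriding [inflow_profile()].
#' @param p_init_mmHg initial uniform pressure; defaults to the estimated
#'   mean arterial pressure so the periodic regime is reached quickly.
#' @return an object of class `sim_result`.
#' @export
simulate_cycle <- function(tree, params, constants = hemo_constants(),
                           numerics = numerics_config(), inflow = NULL,
                           p_init_mmHg = NULL) {
  wall <- wall_model(params$k1, params$k3, p_ref_mmHg = tree$p_ref_mmHg)
  T_s <- 60 / params$HR
  disc <- discretize_tree(tree, wall, params, numerics)
  rho <- constants$rho
  delta <- constants$delta_cm %||% sqrt((constants$mu / rho) * T_s / (2 * pi))

  ## time step from the maximal equilibrium wave speed plus a velocity margin
  dt_cand <- vapply(disc$vessels, function(v) {
    cmax <- sqrt(max(v$f) / (2 * rho))
    v$dx / (1.4 * cmax + numerics$u_margin_cm_s)
  }, 1)
  dt <- numerics$dt_s %||% (numerics$cfl * min(dt_cand))
  nsteps <- as.integer(ceiling(T_s / dt))
  if (is.null(numerics$dt_s)) {
    ## quantise the step count to a geometric grid (ratio 1.25) so that
    ## nearby parameter sets share the same discretisation; this keeps
    ## objective functions smooth in the parameters during fitting at a
    ## mean cost of ~12% extra steps
    k <- ceiling(log(nsteps) / log(1.25))
    nsteps <- as.integer(ceiling(1.25^k))
  }
  dt <- T_s / nsteps
  n_out <- min(numerics$n_out, nsteps)

  t_ms <- seq(0, T_s, length.out = nsteps + 1) * 1000
  qin <- if (is.null(inflow)) inflow_profile(t_ms, params) else inflow(t_ms)
  if (any(!is.finite(qin))) stop("non-finite inflow values")

  if (is.null(p_init_mmHg)) {
    wk <- tree$windkessel
    r_tot <- 1 / sum(1 / ((wk$R1 + wk$R2) * params$S_R))
    p_init_mmHg <- mean(wk$p_out_mmHg) +
      dyn_to_mmHg(lmin_to_mls(params$CO) * r_tot)
  }

  res <- .pw_solve(disc$vessels, list(
    rho = rho, mu = constants$mu, delta = delta,
    pref = mmHg_to_dyn(tree$p_ref_mmHg),
    dt = dt, nsteps = nsteps, n_out = n_out,
    tol = mmHg_to_dyn(numerics$tol_mmHg),
    max_cycles = as.integer(numerics$max_cycles),
    fixed_cycles = as.integer(numerics$fixed_cycles %||% 0L),
    total_pressure = identical(numerics$junction_mode, "total_pressure"),
    inflow = qin, root = unname(disc$idx0[[as.character(tree$root)]]),
    p_init = mmHg_to_dyn(p_init_mmHg)
  ))

  fields <- lapply(seq_along(res$fields), function(i) {
    f <- res$fields[[i]]
    list(p = dyn_to_mmHg(f$p), q = f$q, A = f$A,
         x = seq(0, tree$vessels$length_cm[i], length.out = disc$vessels[[i]]$N))
  })
  names(fields) <- as.character(tree$vessels$id)

  sv <- params$SV
  structure(list(
    fields = fields, time_s = seq(0, T_s, length.out = n_out + 1),
    tree = tree, params = params, constants = constants,
    numerics = numerics, dt_s = dt, nsteps = nsteps,
    cycles = res$cycles, converged = res$converged,
    residuals_mmHg = dyn_to_mmHg(res$residuals),
    conservation = list(
      inflow_volume = res$inflow_volume,
      outflow_volume = res$outflow_volume,
      volume_change = res$volume_change,
      residual_fraction_of_SV =
        (res$inflow_volume - res$outflow_volume - res$volume_change) / sv
    ),
    fistula_flow = if (!is.null(attr(tree, "fistula_cpp")))
      as.numeric(res$fistula_flow) else NULL
  ), class = "sim_result")
}

#' @describeIn simulate_cycle run to the periodic regime and error if the
#'   cycle-to-cycle tolerance is not met within `max_cycles`.
#' @param tol_mmHg,max_cycles override the corresponding `numerics` entries.
#' @export
converge_to_periodic <- function(tree, params, constants = hemo_constants(),
                                 numerics = numerics_config(),
                                 tol_mmHg = numerics$tol_mmHg,
                                 max_cycles = numerics$max_cycles, ...) {
  stopifnot(tol_mmHg > 0)
  numerics$tol_mmHg <- tol_mmHg
  numerics$max_cycles <- max_cycles
  sim <- simulate_cycle(tree, params, constants, numerics, ...)
  if (!sim$converged)
    stop("no periodic convergence after ", sim$cycles,
         " cycles; residual trace (mmHg): ",
         paste(signif(sim$residuals_mmHg, 3), collapse = ", "))
  sim
}

#' Extract the pressure waveform at a site of a simulation
#'
#' @param sim a `sim_result`.
#' @param site a named site (e.g. `"radial_distal"`, `"aortic_root"`) or
#'   `list(vessel=, position=)`.
#' @param what `"p"` (mmHg), `"q"` (cm^3/s) or `"A"` (cm^2).
#' @return a [pressure_waveform()] (for `what = "p"`) or a data frame.
#' @export
site_waveform <- function(sim, site, what = c("p", "q", "A")) {
  what <- match.arg(what)
  s <- resolve_site(sim$tree, site)
  f <- sim$fields[[as.character(s$vessel)]]
  if (is.null(f)) stop("vessel ", s$vessel, " not in simulation")
  x <- s$position * max(f$x)
  j <- findInterval(x, f$x, rightmost.closed = TRUE)
  j <- min(max(j, 1), length(f$x) - 1)
  w <- (x - f$x[j]) / (f$x[j + 1] - f$x[j])
  vals <- (1 - w) * f[[what]][, j] + w * f[[what]][, j + 1]
  t_ms <- sim$time_s * 1000
  if (what == "p") {
    # drop the duplicated cycle endpoint: one period within one sample
    pressure_waveform(t_ms[-length(t_ms)], vals[-length(vals)],
                      HR = sim$params$HR, calibrated = TRUE)
  } else data.frame(time_ms = t_ms, value = vals)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", length(x$fields), " vessels, ", x$cycles,
      " cycles (converged: ", x$converged, "), dt ",
      signif(x$dt_s * 1000, 3), " ms, volume residual ",
      signif(100 * x$conservation$residual_fraction_of_SV, 3), "% of SV\n",
      sep = "")
  invisible(x)
}
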