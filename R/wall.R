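#' Arterial wall stiffness model
#'
#' The local wall stiffness is
#' `F(r0) = (4/3) * (k1 * exp(-k2 * r0) + k3)` in g/(s^2 cm), where `r0` is
#' the vessel radius (cm) at the reference pressure. `k1` governs small
#' arteries (`r0 << 1` cm, where `F ~ (4/3)(k1 + k3)`) and `k3` governs the
#' large ones (`r0 >> 1`, where the exponential term vanishes); `k2` (1/cm)
#' fixes the cross-over scale and is not patient-specific.
#'
#' @param k1 small-artery stiffness coefficient, g/(s^2 cm).
#' @param k3 large-artery stiffness coefficient, g/(s^2 cm).
#' @param k2 exponential rate, 1/cm (fixed, 22.53).
#' @param p_ref_mmHg reference pressure at which vessel radii are defined.
#' @return an object of class `wall_model`.
#' @export
wall_model <- function(k1, k3, k2 = 22.53, p_ref_mmHg = 97) {
  stopifnot(is.numeric(k1), is.numeric(k3), k1 >= 0, k3 > 0, k2 > 0,
            p_ref_mmHg > 0)
  structure(list(k1 = k1, k2 = k2, k3 = k3, p_ref_mmHg = p_ref_mmHg),
            class = "wall_model")
}

#' @describeIn wall_model evaluate the stiffness `F(r0)` (vectorised in `r0`).
#' @param r0 reference radius, cm (> 0).
#' @param wall a `wall_model`.
#' @export
wall_stiffness <- function(r0, wall) {
  if (any(r0 <= 0)) stop("r0 must be positive")
  (4 / 3) * (wall$k1 * exp(-wall$k2 * r0) + wall$k3)
}

## dF/dr0, used by the solver's geometric source term
wall_stiffness_deriv <- function(r0, wall) {
  -(4 / 3) * wall$k2 * wall$k1 * exp(-wall$k2 * r0)
}

#' Pressure-area tube law
#'
#' Closes the 1D flow equations:
#' `p(A) = p_ref + F * (1 - sqrt(A0/A))`, anchored so that `p(A0) = p_ref`
#' (97 mmHg by default, the pressure at which the reference radii are
#' defined). `F` is in CGS; pressures are in mmHg at this interface.
#'
#' @param A cross-sectional area, cm^2.
#' @param A0 reference area at `p_ref`, cm^2.
#' @param F wall stiffness, g/(s^2 cm).
#' @param p_ref_mmHg reference pressure, mmHg.
#' @return pressure in mmHg (`tube_law`) or area in cm^2
#'   (`inverse_tube_law`).
#' @export
tube_law <- function(A, A0, F, p_ref_mmHg = 97) {
  stopifnot(all(A > 0), all(A0 > 0), all(F > 0))
  p_ref_mmHg + dyn_to_mmHg(F * (1 - sqrt(A0 / A)))
}

#' @rdname tube_law
#' @param p pressure in mmHg.
#' @export
inverse_tube_law <- function(p, A0, F, p_ref_mmHg = 97) {
  stopifnot(all(A0 > 0), all(F > 0))
  s <- 1 - mmHg_to_dyn(p - p_ref_mmHg) / F
  if (any(s <= 0))
    stop("pressure not reachable by the tube law (p <= p_ref - F)")
  A0 / s^2
}

#' Linearised pulse wave speed at the reference area
#'
#' `c0 = sqrt(F / (2 rho))`, the local small-amplitude wave speed at `A = A0`.
#'
#' @param r0 reference radius, cm.
#' @param wall a `wall_model`.
#' @param rho blood density, g/cm^3.
#' @return wave speed in cm/s.
#' @export
wave_speed_c0 <- function(r0, wall, rho = 1.055) {
  sqrt(wall_stiffness(r0, wall) / (2 * rho))
}
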