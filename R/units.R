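## Unit conventions: the solver works in CGS (cm, g, s, dyn); pressures cross
## the user-facing boundary in mmHg and flows in ml/s or l/min.

#' Unit conversion helpers
#'
#' The haemodynamic core works in CGS units; pressures are exposed in mmHg
#' (1 mmHg = 1333.22 dyn/cm^2) and cardiac output in l/min.
#'
#' @param p pressure value(s).
#' @return the converted value(s).
#' @name units
NULL

MMHG_DYN <- 1333.22

#' @rdname units
#' @export
mmHg_to_dyn <- function(p) p * MMHG_DYN

#' @rdname units
#' @export
dyn_to_mmHg <- function(p) p / MMHG_DYN

## l/min -> cm^3/s
lmin_to_mls <- function(x) x * 1000 / 60

#' Deterministic per-stage seed derivation
#'
#' Fans one global seed out into independent per-stage seeds (kept below
#' 2^31), so that pipeline stages are individually reproducible.
#'
#' @param seed global integer seed.
#' @param stage integer stage index.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  s <- (as.double(seed) %% 2147483647)
  h <- (s * 48271 + 11 * stage) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
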