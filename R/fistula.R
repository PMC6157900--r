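#' Arteriovenous fistula specification
#'
#' A reduced representation of a dialysis access fistula: a lumped shunt
#' (anastomosis resistance in series with a venous Windkessel) attached to
#' the arterial tree at the access site. The lower-arm site is the distal
#' end of the fistula-arm radial artery; the upper-arm site splits the
#' fistula-arm brachial artery at a configurable fraction and attaches the
#' shunt at the split. The default anastomosis resistance is calibrated so
#' the access flow falls in the clinically typical range (several hundred
#' ml/min up to above 600 ml/min).
#'
#' @param site `"lower_arm"` or `"upper_arm"`.
#' @param resistance anastomosis resistance, dyn s/cm^5.
#' @param venous venous outflow Windkessel ([windkessel_bc()]); the default
#'   is a low-resistance, high-compliance venous bed at 5 mmHg.
#' @param brachial_fraction where along the brachial artery the upper-arm
#'   anastomosis sits.
#' @return object of class `fistula_spec`.
#' @export
fistula_spec <- function(site = c("lower_arm", "upper_arm"),
                         resistance = 6000,
                         venous = windkessel_bc(R1 = 150, R2 = 400,
                                                C = 5e-3, p_out_mmHg = 5),
                         brachial_fraction = 0.5) {
  site <- match.arg(site)
  stopifnot(resistance > 0, brachial_fraction > 0, brachial_fraction < 1)
  structure(list(site = site, resistance = resistance, venous = venous,
                 brachial_fraction = brachial_fraction),
            class = "fistula_spec")
}

#' Attach an arteriovenous fistula to a tree
#'
#' Returns a modified tree carrying the shunt. For the lower-arm site the
#' shunt is attached at the distal end of the fistula-arm radial artery (in
#' parallel with its terminal Windkessel); for the upper-arm site the
#' fistula-arm brachial artery is split at `brachial_fraction` and the shunt
#' drains from the split point. The original topology is otherwise
#' unchanged.
#'
#' @param tree an `arterial_tree` (the packaged nominal tree names the
#'   fistula-arm vessels `l_radial` / `l_brachial`).
#' @param spec a [fistula_spec()].
#' @return the modified `arterial_tree` (carries the fistula attributes used
#'   by the solver).
#' @export
add_fistula <- function(tree, spec) {
  stopifnot(inherits(spec, "fistula_spec"))
  vs <- tree$vessels
  if (spec$site == "lower_arm") {
    site <- tree$named_sites[["radial_fistula_arm"]]
    if (is.null(site)) stop("tree has no 'radial_fistula_arm' named site; ",
                            "valid sites need the packaged nominal tree")
    vid <- site$vessel
    if (!vs$terminal[match(vid, vs$id)])
      stop("lower-arm fistula vessel must be terminal")
  } else {
    bsite <- tree$named_sites[["brachial_mid"]]
    if (is.null(bsite)) stop("tree has no 'brachial_mid' named site")
    bid <- bsite$vessel
    i <- match(bid, vs$id)
    newid <- max(vs$id) + 1L
    frac <- spec$brachial_fraction
    L <- vs$length_cm[i]
    r_mid <- vs$r_in_cm[i] + (vs$r_out_cm[i] - vs$r_in_cm[i]) * frac
    ## distal half becomes a new vessel; proximal keeps the id and gets a
    ## single daughter plus the shunt (a fistula junction)
    distal <- vs[i, ]
    distal$id <- newid
    distal$name <- paste0(vs$name[i], "_distal")
    distal$length_cm <- (1 - frac) * L
    distal$r_in_cm <- r_mid
    vs$length_cm[i] <- frac * L
    vs$r_out_cm[i] <- r_mid
    vs$name[i] <- paste0(vs$name[i], "_proximal")
    vs$d1[i] <- newid; vs$d2[i] <- NA_integer_
    vs <- rbind(vs, distal)
    ## named sites referring to the split vessel keep working on the
    ## proximal part; remap those beyond the split
    for (nm in names(tree$named_sites)) {
      s <- tree$named_sites[[nm]]
      if (s$vessel == bid) {
        if (s$position <= frac) {
          tree$named_sites[[nm]]$position <- s$position / frac
        } else {
          tree$named_sites[[nm]] <- list(vessel = newid,
                                         position = (s$position - frac) /
                                           (1 - frac))
        }
      }
    }
    tree$vessels <- vs
    vid <- bid
  }
  attr(tree, "fistula_cpp") <- list(
    vessel_id = vid, Rf = spec$resistance,
    R1v = spec$venous$R1, R2v = spec$venous$R2, Cv = spec$venous$C,
    p_out_mmHg = spec$venous$p_out_mmHg)
  attr(tree, "fistula_spec") <- spec
  tree
}

#' Radial-to-aortic pressure transfer function
#'
#' Per-harmonic ratio of the discrete Fourier components of the aortic over
#' the radial pressure waveform of one periodic cycle, at integer multiples
#' of the heart rate (harmonic 0, the mean, is excluded).
#'
#' @param sim a `sim_result`.
#' @param radial_site,aortic_site sites (names or `list(vessel=, position=)`).
#' @param n_harmonics number of harmonics reported.
#' @return object of class `transfer_function`: data frame with
#'   `frequency_hz`, `modulus`, `phase`.
#' @export
radial_to_aortic_transfer_function <- function(sim,
                                               radial_site = "radial_distal",
                                               aortic_site = "aortic_root",
                                               n_harmonics = 10) {
  wr <- site_waveform(sim, radial_site)
  wa <- site_waveform(sim, aortic_site)
  n <- length(wr$pressure_mmHg)
  stopifnot(length(wa$pressure_mmHg) == n)
  Fr <- fft(wr$pressure_mmHg); Fa <- fft(wa$pressure_mmHg)
  kmax <- min(n_harmonics, floor((n - 1) / 2))
  ratio <- Fa[2:(kmax + 1)] / Fr[2:(kmax + 1)]
  f0 <- wr$HR / 60
  structure(data.frame(
    harmonic = seq_len(kmax),
    frequency_hz = f0 * seq_len(kmax),
    modulus = Mod(ratio),
    phase = Arg(ratio)
  ), class = c("transfer_function", "data.frame"))
}

#' Fistula-free refitting experiment
#'
#' For each virtual control subject: simulate the radial waveform with an
#' active arteriovenous fistula, then fit the fistula-free model to it and
#' report the waveform approximation error and the percent deviation of each
#' of the six recovered parameters from the generating truth. This
#' quantifies the bias incurred by ignoring the access when modelling
#' dialysis patients (expected: small approximation error, with
#' underestimation of small-artery stiffness `k1` and of the terminal
#' resistance scaling `S_R`).
#'
#' @param subjects list of virtual subjects ([sample_virtual_patient()]).
#' @param fspec a [fistula_spec()].
#' @param config fitting configuration.
#' @param tree nominal tree.
#' @param gen_numerics solver settings for generating the fistula waveforms.
#' @param spec population spec (for the virtual recorder settings; noise is
#'   disabled here so deviations are attributable to the fistula alone).
#' @param start_at_truth seed the search at the generating parameters
#'   (default). The experiment quantifies the *bias* of the fistula-free
#'   model — the location of its optimum relative to the truth — so the
#'   local search descends from the truth to the nearest fistula-free
#'   optimum; a cold global search at desk-scale budgets measures search
#'   noise instead.
#' @return data frame: one row per subject and parameter with `truth`,
#'   `fitted`, `pct_change`, plus the per-subject `rel_error` (percent) and
#'   `converged` flag.
#' @export
fistula_free_refit_experiment <- function(subjects,
                                          fspec = fistula_spec(),
                                          config = fit_config(),
                                          tree = nominal_tree(),
                                          gen_numerics = config$numerics,
                                          spec = population_spec(),
                                          start_at_truth = TRUE) {
  out <- list()
  for (s in subjects) {
    tree_s <- scale_tree_to_height(tree, s$height_cm)
    tree_f <- add_fistula(tree_s, fspec)
    pars <- subject_parameters_at(s, "single", spec)
    row <- tryCatch({
      sim <- simulate_cycle(tree_f, pars, numerics = gen_numerics)
      w <- site_waveform(sim, "radial_distal")
      truth_vec <- unlist(pars[c("k1", "k3", "CO", "tau", "S_R", "S_C")])
      fit <- fit_patient(w, meta = list(HR = s$HR, height_cm = s$height_cm,
                                        brachial_SP = s$brachial_SP,
                                        brachial_DP = s$brachial_DP),
                         tree = tree, config = config,
                         start = if (start_at_truth) truth_vec)
      data.frame(
        subject = s$id,
        parameter = c("k1", "k3", "CO", "tau", "S_R", "S_C"),
        truth = unlist(pars[c("k1", "k3", "CO", "tau", "S_R", "S_C")]),
        fitted = unlist(fit$estimates),
        rel_error = fit$rel_error,
        converged = fit$converged,
        row.names = NULL
      )
    }, error = function(e) {
      data.frame(subject = s$id,
                 parameter = c("k1", "k3", "CO", "tau", "S_R", "S_C"),
                 truth = NA_real_, fitted = NA_real_, rel_error = NA_real_,
                 converged = FALSE, row.names = NULL)
    })
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  res$pct_change <- 100 * (res$fitted - res$truth) / res$truth
  res
}
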