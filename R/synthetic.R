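#' Virtual population specification
#'
#' Parameter and covariate distributions for the two emulated groups: a
#' haemodialysis (HD) cohort measured 8 times across two dialysis sessions
#' and a healthy control group measured once. Model-parameter defaults are
#' the published HD cohort means/SDs (k3 = 14.51 +/- 9.03 x 10^5 g/(s^2 cm),
#' k1 = 2.28 +/- 1.73 x 10^7 g/(s^2 cm), CO = 3.56 +/- 0.8 l/min,
#' tau = 101.08 +/- 20.78 ms, S_C = 13.57 +/- 4.34, S_R = 1.34 +/- 0.56);
#' control stiffness parameters are set ~60% below the pre-dialytic HD level
#' and control bed compliance somewhat lower, emulating the reported group
#' contrast. Covariates follow the published cohort tables (age 61.2 +/- 14.3
#' vs 42.7 +/- 9.3 years, 43% vs 47% male, height 167.9 +/- 9.4 vs
#' 173.4 +/- 10.8 cm); heart rate and brachial pressures are not published
#' and use field-plausible defaults.
#'
#' Session effects are multiplicative factors applied per measurement moment,
#' defaulting to the ratio of the printed before-start and before-end large
#' artery stiffness means (9.92/16.44 at the before-end point) with milder
#' transient reductions of CO and tau; they are an emulation device, not
#' ground truth.
#'
#' @param missingness probability that a scheduled HD recording is missing
#'   (quality exclusion emulated as missing-completely-at-random); default
#'   25/280, the published missing-record rate.
#' @param device_rate_hz waveform resampling rate of the virtual recorder.
#' @param noise_frac amplitude-proportional Gaussian noise SD as a fraction
#'   of the pulse pressure.
#' @param wander_mmHg amplitude of a slow sinusoidal baseline wander.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(missingness = 25 / 280, device_rate_hz = 128,
                            noise_frac = 0.015, wander_mmHg = 0.3) {
  stopifnot(missingness >= 0, missingness <= 1, device_rate_hz > 0,
            noise_frac >= 0, wander_mmHg >= 0)
  par_tab <- function(k1m, k1s, k3m, k3s, COm, COs, taum, taus,
                      SRm, SRs, SCm, SCs)
    data.frame(parameter = c("k1", "k3", "CO", "tau", "S_R", "S_C"),
               mean = c(k1m, k3m, COm, taum, SRm, SCm),
               sd = c(k1s, k3s, COs, taus, SRs, SCs))
  cov_tab <- function(agem, ages, male, hm, hs, wm, ws, hrm, hrs,
                      spm, sps, ppm, pps)
    list(age = c(agem, ages), male_fraction = male, height = c(hm, hs),
         weight = c(wm, ws), HR = c(hrm, hrs), brachial_DP = c(spm, sps),
         pulse_pressure = c(ppm, pps))
  structure(list(
    hd = list(
      params = par_tab(2.28e7, 1.73e7, 14.51e5, 9.03e5, 3.56, 0.8,
                       101.08, 20.78, 1.34, 0.56, 13.57, 4.34),
      covariates = cov_tab(61.2, 14.3, 0.43, 167.9, 9.4, 72.2, 19.9,
                           72, 10, 75, 10, 55, 15)
    ),
    control = list(
      params = par_tab(1.4e7, 1.1e7, 9.0e5, 5.6e5, 3.56, 0.8,
                       101.08, 20.78, 1.20, 0.50, 10.5, 3.5),
      covariates = cov_tab(42.7, 9.3, 0.47, 173.4, 10.8, 78.3, 19.1,
                           66, 9, 75, 8, 48, 12)
    ),
    session_effects = list(
      before_start = c(k3 = 1.00, CO = 1.00, tau = 1.00),
      after_start  = c(k3 = 0.88, CO = 0.95, tau = 0.95),
      before_end   = c(k3 = 9.92 / 16.44, CO = 0.88, tau = 0.90),
      after_end    = c(k3 = 0.92, CO = 0.95, tau = 0.97),
      single       = c(k3 = 1.00, CO = 1.00, tau = 1.00)
    ),
    missingness = missingness,
    device_rate_hz = device_rate_hz,
    noise_frac = noise_frac,
    wander_mmHg = wander_mmHg
  ), class = "population_spec")
}

## truncated normal draw on [max(lo, mean-4sd), mean+4sd]; the latent mean
## is calibrated so the truncated distribution keeps the requested mean
## (one-sided truncation at a positivity bound would otherwise bias wide
## distributions such as k1 upwards)
rtrunc_norm <- function(n, mean, sd, lo = 0) {
  if (sd == 0) return(rep(mean, n))
  a <- max(lo, mean - 4 * sd); b <- mean + 4 * sd
  if (a >= b) stop("infeasible truncated-normal spec (mean ", mean,
                   ", sd ", sd, ", lower bound ", lo, ")")
  trunc_mean <- function(mu) {
    al <- (a - mu) / sd; be <- (b - mu) / sd
    z <- pnorm(be) - pnorm(al)
    mu + sd * (dnorm(al) - dnorm(be)) / z
  }
  mu <- if (trunc_mean(mean) - mean < 1e-9 * sd) mean else
    uniroot(function(m) trunc_mean(m) - mean,
            c(mean - 3 * sd, mean + sd), tol = 1e-9 * sd)$root
  Fa <- pnorm(a, mu, sd); Fb <- pnorm(b, mu, sd)
  qnorm(Fa + runif(n) * (Fb - Fa), mu, sd)
}

#' Draw one virtual subject
#'
#' Model parameters come from truncated normal distributions (truncated at
#' zero and at mean +/- 4 SD); covariates likewise, with gender a Bernoulli
#' draw at the group male fraction. Reproducible under `seed`.
#'
#' @param spec a `population_spec`.
#' @param group `"hd"` or `"control"`.
#' @param seed integer seed.
#' @param id subject identifier.
#' @return list with `id`, `group`, `params` (named baseline parameter
#'   vector), and covariates (`age`, `gender`, `height_cm`, `weight_kg`,
#'   `HR`, `brachial_SP`, `brachial_DP`).
#' @export
sample_virtual_patient <- function(spec, group = c("hd", "control"),
                                   seed = 1, id = 1L) {
  group <- match.arg(group)
  g <- spec[[group]]
  set.seed(derive_seed(seed, 11L))
  draw1 <- function(tab, nm, lo = 0) {
    i <- match(nm, tab$parameter)
    rtrunc_norm(1, tab$mean[i], tab$sd[i], lo)
  }
  params <- vapply(c("k1", "k3", "CO", "tau", "S_R", "S_C"),
                   function(nm) draw1(g$params, nm, lo = switch(
                     nm, k1 = 1e5, k3 = 1e5, CO = 1.0, tau = 40,
                     S_R = 0.2, S_C = 1.0)), 1)
  cv <- g$covariates
  HR <- rtrunc_norm(1, cv$HR[1], cv$HR[2], lo = 45)
  ## keep tau safely inside the default ejection duration T/3
  tau_max <- 0.8 * (60000 / HR) / 3
  params[["tau"]] <- min(params[["tau"]], tau_max)
  DP <- rtrunc_norm(1, cv$brachial_DP[1], cv$brachial_DP[2], lo = 40)
  PP <- rtrunc_norm(1, cv$pulse_pressure[1], cv$pulse_pressure[2], lo = 20)
  list(
    id = id, group = group, params = params,
    age = rtrunc_norm(1, cv$age[1], cv$age[2], lo = 18),
    gender = if (runif(1) < cv$male_fraction) "male" else "female",
    height_cm = min(215, max(125, rtrunc_norm(1, cv$height[1], cv$height[2],
                                              lo = 120))),
    weight_kg = rtrunc_norm(1, cv$weight[1], cv$weight[2], lo = 35),
    HR = HR, brachial_SP = DP + PP, brachial_DP = DP
  )
}

## subject parameters at a measurement moment (session effects applied)
subject_parameters_at <- function(subject, timepoint, spec) {
  m <- spec$session_effects[[timepoint]]
  if (is.null(m)) stop("unknown time point '", timepoint, "'")
  p <- subject$params
  p[["k3"]] <- p[["k3"]] * m[["k3"]]
  p[["CO"]] <- p[["CO"]] * m[["CO"]]
  p[["tau"]] <- p[["tau"]] * m[["tau"]]
  patient_parameters(k1 = p[["k1"]], k3 = p[["k3"]], CO = p[["CO"]],
                     tau = p[["tau"]], S_R = p[["S_R"]], S_C = p[["S_C"]],
                     HR = subject$HR, height_cm = subject$height_cm,
                     brachial_SP = subject$brachial_SP,
                     brachial_DP = subject$brachial_DP)
}

#' Generate one virtual radial recording
#'
#' Runs the forward model for the subject (with session effects applied to
#' the parameters at the given measurement moment), samples the distal
#' radial pressure at the device rate, and adds amplitude-proportional
#' Gaussian noise plus a small sinusoidal baseline wander. The generating
#' ("truth") parameters are attached.
#'
#' @param subject from [sample_virtual_patient()].
#' @param timepoint one of `"before_start"`, `"after_start"`, `"before_end"`,
#'   `"after_end"`, `"single"`.
#' @param spec a `population_spec`.
#' @param seed integer seed for the measurement noise.
#' @param tree nominal arterial tree (height-scaled internally).
#' @param numerics solver settings for the generator.
#' @return list with elements `waveform` (a calibrated `pressure_waveform`),
#'   `truth` (a `patient_parameters`), `timepoint`, and `missing = FALSE`;
#'   on solver failure, `missing = TRUE` with the failure `cause`.
#' @export
generate_recording <- function(subject, timepoint = "single",
                               spec = population_spec(), seed = 1,
                               tree = nominal_tree(),
                               numerics = numerics_config(dx_cm = 1)) {
  pars <- subject_parameters_at(subject, timepoint, spec)
  tree_s <- scale_tree_to_height(tree, subject$height_cm)
  rec <- tryCatch({
    sim <- simulate_cycle(tree_s, pars, numerics = numerics)
    w <- site_waveform(sim, "radial_distal")
    T_ms <- cycle_length_ms(w)
    n <- max(8L, as.integer(floor(spec$device_rate_hz * T_ms / 1000)))
    t_dev <- (seq_len(n) - 1) * 1000 / spec$device_rate_hz
    p <- interp_periodic(w, t_dev)
    set.seed(derive_seed(seed, 13L))
    if (spec$noise_frac > 0)
      p <- p + rnorm(n, 0, spec$noise_frac * (max(p) - min(p)))
    if (spec$wander_mmHg > 0)
      p <- p + spec$wander_mmHg * sin(2 * pi * t_dev / T_ms + runif(1, 0, 2 * pi))
    list(waveform = pressure_waveform(t_dev, p, HR = subject$HR,
                                      calibrated = TRUE),
         truth = pars, timepoint = timepoint, missing = FALSE, cause = NULL)
  }, error = function(e)
    list(waveform = NULL, truth = pars, timepoint = timepoint,
         missing = TRUE, cause = conditionMessage(e)))
  rec
}

#' Generate a full virtual cohort dataset
#'
#' Emulates the study design: each HD subject is scheduled for 2 sessions
#' (after a 3-day and a 2-day interdialytic break) x 4 measurement moments,
#' each independently missing with the population spec's missingness rate;
#' controls are measured once. With `waveforms = "none"` only the truth
#' parameter trajectories and the missingness pattern are generated (fast
#' path for statistical work); `"simulate"` also runs the forward model for
#' every non-missing slot.
#'
#' @param n_hd,n_control group sizes.
#' @param spec a `population_spec`.
#' @param seed master seed; all subject, missingness and noise seeds derive
#'   from it.
#' @param waveforms `"simulate"` or `"none"`.
#' @param tree,numerics forwarded to [generate_recording()].
#' @return object of class `cohort_dataset`: `subjects` data frame and
#'   `recordings` list (subject id, session, timepoint, missing flag, truth
#'   parameters, waveform or NULL).
#' @export
generate_cohort_dataset <- function(n_hd, n_control,
                                    spec = population_spec(), seed = 1,
                                    waveforms = c("simulate", "none"),
                                    tree = nominal_tree(),
                                    numerics = numerics_config(dx_cm = 1)) {
  waveforms <- match.arg(waveforms)
  stopifnot(n_hd >= 0, n_control >= 0)
  subjects <- list(); recordings <- list()
  k <- 0L
  sched <- expand.grid(session = c("3day", "2day"),
                       timepoint = c("before_start", "after_start",
                                     "before_end", "after_end"),
                       stringsAsFactors = FALSE)
  sched <- sched[order(sched$session, decreasing = TRUE), ]
  for (g in c("hd", "control")) {
    n_g <- if (g == "hd") n_hd else n_control
    for (i in seq_len(n_g)) {
      k <- k + 1L
      subj <- sample_virtual_patient(spec, g, seed = derive_seed(seed, 100L + k),
                                     id = k)
      subjects[[k]] <- subj
      slots <- if (g == "hd") sched else
        data.frame(session = "none", timepoint = "single",
                   stringsAsFactors = FALSE)
      for (s in seq_len(nrow(slots))) {
        rseed <- derive_seed(seed, 100000L + 1000L * k + s)
        set.seed(derive_seed(rseed, 7L))
        miss <- (g == "hd") && (runif(1) < spec$missingness)
        rec <- if (miss) {
          list(waveform = NULL,
               truth = subject_parameters_at(subj, slots$timepoint[s], spec),
               timepoint = slots$timepoint[s], missing = TRUE,
               cause = "quality exclusion")
        } else if (waveforms == "simulate") {
          generate_recording(subj, slots$timepoint[s], spec, seed = rseed,
                             tree = tree, numerics = numerics)
        } else {
          list(waveform = NULL,
               truth = subject_parameters_at(subj, slots$timepoint[s], spec),
               timepoint = slots$timepoint[s], missing = FALSE, cause = NULL)
        }
        rec$subject_id <- k
        rec$session <- slots$session[s]
        rec$seed <- rseed
        recordings[[length(recordings) + 1L]] <- rec
      }
    }
  }
  subj_df <- do.call(rbind, lapply(subjects, function(s)
    data.frame(id = s$id, group = s$group, age = s$age, gender = s$gender,
               height_cm = s$height_cm, weight_kg = s$weight_kg, HR = s$HR,
               brachial_SP = s$brachial_SP, brachial_DP = s$brachial_DP,
               stringsAsFactors = FALSE)))
  structure(list(subjects = subj_df, subject_list = subjects,
                 recordings = recordings, spec = spec, seed = seed,
                 waveforms = waveforms),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  n_miss <- sum(vapply(x$recordings, function(r) r$missing, TRUE))
  cat("<cohort_dataset> ", nrow(x$subjects), " subjects (",
      sum(x$subjects$group == "hd"), " HD, ",
      sum(x$subjects$group == "control"), " control), ",
      length(x$recordings), " scheduled recordings, ", n_miss,
      " missing (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Truth-parameter repeated-measures table of a cohort
#'
#' Subjects x measurement-moment matrix of one generating parameter for the
#' HD group (8 columns: 2 sessions x 4 moments); missing recordings are NA.
#'
#' @param ds a `cohort_dataset`.
#' @param parameter one of `"k1"`, `"k3"`, `"CO"`, `"tau"`, `"S_R"`, `"S_C"`,
#'   or `"SV"`.
#' @return numeric matrix with rownames = subject ids and one column per
#'   session/time point.
#' @export
cohort_parameter_table <- function(ds, parameter = "k3") {
  hd_ids <- ds$subjects$id[ds$subjects$group == "hd"]
  cols <- c(t(outer(c("3day", "2day"),
                    c("before_start", "after_start", "before_end",
                      "after_end"), paste, sep = ":")))
  m <- matrix(NA_real_, length(hd_ids), length(cols),
              dimnames = list(hd_ids, cols))
  for (r in ds$recordings) {
    if (!(r$subject_id %in% hd_ids)) next
    cl <- paste(r$session, r$timepoint, sep = ":")
    if (!r$missing)
      m[as.character(r$subject_id), cl] <- r$truth[[parameter]]
  }
  m
}

#' Write / read a cohort dataset on disk
#'
#' The dataset directory holds a JSON manifest (subjects, schedule, seeds,
#' spec) and one waveform CSV per non-missing recording, written at full
#' float precision so a round trip is lossless.
#'
#' @param ds a `cohort_dataset`.
#' @param dir target directory (created if needed).
#' @return `write_cohort_dataset` returns `dir` invisibly;
#'   `read_cohort_dataset` returns the reconstructed `cohort_dataset`.
#' @export
write_cohort_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- lapply(seq_along(ds$recordings), function(i) {
    r <- ds$recordings[[i]]
    fn <- if (!is.null(r$waveform)) sprintf("rec_%04d.csv", i) else NULL
    if (!is.null(fn))
      write_waveform_csv(r$waveform, file.path(dir, fn))
    list(subject_id = r$subject_id, session = r$session,
         timepoint = r$timepoint, missing = r$missing,
         cause = r$cause, seed = r$seed, file = fn,
         truth = unclass(r$truth),
         HR = if (!is.null(r$waveform)) r$waveform$HR else NULL)
  })
  manifest <- list(seed = ds$seed, waveforms = ds$waveforms,
                   spec = unclass(ds$spec),
                   subjects = ds$subjects,
                   subject_list = ds$subject_list,
                   recordings = recs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(dir)
}

#' @rdname write_cohort_dataset
#' @export
read_cohort_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = FALSE)
  subjects <- do.call(rbind, lapply(mf$subjects, function(s)
    data.frame(s, stringsAsFactors = FALSE)))
  spec <- structure(rapply(mf$spec, unlist, how = "replace"),
                    class = "population_spec")
  recordings <- lapply(mf$recordings, function(r) {
    w <- NULL
    if (!is.null(r$file)) {
      w <- read_waveform_csv(file.path(dir, r$file))
      w$HR <- r$HR %||% w$HR
      w$calibrated <- TRUE
    }
    truth <- r$truth
    list(subject_id = r$subject_id, session = r$session,
         timepoint = r$timepoint, missing = isTRUE(r$missing),
         cause = r$cause, seed = r$seed, waveform = w,
         truth = structure(lapply(truth, function(x) x),
                           class = "patient_parameters"))
  })
  subject_list <- lapply(mf$subject_list, function(s) {
    s$params <- unlist(s$params)
    s
  })
  structure(list(subjects = subjects, subject_list = subject_list,
                 recordings = recordings, spec = spec,
                 seed = mf$seed, waveforms = mf$waveforms),
            class = "cohort_dataset")
}
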