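---
title: "Patient-specific pulse wave modelling with pulsewave: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific pulse wave modelling with pulsewave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`pulsewave` simulates blood flow in a bifurcating binary tree of the 55
larger systemic arteries. Each vessel is an axisymmetric, impermeable,
elastic cylinder tapering linearly from its inlet radius to its outlet
radius; blood is incompressible with density $\rho = 1.055$ g/cm$^3$ and
viscosity $\mu = 0.049$ g/(cm s). On each vessel the cross-sectional
averaged 1D equations are solved for area $A(x,t)$ and flow $q(x,t)$:

$$\partial_t A + \partial_x q = 0, \qquad
  \partial_t q + \partial_x\!\left(\frac{q^2}{A} + B\right)
  = -\frac{2\pi\nu r}{\delta}\frac{q}{A} + g(x, A),$$

where $B = f(x)\sqrt{A_0(x)A}/\rho$, the friction term uses a Stokes
boundary layer of thickness $\delta = \sqrt{\nu T / 2\pi}$ ($T$ the cardiac
period), and $g$ collects the geometric source terms produced by the taper.
The system is closed by the tube law

$$p(x, A) = p_{\mathrm{ref}} + f(x)\left(1 - \sqrt{A_0(x)/A}\right),
  \qquad
  f(x) = \tfrac{4}{3}\left(k_1 e^{-k_2 r_0(x)} + k_3\right),$$

anchored so that every vessel is at its reference radius $r_0(x)$ exactly at
$p_{\mathrm{ref}} = 97$ mmHg. $k_2 = 22.53$ cm$^{-1}$ is fixed; $k_1$
governs the stiffness of small arteries ($r_0 \ll 1$ cm) and $k_3$ of the
large ones. The local small-amplitude wave speed is
$c_0 = \sqrt{f/(2\rho)}$, and $c(A) = c_0 (A_0/A)^{1/4}$; note that $c$
*falls* with $A$ under this law, so the Riemann invariants are
$W_\pm = u \mp 4(c - c_0)$.

We resolved the radius-versus-diameter ambiguity in the stiffness law in
favour of the radius: with $k_2 = 22.53$ cm$^{-1}$ the two asymptotic
regimes (small vessels governed by $k_1 + k_3$, large ones by $k_3$) only
separate at radii around $1/k_2 \approx 0.04$–$0.4$ cm, which matches
arterial radii, not diameters.

Each terminal vessel drains into a three-element Windkessel (proximal
resistance $R_1$, distal resistance $R_2$, compliance $C$, venous pressure
5 mmHg). The nominal $R_1, R_2, C$ per terminal are data shipped with the
tree file; at run time they are scaled uniformly by the patient-specific
factors $S_R$ (both resistances) and $S_C$ (compliances). The heart is a
prescribed root inflow: a quarter-sine rise peaking at the ejection-peak
time $\tau$, a quarter-cosine fall to zero at the end of systole (ejection
duration ED, defaulting to $T/3$), zero in diastole, normalised so one beat
ejects the stroke volume $SV = CO/HR$.

## The six patient-specific parameters

| parameter | meaning | unit | cohort-mean default |
|---|---|---|---|
| $k_1$ | small-artery stiffness coefficient | g/(s$^2$ cm) | $2.28\times10^7$ |
| $k_3$ | large-artery stiffness coefficient | g/(s$^2$ cm) | $14.51\times10^5$ |
| CO | cardiac output | l/min | 3.56 |
| $\tau$ | heart ejection peak time | ms | 101.08 |
| $S_R$ | terminal resistance scaling | — | 1.34 |
| $S_C$ | terminal compliance scaling | — | 13.57 |

Everything else (geometry, $k_2$, blood properties, nominal Windkessels) is
fixed at literature-style values and treated as data, not estimated.

# The nominal tree and its calibration

The published description of this model family fixes the 55-vessel
geometry; the exact tables live in antecedent publications, so
`inst/extdata/arterial_tree_55.json` was assembled from the classic
55-artery systemic descriptions with rounded dimensions, strict binary
topology (28 terminals), tapering radii and all lengths at least 2 cm (so
even the shortest vessel keeps a well-posed 3-node grid). It is data:
any file with the same schema can be substituted in `load_tree()`.

Nominal terminal Windkessel values cannot be taken from the paper either.
They were calibrated once, against the printed cohort-mean operating point:
flow shares proportional to the square of the terminal radius, total
peripheral resistance such that $S_R = 1.34$ reproduces ~97 mmHg mean
pressure at CO = 3.56 l/min above venous pressure, $R_1 : R_2 = 1 : 4$, and
compliances such that $S_C = 13.57$ gives a diastolic decay constant
$R_2 C \approx 1.3$ s. Subject height scales all vessel lengths by
`height / 176 cm` (radii unchanged): path lengths dominate wave transit
timing, and no radial scaling rule is available.

# Numerics

The scheme is the standard two-step (Richtmyer) Lax–Wendroff on the
conservation form, with the taper and friction sources evaluated at half
steps. Boundary and junction values are obtained from *conservative
half-cell updates*: the boundary-node area is advanced by the finite-volume
balance of its half cell using the time-averaged boundary flux, coupled by
small Newton solves to the boundary relation (prescribed inflow at the
root; flow conservation plus static-pressure continuity at bifurcations — a
total-pressure variant is available via `junction_mode`; the implicit
Windkessel relation at terminals). With this construction the total blood
volume balances the boundary flux integrals *exactly* (to Newton tolerance,
about $10^{-10}$), which we verify per run: the result of every simulation
carries a conservation audit. A purely characteristic boundary treatment
was rejected because it leaks mass at first order in tapering high-flow
vessels.

Practical settings (all in `numerics_config()`):

* `dx_cm` — target spatial step, default 0.25 cm (3-node minimum per
  vessel). A 1 cm grid changes the radial waveform by < 1 mmHg and a 2 cm
  grid by ~0.5 mmHg more; the coarse grids are what make swarm-scale
  fitting tractable.
* time step — CFL number 0.9 against the fastest equilibrium wave speed
  with a 1.4× stiffening factor and a 400 cm/s velocity margin; an in-run
  CFL audit aborts cleanly if the state ever outruns the step. `dt_s`
  can pin the step explicitly (used in fitting, below).
* periodicity — cycles are repeated until the root pressure trace repeats
  to `tol_mmHg` (default 0.5 mmHg, max-norm), typically 8–12 cycles from
  the mean-pressure initial state. `fixed_cycles` runs an exact cycle
  count instead (again: fitting).
* units — CGS internally; mmHg, ml/s and l/min at the interfaces
  (1 mmHg = 1333.22 dyn/cm$^2$).

# Pulse wave analysis

`pwa_indices()` implements the device-style index set on one calibrated
cycle. Calibration maps the waveform affinely onto the brachial cuff
pressures; shape-derived indices are invariant under it. Landmarks come
from a Savitzky–Golay-smoothed waveform (window 5% of the cycle):

* foot — intersecting tangent: the tangent at the steepest upstroke
  intersected with the end-diastolic baseline, where the baseline is the
  local minimum found by walking back down the upstroke (robust to cycle
  wrap-around and drifting traces);
* systolic peak — global maximum;
* shoulder — nearest secondary systolic local maximum, falling back to the
  zero crossing of the smoothed fourth derivative nearest the peak (the
  classic approach);
* dicrotic notch — first local pressure minimum after the peak; when no
  notch exists the ejection duration falls back to $T/3$ and the result is
  flagged.

The augmented pressure AP is the peak-to-shoulder difference (positive for
late-peak, type A waves; negative for early-peak waves), and
$AI = (SP-DP)/(SP-DP-AP)\times 100\%$ — so $AI = 100\%$ exactly at
$AP = 0$. SEVR is the plain diastolic-to-systolic pressure–time integral
ratio with systole = [foot, foot + ED); no heart-rate (Buckberg)
correction is applied. Model-predicted pulse wave velocity divides the
path length along the tree (via the deepest common ancestor; the headline
path runs aortic arch → femoral) by the foot-to-foot transit time.

# Parameter identification

`fit_patient()` estimates the six parameters from one calibrated radial
waveform by minimising the relative waveform error: the mean absolute
sample difference between the simulated distal-radial waveform and the
recording, normalised by the mean recorded pressure (an L2 variant is a
config switch). Simulated and recorded cycles are aligned at their feet, so
the objective is invariant to a time shift of the recording. Unstable
parameter sets return a finite sentinel (500%) so the search can continue.

The search runs in two stages over a normalised box (per-parameter bounds:
cohort mean ± 4 SD, truncated positive):

1. **Particle swarm** — 20 particles × 30 iterations, constriction
   coefficients (0.729, 1.49445, 1.49445), velocity clamp 0.2, reflecting
   walls, a ring (lbest) neighbourhood topology, deterministic under the
   recorded seed. The ring topology matters: with a fully connected
   (gbest) swarm the population occasionally collapses onto a deceptive
   secondary basin — a distant parameter combination fitting the waveform
   to a few tenths of a percent — before the true basin is found.
2. **Local refinement** — from the swarm's best *and* from the best
   sufficiently distinct particle memory (two separated basins): a
   Nelder–Mead simplex, then box-constrained Levenberg–Marquardt on the
   per-sample residual vector (numerical Jacobian). The damped
   least-squares stage is what actually descends the long, sloppy valley
   of the objective; the simplex alone stalls an order of magnitude
   higher.

Two numerical details matter more than the optimiser brand. The objective
must be *smooth in the parameters*: both the CFL-derived step count and the
periodicity stopping rule jump discontinuously as parameters move, so the
fitting objective runs a fixed cycle count (8) and the solver quantises the
step count onto a geometric grid (ratio 1.25), making the discretisation
locally constant in parameter space at a mean cost of ~12% extra steps.
Without this the refinement stalls on ~0.1%-sized steps in the landscape,
which is exactly the scale at which the weakly identified $k_1$ direction
lives: a ±20% change of $k_1$ moves the objective by only ~0.1%, versus
~20% for CO or $S_R$. The identifiability audit in the test suite keeps
this visible.

# The virtual cohort generator

No patient recordings ship with the package; `generate_cohort_dataset()`
emulates the study design end to end so every downstream stage is testable:

* **design** — HD subjects get 2 sessions (3-day and 2-day interdialytic
  break) × 4 moments (before/after start, before/after end); controls one
  recording. 35 HD subjects hence yield 280 scheduled recordings. Each HD
  slot is missing completely at random with probability 25/280, emulating
  the quality-based exclusions of tonometry practice as a flat rate.
* **parameters** — truncated normals (bounds: zero/positivity and
  mean ± 4 SD) at the printed HD cohort means/SDs. The latent mean is
  calibrated so the *truncated* distribution keeps the printed mean
  (one-sided truncation would otherwise bias the wide $k_1$, $k_3$
  distributions upward by up to ~10%). Inter-parameter correlations default
  to zero — unknown in reality and a stated limitation.
* **group contrast** — control stiffness set ~60% below the pre-dialytic
  HD level, and control bed compliance moderately lower, emulating the
  reported direction and size of the HD-versus-control differences; ages,
  gender mix and heights follow the printed cohort table. Heart rate and
  brachial pressures are not printed anywhere and use field-plausible
  values (HD 72 ± 10 bpm, 130/75 mmHg; controls 66 ± 9, 120/75).
* **session effects** — multiplicative factors per moment; the before-end
  $k_3$ factor is the ratio of the printed before-start/before-end means
  (9.92/16.44), with milder transient CO and $\tau$ reductions. These are
  an emulation device, not ground truth.
* **recording** — forward model, distal radial site, resampled at 128 Hz,
  plus 1.5% amplitude-proportional Gaussian noise and a 0.3 mmHg sinusoidal
  baseline wander (stand-ins for unpublished tonometry characteristics;
  configurable).

What passing tests on this cohort do *not* show: correctness of the
assumed parameter independence, of the chosen session-effect sizes, or of
any tonometry artefact beyond additive noise. They do show that the
pipeline recovers what it generated, at the study's design and noise scale.

# Arteriovenous fistula extension

The dialysis access is modelled as a lumped shunt — an anastomosis
resistance in series with a low-resistance venous Windkessel — attached at
the access site: distal end of the fistula-arm radial artery (lower-arm
access) or a split of the fistula-arm brachial artery (upper-arm). This is
deliberately reduced compared to a full venous-network model; the default
anastomosis resistance (6000 dyn s/cm$^5$) was chosen once so the default
access flow lands in the clinically typical few-hundred ml/min range, with
> 600 ml/min attainable at low resistance. The fistula node conserves flow
exactly and the shunt flow is monotone in the anastomosis resistance.
`fistula_free_refit_experiment()` quantifies the bias of ignoring the
access: fit the fistula-free model to fistula-generated radial waveforms
and report the per-parameter deviations. By default the search descends
from the generating parameters to the nearest fistula-free optimum — the
experiment measures where the misspecified model's optimum *lies relative
to the truth*, and a cold global search at desk-scale budgets lands in
distant local optima whose scatter swamps that bias. At convergence the
fistula-free refit keeps a small waveform error (below 1% on noiseless
virtual subjects) while underestimating the small-artery stiffness `k1`
and the resistance scaling `S_R` on average; the per-subject sign of the
weakly identified `k1` fluctuates.

# Cohort statistics

* **Propensity matching** — logistic model on age and gender, caliper 0.2
  SD of the logit, nearest-neighbour without replacement, randomised order
  under the seed, with Wilcoxon/χ² balance diagnostics and standardized
  mean differences before/after.
* **Repeated measures with missing data** — `wittkowski_test()` ranks each
  subject's observed conditions, weights the centred ranks by
  $\sqrt{12/(n_i+1)}$, and refers the Moore–Penrose quadratic form of the
  column sums (null covariance from within-subject rank exchangeability) to
  $\chi^2_{K-1}$. On complete balanced data this *is* Friedman's statistic,
  which together with a type-I-error simulation under 10% missingness is
  the correctness gate. `scheffe_pairwise()` tests all condition contrasts
  in the same rank metric, referring each squared standardized contrast to
  $\chi^2_{K-1}$ (Scheffé-type: valid post hoc, never anti-conservative
  relative to the unadjusted test).
* **Correlation structure** — pairwise-complete Spearman correlations,
  t-approximation p-values, significance mask at 0.05 (unadjusted by
  default, mirroring the usual white-square display; BH optional), and
  average-linkage clustering on $1-|R|$.
* **Two-group tests** — Wilcoxon rank-sum with normal approximation for
  continuous variables; Yates-corrected χ² for categorical ones.

# Problem sizes used in the shipped checks

The test-suite and acceptance computations run at deliberately small desk
scale, chosen once: single-vessel wave-speed checks on a 100 cm vessel at
0.25 cm resolution; full-tree conservation at 0.5 cm; fitting and the
fistula experiments on the 2 cm grid with a fixed 8-cycle objective; one
virtual subject for the recovery experiment (default budget, 771+
evaluations) and two for the refit-bias experiment at a reduced swarm
budget; 2000 simulated tables for the rank-test calibration; 35 + 32
virtual subjects for the matching demonstration. Cohort-scale fitting of
all 280 recordings is out of desk scope — the recovery experiment plus the
generator's determinism stand in for it.

# Known limitations

* Geometry and nominal Windkessels are reconstructions, not the original
  tables; absolute pressures and PWV are realistic but not authoritative.
* $k_1$ is weakly identified from a single radial waveform (by an order of
  magnitude compared to CO or $S_R$); uniqueness of the six-parameter fit
  cannot be guaranteed, only that each parameter is individually visible.
* The model aorta does not develop a sharp dicrotic notch (the inflow
  profile has no valve-closure backflow), so the ejection-duration fallback
  is exercised on model waveforms.
* Viscoelastic walls, venous networks, gravity, autoregulation and fistula
  maturation are out of scope.
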