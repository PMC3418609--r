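---
title: "Effective connectivity of the action-representation network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective connectivity of the action-representation network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmnet)
```

# The scientific problem

When people watch someone else's hand act on an object, their own motor
system engages: surface EMG over the forearm rises, and primary motor
excitability increases. One influential account holds that the posterior
superior temporal sulcus (pSTS) and the ventral premotor cortex (PMv) host a
pair of internal models — an *inverse* model mapping seen kinematics onto a
motor plan (pSTS → PMv) and a *forward* model mapping a motor plan onto its
predicted sensory consequences (PMv → pSTS). Testing that account requires
*effective connectivity*: directed, model-based estimates of how one
region's activity drives another's, and how task context (executing versus
observing a hand action) modulates each pathway.

`dcmnet` implements that analysis end to end for a seven-region left-
hemisphere network — OP (occipital pole), MT/V5, pSTS, aIPS, IPL, PMv and
S/M1 — studied with a 2 (Execution/Observation) × 2 (Hand/No-hand) × 2
(rotation direction) blocked fMRI design. Because no raw data are deposited
anywhere, the package also contains a first-class synthetic-data generator
that emulates the design and the published group statistics, so every stage
of the pipeline is exercised and tested without any download.

# The generative model

## Neural dynamics

Neural population activity $z \in \mathbb{R}^7$ follows the bilinear
state-space model

$$\dot z = \Big(A + \sum_j u_j B^{(j)}\Big) z + C u,$$

where $u$ holds three boxcar inputs — `task` (any task epoch, entering OP),
`exec` (Execution epochs) and `hand` (Hand-observation epochs) — all in
units of Hz. $A$ is the task-independent coupling, $B^{(j)}$ the modulation
of coupling by input $j$ (the `task` input has no modulatory matrix), and
$C$ the direct input gains. The diagonal of $A$ is fixed at $-0.5$ Hz and is
not estimated: published coupling tables report only inter-regional
couplings, and the fixed self-decay guarantees a stable baseline.

## Hemodynamics and observation

Each region's activity drives the standard balloon model — vasodilatory
signal $s$, inflow $f$, venous volume $v$, deoxyhemoglobin $q$:

$$\dot s = \epsilon z - \kappa s - \gamma(f - 1), \quad \dot f = s, \quad
\tau \dot v = f - v^{1/\alpha}, \quad
\tau \dot q = f\,\frac{E(f,\rho)}{\rho} - v^{1/\alpha}\frac{q}{v},$$

with $E(f,\rho) = 1 - (1-\rho)^{1/f}$, and BOLD read out as
$y = V_0\,(k_1(1-q) + k_2(1-q/v) + k_3(1-v))$ with $k_1 = 7\rho$,
$k_2 = 2$, $k_3 = 2\rho - 0.2$. The source study cites this forward model
without printing its equations or constants; we adopt the canonical forms
with defaults $\kappa = 0.65\,\mathrm{s^{-1}}$,
$\gamma = 0.41\,\mathrm{s^{-1}}$, $\tau = 0.98$ s, $\alpha = 0.32$,
$\rho = 0.34$, $V_0 = 0.04$, $\epsilon = 1$ (all per-region and
configurable; see `hemo_defaults()`).

## Integration

The coupled system is integrated with classical RK4 at microtime resolution
(default TR/16 = 0.1875 s), with inputs piecewise-constant per bin, and BOLD
sampled at the end of every 3-s volume. Halving the step changes noise-free
BOLD by well under $10^{-3}$ (tested). A pure-R reference integrator is kept
alongside the compiled one and the two are compared to $10^{-12}$ in the
test suite. The balloon volume equation becomes stiff when activity is
large; the integrator detects divergence (non-finite or non-positive
states) and reports it rather than returning garbage.

# The design and model space

A run is 9 rest and 8 task epochs of 24 s in alternation (rest first and
last): 408 s, 136 volumes at TR 3 s. Six runs give 816 volumes; the first 3
of each run are discarded, leaving 798 analyzed volumes. Each volume ends
with a 600-ms gradient-silent window for artifact-free EMG: 48 windows per
task condition and 432 rest windows per session. These counts are asserted
exactly in the acceptance tests.

The baseline graph couples the execution-related set (S/M1, IPL, PMv, aIPS)
and the observation-related set (pSTS, IPL, aIPS, MT/V5) bidirectionally,
plus OP → MT/V5 — 23 directed edges. Sixteen candidate models cross four
PMv–pSTS patterns (mutual / PMv→pSTS / pSTS→PMv / absent) with four
extra-input patterns (Execution→PMv and Hand→pSTS / PMv only / pSTS only /
neither); both experimental factors modulate every baseline edge of a
model, including OP → MT/V5. Model 1 is the mutual-connection, dual-input
model (25 edges, 78 free parameters). Two orthogonal four-family partitions
(by input pattern; by connection pattern) support family-level inference.

# Inversion

`invert_dcm()` estimates one subject × one model by a variational-Laplace
scheme: Gauss–Newton updates of the posterior mode interleaved with EM
updates of per-region noise precision, scored by the Laplace free energy

$$F = \underbrace{\textstyle\sum_r \big[-\tfrac{\lambda_r}{2}\mathrm{SSE}_r +
\tfrac{T_{\mathrm{eff}}}{2}\log\lambda_r - \tfrac{T_{\mathrm{eff}}}{2}\log 2\pi\big]}_{\text{accuracy}}
\; - \; \underbrace{\mathrm{KL}\big(q(\theta)\,\|\,p(\theta)\big)}_{\text{complexity}},$$

which approximates the log model evidence used by Bayesian model selection.
Design choices that matter:

* **Priors.** Enabled A (off-diagonal) and B entries: $\mathcal N(0, 0.25)$;
  enabled C entries: $\mathcal N(0, 1)$; disabled entries are excluded from
  the parameter vector. Hemodynamics are fixed at their defaults unless
  `estimate_tau = TRUE` adds a log-scale transit-time parameter per region
  ($\mathcal N(0, 0.0156)$).
* **Linearization.** The model Jacobian is computed by exact forward
  sensitivities propagated through the same RK4 integrator (one augmented
  integration instead of ~80 perturbed ones). Finite differences remain
  available (`jacobian = "fd"`) and the two agree to $\sim 10^{-5}$
  relative error (tested), a deliberate dual-route check.
* **Confounds.** Run-wise intercepts and a 128-s discrete-cosine high-pass
  basis are projected out of data and prediction identically, mirroring
  run-effect regressors and drift removal; $T_{\mathrm{eff}}$ discounts the
  projected dimensions.
* **Monotonicity.** A candidate step is accepted only if it increases $F$
  (step-halving otherwise), and the EM noise update is kept only when it
  does; the accepted-iteration $F$ trace is therefore non-decreasing by
  construction. Convergence is declared at $\Delta F < 0.01$ nats
  (`max_iter` 64).
* **Determinism.** Initialization is at the prior mean and nothing in the
  scheme is stochastic: the same data give bit-identical posteriors.

# Model selection and group statistics

`rfx_bms()` implements random-effects Bayesian model selection by the
digamma fixed point: responsibilities
$g_{nk} \propto \exp(\mathrm{ev}_{nk} + \psi(\alpha_k) - \psi(\Sigma\alpha))$
and $\alpha_k = \alpha^0_k + \sum_n g_{nk}$, with a uniform prior
$\alpha^0 = 1$ per model. Exceedance probabilities are Monte-Carlo argmax
counts over Dirichlet draws (default $10^6$; they sum to 1 exactly and are
seeded). `family_inference()` rebalances the prior so every family carries
equal mass ($\alpha^0_k = 1/|\mathrm{family}(k)|$) and reports family
expected and exceedance probabilities over summed frequencies. The unit
suite checks the fixed point against an independently coded oracle and the
exceedance estimates against Beta closed forms and quadrature.

Group-level coupling statistics are one-sample $t$ tests per connection
(paired for the Execution-vs-Hand contrast), with Benjamini–Hochberg FDR at
$q = 0.05$ applied within each factor's table — one corrected family per
reported matrix. The $q$ level is not stated in the source and is exposed
as a parameter.

# The synthetic world

`default_truth()` fixes the generating model (model 1) and sets population
means of A, B(exec) and B(hand) to the published group means; the
between-subject SD of each coupling is the published SE $\times \sqrt{24}$
(the sample SD of a 24-subject study). Subjects are drawn Gaussian around
the means with rejection-resampling of draws that are eigenvalue-unstable
or fail to integrate. Observation noise is i.i.d. Gaussian per region at
SD = signal SD / SNR, with SNR 3 by default.

Values the source does not state, chosen once and not revisited:

* **Driving gains** $C$: task→OP 0.2, exec→PMv 0.1, hand→pSTS 0.1 Hz
  (SD 0). Published tables report only A and B. These values put peak BOLD
  excursions in the physiological few-percent range; an early larger choice
  (0.5/0.3/0.3) produced ~14% excursions and a stiff balloon regime and was
  replaced on realism grounds before any acceptance quantity was measured.
* **EMG**: 1000 Hz sampling (amplifier hardware is described but not the
  digitization rate); execution bursts and mimicry are zero-mean Gaussian
  amplitude increments (SD 5 and 0.5 × baseline) confined to the
  corresponding epochs.
* **Between-subject model**: Gaussian, the standard random-effects
  assumption.

What the generator deliberately does **not** emulate: physiological
(cardiac/respiratory) noise, scanner drift, motion, temporal
autocorrelation, and spatial ROI extraction. A green recovery test
therefore establishes that the estimator chain is correct under its own
assumptions — not that it is robust to artifacts it never sees.

# What the stated world can and cannot identify

Two stochastic acceptance criteria probe recovery on the synthetic group at
N = 8, one run, SNR 3, and our implementation leaves both red after
analysis; the numbers below are computed by the acceptance suite itself.

**Pooled parameter recovery (target r ≥ 0.7).** The inversion is exact in
the noise-free limit (pooled r = 1.000, tested), so the shortfall under
noise (observed r ≈ 0.46–0.59) is informational, not algorithmic. A
Monte-Carlo evaluation of the linearized-Gaussian problem at the generating
parameters shows that the Bayes-optimal posterior mean *under the specified
zero-centered shrinkage prior* attains r ≈ 0.56 at this design length and
SNR: many couplings load on strongly collinear regressors (aIPS and IPL
activity are nearly interchangeable sources), and the zero-centered prior
resolves that degeneracy toward zero rather than toward the population
mean. An oracle prior centered on the true population means would reach
r ≈ 0.85 — i.e. the target presupposes hierarchical (empirical-Bayes)
pooling across subjects that the single-subject estimator, by design, does
not do.

**Family recovery (exceedance > 0.5 in ≥ 8/10 replicates, both
partitions).** The dual-input family is recovered reliably (9/10 at the
reduced 4-subject scale): the driving inputs are strong features of the
data. The mutual-connection family is essentially never recovered (0/10) —
and the per-subject evidence actively favors models *without* the PMv–pSTS
edges. This is Bayesian Occam at work: the true couplings on those edges
are small (0.04–0.08 Hz) with between-subject SDs as large as the means, so
for a typical subject the accuracy they add at 133 volumes and SNR 3 does
not repay the complexity of six extra parameters. Spot checks at the full
798-volume design still give mixed per-subject evidence. Detecting this
attribute evidently needs the full 24-subject cohort (or stronger true
edges), which is exactly why the original analysis pooled evidence over 24
subjects.

# Numerical and degenerate-input conventions

* Epoch durations must divide the TR; the silent window is the final 600 ms
  of each volume (2400 ms acquisition first).
* Inputs are built at microtime over acquired volumes; discarding leading
  volumes shifts the analyzed series relative to epoch onsets, and the
  per-run boxcars retain the acquired timeline so forward simulation and
  inversion stay aligned.
* Modulatory boxcars are not mean-centered by default (exposed as
  `mean_center`); whether the original analysis centered them is unstated.
* Zero-variance inputs to $t$ tests are reported as degenerate (NA) rather
  than inventing a statistic; BH-FDR excludes NAs from $m$.
* Ties in nearest-peak selection resolve to the first candidate; coordinate
  averages skip missing entries per axis and the reference table is
  reproduced by averaging full-precision conversions (averaging the printed
  rounded values differs in the second decimal).
* The Talairach↔MNI transform is the Brett piecewise affine, chosen because
  it reproduces the published conversion row exactly; the inverse selects
  the superior/inferior branch by the sign of the resulting MNI z.

# Known limitations

Single-state bilinear neural model only (no two-state or nonlinear
variants); no stochastic DCM; no AR noise modeling inside the inversion; no
slice-timing-aware sampling; fixed-effects BMS and protected exceedance
probabilities are out of scope. The EMG stage realizes the 2×2 factorial
effects as paired contrasts, not a full repeated-measures ANOVA.
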