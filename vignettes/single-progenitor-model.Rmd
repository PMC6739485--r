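---
title: "Single-progenitor clone dynamics: model, inference and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-progenitor clone dynamics: model, inference and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spclone)
library(dplyr)
```

## The model

Squamous epithelia such as the esophageal lining are maintained by a
single population of basal progenitor cells. A progenitor divides at
rate $\lambda$ and the division produces two progenitors (probability
$p_{PP}$), two post-mitotic differentiating cells ($p_{DD}$), or one of
each ($p_{PD}$). Differentiating basal cells exit the basal layer
(stratify) at rate $\gamma$, and suprabasal cells are shed from the
tissue surface at rate $\mu$. `spclone` adds one perturbation channel:
division-independent induced differentiation at rate $\rho$, which
converts a progenitor directly into a differentiating cell and is the
model's representation of an acute oxidative challenge (for example a
low-dose irradiation exposure).

A clone founded by one labelled progenitor is observed as a pair
$(m, n)$: $m$ basal cells ($n_P + n_D$) and $n$ suprabasal cells. A
clone with $m = 0$ and $n \ge 1$ is a *floating clone*, destined to be
lost by shedding. Homeostasis requires $p_{PP} = p_{DD}$ and
$\rho = 0$: the average division then yields one progenitor daughter,
progenitor number is a critical branching process, and the mean number
of progenitors per founder is exactly one at all times (a martingale
that both the simulator and the master equation must reproduce).

Selective pressure enters as a *fate tilt* $\delta$:
$p_{PP} = r(1+\delta)$, $p_{DD} = r(1-\delta)$ with $r$ the
symmetric-division probability. The expected net progenitor gain per
division is $2r\delta$, so positive tilt drives clonal expansion and
negative tilt drives clone loss.

The simulator (`simulate_clone()`, `simulate_cohort()`,
`simulate_tissue()`) performs exact continuous-time Markov simulation:
next-event sampling with piecewise-constant rates, re-sampled at
schedule boundaries and feedback updates (valid by memorylessness).
Clone sizes are small, so exactness is cheap, and it allows a strict
cross-check against the master-equation oracle. Rates are configured
per day and converted to per hour once; all internal clocks are hours.

## Default parameters

The study system provides no measured rates for these conditions, so
the defaults are order-of-magnitude calibration choices, documented
here and freely configurable (`scenario_defaults()`):

| parameter | default | meaning |
|---|---|---|
| $\lambda$ | 2/7 per day | about two divisions per progenitor per week |
| $r$ | 0.1 | one division in five is symmetric |
| $\gamma$ | 0.5 per day | basal residence of committed cells, about 2 days |
| $\mu$ | 0.5 per day | suprabasal transit, about 2 days |
| $\rho_{\text{wave}}$ | 0.5 per day for 24 h | post-exposure differentiation wave |
| $\tau_S$ | 8 h | S-phase duration for EdU labelling |

The criterion for the baseline set is that an unperturbed simulated
tissue is statistically stationary in basal density and clone-size
distribution; the calibration procedure, not the values, is the
contract.

## Perturbation response model

Each exposure event triggers, in responsive cells, an induced
differentiation wave: $\rho = \rho_{\text{wave}}$ for `wave_h` hours
(default 24 h). The response keys on exposure *events*, not absolute
dose, because no dose-response function is available within scope; dose
values are carried as metadata. The choices encode the observed
phenotype sequence: differentiation first (proliferation unchanged at
24 h), compensatory proliferation later (rising by 48 h), homeostasis
restored by day 10.

* **Wild type**: wave after every exposure; recovery via feedback.
* **p53 mutant**: resistant, no wave ($\rho = 0$); expands passively
  when wild-type neighbours differentiate.
* **Antioxidant (NAC)**: suppresses the wild-type wave. Combined with
  exposures it *reverses* the asymmetry: the mutant now receives a
  partial wave ($\rho =$ `nac_rho`, default 0.25/day) plus a negative
  fate tilt (`nac_delta`, default $-0.3$) for `nac_window_h` (72 h)
  after each exposure. The reversal direction is the documented
  phenotype; its partitioning between an induced-differentiation
  channel and a tilt channel is a design choice of this package, made
  so that mutant clones show the full reversal signature (loss of
  basal cells, more floating clones, more differentiated EdU-labelled
  cells) at a depletion magnitude of a few fold over a five-dose
  course rather than an order of magnitude.
* **NAC alone**: no effect on either genotype.

## Competition through the shared niche

Clones interact only through total basal density $B(t)$ (well-mixed
pool; no spatial lattice). At each feedback update (every 6 h):

* fate tilt $\delta(t) = \operatorname{clamp}(k_{fb}\,(1 - B/B_0),
  \pm\delta_{\max})$, applied additively to every genotype's symmetric
  outcome probabilities;
* division rate multiplied by $1 + k_\lambda \max(0, 1 - B/B_0)$,
  capped at `lambda_mult_max`.

Whether post-wave compensation is carried by fate bias, by division
rate, or both is not empirically resolved; the rule exposes both knobs
and the defaults use both, because tilt alone (bounded by probability
validity at $|\delta| \le 1$) cannot restore a 15% basal deficit
within the observed ten days, whereas a transient proliferative burst
can. Gains ($k_{fb} = 6$, $k_\lambda = 12$) were calibrated so that a
single-exposure tissue returns to within a few percent of control
density by day 10 while an unexposed tissue stays stationary.

The reference density $B_0$ is the homeostatic basal count
$(1 + \lambda/\gamma)$ per founder: each progenitor is accompanied at
stationarity by $\lambda/\gamma$ committed basal cells awaiting
stratification. (Using the founder count itself would make every
control tissue start 36% "too dense" once the committed pool fills.)

## The experiment emulator

`preset_scenario()` / `generate_experiment()` emulate the lineage-
tracing protocols: clones induced at clonal density (one labelled
progenitor each) seven days before the first exposure; exposure courses
of 0, 1, 5 or 10 doses with at least 3-day spacing; an optional EdU
pulse 1 h before the final exposure; samples at 24 h to 30 days after
the last exposure. Animals are independent replicates (default 4 per
condition) drawn sequentially from the scenario's root seed, and
per-animal means are the unit for scalar comparisons, while the
Peacock test pools clones across animals — both mirroring how such
experiments are reported. The default tracked cohort per animal is
1700 wild-type and 300 mutant clones: mutant clones are a 15% minority
of labelled cells (mutant alleles are induced in scattered single
cells) while still giving a few hundred scored mutant clones per
condition, the scale at which mutant clone statistics are reported.

EdU labelling is proliferation-proportional: each progenitor is
labelled with probability $\min(1, \lambda \tau_S / 24)$, labels are
inherited by both daughters and never removed. Ignoring label dilution
is adequate for chases of 48 h or less (about one division); longer
chases would overestimate labelled-cell counts.

What the generator does *not* emulate: spatial clone geometry and
merging, apoptosis (negligible at these doses), dose-response within an
exposure, measurement error in cell counting, litter or cage effects.
Passing tests on synthetic cohorts therefore demonstrates the internal
consistency of the pipeline and the qualitative reproduction of the
perturbation phenotypes, not quantitative agreement with any animal
dataset.

## The master equation: oracle and likelihood

`build_generator()` assembles the truncated generator over states
$(n_P \le P_{\max}, n_D \le D_{\max}, n_S \le S_{\max})$ (defaults 20,
20, 30) with an absorbing *leak* state receiving all flux across the
boundary, so probability is conserved exactly. `master_evolve()`
integrates $\dot p = pQ$ by uniformisation — Poisson-weighted powers of
the discrete skeleton, with the Poisson tail truncated at $10^{-13}$ —
which is unconditionally stable and mass-conserving. The leak is
monitored: above $10^{-6}$ the state space is enlarged by 50% per axis
and the evolution restarted (at most twice, then a warning stands).

`clone_size_marginal()` folds states to the observable $(m, n)$;
`log_likelihood()` sums $\log f_{m,n}(t)$ over clones, by default
conditioned on clone visibility ($m + n \ge 1$), because microscopy
cannot count fully shed clones. `fit_tilt()` profiles the likelihood
over a tilt grid (default $\delta \in [-0.6, 0.6]$, step 0.025) with
the other rates fixed: joint fitting from single-time clone data is
weakly identified, so only $\delta$ is estimated by default. The
estimate is the grid maximiser refined by quadratic interpolation; the
confidence interval is the profile likelihood-ratio set
($\chi^2_1$ threshold), with linear interpolation of the crossings. A
flat profile is flagged non-identifiable rather than returned
silently.

The recovery design used in the validation suite observes 1000 clones
once at 30 days: long enough that a tilt of $\pm 0.2$ separates
clearly from criticality (bias below 0.01, root-mean-square error
below 0.04 in 100-replicate simulations), short enough that the
default truncation leaks less than $10^{-5}$ even at the largest grid
tilts.

## Peacock's two-dimensional two-sample test

Clone-size distributions are compared with the two-dimensional
Kolmogorov-Smirnov statistic: the maximum absolute difference between
the two samples' empirical quadrant probabilities. The implementation
uses the full pooled-coordinate lattice (every pooled $x$ crossed with
every pooled $y$ — the original construction, affordable at clone-size
scales) and evaluates each corner in all four orientations under both
boundary conventions ($\le$ and $<$), taking the overall maximum. On
heavily tied integer data this makes the supremum well defined and
deterministic; a brute-force enumeration oracle
(`brute_force_statistic()`) is part of the package and the statistic
is required to agree with it exactly.

The default null is a permutation of the pooled points (exact,
conditional on the pooled data) with the add-one estimator
$p = (1 + \#\{D^* \ge D\})/(B+1)$, because the asymptotic
approximation is unreliable for tied integer data (it is available,
labelled, via `method = "asymptotic"`). Two numerical notes: the
smallest attainable $p$ is $1/(B+1)$; and for small samples the
statistic's value lattice makes the test *conservative* (null
rejection a little below nominal — about 0.04 at $n = 200$ per sample
— approaching nominal at the cohort sizes of about 1000 clones per
condition where the test is actually used). It is never
anti-conservative.

## Lineage-tracing statistics

`clone_size_histogram()` builds the normalised $f_{m,n}$ grid (default
caps 12/12; floating clones included, since the heatmaps index from
zero basal cells). Clones beyond the caps are clipped to the edge cell
by default so no mass is lost (the alternative, dropping them, is a
flag); the underlying data are never capped for the Peacock test or
the geometric median, which operate on raw pairs. `residual_map()` is
the entrywise difference of two histograms (zero-sum by construction).
The geometric median — the summary location used for clone-size
heatmaps — is computed by Weiszfeld iteration with the Vardi-Zhang
step when an iterate lands on a data point; for degenerate (collinear,
even-count) sets the minimiser is a segment and any point of it is a
valid answer. `density_estimate()` compares Poisson-sampled
per-field basal counts between conditions, mirroring counting cells in
random microscope fields.

## Numerical and interface conventions

Tables are tab-separated with one header line; histograms are dense
TSV matrices with explicit $m$/$n$ indices; scalar results are JSON
with a metadata block (package version, seed, configuration hash)
sufficient to regenerate any artifact bit-identically. All simulation
functions accept a seed and are deterministic given it; within a
cohort, clones are simulated sequentially from one stream, so the
whole experiment is reproduced by its root seed. Warnings (truncation
leak, undefined EdU ratios, clipped likelihood cells) are never
silently suppressed.

## Worked example

```{r example, eval = FALSE}
ctrl <- generate_experiment(preset_scenario("ctrl", seed = 1))
ldir <- generate_experiment(preset_scenario("ldir50x1", seed = 2))

wt24 <- function(e) dplyr::filter(e$clones, time_h == 24, genotype == "WT")
floating_fraction(wt24(ctrl))
floating_fraction(wt24(ldir))

h0 <- clone_size_histogram(wt24(ctrl))
h1 <- clone_size_histogram(wt24(ldir))
autoplot(residual_map(h0, h1))
peacock_test(wt24(ctrl), wt24(ldir), n_perm = 999, seed = 3)

fit <- fit_tilt(
  dplyr::filter(simulate_cohort(1000, apply_tilt(balanced_fate_params(), 0.2),
                                sample_times_h = 720, seed = 4), observable),
  balanced_fate_params())
tidy(fit)
```

## Known limitations

* Competition is mean-field; spatially clustered clone loss and local
  niche effects are out of reach.
* The response model is event-based; graded dose effects cannot be
  explored with it.
* The likelihood treats clones as independent; under density feedback
  clones are weakly coupled, so tilt estimates from feedback-coupled
  tissues are approximate (they remain directionally reliable, which
  is how they are used here).
* Label dilution is ignored, restricting EdU readouts to short chases.
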