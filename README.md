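# spclone

Stochastic modelling and analysis of clonal dynamics in squamous
epithelia maintained by a single progenitor population, with the
statistical pipeline used in clonal lineage-tracing studies of cell
competition — for example, how low-dose oxidative stress changes the
balance between wild-type and p53-mutant progenitors in the mouse
esophagus, and how antioxidant co-treatment reverses it.

## The model

Proliferation is confined to the basal layer. A progenitor divides at
rate λ with three possible outcomes,

    P → P + P   with probability p_PP
    P → P + D   with probability p_PD
    P → D + D   with probability p_DD

post-mitotic basal cells D stratify into the suprabasal compartment at
rate γ, and suprabasal cells are shed at rate μ. A perturbation channel
ρ converts progenitors directly to differentiating cells
(division-independent), modelling an acute oxidative challenge. A clone
founded by one labelled progenitor is observed as (m, n): m basal and n
suprabasal cells; m = 0 with n ≥ 1 is a "floating" clone destined for
loss.

Homeostasis is the critical balance p_PP = p_DD, ρ = 0 (each division
yields on average 50% progenitor and 50% differentiating daughters).
Selection is a fate tilt δ: p_PP = r(1+δ), p_DD = r(1−δ), giving an
expected net progenitor gain of 2rδ per division.

The package provides:

* an exact continuous-time Markov simulator of clones, cohorts and
  two-genotype tissues competing through a shared basal-density
  feedback (`simulate_clone()`, `simulate_cohort()`,
  `simulate_tissue()`);
* an experiment emulator with named presets of the lineage-tracing
  protocols — exposure courses (1, 5 or 10 doses), antioxidant
  co-treatment, EdU pulse-chase — producing clone tables with the
  study's observation model (`preset_scenario()`,
  `generate_experiment()`);
* the lineage-tracing readouts: 2D clone-size histograms f(m, n) and
  residual maps, geometric-median clone size, floating-clone fraction,
  basal density from field counts, EdU cohort statistics
  (`clone_size_histogram()`, `residual_map()`, `geometric_median()`,
  `floating_fraction()`, `edu_readouts()`, `density_estimate()`);
* Peacock's two-sample two-dimensional Kolmogorov–Smirnov test with a
  permutation null and an exact brute-force oracle (`peacock_test()`);
* a truncated master-equation solver, both exact oracle for the
  simulator and likelihood engine recovering the fate tilt from clone
  tables with profile-likelihood intervals (`master_evolve()`,
  `fit_tilt()`).

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects
have `tidy()`/`glance()` methods and results have `autoplot()`
displays. A thin command-line front end (`spclone_cli()`, installed at
`inst/scripts/spclone`) exposes `simulate`, `analyze`, `compare`,
`recover` and `presets` subcommands over TSV/JSON/YAML files.

## Worked example

Emulate an unexposed control and a single low-dose exposure, then
compare the 24 h clone-size distributions:

```r
library(spclone)
library(dplyr)

ctrl <- generate_experiment(preset_scenario("ctrl", seed = 1))
ldir <- generate_experiment(preset_scenario("ldir50x1", seed = 2))
wt24 <- function(e) filter(e$clones, time_h == 24, genotype == "WT")

floating_fraction(wt24(ctrl))
#> # A tibble: 1 × 3
#>   n_clones n_floating floating_pct
#> 1     6325        426         6.74
floating_fraction(wt24(ldir))
#> # A tibble: 1 × 3
#> 1     6277        657         10.5

peacock_test(wt24(ctrl), wt24(ldir), n_perm = 999, seed = 3)
#> Peacock two-sample 2D Kolmogorov-Smirnov test
#>   D = 0.0587, p = 0.001 (permutation, 999 permutations), n1 = 6325, n2 = 6277
```

Twenty-four hours after the exposure the irradiated cohort has more
floating clones (10.5% vs 6.7% — progenitors differentiated and left
the basal layer) and a clone-size distribution the Peacock test
separates at the smallest attainable p (0.001 with 999 permutations).

Recovering a known fate bias from simulated clones:

```r
co <- simulate_cohort(1000, apply_tilt(balanced_fate_params(), 0.2),
                      sample_times_h = 720, seed = 4)
fit_tilt(filter(co, observable), balanced_fate_params())
#> <tilt_fit> delta = 0.2223 [0.1618, 0.2836] (95% profile CI), n = 679 clones
```

The tilt used to generate the cohort (δ = 0.2) is recovered with its
profile confidence interval; 679 of the 1000 induced clones were still
visible (m + n ≥ 1) at 30 days.

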