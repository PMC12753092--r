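---
title: "Correcting Ks-based divergence times for ancestral population size: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting Ks-based divergence times for ancestral population size: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksdate)
```

## The problem

The distribution of per-ortholog synonymous divergence (Ks) between two
sister species is a workhorse for dating speciation events: under a
molecular clock, the mean Ks divided by twice the substitution rate gives a
divergence time. But orthologous loci do not split when the species do.
With no post-divergence gene flow, each pair of orthologous lineages
coalesces inside the *ancestral* population, on average 2Ne generations
before the species split, where Ne is the ancestral effective population
size. Mean-Ks dating therefore overestimates the species divergence time T
by 2Ne/T in relative terms — 10% for Ne = 50,000 and T = 10^6 generations,
and far more for recent splits.

The key observation exploited here is that the same coalescent process that
biases the mean also spreads the distribution: the coalescent waiting time
for two lineages has standard deviation 2Ne generations, so Ne leaves a
signature in Var(Ks) that can be read off the very same Ks table used for
dating, without population-level resequencing data.

## Model

With one lineage sampled per species, the per-locus gene divergence time is

$$\tau = T + c, \qquad c \sim \mathrm{Exp}(\text{mean } 2N_e),$$

in generations (the discrete-generation coalescent is approximated by its
continuous exponential limit). Mutations accumulate along the two branches
as a Poisson process with rate $\mu$ per site per generation, and multiple
hits at a site are resolved under Jukes–Cantor dynamics, giving the
conditional site-difference probability
$p(\tau) = \tfrac34\left(1 - e^{-8\mu\tau/3}\right)$ and the per-locus
estimate $\widehat{K_s} = -\tfrac34\log\!\left(1 - \tfrac43\hat p\right)$
from the observed p-distance $\hat p$.

Two exact moment identities anchor everything:

* $\mathbb{E}[K_s] = 2\mu(T + 2N_e)$, hence the corrected date
  $\hat T = \overline{K_s}/(2\mu) - 2\hat N_e$;
* the between-locus (coalescent) component of the variance is
  $\mathrm{Var}_{\text{coal}}(K_s) = 16\mu^2 N_e^2$, which inverts to the
  analytic estimator $\hat N_e = \sqrt{\mathrm{Var}(K_s)}/(4\mu)$.

The total variance, however, also contains a within-locus sampling term
from observing only L sites per locus,
$\mathbb{E}\!\left[(\mathrm{JC}')^2\, p(1-p)/L\right] \approx
\overline{K_s}/L$ to first order. The analytic inversion is therefore
trustworthy only where the coalescent term dominates; empirically (and in
the closed forms) that regime begins around Ne ≈ 450,000 at L = 1,000 and
μ = 10⁻⁸, which is the regime-switch threshold hard-wired into
`predict_ne()`.

## The simulator

`simulate_ks_values()` follows the generative model literally: a TMRCA draw
per locus, a Poisson number of substitution events with mean 2μLτ, uniform
placement of events over sites, and the Jukes–Cantor k-hit collapse (a site
hit k times along the two-branch path differs with probability
$\tfrac34(1 - (-1/3)^k)$). `simulate_sequence_pairs()` produces the same
process as explicit aligned FASTA pairs (ancestral sequence mutated
independently along each branch), so the fast path and the
sequence-then-re-estimate path can be cross-checked distributionally — one
of the test suite's core consistency checks, with the closed-form binomial
marginalization serving as an independent oracle.

Design choices worth knowing:

* **Substitution model.** Jukes–Cantor throughout — the minimal neutral
  model consistent with treating all-site divergence of neutrally evolving
  sequence as synonymous divergence. Empirical Ks tables computed under
  codon models are ingested as-is and treated as the same quantity.
* **Saturation.** The JC inversion diverges at p = 3/4. The simulator
  refuses configurations whose *expected* Ks exceeds 3 substitutions/site;
  individual saturated loci (p ≥ 3/4, possible in the binomial tail) are
  dropped with a warning and counted. Ingested tables use a configurable
  ceiling (default Ks ≤ 5, the usual working range of wgd-style outputs)
  because a handful of saturated values would otherwise dominate the
  variance.
* **Bottlenecks.** `simulate_bottleneck_scenario()` reduces one daughter
  population after the split. With one lineage per species this cannot
  change the TMRCA distribution (the two lineages can only meet in the
  ancestral population) and the per-generation mutation rate is
  size-independent, so branch lengths are unchanged; the scenario simulates
  the three branch segments explicitly and exists to confirm that the
  estimator is not perturbed by post-divergence demography, which is
  exactly what the robustness sweep measures.
* **ms units.** Configurations can be given in Hudson's (θ = 4Neμ,
  t = T/4Ne) units via `sim_config_ms()` and are converted to the native
  (Ne, μ, T) parameterization.
* **Determinism.** A single integer seed in the config makes every run
  byte-identical; the seed is recorded in training metadata and CLI
  provenance blocks.

## The variance-to-Ne model

Below the analytic regime the variance–Ne relationship is strongly
nonlinear (the sampling term bends it away from the 16μ²Ne² parabola), so
`train_variance_model()` learns it per substitution-rate category from
simulations: 23 log-spaced Ne values spanning 500–500,000 crossed with
divergence times T ∈ {10⁴, 10⁵, 10⁶} generations (pooled), 10,000 loci of
1,000 bp per cell. A GAM of Ne on a smooth of log₁₀ Var(Ks)
(`mgcv::gam`, default smoothing) is fitted through the pooled cloud and
frozen as a dense monotone grid (monotone projection, then monotone cubic
interpolation at prediction time), which makes the persisted model a plain
JSON file independent of the fitting machinery. Rates are handled as 23
log-spaced categories over 10⁻¹⁰–10⁻⁷ per site per generation; an input μ
is matched to the nearest available category and refused beyond a 25%
relative gap (within-category variation has little influence on the
relationship).

Two honest limitations of this construction, both visible in the package's
own diagnostics rather than hidden:

* **Small-Ne identifiability.** For Ne small enough that 16μ²Ne² falls
  below the sampling term (which depends on T through the mean), Var(Ks)
  carries almost no information about Ne, and the pooled-T cloud is
  genuinely degenerate there. Consequently the reported fit R² (raw-Ne
  response, as `fit_r2`) plateaus near 0.975 rather than 1, and
  predictions below Ne ≈ 10⁴ (at μ = 10⁻⁸, T = 10⁶, 10⁴ loci) should be
  read as order-of-magnitude. The estimator is accurate in the regime the
  method is meant for — Ne from a few 10⁴ upward, where the recovery
  properties in the test suite hold to better than 20%.
* **Monte-Carlo noise floor.** The sampling error of a variance over n
  loci is ≈ Var·√(2/n); Ne signals below that floor (e.g. Ne = 5,000 at
  μ = 10⁻⁸, T = 10⁶, n = 10⁴) are unrecoverable from Var(Ks) by any
  estimator, which bounds what "parameter recovery" can promise.

`predict_ne()` interpolates the frozen grid, switches to the analytic
closed form whenever the interpolated value exceeds 450,000 (the two agree
to well under 15% at the boundary), refuses variances below the trained
range, and routes variances above it directly to the analytic regime
(which governs there by construction). A pre-trained store for μ = 10⁻⁸
and 10⁻⁹ ships in `inst/extdata/models/` and can be regenerated with one
`train` CLI call or `train_model_store()`.

## Dating

`correct_divergence()` applies the order of operations: multiple-hit
correction per locus (done by the readers/simulator), then the mean, then
the 2Ne subtraction. Negative corrected times are *reported with a
warning, never clamped* — a negative value is the user's signal that the
Ne correction exceeded the divergence signal, i.e. the split is too recent
for this method at that Ne. When μ is supplied per year it is converted by
the generation time g (`convert_rate()`); note that the estimated Ne then
depends on g, because the whole framework operates in per-generation
units — reporting dates under two candidate generation times will also
change the inferred Ne, and both are reported side by side in the JSON
report.

## Robustness experiments

`run_bottleneck_sweep()` dates the three reduction scenarios (1/2, 1/5,
1/10) with the full pipeline and summarizes the signed relative accuracy
RA = (T̂ − T)/T; `run_length_sweep()` simulates L ∈ {500, 1000, 1500,
2000} bp and compares the *normalized variance* CV² = Var(Ks)/mean(Ks)²
across lengths, each length's deviation taken from the mean normalized
variance of the stable lengths (L ≥ 1000). CV² is used because the raw
variance contains the 1/L sampling term: short loci (500 bp) inflate it
severely, which is exactly the instability the sweep is designed to
expose. Both runners average a small number of replicates (default 5) per
scenario so the reported statistic is stable rather than a single draw.
Default problem sizes — 10,000 loci of 1,000 bp, Ne = 5×10⁴, T = 10⁶
generations, μ = 10⁻⁸ — are the package's canonical study conditions; the
unit-test suite exercises the same code at reduced sizes (≈2,000 loci) to
keep it fast.

## What the simulations do and do not show

The generator emulates neutral, freely recombining (between loci),
non-recombining (within loci), clock-like divergence of two species with a
constant-size panmictic ancestor and no migration. Real ortholog sets
violate several of these: alignment error, codon structure and selection
on synonymous sites, rate variation among loci and lineages, gene flow
after divergence, and duplicated/misassigned orthologs all add variance
that this model would read as extra Ne. A passing test suite therefore
demonstrates internal correctness of the estimator under its stated model,
not robustness to those real-data pathologies; the saturation ceiling and
the reported drop counts in `read_ks_table()` are the only line of defense
the package itself provides, and users should regard empirical Ne
estimates as upper bounds in the presence of unmodeled variance.

## Numerical conventions

Unbiased (n−1) sample variance everywhere; arithmetic mean; ambiguity
codes and gaps excluded per site in p-distances; JC round-trip exact to
1e-12 over d ∈ [0, 3]; monotone projection of the frozen grid via a
running maximum with a 5%-of-range tolerance before declaring a training
failure; `monoH.FC` interpolation in log–log space; one global RNG stream
per seeded run.
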