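---
title: "Models and estimators for CRISPR immunity against beneficial plasmids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators for CRISPR immunity against beneficial plasmids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprflux)
```

crisprflux implements the quantitative machinery for studying a specific
evolutionary trade-off: a CRISPR-Cas locus that targets a conjugative
plasmid protects its host from parasitic DNA, but also locks the host out
of any benefit the plasmid carries (say, an antibiotic-resistance gene).
In *Staphylococcus epidermidis* populations the resolution of this
trade-off turns out to happen on the host side — cells that have lost or
inactivated the CRISPR-Cas locus pre-exist at surprisingly high frequency
and soak up the plasmid — rather than through plasmid target mutations.
The package provides the five analysis components needed to quantify that
claim, plus seeded generators for every input format so the whole pipeline
is testable without external data.

## End-point conjugation rates

A filter mating yields donor, recipient and transconjugant densities
(cfu/ml). The end-point rate parameter

$$\Gamma = \frac{T}{D \times R}$$

normalises the transconjugant yield by the mass-action encounter term, so
matings run at different densities can be compared. `compute_gamma()` adds
`gamma` and `frequency` (= T/R) columns to a mating table; rounding to the
two significant figures used in printed tables happens only at the
reporting layer (`report_signif()`).

Two derived group statistics compare immune with permissive matings of the
*same* plasmid:

* `fold_reduction()` — mean permissive Γ over mean immune Γ; CRISPR
  immunity typically costs the plasmid three to four orders of magnitude.
* `estimate_escape_fraction()` — the reciprocal ratio, read as the
  standing fraction of CRISPR-defective recipients, because transfer into
  an "immune" population is really transfer into its defective minority.

Group aggregation uses the arithmetic mean of per-mating Γ by default.
The choice is genuinely open (no aggregation rule is stated alongside the
published fold-reduction figure); the arithmetic mean is the conservative
reading of "mean rate", and a geometric option is exposed for users who
prefer log-scale averaging of rate parameters. The escape fraction is
reported dimensionless; converting it to a per-generation or per-hour rate
requires a growth model and is left to the caller.

```{r gamma}
matings <- read_matings(crisprflux_example("table1_matings.tsv"))
pg0400 <- dplyr::filter(matings, donor_plasmid == "pG0400")
report_signif(compute_gamma(pg0400)$gamma)
estimate_escape_fraction(pg0400)
```

## Fluctuation analysis

The classic fluctuation-test logic distinguishes pre-existing mutants from
mutants induced by the selective encounter: if CRISPR-defective recipients
arise *before* mating, transconjugant counts across independently grown
cultures are wildly overdispersed (early mutations found large clones),
while aliquots of one culture give near-Poisson counts.

`fluctuation_summary()` computes mean, median, variance and the
variance/mean ratio per design. Two conventions matter and are fixed
deliberately:

* **Population variance** (divide by *n*, not *n* − 1). Only this
  convention reproduces the printed variance/mean ratios (226 for
  independent cultures, 4 for aliquots, 45 after jackpot exclusion) after
  integer rounding, so it is pinned in the tests. The printed raw
  variances differ from recomputation on the printed counts by <0.2%
  (likely intermediate rounding upstream); the ratios are what the tests
  assert.
* **Jackpot rule.** The source analysis dropped its single largest count
  without stating a rule. `detect_jackpot()` implements an explicit,
  configurable screen — counts above `multiplier` × median, default 4 —
  which flags exactly the published jackpot on the packaged data and
  nothing else.

`simulate_fluctuation()` is the forward model: each culture grows from
`n0` to `n_final` cells by discrete doublings; at every generation the
newly produced cells mutate with probability `mu_g` each (a Poisson draw
with mean `mu_g` × the post-doubling population — under this convention
the expected mutant count is `mu_g * n_final * log2(n_final/n0)`, the
standard Luria–Delbrück expectation, which the tests verify to 10%);
existing mutant lineages double deterministically. Mating then converts
each mutant to a transconjugant independently with probability
`p_transfer`, whose default order (1e-4) follows the permissive
conjugation frequencies in the mating table. A fully stochastic birth
process adds nothing at these population sizes and is out of scope.
`n_final` is rounded to a whole number of doublings of `n0` so the growth
model stays exact.

`estimate_mu()` inverts the forward model by mean matching: a fixed
log-spaced grid of candidate rates is simulated under the given seed and
the observed mean transconjugant count is interpolated between the
bracketing grid points. Because the grid depends only on the known
parameters and the seed, the estimate is monotone in the observed mean.
Full maximum-likelihood fluctuation estimators exist, but mean matching
(with a P0-style upper bound when every count is zero) is sufficient for
the order-of-magnitude claim this analysis supports, and keeps the
estimator transparently tied to the simulator.

## The six-population plasmid-dynamics model

`simulate_plasmid_dynamics()` implements a batch-culture model with six
populations: immune recipients CP, CRISPR-negative recipients CN, donors
with the targeted wild-type plasmid D1, donors with an escape-mutant
plasmid D2, and transconjugants T1 (wild-type plasmid, only in CN hosts)
and T2 (escape plasmid, any host). The deterministic skeleton is Monod
growth, ψ(R) = ν~max~R/(k+R), with resource drawdown e·ψ·ΣN, and bilinear
conjugation at rate γ: D1 and T1 convert CN into T1; D2 and T2 convert
both CP and CN into T2. The two mutation channels — CRISPR loss CP→CN at
rate µ and plasmid escape D1→D2 at rate ν~pl~ — are rare discrete events,
so they are injected stochastically: after every deterministic step of
length `dt`, Poisson-distributed event counts are moved between
compartments. This "semi-stochastic" hybrid captures the essential noise
source (early mutation events amplify clonally and dominate run-to-run
variance) at a tiny fraction of the cost of an event-driven simulation.

Numerical choices:

* Euler steps with `dt = 0.01` h by default (RK4 available); at this step
  the 24-h deterministic solution is converged to better than 1%.
* At resource exhaustion the step is shortened so consumption stops
  exactly at R = 0; naive clamping would create biomass from nothing.
  With this guard, e·ΣN + R is conserved along every run to ~1e-9
  relative, which the tests assert.
* Negative densities are clamped to zero after each step; volume defaults
  to 1 ml so densities double as counts for the Poisson draws.
* The same stepping loop exists twice — a compiled kernel and a plain R
  reference — and a test pins them to identical output, RNG stream
  included.

### The clock calibration

The verbal model statement says mutation probabilities are "per cell per
hour", which leaves two structural choices open at stationary phase: do
mutation and conjugation continue at full rate when growth stops? Both
switches are exposed (`mutation_clock`, `conjugation_clock`) and resolved
empirically against the three published 24-h ensemble outcomes (scenario
A: T1, T2 < 1 cfu/ml; scenario B: T2 = 99.5 ± 27.0; scenario C:
T1 = 102.3 ± 27.5, each over 20 runs):

* With **constant** conjugation, transfer continues for the ~12 h of
  stationary phase and the focal transconjugant means come out 2,400–4,100
  cfu/ml — 25–40× the published values, for either mutation clock.
* With **growth-scaled** conjugation (γ·ψ/ν~max~, the classic
  Levin–Stewart–Simonsen formulation in which transfer tracks physiology),
  the means land at ~130–140 (B) and ~130 (C) with standard deviations of
  40–70, and scenario A exceeds 1 cfu/ml in well under 1% of runs.

`scenario_preset()` therefore pins `per_division` mutation plus
`growth_scaled` conjugation — the coherent "everything tracks growth"
formulation — while `dynamics_params()` keeps the literal per-hour
defaults for users who want the verbatim reading. The calibrated variant
reproduces the published *contrasts* (which transconjugant type wins by
orders of magnitude, and scenario A's near-zero yields) and the order of
magnitude of the means, but its true ensemble means sit ~30% above the
published point values, just outside the ±1 SD band; the remaining gap
presumably lies in unpublished details of the original implementation and
is documented rather than absorbed into parameter adjustments.

```{r scenario, eval = FALSE}
sc <- scenario_preset("C")
ens <- run_ensemble(sc$params, sc$init, n_runs = 20, seed = 1)
glance(ens)
autoplot(simulate_plasmid_dynamics(sc$params, sc$init, seed = 1))
```

## Serial-transfer competition fitness

Pairwise competitions under daily 1/100 dilution follow the logistic
selection model dq/dt = −q(1−q)s in generation time, with
log2(100) ≈ 6.64 generations per transfer. The closed form is linear in
logit(q), so `predict_frequency()` (forward) and `estimate_s()`
(least-squares on the logit scale, slope negated; s > 0 means the
plasmid-bearing competitor loses) are exact inverses on noise-free data —
a property the tests check to machine precision. Frequencies of exactly 0
or 1 have no logit and are dropped with a warning; fixation handling
beyond that is out of scope. The neutrality call (|s| < 0.01 per
generation, or a 95% CI spanning zero) is an explicit, configurable
convention — the published fitness statements are qualitative, so some
threshold had to be chosen; 1% per generation is below what a 5-transfer,
200-colony experiment can reliably resolve.

## Escape-genotype spectrum

`parse_genotype()` understands the compact notation used for
transconjugant genotypes (spacer deletions `Δspc1,2`, IS-element
insertions `csm6(617)::IS256-d`, single-nucleotide deletions with their
frameshift consequence, nonsense/missense substitutions, and large
chromosomal deletions `Δ2387081–2520252 (IS256)`), with strict errors on
anything unparseable. Coordinates are 1-based inclusive — span =
end − start + 1 is the only convention that reproduces both the published
minimum (65,712 nt) and maximum (306,488 nt) deletion spans from their
printed coordinate pairs. `genome_fraction()` defaults to the
2,616,530-nt chromosome length; the published "11.6% of the genome" for
the largest deletion implies a ~2.64-Mb denominator (chromosome plus
resident plasmid), so the length is a parameter and the package's tests
accept both readings. The packaged genotype fixture transcribes all 111
analyzed isolates (the two excluded donor contaminants are absent);
`tally_spectrum()` and `deletion_spans()` recover the published counts
(55 locus deletions among 16 distinct variants, 24 insertions, 14 spacer
deletions) exactly.

```{r spectrum}
genotypes <- read_genotypes(crisprflux_example("table2_genotypes.csv"))
tally_spectrum(genotypes)
summarize_spans(deletion_spans(genotypes))
```

## Synthetic data

Every input the analyses consume can be generated with a seed:
`make_mating_counts()` (Poisson plating noise around a true Γ — the
simplest observation model for single-plate cfu counts; an overdispersion
hook can be added via repeated draws), `make_competition_trajectory()`
(binomial colony sampling around the deterministic frequency path), and
`make_genotype_table()` (multinomial category draws filled from template
grammars, always parseable). Fluctuation data are generated by
`simulate_fluctuation()` itself — the generator *is* the model, so there
is no duplicate logic to drift apart. All generators are bit-reproducible
under a fixed seed.

What the generators deliberately do not emulate: plating dilution-series
error structure, PCR or sequencing artifacts, between-day batch effects,
and any fitness cost of plasmid carriage (the published control found
carriage approximately neutral). Passing tests on synthetic data
therefore demonstrate correctness of the estimators under the stated
noise models, not robustness to every real-world complication.

## Problem sizes and runtime

The test suite and the reproduction script are sized for a desk machine:
fluctuation simulations use cultures of 2^7 → 2^20 cells (13 doublings),
Monte-Carlo calibrations use 200–1000 replicates, ensemble checks use
10–50 runs at `dt` = 0.01 h. These sizes were chosen so every stochastic
assertion has comfortable margin (3 SE or better) while the whole suite
runs in well under a minute.

## Known limitations

* The dynamics model is a reconstruction from the published verbal
  description and parameter list; see the clock-calibration section for
  the one quantitative residual it leaves.
* `estimate_mu()` matches means only; it does not exploit the full
  mutant-count distribution and inherits the discrete-doubling
  approximation of the simulator.
* The genotype parser covers the notation forms that occur in the
  packaged table (plus the synthetic grammar); novel notation will raise
  a parse error rather than guess.
* No spatial structure (filter geometry), plasmid segregation loss, or
  phage predation — all out of scope for the questions this package
  addresses.
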