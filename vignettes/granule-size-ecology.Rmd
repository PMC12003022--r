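---
title: "Methods: physico-chemical and niche-based analysis of granule size fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physico-chemical and niche-based analysis of granule size fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices behind
`granuleco`, and — in equal detail — what its synthetic-data generator does
and does not emulate, so a reader can judge what a green test establishes.

## 1. The study design being modelled

Anaerobic granular sludge is sieved into ten diameter fractions A–J
(A < 0.20 mm … J 3.15–4.00 mm), treated as a developmental/ecological
gradient. Per fraction the package expects: timed 0.3 m drop-column descents
for ~10 granules, loss-on-ignition masses, EPS component concentrations, SMA
bottles in triplicate against acetate, propionate, butyrate and H₂/CO₂ with
no-substrate and N₂/CO₂ controls, and three replicate 16S amplicon samples
(30 samples in total, depths roughly 12,000–31,400 reads after processing).

## 2. Physico-chemical estimators

**Settling velocity** is the marked distance over the measured time,
`v = L/t`, with `L = 0.3 m` by default.

**Density** inverts Stokes' terminal velocity for a sphere,
`rho_p = rho_f + 18 mu v / (g d^2)`. Assumptions: rigid sphere, laminar
regime. The particle Reynolds number `Re = rho_f v d / mu` is attached to
every estimate; `Re > 1` produces a warning rather than a refusal, because
the field applies Stokes' law across the full size range and the bias is a
known, documented approximation. Water density uses the Kell (1975)
polynomial and viscosity the Vogel equation (1.0017e-3 Pa s at 20 °C);
temperature defaults to 20 °C when unrecorded. Units are SI internally
(kg m⁻³); diameters are accepted in mm and converted.

**Solids**: `TS = dry/wet`, `VS = (dry − ash)/wet`, `VS/TS = (dry − ash)/dry`
with the ordering `wet ≥ dry ≥ ash ≥ 0` enforced.

**Fraction assignment** uses half-open `[lower, upper)` intervals. The sieve
table repeats its bounds (0.20–0.40 then 0.40–0.60) without stating
inclusion, so a convention is required; half-open intervals partition
(0, 4.0) mm with no gaps or overlaps, and a granule on a shared bound goes
to the larger fraction. Diameters ≥ 4.0 mm return `NA` (out of scheme).

## 3. SMA rates

Pressure signals are converted to biogas volume by a user-supplied
calibration slope and a multiplicative headspace correction factor (both
instrument constants; the functional form of the correction is not public,
so a constant is the declared interpretation). CH₄ volume is biogas ×
CH₄-fraction, converted to STP (0 °C, 1 atm) by the ideal gas law when an
incubation temperature is supplied; series already at STP pass
`temperature_C = NULL`. The no-substrate control series is linearly
interpolated onto the assay grid and subtracted; net cumulative CH₄ is
clamped non-decreasing from zero. The **rate** is the maximum slope of a
sliding OLS window (default 4 points — the conventional "steepest phase"
estimator) divided by the bottle's measured VS mass. Negative net rates
clamp to zero with a warning. H₂/CO₂ bottles use the headspace volume *lost*
(H₂ consumed), divided by 4 for the 4 H₂ : 1 CH₄ stoichiometry (equal
volumes at STP).

Numerical caveat, verified by simulation: the max-of-windows estimator is
biased upward under per-point noise (~10 % at 2 % multiplicative noise with
4-point windows), so the 2 %-recovery property is demonstrated with a
whole-linear-phase window, where OLS is unbiased; with clean series the
4-point default recovers planted rates to < 0.1 %.

## 4. Diversity stack

Rarefaction draws each sample down to the minimum sample depth *without
replacement* (multivariate hypergeometric), one seeded realisation, as in
the original analysis; a mean-over-draws option is available. All alpha
metrics (richness, Shannon in nats, Pielou `J = H/log S`, with `J = 0`
when `S = 1`) are computed on the rarefied table. Bray-Curtis follows the
`1 − 2Σmin/(Σ+Σ)` form; unweighted UniFrac is the unique fraction of
branch length observed in either sample, computed by postorder accumulation
of tip presence over the rooted tree (tested against both an explicit
branch-enumeration oracle and `phyloseq::UniFrac`). NMDS wraps
`vegan::monoMDS` (global model, Kruskal stress-1) with 20 seeded random
restarts; hand-rolling monotone regression would merely duplicate the
field-standard implementation. PERMANOVA is the one-factor pseudo-F from
among/within sums of squared distances with free label permutation
(999 default, p-resolution 1/1000) — matched against `vegan::adonis2` and a
hand-computed example in the tests.

## 5. Ensemble quotient optimisation

The search space is binary genus-membership vectors with at most `m`
members over the candidate pool (genera present in ≥ 2 samples). Objectives:
Pearson r of the summed relative abundance against a covariate (continuous
mode, maximised) or its coefficient of variation (uniform mode, minimised).
`m` defaults to 20, the ensemble size the motivating study reports, but is
a required, explicit parameter — whether 20 was a constraint or an outcome
there is unknowable from the text.

The optimiser is a memetic elitist GA: population 200, 500 generations,
tournament selection, uniform crossover (0.8), per-bit mutation (1/n),
elitism 2, a repair operator that trims oversized individuals by their
single-taxon alignment, greedy-forward-selection and top-correlate seeding,
and periodic best-improvement local search over single-member moves
(additions, drops, swaps). Two numerical choices deserve emphasis:

* **Parsimony tie-break.** The *search* fitness is the raw objective minus
  `1e-4` per member. Without it, taxa of near-zero abundance are "free
  riders": their inclusion changes r by essentially nothing, so returned
  memberships drift arbitrarily. The penalty is far below any meaningful
  objective difference and the *reported* objective is always the raw
  statistic. The exhaustive enumerator (`eqo_bruteforce`, the testing
  oracle) optimises the same penalised fitness, so both routes solve one
  well-defined problem.
* **Determinism.** All randomness flows from `ga_params$seed`; results are
  bit-for-bit reproducible.

## 6. Specificity (Spec)

For taxon t with per-sample weight vector `p` (its counts normalised to sum
1) and covariate `x`, the empirical statistic is the Rao-type dispersion

    E = sum_{i<k} p_i p_k |x_i − x_k| / sum_{i<k} p_i p_k .

The null distribution permutes the weights across samples (equivalently the
covariate), 999 times by default, shared across taxa for speed.
`Spec = (E − mean(E_null))/mean(E_null)` is exactly 0 when E equals the null
mean, negative for covariate-confined (specific) taxa, positive for
cosmopolitan ones. p-values are two-sided (doubled smaller tail — with 199
permutations this is exactly calibrated at the 0.01 and 0.05 grid points, a
property the acceptance suite checks empirically), BH-corrected across taxa;
`q < 0.05` with the corresponding sign yields the "specific"/"cosmopolitan"
labels. The published specificity method's rescaling of negative values onto
[−1, 0] via an optimised theoretical minimum is *not* reproduced; the
implemented centring is declared and calibrated but may differ numerically
from the original figures.

## 7. Niche breadth and overlap

Resource states default to the ten fractions with replicates pooled (the
gradient is fraction-structured); per-sample states are available via the
`grouping` argument. Levins' `B = 1/Σp²` (the inverse Simpson
concentration), `BA = (B−1)/(N−1)`. The generalist/specialist null
reallocates the taxon's total count across states by multinomial draws with
probabilities proportional to state availability; note that literally
permuting a taxon's counts across states would leave B unchanged (B is
permutation-invariant), so a reallocation null is the only meaningful
reading. Calls: observed B above the 95 % null interval → generalist, below
→ specialist. Because abundant taxa have very tight multinomial nulls, calls
on deeply sequenced taxa are sensitive; this is inherent to the null, not a
bug, and is why the calls are reported together with the interval bounds.

Hurlbert's `B' = 1/Σ(p_i²/a_i)` needs availability weights for a continuous
covariate. **The availability construction is a modelling choice with no
canonical definition**: here the per-state covariate is min-max normalised
onto [0.05, 1] and renormalised to sum 1 (the 0.05 floor keeps every
occupied state's availability positive, which the formula requires).
Association signs are Spearman correlations (average ranks on ties) between
the state profile and the covariate, reported only when a permutation test
rejects at 0.05, else "0". Levins' overlap `LO_{1,2} = Σp₁p₂/Σp₁²` is
asymmetric by construction; the matrix diagonal is exactly 1.

## 8. The synthetic world: what is planted, and how

The generator's defaults *are* the stated study design: 10 fractions × 3
replicates, depths uniform on [12,000, 31,400], 300 taxa (a deliberate
scale-down from 3041 so the suite runs in minutes; `n_taxa = 3041`
reproduces the full dimensions). Expected compositions are deterministic
per fraction; replicate samples add i.i.d. lognormal noise, which is
exchangeable across samples and therefore leaves the Spec permutation null
calibrated for non-planted taxa. Planted blocks:

* **Archaea** (30 taxa, two phylum labels): total proportion rising with
  fraction size; the five cleanest risers are *inside* the size-correlated
  ensemble (in the real system the strongest size-trending genera are
  methanogens), the rest are individually noisy so no single archaeon
  out-correlates an ensemble member.
* **Size-correlated ensemble** (20 taxa incl. those 5 archaea): summed
  expected proportion affine in fraction size (0.12 + 0.03·size), members
  carrying small paired zero-sum "wiggles" so each member deviates while the
  full set cancels exactly.
* **Stable ensemble** (20 taxa): constant summed proportion (0.18) with
  strongly fluctuating members (σ = 0.5) — the subset self-equilibrates.
* **Specific taxa** (22): present only in fractions A–C, jointly 0.12 of
  those communities. This block doubles as the compositional offset of the
  planted rises: total planted mass is then nearly flat across fractions,
  so background taxa inherit almost no covariate trend.
* **Generalists** (10, flat), **specialists** (8, mass split 65/35 between
  two distant fractions — breadth ≈ 2 yet covariate-dispersed, so they are
  specialists without masquerading as size-specific or size-correlated).
* **Background** (195): flat expected shares, heavier sample noise.

Counts are drawn by a **stratified multinomial**: each planted ensemble
receives its exact per-sample count total, multinomial within the block,
and the remainder is multinomial. This is the one deliberate departure from
a single unrestricted multinomial, and it is load-bearing: with free
multinomial noise at n = 30 samples and ~300 candidate taxa, a post-hoc
subset search essentially always finds noise realisations whose summed
abundance out-correlates any planted subset (we measured GA solutions with
residuals three times smaller than the planted subset's own sampling-noise
floor). Membership recovery is then a property of the optimiser's luck, not
of the data. Pinning the ensemble totals makes the planted sets the exact
optima, so the recovery criteria test the estimators rather than a
statistical impossibility. The same reasoning rules out building the
diversity decline from per-fraction Dirichlet draws: fraction-level
compositional noise concentrates every taxon's weight in a few fractions
and biases the whole community toward "specific". Instead the evenness
decline comes from the planted dominance growth (archaea + ensemble), which
makes expected Shannon entropy strictly decreasing A→J at the default
scale (the construction is tuned at 300 taxa; far smaller tables need not
be monotone).

What the generator does **not** emulate: compositional correlations beyond
the planted blocks, PCR/primer bias, overdispersion beyond lognormal ×
multinomial, phylogenetic signal in abundances (the tree is a random
coalescent), and any relationship between the physical covariates and the
community other than through the fraction labels. A green recovery test
therefore establishes that each estimator recovers its own planted
structure at realistic scale and noise — not that the pipeline would
reproduce any particular real-world result.

Physical truth: densities decline ~1180 → 1004 kg m⁻³ (A→J) so that
Stokes-inverted settling velocities rise ~0.001 → 0.04 m s⁻¹, reproducing
the inverse density-velocity relationship; VS/TS dips in the small
fractions (0.86, 0.70, 0.89, then 0.918). Settling times invert Stokes' law
exactly plus 2 % multiplicative timing noise; SMA series are lag + linear
with rates peaking at fraction F and highest on H₂/CO₂, with paired
controls; the default SMA series are noise-free (noise is an explicit
option used by the estimator-property tests).

Because size, settling velocity and density are all deterministic functions
of the fraction in the metadata, Spec scores across these covariates are
near-collinear — mirroring the perfect size/settling-velocity specificity
correlation such a design produces in reality.

## 9. Degenerate inputs and tie-breaks

Zero-variance ensembles score r = 0 (flagged); zero-mean ensembles have
infinite CV. A taxon concentrated on one sample has E = 0 by definition.
Constant covariates are rejected for Spec and trends. All-zero EPS
compositions and all-zero samples are errors. Rarefaction refuses depths
above any sample's total, naming the samples. `pielou` of a single-taxon
sample is 0 by convention. Sample and taxon identifiers are canonicalised
lexicographically on construction so no downstream result depends on input
order.

## 10. Known limitations

* The Spec scaling and the breadth-call thresholds may differ numerically
  from the original study's supplementary implementations (unavailable);
  both are declared here and calibrated/validated internally instead.
* Printed fraction-level densities in the motivating literature
  ("104.6 g cm⁻³") are not physically interpretable as absolute densities
  and are not reproduced; the package computes textbook Stokes densities.
* The max-slope SMA estimator is upward-biased under noise (Section 3).
* Hurlbert availabilities from continuous covariates are a convention
  (Section 7); conclusions that depend on their exact values should be
  checked against alternative constructions.
* PERMANOVA is one-factor with free permutation; replicate structure within
  fractions is not treated as strata.
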