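---
title: "From spent media to soil: the metaboweb model and its assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spent media to soil: the metaboweb model and its assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboweb)
library(dplyr)
```

## The question and the statistical frame

Exometabolite profiling measures, for a cultured isolate, which metabolites
it depletes from or enriches into a defined medium. `metaboweb` asks
whether those laboratory phenotypes survive transfer to an intact soil
community: if an isolate consumes a metabolite in culture, the abundance of
its closest environmental relative should correlate *negatively* with that
metabolite's soil-water level across a wetting time course, and a released
metabolite should correlate *positively*.

Each isolate × metabolite pair therefore contributes one *directional
prediction* (sign −1 or +1), each evaluated pair one *observation*
(`sign(rho)` of a Spearman correlation), and the experiment-level question —
"is laboratory behaviour predictive at all?" — reduces to the number of
sign matches `k` among `n` evaluated pairs, tested against `Bin(n, 1/2)`
with an exact two-tailed binomial test. We use the symmetric doubling rule
`p = min(1, 2 min(P(X ≤ k), P(X ≥ k)))`, which coincides with the
minimum-likelihood rule at `p0 = 1/2`; for general `p0` the
minimum-likelihood rule is applied, always by exact pmf summation.

Two deliberate choices shape the evaluated set:

* **Directionality uses `sign(rho)` only.** The `|rho| ≥ 0.5`
  "highly correlated" threshold is reported as a flag and drives nothing,
  and FDR-adjusted q-values only decorate foodweb edges with stars. Mixing
  strength thresholds into the sign test would change its null
  distribution.
* **Unevaluable pairs are excluded, not failed.** A pair whose correlation
  cannot be computed (fewer than four complete observations, zero variance)
  or whose `rho` is exactly 0 carries no directional information; counting
  it as a failure would bias the binomial test downward. Exclusions are
  logged and reported.

## Filtering before the test

Predictions are evaluated only for metabolites whose soil dynamics are
credibly biological and informative:

* **QC**: samples with a failed `qc_pass` flag are dropped.
* **Two-fold dynamic range**: a metabolite is kept when the ratio of its
  maximum to minimum positive per-(stage, time) mean peak area is ≥ 2.
  Metabolites with fewer than two non-missing cells are unevaluable. The
  rule is scale-invariant by construction.
* **Killed controls**: autoclaved biocrust tracks abiotic dynamics
  (leaching, sorption). Per metabolite we fit
  `log(1 + area) ~ condition * time` with condition categorical and time
  continuous, and call the metabolite *biologically controlled* when it is
  absent from the killed controls entirely ("detected" = ≥ 50% of
  replicates non-missing in ≥ 1 cell) or when the condition main effect or
  the condition × time interaction is significant at `alpha`. A Tukey HSD
  across condition × time cell means is attached as a supplementary table
  but does not drive the verdict — a model-level F-test is an unambiguous,
  reproducible rule, whereas a verdict assembled from many pairwise
  post-hoc contrasts requires an aggregation convention that would itself
  be arbitrary. Because killed controls exist only for one late
  successional stage, the default comparison uses the matched active stage
  (`compare_all = TRUE` pools all stages instead). Missing areas are
  treated as missing, never as zeros.

The `log(1 + area)` transform (also used before PCA) reflects that peak
areas are positive, span decades, and have roughly constant coefficient of
variation; the `+ 1` keeps occasional zeros finite.

Note the composite verdict rejects a true null in roughly
`1 − (1 − alpha)^2` of cases, not `alpha` — it trades a slightly elevated
false-"biological" rate for sensitivity, which is conservative in the
pipeline's direction of use (a false positive here merely *admits* a
metabolite into the concordance test). The per-F-test size is what the
test suite checks under label permutation.

## Marker matching

Community abundances come from a single-copy ribosomal-protein marker
family chosen by total assembled-gene count across the dataset (ties break
alphabetically). Isolates are matched to environmental taxa by global
Needleman–Wunsch percent identity (match +1, mismatch −1, linear gap −2;
identity = identical columns / full alignment length, gap columns
included — the denominator is stated explicitly because percent identity is
not standardized across tools). Matching is a pure argmax with the full
ranked list retained; no identity floor is imposed, since any cutoff
between genus- and species-level similarity would be arbitrary — users can
apply their own threshold to the ranked output. `fragment_identity()`
offers a fragment-based whole-genome identity in the spirit of
fragment-ANI: non-overlapping 1020-nt fragments, each aligned to its
best-scoring location in the target by local alignment, with fragments
below 70% coverage or 30% identity dropped; these are the conventional
fragment-ANI filter values. We align each fragment directly by
Smith–Waterman rather than seeding with k-mers: at the genome sizes this
utility targets the exact alignment is affordable and avoids seed-miss
artifacts.

## The synthetic wet-up generator

No public dataset pairs replicated soil-water metabolomics with
marker-resolved community profiles *and* known interaction ground truth,
so the package ships a generator whose defaults reproduce the reference
study design: stages A–D, sampling at 0.05 h (3 min), 9, 18, 42 and
49.5 h, five active replicates (100 active samples), triplicate killed
controls from the latest stage, and one metagenome per (stage, time) cell
(so abundances carry no replicate index and are attached to every
metabolite replicate of their cell).

**Abundance.** Each taxon follows a log-time Gaussian pulse
`B(t) = baseline + amplitude · exp(−(ln t − ln t_peak)² / (2w²))`, scaled
by a per-stage multiplier. Log-time is the natural axis for wet-up
dynamics: it lets an "early" responder peak at the first sampled minute
and still decay smoothly over two days. The default community is an early
phototroph (peak 0.05 h, the primary producer), a mid and a late
heterotroph (peaks 42 and 49.5 h), and a flat generalist; a constant
"background" taxon absorbs unmodeled read mass so focal relative
abundances stay realistic (the early phototroph opens near 23% and decays
to ~2%).

**Pools.** Metabolite mass balance is integrated per stage by forward
Euler (default step 0.05 h):
`dM/dt = leach·exp(−t/τ) + Σ r_i B_i − Σ u_i B_i · M/(K + M)`, clamped at
zero. The leaching term is the abiotic wet-up pulse; killed mode simply
zeroes every biological term, which is exactly the autoclaved-control
contrast. The default leach decay τ = 24 h keeps killed controls rising
gradually through the time course and gives consumed metabolites a low
but detectable steady state instead of decaying below the detection
limit — both features of real wet-up data. Uptake saturates at `u·B`
(Michaelis–Menten in the pool), with half-saturation K = 5 concentration
units.

**Observation.** Peak areas are `gain · M · exp(ε)`, `ε ~ N(0, σ²)` with
σ = 0.25 — multiplicative lognormal noise, matching the roughly constant
CV of LC/MS peak areas — and areas under the detection limit (0.01) are
recorded missing. Marker reads are multinomial draws (depth 20,000) over
focal plus background abundances. Isolate spent-media profiles follow the
closed form `FC = exp(−u·c·T) · (1 + r·c·T / M₀)` with culture biomass
c = 3 and incubation T = 48 h, times lognormal noise (σ = 0.12); these
culture constants were chosen once so that the default rates land the
classes comfortably on the 0.5 / 2 thresholds. Isolate markers are
environmental markers mutated at 10% per-site divergence, mimicking the
isolate-to-MAG identity gap seen in real marker comparisons. All
randomness flows from one root seed through named substreams (observation
noise per condition, reads, profiles, markers), so a scenario + seed pair
is bit-reproducible.

**Ground truth.** A pair's expected sign is −1 iff the taxon only takes
the metabolite up, +1 iff it only releases it, 0 otherwise. The default
twelve metabolites span released-then-consumed (producer → heterotroph
hand-off), consumed-only, released-only and neutral regimes — 17 signed
pairs. Release is assigned to taxa whose pools can track their abundance
over the sampled window and consumption to the rising heterotrophs; with
only five time points, a released pool that outlives its short-pulsed
producer would genuinely decorrelate from it, which is a real ambiguity of
such designs, not something the validation should hide.

**What passing tests do and do not show.** The generator produces clean
unimodal responses, independent lognormal noise, and interactions strong
enough to dominate the sampled window. Recovery of ≥ 90% of ground-truth
signs under these conditions validates the statistical machinery — the
plumbing from tables to verdicts to the binomial test — not the ecological
difficulty of real soil, where compositional effects, shared responses to
wetting, weaker kinetics and unmodeled taxa will lower concordance.

## Numerical choices and degenerate inputs

* Euler integration at the default step agrees with a 50×-finer step to
  well under 1% relative error on the default scenarios (tested); the step
  is a config option.
* Spearman p-values use the t approximation
  `t = rho·sqrt((n−2)/(1−rho²))` on n − 2 df, with average ranks for ties
  and `|rho| = 1` reported as p = 0. With 100 pooled samples per pair the
  t approximation is accurate far beyond the precision used anywhere
  downstream.
* Hierarchical clustering uses correlation distance (1 − Pearson between
  profiles) with average linkage — shape similarity, insensitive to the
  row scaling already applied — and relabels clusters in input order for
  determinism. Zero-variance profiles get maximal distance rather than NA.
* Ties everywhere break deterministically (alphabetical family and taxon
  labels, input-order clusters).
* Degenerate inputs error loudly and early: empty tables, all-missing
  rows, zero-sum count columns (naming the sample), zero control means,
  released metabolites with zero culture pool, non-positive times.

## Calibration experiments in the test suite

The suite validates the machinery with three property-style experiments,
sized as follows:

* **Sign recovery**: the full pipeline on the default scenario, seeds
  1–20 (340 signed pairs).
* **Null calibration of the binomial test**: flat pools plus noise,
  random sign predictions, 500 seeded runs. The exact two-sided binomial
  test is discrete, so its true size depends on the trial count and never
  exceeds the nominal level; at 44 trials (4 taxa × 11 metabolites, the
  null scenario default) the exact size is 4.88%, the closest attainable
  to 5%, which is what the observed rejection rate is compared against.
  At 48 trials, for contrast, the exact size is only 2.9% — a reminder
  that "significant at 0.05" is conservative for this test.
* **Killed-control size**: condition labels permuted within time strata
  on null data, 200 permutations; each F-test's rejection rate is compared
  to its nominal `alpha` (the composite verdict is intentionally not
  `alpha`-sized; see above).

## Known limitations

* Correlations pool across stages and times by default (a per-stage mode
  exists); time-lagged, partial or compositional correlation structures
  are out of scope, as are dynamic resource-utilization or flux models.
* The killed-control ANOVA assumes approximately lognormal peak areas and
  uses killed controls from a single stage, as in the experimental design
  it mirrors.
* `fragment_identity()` is a demonstrator for synthetic genomes, not a
  replacement for production ANI tooling on real assemblies.
* The generator does not simulate raw reads, chromatograms, diel cycles,
  or rare-taxon effects; metabolite identification and assembly/binning
  are upstream of this package's scope.
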