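---
title: "Models and methods: the tempo of mitogenome evolution from serially sampled sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotempo)
```

## The problem

Human mitochondrial DNA accumulates substitutions fast enough that
radiocarbon-dated ancient mitogenomes, compared against their modern
phylogenetic equivalents, calibrate the substitution rate directly at
many depths in time. Two empirical patterns complicate the naive
molecular clock. First, rate estimates depend on the age of the
calibration window: windows of a few thousand years yield apparent rates
several-fold above the germline mutation rate, while windows of tens of
thousands of years fall back to or below it — the time-dependency
effect, attributable to demography (a growing population keeps more
transient lineages alive, so more segregating variation is counted).
Second, neutral transient polymorphisms persist on the order of 2Ne
generations in a haploid, maternally inherited genome, so an ancestral
haplotype can survive unmutated alongside heavily mutated descendants;
intraspecific trees collapse those survivors into the founding node and
thereby shorten rho-based coalescence ages.

`mitotempo` implements the full chain: variant-profile representation of
mitogenomes, period binning with modern matching, the pairwise rate
estimator, the persistence model, rho dating with divergent-lineage
selection, and a simulator that generates tip-dated samples in which all
of these effects are present by construction.

## Sequence model

A mitogenome is a set of variant calls against the 16,569-bp rCRS
coordinate frame: substitutions (`73G`), insertions (`309.1C`) and
deletions (`522d`). Multi-position deletions are recorded once, at their
first position, so one mutational event is one call. Site filtering
follows the standard practice for these data: indel calls inside the
three length-variable regions around positions 309, 522 and 16,193 are
removed, as is every call at the hypermutable site 16,519. The anchor
positions name regions rather than exact intervals, so the default
windows are the homopolymeric/AC-repeat tracts those anchors sit in
(303–315, 513–524, 16,180–16,195); both the windows and the excluded
sites are fields of `exclusion_policy()` and can be overridden. Because
16,519 is excluded as a hypermutable *site*, the default drops
transversions there as well as the common transition.

The pairwise difference between two profiles is the size of the
symmetric difference of their filtered call sets. Recurrent and parallel
mutations are not resolved against the mtDNA tree (that requires a
reference phylogeny and is out of scope), so counts carry a slight
upward bias at hypervariable positions; the simulator's coalescent mode
conversely allows recurrent hits and therefore a slight undercount. Both
caveats are second-order at intraspecific divergence levels.

The packaged reference (`synthetic_reference()`) is a deterministic
16,569-bp stand-in with human mtDNA base composition — coordinates and
lengths match the rCRS, base identities do not. It is sufficient for
simulation, testing and any computation that only uses coordinates;
analyses of real sequences should pass the actual rCRS FASTA to
`mito_reference()`.

## Periods, matching, and the observed/expected table

Ancient samples are grouped into dated periods either by explicit age
edges (half-open intervals) or by equal-count quantile binning. Each
ancient is matched to "phylogenetically equivalent" moderns by longest
shared haplogroup-label prefix — labels are the only key available
without re-deriving the phylogeny; ties return all tied moderns, and the
default pairing keeps one best match per ancient (exhaustive cross-pairs
are available via `build_pairs(mode = "cross")`). A period's age is the
average of its ancients' calibrated ages weighted by pair
participation, which is what "weighted average of the calibrated ages"
must mean when ancients are reused across pairs; a plain mean is a
config switch.

Within a period, differences are summarized per macrohaplogroup and
pooled by pair count, `sum(n_g * mean_g) / sum(n_g)`. Homogeneity across
macrohaplogroups is checked with Welch's t-test between the two most
divergent groups — group sizes and variances in these tables are highly
unequal, so the unequal-variance form is the defensible one.

The *expected* column extrapolates the youngest period's per-year
difference rate linearly: `expected_k = (obs_1 / T_1) * T_k`. That rule
is a reconstruction — verified against all ten rows of the packaged
published table, where it reproduces the printed values to two decimals
(one row appears truncated rather than rounded, and one printed pooled
total evidently used unrounded group means; the reproduction script
`analysis/02_periods.R` prints both comparisons). The anchor period is
configurable.

## The rate estimator

For a period of age `T` with `n` modern–ancient pairs and total
difference count `sum(d_ij)`,

```
theta_genome = sum(d_ij) / (n * T)        per genome per year
theta_site   = theta_genome / L           per site per year
```

with `L = 16569` by default. The published per-site rates are not
jointly recoverable from the published pooled counts with any single
`L`, so the package always reports both scales and leaves `L`
configurable rather than tuning it. The modern sample age (−50 BP) is
ignored in `T`, matching the single-`T` structure of the estimator.
Counts are Poisson under the mutation model, so the interval is the
exact Garwood interval on `sum(d_ij)` scaled by the exposure `n * T *
L`; its coverage is verified by simulation (93–97% band). The pooled
estimator equals the pair-weighted mean of per-macrohaplogroup
estimators exactly, because all groups share `T` and `L`.

Time dependency is assessed by unweighted OLS of the per-period rate on
the period age; the slope is reported in (per site per year) per year
with a two-sided p-value. No transformation is applied — with ten
periods and a monotone decaying curve the sign of the slope, not the
functional form, is the claim being tested.

## Persistence of transient polymorphisms

`persistence_model()` carries four constants: `Ne` (effective number of
females), generation time (25 yr), the ploidy factor (2 for mtDNA, 4
for autosomes), and a genome-wide mutation-success rate
`lambda_genome = 1.947e-4` per year. Persistence is `ploidy_factor * Ne`
generations; with `Ne = 5000` that is 10,000 generations or 250,000
years. Mutation-free survival over `t` years is the Poisson zero class
`exp(-lambda * t)`. The lambda constant is kept verbatim as configured
input: deriving it as mean-site-rate × length with the two germline
rates implies ≈ 12,206 sites, which matches no standard mitogenome
partition, so the package exposes `genome_rate()` for users who prefer
an explicit derivation but does not silently substitute it.

## Rho dating and divergent-lineage selection

`rho` is the mean mutation count between a clade's root haplotype and
its tips; age = `rho * years_per_mutation`. Two calibrations are
packaged: one mutation / 3624 years (modern phylogeny,
purifying-selection corrected) and one mutation / 2454 years (mean of
ancient tip-dated estimates); ages under the two differ by the fixed
factor 3624/2454 ≈ 1.477. The uncertainty attached is the
star-genealogy standard error `sqrt(rho/n)` — exact when tips are
independent Poisson counts, an understatement when the clade has deep
internal structure; the tree-partitioned variance would need the tree,
which this package deliberately does not build.

Selection modes counteract the persistent-lineage shortening:
`"max"` keeps tips at the maximum count after discarding clear outliers
(Tukey fence `Q3 + 1.5*IQR` — a standard, parameter-free reading of
"excluding clear outsiders"), `"upper_quartile"` keeps counts at or
above the 75th percentile (the quartile adjacent to the maximum; the
phrase "lower interquartile" in the source literature conflicts with
choosing maximal counts, and this is the reading consistent with it).
Root haplotypes are supplied, not inferred.

## The simulator

Genealogy mode implements the persistent-ancestor scenario directly:
one ancestral profile at age `T`; each modern tip is an exact ancestral
copy with probability `persistent_fraction`, otherwise it split from
the persistent lineage `s` years ago and carries
`K ~ Poisson(mu_site * L * s)` private substitutions at fresh positions
(collision-free, so counts are exact). Two divergence conventions are
provided because they serve different checks: `"ancestral"` (`s = T`
for every derived tip) makes the modern–ancestor estimator exactly
calibrated, which is what the estimator-recovery test needs;
`"uniform"` (`s ~ U(0, T)`) is the genealogy picture in which derived
lineages sprout in different generations, and is the setting in which
all-tips rho underestimates the root age while upper-quartile selection
recovers most of it.

Coalescent mode draws a continuous-time serial-sample coalescent for
tip-dated samples under a piecewise-exponential `Ne(t)`; within each
demography piece the pair-coalescence intensity integrates in closed
form, so event times are drawn by inversion with no discretization. It
was checked against the closed form `E[TMRCA] = Ne` generations for a
haploid pair at constant size. Mutations fall on branches as
`Poisson(branch_years * mu_site * L)` at uniform positions with
uniform non-current target base (recurrent hits and back-mutations
possible). Tips are labelled by the deepest `clades` subtrees (M, N, R,
then further letters), with one sublevel (`M1`, `M2`, ...) so that
prefix matching has structure to work with; labels beyond M/N/R map to
the macrohaplogroup bucket `L-other`.

Default study conditions: `mu_site = 1.6e-8` per site per year (between
the two germline pedigree estimates), generation time 25 years, an
ancestral `Ne` of 5,000 females constant into the deep past and growing
exponentially 20-fold over the last 10,000 years (the "explosive recent
growth" premise at a conservative magnitude), sampling tiers from
modern (−50 BP) to 45,000 BP. These are set once in
`simulation_config()` and the property tests run at them; users can
override every field.

What the simulator deliberately omits: selection, recombination (absent
in mtDNA), heteroplasmy, sequencing error and ancient-DNA damage, and
indels (the analysis excludes them anyway). Passing tests therefore
show that the estimators behave as designed under the neutral
serial-coalescent model — not that real data are free of damage
artefacts or selection.

## Numerical and degenerate-input choices

* Exact Poisson interval via `qgamma`; `ci_low = 0` at zero counts.
* Welch's test between two constant samples is undefined; the package
  returns p = 1 for identical constants and p = 0 for different ones.
* Quantiles use R's default type 7; the upper-quartile rule is `>=`,
  so a constant sample keeps all members.
* Half-open period intervals `[low, high)`; samples outside the edge
  range are an error, as is an empty bin.
* `match_modern` with no shared leading character returns an empty
  match with a warning rather than an error, so one unmatched ancient
  does not abort a whole period.
* All simulation draws are reproducible from `(config, seed)`; the
  fixture writer stores the seed and a configuration hash in the truth
  JSON.

## Problem sizes

The property checks run at: 200 genealogy replicates of 50 tips for
estimator recovery; 100 coalescent replicates (~48 tips over three
tiers) for the time-dependency direction; 200 genealogy replicates with
`persistent_fraction = 0.3` for the shortening effect; 2,000 Poisson
replicates for interval coverage; 1,000 two-group draws for the size of
the homogeneity test; 4,000 two-tip coalescent draws against the
closed-form pairwise diversity; and 200 seeds of 2,000 tips for the
Poisson mean of the generator. The workflow scripts under `analysis/`
use a 110-tip data set with five ancient tiers.

## Known limitations

Raw symmetric-difference counting (no tree-aware recurrent-mutation
resolution); star-genealogy rho variance; haplogroup matching by label
prefix only; the synthetic reference is not the rCRS; the published
per-site headline rates are reproduced only as fold-change inputs, not
re-derived, because their site denominator is not stated with the
published tables.
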