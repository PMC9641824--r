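---
title: "Methods: from GPS fixes and ASV tables to migration–microbiota associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from GPS fixes and ASV tables to migration–microbiota associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, rules and numerical choices behind
`migrobiome`, in the spirit of a methods section: what each stage assumes,
which parameters matter, and what the synthetic-data generators do and do
not emulate.

## Movement segmentation

**Geodesy.** All distances and courses are loxodromes (rhumb lines) on a
sphere of radius 6371 km. A constant-bearing path is the natural reference
for a migrating bird holding a compass course, and on the scale that
matters here the spherical–ellipsoidal discrepancy (≲ 0.5%) is far below
the 19/40/50-km decision thresholds. Distances between poles of differing
longitude are refused (the loxodrome is undefined); pure meridian paths
reproduce the great-circle length exactly, which the tests exploit as an
analytic limit.

**Daily metrics.** Fixes are first restricted to daylight — sunrise/sunset
from the NOAA fractional-year solar approximation at the day's median
position, sun-centre altitude −0.833° — and subsampled to one fix per
60-minute grid slot anchored at sunrise (nearest fix per slot; an
already-hourly stream passes through unchanged). Days are bounded by local
solar midnight (UTC shifted by longitude/15 h). The roosting sites are the
first and last retained daylight fix; from them come the daily beeline,
its azimuth, and the turning angle (smallest absolute circular difference
against the previous day's azimuth, hence in [0°, 180°] and missing on the
first day). The total daily path is the sum of consecutive-fix rhumb
distances. By construction beeline ≤ total (+1 µm tolerance), a property
the tests assert on arbitrary inputs.

**Day classification.** A day is *migratory* iff total > 40 km and/or
beeline > 19 km, else *stopover*. This is a pure per-day threshold rule —
permuting days permutes labels.

**Endpoints.** Three mutually exclusive track endings:

* *Arrival*: the first day d whose beeline is ≤ 50 km **or** whose azimuth
  leaves the northern sector (270°, 360°) ∪ [0°, 90°), **and** whose
  turning angle exceeds 100°, provided (i) some earlier day was a northern
  long-distance (> 50 km) day — a cessation presupposes the behaviour
  ceased — and (ii) no northern long-distance day occurs within the next 5
  days. The lookahead window replaces the visual track inspection a human
  analyst would do; 5 days comfortably exceeds any mid-migration stopover
  run the generator produces (≤ 4 days) while still rejecting pauses that
  resume. The > 50 km criterion is evaluated on the daily **beeline**,
  parallel to the directional criterion that is necessarily beeline-based.
  The arrival location is the previous day's roost; the arrival date is
  day d itself.
* *Death*: the first ≥ 24-h window in which every fix stays within 0.5 km
  of the window start and all accelerometer variance lies below the
  flatline ceiling — 1% of the migratory-day mean activity variance when
  migratory days exist, else an absolute default of 0.01 (the generator
  emits migratory-day variances near 1). A window is only certified if the
  fix stream actually spans it.
* *Loss*: the stream ends with neither rule fired; no endpoint location is
  reported.

If both rules fire on the same day, death wins by default (configurable):
a flatlining bird should not be scored as arrived. Earlier dates otherwise
take precedence.

**Distance accounting.** The post-stopover migration distance sums total
daily path over migratory days before the endpoint (on the subsampled
hourly track, the same series the classifier saw). The total migration
distance — wintering grounds → capture stopover → breeding grounds — is
the sum of two beelines and is only defined when both remote sites are
known. Death tracks additionally report the rhumb distance from the
capture point to the death location and the days survived since the first
segmented day.

## Body condition

The scaled mass index standardizes each bird's mass to the cohort's
arithmetic mean wing length, `SMI_i = M_i (L̄/L_i)^b`, with `b` the
standardized major axis slope of ln M on ln L (OLS slope divided by the
Pearson correlation, equivalently sign(r)·sd(lnM)/sd(lnL)). Because the
mass–size allometry differs between the sexes in strongly dimorphic
raptors, `smi()` refuses mixed-sex input; `add_condition()` splits,
computes and recombines. If every wing equals the mean the exponent base
is 1 and the index degenerates gracefully to mass itself; a zero-variance
wing vector otherwise leaves the slope undefined and errors. EURING age
code 5 maps to juvenile (first-year), ≥ 6 to adult.

## Microbiota preprocessing

The ladder runs in a fixed order — contaminant removal, taxonomy filter,
depth filter, rarefaction — and each later step is idempotent on the
ladder's own output.

* *Contaminants*: per taxon, a 2×2 presence/absence table (negative
  controls vs true samples) scored by Pearson chi-square, switching to the
  one-sided Fisher exact test whenever an expected cell is below 5. The
  score is directional: a taxon whose presence fraction in controls does
  not exceed that in samples scores 1 and can never be flagged. Flagging
  threshold 0.5. Taxa absent everywhere are warned about and left
  unflagged.
* *Taxonomy filter*: removes taxa not assigned to kingdom Bacteria, family
  Mitochondria, order Chloroplast, or with unresolved phylum, logging
  counts per rule.
* *Depth filter*: samples with fewer than 10,000 reads are dropped;
  exactly 10,000 is retained (a "minimum read depth" is inclusive).
* *Rarefaction*: each sample is subsampled **without replacement** to the
  post-filter minimum depth (configurable), seed 999 by convention; taxa
  left with zero totals are removed. Per-cell counts can never exceed the
  originals, and the expected rarefied count is the hypergeometric mean
  `depth · c_t / C` — both tested.

## Diversity and community comparison

Shannon uses natural logs; Chao1 is the bias-corrected
`S_obs + F₁(F₁−1)/(2(F₂+1))`; Faith's PD is the branch-length sum of the
subtree spanning the observed taxa and the root, computed from an
edge × tip incidence matrix so a whole table is one sparse product. The
normalizing transforms applied before linear modelling are log₁₀
(Shannon), reciprocal (Faith's PD) and identity (Chao1).

Four dissimilarities: Bray–Curtis on counts; Jaccard on presence/absence
by default (the quantitative Ružička variant sits behind
`binary = FALSE` — which variant a given study used is rarely stated, so
the choice is an explicit flag, binary by default to pair with the
unweighted phylogenetic metric); unweighted UniFrac (branch length unique
to one sample over branch length covered by either); and weighted UniFrac
in its **non-normalized** form `Σ b_e |p_e − q_e|`, the common default of
the standard toolchain. Tree tips never observed in the table contribute
nothing.

PERMANOVA partitions the Gower-centred inner-product matrix
`G = −½ J D² J`. Marginal (`by = "margin"`) term sums of squares are
tr(H_full G) − tr(H_−t G); sequential mode adds terms in order and its R²
column sums to 1. The pseudo-F compares each term to the full-model
residual, and p = (1 + #{F* ≥ F}) / (1 + n_perm) over label permutations
(9999 by default) — the unbiased estimator, with ties counted as
exceedances at a relative tolerance of 1e−8. A user-supplied permutation
matrix allows exhaustive enumeration on small designs, which the tests use
to match an enumeration oracle exactly. Aliased (confounded) terms error
with the term named. The dispersion test embeds samples by principal
coordinates keeping negative-eigenvalue axes as imaginary parts, measures
each sample's distance to its group's spatial median (Weiszfeld geometric
median; d² = d²_real − d²_imag, clamped at 0), and permutes group labels
around a one-way F. PCoA elsewhere reports raw eigenvalues without
correction.

## Differential abundance

The bias-corrected model treats each sample's unknown sampling fraction as
an offset: `log(count + 1) = d_i + α_j + β_j x_i`. Offsets and per-taxon
regressions are alternated, the offset update being each sample's median
residual across taxa, pinned to mean zero (the offset–intercept
translation invariance is otherwise unidentifiable). Because a raw median
update can cycle between tie configurations, the step is damped (halved
whenever the offset change stops shrinking) until the largest change falls
below 1e−6. This is a deliberately transparent implementation of the
bias-correction idea — iterated robust offsets before per-taxon Wald
tests — not a port of any particular released estimator; its null
behaviour and power are established by simulation in the test suite.
W = β/se with a standard-normal p, BH-adjusted; a taxon is *selected* when
q < 0.01 **and** |W| exceeds the 85th percentile of |W| within the tested
set (recomputed per analysis, before the q filter — the percentile is
relative to each analysis's own W distribution). Only taxa present in more
than 10% of samples are tested; two-level factors are coded 0/1 so
positive coefficients mean higher abundance in the second level or with a
rising covariate.

## Association layer

AICc model sets fit each candidate by OLS after centring/scaling numeric
covariates and rank by
`AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n−k−1)`, k counting the residual
variance; additive normal-likelihood constants are dropped, which leaves
ΔAICc, Akaike weights and the ΔAICc < 2 best set untouched. Two-sample
comparisons use the Welch unequal-variance form throughout (fractional
Satterthwaite df), with the zero-variance-equal-means corner returned as
t = 0, p = 1. The Scheirer–Ray–Hare test ranks the pooled response
(midranks absorb ties into the total mean square), decomposes the ranks by
a two-way ANOVA, and refers H = SS_term/MS_total to χ² on the term's df;
collapsing one factor to a single level reduces it exactly to
Kruskal–Wallis, which the tests assert. Families of tests reported with an
adjusted p use Benjamini–Hochberg, with the family label recorded in the
output — which tests share a family is an explicit analysis choice, not an
inference.

## What the generators emulate — and what they do not

*Tracks* move on the same spherical rhumb geometry the analyzer uses, so
daily beelines are exact by construction and any segmentation error is the
classifier's, not a geodesy mismatch. Migratory days draw a heading from a
wrapped normal clamped to ±80° of north and a step around 150 km/day
(floored at 45 km); stopover days wander within a few km of an anchor
roost; arrival plants a reversed-bearing short day; death appends
flatline-variance stationary days; loss truncates mid-stream. Fixes sit in
a fixed 05:00–15:00 UTC window, inside civil daylight across the simulated
April–May latitudes. Not emulated: wind and thermals, night flight, fix
dropouts, device noise, multi-year tracks — so a perfect recovery score
shows the rules are self-consistent, not that real tracks are this clean.

*Morphometrics* draw wing lengths log-normally around sex-specific means
(390/365 mm), mass allometrically (exponent 2 on logs) with residual noise
calibrated so the marginal distributions match 629 ± 77 g (females) and
518 ± 60 g (males), and subtract 2 g per Julian day of capture from the
mass residual by default — a deliberately detectable condition–date slope.

*Communities* are Dirichlet-multinomial (concentration 50 over 150 taxa):
overdispersed but not zero-inflated, the simplest count model under which
rarefaction and the diversity indices behave as assumed. Planted effects
act on log relative abundances before normalization: +1.5 on eight taxa in
males; a per-day spread multiplier `exp(−s·(date − mean))` so a negative
`s` lowers evenness (and Shannon) with capture date; −0.8 per SD of
condition on one *Escherichia-Shigella*-like taxon that owns its genus.
Contaminant taxa are planted deterministically (5 reads each) into every
negative control — making the expected output of the prevalence classifier
computable — and appear in true samples only at trace probability.
Off-target taxa exercise each taxonomy-filter rule. Depths are uniform on
14,523–76,393 reads with (by default) one sample drawn below the
10,000-read floor and six samples flagged as amplification failures, so
the default exclusion ladder is 54 − 6 − 1 = 47. With every effect at
zero the samples are exchangeable, which underwrites the type-I
calibration tests. Real 16S data differ in ways the generator ignores:
taxon–taxon correlation structure, zero inflation, variable library
composition bias, chimeras and contamination gradients.

The default pipeline configuration fixes the study design: 36 females and
18 males; 38 tagged birds = 19 arrivals + 15 deaths + 4 connection losses
(survival among tracked birds excluding losses: 19/34 ≈ 56%); 11 of the 15
deaths occur at the stopover without departing, after a capped-geometric
few-day wait, and the rest strike within the first days en route, giving
the right-skewed sub-kilometre-median death-distance pattern; adults plan
~29 migratory days against ~15 for juveniles, with later capture dates
shortening the plan — which is what makes capture date, condition and
migration distance correlated downstream.

## Problem sizes and determinism

Simulation-based checks in the tests and the acceptance script use sizes
chosen to keep the whole suite in the minutes range on one core while
leaving comfortable statistical margins: 100 seeded track scenarios for
segmentation recovery, 200 null replicates for PERMANOVA type-I (n = 12,
199 permutations each), 100 replicates each for the differential-abundance
null and power studies (32–40 samples × 60 taxa), and 50 replicates per
planted-slope recovery. Every stochastic step — generators, rarefaction,
permutation tests, the pipeline stages — is seeded explicitly; two
pipeline runs under one configuration are byte-identical, and the manifest
(seeds, configuration, per-stage row counts) suffices to reproduce any
table.

## Known limitations

Endpoint detection assumes accelerometer summaries are present for death
calls; without them only arrival/loss are distinguishable. The arrival
rule needs the lookahead window, so arrivals within `lookahead` days of
the stream's end are certified only because nothing follows; a bird that
resumes after a 6-day pause would be scored arrived. The dispersion test's
spatial medians come from an iterative solver, so distances agree with
independent implementations to ~1e−5, not machine precision. The
differential-abundance estimator shares the bias-correction *idea* but not
code lineage with released implementations; its pseudocount makes
depth-rescale invariance approximate for small counts. And the 85th-|W|
percentile rule always nominates ~15% of taxa as candidates, so selection
depends on the q-filter for its error control.
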