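---
title: "Methods: blood-meal network metrics, null models and habitat effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood-meal network metrics, null models and habitat effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodmealnets)
```

## The problem

Blood-feeding flies (mosquitoes, biting midges, tsetse, sand flies, black
flies) connect vertebrate communities through their feeding choices, and
those connections are the routes along which vector-borne pathogens move.
Molecular identification of the host species in an insect's blood meal
turns field collections into weighted bipartite networks: Diptera species
in the rows, vertebrate hosts in the columns, and the number of identified
blood meals of each fly-host pair in the cells. This package compiles such
records into per-study, per-habitat networks and asks how network
structure varies with two large-scale drivers: absolute latitude and
anthropogenic habitat modification (Agricultural, Near-natural,
Village/Urban).

## Records and taxonomic resolution

The input is one CSV row per (study, site, habitat, fly taxon, host
taxon) with a blood-meal count. Both taxa carry a rank. Records not
resolved to species level are handled with three rules, applied per side
(fly, host):

1. labels above family rank are removed;
2. a single unresolved taxon within a genus (or family) in a study keeps
   a genus-level node, labelled `"<Genus> spp."`;
3. several unresolved taxa sharing a genus within a study are collapsed
   into one genus node only when a user-supplied sympatry table says no
   congeneric (confamilial) species co-occur at that location; otherwise
   — including when the genus is missing from the table — all such rows
   are removed and the decision is logged, never silently kept.

Ambiguity is judged within a `study_id` because sympatry is a property of
the study location; the alternative (global pooling) would delete records
that are perfectly unambiguous locally. The resolution log reconciles row
counts exactly: input rows = output rows + removed rows + rows merged by
collapsing.

Networks are keyed by (study, habitat): a study that sampled several
habitat types contributes one network per habitat, and several sites of
one study in the same habitat are pooled. Studies contributing a single
Diptera species are excluded — a one-row matrix is not a network.

## Metrics

**Interaction evenness.** IE = *H* / ln *L*, where *H* is the Shannon
entropy of the link-weight proportions and *L* the number of links. IE is
1 when every link carries the same weight and low when few species pairs
dominate. Two denominator conventions exist in the literature: the number
of *realized* links (positive cells), which matches the formula as
usually printed, and the number of *all* matrix cells (rows x columns),
the default of some widely used network toolkits. Both are implemented;
`realized_links` is the default and the mode is recorded in every output
row. The two scales differ systematically (all-cells values are lower),
so comparisons across studies must fix the mode. Natural logarithms are
used throughout. A single-link network has ln 1 = 0 in the denominator;
the metric is flagged undefined rather than returning infinity.

**H2' specialisation.** H2' standardises the observed two-dimensional
entropy between the extremes achievable by any nonnegative *integer*
matrix with the observed row and column totals:
H2' = (H2max − H2) / (H2max − H2min), 0 at the random-expectation
extreme, 1 at maximal specialisation. The extrema are a discrete
optimisation problem. H2max starts from the floor of the proportional
expectation r_i c_j / m and hands the remaining units to the most
underfilled cells whose marginals still have a deficit. H2min packs the
largest remaining row total against the largest remaining column total
(three deterministic tie-break variants). Both are refined by a steepest
2x2 unit-swap search — the elementary move that preserves marginals — and,
for matrices up to 4x4, the search is additionally seeded from every
northwest-corner vertex of the transportation polytope, because entropy
minima sit at vertices and a single greedy start can strand in a local
optimum. The refinement is applied to matrices up to 400 cells (larger
networks use the unrefined fills, whose error is negligible relative to
the observed-vs-extreme spread). The tests verify the heuristics against
exhaustive enumeration of all integer matrices with the observed marginals
for shapes up to 3x3 and totals up to 12. If the observed entropy ever
escapes the heuristic interval it is clamped in, with a warning and a
flag; on the enumerable scale the tests require zero clamps. When the
marginals admit no entropy range at all (e.g. any 1 x n matrix) H2' is
returned as 0 with a degeneracy flag, and flagged networks are excluded
from the model stage, so model tables stay rectangular.

## The domestic-host removal null model

To ask whether humans and their domesticated animals (chickens, dogs,
cats, goats, cattle, horses, pigs, sheep) structure evenness, the k
domestic host columns of a network are deleted (targeted removal;
emptied fly rows are then dropped, since IE is defined over the remaining
community) and the resulting IE is compared against the distribution of
IE after deleting k hosts drawn uniformly at random from all host
species, replicated 100 times: z = (IE_targeted − mean) / sd. Random
draws are uniform over host *species*, not abundance-weighted, matching
the design being emulated. Replicates that leave fewer than two links
(IE undefined) are redrawn, up to ten times the replicate count, after
which the network is skipped. Networks are skipped — with a recorded
reason — when they contain no domestic host, when every host is domestic
(random removal would equal targeted removal), or when targeted removal
itself leaves IE undefined. When the random distribution is degenerate
(sd = 0) and the targeted value equals it, z = 0; otherwise z is flagged
undefined. Everything is reproducible from one integer seed, and each
network in a batch gets `seed + index` so results do not depend on
evaluation order.

## Rarefaction

Sampling completeness per habitat is assessed with sample-based
interpolation and extrapolation of richness at Hill order q = 0 for
incidence data. The sampling unit is one blood meal — the natural effort
axis for this data type — so the incidence frequency Y of a host or fly
taxon is the number of meals involving it, and that of an interaction is
its link weight (each meal realises exactly one interaction, so the
interaction frequencies sum to the habitat total T). Interpolation uses
the exact hypergeometric expectation S_obs − Σ C(T−Y_i, t)/C(T, t),
computed with log-binomials; extrapolation uses the Chao2 estimate of
undetected richness Q0 = ((T−1)/T) Q1²/(2Q2) (bias-corrected form when
Q2 = 0) and S_obs + Q0 (1 − (1 − Q1/(Q1 + T·Q0))^t*). Curves run on a
40-knot grid from 1 to 2T — the conventional doubling endpoint — and are
continuous at T. Confidence bands are out of scope; the curves serve the
qualitative completeness judgement only.

## The model stage

Per-network metrics are modelled with Gaussian-error GLMs:

    metric ~ habitat + |latitude| + S + log(m) + family
             + family:|latitude| + family:habitat

with S = host + fly richness and m = matrix size (total meals) included
to control for network-size effects, and each network classified by its
dominant Diptera family (the family with the most interactions;
alphabetical tie-break, flagged). Absolute latitude folds the two
hemispheres together. Term importance is judged by nested-model deviance
comparisons respecting marginality: main effects are tested among main
effects only, interactions against the full main-effects model. The
statistic reported is the raw deviance change (for a Gaussian response,
the change in residual sum of squares). Because the reference treatment
of that statistic is ambiguous across reporting conventions, three
p-values are emitted side by side: the exact Gaussian F test (the
default, and the one whose type-I error the tests calibrate), the
dispersion-scaled chi-square, and the raw-deviance chi-square. Habitat
contrasts use Tukey's HSD on model-adjusted (estimated marginal) habitat
means by default, with a raw-group-means mode available. Richness trends
with latitude are fit as `richness ~ |latitude| + meals`, the meal count
standing in for sampling effort.

## The synthetic-data generator

No compiled literature dataset ships with the package, so a generator
produces record sets with the statistical structure the analysis
assumes. Each network is drawn from a Dirichlet-multinomial hierarchy:

* a host community: the domestic hosts present carry a habitat-specific
  expected meal share (Dirichlet noise centred exactly on a conditional
  profile, so habitat aggregates are preserved in expectation), and wild
  hosts share the complement with Dirichlet concentration `dominance`;
* a preference row per fly species, Dirichlet-centred on the community
  with concentration `preference_strength` (small values give
  specialists);
* relative fly activity, Dirichlet with concentration
  `activity_concentration`; and
* one multinomial draw of the network's blood meals over the resulting
  (fly, host) cell probabilities, with at least two fly species
  guaranteed.

The default scenario emulates a compiled dataset of 47 networks
(14 Agricultural, 18 Near-natural, 15 Village/Urban), roughly 190 meals
per network, flies drawn from five families at frequencies 24:12:4:4:2,
and latitudes spanning about 34°S-60°N with no structural latitude
effect. Domestic hosts dominate Agricultural networks (cattle ~51% and
domestic hosts ~81% of meals in expectation), Village/Urban networks are
~26% human meals, and Near-natural networks carry ~52% domestic meals
spread across more species. Concentrations were calibrated once, at
design time, so the per-habitat mean interaction evenness reproduces the
qualitative pattern such compilations show — Agricultural lowest by
roughly 0.1 with within-habitat spread near 0.07 — while realized
richness S stays balanced across habitats (a deliberately larger
Agricultural wild-host pool offsets the meals absorbed by cattle), so the
habitat signal is not an artefact of network size. Latitudes are
attached with no effect on structure; a `latitude_effect` knob exists
for power experiments. A `null_scenario()` makes every habitat
statistically identical for calibration runs.

What the generator does *not* emulate: phylogenetic structure in host
choice, spatial or temporal autocorrelation among sites of a study,
method-driven detection biases of the underlying publications, and
abundance data for hosts (interactions are the only signal, as in the
data type itself). Passing tests on synthetic data therefore demonstrate
the pipeline's statistical behaviour under the assumed generative model,
not the ecological conclusions one would draw from any particular
compiled dataset.

## Numerical and design choices

* Natural logs everywhere; entropy kernels treat 0 log 0 as 0.
* Node ordering is lexicographic, so matrices and all downstream output
  are invariant to input row order.
* Degenerate metrics flag rather than error inside batch summaries, and
  flagged networks are excluded from model tables (with an exclusion
  count).
* The swap search accepts improvements above 1e-10 nats to avoid cycling
  on round-off; extrema equality with enumeration is asserted at 1e-9.
* Uniform-weight matrices return IE = 1 identically, avoiding round-off
  below 1 on the evenness boundary.
* `run_null_models()` derives per-network seeds as `seed + index`.
* Problem sizes in the test suite: enumeration fixtures up to 3x3 with
  m ≤ 12 (500 in the acceptance suite, plus module-level sets), subset
  enumeration up to T = 8, calibration at 60 networks x 500 replicates
  (type I) and the 47-network default scenario x 200 replicates (power)
  and x 100 seeds (habitat ordering).

## Known limitations

* The H2min/H2max search is exact only where verified by enumeration;
  for very large, very uneven matrices the unrefined fills could in
  principle be beaten by the observed arrangement, which is why clamping
  is logged and flagged rather than silent.
* The all-cells IE mode and the realized-links mode are not comparable;
  outputs carry the mode label so tables cannot silently mix them.
* Null-model z-scores are per network; the habitat-level summary reports
  the mean targeted-removal IE with its standard error (sd/√n), not a
  pooled z.
* The generator's domestic-host list matches labels case-insensitively
  through a small synonym map ("Bos taurus" = cattle); real compilations
  will need the user-extensible list.
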