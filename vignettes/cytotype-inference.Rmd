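---
title: "Cytotype inference from flow cytometric genome sizes: models, parameters and design choices"
author: "fcploidy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cytotype inference from flow cytometric genome sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcploidy)
```

## The problem

Mixed-ploidy plant complexes — groups of closely related plants in which
diploids coexist with several polyploid lineages — are commonly surveyed by
flow cytometry (FCM). Each plant's nuclei are co-chopped and co-stained with
an internal standard of known DNA content, and the ratio of the sample peak's
mean fluorescence to the standard peak's mean fluorescence, multiplied by the
standard's 2C-value, gives the plant's genome size (GS) in picograms. Genome
size separates ploidy levels, and often also distinguishes lineages *within*
a ploidy level ("homoploid" genome-size groups). The analysis this package
implements runs:

1. **Evaluation**: from per-particle fluorescence events to per-sample peak
   means, coefficients of variation (CV) and a genome size; analyses whose
   peak CVs reach 2.5% are discarded.
2. **Mixture modelling**: a one-dimensional Gaussian finite mixture over the
   retained genome sizes, fitted by EM, with the number of components chosen
   by comparing candidate k (by default 8 and 9) under a redundancy
   criterion.
3. **Delimitation**: mixture components become genome-size groups, anchored
   to ploidy by a small subset of chromosome-counted individuals (the
   monoploid number is x = 7, so ploidy = 2n / 7); interval boundaries
   follow two rules (below) and every individual is assigned to one group or
   left unassigned.
4. **Population structure**: per-population cytotype composition, pure
   versus mixed populations, upset-style combination counts, and a
   descriptive association between group presence and habitat class
   (natural versus anthropogenic), with a permutation diagnostic.

Because the field collections behind such a survey are not shipped with the
package, a synthetic-data generator reproduces the statistical structure the
analysis assumes, end to end, with known ground truth.

## The generative model

`simulate_events()` draws one analysis: the standard peak sits at an
arbitrary reference channel (200 by default — only the *ratio* of peak
positions is meaningful, the GS formula is scale-free), the sample peak at
`200 * GS / 3.38`, each peak Gaussian with relative SD equal to its CV.
Debris is a truncated exponential over the channels below the lower peak,
with a default debris fraction of 0.2 — a visible left shoulder, as chopped
leaf tissue produces, while leaving both peaks dominant. Doublets, G2 peaks
and spectral effects are deliberately not modelled: the evaluation pipeline
under test never uses them, so they would only add unvalidated knobs.

`simulate_study()` composes a survey: 133 populations of 15 individuals by
default, each individual's true GS drawn from `Normal(gs_mean, gs_sd)` of
its cytotype. The default eight-group panel (`default_cytotypes()`) uses the
published group means and SDs of a well-studied mixed-ploidy halophyte
complex (2x 2.587±0.036 through 7x 8.643±0.100 pg). Those SDs act as
*between-individual* spread; the configured CVs act *within* an analysis.
The panel's mixing proportions are not published, so the defaults (0.10,
0.17, 0.03, 0.03, 0.04, 0.12, 0.43, 0.08) are this package's own choice,
shaped to the qualitative field pattern — the heaviest hexaploid group
clearly prevailing, the second tetraploid and the odd ploidies rare. They
are a scenario, not a reported result.

Three further design choices deserve a note:

* **Quality failures.** 15% of analyses are generated with inflated CVs
  (3.2–5%), so the 2.5% filter has realistic work; the comparable field
  attrition in surveys of this kind is of the same order.
* **Anchors.** 39 chromosome-counted individuals are sampled uniformly
  *within* each cytotype present, allocated proportionally to group
  frequency with a minimum of three per group (one anchor cannot anchor a
  group robustly: a single boundary individual captured by the
  neighbouring mixture component would leave the group uncovered). We
  read "representative coverage" as group-coverage sampling rather than
  deliberate extreme-GS picking; the alternative is discussed under
  *Limitations* because it changes the delimitation's failure mode, not
  its failure rate. Anchors are drawn among analyses without injected
  quality failures — counting chromosomes presupposes a usable plant.
* **Habitats.** Each cytotype carries an "anthropogenic propensity"; a
  population's probability of being anthropogenic is the minimum propensity
  over the cytotypes in its mixture, so groups with propensity 0 (the
  diploid and the pentaploid, by default) never occur on anthropogenic
  sites — the qualitative pattern reported for this kind of complex.

All randomness derives from one master seed through deterministic
hierarchical splitting, so any individual's events can be re-simulated in
isolation.

## Peak evaluation

Histograms use equal-width, half-open `[low, high)` bins (256 by default).
Peak detection ranks smoothed local maxima by **topographic prominence**
(height above the highest saddle toward higher terrain): noise ripples on
the decaying debris shoulder are tall but barely prominent, so a prominence
floor (5% of the tallest bin) removes them without any debris-specific
special-casing. Windows expand from each maximum until counts fall below 2%
of the peak height or rise again after a genuine valley.

The standard peak is the detected peak nearest the configured reference
channel; the sample peak is the largest remaining peak. When only one peak
is found the sample and standard are taken to coincide — GS equal to the
standard — and the measurement is flagged, because a co-stained histogram
cannot resolve a sample whose GS matches the standard. Peak CVs use the
population-SD convention (divide by n): the in-window events are the whole
recorded peak, not a subsample. The CV filter is strict (`< 2.5`) and
applies to both peaks; the source protocol says "coefficients of variation"
without specifying which peak, and a noisy standard corrupts the ratio
exactly as a noisy sample does, so both is the defensible reading.

## Mixture fitting and model choice

`fit_gmm()` maximises the mixture likelihood by EM (compiled inner loop;
convergence when the absolute log-likelihood change falls below 1e-8, with
an iteration cap of 1e6). Component SDs are floored at 1e-4 pg — instrument
CVs bound real peak dispersion well away from zero, and the floor prevents
the classic one-point-spike degeneracy.

Initialisation matters more than anything else in 1D mixtures. The
canonical fit (`n_restarts = 1`) is deterministic: component means start
at the k strongest modes of a narrow-bandwidth kernel density estimate
(`bw = sd/30`), where modes are picked greedily by the probability mass
they carry, with a minimum separation of four bandwidths and a 1% mass
floor; each starting component takes the local SD and mass of the data
around its mode, so sparse components are not dragged off their clusters
by heavy neighbours in the first iterations. Mass-ranking keeps genuinely
sparse groups ahead of shot-noise ripples riding on dense clusters. When
the density shows fewer than k modes the surplus components are seeded
*co-located* on existing modes; since it is not knowable from the density
alone which mode hides substructure, one variant per candidate site is
run briefly and the two most promising are continued to convergence.
Co-located seeding is the point: an over-specified k then converges to a
vestigial or duplicated component — which the redundancy test can
recognise — rather than to an arbitrary re-partition of an overlap
region. With `n_restarts > 1` (the pipeline's default for its candidate
fits), k-means, quantile and random-point starts join the portfolio and
every start runs to full convergence, the best likelihood winning — a
thorough mode that markedly stabilises fits when group prevalences are
very unequal.

`redundancy_test()` flags a component as adding no interpretable structure
when (i) its weight is below 2% — a fitted "group" of a handful of
individuals; (ii) its 1st–99th percentile interval lies wholly inside
another component's interval *and* its centre sits within that component's
SD (a duplicated-centre fit); or (iii) its density overlap with a heavier
component exceeds 0.4 on the Bhattacharyya coefficient scale. The 0.4
threshold sits well above the most overlapping pair of genuinely distinct
genome-size groups in the default panel (the two tetraploid groups against
the pentaploid reach ≈ 0.28) and well below the near-total overlap of split
fits (≥ 0.45 in practice). `select_model()` then keeps the largest k whose
fit has no redundant component, reporting AIC/BIC as diagnostics only; if
every candidate is flagged it falls back to the smallest k with a warning.

## Delimitation

Each component's provisional interval is its 1st–99th percentile range
(`qnorm` closed form). For adjacent groups of *different* ploidy whose
intervals overlap, the boundary is instead set by the chromosome-counted
individuals: the lower group reaches up to the highest anchored GS of its
ploidy, the upper group down to the lowest anchored GS of its ploidy, and
the zone between (if any) is no-man's-land. Adjacent groups of the *same*
ploidy keep their percentile edges; their shared zone makes membership
ambiguous. The outermost edges are unbounded by default (boundaries are
defined only *between* groups); `bounded_tails = TRUE` restores percentile
tails. Intervals are half-open `[low, high)`, except that an anchor-derived
upper edge includes the anchor itself — the counted individual that defines
a boundary belongs to its own group, not to limbo.

When the selected model contains a redundant component that captured no
chromosome-counted anchor — typically a vestigial twin of a real group —
the pipeline drops it before delimitation rather than aborting: it
duplicates structure another component carries and cannot be anchored.
A component without anchors that is *not* redundant still aborts the
run; it flags a real group that needs chromosome counts.

Assignment is purely interval-based: a sample in exactly one interval gets
that label; in zero or two or more, `UNASSIGNED` with a rationale. We
deliberately do not fall back to max-posterior assignment in ambiguous
zones — the conservative reading keeps the delimitation auditable.
Component-to-ploidy mapping takes the *majority* ploidy of each component's
anchors, surfacing minority anchors with a warning: at realistic overlaps a
boundary anchor is occasionally captured by the neighbouring component, and
treating that as fatal would make the method unusable on exactly the data
it is designed for. An exact tie remains an error. Chromosome counts not
divisible by x = 7 are rejected as putative aneuploids.

## Population structure

`summarize_populations()` counts groups per population; `UNASSIGNED`
individuals are excluded from the group set but reported, so "mixed" means
two or more *delimited* groups. `intersection_counts()` is the tabular
upset plot: one row per observed group combination, split by habitat.
`habitat_association()` adds a permutation diagnostic (habitat labels
shuffled across populations, 10^4 permutations by default, seeded,
two-sided p via the add-one estimator). The underlying survey reports no
formal habitat test; the permutation test is this package's diagnostic and
is labelled as such. Because the statistic (count of anthropogenic
populations containing a group) is discrete, the permutation p-values are
super-uniform — conservative — under the null; the test suite therefore
checks one-sided type-I control rather than exact uniformity.

## Problem sizes and what the tests show

The validation suite runs on synthetic studies of 40–80 populations
(600–1200 individuals, 1200–3500 particles per analysis) and on direct
genome-size draws of n = 1200 from the eight-group panel — the scale at
which all eight groups are identifiable and fits complete in seconds.
Parameter recovery holds to within three Monte-Carlo standard errors (the
empirical across-replicate SD of each fitted mean; the plug-in
`sd/sqrt(n*w)` under-covers for overlapping components, which lose
information to mixing). Model choice between k = 8 and k = 9 lands on 8 in
19–20 of 20 replicates under both balanced and field-like weights.

What passing tests do *not* show: the generator draws clean Gaussian peaks
with independent events; real histograms carry doublets, G2 peaks,
tissue-dependent debris and day effects, and real GS groups need not be
Gaussian. Recovery rates here are therefore an upper bound on what the same
pipeline achieves on field data.

## Known limitations

* **Unassigned mass is structural.** With the published group parameters,
  the delimitation rules themselves leave boundary mass unlabelled: the
  homoploid percentile rule creates ambiguous zones among the three
  hexaploid groups (≈ 4–5% of individuals under the default prevalences),
  and the heteroploid anchor rule creates gaps whose width depends on
  anchor density — with 39 anchors allocated proportionally, rare groups
  get one or two anchors whose extremes sit ~0.5 SD from the group centre.
  End to end, ≈ 84–89% of QC-passed individuals receive their generating
  label while ≈ 99% of *assigned* individuals do; the shortfall is almost
  entirely unassignment, not mislabelling. Sampling anchors at the group
  extremes instead does not fix this: it converts gaps into
  ambiguous-overlap zones of similar mass. Users who need every individual
  labelled should treat `UNASSIGNED` as "needs a chromosome count", which
  is what the conservative rule intends.
* **Sample/standard overlap.** A sample whose GS is near the standard's
  2C-value cannot be evaluated from a co-stained histogram; such analyses
  are flagged, not resolved. Choose a standard away from the expected GS
  range.
* **The redundancy thresholds** (2% weight, 0.4 Bhattacharyya) are
  calibrated to genome-size-group separations of the default panel's order;
  complexes with much tighter homoploid structure may need them revisited,
  and both are arguments.
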