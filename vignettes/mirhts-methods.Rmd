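---
title: "Models and methods behind mirhts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirhts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mirhts implements the computational skeleton of a gain-of-function pooled
lentiviral microRNA (miR) screen and its validation arithmetic: candidate
calling from multi-timepoint dropout data, selection-coefficient estimation
from GFP competition assays, absolute and relative qPCR quantitation, a
multi-source target-prioritization filter with a 3'UTR seed-site scanner,
and the normalization formulas of the downstream validation assays. Every
stage can be exercised on synthetic data whose generative model matches the
assumptions the analysis makes, so the whole pipeline is testable without
any external download.

This vignette records the models, the defaults and why they were chosen,
and what the synthetic generators do and do not emulate.

## The pooled dropout screen

### Generative model

`simulate_screen()` draws one detection table per replicate screen under
four mechanisms:

1. **Transduction.** Each of the `n_cells_infected` cells receives a
   Poisson(MOI) number of viral integrations; a cell is transduced if it
   receives at least one. The expected transduced fraction is therefore
   `1 - exp(-MOI)` (25.9% at the default MOI of 0.3). The commonly quoted
   "~30% at MOI 0.3" is the linear small-MOI approximation of the same
   model; the Poisson value is what the simulator uses and it is recorded in
   the dataset's `truth` metadata. Transduced founder cells are assigned to
   the 578 library constructs multinomially according to the library
   representation.
2. **Growth.** Each clone grows deterministically and exponentially: a
   construct with per-day relative fitness `w` contributes `n0 * w^t` cells
   at day `t`, and untransduced cells grow at `w = 1`. Keeping growth
   deterministic (stochasticity enters only through transduction and
   sampling) is the simplest model that reproduces dropout kinetics; genetic
   drift within a multi-hundred-thousand-cell culture is negligible at these
   population sizes.
3. **Sampling.** At each timepoint (days 4, 12, 20, 28 by default) 2e6
   cells are drawn multinomially from the culture; a construct's template
   copy number is its sampled cell count, assuming one scorable integration
   per transduced cell.
4. **Detection.** qPCR detection of a construct succeeds with probability
   logistic in `log10(copies)`, centered at `dropout_floor` with slope 4
   per decade. This models the "Monte Carlo effect": when template copies
   per reaction are low, amplification becomes sporadic, so a construct can
   be detected at one timepoint and missed at another without any real
   abundance change. Published descriptions of this failure mode are
   qualitative, so the floor and slope are explicit parameters; the default
   floor of 50 copies is a realistic order of magnitude for nested PCR off
   a genomic DNA sample, low enough that a healthy neutral construct
   (hundreds of sampled cells) is detected essentially always, and the
   slope of 4/decade makes detection collapse within roughly one decade
   around the floor. Setting `dropout_floor = 0` gives deterministic
   detection of any positive copy number.

Library representation defaults to uniform. Real pooled libraries are
somewhat skewed, and the uniformity of the original library is not public;
`representation = "lognormal"` adds a configurable log-normal skew for
robustness experiments.

### Candidate calling

The original screen's selection statistic lives in a prior publication and
is not restated in the source this package accompanies, so `call_depleted()`
defines an explicit, reproducible ratio rule with the same qualitative
behavior: a construct must be detected at the reference timepoint (day 4),
and its abundance must fall to `depletion_ratio` (default 0.5) times its
reference abundance, inclusively, at `min_later_tps` (default 2) or more
later timepoints. Non-detection counts as abundance zero. Constructs
undetected even at the reference timepoint are not callable by the ratio
rule; `rescue_never_detected()` flags them as candidates when the same
library detected them at the reference timepoint in another screened cell
line — complete absence despite confirmed representation is consistent with
very strong growth inhibition (it can also reflect failed transduction,
which is why such candidates still require validation). Consensus requires
a call in at least `min_screens = 2` of the replicate screens.

`validation_rate()` is deliberately dumb bookkeeping —
`100 * validated / (validated + not_validated)` over consensus candidates —
because that is how screen validation rates are reported.

On the package's reference scenario (`planted_screen_scenario()`: five
constructs planted at fitness 0.85/day among 573 neutral ones), the test
suite asserts consensus recall at least 0.8 and a neutral false-positive
rate at most 0.05 at a fixed seed; a planted fitness of 0.85/day shrinks a
clone to about 2% of its reference share by the last timepoint, so recall is
in practice driven by detection at the reference timepoint. Raising the
dropout floor toward the typical per-construct copy number inflates false
candidates in an all-neutral screen, which the suite also asserts — the
direction, not a magnitude, because the magnitude depends on the floor and
slope chosen.

## GFP competition fitness

Two populations growing exponentially at per-day log-fitness difference `s`
give a GFP+ fraction

    p_t = p0 * exp(s t) / (p0 * exp(s t) + 1 - p0),

which is exactly linear on the logit scale:
`logit(p_t) = logit(p0) + s t`. `fit_selection()` therefore runs ordinary
least squares of `logit(p)` on day; the slope is `s` and the intercept
recovers `p0`. The model is chosen for this exact linearity — raw-percentage
plots of the same assay are curved, and fitting them directly would weight
points unevenly.

Observed fractions of 0 or 1 (possible with finite flow-event counts) are
clamped to `[pseudo, 1 - pseudo]` before the logit; `pseudo` defaults to
`1/(2 * events_per_measurement)` — half a count — matching the resolution of
the measurement. Weekly sampling over 35 days is the default grid; any
non-degenerate day grid works.

`classify_inhibitory()` calls a construct growth-inhibitory when the
one-sided upper `1 - alpha` confidence bound of `s` lies below a threshold
(defaults: `alpha = 0.05`, threshold 0). Published competition assays of
this kind are typically read by eye ("no change over 35 days"); the CI rule
is a reproducible substitute that makes the underpowered case explicit: a
negative point estimate with a wide interval is *not* called inhibitory.

The estimator is consistent and nearly unbiased under the generator: the
suite checks that the mean of 200 estimates per true `s` in
{-0.06, -0.03, 0} (10^4 events/point, 6 weekly points) is within 0.002/day
of truth, and that a single series recovers `s = -0.05` within 0.005/day.
For orientation, a decline from 46% to 10% GFP+ over 35 days corresponds to
`s = (logit(0.10) - logit(0.46)) / 35 = -0.0582` per day.

## qPCR quantitation

The standard-curve model is `Ct = intercept + slope * log10(copies)`, with
amplification efficiency `10^(-1/slope) - 1` (slope -3.3219 is perfect
doubling). `fit_standard_curve()` requires at least three points spanning at
least two decades and refuses degenerate (constant-Ct) input; a warning is
raised when the implied efficiency leaves (0, 1.2].

Absolute quantitation inverts the line (`ct_to_copies()`) and divides by
the cell equivalents of the RNA input (`cell_equivalents()`: at 12.5 pg
total RNA per cell, a 10 ng input represents 800 cells). Absolute estimates
are only trusted within the curve's calibrated range: `below_detection()`
flags undetermined Cts and Cts implying fewer copies than the lowest
standard (the default limit of detection, exposed as a parameter because
fixed-copy rules are also in use).

Relative quantitation caps Cts at 35 first (`cap_ct()`; undetermined
reactions are assigned the cap, a documented extension of the same rule)
and then applies either the ΔΔCt fold change
`2^-((target - control) - (ref_target - ref_control))` or the within-sample
ratio `2^-(target - control)`. Capping applies to relative quantitation
only; absolute quantitation reports below-detection instead. Fold changes
use base 2 and curves base 10, per field convention. Replicate Cts are
averaged arithmetically before the formulas.

The end-to-end test simulates plates from known truths of 1,814 and 3,656
copies/cell (three independent single-well measurements, 0.1-cycle Ct
noise, a 7-point standard curve refit from simulated standards) and
requires recovery within 10%; with these settings the curve-fit error, not
the sample wells, dominates the residual spread.

## Target prioritization

`build_sets()` forms the three gene sets of the filter: Set 1, predicted
targets (either prediction source) of the hit miRs; Set 2, predicted targets
of the tested non-inhibitory miRs; Set 3, genes whose expression call in the
screened cell line is "marginal" or "present" (inclusive of marginal,
exactly as the calls are defined). A tested miR whose overexpression could
not be confirmed must simply be left out of the non-hit list — its targets
are then not excluded. `filter_targets()` is pure set algebra:
`(Set1 ∩ Set3) \ Set2`.

`annotate_and_shortlist()` models the manual curation step as a declarative
input: an annotation table of `growth_related` and literature flags. The
pipeline makes no claim to reproduce curation — it joins against whatever
table the user supplies. Within growth-related genes, the shortlist flags
genes that are literature-linked to leukemia/oncogenesis or predicted by
*both* sources for at least one hit miR, and ranks flagged genes by
strongest predictorA score (ascending, more negative = stronger), ties by
predictorB score (descending), then alphabetically. Score semantics follow
the two database conventions (context-type scores vs 0-100 target scores);
the scores are consumed, never recomputed.

Gene symbols are matched case-insensitively with an optional alias map,
because cross-database joins of this kind are symbol-based and symbol drift
is the main failure mode.

The synthetic universe (`simulate_prediction_universe()`) plants true
targets so that they are guaranteed to survive the filter, and populates
every other Venn region with decoys at configurable rates. The default
rates (30% hit-predicted, 40% non-hit-predicted, 60% expressed, 20%
growth-related, 5% literature-flagged, 30% both-source) were chosen once so
that every region is non-empty and the funnel of stage sizes strictly
decreases, mimicking the shape of a real prioritization (hundreds of
predictions, dozens growth-related, a handful shortlisted). Published stage
counts of any particular study are database-version-dependent and are not
asserted anywhere.

### Seed-site scanning

`find_seed_sites()` scans the UTR sense strand for Watson-Crick matches to
the miR seed (positions 2-7, 5'→3'), then classifies each locus by its
flanks: pairing to miR position 8 plus an A opposite miR position 1 is an
`8mer-A1`; position-8 pairing alone a `7mer-m8`; the A1 adenine alone a
`7mer-A1`. The longest class wins at a locus and bare 6mers are not
reported. Two conventions matter and are fixed here: coordinates are
1-based inclusive on the UTR (so a 7mer spans e.g. 66-72 and an 8mer
759-766), and the A1 position must be an adenine on the UTR regardless of
the miR's first base — it is recognized by Argonaute, not paired. Ambiguous
bases never match and raise a warning. miR sequences are always inputs;
the package hard-codes none.

`plant_utr_sites()` builds test UTRs: a random background is first scrubbed
of every seed-core occurrence (all three site classes contain the 6-nt
core, so a core-free background carries no spurious site), sites are then
written at the requested positions, flanking bases that would silently
upgrade a planted 7mer to an 8mer are repaired, and the result is verified
by a rescan. `apply_site_deletion()` excises a site's span, emulating
deletion reporter constructs: deleting one of two sites leaves exactly the
other (shifted when downstream), deleting both leaves none.

## Validation-assay arithmetic

All of these are small normalization formulas with explicit conventions:

- `relative_luciferase()`: firefly/renilla per well, then mean of
  well-level ratios (not ratio of means — the per-well ratio is the
  transfection-normalized observable), mimic group over construct-only
  group.
- `growth_fold()`: blank-subtracted ratio of mean readouts; blank
  subtraction defaults to 0 and is exposed because protocols differ.
- `quadrant_frequencies()` and `cell_cycle_fractions()`: fixed-threshold
  gating of event tables (subG1 below the 2N window; S = BrdU+; G0/G1 =
  BrdU- within 2N; G2/M = BrdU- above it). Fractions are of all events in
  the supplied table; any viability pre-gate is assumed applied upstream,
  and no automated gating is attempted. Fractions sum to 1 exactly.
- `densitometry_relative()`: band over loading control, relative to the
  reference lane.
- `rescue_effect()`: percent growth gain of miR + ORF over miR + empty
  vector, alongside the deficit of miR + empty vector versus the
  double-empty-vector baseline.

Every one of these is invariant to global multiplicative instrument gain,
and the suite asserts it.

## Reproducibility, sizes and limits

All generators take explicit integer seeds and are bit-reproducible under
them; `run_pipeline()` fans one global seed out deterministically to
per-stage seeds and records the seed, the full config echo and the md5 of
every artifact in its manifest, so identical config and seed give
byte-identical outputs. Interchange is header-checked TSV (schema violations
are reported with column names and line numbers), FASTA for sequences
(via Biostrings) and JSON for summaries.

The test suite runs the full library size where it matters (578 constructs,
2e6 sampled cells) because the multinomial simulations are cheap; the
heavier property suites use 100 random filter universes, 1,000 random
scanner sequences and 600 simulated competition series, which keeps the
whole suite under a minute on one core.

What the synthetic data does *not* emulate, and hence what green tests do
not establish about real screens: PCR amplification bias and primer-specific
efficiency differences across constructs; integration-site effects and
multiple integrations per cell (MOI 2 validation conditions violate the
single-integration reading of template copies); culture bottlenecks and
drift between sampling days; miR expression heterogeneity within a clone;
and any property of real prediction databases beyond their table schema.
The filter reproduces set algebra over its inputs, not the biology of the
inputs themselves.
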