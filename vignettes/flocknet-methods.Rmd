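---
title: "Methods: inferring and testing foraging social networks from RFID streams"
author: "flocknet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring and testing foraging social networks from RFID streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flocknet)
```

## The problem

Automated feeders fitted with RFID antennae log every visit of a
PIT-tagged bird as a `(tag, time, location)` record. When the feeder's
access flap is driven by a programmable controller, *rules* can be
imposed on who may feed where — for instance, granting one feeder of a
pair only to birds whose tag ends in an odd digit and its twin only to
even-tagged birds. Splitting a wintering songbird population this way for
a period, bracketed by unrestricted periods, turns tag parity into a
randomised treatment: any parity structure appearing in the association
network is caused by the imposed constraint, and any parity structure in
*unmanipulated* contexts (ephemeral food patches, nest-box prospecting)
measures carry-over between social contexts.

`flocknet` implements the full inference chain for such an experiment —
event detection, network construction, assortment testing, and
cross-context consistency analysis — together with a synthetic-data
module that simulates the whole design, so that every stage can be
validated against ground truth without access to field data.

## Gathering-event detection

Feeder detections arrive in bursts as flocks come in to feed. For each
location and day, `segment_stream()` fits a one-dimensional Gaussian
mixture to the detection timestamps and assigns every detection to its
maximum-responsibility component; each component is a *gathering event*,
the sampling unit for associations. Choices that matter:

* **Per location-day fitting.** Fitting each location-day slice bounds
  the number of components, keeps every fit small, and makes the
  partition reproducible and parallel in structure. Days are half-open
  `[d·86400, (d+1)·86400)` windows in seconds from scenario start.
* **Model selection.** The number of components is chosen by BIC over
  `1..max_components_per_day` (default 50), using `mclust`'s
  deterministic model-based hierarchical initialisation. A
  variational-style alternative (`model_selection = "prune"`) fits the
  largest supported mixture once and keeps the components that receive
  detections.
* **Ties and merging.** Components are ordered by mean so responsibility
  ties break towards the earlier event; components whose assigned time
  spans overlap by more than `merge_overlap_threshold` (default 0.25 of
  the shorter span) are merged, since heavily overlapping components
  describe one gathering.
* **Membership.** Repeated reads of a tag within an event all inform the
  fit but count once for membership. Events below
  `min_event_detections` are discarded.

Nest-boxes are different: only a couple of birds prospect a given box
per day, landing repeatedly over hours. `daily_nestbox_groups()`
therefore defines one event per box per calendar day, with the distinct
visitors as members.

## Association networks

Events become a binary group-by-individual (GBI) matrix
(`events_to_gbi()`), and `hwi()` converts it to a weighted network using
the half-weight index. For a dyad with `x` joint events and `nA`, `nB`
events per individual,

$$\mathrm{HWI} = \frac{x}{x + (y_A + y_B)/2} = \frac{2x}{n_A + n_B},$$

which lies in `[0, 1]` and corrects for unequal observability. Because
each gathering event is its own sampling unit, the general index's
"both seen but apart in the same sample" term is zero by construction.
Individuals with no events in a window are dropped from that window's
roster rather than kept as isolates, matching the convention that matrix
comparisons include only individuals observed in both matrices
(`align_common()`). Rosters are ordered lexicographically everywhere so
outputs are stable.

## Assortment by tag parity

`assortativity_weighted()` computes the weighted discrete assortativity
coefficient from the mixing matrix `e` (fraction of total edge weight
joining each ordered pair of types, marginals `a_i`):

$$r = \frac{\sum_i e_{ii} - \sum_i a_i^2}{1 - \sum_i a_i^2}.$$

A perfectly segregated network scores exactly 1; a network whose edge
weight all lies within one type leaves `r` undefined and returns `NA`,
which is excluded from summaries. The standard error is a jackknife over
nonzero dyads, `se² = Σ_m (r₍₋ₘ₎ − r)²`, each `r₍₋ₘ₎` recomputed with
one dyad's weight zeroed.

Since dyadic observations are not independent, significance comes from
**node permutations**: shuffling node types (equivalently, jointly
permuting rows and columns) preserves the association pattern, each
node's weighted degree, and the type counts. The p-value uses the
add-one Monte-Carlo estimator `(1 + #extreme)/(1 + n_perm)` — never
exactly zero — two-tailed on `|r|` by default with a one-tailed
(`greater`) option for directional "is it assorted" questions. The 95%
null range is reported as empirical 2.5/97.5 percentiles with linear
interpolation.

## Matrix comparisons

`mantel_test()` correlates strictly-lower-triangle entries of two
aligned matrices, with significance from joint row/column permutations
of the second matrix. The 95% range is an *individual-level bootstrap*:
rows/columns are resampled jointly, dyads formed by two copies of the
same individual are excluded, and percentile limits are taken over the
resampled correlations. (A bootstrap interpretation is one of several
reasonable constructions for an interval on a Mantel statistic; it is
documented here as the package's choice.)

`mrqap_dsp()` regresses a dependent matrix on several predictors by OLS
on the lower triangles (intercept included, coefficients
unstandardised). Per-predictor p-values follow double semi-partialing:
predictor `j` is residualised on the remaining predictors, the residual
*matrix* is row/column permuted, the full model is refitted with the
permuted residual in `j`'s place, and the refitted raw coefficient forms
the null. Raw-coefficient nulls (rather than pivotal statistics) are
used. Collinear predictor sets are rejected by name; missing dyads are
not supported because alignment guarantees complete matrices.

In the pipeline, the dependent matrix is a context network (patches or
nest-boxes), and the predictors are (i) the feeder association network
and (ii) a binary spatial range-overlap matrix scoring 1 for dyads that
used at least one common feeder *site* in the reference window (the two
parity feeders of a pair collapse onto their parent site). This
separates fine-scale social association from mere spatial co-occurrence.

## The synthetic experiment

`scenario_config()` defaults describe the emulated design: 339 tagged
individuals, 6 feeder sites, 40/90/6-day pre/during/post periods,
bursty visitation (~82 events per site-day, mean flock 3.8, mean event
duration 191 s), four ephemeral patches per deployment, and nest-boxes
receiving on average 1.7 distinct visitors per box-day. During the
manipulation each site splits into an odd- and an even-restricted feeder
sharing the site's event rate; birds of the mismatched parity still
approach at relative propensity `denied_visit_rate` (0.1) and are logged
with `access_granted = FALSE`. Denied reads are *included* in network
construction by default — the antennae record all visits and the birds
were present — with `include_denied_visits = FALSE` available.

The social mechanism is a latent preference matrix `P`, zero at start:

* **Learning.** At the end of each day, `P` is blended towards the
  day's granted feeder co-memberships (row-normalised, symmetrised) at
  rate 0.8. The memory is deliberately *short* (half-life well under a
  day): these are fission–fusion flocks whose composition is fluid, so
  associations largely reflect recent co-foraging. This is what lets the
  network recover within days once the restriction is lifted.
* **Feeder recruitment.** Flocks build by sequential recruitment from
  the site's pool, each candidate weighted by
  `Π (1 + strength · P[cand, recruited])` with `strength = 5` — a mild
  partner bias on top of availability.
* **Context parties.** Birds reach an ephemeral patch, or land on a
  nest-box entrance, in small parties of current associates
  (co-travel): recruitment is *proportional* to preference towards the
  members already present plus a small baseline (0.06) for unaffiliated
  joiners. This is why structure imposed at the feeders is expressed at
  contexts where no rule applies — and why it disappears there within
  days of the restriction ending. Context parties sample the preference
  state of the *same day's* foraging.
* **Range drift.** Each bird shifts one home site to a neighbouring
  site with probability 0.08 per day. This slow drift makes networks
  closer in time more similar, producing the gradual, monotone approach
  of the windowed networks towards the post-treatment structure.

Child random streams are derived from the root seed with fixed offsets
per period and context, so adding a context never perturbs another's
draws, and identical configurations yield byte-identical streams.

What the generator does **not** emulate: explicit movement between
detections, species differences, immigration/emigration, weather-driven
activity, or feeder hardware failure. Passing tests therefore show that
the inference chain recovers imposed structure from data with realistic
sampling properties — not that every property of field data is captured.

## Validation scales

The test suite validates the chain at reduced scale so that a full run
stays light: the main recovery scenario uses 100 individuals,
10/20/6-day periods, ~25 events per site-day, and 1000 permutations;
the windowed-consistency check uses 60 individuals over 20 replicate
seeds; calibration of test size uses 500 label-randomised replicates.
Enumeration oracles (all GBIs at N ≤ 4, all 120 node permutations at
n = 5) anchor the index, the assortativity coefficient, the MRQAP OLS
and the Mantel null exactly.

## Known limitations

* Only the half-weight index is provided (no simple-ratio variant), and
  no temporal decay weighting within windows.
* Consistency windows are anchored at period boundaries; calendar-week
  anchoring would shift window contents slightly.
* The Mantel interval is a bootstrap construction, not an exact
  interval; with few common individuals it can be wide or undefined.
* Mixture segmentation assumes bursts are separated in time at one
  location; co-located simultaneous flocks are merged into one event.
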