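# flocknet

Inference and hypothesis testing for wild-bird foraging social networks
built from RFID detection streams — with a built-in simulator of a
selective-feeder field experiment that imposes social segregation by
PIT-tag parity.

## The problem

Feeding stations fitted with RFID antennae log every visit of a
PIT-tagged bird. With programmable access flaps, feeders can *impose*
rules on who may forage where: during a manipulation period each feeder
pair grants one feeder to birds whose tag ends in an odd digit and the
other to even-tagged birds, splitting the population into two random
halves. Comparing association networks before, during and after the
manipulation — and at unmanipulated contexts (ephemeral food patches,
nest-box prospecting) — asks three questions:

1. Does the imposed constraint create assortment by tag parity?
2. Does that assortment *carry over* into contexts with no access rules,
   and is the carry-over social rather than merely spatial?
3. Does the network recover once the constraint is lifted?

`flocknet` implements the full inference chain used for such
experiments, for behavioural ecologists working with spatio-temporal
detection streams:

* **Gathering-event detection** — a 1-D Gaussian mixture over detection
  times per location-day (`segment_stream()`, via `mclust`, BIC model
  selection); daily grouping for nest-boxes (`daily_nestbox_groups()`).
* **Association networks** — group-by-individual matrices
  (`events_to_gbi()`) and the half-weight index
  `HWI = x / (x + (y_A + y_B)/2)` (`hwi()`), time-windowed networks
  (`window_networks()`), binary spatial range-overlap matrices
  (`spatial_overlap()`).
* **Assortment** — weighted discrete assortativity
  `r = (Σᵢ eᵢᵢ − Σᵢ aᵢ²) / (1 − Σᵢ aᵢ²)` from the mixing matrix,
  jackknife SE, and node-permutation nulls
  (`assortativity_weighted()`, `jackknife_se()`,
  `node_permutation_null()`).
* **Matrix comparisons** — Mantel tests with permutation p and
  individual-bootstrap 95% ranges (`mantel_test()`), and MRQAP with
  double semi-partialing (`mrqap_dsp()`).
* **Synthetic experiment** — `scenario_config()` /
  `simulate_experiment()` simulate the three-period design with ground
  truth: preference-driven flock recruitment, parity-restricted feeders,
  denied-visit records, patch deployments and nest-box recording.
* **Pipeline** — `run_full_analysis()` produces the assortment table,
  windowed consistency curves, and cross-context Mantel/MRQAP
  comparison tables; `flocknet_cli()` exposes it all as a command-line
  tool (`simulate`, `detect-groups`, `build-networks`, `assort`,
  `compare`, `run-all`).

## Worked example

Simulate a reduced-scale experiment (100 birds, 10/20/6-day periods)
and run the whole analysis:

```r
library(flocknet)
run <- simulate_experiment(demo_config(rng_seed = 1))
ana <- run_full_analysis(run, analysis_plan(n_perm = 1000, seed = 1))
print(ana)
```

```
Assortment by tag parity (node-permutation null):
          context period        r     se null_lo null_hi        p n_nodes
 selective_feeder    pre -0.00944 0.0227 -0.0359  0.0256 0.702000     100
 selective_feeder during  0.70100 0.0119 -0.0466  0.0394 0.000999     100
 selective_feeder   post  0.01480 0.0277 -0.0451  0.0458 0.606000     100
  ephemeral_patch    pre  0.00883 0.0389 -0.0687  0.0388 0.819000      62
  ephemeral_patch during  0.11600 0.0337 -0.0613  0.0486 0.000999      93
         nest_box during  0.26600 0.0485 -0.1120  0.0849 0.000999      99
         nest_box   post -0.01030 0.0622 -0.1240  0.1080 0.869000      97
```

Reading the table: at the feeders, assortment by tag parity appears
*only* while the restriction is active (`r = 0.70`, far above the
permutation null's 95% range) and vanishes within days of the feeders
reopening (`r = 0.015`, p = 0.61). The imposed segregation carries over
into the contexts with no access rules — patches (`r = 0.116`) and
nest-boxes (`r = 0.266`) are significantly assorted during the
manipulation only. The MRQAP rows of the comparison table separate the
two candidate explanations for that carry-over: the feeder *social*
network predicts the patch and nest-box networks about 5–10× more
strongly than binary spatial range overlap does
(e.g. `social_coeff = 0.158` vs `spatial_coeff = 0.029` for the
during-period patches), so the carry-over is social, not just shared
space. `ana$consistency` holds the windowed Mantel curves showing the
during-period network gradually and monotonically approaching its
post-treatment structure.

The same analysis from a shell:

```sh
Rscript inst/exec/flocknet run-all \
  --config inst/extdata/demo_scenario.json --out-dir out --seed 1
```

Every output file gets a JSON provenance sidecar (inputs, parameters,
seed, package version).

## Documentation

The methods vignette (`vignettes/flocknet-methods.Rmd`) describes the
models, the synthetic generator's mechanisms and defaults, numerical
choices, and known limitations.
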