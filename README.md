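# shiftstate

Which conformational state of a membrane protein does a solid-state NMR
sample actually contain? When candidate structures differ only subtly — say
a partially open (PO) versus a fully open (FO) ion-channel gate — absolute
chemical-shift predictions from MD ensembles are too noisy to decide.
`shiftstate` implements a statistical pipeline that decides anyway, by

1. modelling each nucleus's ensemble of predicted chemical shifts with a
   Bayesian **skew-normal** likelihood,
2. keeping only nuclei whose candidate-state ensembles are statistically
   distinguishable (credible-interval and effect-size filters), and
3. comparing **difference shifts** — simulation against a closed reference
   state, experiment against a deactivated condition — so that systematic
   prediction and referencing errors cancel.

It is aimed at structural-biology groups combining SSNMR assignments with
MD trajectories and per-snapshot shift predictors such as SPARTA+ or
SHIFTX2.

## The model

For one nucleus, one simulated state and one prediction method, the
predicted shifts *d* are modelled as

    L(d | mu, sigma, alpha) = (2 / sigma) * phi((d - mu)/sigma)
                              * Phi(alpha * (d - mu)/sigma)

with phi/Phi the standard normal pdf/cdf, and priors
`mu ~ Normal(mean(d), 10 ppm)`, `sigma ~ half-Cauchy(10 ppm)`,
`alpha ~ Normal(0, 10)`. The scientific quantity is the **distribution
mean**

    CS_sim = mu + sigma * sqrt(2/pi) * alpha / sqrt(1 + alpha^2),

the predicted NMR peak position, summarized by the 94% highest-density
interval of its posterior. Two candidate states are distinguishable at a
nucleus when the difference-in-means interval center exceeds the
experimental tolerance (0.2 ppm for C/CA/CB, 0.5 ppm for N) **and** the
effect size `(CS_FO - CS_PO) / sqrt((var_FO + var_PO)/2)` exceeds 0.5 in
absolute value. For each surviving nucleus the discrepancies

    ddCS^X = (CS_sim^X - CS_sim^Closed) - (CS_exp^act - CS_exp^deact)

are compared for X = PO, FO; the state with the smaller |ddCS| center is
the verdict. A flowchart classifier additionally sorts every assigned
nucleus into marker classes A, B1/B2, C1/C2, D1/D2, E1/E2 from the three
pairwise state distinguishabilities and the experimental marker status.

## Worked example

A synthetic panel with known ground truth: 20 nuclei whose three simulated
states are mutually separated by 3.5 tolerances, with the experimental
table generated from the PO state.

```r
library(shiftstate)
sc    <- preset_scenario("e2_panel", seed = 1)
preds <- sample_scenario(sc)            # per-snapshot predicted shifts
exps  <- make_experimental_tables(sc)   # activated + deactivated table
run   <- run_pipeline(preds, exps,
                      sampler = sampler_config(iter = 500, warmup = 500),
                      seed = 1)
print(run)
```

```
Chemical-shift state-assignment run
  eligible nuclei:       20
  fits (nucleus x state x method): 60
  discriminating (PO vs FO): 20
  nucleus-level tally:   PO 100%, FO 0%, undetermined 0%
  residue-level tally:   PO 100%, FO 0%, undetermined 0%
  classes:  E2:20
```

All 20 nuclei pass the discrimination filter, every verdict recovers the
planted PO truth, and every nucleus lands in class E2 (all three states
distinct, experimental marker). Per-nucleus detail sits in
`run$verdicts`; e.g. the first row shows `dd_po_center = 0.037` ppm versus
`dd_fo_center = 1.44` ppm — the PO prediction is 40x closer to the
experiment:

```
  residue_number atom  method exp_delta dd_po_center dd_fo_center verdict marker_status
1             33   CA SPARTA+     0.737        0.037         1.44      PO        marker
```

`plot(run, "filter")` and `plot(run, "ddcs")` draw the credible-interval
panels behind these tables. Real data enter through
`read_prediction_table()` (SPARTA+, SHIFTX2 or a generic long TSV) and
`read_experimental_table()`; trajectory curation helpers
(`exclude_after_water_entry()`, `stable_gate_window()`, `gate_distance()`,
`occupancy_string()`) cover the usual MD quality filters.

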