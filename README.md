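# sagesurv

Prognosis prediction for early stage (I–II) non-small-cell lung cancer
(NSCLC) patients after surgical resection, by combining two channels of
information that are usually modelled separately:

- **non-imaging clinical data** (sex, age, tumour lobe, histology,
  pathological TNM sub-stage), encoded as the *edges* of a patient
  population graph — two patients are connected, and weighted, by how
  clinically similar they are; and
- **tumour imaging features**, encoded as the *node features* — a
  fixed-length vector summarizing the patient's CT tumour region.

A two-layer edge-weighted GraphSAGE network is trained transductively on
this graph with a Cox proportional-hazards partial-likelihood loss and
emits one log-risk score per patient for overall survival (OS) or
recurrence-free survival (RFS). The package also ships the complete
evaluation stack used in this setting — fixed-horizon AUC with bootstrap
CIs, Kaplan–Meier curves stratified at the training-median risk with
log-rank tests, continuous net reclassification improvement (NRI),
integrated discrimination improvement (IDI), and decision curve analysis —
plus a synthetic cohort generator so the whole pipeline runs without
patient data.

## The model

Patients are nodes. For a pair (a, b), four clinical component scores are
computed — demographics (sex match + a piecewise age kernel), tumour lobe
match, histology match, stage match — and combined (sum by default) into a
similarity `s(a,b)`; an edge with weight `s(a,b)` is created when
`s(a,b) ≥ τ` (default τ = 2 on the 0–5 scale). Each GraphSAGE layer
updates node v as

```
agg_v = Σ_{u∈N(v)} w_uv h_u / Σ_{u∈N(v)} w_uv
h'_v  = ReLU(W [h_v ; agg_v] + b)
```

so neighbours contribute in proportion to their clinical similarity. A
linear head maps the final embedding to a scalar risk `s_v`, trained by
minimizing the negative mean Cox partial log-likelihood over the training
nodes

```
L = −(1/D) Σ_{i: δ_i=1} [ s_i − log Σ_{j: t_j ≥ t_i} exp(s_j) ]
```

with Breslow handling of ties (Efron optional). The whole graph is visible
during training; only the loss is masked (transductive training).

## Worked example

```r
library(sagesurv)

coh     <- generate_cohort(cohort_spec(n_patients = 800, seed = 1))
records <- assign_splits(coh$records, seed = 1)
g       <- build_graph(records, coh$features, similarity_config())
fit     <- train_survival_model(g, train_config(endpoint = "OS", seed = 1))
report  <- evaluate_models(fit$risks, stage_baseline_risk(records),
                           records$os_time, records$os_event,
                           g$masks$train, g$masks$test,
                           endpoint = "OS", seed = 1)
print(report)
```

prints

```
Synthetic cohort: 800 patients, 32 features (seed 1)
  OS events: 237 (29.6%)  RFS events: 287 (35.9%)
Population graph: 800 patients, 212727 edges (mean degree 531.8), 32 features
  split: 600 train / 100 val / 100 test
GraphSAGE survival fit (OS): 113 epochs run, best validation loss 4.1237 at epoch 83
Evaluation report (OS, 60-month horizon, n = 100):
  AUC          0.756 (95% CI 0.625-0.876)   baseline 0.576 (0.453-0.702)
  log-rank p   0.001531 (high vs low risk)
  NRI          0.439 (0.004-0.916)
  IDI          0.180 (-0.015-0.355)
```

The AUC row compares the graph model against the stage-ordinal baseline
(the clinical-staging stand-in) at the 5-year horizon on the held-out test
nodes; the log-rank p tests separation of the KM curves of the high- and
low-risk groups split at the training-median risk; NRI and IDI quantify how
much reclassification and discrimination the image-aware graph model adds
over staging alone. `run_pipeline(run_config(...))` performs the same steps
end to end and writes every artifact (graph TSVs, model archive, risks CSV,
JSON reports, KM/decision-curve PNGs, logs) to a directory; a thin CLI over
it lives in `inst/cli/sagesurv.R`.

The image preprocessing path (`normalize_volume()` → `standardize_crop()`
→ `resize_volume()` → `make_montage()` → `featurize()`) turns a raw CT
tumour ROI (NIfTI) into the standardized 384×384 six-by-six slice montage
and a node feature vector; `generate_volume()` provides phantom inputs.

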