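# neuralhypernet

Neural hypernetworks for clinical diagnosis from incomplete records:
Q-analysis of a patient–descriptor simplicial complex coupled with a
shallow feed-forward neural network, developed around pulmonary
embolism (PE) triage. The intended users are biostatisticians and
clinical-ML researchers who need to classify patients from tabular
records in which a large share of entries was never recorded — and
recorded *selectively* (missing not at random) — without resorting to
row deletion or imputation.

## The method

**Augmented vertex set.** Each clinical variable `V` is discretized
into a vertex/antivertex descriptor pair using a clinical threshold
map: `V[1]` fires when the value is in the risk range (e.g.
`Age[1] = {Age ≥ 65}`, `dDimer[0] = {dDimer ≤ 230}`), `V[0]` when it is
in the non-risk range, and a missing value fires neither — the pair
`⟨0,0⟩`. "Observed normal" and "not observed" therefore remain
distinct, and no value is imputed. Nineteen retained clinical
variables project into 38 boolean descriptors; the clinicians' own
prediction scores (Wells, Revised Geneva, Wicki) are excluded from all
feature sets.

**Q-analysis.** In the 0/1 patient × descriptor incidence relation,
each descriptor is a simplex whose vertices are its patients; a
descriptor occurring `n` times is an `(n−1)`-simplex. With
`S[i,j] = |patients with both i and j| − 1` (the shared-face matrix),
descriptors are *q-near* when `S[i,j] ≥ q` and *q-connected* when
chained by q-near pairs. Scanning all q levels yields the maximal
connected component's size profile; the longest high-q interval on
which the diagnosis descriptor's component membership is constant (the
plateau, or stability zone) identifies the *connected higher
dimensional set* — the structural backcloth, too widely shared to
discriminate — and its complement, the *unconnected set* that carries
the diagnostic traffic.

**Classifier and metrics.** A three-layer sigmoid network (one hidden
layer) is trained by backpropagation with momentum on the MSE
(defaults: learning rate 0.5, momentum 0.9, hidden-width sweep under
stratified 10-fold cross-validation, 85/15 stratified holdout). The
output neuron is read as the probability of PE. Performance is
summarized by the ROC/AUC (midrank statistic) and by the Jaccard
coefficient `J(Ann, MD) = |Ann ∩ MD| / |Ann ∪ MD|` between the
classifier's and the clinicians' positive-decision sets.

Because no clinical cohort is distributed, the package includes a
synthetic cohort generator (`generate_cohort()`) reproducing the
setting's statistical structure: 58 % prevalence, a non-uniform ~24 %
missing-entry pattern, MNAR masking, and configurable per-variable
log-odds effects of the diagnosis on threshold crossing.

## Worked example

```r
library(neuralhypernet)

cfg <- pipeline_config(
  synth = synthetic_config(n_patients = 600, seed = 1,
                           effect_sizes = c(dDimer = 2, FC = 2, Shockindex = 2,
                                            PO2 = 2, Age = 2)),
  sweep_sizes = c(2, 5, 8), k = 5,
  ann = ann_config(hidden_neurons = 8, max_epochs = 150),
  seed = 42)
res <- run_pipeline(cfg, "demo-out")
#> cohort: 600 patients
#> incidence: 40 descriptors
#> plateau: q = [0, 27], 40 members
#> sweep: best hidden width 8
#> evaluation: AUC 0.894, Jaccard 0.667 over 90 validation patients

res$evaluation
#> Evaluation over 90 patients: AUC 0.894, Jaccard 0.667
#>   confusion TP 40 FP 8 TN 30 FN 12 (threshold 0.50)
```

Reading the output: a 600-patient cohort with five planted log-odds-2
effects is generated, discretized into the 40-descriptor Q-analysis
view (19 clinical variable pairs plus the diagnosis pair), profiled
across all q levels, split 85/15, swept over three hidden widths (the
5-fold mean AUC picks width 8), trained, and scored on the 90 held-out
patients: the network recovers the planted signal (validation AUC
0.894) and agrees with the reference decisions on two thirds of the
positive-decision union (Jaccard 0.667). On synthetic cohorts the
plateau typically sits low in the q-structure (here q = [0, 27] with
all 40 descriptors) because synthetic co-occurrence is flatter than
clinical data; see the methods vignette.

Every artifact (cohort, incidence, shared-face matrix, q-profile,
plateau report, sweep table, model weights, evaluation report, run
log) is written to the output directory, and two runs with the same
config and seed are byte-identical.

A thin command-line front end is installed at
`system.file("cli", "neuralhypernet.R", package = "neuralhypernet")`
(YAML config; `--config`, `--outdir`, `--seed`, `--stage`).

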