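# vdjmh

Microhomology-aware modeling of V(D)J junction trimming and ligation.

## What it does

When a V gene and a J gene are joined during V(D)J recombination, each
end can be trimmed and the two ends ligated — sometimes guided by
*microhomology* (MH): short stretches of identical sequence between the
trimmed V suffix and the trimmed J prefix. Junctions without
N-insertions can be explained by a set of annotations `(t_V, t_J, m)` —
trim amounts on each gene plus the number of shared nucleotides, counted
once in the observed sequence. Annotation tools that assign shared
nucleotides to a single gene ignore the MH-bearing explanations;
`vdjmh` enumerates all of them and quantifies how much MH biases the
recombination choices.

The core is a two-step conditional-logit model of junction formation,
conditional on the gene pair `S`:

    P(T, m | S) = P(T | S) × P(m | T, S)
    P(T | S)    ∝ 10^( x(T, S) · β_trim )     over the 289 trimming scenarios
    P(m | T, S) ∝ 10^( β_lig · m )            over the feasible MH counts

with trim indices in `[-2, 14]` (−2 keeps both P-nucleotides, 0 trims to
the germline boundary). The trimming covariates `x(T, S)` are per-gene
trimming-motif one-hots, GC/AT base counts beyond the motif on each
side, and the average MH available under the trimming scenario; the
ligation step has the single covariate `m`. Coefficients are
log10-odds. Because the true annotation of each junction is latent, the
model is fitted by expectation-maximization over the annotation sets,
with bootstrap/Wald significance tests, likelihood-ratio comparison of
nested models, per-sequence log loss and mean-absolute-error model
evaluation, and a comparison of annotation rankings between the full
model and its no-MH ablation. A seeded simulator generates germline
panels and repertoires under four MH regimes (`none`, `trim_only`,
`lig_only`, `both`) so the entire pipeline is testable without external
data.

## Worked example

```r
library(vdjmh)

cfg <- simulation_config(n_v = 6, n_j = 5, regime = "both",
                         n_sequences = 20000, seed = 1)
panel   <- make_fixture_germlines(cfg)
records <- simulate_repertoire(panel, cfg)
dataset <- annotate_records(records, panel)
dataset
#> <annotated_dataset> 20000 sequences, 30 V-J pairs, 78386 (sequence, annotation) rows
#>   sequences with multiple annotations: 11927 (59.6%)

fit_full <- fit_em(dataset)
fit_full
#> <vdjmh_fit> 32 parameter(s), log-likelihood -99639.7165, 21 EM iteration(s)
#>   microhomology coefficients (log10-odds): trimming 0.4486, ligation 0.1311

fit_nomh <- fit_em(dataset, ablation = c("mh_trim", "mh_lig"))
likelihood_ratio_test(fit_full, fit_nomh)
#> LRT: statistic = 2261.9317, df = 2, p = 0
```

The simulation drew trimming and ligation scenarios with MH effects
0.4484 (trimming) and 0.1272 (ligation); the fit recovers both on the
log10-odds scale, and the likelihood-ratio test (2 degrees of freedom,
one per MH coefficient) overwhelmingly rejects the no-MH model on data
generated with MH effects. `per_sequence_log_loss()`,
`mean_absolute_error()` and `compare_top_annotations()` quantify how
much predictive accuracy and annotation rankings change when MH terms
are dropped; `bootstrap_se()` + `wald_report()` give per-parameter
significance at a Bonferroni threshold (0.05/32 ≈ 0.0016 for the full
model).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the pipeline end to end against the installed package — generates a
seeded synthetic world under the `both` regime, fits the full and no-MH
models, and prints the germline MH summary, parameter recovery, LRT,
log loss, MAE and ranking-comparison statistics — then writes the
acceptance JSON to `--out`.

## Layout

* `R/germline_io.R` — germline genes, P-nucleotide extension, trimming,
  productivity rule, FASTA I/O.
* `R/scenario_space.R` — feasible ligation sets, average MH, exhaustive
  annotation enumeration, record filters, germline MH summaries.
* `R/features.R` — trimming/ligation covariates.
* `R/choice_model.R` — the two-step conditional-logit model.
* `R/em_fit.R` — EM fitting over latent annotations.
* `R/evaluation_stats.R` — bootstrap, Wald, LRT, log loss, MAE,
  annotation-ranking comparison.
* `R/synthetic_data.R` — seeded panel and repertoire simulator.
* `vignettes/microhomology-choice-model.Rmd` — the model, its
  assumptions, defaults and limitations.
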