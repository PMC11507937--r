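---
title: "Modeling microhomology in V(D)J junction trimming and ligation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling microhomology in V(D)J junction trimming and ligation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjmh)
```

## The problem

During V(D)J recombination, a V gene and a J gene are joined after each
end is nicked open (leaving two palindromic P-nucleotides, modeled here
as hairpin opening at position +2), optionally trimmed, and ligated.
Short stretches of identical sequence between the trimmed V suffix and
the trimmed J prefix — *microhomology* (MH) — can guide the join. When a
junction contains no N-insertions, the germline gene sequences determine
exactly which MH-mediated explanations are possible, so zero-insertion
junctions are the natural substrate for quantifying MH effects from
repertoire data.

Standard annotation tools assign shared junction nucleotides to only one
gene. `vdjmh` instead enumerates, for every zero-insertion junction
$X$, the complete set $A_X$ of *MH-adapted annotations*
$(t_V, t_J, m)$: trim amounts for both genes plus the number $m$ of
shared nucleotides, counted once in the observed sequence. Trim indices
follow the IGoR convention: $-2$ keeps both P-nucleotides, $0$ deletes
exactly to the germline gene boundary, and values run to $14$ (deeper
trimming is excluded as likely reflecting a different mechanism).

## The two-step choice model

Conditional on a gene pair $S$, a junction is generated in two steps:

1. **Trimming scenario choice.** A pair $T = (t_V, t_J)$ is drawn from
   the full $17 \times 17 = 289$ grid with conditional-logit
   probabilities
   $P(T \mid S) \propto 10^{\,x(T,S) \cdot \beta_{\text{trim}}}$.
   The covariates $x(T, S)$ are, per gene in trimming orientation (V as
   is, J reverse-complemented): a one-hot *trimming motif* around the
   trim site (default 1 retained + 2 removed positions — a
   three-nucleotide window), GC counts retained-side beyond the motif
   (a sequence-breathing proxy; AT counts excluded by default), AT and
   GC counts removed-side beyond the motif (absolute-position and
   breathing proxies), plus the *average MH* available between the two
   trimmed sequences, $\overline{m}(T, S)$ — the mean of the feasible
   ligation set, blunt join included.
2. **Ligation scenario choice.** Given $T$, the MH count $m$ is drawn
   from the feasible set (all $m$ whose trimmed-V suffix equals the
   trimmed-J prefix, plus $m = 0$) with
   $P(m \mid T, S) \propto 10^{\,\beta_{\text{lig}} m}$.

All coefficients are on the log10-odds scale, so a parameter is read
directly as the change in the $\log_{10}$ odds of a scenario per unit
increase of its feature. The full default model has 32 parameters: 12
motif one-hots and 3 base counts per gene, the trimming-MH coefficient,
and the ligation-MH coefficient.

Productivity enters by restriction: when an analysis conditions on a
productivity class $Q$, the joint distribution
$P(T, m \mid S) = P(T \mid S) P(m \mid T, S)$ is restricted to the
$(T, m)$ cells of that class and renormalised. The restriction is
applied at the joint level (a single consistent interpretation; applying
it per step instead would change both factors' normalisers and is not
obviously well defined when a step has no $Q$-compatible choice).

## Latent annotations and EM

The true annotation of an observed junction is latent — any member of
$A_X$ could have produced it. The observed-data likelihood of a
junction is therefore $\sum_{(T,m) \in A_X} P(T, m \mid S, Q)$, and
fitting proceeds by expectation-maximization over the latent assignment:
the E-step weighs each candidate annotation by its posterior under the
current parameters; the M-step maximises the weight-aggregated
conditional-logit log-likelihood. Because the aggregated objective
depends on the data only through weighted counts per $(S, T, m)$ cell,
both steps run on sufficient statistics; with no productivity
restriction the M-step objective is concave (up to the per-motif-
position gauge), so the M-step optimum is essentially unique.

Numerical choices:

* **Initialisation** is all-zero parameters (the uniform model), making
  results deterministic run to run; the M-step warm-starts from the
  previous iterate.
* **Convergence** requires both a relative log-likelihood change below
  `tol_loglik` (default `1e-8`) and a maximum absolute parameter change
  below `tol_param` (default `1e-6`), within `max_iter = 50`
  iterations. Non-convergence returns the best-so-far fit with a
  warning and an `unconverged` flag.
* The **M-step** uses BFGS with analytic gradients on the
  mean-per-observation objective, restarting (fresh Hessian
  approximation) until the gradient infinity norm falls below
  `mstep_grad_tol` (default `1e-5`).
* **Full one-hot coding** is used for motif positions (no reference
  level dropped). The softmax is invariant to adding a constant per
  motif position, so individual motif coefficients are only identified
  up to this gauge; MH and base-count coefficients are unaffected.
* Probabilities use a max-shifted base-10 softmax for overflow safety;
  ligation weights need no shift because $m$ is capped.

Ablated term groups (`mh_trim`, `mh_lig`, `motif`, `base_5p`,
`base_3p`) are *structurally absent* from the parameter vector rather
than fixed at zero, so model comparisons are explicit; ablating
`mh_lig` makes the ligation step exactly uniform over feasible counts.

## Inference and evaluation

* **Bootstrap standard errors** resample sequences with replacement and
  refit (warm-started from the full-data estimate with a reduced
  iteration cap — legitimate because the M-step objective is concave, so
  the warm start changes only the path, not the optimum). The reference
  analysis uses 1000 replicates; everything is reproducible from a
  seed.
* **Wald tests** compare each coefficient to zero with a two-sided
  normal test at the Bonferroni threshold $\alpha / p$ (0.05 / 32
  $\approx$ 0.0016 for the default model).
* **Likelihood-ratio test**: $2(\mathcal{L}_{\text{full}} -
  \mathcal{L}_{\text{reduced}})$ against $\chi^2_{df}$ with $df$ the
  number of extra parameters (2 for the MH ablation).
* **Per-sequence log loss** is the negative observed-data
  log-likelihood divided by the number of sequences, with frozen
  parameters.
* **MAE** compares the model joint distribution with the empirical
  scenario distribution built from fractional (E-step posterior)
  annotation assignments, averaged unweighted over all cells of the
  observed pairs' choice sets. The weighting across cells is a design
  choice recorded here; per-pair-count weighting would emphasise heavily
  used pairs.
* **Ranking comparison** restricts to junctions with $\ge 2$
  annotations, finds each model's top annotation (ties broken by lower
  $t_V$, then lower $t_J$, then higher $m$), and reports per-pair
  proportions of disagreement, the *relative confidence*
  $|P_{\text{full}}(\text{top}_{\text{full}}) -
  P_{\text{full}}(\text{top}_{\text{noMH}})|$, and the Pearson
  correlation between per-pair disagreement and mean annotation MH.

## The synthetic world

`simulation_config()` + `make_fixture_germlines()` +
`simulate_repertoire()` generate a panel and a zero-insertion repertoire
with the statistical structure the analysis assumes, under four MH
regimes: `none`, `trim_only`, `lig_only`, `both`. Active effects default
to the reference point estimates 0.4484 (trimming) and 0.1272
(ligation); all other generating coefficients are zero, isolating the MH
effects the regimes are named for.

Defaults and their rationale:

* **Panel of 20 V × 15 J genes, 20–30 nt**: large enough for pair-level
  statistics, small enough for desk-scale EM; genes must be at least
  15 nt to support 14-nt trims.
* **`mh_plant_rate = 0.5`**: with probability 0.5 each J gene receives a
  2–4 nt word copied from a random V gene's 3'-terminal region into its
  5' region at a small random offset (offset 0 plants terminal MH,
  larger offsets interior MH). Planting is per J gene rather than per
  pair because genes are shared across the V × J grid; a planted word
  creates MH structure in many pairs at once, as germline-encoded MH
  does. Unplanted sequence still shares ~1-nt matches by chance, so
  feasible ligation sets are non-trivial even at rate 0.
* **Productivity labels** come from a deterministic stand-in rule (the
  upstream definition used for real data is not reproducible here):
  in-frame iff the net length change relative to the untrimmed blunt
  join is a multiple of three, and stop-free in a 30 nt window each side
  of the join, in the frame anchored by the V gene's `frame_offset`.
  Real-data records carry their own productivity flag, which takes
  precedence. Nonproductive-only filtering in the simulator uses
  rejection sampling.
* The simulator samples from the same probability code paths the fitter
  evaluates (pair tables and cell joint probabilities), so
  simulate-and-refit is a closed loop; the test suite holds a separate
  brute-force evaluator against this path.

What the simulator does **not** emulate: N-insertions, sequencing
error, allele collapsing, thymic selection, gene-usage modeling (pair
identity is always conditioned on), and real germline sequence
composition. A green simulation test therefore establishes internal
consistency — the estimator recovers the generating process and the
test statistics are calibrated under it — not agreement with any
particular organism's repertoire.

## Other design decisions

* **MH is top-strand identity** between trimmed V suffix and trimmed J
  prefix; double-stranded overhang complementarity reduces to identity
  in top-strand coordinates, and the merged junction counts shared
  nucleotides once.
* **`m_cap = 10`**: germline MH stretches of 1–4 nt are the regime of
  interest; 10 is a safe superset and keeps ligation weights bounded.
* **Exactly two P-nucleotides** per end (hairpin opening at +2),
  matching the trim floor of $-2$; other opening positions are out of
  scope.
* **Retained-side base counts** span the whole retained gene beyond the
  motif (no fixed window is imposed).
* The trimming choice set is always the full 289-scenario grid; the
  observed junction restricts only the posterior over $A_X$, never the
  choice-set normalisation.
* An **unexplainable junction** (no $(t_V, t_J, m)$ reproduces it) is
  an error by default so data problems surface; `skip_unexplainable`
  drops such records with a warning.
* Exhaustive enumeration of $A_X$ can only be a superset of pipelines
  that adapt a fixed number of precomputed annotations; the difference
  is a known asymmetry, not reconciled here.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_v = 6, n_j = 5, regime = "both",
                         n_sequences = 20000, seed = 1)
panel <- make_fixture_germlines(cfg)
records <- simulate_repertoire(panel, cfg)
dataset <- annotate_records(records, panel)

fit_full <- fit_em(dataset)
fit_nomh <- fit_em(dataset, ablation = c("mh_trim", "mh_lig"))

likelihood_ratio_test(fit_full, fit_nomh)
per_sequence_log_loss(dataset, fit_full$params)
compare_top_annotations(dataset, fit_full, fit_nomh)
```

## Limitations

* Zero-insertion junctions only; inserting sequences would require
  latent insertion identities and are out of scope.
* The productivity rule is a stand-in for synthetic data and choice-set
  restriction; analyses of real data should rely on the records' own
  flags.
* Reproducing published real-repertoire estimates requires the original
  repertoire downloads and germline reference; the package's tests are
  property- and simulation-based by design.
* Motif window composition (1 retained + 2 removed) is a configurable
  assumption; only the three-nucleotide total is fixed by precedent.
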