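---
title: "Learning medical concept embeddings from visit sequences with self-attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning medical concept embeddings from visit sequences with self-attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Longitudinal EHR data arrive as a sequence of visits per patient, each visit
an *unordered set* of medical entities — symptoms, medications, lab tests and
diagnoses extracted from the notes of one encounter. Two structures carry the
signal: which entities co-occur *within* a visit, and how visit content
evolves *across* a patient's timeline. Plain skip-gram embeddings flatten both
into a fixed token window and weight all context equally; `ehrvec` instead
contextualizes every entity against the rest of its visit with multi-head
self-attention before asking it to predict its co-occurring entities.

## Model

Let `W` be the `h x c` embedding matrix (`h` = vocabulary size, `c` = vector
dimension); row `W[i,]` is the vector of entity `i`. For a visit with entity
set `E_t`, the rows of `W` for `E_t` form the matrix `X`, which passes
through two sublayers:

1. **Multi-head scaled dot-product attention.** Per head,
   `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V` with
   `Q = X Wq`, `K = X Wk`, `V = X Wv` and `d_k = c / n_heads`; the
   `sqrt(d_k)` scaling keeps the logits out of the softmax's saturated
   region. Head outputs are concatenated and passed through an output
   projection. Entities within a visit are an unordered set, so there is no
   positional encoding; the layer is permutation-equivariant by
   construction (a property the test suite asserts).
2. **Position-wise feed-forward network** with a residual path:
   `Z = M + relu(M W1) W2`, applied row-independently. No biases and no
   layer normalization are used; the sublayer is a toggle-free minimal
   realization of "deep feed-forward on top of attention", and the residual
   keeps the identity solution reachable at initialization.

The contextualized rows `z_i` of `Z` drive a shared-matrix co-occurrence
softmax:

* **Within-visit loss.** Every ordered pair `(i, j)`, `i != j`, of distinct
  entities in the visit contributes
  `-log softmax(z_i . W[j,])`, the softmax taken over all `h` vocabulary
  entities (the denominator includes the diagonal term `k = i`). `W` is
  shared between the lookup (input) side and the output side, which keeps
  the objective in the classical skip-gram form
  `log p(e_j | e_i) = W[i,]'W[j,] - log sum_k exp(W[k,]'W[i,])` while giving
  the attention layers a differentiable role through `z_i`.
* **Cross-visit loss.** The mean contextualized vector `v_t` of visit `t`
  predicts, through the same softmax, every entity of the visits `s` with
  `|s - t| <= w` of the same patient. This is the visit-sequence coupling:
  it rewards vectors that anticipate what neighbouring encounters contain.

The total per-visit loss is `within + lambda * cross`. Gradients for `W`
(both sides), all head projections, the output projection and the FFN are
derived analytically and verified against central finite differences to
better than `1e-5` (observed: ~`1e-10`) by `numerical_gradient_check()`.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `dim` (`c`) | 512 (desk scale: 32) | entity vector dimension |
| `n_heads` | 8 (desk scale: 4) | attention heads; `d_k = c / n_heads` |
| `epochs` | 20 | full passes over the visit list |
| `dropout` | 0.1 | applied to attention weights, training only |
| `optimizer` | Adadelta (`rho = 0.95`, `eps = 1e-6`) | published configuration |
| Adam `lr` | 0.002 | desk-scale alternative (see below) |
| `window` (`w`) | 1 | cross-visit prediction window, in visits |
| `lambda` | 1.0 | weight of the cross-visit term |

The published configuration (512 dimensions, 8 heads, Adadelta, dropout 0.1,
20 epochs) is what `train_config()` returns with no arguments. Everything
the tests and examples run uses `dim = 32`, `n_heads = 4` on the default
synthetic corpus: at `h = 100` the planted structure is recoverable in 32
dimensions in under a minute on one CPU, and nothing in the architecture
changes with scale.

**Why Adam at `lr = 0.002`.** The batch unit is one visit and the loss is a
*sum* over up to `m(m-1)` pairs, so per-step gradients are large. With Adam's
unit-scale steps, `lr = 0.01` makes the epoch loss oscillate upward on the
default corpus; a stability sweep over {0.001, 0.002, 0.005} showed all three
converge cleanly, and 0.002 was fixed as the default. Adadelta needs no such
tuning and also converges, but is slower to separate topics at desk scale.

Full-vocabulary softmax is used throughout: it is exact and reproducible at
`h` up to a few thousand, which covers both the synthetic corpus and
realistically sized clinical vocabularies after frequency filtering.

## Preprocessing contract

`read_corpus()` ingests line-delimited JSON (one patient per line). The
chain `filter_patients() |> sort_visits_temporally() |> build_vocabulary()
|> index_corpus()` enforces the cohort rules: patients with fewer than two
visits or with a missing/unparseable first-visit date are excluded; visits
are stably sorted by day; duplicate entities within a visit are removed. The
deduplication choice follows from the objective: the within-visit sum runs
over distinct ordered pairs, and repeated mentions in one note would only
inflate self-similar pairs without adding co-occurrence information.
Timestamps are day-resolution — integer day offsets or ISO dates; ordering
uses days only, since visit intervals range from days to months and
finer-grained ordering is not meaningful in discharge data.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` plants `n_topics` comorbidity topics, each owning 10
category-typed entities (4 symptoms, 3 medications, 2 lab tests, 1
diagnosis), plus 50 background entities. A patient carries one latent topic
at a time and drifts to an *adjacent* topic index with probability 0.15 per
visit — a chain, not uniform switching, so that visit order carries
information and sequence-aware models are distinguishable from
bag-of-visits ones. Visits draw 3–8 topic entities, each replaced by
background noise with probability 0.2; visit counts follow `2 + geometric
(p = 0.45)` truncated at 30, reproducing the heavy sub-10-visit skew of
real multi-visit cohorts (the default corpus has ~99% of patients under 10
visits); intervals are uniform on 3–90 days.

It does **not** emulate: real code ontologies (ICD, ATC), category-dependent
co-occurrence asymmetries, visit-length correlation with disease severity,
measurement values on lab tests, or censoring/fragmentation of records.
Passing the planted-structure tests therefore shows the estimator recovers
block co-occurrence structure transmitted through noisy visits — it does not
certify clinical validity on real notes, which in the original evaluation
protocol required human experts.

## Evaluation protocol

* `rank_by_similarity()` ranks all other entities by cosine against a query,
  optionally filtered to one category *after* scoring, so reported cosines
  are unconditional — per-category tables stay comparable.
* `top_entities_in_dimension()` reads a single embedding dimension as an
  interpretable axis: the `k` largest column values name the entities that
  load on it. "Largest" means the maxima; negative extremes are not
  reported.
* The intrusion protocol (`build_intrusion_set()`,
  `simulated_expert_choice()`, `model_precision()`) plants one entity drawn
  from the bottom half of a ranking among the query's top five neighbors and
  asks a judge to spot it; MP is the fraction of instruments judged
  correctly. The bundled judge picks the presented entity with the largest
  mean cosine distance to the other five. Because that is the same geometry
  the model optimizes, its MP measures *internal coherence* of the
  neighborhoods; it is a consistency check, not a replacement for clinical
  judgment. Human answers can be substituted via `read_human_answers()`.

## Numerical choices and degenerate inputs

* Softmaxes are always max-subtracted; log-likelihoods use log-sum-exp.
* Cosines are clamped to `[-1, 1]` against rounding; a zero-norm vector is
  an error rather than a silent `NaN`, since it signals a broken training
  run.
* Ties in rankings and dimension profiles break by vocabulary index
  ascending; the simulated judge's ties resolve to the lowest presented
  index. All tie rules are deterministic so seeded runs are bit-identical.
* `W` initializes uniform on `(-0.5/c, +0.5/c)`; projections are Gaussian
  with sd `1/sqrt(c)`; every random draw (initialization, epoch shuffling,
  dropout masks, intruder draws) descends from one user-supplied seed, and
  seeded functions restore the caller's RNG state.
* Degenerate cases fail fast: empty corpus or `h < 2` refuses to train;
  `epochs = 0` returns the seeded initialization unchanged; single-entity
  visits contribute zero within-visit loss but still participate in the
  cross-visit term.

## Worked example

```{r, eval = FALSE}
library(ehrvec)

sim <- generate_corpus(sim_config(seed = 7))
records <- filter_patients(sim$records)
records <- lapply(records, sort_visits_temporally)
vocab <- build_vocabulary(records)
indexed <- index_corpus(records, vocab)

fit <- train_ehr2vec(indexed, vocab,
                     train_config(dim = 32, n_heads = 4, ff_dim = 128,
                                  epochs = 20, optimizer = "adam", seed = 7))
tail(fit$trace, 1)

# nearest neighbors of a planted topic-1 symptom
rank_by_similarity(fit$embedding, "t1_symptom_1", top_n = 5)

# automated intrusion evaluation
run_intrusion_eval(fit$embedding,
                   queries = names(sim$truth)[!is.na(sim$truth)],
                   n_sets = 50, seed = 7)
```

## Known limitations

* Training is plain R matrix code: exact, dependency-free and fast at desk
  scale, but a 512-dimensional run over tens of thousands of patients would
  want a compiled backend and sampled softmax (a config hook exists for
  neither yet; full softmax only).
* The cross-visit term uses a fixed symmetric window in *visit index*, not
  calendar time; long gaps between visits are treated like short ones.
* The attention sublayer carries no residual connection or layer norm;
  deeper stacks would need both.
* Within-visit duplicate mentions are discarded; if mention frequency
  carries signal in a corpus, it is lost by design.
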