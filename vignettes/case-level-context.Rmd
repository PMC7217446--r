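---
title: "Case-level context for classifying sequences of clinical reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-level context for classifying sequences of clinical reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(casecontext)
```

## The problem

Clinical documents rarely arrive alone. A cancer case accumulates a sequence
of pathology reports over time — an initial biopsy, tests of neighbouring
sites, follow-ups — and registries require every report of a case to carry
the *aggregate* labels of that case (site, subsite, laterality, histology,
behavior, grade). A classifier that reads one report at a time faces two
structural obstacles:

* **addendum reports** contain no usable evidence for some or all label
  tasks, yet still need the case's labels;
* **distributed evidence**: the information that determines a label may be
  spread across several reports, none of which is conclusive alone.

`casecontext` implements a modular remedy. A *document encoder* maps each
report $d_i$ to an embedding $e_i$ (its penultimate-layer representation),
and a *context mechanism* transforms the case's embedding sequence
$e_0, \dots, e_n$ into context-aware outputs $o_0, \dots, o_n$ from which a
label head predicts $y_i$. Two scenarios are supported: *bidirectional*
(offline — all reports of the case are available) and *unidirectional*
(online — report $i$ may only use reports $\le i$).

## Models

**Encoders.** Two per-report baselines are provided. The word-level CNN
embeds tokens, convolves windows of 3/4/5 consecutive words (ReLU, 100
feature maps per window by default), and max-pools over time; the three
pooled blocks concatenate into a 300-dimensional document embedding. The
hierarchical self-attention encoder ("HiSAN-lite") runs one self-attention
layer over the tokens of each line, attention-pools each line to a vector,
runs self-attention over the line vectors, and pools them into the document
embedding. It is a deliberate simplification of the published hierarchical
self-attention network — one attention layer per level, learned-query
pooling — not a re-implementation of that network's exact architecture.
Encoders are strictly per-document: no information flows between reports at
this stage.

**Context mechanisms.** Five are implemented:

1. *Concatenation* — all reports of the case (or, online, all reports up to
   and including the target) are joined into one token sequence with a
   dedicated separator token and classified as a single document. This is
   only valid because every report of a case shares its labels; the target
   report itself is always included, otherwise the first report of a case
   would have no input at all.
2. *GRU* — a gated recurrent unit (hidden size 300) over the embedding
   sequence, with an independent reversed pass concatenated in the
   bidirectional scenario: $z_t = \sigma(W_z[h_{t-1}, x_t] + b_z)$,
   $r_t = \sigma(W_r[h_{t-1}, x_t] + b_r)$,
   $c_t = \tanh(W_c[r_t \circ h_{t-1}, x_t] + b_c)$,
   $h_t = (1 - z_t) \circ h_{t-1} + z_t \circ c_t$.
3. *Self-attention* — multi-head (6 heads, 300 dimensions by default)
   scaled dot-product attention over the embedding sequence. Queries, keys
   and values come from window-one 1D convolutions with ELU activations
   applied to the input plus a learned table of absolute positional
   embeddings. The online scenario masks the score matrix to its lower
   triangle so position $i$ attends only to positions $\le i$.
4. & 5. Either of 2./3. followed by a linear-chain CRF instead of the
   softmax head.

**Heads.** The softmax head scores each report independently,
$P(y_i = k) \propto \exp(w_k o_i + b_k)$, computed in log-space. The
linear-chain CRF scores a whole label sequence as
$\sum_i \psi(o_i, y_i) + \sum_{i \ge 1} T[y_{i-1}, y_i]$ with emission
scores $\psi$ from a linear projection of $o_i$ and a learned transition
matrix $T$, normalised by the forward algorithm. Because all reports of a
case share one label, a trained CRF is expected to learn strongly
diagonally dominant transitions — label changes inside a case should be
penalised — and the test suite asserts exactly that on trained models.
Decoding is Viterbi with ties broken toward the lowest class index; no
explicit start/stop scores are used (the first label is scored by its
emission alone); training maximises the per-case log-likelihood, averaged
per report.

## Numerical and design choices

* **Attention scaling.** The per-head scores are divided by
  $\sqrt{d/h}$ (Transformer convention), with a configuration switch
  `attn_scale = "d"` that divides by the full dimension instead, since both
  conventions appear in the literature for this architecture family. The
  default is `"sqrt_d"`.
* **No residual connections or layer normalisation** are used in the
  context attention block, and only one context layer is applied — the
  mechanism is a thin add-on, not a deep Transformer stack.
* **All CRF path computations are in log-space**; the forward-algorithm
  partition function is checked against exhaustive path enumeration (all
  $K^{n+1}$ paths for small $K$, $n$) to $10^{-6}$ in the test suite.
* **Gradients are hand-derived** for every component (CNN, hierarchical
  attention, GRU backpropagation-through-time, attention blocks, CRF via
  forward–backward marginals) and verified against central finite
  differences at $10^{-6}$ tolerance in the tests. The max-over-time pool
  of the CNN is non-differentiable at ties (e.g. biases initialised exactly
  at the ReLU kink); the implementation takes the first-argmax subgradient,
  and gradient checks are run at generic points.
* **Batch-composition invariance.** Batched CNN encoding pads documents to
  the longest in the batch; candidate pooling windows are masked to each
  document's true length so a report's embedding never depends on what else
  was in its batch.
* **Padding embedding** (vocabulary id 1) is fixed at zero and excluded
  from gradient updates, so zero-padding short documents is exactly neutral.
* **Date ties** within a case sort stably with report id as secondary key;
  the year of the report date alone decides the train/test cutoff.
* **Cases longer than the positional table** (default 64 reports) are
  truncated oldest-first with a warning.
* **Missing labels** are permitted: softmax losses and accuracy skip
  unlabelled reports; CRF training skips cases with missing labels for the
  trained task.

## Training regimes

Training uses Adam (learning rate $10^{-4}$) on batches of 64 — documents
for encoders, whole case sequences for context models — with early
stopping: when validation accuracy has not improved for 5 consecutive
epochs, training stops and the parameters of the best validation epoch are
restored. A hard cap (default 100 epochs) bounds runs that keep improving.
Cross-validation is not used; each run uses a single date-based split.

In the **modular** regime the encoder is first trained alone on individual
reports with a temporary softmax head; it is then frozen, document
embeddings are extracted once, and the context model is trained on the
stored embedding sequences. The encoder's parameters are bit-identical
before and after step two, which the test suite asserts. In the
**end-to-end** regime the pretrained encoder continues to fine-tune jointly
with the context mechanism and head. The two regimes are expected to land
within about two accuracy points of each other, and do on the synthetic
benchmark.

## The synthetic benchmark

Real registry corpora are private, so the package ships a generator that
reproduces the *structure* that makes case-level context necessary, not the
language of pathology reports:

* case lengths are $2 + \mathrm{Geometric}(p)$ with $p$ set so the mean is
  3.2 reports per case (minimum 2, mirroring the removal of single-report
  cases, which have no case-level context to exploit);
* each class of each task owns a pair of cue tokens unique to that class;
  with probability `cue_split_rate` (default 0.5) the case's evidence is
  split so that each signal report carries only one of the two cue tokens;
* each report is an addendum (background tokens only) with probability
  `addendum_rate` (default 0.3), but every case keeps at least one signal
  report — flags are redrawn while all are set — since a case whose every
  report lacked evidence could never have been labelled from its reports in
  the first place;
* background text is Zipf-distributed over 2,000 token types (default 30
  tokens per report), so rare types exercise the unknown-token mapping, and
  case start dates spread over 2010–2017 so the 2016 date cutoff produces a
  non-trivial test set.

Cue tokens are deliberately class-unique: a signal report is fully
classifiable on its own, which gives the per-report baseline the closed
form ceiling $(1 - a) + a/K$, where $a$ is the marginal addendum fraction
(`addendum_fraction()` computes it exactly, accounting for the at-least-
one-signal constraint) and $K$ the number of classes. With the defaults
this is $\approx 0.79$ for $K = 4$. A context model that can see the rest
of the case has no such ceiling, which is precisely the gap the package is
built to close: on the synthetic benchmark (2,000 cases, $K = 4$, reduced
dimensions — 32-dimensional word embeddings, 12 feature maps per window,
hence 36-dimensional document embeddings) the per-report CNN baseline lands
near its ceiling, bidirectional self-attention exceeds 95% accuracy, and
the masked (online) variant falls strictly between the two, on every seed
tried. These problem sizes were chosen so a full experiment trains in
minutes on one CPU while leaving the ordering unambiguous.

An embedding-level generator (`generate_embedding_sequences()`) bypasses
text entirely — signal reports are Gaussian draws around class centroids at
pairwise distance $\delta$, addenda around the origin — and is used to test
context mechanisms and heads without encoders.

**What passing these tests does and does not show.** The generator
reproduces label sharing, addendum structure, split evidence, skewed token
frequencies and date-based splits; it does not reproduce clinical language,
section structure, label-set sizes in the hundreds, class imbalance, or
inter-annotator noise. Results on it validate the machinery and the
qualitative ordering of the methods, not absolute accuracies on real
registry data.

## Evaluation

Accuracy (identical to micro-F in single-label classification) and macro
F-score are the two metrics. Macro-F averages per-class F1 unweighted over
the classes present in the ground truth of the evaluated split; a class
with a zero denominator contributes 0. Averaging over observed classes
(rather than the full schema) keeps the metric meaningful when a task's
schema has hundreds of classes of which a split realises few; the choice is
the package's own.

95% confidence intervals use the percentile bootstrap: resample
prediction–truth pairs with replacement to the original size, recompute the
metric, repeat 1,000 times, and take the 2.5/97.5 percentiles. Pairs of
models are compared with McNemar's test on their discordant error counts
$b$ and $c$: the exact two-sided binomial test when $b + c < 25$, otherwise
the $\chi^2$ approximation with continuity correction
$(|b - c| - 1)^2/(b + c)$; when $b + c = 0$ the comparison is degenerate
and $p = 1$.

## Known limitations

* The label-sharing assumption is load-bearing: concatenation is rejected
  outright when labels differ within a case, and the CRF's learned
  transition prior is only an advantage under near-constant label
  sequences.
* Concatenation with the hierarchical encoder is refused when the estimated
  concatenated length exceeds a configurable cap, since quadratic attention
  over tens of thousands of tokens is not practical.
* One model is trained per task; no parameter sharing across tasks.
* Word embeddings are learned from the corpus at hand; no pretrained
  vectors are consumed.
* The pure-R implementation favours clarity and testability over speed; it
  is sized for corpora of thousands of cases, not hundreds of thousands.
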