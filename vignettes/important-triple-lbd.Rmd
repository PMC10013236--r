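---
title: "Literature-based discovery from important triples: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature-based discovery from important triples: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noveltylbd)
```

## The problem

Open literature-based discovery (LBD) under the A–B–C model proposes a
*candidate hidden knowledge pair* (CHKP) A–C whenever relations A→B and
B→C appear in the literature but A→C does not. Applied to
subject–predicate–object (SPO) predications between biomedical concepts
(UMLS CUIs, as produced by extractors such as SemRep), this generates
millions of candidates, most of which chain through *background
knowledge* — generic relations like "diabetes is a process of a
patient" that carry no discovery value. `noveltylbd` implements the
two-part remedy this package is built around: (1) restrict the
discovery input to *important* triples, the ones expressing a paper's
novel contribution, identified by machine learning; and (2) evaluate
with timeslicing gold standards constructed to avoid rewarding
background knowledge.

## The discovery model

The knowledge graph has one vertex per concept identifier and a
directed binary edge subject→object for every distinct triple;
predicates are ignored at this stage and duplicate edges collapse
(`build_graph()`). With binary adjacency matrix $A$, the square
$A^2 = (s_{ij})$ counts walks of length two, so the CHKP set is

$$\{(i, j) : s_{ij} > 0,\; a_{ij} = 0,\; i \neq j\},$$

computed sparsely (`square_adjacency()`, `extract_chkps()`), with
$s_{ij}$ retained as the linking-term count. Two design points were
genuinely open:

* **Directionality.** The matrix condition is literal: a known reverse
  edge C→A does not suppress the CHKP (A, C). A
  `suppress_symmetric` flag exists but is off by default, because the
  defining condition is "zero in the original adjacency matrix", not
  "unconnected in either direction".
* **Self-pairs.** Mutual edges make $s_{ii} > 0$; the diagonal is
  excluded always, since a concept hidden-connected to itself is
  meaningless.

Closed discovery is served by `linking_terms()`, the intersection of
out-neighbours of A and in-neighbours of C.

## Importance labeling by triple similarity

The labeling hypothesis: a paper's novel contribution appears both in
its abstract and in its body. Two triples are compared by summing three
cosine similarities — subject vs. subject and object vs. object under
concept embeddings (cui2vec-style), predicate vs. predicate under word
embeddings (GloVe-style) — giving a score in $[0, 3]$. A body triple's
importance score is its maximum similarity against all abstract triples
of the same document (never another document's abstract). Labels use
two thresholds with a deliberate gap: score $\ge 2.5$ → *important*,
$\le 1.5$ → *not important*, anything between is discarded so the two
classes are well separated. The thresholds are configuration
(`similarity_config()`), not fitted here.

Numerical choices:

* Cosine similarity can be negative, yet the score interval is stated
  as $[0, 3]$. Each cosine is therefore clamped at 0 by default
  (`clamp_negative_cosines`), making the interval literally true; an
  unclamped mode is available for inspection.
* The cosine of a vector with itself is returned as exactly 1 (an
  equal-vector short-circuit before the floating-point division), and
  results are clipped into $[-1, 1]$. This makes "a triple copied
  verbatim from the abstract scores exactly 3" an exact identity
  rather than an approximation.
* A multi-token predicate absent from the word-embedding store (e.g.
  `PROCESS_OF`) falls back to the componentwise mean of its
  underscore-split, lower-cased token vectors — a standard
  bag-of-words composition, documented so results are reproducible.
* A predication whose embeddings cannot be resolved is skipped and
  counted, never silently scored 0, which would bias the labeled set
  toward *not important*.

Class balance follows the training recipe for these models: the
*not important* majority is randomly undersampled to the minority size
(`balance_by_undersampling()`, seeded).

## The two importance classifiers

### Feature-based network

`train_feature_model()` fits a fully connected network over features
drawn from full text: the section name (one-hot), the TextRank score of
the triple's sentence, and the taxonomy depths of the two concepts.
The architecture is the tuned one for this model family: hidden layers
of halving widths ending in a single sigmoid unit, ReLU elsewhere,
binary cross-entropy loss, depth 4, 200 epochs, no dropout. The first
layer width (default 16) and Adam step size are free settings; the
optimizer and width are not dictated by the model family, and
full-batch Adam was chosen for exact seed-reproducibility at these data
sizes.

TextRank, CUI depth, or both can be missing (no sentence text, concept
absent from the hierarchy). One model is trained per observed
*availability pattern*, and at prediction time the applicable model
using the most features wins, with ties broken by the lexicographically
first pattern identifier — a fixed, documented rule rather than an
arbitrary one. TextRank itself is the classic sentence-graph
construction: undirected edges weighted by shared-token counts
normalized by the sum of log sentence lengths, damping 0.85,
convergence tolerance 1e-6, at most 100 iterations, scores
sum-normalized to 1; the degenerate all-length-one pair falls back to
the raw overlap count. The depth feature is the shortest path from the
hierarchy root. Abstract-only deployment simply loses the TextRank
feature and routes to a reduced-pattern model.

### Masked triple language model

`train_triple_lm()` treats each triple as a three-word sentence over a
word-level vocabulary — concept identifiers have no meaningful
subwords, so no subword tokenizer is used. Training hides exactly one
of the three positions, chosen uniformly at random per example per
epoch, and optimizes softmax recovery of the hidden element from the
other two; fraction-based masking is meaningless for three-token
inputs. The vocabulary reserves mask/pad/unknown/delimiter tokens and
orders content tokens frequency-descending with lexicographic
tie-breaks, so it is reproducible; tokens beyond `vocab_size` map to
the unknown token with a warning. The two capacity knobs exposed for
tuning are the vocabulary size and the number of hidden layers.

The encoder is deliberately small: token plus position embeddings,
concatenated across the three slots, then `hidden_layers` ReLU layers
of constant width $3d$. The unmasked final activation is the triple's
embedding; `finetune_classifier()` trains a sigmoid head over these
frozen embeddings with binary cross-entropy. The decision threshold is
fixed at 0.5 throughout. A transformer implementation would be
overparameterized at the corpus sizes this package targets; the
masked-element objective, word-level tokenizer, and
embedding-then-binary-head pipeline are the load-bearing ingredients
and are preserved exactly.

## Timeslicing evaluation

`timeslice()` splits a corpus at a cutoff date $D$: *pre* is strictly
before $D$, *post* is on or after it (the boundary day had to land
somewhere; it is post, and the convention is enforced everywhere).
CHKPs generated from the pre slice are scored against gold standards
built from the post slice (`build_gold_standard()`), in three variants
of decreasing background-knowledge contamination: all post triples,
abstract-only post triples, and post triples labeled important.
Precision is the exact fraction of CHKPs found in the gold pairs;
matching is on ordered (subject, object) pairs by default, with an
unordered flag. Because "percentage precision" tables are ambiguous
between proportions and percentages, the report always carries both.
Recall is deliberately not reported: enumerating every inferable pair
trivially maximizes it, so it says nothing about usefulness. An empty
CHKP set has undefined precision (an error, not 0). CHKPs absent from
every gold standard are exported as the "as yet undiscovered"
candidates.

## The synthetic generator

`synthetic_spec()` defines desk-scale study conditions; generation is a
pure function of the spec (every random draw sits under the spec seed).
Defaults: 60 documents straddling a 2021-01-01 cutoff (one year of
pre-window, 88 days of post-window, matching a roughly three-month
training window after the cutoff), 60 concepts, 16-dimensional
embeddings, 2 novel triples per document, a shared pool of 12
background triples of which 4 are drawn into each body, and 2 planted
hidden chains. These sizes keep every stage observable (hundreds of
predications, tens of CHKPs) while the structure below makes expected
outcomes provable rather than tuned.

* **Separability by orthogonality.** Concepts and predicates used by
  novel triples occupy one coordinate block of the embedding space,
  background ones the complementary block. A novel body triple is a
  verbatim copy of an abstract triple (score exactly 3); a background
  body triple is orthogonal to every abstract triple in all three
  components (score exactly 0). Labels are exact by construction, not
  by margin tuning.
* **Planted discovery structure.** Novel subjects and objects are
  drawn from disjoint pools, so ordinary novel edges never chain; the
  only two-step walks among novel-role edges are the planted
  A→B→C chains (pre-cutoff), whose A→C realization appears
  post-cutoff. The pre-slice CHKP set over novel triples is therefore
  exactly the planted (A, C) pairs.
* **Background that chains.** The background pool is a concept path
  b1→b2→…, shared across documents (high document frequency), so
  unfiltered discovery emits background CHKPs (bi, bi+2) that appear
  in no gold standard. This reproduces, directionally, the reduction
  phenomenon: importance filtering strictly shrinks the CHKP set and
  strictly raises precision against the background-avoiding gold.
* **Gap noise ("hard mode").** With `noise_rate > 0`, novel triples
  spawn variants whose concepts are mixed-profile (cosine $1/\sqrt2$
  to the original), scoring exactly $1 + \sqrt2 \approx 2.414$ —
  inside the (1.5, 2.5) gap — to exercise the discard logic. Noise
  concepts are absent from the hierarchy, exercising the
  missing-feature model selection.

What the generator does *not* emulate: extraction noise (mislabeled
SPO roles, wrong word senses), realistic publication-date dynamics,
degree distributions of real concept graphs, or abstracts that
themselves contain background knowledge. Passing tests on this corpus
therefore demonstrate correctness of the machinery and the qualitative
filtering phenomenon, not expected precision on real literature.

## The pipeline and its closure property

`run_pipeline()` wires the stages: timeslice → similarity-label the
post slice (training data deliberately disjoint from the pre-cutoff
discovery input) → train a classifier → predict importance of
pre-cutoff triples → discover from all triples and from the important
subset → evaluate both against the gold variants. Artifacts (config,
labeled set, CHKP exports, report, JSON stage log) are persisted when
`out_dir` is set, with fixed-format numbers so reruns are
byte-identical.

The classifier is selectable: `triple_lm`, `feature`, `similarity`
(the threshold labels used directly as the filter), or `none`. The
end-to-end exactness guarantee — the filtered pipeline recovers
precisely the planted pairs with precision 1.0 — is stated for the
`similarity` mode. The reason is a real property of the data split,
worth understanding: each planted chain's linking concept B occurs
only before the cutoff, while the classifiers train on post-cutoff
labels, so B is out of their training support and their behaviour on
it is not guaranteed. The learned classifiers are instead held to a
≥90% held-out agreement standard on the separable labeled set, which
is what a learned component can honestly promise. Feature-classifier
predictions are made per predication and aggregated to triples by
"important if any occurrence is important".

## Problem sizes and degenerate inputs

The shipped tests run the generator at 10–60 documents (250 for the
classifier-recovery checks, giving >500 instances per class) and
verify the discovery algebra against brute-force enumeration on
hundreds of random graphs of up to 200 vertices; these sizes were
chosen so the full suite completes in well under a minute while every
claim is still exercised at non-trivial scale. Degenerate inputs are
defined rather than left to chance: empty corpora and empty CHKP
exports are valid, a document without abstract triples is skipped and
counted, an empty CHKP set makes precision an error, a single sentence
has TextRank 1, and a single-class availability pattern is skipped
with a warning.

## Known limitations

* The feature network and triple language model are trained full-batch;
  corpora beyond ~10⁵ labeled instances would need minibatching.
* The triple LM's generalization to concepts unseen in fine-tuning is
  limited (see the closure discussion above) — also true of the
  original modeling approach, but more visible at desk scale.
* Adjacency squaring is exact and sparse, but the CHKP set itself can
  be quadratic in vertex count for dense graphs; the package targets
  corpus scales where the export remains enumerable.
* Embedding stores are plain text and held in memory; no memory-mapped
  format is provided.
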