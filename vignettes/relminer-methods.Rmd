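---
title: "Methods: a document-level biomedical relation-extraction pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a document-level biomedical relation-extraction pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relminer)
```

## Overview

`relminer` implements a sequential pipeline over PubMed-style abstracts:
named entity recognition (NER), entity linking (EL), relation extraction
(RE), and novelty detection (ND). The document model is offset-anchored:
the annotated text of an abstract is `title + " " + abstract`, all mention
spans are 0-based half-open character intervals into that string, and the
PubTator exchange dialect is read and written losslessly
(`parse_pubtator()`, `write_pubtator()`). Relations hold between entity
*identifiers* at the document level and are undirected; an entity commonly
has several mentions in one abstract, which drives several design choices
below.

All neural components are written in base R matrix algebra with
hand-derived gradients (verified against finite differences in the test
suite), so that every mechanism is inspectable and runs on one CPU. A
pluggable "tiny encoder" — an embedding table followed by width-3
convolutional mixing layers with tanh, defaults 32 dimensions and 2 layers
— stands in for a large pretrained contextual model. It honors the same
contract a pretrained encoder would: a fixed vocabulary with special
tokens, per-token final-layer vectors, a 512-token maximum, determinism
given fixed weights, and gradients that reach the input embeddings (needed
for fine-tuning and for adversarial perturbation). Each extra layer widens
the receptive field by one token on each side; with the default two layers
a token's vector summarizes a ±2-token window.

Tokenization is whitespace-plus-punctuation with exact character spans.
The tiny encoder is word-level with an `[UNK]` fallback rather than
subword-based: with a from-scratch toy encoder, whole-word tokens keep the
offset bookkeeping exact and remove the need for subword alignment rules.

## Token NER with task-oriented tags

NER is token classification under the BIO scheme: `B-<type>` opens a
mention, `I-<type>` continues it, and outside tokens carry a *scoped*
outside label `O-<tag>`. The scope mechanism supports merging training
corpora with different annotated type inventories: each instance is
wrapped in task tokens (`<ALL>` … `</ALL>`, `<GENE>` … `</GENE>`, …)
naming the types its corpus annotates, so that a gene-only corpus never
teaches the model that an unannotated disease is a true negative. The
`ALL` tag is reserved for a corpus annotated with all six types.

Defaults in `token_ner_config()` (learning rate 3e-5, batch 16, 22
epochs, cross-entropy) are the reference recipe for a large pretrained
encoder; runs on the toy encoder need far larger learning rates (the test
suite uses 1e-2) because the network is orders of magnitude smaller.
Instances from the all-types corpus are whole abstracts, auxiliary
corpora are split at sentence boundaries; both are truncated at 512
tokens with a warning. Wrapper tokens are labeled `O-<tag>` but masked
from the loss — including them would let the model earn loss on positions
that carry no linguistic content.

Decoding repairs ill-formed label sequences deterministically and
locally: an orphan `I-` run is treated as a mention; a type change inside
a run splits it. Two post-processing rules then merge fragmented
predictions to a fixpoint: consecutive same-type mentions with no
character between them are combined (`"A"` + `"(1)-adenosine receptor"`),
and two Disease mentions separated by exactly one character that is not a
slash are combined (`"benign"` + `"tumor"`); the slash exception keeps
disjunctions like `"colon/rectal"` apart. Merged mentions reset their
identifiers, since linking happens downstream.

The alternative span head (`fit_span_ner()`) enumerates all spans up to
30 tokens, represents each as `[start vector; end vector; width
embedding]`, and classifies with a two-layer feed-forward network. The
width embedding and the greedy confidence-ordered overlap resolution are
our choices where the lineage this head follows leaves them open;
negatives are subsampled at 4× the positives per document (seeded)
because the span count is quadratic in document length.

## Entity linking

Disease and Chemical mentions are linked by dense retrieval: a residual
convolutional encoder (ResCNN) embeds mention strings and vocabulary
synonyms into one space, and candidates are ranked by cosine similarity
with identifier-level deduplication. The architecture is a frozen token
embedding layer; `n_encoder_blocks` blocks of a convolution bank (filter
widths 1/3/5, `n_filters` each, ReLU), a position-wise feed-forward
projection and a residual add; and a pooling layer (max, mean, or
attention). An initial linear projection brings the frozen embeddings to
`feature_size` so the residual additions are well-typed; widths {1,3,5}
follow common multi-width banks — neither is dictated by the lineage
design, so both are package choices. Tuned per-vocabulary optima are
exposed as `rescnn_config_disease()` (attention pooling, 4 blocks) and
`rescnn_config_chemical()` (max pooling, 3 blocks), both with learning
rate 1e-3, feature size 256, dropout 0.25, 300 filters, 100 epochs with
evaluation every 5.

Text is normalized before indexing or encoding (lowercase, collapsed
whitespace, outer punctuation stripped). The index holds one entry per
(identifier, normalized synonym) pair; training-corpus mention surfaces
are appended as additional entries before evaluation (`source =
"corpus"`), which is monotone growth and makes exact re-retrieval of seen
surfaces trivial — the intended behavior for a dictionary-backed linker.

The training objective is not fixed by the architecture, so the package
uses an online hard-negative triplet loss on cosine similarity with
margin 0.2: each mention is pulled toward the best-scoring synonym of its
gold identifier and pushed from the highest-scoring synonym of any other
identifier, negatives mined from the current index each epoch.
Ties in retrieval break by (score descending, identifier ascending); no
similarity floor is applied by default (an optional threshold exists in
`hybrid_link()`).

Gene, Species, Variant and CellLine mentions are linked by span-matching
against an external linker's prediction file: exact (start, end, type)
match first, then partial overlap of the same type — at least one shared
character, largest overlap, then leftmost. Mentions still unresolved fall
back to an exact-surface lookup dictionary built from the external
predictions (most frequent identifier per (type, surface)). Hybrid
linking never alters spans or types, only identifiers.

## Relation extraction

Candidate pairs are all unordered pairs of distinct linked identifiers
whose type combination occurs with at least one gold relation in the
training corpus (the allowed set is recomputed at training time and
stored with the model); pairs without a gold relation are `NoRelation`
negatives, not subsampled by default since abstracts yield few pairs.
For each candidate, every mention of both entities is wrapped in the
single untyped marker pair `[E]` … `[/E]` — one marked sequence per
candidate pair, markers only on that pair's mentions — and the open
marker's final-layer vector represents its mention.

With mention sets `M1`, `M2`, prediction selects the mention pair with
the highest dot product (max pooling over pairs), builds the two
directional representations `[e1; e2; e1⊙e2]` and `[e2; e1; e2⊙e1]`,
passes both through one linear classifier over the nine labels, and sums
the logits before the argmax — which makes the prediction exactly
invariant under exchanging the entity roles, the core bidirectionality
property. The training loss is the sum of both directions'
cross-entropies.

One training-time choice is the package's own: the hard argmax over
mention-pair dot products gives the pair ranking no gradient, and from a
random initialization the selection cannot learn which mentions matter.
Training therefore pools the pair representations with a softmax over the
dot products (temperature `re_config()$pair_temperature`, default 1.0) —
a smooth relaxation of exactly the same max pooling, in the same spirit
as the logsumexp pooling the novelty model uses — while inference keeps
the hard argmax. Tie in summed logits resolves to the lowest label index
with `NoRelation` ordered last, so a tie never invents a relation.

Adversarial training follows the three-step projected-gradient-descent
recipe: after each batch's clean update, the input token embeddings are
perturbed three times along the normalized loss gradient (step 0.3) with
the accumulated perturbation projected onto an L2 ball of radius 1.0
(Frobenius norm over the sequence's embedding matrix), and the model is
updated on the perturbed input. Only the step count is fixed by the
recipe; the norm, radius and step size are package defaults exposed in
`adversarial_config()`. The perturbation is applied to the full input
embedding matrix, marker positions included.

## Novelty detection

The novelty model reuses the marker machinery but replaces pair selection
with logsumexp pooling over *all* mention markers of each entity —
`max(x) ≤ logsumexp(x) ≤ max(x) + log n` coordinate-wise, so every
mention contributes with smooth max-like weighting. The two pooled entity
vectors are concatenated (entity order canonicalized by sorted
identifiers, making the representation well-defined for undirected pairs)
and classified Novel / No. Training uses only pairs that carry a gold
relation — no negative examples, since in the pipeline the inputs already
have an identified relation — and fine-tunes its own encoder, separate
from the RE encoder. Defaults: 4 epochs, learning rate 2e-5, batch 32,
Adam. The `{Novel, No}` label strings follow the benchmark release; the
parser's alias table also absorbs `None`.

## Evaluation

All metrics are micro-averaged from pooled counts and reported on the
percent scale at two decimals with half-up rounding (matching how such
tables are conventionally printed; `round()`'s round-half-even would
differ on exact midpoints). NER counts exact span+type matches as true
positives and reports partial matches (span overlap, same type)
separately while still counting them as errors. EL compares document-level
(PMID, type, identifier) tuple *sets*: multi-identifier mentions expand
into multiple tuples and repeats collapse. Relation matching keys on
(PMID, sorted pair), optionally extended by type and by novelty; dropping
the type gives binary relation classification. The bootstrap draws 100
documents with replacement 1000 times (both defaults overridable),
computes each system's overall F1 per sample, and reports the mean
difference with a 2.5/97.5 percentile interval from a single seeded
generator. McNemar's test defaults to the exact two-sided binomial form
(`2·P(X ≤ min)` capped at 1), with the continuity-corrected chi-square
variant behind a flag, as the exact variant is well-defined for the small
discordant counts typical here.

## The synthetic generator — what it does and does not show

`synthetic_spec()` fixes the toy study conditions: 200 training and 50
development abstracts at seed 7; entity inventories of 30 genes, 25
diseases, 20 chemicals, 10 variants, 6 species, 5 cell lines with unique
pronounceable stems; 2–5 vocabulary synonyms per Disease/Chemical
identifier built from casing, generic-word swaps, plurals, suffix tokens
and abbreviations, with one extra variant per identifier held out of the
vocabulary and used for 10% of mention surfaces (so the linker must
generalize, not only memorize); 2–5 entities and 1–3 relations per
document; mention counts per entity distributed 60/30/10% over 1/2/3;
relation types skewed as in real benchmark corpora (the three dominant
types ≈ 96%); novelty Novel with probability 0.5; span-boundary and
unlinked-mention noise available but 0 by default.

Relations are realized as trigger sentences — a type-specific trigger word
immediately before each of the two mentions, with a sentence-initial
lexical cue ("previously" for background, "notably" for novel) — and
extra mentions appear in one of three background sentence templates.
Two template decisions matter for learnability and are deliberate: the
two mentions of a relation are separated only by the trigger, so the
partner's closing marker lies inside the default encoder's ±2 receptive
field; and background templates vary, because a single repeated template
would give all plain mentions near-identical contextual vectors — both
unrealistic and degenerate for dot-product pooling. A rule-based oracle
(`oracle_relations()`) reads the triggers back and attains F1 = 100 on
zero-noise corpora, establishing that the generated signal is complete.

Passing the seeded recovery suite (token NER micro-F1 ≥ 0.90, linker
top-1 ≥ 0.95 on clean mentions, RE micro-F1 ≥ 0.80, ND accuracy ≥ 0.85,
and byte-identical pipeline reruns) therefore shows that each mechanism —
tagging, retrieval, marker-based bidirectional classification, pooled
novelty classification — can recover structure it is designed to carry,
end to end, deterministically. It does not show performance on real
biomedical language: the generator has no ambiguous surface forms shared
across identifiers, no discontinuous or nested gold mentions, no
relations whose evidence spans sentences without a trigger, and its
lexical novelty cue is far cleaner than rhetorical novelty in real
abstracts. Scores on these corpora are upper bounds of mechanism
correctness, not estimates of benchmark performance.

## Numerical and reproducibility choices

Optimization is Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) throughout, with
Gaussian fan-in-scaled initialization. Cross-entropies and logsumexp are
max-shifted; cosine computations guard zero norms at 1e-12. Every source
of randomness funnels through an internal `with_seed()` that restores the
caller's RNG state, so corpus generation, weight initialization, batch
shuffling, dropout masks and negative mining are all bit-reproducible
given the configured seeds, and prediction paths consume no randomness at
all — which is what makes whole-pipeline reruns byte-identical. String
orderings that feed any computation (vocabulary order, candidate-pair
enumeration, type-pair keys) use radix sorting, so results do not depend
on the session locale's collation. Test-suite and acceptance runs use the
problem sizes quoted above (200/50 documents, 32-dimensional encoder,
reduced ResCNN: 2 blocks, 32 filters, feature size 48) — chosen so the
full suite exercises every training loop in a few minutes of one CPU.

## Known limitations

Candidate pairs are generated per document only (no cross-document
relations), relation direction is not recovered (the benchmark's
relations are undirected), nested predicted mentions are resolved away by
the span head and never produced by the token head, and the EL module
does not attempt context-sensitive disambiguation: the mention string is
the encoder's only input, so two identical surfaces always link to the
same identifier regardless of context. The auxiliary-corpus format
adapter covers the PubTator dialect; BioC XML is out of scope.
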