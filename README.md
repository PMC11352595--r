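# relminer

An R implementation of an end-to-end pipeline for document-level biomedical
relation extraction from PubMed-style abstracts. Four tasks run sequentially
over each abstract:

1. **NER** — locate typed entity mentions (Gene, Disease, Chemical, Species,
   Variant, CellLine) as character spans;
2. **EL** — normalize each mention to a controlled-vocabulary identifier
   (e.g. MEDIC for diseases, CTD for chemicals);
3. **RE** — classify every candidate pair of entity identifiers into one of
   eight undirected relation types (Association, Positive_Correlation,
   Negative_Correlation, Bind, Comparison, Conversion, Cotreatment,
   Drug_Interaction) or no relation;
4. **ND** — label each extracted relation as a *novel* finding of the paper
   versus previously known background.

The package is aimed at text-mining researchers who want the pipeline's
mechanisms as inspectable, testable R code: every model is built from
explicit matrix algebra with hand-derived gradients, and a seeded
synthetic-corpus generator with a tiny pluggable contextual encoder lets the
whole pipeline train and evaluate on one CPU in minutes.

## The models

**Token NER.** BIO sequence labeling (`B-<type>` / `I-<type>` / scoped
`O-<tag>`) with a softmax head over contextual token vectors, trained with
cross-entropy. Multiple corpora with different annotated type inventories
are merged by wrapping each instance in *task tokens* (`<ALL>`, `<GENE>`,
...) and scoping the outside labels (`O-ALL`, `O-GENE`, ...), so a
gene-only corpus does not teach the model that unannotated diseases are
negatives. Predicted fragments are merged by two post-processing rules
(zero-gap same-type merge; one-character non-slash gap between diseases).
An alternative span-classification head scores all token spans up to width
30 with a two-layer feed-forward network.

**Entity linking.** A residual convolutional mention encoder (ResCNN):
frozen token embeddings, then blocks of a multi-width convolution bank, a
position-wise feed-forward layer and a residual connection, then max / mean
/ attention pooling into a fixed-size vector. Identifier synonyms are
embedded into an index and mentions retrieve candidates by cosine
similarity; training uses an online hard-negative triplet loss. Entity
types without a trained encoder are linked by span-matching against an
external linker's predictions, with an exact-surface lookup dictionary as
fallback.

**Relation extraction.** Every mention of a candidate pair is wrapped in
untyped marker tokens `[E]` ... `[/E]`. With marker embeddings `e1`, `e2`
the pair is represented bidirectionally as

    v_fwd = [e1; e2; e1 ⊙ e2],   v_rev = [e2; e1; e2 ⊙ e1]

and the loss is the sum of both directions' cross-entropies; at prediction
the two logit vectors are summed, so the decision is exactly invariant
under exchanging the entities. With several mentions per entity the mention
pair with the highest dot product is selected (max pooling over pairs).
Training additionally perturbs the input token embeddings three times by
projected gradient descent (PGD) within an L2 ball and fits the perturbed
inputs, for robustness.

**Novelty detection.** For each extracted relation, all mention marker
embeddings of each entity are pooled coordinate-wise with logsumexp — a
smooth version of max pooling satisfying
`max(x) ≤ logsumexp(x) ≤ max(x) + log n` — and the two entity vectors are
concatenated and classified Novel / No. Only pairs with an identified
relation are used for training (no negative examples).

**Evaluation.** Document-level micro precision / recall / F1 throughout:
NER by exact span+type match (partial matches reported separately), EL by
(PMID, type, identifier) tuple sets, RE by (PMID, pair [, type] [, novelty])
keys with pairs canonicalized as unordered. Top-k retrieval accuracy,
bootstrap resampling of F1 differences, McNemar's exact test, and an RE
error breakdown (type confusion vs non-related) complete the module.

## Worked example

```r
library(relminer)

spec  <- synthetic_spec(seed = 7)          # the toy study conditions
train <- make_corpus(spec, 60, "train")
dev   <- make_corpus(spec, 20, "dev")
print(train)
#> <corpus: 60 documents, 400 mentions, 106 relations>

st <- corpus_stats(train)
print(st$relation_share_pct[1:3])
#>          Association Positive_Correlation Negative_Correlation
#>                41.51                31.13                24.53

enc <- make_tiny_encoder_for(spec)         # 32-dim toy contextual encoder
re  <- fit_re_corpus(train, enc,
                     re_config(epochs = 8, learning_rate = 1e-3, batch_size = 16),
                     adv = adversarial_config(), seed = 42)
pred <- corpus(lapply(dev, function(d)
  document(d$doc_id, d$title, d$abstract, d$mentions,
           predict_doc_relations(re, d))))
prf <- prf_from_counts(match_relations(dev, pred))
cat(sprintf("RE micro-P/R/F1 on held-out docs: %.2f / %.2f / %.2f\n",
            prf$precision, prf$recall, prf$f1))
#> RE micro-P/R/F1 on held-out docs: 90.00 / 93.10 / 91.53
```

The three dominant relation types carry most of the probability mass by
design, mirroring the skew of real benchmark corpora, and the relation
extractor recovers the planted document-level relations with high micro-F1
from gold entities. Corpora read and write losslessly in the PubTator
exchange format (`parse_pubtator()` / `write_pubtator()`).

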