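---
title: "Methods: drug-target relation extraction with dtirex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-target relation extraction with dtirex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtirex)
```

## The task and the pipeline

Given an abstract with annotated chemical and gene/protein mention spans,
the task is to assign zero or more of 13 interaction types to each
chemical–gene pair. `dtirex` treats this as sentence-level multi-label
classification: every chemical–gene pair whose two spans fall inside the
same sentence becomes one instance; the candidate pair is localized with
entity marker tokens; an encoder maps the (optionally
description-augmented) text to a context vector; a fully connected layer
produces 13 sigmoid probabilities; probabilities from an ensemble of
seed-varied models are averaged and thresholded per class; predictions are
scored against gold tuples with micro-averaged F1.

This vignette records the modelling assumptions, the tunable parameters
and their defaults, the numerical choices, and what the synthetic-data
experiments do and do not demonstrate.

## Corpus dialect and offsets

Corpus files are plain UTF-8 TSVs without headers. A document's working
text is `title + TAB + abstract`; all character offsets are 0-based,
half-open, over raw code points of this concatenation (the convention of
the DrugProt distribution; stated here explicitly because it is easy to
get wrong by one). `read_entities()` verifies every mention's surface
string against its offsets, and refuses mentions that straddle the
title/abstract tab rather than guessing their sentence. Gold relation
files may repeat tuples; predictions are deduplicated and sorted on
write so output files are deterministic.

The entities TSV accepts an optional seventh column carrying the
normalized identifier (MeSH for chemicals, NCBI Gene for `GENE-Y`), which
is how already-normalized corpora feed the description augmentation;
`GENE-N` mentions simply leave it empty. External annotation and
normalization services are out of scope: the package consumes their
output, it does not call them.

## Sentence splitting

No splitter is bundled with the corpora, so the package fixes a
deterministic rule: a sentence boundary is a run of `.?!` followed by
whitespace and an uppercase letter or digit, unless the token ending at
the punctuation is on a small abbreviation stop-list (`e.g.`, `i.e.`,
`Fig.`, `et al.`, ...). The title is always its own sentence. The same
rule powers `first_sentence()`, which implements the convention of using
only the first sentence of a chemical's CTD definition. The rule is
simple, dependency-free and idempotent; it will split differently from
trained sentence models on unusual prose, which mainly shifts which
pairs count as same-sentence. Cross-sentence gold relations are excluded
from instance generation but counted (`unreachable_gold`), because they
bound attainable recall.

## Instance construction

Markers are inserted as `[HEAD-S] `/` [HEAD-E]` around the chemical and
`[TAIL-S] `/` [TAIL-E]` around the gene, start markers carrying a
trailing space and end markers a leading one, so deleting the four fixed
marker-plus-space strings restores the sentence byte for byte
(`strip_markers()` is the exact inverse; this invariant is tested).
Insertion works on the four boundary offsets from the sentence slice
directly, so earlier offsets are never invalidated. Pairs with
overlapping chemical/gene spans (possible in noisy annotations) are
skipped with a warning rather than producing ambiguous markup.

Candidate pairs with no gold annotation carry the all-zero label; there
is no explicit NONE class, matching the thresholding scheme where "no
probability reaches its threshold" is the negative outcome.

Augmented model text is `marked_text [SEP] chem_desc [SEP] gene_desc`.
The literal `[SEP]` string is encoder-agnostic; a transformer adapter is
free to re-map it to its native separator. A whitespace-token budget
(default 512) caps the text; the marked sentence is kept whole because it
carries the pair and its label signal, then the chemical description,
then the gene description is truncated. Descriptions are stored verbatim
and truncated only here.

## The 576 protein sequence descriptors

The descriptor vector is a fixed concatenation: 20 monopeptide
frequencies (alphabetical one-letter order), 400 dipeptide frequencies
(row-major over the same order, overlapping pairs divided by L−1), and
156 physicochemical features. Non-standard residues (B, J, O, U, X, Z)
are removed before counting — the 20/400 block sizes mandate the standard
alphabet — with a message reporting the removal count.

The 156-feature block is a documented manifest
(`physchem_manifest()`, shipped as `inst/extdata/physchem_manifest.tsv`):

* six whole-sequence features: length, molecular weight (free amino acid
  masses of the Fasman 1976 scale minus one water, 18.01524 Da, per
  peptide bond), aromaticity (fraction F/W/Y), instability index
  (Guruprasad et al. 1990 dipeptide weights, scaled by 10/L), GRAVY
  (mean Kyte–Doolittle hydropathy) and isoelectric point;
* 15 statistics for each of ten AAindex scales — Kyte–Doolittle
  hydropathy, Vihinen flexibility, Charton–Charton polarizability and
  free energy of solution, Charton steric parameter, Grantham polarity,
  Zimmerman residue isoelectric point, Bigelow volume, Fasman residue
  mass, Hopp–Woods hydrophilicity — namely mean, sd, min, max of the
  per-residue profile and normalized Moreau–Broto autocorrelations at
  lags 1–11 (profiles standardized by each scale's own 20-value mean and
  sd; lags beyond the sequence length are 0). For the flexibility scale
  the four summary statistics are computed on 9-residue sliding-window
  means, the conventional presentation of flexibility profiles.

Scale values are read at runtime from the AAindex database shipped with
`seqinr`, keyed by accession, so the exact numbers are auditable
configuration rather than hidden constants. The isoelectric point uses
the EMBOSS pK set (N-terminus 8.6, C-terminus 3.6, K 10.8, R 12.5,
H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1) with bisection on [0, 14] to a
residual charge below 1e−9; pI values from other pK tables (e.g.
Bjellqvist) differ by a few tenths of a unit, which matters only if
descriptors from different tools are mixed. `l2_normalize()` implements
the unit-Euclidean-norm preprocessing used when descriptors are fused
with text embeddings; all-zero vectors are returned unchanged with a
warning rather than producing NaN.

## Encoder contract and reference encoder

An encoder is anything mapping texts to fixed-length vectors — the role
of a transformer's `[CLS]` context embedding. The contract
(`custom_encoder()`) demands only determinism given configuration and
seed, and a fixed output dimension; heavyweight pretrained backbones sit
behind it without changing any other stage, and are deliberately not
bundled or fine-tuned here.

The reference implementation, `hashed_encoder()`, is a seeded
feature-hashing bag-of-tokens encoder: whitespace tokenization
(lowercased; marker and `[SEP]` tokens survive as tokens), a seeded
31-multiplier rolling hash mod 2^24 (kept exact in doubles) into `dim`
buckets with a second hash choosing the sign, counts accumulated and each
row L2-normalized. Default `dim = 512`: small enough to train in seconds,
large enough that hash collisions among a few hundred corpus tokens are
rare; at 128–192 buckets collision noise measurably degrades a
trigger-separable corpus.

## Loss, optimization and numerical safety

The focal loss is used exactly as summed over instance–class terms,

$$\mathrm{loss} = -\sum_i\big[y_i (1-p_i)^{\gamma}\log(p_i+\epsilon) +
(1-y_i)\, p_i^{\gamma}\log(1-p_i+\epsilon)\big],$$

with defaults $\gamma = 0.5$ and $\epsilon = 10^{-6}$; `loss = "bce"`
selects the $\gamma = 0$ special case (the package verifies the exact
reduction against an independent cross-entropy oracle). `focal_loss()`
reports the summed form as written; inside the trainer the gradient is
divided by the number of instances so that the step size does not depend
on corpus size. Probabilities are clamped to $[10^{-7}, 1-10^{-7}]$
before the loss: $\epsilon$ alone does not bound $\log(1-p+\epsilon)$ as
$p \to 1$ in floating point, and the clamp also keeps the
$(1-p)^{\gamma-1}$ gradient factors finite.

Training is full-batch gradient descent with Adam (moment decays
0.9/0.999), `learning_rate = 0.3`, `epochs = 1000`, and a small L2
penalty on the head weights (`weight_decay = 3e-5`, bias excluded). The
source does not state optimizer settings, so these are the package's own
defaults, chosen once: full-batch updates keep runs bit-reproducible
(same seed, same state — serialized states compare identical); the weight
decay concentrates logit mass on tokens that recur across many instances
of a class instead of tokens that co-occur with a label a handful of
times, which is what makes the head generalize from lexical signal; much
larger decay caps trigger-token weights below what the 0.5 decision
threshold requires and collapses recall, so the value is deliberately
small. A single integer seed drives weight initialization (and the
encoder's hash seed is set per member), with the RNG state restored
afterwards. Non-finite weights or loss abort with a diagnostic naming
the epoch, seed and learning rate — seed-dependent non-convergence is a
real phenomenon in this family of models and should fail loudly, not
silently.

Sequence descriptors are fused by concatenation with the context vector
(`fuse_features()`), optionally through a seeded random Gaussian
projection; the descriptor rows are expected L2-normalized.

## Ensembles and thresholds

`average_probs()` is the unweighted element-wise mean of the members'
probability matrices — members are interchangeable peers; no weighting or
voting. Thresholds are inclusive (`>=`), so a probability of exactly 0.5
is predicted at the default threshold. Per-class overrides exist for rare
classes whose probabilities are systematically depressed by their scarce
training signal; the `CGDE` preset accepts `AGONIST-INHIBITOR` (about
0.1 % of gold relations) at `>= 0.2` instead of `>= 0.5`. No other class
receives an override in any preset. The five presets (`SBE`, `GDE`,
`CDE`, `CGDE`, `SFTDE`) differ only in which augmentations the members
see (none / gene / chemical / both / gene + sequence features) and in
that override. Lowering a threshold can only add predictions
(monotonicity; tested).

## Evaluation conventions

Matching is exact on `(doc_id, rtype, arg1, arg2)` after collapsing both
sides to sets — the tuple semantics of challenge scorers. Metrics are
reported on the 0–100 scale. The 0/0 conventions are explicit: a
precision or recall whose denominator is 0 while the opposite count is
nonzero is 0; a class with no gold and no predictions reports zeros with
an `empty_class` flag; and only when gold and predictions are both empty
overall are micro metrics reported as 100 with an `empty` flag (nothing
to find, nothing wrongly found). Other scorers may choose differently in
these corner cases; the flags make the situation auditable.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` produces documents whose abstract sentences each
contain one chemical and one gene mention plus filler words, with the
gold class drawn from a configurable distribution
(`drugprot_class_prior()` mirrors the real training-set skew: INHIBITOR
dominant, AGONIST-INHIBITOR near 0.1 % — of the published counts only
the five stated ones are used; the remaining types carry plausible
mid-range weights). Three design choices matter:

* **Trigger lexicon.** Each class owns one unique, otherwise-unused
  lexeme; at `trigger_strength = 1` every positive sentence contains its
  class trigger, so the corpus is linearly separable in any
  bag-of-tokens space *by construction*. End-to-end learnability tests
  are therefore constructive guarantees, not empirical luck.
* **Pooled entity surfaces.** Chemical and gene names are drawn from
  finite pools and recur across documents, as compound names and gene
  symbols do in real literature. Unique-per-pair names would let the
  head memorize entities instead of learning the relation signal and
  would make held-out generalization unmeasurable. Chemicals keep one
  MeSH ID per surface; gene mentions get mention-unique NCBI IDs (gene
  symbols are ambiguous; normalization is assumed done), which is what
  allows pair-specific description cues.
* **Description-borne signal.** With `description_informativeness > 0`,
  a positive pair whose sentence trigger was withheld plants its class
  cue in the gene's description instead. At `trigger_strength = 0,
  informativeness = 1` the relation is invisible from the sentence alone
  — the synthetic analogue of an abstract that mentions an exposure and
  a gene while only background knowledge about the gene reveals the
  interaction type. On such corpora the gene-description ensemble beats
  the sentence-only ensemble by a wide margin (about 0.92–0.98 vs
  0.04–0.11 held-out micro-F1 at the 300-document size), reproducing the
  qualitative benefit of description augmentation.

The generator does **not** simulate realistic biomedical prose: no
multi-pair sentences (instance enumeration is instead tested on separate
random documents with several mentions per sentence), no coreference, no
nested or overlapping mentions, no annotation noise beyond an optional
label-flip rate. Passing its tests shows the machinery is correct and
that the architecture can exploit sentence- and description-level signal;
it says nothing about absolute performance on real abstracts, which is
dominated by encoder quality.

A ledger accompanies every generated corpus, recording each pair's class
and where its signal lives; it is the exact oracle the tests compare
against (gold counts, reachable pairs, cue placement).

## Problem sizes and runtime

Validation experiments use corpora of 40–300 documents (roughly 130–1000
training instances), 512 hash buckets, 1000 Adam steps and 3-seed
ensembles — sizes chosen so the full suite runs in about two minutes on
one CPU while leaving the end-to-end margins wide (separable corpora
score ≥ 0.99 held-out micro-F1 across seeds against the 0.95 bar). The
test-set split is 25 % of documents, sampled by document so no sentence
leaks across the split.

## Known limitations

* The bundled encoder is a bag of hashed tokens: no word order, no
  subwords, no pretraining. It is the reference implementation of the
  encoder contract, not a competitive biomedical language model.
* The sentence splitter is rule-based; prose with unusual punctuation
  will shift sentence boundaries and hence the same-sentence pair set.
* Only same-sentence pairs are modelled; document-level relations are
  counted as unreachable rather than extracted.
* The 156 physicochemical features are a documented, reproducible
  manifest covering the named property families; other descriptor
  toolkits will produce different (equally valid) 156-feature choices,
  so vectors are comparable only within one manifest.
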