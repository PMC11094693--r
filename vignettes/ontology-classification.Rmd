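---
title: "Learning chemical ontology placement from SMILES"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning chemical ontology placement from SMILES}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OntoSmiles)
```

## The problem

A curated chemical ontology such as ChEBI arranges classes of molecules in
a subsumption (is_a) hierarchy below a root like *chemical entity*. Many
classes carry a SMILES string describing their structure. Placing a novel
structure means predicting which existing classes subsume it — a multi-label
classification problem whose labels are themselves partially ordered. This
package implements that pipeline: select label classes from the ontology,
build transitively-labeled datasets, tokenize SMILES, train a Transformer
encoder with a class-balanced loss, and evaluate predictions in ways that
respect the hierarchy.

Only the is_a fragment of the ontology defines the label structure here.
Other OBO relationship types (parthood, functional parent) and logical
axioms are deliberately ignored: subsumption is what the classifier
predicts, and mixing in other relations would conflate "is a kind of" with
"is related to".

## From ontology to dataset

**Label selection.** A class becomes a label when it is a proper transitive
subclass of the chosen root and has at least `minMembers` proper transitive
subclasses carrying a SMILES annotation. A class's own SMILES does not
count toward its member count — membership is about how many training
examples the class can contribute, and the class itself contributes at most
one. (If the other convention is ever wanted it is a one-line change in
`memberCount`.) Two thresholds matter in practice on ChEBI release 200:
100 members (854 labels) and 50 members (1332 labels); lowering the
threshold can only widen the selection, which the test suite checks as a
monotonicity property. Labels are ordered by a locale-independent
lexicographic CURIE sort so that column indices are reproducible across
machines.

**Labeling.** Every SMILES-annotated proper subclass of the root becomes a
training molecule; its binary label vector marks each selected label that
is a proper transitive superclass of its class. This transitive closure
implies a structural invariant — an ancestor's label column dominates a
descendant's elementwise — that must hold for every dataset the builder
produces, and is asserted over random fixtures in the tests. Molecules
whose ancestors contain no selected label keep an all-zero row by default
(a flag drops them): they are legitimate inputs a model should learn to
say little about, and silently removing them would bias the split sizes.

**Molecule identity.** Molecules are identified by their class CURIE, not
by their SMILES text. Chemical ontologies contain distinct classes with
identical structures (stereo-unspecified duplicates and the like), and no
structure normalization or deduplication is attempted — the dataset
mirrors the ontology as it is. Whether identical SMILES may occur on both
sides of the train/test split is therefore governed by the ontology, not
by the package; the default is to leave them.

**Splitting.** The standard split is 85% train, 2.25% validation, 12.75%
test, assigned by a seeded Fisher–Yates permutation and largest-remainder
rounding (ties broken train > test > validation, so the single molecule of
a degenerate dataset trains rather than tests). On 10000 molecules this
gives exactly 8500/225/1275.

**Cross-version protocol.** To compare models trained on two releases of
an ontology, the newer release's dataset is split first; the older
release's dataset is then built excluding every molecule in the newer test
set and split 97.75/2.25 into train/validation only. Both models are
evaluated on the same test molecules, with the test labels reduced to the
older release's label set (classes that fell below the threshold in the
older release simply have no column). Zero split fractions are allowed in
`splitConfig` precisely so this protocol is expressible.

## Tokenization

SMILES are tokenized by a greedy longest-match scan over an explicit
inventory: bracket atoms `[...]` as single tokens (isotope, chirality,
H-count, charge and class included), the two-letter halogens `Cl` and
`Br`, single-letter organic-subset and aromatic atoms, bond symbols, ring
closure digits and `%nn` pairs, branch parentheses, dot and stereo
slashes. The defining property is losslessness: concatenating the tokens
reproduces the input exactly, checked on 10000 generated strings. A naive
character split would read `Cl(O)O` as a carbon followed by a stray `l`;
here `Cl` stays one chlorine token. Characters outside the alphabet fail
immediately with their position — at tokenization time, not at encoding
time — so corpus errors surface before any training. The unknown-token
index exists only for vocabulary misses at encoding time (a token seen at
prediction that was absent from the training corpus).

## Class-balanced loss

Ontology-derived datasets are extremely imbalanced: generic classes have
tens of thousands of members, specific ones barely pass the selection
threshold. The loss therefore weights each label class C by the inverse of
its *effective number*

$$E_{|C|} = \frac{1-\beta^{|C|}}{1-\beta}, \qquad
  w_C = \frac{1-\beta}{1-\beta^{|C|}},$$

the expected coverage of |C| potentially overlapping unit volumes: each
additional member of an already-large class adds less new information.
With the default β = 0.99, weights range over (0.01, 1], equal 1 for
singleton classes and decrease strictly with class size; β = 0 disables
the re-weighting (all weights 1) and β → 1 approaches inverse-frequency
weighting. The weights multiply the whole per-label binary cross-entropy
(both the positive and the negative term): weighting only the positive
term would change the decision threshold semantics per class, and the
chosen form keeps the weighted loss a plain reweighting of the standard
one. No renormalization of the weights is applied by default; a
`rescale` flag restores the sum-to-class-count variant some
implementations use. Probabilities are clamped at 1e-12 before the
logarithm.

## The encoder

The classifier is a pre-norm Transformer encoder — learned token and
position embeddings, per block LayerNorm → multi-head self-attention →
residual and LayerNorm → GELU feed-forward → residual, a final LayerNorm,
and a sigmoid multi-label head read from the sequence-start (CLS)
position. Forward and backward passes are hand-written base-R matrix code
(the linear projections are single BLAS calls over the whole batch; only
the T×T attention products loop over samples and heads), optimized with
Adam. This keeps the attention mechanism — and therefore the per-layer,
per-head attention maps that make predictions inspectable — while staying
trainable from scratch in seconds to minutes on one CPU.

Defaults (2 layers, 4 heads, width 32, feed-forward 64, max length 24,
dropout 0.1, learning rate 3e-3, batch 64) are sized for the synthetic
benchmark below; they are configuration, not architecture. Model selection
keeps the parameters of the epoch with the best validation micro F1;
`patience` optionally stops training after that many epochs without
improvement. All randomness — initialization, batch shuffling, dropout —
derives from the single `seed`, so a seed fixes the entire loss
trajectory. Inference applies no dropout and is invariant to the batch
size. The decision threshold defaults to 0.5 with the ≥ convention;
nothing in training calibrates a threshold, so it is exposed per
prediction call. The numeric corner cases are handled conservatively:
attention scores are max-shifted before exponentiation, padding positions
are masked out of the keys in every layer (so they can never influence
valid positions), and a non-finite training loss aborts with an error
rather than continuing silently.

## The synthetic benchmark

Real ontology snapshots are hundreds of megabytes; the package instead
ships a generator that reproduces the *statistical shape* of the task at
test scale. A seeded random DAG provides the hierarchy; a configurable
number of "concept" classes (direct children of the root) each receive a
unique single-token SMILES motif from a fixed pool (halogens, charged and
bracketed atoms); molecules are new leaf classes below one concept
(optionally also below a second, size-proportionally sampled concept, and
below motif-bearing subconcepts when a two-level hierarchy is wanted),
whose SMILES concatenate the motifs of all their concept ancestors in
random order, separated by unbranched alkyl filler. Class sizes follow a
log-uniform draw over a configurable range, with one concept pinned to
each end so the realized spread always spans at least an order of
magnitude; the default benchmark has 20 concepts and 2000 molecules.

Because every label is decodable from token content by construction,
"the model learns the task" is a stable acceptance property, certified
independently by a bag-of-tokens ridge-logistic baseline (macro F1 ≥ 0.9).
What the generator does **not** emulate: chemical validity of the
generated structures (the filler-motif concatenations are token-level
constructs, not valence-checked molecules), realistic SMILES grammar
diversity (rings, branches and stereochemistry appear in tests of the
tokenizer, not in the benchmark molecules), label noise, and the depth
structure of real ontologies beyond two levels. Passing the benchmark
therefore demonstrates that the pipeline's machinery — closure labeling,
weighting, optimization, evaluation — works end to end; it does not
certify chemical accuracy on real data, which depends on scale and
pre-training far beyond a desk run.

## Evaluation choices

**Micro F1** is datapoint-averaged: the mean over molecules of the F1
between predicted and true label sets. This matches the "how good is a
typical prediction" reading; the pooled-count micro F1 used by some
toolkits weights molecules by their label counts instead, and is available
behind `micro = "pooled"` for comparability. A molecule with empty truth
and empty prediction scores 1 (the model was right to say nothing).

**Macro F1** averages per-label F1. Labels with neither a true nor a
predicted positive in the evaluated partition are excluded from the mean
and reported (scoring them 0 would punish a model for classes absent from
the partition; scoring them 1 would reward it for nothing); labels with
truths but no correct predictions score 0.

**Specificity.** Three views, all over the subsumption order: the
path-length histogram from correct non-redundant predictions to the root
(deeper is more specific, and redundant superclasses are first removed so
one deep hit is not double-counted through its ancestors); the distance
between asserted and predicted parents (0 is the best case — the model
names the exact asserted parent; only pairs where the prediction is the
parent or one of its superclasses are comparable, and molecules with no
comparable pair are excluded and counted); and the four-way comparison of
two models, which classifies every (molecule, correct prediction C1 of
model A) pair by what model B got right on the same molecule: the same
class → equally specific; a proper subclass of C1 → A is less specific; a
proper superclass → A is more specific; nothing comparable → not
comparable. Equality is checked first, then the subclass case, then the
superclass case — a deterministic total rule for the (rare) case where B
predicts classes on both sides of C1. Pairs rather than molecules are the
counting unit, so the four percentages partition the pairs and sum to 100.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the full pipeline at the
scales the package's own benchmarks define: 2000 molecules / 20 labels for
learnability (12 epochs, three seeds), 1000 molecules / 8 labels for the
weighting comparison (8 epochs, both arms at equal epochs), 1200 molecules
/ 6+12 labels for the two-granularity specificity comparison, and
10000 molecules for the split arithmetic. Oracle equivalences (exhaustive
DFS path enumeration, igraph shortest paths, hand-computed F1 values) run
on graphs of at most a dozen nodes where brute force is exact. Ties,
rounding and degenerate inputs follow the conventions documented above:
largest-remainder apportionment with the train > test > validation tie
order, ≥ at the decision threshold, clamped logarithms, and lexicographic
label order throughout.

## Known limitations

The encoder is trained from scratch per dataset; no pre-training on an
external molecule corpus is attempted, which is the main reason results on
real ontology snapshots would trail a large pre-trained model. The OBO
reader covers the tags the pipeline needs (id, name, is_a, is_obsolete,
the SMILES property) rather than the full OBO specification. Curation
status (e.g. ChEBI's star ratings) is not used to filter classes. The
specificity comparison requires both models' predictions over the same
molecules; it does not align label sets beyond the subsumption order
itself.
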