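#' @import methods
#' @importFrom stats rnorm runif setNames predict glm.fit binomial
#' @importFrom utils head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' OntologyGraph: a directed acyclic subsumption graph
#'
#' Container for the is_a (subsumption) fragment of a chemical ontology such
#' as ChEBI. Classes are identified by CURIEs (e.g. \code{"CHEBI:24431"});
#' each class may carry a SMILES annotation. Edges run child -> parent and
#' only is_a relationships are represented; other OBO relationship types
#' (parthood, functional parent, ...) are deliberately not part of the
#' subsumption order.
#'
#' @slot ids character vector of class CURIEs (unique, non-empty).
#' @slot classNames character vector of human-readable names, parallel to
#'   \code{ids}.
#' @slot smiles character vector parallel to \code{ids}; \code{NA} where a
#'   class carries no SMILES annotation.
#' @slot parents list parallel to \code{ids}; each element the character
#'   vector of direct is_a parents (possibly empty, no duplicates).
#' @slot metadata list of free-form provenance (source file, generator seed,
#'   concept assignments for synthetic graphs, ...).
#'
#' @seealso [loadOBO()], [transitiveSuperclasses()], [selectLabelClasses()],
#'   [countPaths()], [generateOntology()]
#' @export
setClass("OntologyGraph",
  representation(
    ids = "character",
    classNames = "character",
    smiles = "character",
    parents = "list",
    metadata = "list"
  ),
  prototype(
    ids = character(), classNames = character(), smiles = character(),
    parents = list(), metadata = list()
  )
)

.validOntologyGraph <- function(object) {
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) msg <- c(msg, "class ids must be unique")
  if (any(!nzchar(object@ids))) msg <- c(msg, "class ids must be non-empty")
  if (length(object@classNames) != n || length(object@smiles) != n ||
      length(object@parents) != n) {
    msg <- c(msg, "ids, classNames, smiles and parents must be parallel")
  } else if (n > 0L) {
    allp <- unlist(object@parents, use.names = FALSE)
    endpointsOk <- !length(allp) || all(allp %in% object@ids)
    if (!endpointsOk) {
      bad <- setdiff(allp, object@ids)
      msg <- c(msg, paste0("edge endpoints not registered: ",
                           paste(head(bad, 3L), collapse = ", ")))
    }
    if (any(vapply(object@parents, anyDuplicated, 0L) > 0L)) {
      msg <- c(msg, "duplicate is_a edges")
    }
    if (endpointsOk) {
      cyc <- .findCycle(object@ids, object@parents)
      if (!is.null(cyc)) {
        msg <- c(msg, paste0("subsumption graph contains a cycle: ",
                             paste(cyc, collapse = " -> ")))
      }
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("OntologyGraph", .validOntologyGraph)

#' ClassSelection: label classes chosen by membership threshold
#'
#' The set of ontology classes used as prediction labels: every proper
#' transitive subclass of \code{root} with at least \code{minMembers}
#' SMILES-annotated proper subclasses. Labels are kept in lexicographic CURIE
#' order so label indices are stable across runs.
#'
#' @slot versionTag free-text tag for the ontology release (e.g. "v200").
#' @slot root CURIE of the selection root (ChEBI uses \code{"CHEBI:24431"},
#'   chemical entity).
#' @slot minMembers positive integer membership threshold (100 and 50 are the
#'   conventional coarse/fine choices).
#' @slot labels ordered character vector of label CURIEs.
#' @slot memberCounts named integer vector, member count |C| per label.
#' @export
setClass("ClassSelection",
  representation(
    versionTag = "character", root = "character", minMembers = "integer",
    labels = "character", memberCounts = "integer"
  )
)

setValidity("ClassSelection", function(object) {
  msg <- character()
  if (length(object@minMembers) != 1L || object@minMembers < 1L)
    msg <- c(msg, "minMembers must be a positive integer")
  if (!identical(object@labels, .lexSort(object@labels)))
    msg <- c(msg, "labels must be in lexicographic CURIE order")
  if (!all(object@labels %in% names(object@memberCounts)))
    msg <- c(msg, "every label needs a member count")
  if (length(object@memberCounts) &&
      any(object@memberCounts[object@labels] < object@minMembers))
    msg <- c(msg, "all member counts must be >= minMembers")
  if (length(msg)) msg else TRUE
})

#' PathHistogram: distribution of subsumption path lengths
#'
#' Counts of distinct directed paths by length (number of edges traversed)
#' between classes of an [OntologyGraph-class]. An empty histogram means the
#' target is unreachable from every source.
#'
#' @slot counts named numeric vector; names are path lengths, values are
#'   positive path counts.
#' @seealso [countPaths()], [rootPathHistogram()]
#' @export
setClass("PathHistogram", representation(counts = "numeric"))

setValidity("PathHistogram", function(object) {
  msg <- character()
  if (length(object@counts)) {
    if (is.null(names(object@counts)) ||
        any(is.na(suppressWarnings(as.integer(names(object@counts))))))
      msg <- c(msg, "counts must be named by integer path lengths")
    if (any(object@counts <= 0)) msg <- c(msg, "all counts must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' LabeledDataset: molecules x label classes with split assignments
#'
#' A \linkS4class{SummarizedExperiment} whose assay \code{"labels"} is the
#' binary label matrix with label classes as rows and molecules (SMILES
#' annotated ontology classes) as columns; \code{colData} carries the SMILES
#' string and the train/validation/test split assignment of each molecule.
#' \code{labels[j, i] == 1} iff label j is a proper transitive superclass of
#' molecule i's ontology class.
#'
#' Rows follow the lexicographic label order of the generating
#' [ClassSelection-class]; use [labelMatrix()] for the molecules x labels
#' orientation used by the models.
#'
#' @seealso [buildLabeledDataset()], [splitDataset()], [datasetPartition()]
#' @export
setClass("LabeledDataset", contains = "SummarizedExperiment")

setValidity("LabeledDataset", function(object) {
  msg <- character()
  if (!"labels" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'labels' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("smiles", "split") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'smiles' and 'split'")
  else {
    sp <- cd$split
    ok <- is.na(sp) | sp %in% c("train", "validation", "test")
    if (!all(ok)) msg <- c(msg, "split values must be train/validation/test or NA")
  }
  if (length(msg)) msg else TRUE
})

#' TokenVocabulary: token to index mapping for SMILES sequences
#'
#' Indices are 0-based and contiguous; the three special tokens (padding,
#' unknown, sequence start) occupy indices 0..2, followed by the distinct
#' corpus tokens in lexicographic order.
#'
#' @slot tokens ordered character vector, position k holds the token with
#'   index k-1.
#' @slot specials named character vector with entries \code{pad}, \code{unk},
#'   \code{start}.
#' @seealso [buildVocabulary()], [encodeTokens()]
#' @export
setClass("TokenVocabulary",
  representation(tokens = "character", specials = "character"))

setValidity("TokenVocabulary", function(object) {
  msg <- character()
  if (!all(c("pad", "unk", "start") %in% names(object@specials)))
    msg <- c(msg, "specials must name pad, unk and start tokens")
  if (anyDuplicated(object@tokens)) msg <- c(msg, "tokens must be unique")
  if (!all(object@specials %in% object@tokens))
    msg <- c(msg, "special tokens must be present in the vocabulary")
  if (anyDuplicated(object@specials)) msg <- c(msg, "special tokens must be distinct")
  if (length(msg)) msg else TRUE
})

#' TokenSequence: a tokenized SMILES string
#'
#' The tokenization is lossless: \code{paste(tokens, collapse = "")} equals
#' \code{source} exactly.
#'
#' @slot tokens ordered character vector of tokens.
#' @slot source the original SMILES string.
#' @seealso [tokenizeSmiles()]
#' @export
setClass("TokenSequence", representation(tokens = "character", source = "character"))

setValidity("TokenSequence", function(object) {
  if (!identical(paste(object@tokens, collapse = ""), object@source))
    "token concatenation must reproduce the source SMILES" else TRUE
})

#' ClassWeights: effective-number loss weights per label class
#'
#' Weight of a class C with |C| members is the inverse of its effective
#' number: w_C = (1 - beta) / (1 - beta^|C|). Weights lie in (1 - beta, 1]
#' and strictly decrease as the member count grows.
#'
#' @slot weights named numeric vector, label CURIE -> weight.
#' @slot beta the overlap parameter in [0, 1).
#' @slot memberCounts named integer vector of the |C| used.
#' @seealso [classWeights()], [effectiveNumber()]
#' @export
setClass("ClassWeights",
  representation(weights = "numeric", beta = "numeric", memberCounts = "integer"))

setValidity("ClassWeights", function(object) {
  msg <- character()
  b <- object@beta
  if (length(b) != 1L || b < 0 || b >= 1) msg <- c(msg, "beta must be in [0, 1)")
  if (length(object@weights)) {
    if (is.null(names(object@weights))) msg <- c(msg, "weights must be named")
    if (any(object@weights <= 0)) msg <- c(msg, "weights must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' TrainedModel: a trained Transformer multi-label classifier
#'
#' Opaque encoder parameters plus everything needed to reproduce and apply
#' the model: the vocabulary, the label order (identical to the training
#' dataset's), the configuration, and the per-epoch training log.
#'
#' @slot params named list of parameter matrices/vectors.
#' @slot config the [encoderConfig()] list used for training.
#' @slot vocab the [TokenVocabulary-class] the model was trained with.
#' @slot labelOrder ordered character vector of label CURIEs.
#' @slot trainingLog data.frame with one row per epoch (loss, validation
#'   micro F1).
#' @slot bestEpoch epoch whose validation micro F1 selected the returned
#'   parameters.
#' @slot vocabHash character hash of the vocabulary token list.
#' @seealso [trainClassifier()], [predict,TrainedModel-method],
#'   [attentionMaps()]
#' @export
setClass("TrainedModel",
  representation(
    params = "list", config = "list", vocab = "TokenVocabulary",
    labelOrder = "character", trainingLog = "data.frame",
    bestEpoch = "integer", vocabHash = "character"
  )
)

#' PredictionSet: per-molecule label probabilities and thresholded sets
#'
#' @slot smiles character vector of the input SMILES (order preserved).
#' @slot probabilities numeric matrix, molecules x labels, in [0, 1]; rows of
#'   failed inputs are NA.
#' @slot threshold decision threshold; the predicted set of a molecule is
#'   every label with probability >= threshold.
#' @slot predicted list of character vectors of predicted label CURIEs.
#' @slot itemErrors data.frame (index, smiles, message) of inputs that failed
#'   tokenization or encoding; the batch is never aborted by them.
#' @seealso [predict,TrainedModel-method]
#' @export
setClass("PredictionSet",
  representation(
    smiles = "character", probabilities = "matrix", threshold = "numeric",
    predicted = "list", itemErrors = "data.frame"
  )
)

setValidity("PredictionSet", function(object) {
  msg <- character()
  p <- object@probabilities
  if (nrow(p) != length(object@smiles))
    msg <- c(msg, "one probability row per input SMILES")
  if (length(object@predicted) != length(object@smiles))
    msg <- c(msg, "one predicted set per input SMILES")
  fin <- p[is.finite(p)]
  if (length(fin) && (min(fin) < 0 || max(fin) > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: micro/macro F1 over a dataset partition
#'
#' Micro F1 is datapoint-averaged: the mean over molecules of the F1 between
#' the predicted and true label sets of that molecule. Macro F1 averages
#' per-label F1 over labels that occur (in truth or prediction) in the
#' evaluated partition; the remaining labels are listed in
#' \code{excludedLabels}.
#'
#' @slot microF1,macroF1 numeric scalars in [0, 1].
#' @slot perClassF1 named numeric vector of per-label F1 (NA for excluded
#'   labels).
#' @slot nMolecules,nLabels integers.
#' @slot excludedLabels character vector of labels excluded from the macro
#'   mean.
#' @slot micro aggregation variant used ("datapoint" or "pooled").
#' @seealso [f1Report()]
#' @export
setClass("MetricsReport",
  representation(
    microF1 = "numeric", macroF1 = "numeric", perClassF1 = "numeric",
    nMolecules = "integer", nLabels = "integer",
    excludedLabels = "character", micro = "character"
  )
)

#' SpecificityTable: four-way specificity comparison of two models
#'
#' For every (molecule, correct prediction C1 of model A) pair, model B's
#' correct predictions place the pair into exactly one of four categories:
#' equally specific (B also predicts C1), less specific for A (B predicts a
#' proper subclass of C1), more specific for A (B predicts a proper
#' superclass of C1), or not comparable (B predicts nothing in C1's
#' taxonomic branch).
#'
#' @slot counts named integer vector over the four categories.
#' @slot percentages named numeric vector summing to 100.
#' @slot nPairs total number of evaluated (molecule, prediction) pairs.
#' @seealso [specificityComparison()]
#' @export
setClass("SpecificityTable",
  representation(counts = "numeric", percentages = "numeric", nPairs = "integer"))

setValidity("SpecificityTable", function(object) {
  cats <- c("more_specific", "less_specific", "equally_specific", "not_comparable")
  msg <- character()
  if (!identical(names(object@counts), cats))
    msg <- c(msg, "counts must cover the four categories in canonical order")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (sum(object@counts) > 0 && abs(sum(object@percentages) - 100) > 0.05)
    msg <- c(msg, "percentages must sum to 100 within 0.05")
  if (length(msg)) msg else TRUE
})
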