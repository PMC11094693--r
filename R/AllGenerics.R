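#' @rdname OntologyGraph-class
#' @param graph an [OntologyGraph-class]
#' @export
setGeneric("classIds", function(graph) standardGeneric("classIds"))

#' @rdname OntologyGraph-class
#' @export
setGeneric("classSmiles", function(graph) standardGeneric("classSmiles"))

#' @rdname transitiveSuperclasses
#' @export
setGeneric("transitiveSuperclasses",
  function(graph, id) standardGeneric("transitiveSuperclasses"))

#' @rdname memberCount
#' @export
setGeneric("memberCount", function(graph, id) standardGeneric("memberCount"))

#' @rdname selectLabelClasses
#' @export
setGeneric("selectLabelClasses",
  function(graph, root, minMembers, versionTag = "") standardGeneric("selectLabelClasses"))

#' @rdname directNonredundantParents
#' @export
setGeneric("directNonredundantParents",
  function(graph, parents) standardGeneric("directNonredundantParents"))

#' @rdname countPaths
#' @export
setGeneric("countPaths",
  function(graph, sources, target) standardGeneric("countPaths"))

#' @rdname ontologyFragment
#' @export
setGeneric("ontologyFragment",
  function(graph, predictedParents, root, newLabel = "novel molecule")
    standardGeneric("ontologyFragment"))

#' @rdname LabeledDataset-utils
#' @param x a [LabeledDataset-class]
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' @rdname LabeledDataset-utils
#' @export
setGeneric("labelOrder", function(x) standardGeneric("labelOrder"))

#' @rdname LabeledDataset-utils
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname LabeledDataset-utils
#' @export
setGeneric("splitAssignments", function(x) standardGeneric("splitAssignments"))

#' @rdname LabeledDataset-utils
#' @param partition one of "train", "validation", "test"
#' @export
setGeneric("datasetPartition",
  function(x, partition) standardGeneric("datasetPartition"))

#' @rdname attentionMaps
#' @export
setGeneric("attentionMaps", function(model, smiles) standardGeneric("attentionMaps"))

#' @rdname PathHistogram-class
#' @param x a [PathHistogram-class]
#' @export
setGeneric("pathCounts", function(x) standardGeneric("pathCounts"))
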