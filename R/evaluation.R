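#' Micro and macro F1 report for a prediction set
#'
#' Micro F1 follows the datapoint-averaged definition: the mean over
#' molecules of the per-molecule F1 between the predicted and true label
#' sets (a molecule with empty truth and empty prediction scores 1). The
#' pooled-count variant familiar from other toolkits is available via
#' \code{micro = "pooled"}; the two differ whenever per-molecule set sizes
#' vary, so reports state which variant they carry.
#'
#' Macro F1 averages per-label F1. Labels with neither a true nor a
#' predicted positive in the evaluated partition carry no signal and are
#' excluded from the macro mean (they are listed in \code{excludedLabels});
#' labels with true positives but no correct predictions score 0.
#'
#' @param predictions a [PredictionSet-class] aligned with \code{truth}
#'   (same molecules, same order)
#' @param truth a [LabeledDataset-class] partition
#' @param micro "datapoint" (default) or "pooled"
#' @return a [MetricsReport-class]
#' @examples
#' ## 2 molecules, 2 labels: truth [[1,0],[1,1]], predicted [[1,0],[1,0]]
#' ## micro = (1 + 2/3)/2 = 5/6, macro = (1 + 0)/2 = 0.5
#' @export
f1Report <- function(predictions, truth, micro = c("datapoint", "pooled")) {
  micro <- match.arg(micro)
  labs <- labelOrder(truth)
  if (!identical(colnames(predictions@probabilities), labs))
    stop("prediction label order does not match the truth label order")
  tMat <- labelMatrix(truth) == 1
  n <- nrow(tMat)
  if (length(predictions@smiles) != n)
    stop("predictions and truth must cover the same molecules")
  pMat <- matrix(FALSE, n, length(labs), dimnames = list(NULL, labs))
  for (i in seq_len(n)) pMat[i, predictions@predicted[[i]]] <- TRUE
  microF1 <- if (micro == "datapoint") {
    mean(vapply(seq_len(n), function(i) .setF1(pMat[i, ], tMat[i, ]), numeric(1)))
  } else {
    tp <- sum(pMat & tMat); fp <- sum(pMat & !tMat); fn <- sum(!pMat & tMat)
    if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  }
  perClass <- vapply(seq_along(labs), function(j) {
    tj <- tMat[, j]; pj <- pMat[, j]
    if (!any(tj) && !any(pj)) return(NA_real_)
    .setF1(pj, tj)
  }, numeric(1))
  names(perClass) <- labs
  excluded <- labs[is.na(perClass)]
  macroF1 <- if (all(is.na(perClass))) NA_real_ else mean(perClass, na.rm = TRUE)
  new("MetricsReport", microF1 = microF1, macroF1 = macroF1,
      perClassF1 = perClass, nMolecules = as.integer(n),
      nLabels = as.integer(length(labs)), excludedLabels = excluded,
      micro = micro)
}

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport over", object@nMolecules, "molecules x",
      object@nLabels, "labels\n")
  cat(sprintf("  micro F1 (%s): %.4f\n", object@micro, object@microF1))
  cat(sprintf("  macro F1: %.4f (%d labels excluded)\n",
              object@macroF1, length(object@excludedLabels)))
})

#' @rdname MetricsReport-class
#' @param x a MetricsReport
#' @export
microF1 <- function(x) x@microF1

#' @rdname MetricsReport-class
#' @export
macroF1 <- function(x) x@macroF1

#' @rdname MetricsReport-class
#' @export
perClassF1 <- function(x) x@perClassF1

#' Correct non-redundant predictions
#'
#' Intersects the predicted classes with the molecule's true ancestors and
#' then removes every class that is a transitive superclass of another
#' remaining member, leaving only the deepest (most informative) correct
#' predictions. The result never contains two comparable classes.
#'
#' @param graph an [OntologyGraph-class]
#' @param predicted character vector of predicted class CURIEs
#' @param trueAncestors character vector of the molecule's true ancestor
#'   CURIEs
#' @return character vector (sorted)
#' @export
correctNonredundant <- function(graph, predicted, trueAncestors) {
  correct <- intersect(unique(as.character(predicted)),
                       unique(as.character(trueAncestors)))
  if (!length(correct)) return(character())
  directNonredundantParents(graph, correct)
}

#' Path-length histogram from correct predictions to the root
#'
#' For every molecule, takes its correct non-redundant predictions and
#' accumulates [countPaths()] from them up to \code{root} into one
#' histogram — the depth profile of what a model gets right: the deeper the
#' predicted classes sit, the longer the root paths.
#'
#' @param predictions a [PredictionSet-class] aligned with \code{truth}
#' @param truth a [LabeledDataset-class] partition
#' @param graph the [OntologyGraph-class] the labels live in
#' @param root CURIE of the ontology root
#' @return a [PathHistogram-class]
#' @export
rootPathHistogram <- function(predictions, truth, graph, root) {
  .idIndex(graph, root)
  labs <- labelOrder(truth)
  tMat <- labelMatrix(truth) == 1
  total <- numeric()
  for (i in seq_len(nrow(tMat))) {
    cnr <- correctNonredundant(graph, predictions@predicted[[i]], labs[tMat[i, ]])
    if (!length(cnr)) next
    h <- pathCounts(countPaths(graph, cnr, root))
    for (k in names(h)) total[k] <- (if (k %in% names(total)) total[k] else 0) + h[[k]]
  }
  PathHistogram(total)
}

# shortest upward distance (in is_a edges) from `from` to every ancestor;
# named integer vector including from itself at distance 0
.upwardDistances <- function(graph, fromIdx, parentIdx) {
  dist <- rep(NA_integer_, length(graph@ids))
  dist[fromIdx] <- 0L
  queue <- fromIdx
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (p in parentIdx[[v]]) if (is.na(dist[p])) {
      dist[p] <- dist[v] + 1L
      queue <- c(queue, p)
    }
  }
  setNames(dist[!is.na(dist)], graph@ids[!is.na(dist)])
}

#' Distances between asserted parents and predicted classes
#'
#' For each molecule, the asserted parents are the direct non-redundant
#' parents of its ontology class (the minimal elements of its ancestor
#' set). Every (asserted parent, predicted class) pair in which the
#' predicted class is that parent or one of its transitive superclasses is
#' comparable; its distance is the shortest upward path from the parent to
#' the predicted class, with 0 the best case (the model predicted the
#' asserted parent itself). Per molecule the minimum and mean over
#' comparable pairs are reported; molecules with no comparable pair get NA
#' and are counted in the \code{"nExcluded"} attribute.
#'
#' @param predictions a [PredictionSet-class] aligned with \code{truth}
#' @param truth a [LabeledDataset-class] partition whose molecule ids are
#'   classes of \code{graph}
#' @param graph an [OntologyGraph-class]
#' @return data.frame (id, minDistance, meanDistance, nComparable) with
#'   attribute \code{nExcluded}
#' @export
parentDistance <- function(predictions, truth, graph) {
  ids <- molecules(truth)$id
  pidx <- .parentIdx(graph)
  out <- data.frame(id = ids, minDistance = NA_real_, meanDistance = NA_real_,
                    nComparable = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    mi <- .idIndex(graph, ids[i])
    anc <- graph@ids[.reach(pidx, mi)]
    if (!length(anc)) next
    asserted <- directNonredundantParents(graph, anc)
    correct <- intersect(predictions@predicted[[i]], anc)
    if (!length(correct)) next
    dists <- numeric()
    for (a in asserted) {
      up <- .upwardDistances(graph, .idIndex(graph, a), pidx)
      hit <- correct[correct %in% names(up)]
      if (length(hit)) dists <- c(dists, unname(up[hit]))
    }
    if (length(dists)) {
      out$minDistance[i] <- min(dists)
      out$meanDistance[i] <- mean(dists)
      out$nComparable[i] <- length(dists)
    }
  }
  attr(out, "nExcluded") <- sum(out$nComparable == 0L)
  out
}

#' Four-way specificity comparison between two models
#'
#' For every molecule and every correct prediction C1 of model A, model B's
#' correct predictions on the same molecule decide the category: if B also
#' predicts C1 the pair is \emph{equally specific}; otherwise if B predicts
#' a proper subclass of C1, A's prediction is \emph{less specific}; else if
#' B predicts a proper superclass of C1, A's is \emph{more specific}; and if
#' B predicts nothing comparable to C1 in the subsumption order the pair is
#' \emph{not comparable}. A prediction is "correct" when the predicted class
#' is among the molecule's true transitive ancestors. Counts and percentages
#' over all (molecule, C1) pairs are returned; the label sets of the two
#' models may differ (that is the point of the comparison).
#'
#' @param predsA,predsB [PredictionSet-class] objects over the same
#'   molecules in the same order (models A and B)
#' @param truth a [LabeledDataset-class] partition whose molecule ids are
#'   classes of \code{graph}; used for the molecule list and order
#' @param graph an [OntologyGraph-class] providing the subsumption order and
#'   the true ancestor sets
#' @return a [SpecificityTable-class]
#' @export
specificityComparison <- function(predsA, predsB, truth, graph) {
  ids <- molecules(truth)$id
  if (length(predsA@smiles) != length(ids) ||
      length(predsB@smiles) != length(ids))
    stop("both prediction sets must cover the truth molecules")
  pidx <- .parentIdx(graph)
  ancCache <- new.env(parent = emptyenv())
  ancestorsOf <- function(id) {
    hit <- get0(id, envir = ancCache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    a <- graph@ids[.reach(pidx, .idIndex(graph, id))]
    assign(id, a, envir = ancCache)
    a
  }
  counts <- c(more_specific = 0, less_specific = 0, equally_specific = 0,
              not_comparable = 0)
  for (i in seq_along(ids)) {
    anc <- ancestorsOf(ids[i])
    corrA <- intersect(predsA@predicted[[i]], anc)
    if (!length(corrA)) next
    corrB <- intersect(predsB@predicted[[i]], anc)
    for (c1 in corrA) {
      cat1 <- if (c1 %in% corrB) {
        "equally_specific"
      } else {
        sub1 <- corrB[vapply(corrB, function(b) c1 %in% ancestorsOf(b), logical(1))]
        if (length(sub1)) "less_specific"
        else if (any(corrB %in% ancestorsOf(c1))) "more_specific"
        else "not_comparable"
      }
      counts[cat1] <- counts[cat1] + 1
    }
  }
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else counts * 0
  new("SpecificityTable", counts = counts, percentages = pct,
      nPairs = as.integer(total))
}

setMethod("show", "SpecificityTable", function(object) {
  cat("SpecificityTable over", object@nPairs, "(molecule, prediction) pairs\n")
  tb <- data.frame(category = names(object@counts),
                   n = as.integer(object@counts),
                   percent = sprintf("%.2f%%", object@percentages))
  print(tb, row.names = FALSE)
})

#' @rdname SpecificityTable-class
#' @param x a SpecificityTable
#' @export
specificityCounts <- function(x) x@counts

#' @rdname SpecificityTable-class
#' @export
specificityPercentages <- function(x) x@percentages

#' Write a metrics report / histogram as JSON or TSV
#'
#' @param report a [MetricsReport-class]
#' @param jsonPath,tsvPath output paths (either may be NULL)
#' @return invisibly, the list written
#' @export
writeMetricsReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
  out <- list(microF1 = report@microF1, macroF1 = report@macroF1,
              micro = report@micro, nMolecules = report@nMolecules,
              nLabels = report@nLabels,
              excludedLabels = report@excludedLabels,
              perClassF1 = as.list(report@perClassF1))
  if (!is.null(jsonPath))
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, na = "null", digits = NA)
  if (!is.null(tsvPath)) {
    tb <- data.frame(label = names(report@perClassF1), f1 = report@perClassF1)
    utils::write.table(tb, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}

#' @rdname writeMetricsReport
#' @param histogram a [PathHistogram-class]
#' @param path output TSV path (columns: length, count)
#' @export
writePathHistogram <- function(histogram, path) {
  utils::write.table(pathLengthTable(histogram), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
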