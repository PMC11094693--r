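#' Split configuration
#'
#' Proportions for the train/validation/test partition. The conventional
#' split is 85\% train, 2.25\% validation and 12.75\% test; the prior-version
#' protocol reuses an existing test set and splits the remainder
#' 97.75/2.25/0. Fractions must sum to 1 (zero fractions are allowed so the
#' latter protocol is expressible).
#'
#' @param train,validation,test fractions in [0, 1] summing to 1
#' @param seed integer seed driving the split permutation
#' @return a named list
#' @export
splitConfig <- function(train = 0.85, validation = 0.0225, test = 0.1275, seed = 0L) {
  fr <- c(train = train, validation = validation, test = test)
  if (any(fr < 0) || any(fr >= 1 + 1e-9)) stop("fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-9) stop("fractions must sum to 1")
  list(train = train, validation = validation, test = test, seed = as.integer(seed))
}

#' Build a transitively labeled multi-label dataset
#'
#' One molecule per SMILES-annotated proper subclass of the selection root;
#' the binary label matrix is filled by transitive closure: label j is set
#' for molecule i iff j is a proper transitive superclass of i's ontology
#' class. Molecules whose ancestors contain no selected label get an all-zero
#' row; they are retained by default (set \code{dropEmpty = TRUE} to remove
#' them).
#'
#' @param graph an [OntologyGraph-class]
#' @param selection a [ClassSelection-class] derived from \code{graph}
#' @param dropEmpty drop molecules with all-zero label rows
#' @return a [LabeledDataset-class] with no split assigned
#' @export
buildLabeledDataset <- function(graph, selection, dropEmpty = FALSE) {
  if (!all(selection@labels %in% graph@ids))
    stop("selection/graph mismatch: labels missing from graph: ",
         paste(head(setdiff(selection@labels, graph@ids), 3L), collapse = ", "))
  ri <- .idIndex(graph, selection@root)
  children <- .childIdx(graph)
  belowIdx <- .reach(children, ri)
  hasSmiles <- !is.na(graph@smiles) & nzchar(graph@smiles)
  molIdx <- belowIdx[hasSmiles[belowIdx]]
  molIdx <- molIdx[order(graph@ids[molIdx], method = "radix")]
  molIds <- graph@ids[molIdx]
  labels <- selection@labels
  pidx <- .parentIdx(graph)
  mat <- matrix(0L, nrow = length(labels), ncol = length(molIds),
                dimnames = list(labels, molIds))
  labelPos <- setNames(seq_along(labels), labels)
  for (k in seq_along(molIdx)) {
    anc <- graph@ids[.reach(pidx, molIdx[[k]])]
    hits <- labelPos[anc[anc %in% labels]]
    if (length(hits)) mat[hits, k] <- 1L
  }
  empty <- colSums(mat) == 0L
  if (any(empty)) {
    if (dropEmpty) {
      mat <- mat[, !empty, drop = FALSE]
      molIds <- molIds[!empty]
      molIdx <- molIdx[!empty]
    } else {
      warning(sum(empty), " molecule(s) carry no selected label (all-zero rows retained)")
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(labels = mat),
    colData = S4Vectors::DataFrame(
      smiles = graph@smiles[molIdx],
      split = rep(NA_character_, length(molIdx)),
      row.names = molIds),
    metadata = list(root = selection@root, versionTag = selection@versionTag,
                    minMembers = selection@minMembers, splitSeed = NA_integer_,
                    memberCounts = selection@memberCounts)
  )
  new("LabeledDataset", se)
}

#' @rdname LabeledDataset-utils
#' @export
setMethod("molecules", "LabeledDataset", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(id = rownames(cd), smiles = cd$smiles, split = cd$split,
             stringsAsFactors = FALSE, row.names = NULL)
})

#' @rdname LabeledDataset-utils
#' @export
setMethod("labelOrder", "LabeledDataset", function(x) rownames(x))

#' LabeledDataset accessors
#'
#' \code{molecules} returns the molecule table (id, smiles, split);
#' \code{labelOrder} the ordered label CURIEs; \code{labelMatrix} the binary
#' matrix in molecules x labels orientation; \code{splitAssignments} the
#' named split vector; \code{datasetPartition} the sub-dataset of one
#' partition.
#'
#' @name LabeledDataset-utils
#' @rdname LabeledDataset-utils
#' @export
setMethod("labelMatrix", "LabeledDataset",
          function(x) t(SummarizedExperiment::assay(x, "labels")))

#' @rdname LabeledDataset-utils
#' @export
setMethod("splitAssignments", "LabeledDataset", function(x) {
  cd <- SummarizedExperiment::colData(x)
  setNames(cd$split, rownames(cd))
})

#' @rdname LabeledDataset-utils
#' @export
setMethod("datasetPartition", "LabeledDataset", function(x, partition) {
  partition <- match.arg(partition, c("train", "validation", "test"))
  sp <- SummarizedExperiment::colData(x)$split
  if (all(is.na(sp))) stop("dataset has no split; call splitDataset() first")
  x[, !is.na(sp) & sp == partition]
})

setMethod("show", "LabeledDataset", function(object) {
  sp <- SummarizedExperiment::colData(object)$split
  cat("LabeledDataset:", ncol(object), "molecules x", nrow(object), "labels\n")
  if (any(!is.na(sp))) {
    tb <- table(factor(sp, levels = c("train", "validation", "test")))
    cat("  split:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  } else cat("  split: none\n")
})

# Largest-remainder apportionment of n items to fractions; ties on the
# fractional part are broken train > test > validation.
.apportion <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact + 1e-9)
  rem <- exact - base
  left <- n - sum(base)
  if (left > 0) {
    prio <- match(names(fractions), c("train", "test", "validation"))
    ord <- order(-rem, prio)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  setNames(as.integer(base), names(fractions))
}

#' Assign a random train/validation/test split
#'
#' Molecules are permuted by a seeded Fisher-Yates shuffle and partitioned
#' into blocks whose sizes come from largest-remainder rounding of the
#' configured fractions (ties broken train > test > validation). With the
#' default fractions a 10000-molecule dataset splits exactly into
#' 8500/225/1275.
#'
#' @param dataset a [LabeledDataset-class] without a prior split
#' @param config a [splitConfig()]
#' @return the dataset with split assignments recorded
#' @export
splitDataset <- function(dataset, config = splitConfig()) {
  sp <- SummarizedExperiment::colData(dataset)$split
  if (any(!is.na(sp))) stop("dataset already has a split")
  n <- ncol(dataset)
  sizes <- .apportion(n, c(train = config$train, validation = config$validation,
                           test = config$test))
  perm <- .withSeed(config$seed, sample.int(n))
  assign <- rep(NA_character_, n)
  offset <- 0L
  for (part in c("train", "validation", "test")) {
    k <- sizes[[part]]
    if (k > 0L) assign[perm[(offset + 1L):(offset + k)]] <- part
    offset <- offset + k
  }
  SummarizedExperiment::colData(dataset)$split <- assign
  S4Vectors::metadata(dataset)$splitSeed <- config$seed
  validObject(dataset)
  dataset
}

#' Prior-version training data aligned to a newer test set
#'
#' Implements the cross-version protocol: a dataset built from an older
#' ontology release must never train on molecules that sit in the newer
#' release's test set, so both models can be evaluated on that same test
#' set. The older release's dataset is built from \code{oldGraph} and
#' \code{oldSelection}, molecules present in \code{newDataset}'s test
#' partition are discarded, and the remainder is split 97.75/2.25 into
#' train/validation. The shared test set is relabeled to the old label set:
#' via old-graph transitive closure where the molecule exists in the old
#' graph, via the new dataset's columns for labels the two selections share
#' otherwise, and zero elsewhere.
#'
#' @param oldGraph the older release's [OntologyGraph-class]
#' @param oldSelection the older release's [ClassSelection-class]
#' @param newDataset the newer release's split [LabeledDataset-class]
#' @param seed seed for the 97.75/2.25 split
#' @return list with elements \code{trainval} (old-release dataset, split
#'   train/validation) and \code{test} (shared test set relabeled to the old
#'   labels)
#' @export
derivePriorVersionDataset <- function(oldGraph, oldSelection, newDataset, seed = 0L) {
  testDs <- datasetPartition(newDataset, "test")
  testIds <- molecules(testDs)$id
  old <- buildLabeledDataset(oldGraph, oldSelection)
  keep <- !(molecules(old)$id %in% testIds)
  if (!any(keep)) stop("no training molecules remain after excluding the shared test set")
  old <- old[, keep]
  old <- splitDataset(old, splitConfig(train = 0.9775, validation = 0.0225,
                                       test = 0, seed = seed))
  # relabel the shared test set to the old label order
  oldLabels <- oldSelection@labels
  newLabels <- rownames(testDs)
  mat <- matrix(0L, nrow = length(oldLabels), ncol = length(testIds),
                dimnames = list(oldLabels, testIds))
  inOld <- testIds %in% oldGraph@ids
  pidx <- .parentIdx(oldGraph)
  for (k in which(inOld)) {
    anc <- oldGraph@ids[.reach(pidx, match(testIds[k], oldGraph@ids))]
    hits <- oldLabels[oldLabels %in% anc]
    if (length(hits)) mat[hits, k] <- 1L
  }
  shared <- intersect(oldLabels, newLabels)
  if (any(!inOld) && length(shared)) {
    newMat <- SummarizedExperiment::assay(testDs, "labels")
    mat[shared, !inOld] <- newMat[shared, !inOld, drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(labels = mat),
    colData = S4Vectors::DataFrame(
      smiles = molecules(testDs)$smiles,
      split = rep("test", length(testIds)),
      row.names = testIds),
    metadata = list(root = oldSelection@root, versionTag = oldSelection@versionTag,
                    minMembers = oldSelection@minMembers,
                    splitSeed = S4Vectors::metadata(newDataset)$splitSeed,
                    relabeledFrom = S4Vectors::metadata(newDataset)$versionTag)
  )
  list(trainval = old, test = new("LabeledDataset", se))
}

#' Serialize / read a LabeledDataset as plain-text files
#'
#' Writes \code{molecules.tsv} (id, smiles, split), \code{labels.tsv} (a
#' sparse 1-based coordinate list: molecule row, label column),
#' \code{label_order.txt} and \code{metadata.json} into \code{dir}.
#'
#' @param dataset a [LabeledDataset-class]
#' @param dir output directory (created if needed)
#' @return \code{dir} (writer) or a [LabeledDataset-class] (reader)
#' @export
writeLabeledDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mol <- molecules(dataset)
  utils::write.table(mol, file.path(dir, "molecules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mat <- SummarizedExperiment::assay(dataset, "labels")
  nz <- which(mat != 0L, arr.ind = TRUE)
  coo <- data.frame(row = nz[, "col"], col = nz[, "row"])  # molecules, labels
  coo <- coo[order(coo$row, coo$col), , drop = FALSE]
  utils::write.table(coo, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(rownames(dataset), file.path(dir, "label_order.txt"))
  md <- S4Vectors::metadata(dataset)
  if (!is.null(md$memberCounts)) md$memberCounts <- as.list(md$memberCounts)
  jsonlite::write_json(md, file.path(dir, "metadata.json"), auto_unbox = TRUE,
                       na = "null")
  invisible(dir)
}

#' @rdname writeLabeledDataset
#' @export
readLabeledDataset <- function(dir) {
  mol <- utils::read.table(file.path(dir, "molecules.tsv"), sep = "\t",
                           header = TRUE, colClasses = "character",
                           quote = "", comment.char = "")
  labels <- readLines(file.path(dir, "label_order.txt"))
  coo <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t", header = TRUE)
  mat <- matrix(0L, nrow = length(labels), ncol = nrow(mol),
                dimnames = list(labels, mol$id))
  if (nrow(coo)) mat[cbind(coo$col, coo$row)] <- 1L
  md <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  md$memberCounts <- unlist(md$memberCounts)
  sp <- mol$split
  sp[sp == "NA" | sp == ""] <- NA_character_
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(labels = mat),
    colData = S4Vectors::DataFrame(smiles = mol$smiles, split = sp,
                                   row.names = mol$id),
    metadata = md)
  new("LabeledDataset", se)
}
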