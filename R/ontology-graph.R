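#' Construct an OntologyGraph from parts
#'
#' Low-level constructor used by [loadOBO()] and the synthetic generators.
#' Validates uniqueness of ids, registration of edge endpoints and
#' acyclicity.
#'
#' @param ids character vector of class CURIEs.
#' @param classNames character vector of names (recycled from ids if missing).
#' @param smiles character vector of SMILES annotations (`NA` where absent).
#' @param parents list of character vectors of direct is_a parents.
#' @param metadata free-form provenance list.
#' @return an [OntologyGraph-class]
#' @examples
#' g <- OntologyGraph(
#'   ids = c("X:1", "X:2", "X:3"),
#'   parents = list(character(), "X:1", "X:1"),
#'   smiles = c(NA, NA, "CCO"))
#' transitiveSuperclasses(g, "X:3")
#' @export
OntologyGraph <- function(ids, classNames = ids, smiles = rep(NA_character_, length(ids)),
                          parents = rep(list(character()), length(ids)),
                          metadata = list()) {
  new("OntologyGraph", ids = as.character(ids), classNames = as.character(classNames),
      smiles = as.character(smiles), parents = parents, metadata = metadata)
}

setMethod("classIds", "OntologyGraph", function(graph) graph@ids)

setMethod("classSmiles", "OntologyGraph",
          function(graph) setNames(graph@smiles, graph@ids))

#' @describeIn OntologyGraph-class number of classes
#' @param x an OntologyGraph
#' @export
setMethod("length", "OntologyGraph", function(x) length(x@ids))

setMethod("show", "OntologyGraph", function(object) {
  nE <- sum(lengths(object@parents))
  nS <- sum(!is.na(object@smiles))
  cat("OntologyGraph with", length(object@ids), "classes,", nE,
      "is_a edges,", nS, "SMILES annotations\n")
  roots <- object@ids[lengths(object@parents) == 0L]
  if (length(roots))
    cat("  root(s):", paste(head(roots, 3L), collapse = ", "),
        if (length(roots) > 3L) "..." else "", "\n")
})

.idIndex <- function(graph, id) {
  i <- match(id, graph@ids)
  if (anyNA(i)) stop("unknown class id: ", paste(id[is.na(i)], collapse = ", "))
  i
}

# integer adjacency (child -> parent indices), computed once per call site
.parentIdx <- function(graph) lapply(graph@parents, match, graph@ids)

.childIdx <- function(graph, parentIdx = .parentIdx(graph)) {
  n <- length(graph@ids)
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in parentIdx[[i]]) children[[p]] <- c(children[[p]], i)
  children
}

# BFS over an integer adjacency list from `start`; returns reached indices,
# excluding `start` itself.
.reach <- function(adj, start) {
  n <- length(adj)
  seen <- logical(n)
  queue <- start
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  seen[start] <- FALSE
  which(seen)
}

#' Transitive superclasses of a class
#'
#' All ancestors reachable from \code{id} along is_a edges; the class itself
#' is excluded.
#'
#' @param graph an [OntologyGraph-class]
#' @param id a class CURIE present in the graph
#' @return character vector of ancestor CURIEs (lexicographically sorted)
#' @examples
#' g <- OntologyGraph(c("A", "B", "C"), parents = list(character(), "A", "B"))
#' transitiveSuperclasses(g, "C")  # "A" "B"
#' @export
setMethod("transitiveSuperclasses", "OntologyGraph", function(graph, id) {
  i <- .idIndex(graph, id)
  .lexSort(graph@ids[.reach(.parentIdx(graph), i)])
})

# Member counts (|C| = number of proper transitive subclasses carrying a
# SMILES annotation) for every class at once, bottom-up over the DAG.
.memberCountsAll <- function(graph) {
  pidx <- .parentIdx(graph)
  n <- length(graph@ids)
  hasSmiles <- !is.na(graph@smiles) & nzchar(graph@smiles)
  children <- .childIdx(graph, pidx)
  ord <- .topoOrder(graph@ids, pidx)          # parents before children
  descend <- vector("list", n)                # SMILES-bearing proper descendants
  counts <- integer(n)
  for (v in rev(ord)) {                       # children before parents
    sets <- lapply(children[[v]], function(ch) {
      if (hasSmiles[ch]) c(ch, descend[[ch]]) else descend[[ch]]
    })
    d <- unique(unlist(sets, use.names = FALSE))
    descend[v] <- list(d)
    counts[v] <- length(d)
  }
  setNames(counts, graph@ids)
}

#' Member count of a class
#'
#' The number of proper transitive subclasses of \code{id} that carry a
#' SMILES annotation. A class's own SMILES does not count toward its member
#' count.
#'
#' @inheritParams transitiveSuperclasses
#' @return integer
#' @export
setMethod("memberCount", "OntologyGraph", function(graph, id) {
  .idIndex(graph, id)
  unname(.memberCountsAll(graph)[id])
})

#' Select label classes by membership threshold
#'
#' Every proper transitive subclass of \code{root} with at least
#' \code{minMembers} SMILES-annotated proper subclasses becomes a label
#' class. On ChEBI release 200 rooted at chemical entity (CHEBI:24431) the
#' thresholds 100 and 50 yield the coarse (854-label) and fine (1332-label)
#' selections. Labels are returned in lexicographic CURIE order.
#'
#' @param graph an [OntologyGraph-class]
#' @param root CURIE of the selection root
#' @param minMembers positive integer membership threshold
#' @param versionTag free-text release tag stored with the selection
#' @return a [ClassSelection-class]
#' @export
setMethod("selectLabelClasses", "OntologyGraph",
function(graph, root, minMembers, versionTag = "") {
  ri <- .idIndex(graph, root)
  stopifnot(minMembers >= 1)
  counts <- .memberCountsAll(graph)
  children <- .childIdx(graph)
  below <- graph@ids[.reach(children, ri)]    # proper subclasses of root
  labels <- .lexSort(below[counts[below] >= minMembers])
  new("ClassSelection", versionTag = as.character(versionTag), root = root,
      minMembers = as.integer(minMembers), labels = labels,
      memberCounts = setNames(as.integer(counts[labels]), labels))
})

setMethod("show", "ClassSelection", function(object) {
  cat("ClassSelection", if (nzchar(object@versionTag)) object@versionTag else "",
      "\n  root:", object@root, " minMembers:", object@minMembers,
      "\n  labels:", length(object@labels), "\n")
})

#' @rdname ClassSelection-class
#' @param x a ClassSelection
#' @export
labelClasses <- function(x) x@labels

#' @rdname ClassSelection-class
#' @export
memberCounts <- function(x) x@memberCounts

#' Remove redundant superclasses from a parent set
#'
#' Keeps only the parents that cannot be inferred from any other member of
#' the set: a class is dropped when it is a transitive superclass of another
#' member. Applied to a class's full ancestor set this yields its direct
#' non-redundant parents.
#'
#' @param graph an [OntologyGraph-class]
#' @param parents character vector of class CURIEs
#' @return character vector (subset of \code{parents}, sorted)
#' @export
setMethod("directNonredundantParents", "OntologyGraph",
function(graph, parents) {
  parents <- unique(as.character(parents))
  if (!length(parents)) return(character())
  idx <- .idIndex(graph, parents)
  pidx <- .parentIdx(graph)
  anc <- lapply(idx, function(i) .reach(pidx, i))
  redundant <- vapply(seq_along(idx), function(k) {
    any(idx[k] %in% unlist(anc[-k], use.names = FALSE))
  }, logical(1))
  .lexSort(parents[!redundant])
})

#' Count directed subsumption paths by length
#'
#' Number of distinct directed is_a paths from each source class up to
#' \code{target}, aggregated over sources and tallied by path length (edge
#' count), via memoized dynamic programming over the DAG. A source equal to
#' the target contributes one path of length 0.
#'
#' On ChEBI release 200, the two direct parents of CHEBI:71342 reach
#' CHEBI:24431 by nine paths of length 12 and nine of length 14.
#'
#' @param graph an [OntologyGraph-class]
#' @param sources character vector of source CURIEs
#' @param target target CURIE
#' @return a [PathHistogram-class]
#' @export
setMethod("countPaths", "OntologyGraph", function(graph, sources, target) {
  ti <- .idIndex(graph, target)
  si <- .idIndex(graph, unique(as.character(sources)))
  pidx <- .parentIdx(graph)
  memo <- vector("list", length(graph@ids))
  done <- logical(length(graph@ids))
  countsFrom <- function(v) {                  # named numeric: length -> paths
    if (done[v]) return(memo[[v]])
    res <- if (v == ti) c("0" = 1) else numeric()
    for (p in pidx[[v]]) {
      up <- countsFrom(p)
      if (length(up)) {
        shifted <- setNames(up, as.character(as.integer(names(up)) + 1L))
        for (k in names(shifted)) {
          res[k] <- (if (k %in% names(res)) res[k] else 0) + shifted[[k]]
        }
      }
    }
    memo[[v]] <<- res; done[v] <<- TRUE
    res
  }
  total <- numeric()
  for (s in si) {
    h <- countsFrom(s)
    for (k in names(h)) total[k] <- (if (k %in% names(total)) total[k] else 0) + h[[k]]
  }
  PathHistogram(total)
})

#' Construct a PathHistogram
#'
#' @param counts named numeric vector (names = path lengths); zero entries
#'   are dropped.
#' @return a [PathHistogram-class]
#' @export
PathHistogram <- function(counts = numeric()) {
  counts <- counts[counts > 0]
  if (length(counts)) {
    ord <- order(as.integer(names(counts)))
    counts <- counts[ord]
  }
  new("PathHistogram", counts = counts)
}

setMethod("pathCounts", "PathHistogram", function(x) x@counts)

#' @describeIn PathHistogram-class histogram as a two-column data.frame
#' @export
pathLengthTable <- function(x) {
  data.frame(length = as.integer(names(x@counts)), count = as.numeric(x@counts))
}

setMethod("show", "PathHistogram", function(object) {
  if (!length(object@counts)) {
    cat("PathHistogram: target unreachable (no paths)\n")
  } else {
    cat("PathHistogram over", sum(object@counts), "paths\n")
    print(pathLengthTable(object), row.names = FALSE)
  }
})

#' Extended-ontology fragment for a predicted placement
#'
#' Builds the ontology fragment returned for a classified molecule: one
#' fresh class (named \code{newLabel}) attached below every predicted parent,
#' together with all classes and is_a edges lying on any path from a
#' predicted parent up to \code{root} — the sub-ontology a user needs to see
#' where the molecule was placed.
#'
#' @param graph an [OntologyGraph-class]
#' @param predictedParents character vector of predicted parent CURIEs
#'   (empty yields a lone fresh node, with a warning)
#' @param root CURIE of the fragment root
#' @param newLabel name given to the fresh class
#' @return an [OntologyGraph-class] fragment; the fresh class has id
#'   \code{"NEW:0000001"}
#' @export
setMethod("ontologyFragment", "OntologyGraph",
function(graph, predictedParents, root, newLabel = "novel molecule") {
  predictedParents <- unique(as.character(predictedParents))
  newId <- "NEW:0000001"
  if (newId %in% graph@ids) newId <- "NEW:9999999"
  if (!length(predictedParents)) {
    warning("no predicted parents; fragment is the lone new class")
    return(OntologyGraph(ids = newId, classNames = newLabel,
                         metadata = list(fragmentOf = root)))
  }
  pi <- .idIndex(graph, predictedParents)
  ri <- .idIndex(graph, root)
  pidx <- .parentIdx(graph)
  # cone above the parents ...
  above <- unique(c(pi, unlist(lapply(pi, function(i) .reach(pidx, i)))))
  # ... restricted to classes from which root is reachable (or root itself)
  reachesRoot <- vapply(above, function(v) v == ri || ri %in% .reach(pidx, v), logical(1))
  keep <- above[reachesRoot]
  keepIds <- graph@ids[keep]
  parents <- lapply(keep, function(v) {
    up <- pidx[[v]]
    kept <- up[up %in% keep]
    graph@ids[kept]
  })
  OntologyGraph(
    ids = c(newId, keepIds),
    classNames = c(newLabel, graph@classNames[keep]),
    smiles = c(NA_character_, graph@smiles[keep]),
    parents = c(list(intersect(predictedParents, keepIds)), parents),
    metadata = list(fragmentOf = root, newClass = newId)
  )
})
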