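# Synthetic ontology + molecule generator. Emulates the statistical shape of
# ontology-derived training data — a rooted DAG hierarchy, heavy-tailed
# class sizes, and class membership determined by molecular structure — at a
# scale where every pipeline stage is testable in seconds. Each "concept"
# class owns a unique SMILES motif; molecules attached below a concept
# carry the motifs of all their concept ancestors, joined by plain alkyl
# filler, so the labels are decodable from token content by construction
# and "the model learns the task" is a stable property rather than a flaky
# one.

# fixed pool of tokenizer-distinct motif tokens (filler chains use only "C")
.MOTIF_POOL <- c(
  "Cl", "Br", "I", "F", "N", "O", "S", "P", "B",
  "[N+]", "[O-]", "[Se]", "[Si]", "[Na]", "[K]", "[Li]", "[Mg]", "[Ca]",
  "[Fe]", "[Zn]", "[Cu]", "[Ag]", "[Au]", "[As]", "[Te]", "[Sn]", "[Al]",
  "[Ti]", "[Pt]", "[Pd]")

#' Synthetic fixture configuration
#'
#' Parameters of the synthetic ontology/molecule generator. The defaults
#' define the standard motif benchmark: 20 concept classes over a 3-level
#' DAG, 2000 molecules, class sizes spanning the 20-400 range (at least a
#' 10x spread between the smallest and largest class, mirroring the
#' heavy-tailed imbalance of curated chemical ontologies).
#'
#' @param nClasses classes in the base DAG (excluding generated molecules)
#' @param maxDepth depth of the base DAG below the root
#' @param multiParentProbability chance of an extra is_a parent per class
#' @param nLabelClasses number of concept (label) classes
#' @param moleculesPerLabel length-2 range of relative class sizes; one
#'   concept is pinned to each end so the imbalance span is guaranteed
#' @param nMolecules total number of generated molecules
#' @param motifLength atoms per motif fragment (>= 1; the first atom is the
#'   concept's distinctive token, the rest alkyl)
#' @param subconceptsPerConcept when > 0, each concept additionally gets
#'   this many subconcept children with motifs of their own; molecules
#'   attached below a subconcept carry both motifs, giving the benchmark a
#'   two-level label hierarchy (used by the specificity comparison)
#' @param extraConceptProbability chance a molecule joins a second,
#'   independent concept (multi-label molecules)
#' @param fillerLength length-2 range of the alkyl filler runs between
#'   motifs
#' @param seed integer RNG seed
#' @return a named list
#' @export
fixtureConfig <- function(nClasses = 61L, maxDepth = 3L,
                          multiParentProbability = 0.2,
                          nLabelClasses = 20L,
                          moleculesPerLabel = c(20L, 400L),
                          nMolecules = 2000L, motifLength = 1L,
                          subconceptsPerConcept = 0L,
                          extraConceptProbability = 0.3,
                          fillerLength = c(1L, 4L), seed = 0L) {
  stopifnot(nClasses >= 1, maxDepth >= 1, nLabelClasses >= 1,
            nLabelClasses <= nClasses,
            length(moleculesPerLabel) == 2L, all(moleculesPerLabel >= 1),
            moleculesPerLabel[1] <= moleculesPerLabel[2],
            nMolecules >= nLabelClasses, motifLength >= 1,
            subconceptsPerConcept >= 0,
            multiParentProbability >= 0, multiParentProbability <= 1,
            extraConceptProbability >= 0, extraConceptProbability <= 1)
  list(nClasses = as.integer(nClasses), maxDepth = as.integer(maxDepth),
       multiParentProbability = multiParentProbability,
       nLabelClasses = as.integer(nLabelClasses),
       moleculesPerLabel = as.integer(moleculesPerLabel),
       nMolecules = as.integer(nMolecules), motifLength = as.integer(motifLength),
       subconceptsPerConcept = as.integer(subconceptsPerConcept),
       extraConceptProbability = extraConceptProbability,
       fillerLength = as.integer(fillerLength), seed = as.integer(seed))
}

.toyId <- function(i) sprintf("TOY:%07d", i)

#' Generate a random rooted DAG ontology
#'
#' Class 1 is the root; every other class is assigned a depth (cycling
#' through 1..maxDepth) and draws one parent uniformly from the
#' shallower classes, plus one extra parent with probability
#' \code{multiParentProbability}. Acyclic by construction (edges always
#' point to strictly shallower classes) and fully seeded.
#'
#' @param config a [fixtureConfig()]
#' @return an [OntologyGraph-class]; depths are recorded in
#'   \code{metadata$depths}
#' @export
generateOntology <- function(config = fixtureConfig()) {
  n <- config$nClasses
  .withSeed(.subSeed(config$seed, 1L), {
    ids <- .toyId(seq_len(n))
    depths <- c(0L, if (n > 1L) ((seq_len(n - 1L) - 1L) %% config$maxDepth) + 1L)
    parents <- vector("list", n)
    parents[[1L]] <- character()
    for (i in seq_len(n)[-1L]) {
      pool <- which(depths < depths[i])
      first <- pool[sample.int(length(pool), 1L)]
      ps <- first
      rest <- setdiff(pool, first)
      if (length(rest) && runif(1) < config$multiParentProbability)
        ps <- c(ps, rest[sample.int(length(rest), 1L)])
      parents[[i]] <- ids[sort(ps)]
    }
    OntologyGraph(ids = ids, classNames = paste("class", seq_len(n)),
                  parents = parents,
                  metadata = list(depths = setNames(depths, ids),
                                  seed = config$seed))
  })
}

# Largest-remainder scaling of relative sizes to a fixed total; every share
# is kept >= 1 by taking from the largest.
.scaleCounts <- function(sizes, total) {
  exact <- total * sizes / sum(sizes)
  base <- floor(exact)
  rem <- exact - base
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(-rem)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  while (any(base == 0)) {
    z <- which.min(base); m <- which.max(base)
    base[z] <- base[z] + 1; base[m] <- base[m] - 1
  }
  as.integer(base)
}

#' Attach structure-defined molecules to an ontology
#'
#' Designates the first \code{nLabelClasses} depth-1 classes as concepts and
#' gives each a unique SMILES motif from a fixed tokenizer-distinct pool.
#' Molecules are new leaf classes attached below a concept (or below one of
#' its subconcepts when \code{subconceptsPerConcept > 0}, in which case the
#' subconcept contributes a second motif); with probability
#' \code{extraConceptProbability} a molecule joins a second concept. A
#' molecule's SMILES is the concatenation of all its concept ancestors'
#' motifs in random order, separated by unbranched alkyl filler, so every
#' label is decodable from the token content. Class sizes follow the
#' \code{moleculesPerLabel} range scaled to \code{nMolecules}, with one
#' concept pinned to each end of the range (>= 10x imbalance span).
#'
#' @param graph an [OntologyGraph-class] from [generateOntology()]
#' @param config the same [fixtureConfig()]
#' @return the augmented [OntologyGraph-class]; concepts, subconcepts and
#'   motifs are recorded in the metadata
#' @export
generateMolecules <- function(graph, config = fixtureConfig()) {
  depths <- graph@metadata$depths
  if (is.null(depths)) stop("graph lacks depth metadata; use generateOntology()")
  level1 <- names(depths)[depths == 1L]
  k <- config$nLabelClasses
  if (length(level1) < k)
    stop("only ", length(level1), " depth-1 classes for ", k,
         " concepts; increase nClasses or lower nLabelClasses")
  concepts <- level1[seq_len(k)]
  s <- config$subconceptsPerConcept
  needed <- k * (1L + s)
  if (needed > length(.MOTIF_POOL))
    stop("motif pool exhausted: ", needed, " motifs needed, ",
         length(.MOTIF_POOL), " available")
  .withSeed(.subSeed(config$seed, 2L), {
    motifTokens <- .MOTIF_POOL[seq_len(needed)]
    motifOf <- setNames(
      vapply(motifTokens, function(m)
        paste0(m, strrep("C", config$motifLength - 1L)), character(1)),
      motifTokens)
    conceptMotif <- setNames(unname(motifOf[seq_len(k)]), concepts)
    ids <- graph@ids; classNames <- graph@classNames
    smiles <- graph@smiles; parents <- graph@parents
    subconceptsOf <- setNames(rep(list(character()), k), concepts)
    subMotif <- character()
    if (s > 0L) {
      next_m <- k + 1L
      for (ci in seq_len(k)) {
        subIds <- .toyId(500000L + (ci - 1L) * s + seq_len(s))
        subconceptsOf[[concepts[ci]]] <- subIds
        for (si in seq_len(s)) {
          ids <- c(ids, subIds[si])
          classNames <- c(classNames, paste0("subconcept ", ci, ".", si))
          smiles <- c(smiles, NA_character_)
          parents <- c(parents, list(concepts[ci]))
          subMotif[subIds[si]] <- unname(motifOf[next_m])
          next_m <- next_m + 1L
        }
      }
    }
    # heavy-tailed concept sizes: pin the extremes, log-uniform in between
    rng <- config$moleculesPerLabel
    sizes <- c(rng[1], rng[2],
               if (k > 2L) round(exp(runif(k - 2L, log(rng[1]), log(rng[2])))))
    sizes <- sizes[seq_len(k)]
    counts <- .scaleCounts(sizes, config$nMolecules)
    # with subconcepts: a fixed small band per subconcept, a floored direct
    # share per concept, so concept totals always exceed subconcept counts
    attachAt <- character(0)       # attachment class per molecule
    for (ci in seq_len(k)) {
      subs <- subconceptsOf[[concepts[ci]]]
      if (length(subs)) {
        subN <- pmin(sample(20:45, length(subs), replace = TRUE),
                     max(1L, counts[ci] %/% (2L * length(subs))))
        direct <- max(counts[ci] - sum(subN), max(1L, counts[ci] %/% 2L))
        attachAt <- c(attachAt, rep(concepts[ci], direct),
                      rep(subs, times = subN))
      } else {
        attachAt <- c(attachAt, rep(concepts[ci], counts[ci]))
      }
    }
    nMol <- length(attachAt)
    molIds <- .toyId(1000000L + seq_len(nMol))
    filler <- function() strrep("C", sample(config$fillerLength[1]:config$fillerLength[2], 1L))
    molParents <- vector("list", nMol)
    molSmiles <- character(nMol)
    for (j in seq_len(nMol)) {
      at <- attachAt[j]
      if (at %in% concepts) {
        topConcept <- at
        ms <- conceptMotif[[at]]
      } else {
        topConcept <- parents[[match(at, ids)]][1L]
        ms <- c(subMotif[[at]], conceptMotif[[topConcept]])
      }
      ps <- at
      if (runif(1) < config$extraConceptProbability && k > 1L) {
        # co-membership proportional to class size, so the configured
        # imbalance span survives the multi-label assignments
        pool <- setdiff(concepts, topConcept)
        other <- sample(pool, 1L, prob = counts[match(pool, concepts)])
        ps <- c(ps, other)
        ms <- c(ms, conceptMotif[[other]])
      }
      ms <- sample(ms)
      molParents[[j]] <- ps
      molSmiles[j] <- paste0(paste0(vapply(ms, function(m) paste0(filler(), m),
                                           character(1)), collapse = ""), filler())
    }
    meta <- graph@metadata
    meta$concepts <- concepts
    meta$subconcepts <- subconceptsOf
    meta$conceptMotif <- conceptMotif
    meta$subconceptMotif <- subMotif
    OntologyGraph(
      ids = c(ids, molIds),
      classNames = c(classNames, paste("molecule", seq_len(nMol))),
      smiles = c(smiles, molSmiles),
      parents = c(parents, molParents),
      metadata = meta)
  })
}

#' Generate a complete learnable benchmark
#'
#' Composes the full pipeline: random ontology, structure-defined molecules,
#' label selection at the threshold that keeps exactly the concept (and
#' subconcept) classes, transitive labeling, and the standard
#' 85/2.25/12.75 split. Identical seeds give byte-identical serialized
#' datasets.
#'
#' @param config a [fixtureConfig()]
#' @param split a [splitConfig()] (defaults to the standard fractions with
#'   the fixture seed)
#' @return list with elements \code{graph}, \code{selection} and
#'   \code{dataset} (split [LabeledDataset-class])
#' @export
generateBenchmark <- function(config = fixtureConfig(),
                              split = splitConfig(seed = config$seed)) {
  g <- generateMolecules(generateOntology(config), config)
  counts <- .memberCountsAll(g)
  conceptish <- c(g@metadata$concepts,
                  unlist(g@metadata$subconcepts, use.names = FALSE))
  thr <- min(counts[conceptish])
  sel <- selectLabelClasses(g, .toyId(1L), thr,
                            versionTag = paste0("toy-seed", config$seed))
  ds <- splitDataset(buildLabeledDataset(g, sel), split)
  list(graph = g, selection = sel, dataset = ds)
}
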