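# Shared fixture builders and independent oracles. Oracles deliberately use
# different algorithms (plain recursion, igraph) than the package internals.

# graph from a child -> parents edge list, e.g. list(B = "A", C = c("A","B"))
toyGraph <- function(edges, smiles = character(), ids = NULL) {
  allIds <- unique(c(names(edges), unlist(edges, use.names = FALSE), ids,
                     names(smiles)))
  OntologyGraph(
    ids = allIds,
    smiles = ifelse(allIds %in% names(smiles), smiles[allIds], NA_character_),
    parents = lapply(allIds, function(i)
      if (i %in% names(edges)) as.character(edges[[i]]) else character())
  )
}

# random DAG on n nodes: node i > 1 draws 1-2 parents among 1..i-1
randomDAG <- function(n, seed, smilesProb = 0) {
  set.seed(seed)
  ids <- sprintf("N:%03d", seq_len(n))
  parents <- vector("list", n)
  parents[[1]] <- character()
  for (i in seq_len(n)[-1]) {
    k <- min(sample(1:2, 1), i - 1L)
    parents[[i]] <- ids[sample.int(i - 1L, k)]
  }
  sm <- rep(NA_character_, n)
  if (smilesProb > 0) {
    hit <- runif(n) < smilesProb
    sm[hit] <- "CC"
  }
  OntologyGraph(ids = ids, smiles = sm, parents = parents)
}

# exhaustive DFS path enumeration oracle: counts of distinct directed paths
# from each source up to target, by edge count
dfsPathOracle <- function(graph, sources, target) {
  parents <- setNames(graph@parents, classIds(graph))
  lengths <- integer()
  walk <- function(node, depth) {
    if (node == target) {
      lengths <<- c(lengths, depth)
      # target may still have parents, but paths end here: a path to the
      # target is counted exactly when it arrives
    }
    for (p in parents[[node]]) walk(p, depth + 1L)
  }
  for (s in sources) walk(s, 0L)
  if (!length(lengths)) return(numeric())
  tb <- table(lengths)
  setNames(as.numeric(tb), names(tb))
}

# igraph mirror of a graph (edges child -> parent) for ancestor/distance
# oracles
asIgraph <- function(graph) {
  el <- do.call(rbind, lapply(seq_along(graph@ids), function(i) {
    ps <- graph@parents[[i]]
    if (length(ps)) cbind(graph@ids[i], ps)
  }))
  igraph::graph_from_data_frame(
    as.data.frame(el %||% matrix(character(), ncol = 2)),
    directed = TRUE, vertices = classIds(graph))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random strings over the SMILES token inventory (grammar-agnostic: the
# tokenizer guarantees losslessness, not chemical validity)
randomSmilesStrings <- function(n, seed) {
  set.seed(seed)
  pool <- c("C", "c", "N", "n", "O", "o", "S", "s", "P", "B", "F", "I",
            "Cl", "Br", "[NH4+]", "[O-]", "[C@@H]", "[13C]", "[Fe+2]",
            "(", ")", "=", "#", "-", "/", "\\", ".", "1", "2", "9", "%10",
            "%99", "*", ":", "$")
  vapply(seq_len(n), function(i) {
    paste(sample(pool, sample(1:40, 1), replace = TRUE), collapse = "")
  }, character(1))
}

# deterministic tiny benchmark used by several expensive-ish tests
smallBenchmark <- function(seed = 11, nMolecules = 240, nLabelClasses = 6) {
  generateBenchmark(fixtureConfig(nClasses = 19, maxDepth = 3,
                                  nLabelClasses = nLabelClasses,
                                  moleculesPerLabel = c(10, 100),
                                  nMolecules = nMolecules, seed = seed))
}

# hand-built PredictionSet over explicit label sets
mkPreds <- function(sets, labels, smiles = NULL) {
  n <- length(sets)
  probs <- matrix(0, n, length(labels), dimnames = list(NULL, labels))
  for (i in seq_len(n)) probs[i, sets[[i]]] <- 1
  new("PredictionSet", smiles = smiles %||% paste0("C", seq_len(n)),
      probabilities = probs, threshold = 0.5, predicted = sets,
      itemErrors = data.frame(index = integer(), smiles = character(),
                              message = character()))
}

# dataset whose truth matrix is given directly (molecule ids must be graph
# classes when graph-based evaluation is exercised)
mkTruth <- function(truthMat, labels, ids) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(labels = t(matrix(truthMat, ncol = length(labels),
                                    dimnames = list(ids, labels)))),
    colData = S4Vectors::DataFrame(smiles = paste0("C", seq_along(ids)),
                                   split = rep("test", length(ids)),
                                   row.names = ids))
  new("LabeledDataset", se)
}

# stub model with all-zero parameters (=> every logit 0, probability 0.5)
zeroLogitModel <- function(labels = c("L:1", "L:2"), vocabTokens = c("C", "O")) {
  vocab <- buildVocabulary(list(vocabTokens))
  cfg <- encoderConfig(layers = 1L, heads = 2L, embeddingDim = 8L,
                       maxLength = 8L, epochs = 1L, seed = 1L)
  params <- OntoSmiles:::.initParams(cfg, vocabularySize(vocab), length(labels))
  params <- lapply(params, function(p) p * 0)
  new("TrainedModel", params = params, config = cfg, vocab = vocab,
      labelOrder = labels,
      trainingLog = data.frame(epoch = integer(), trainLoss = numeric(),
                               valMicroF1 = numeric()),
      bestEpoch = 0L, vocabHash = "stub")
}
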