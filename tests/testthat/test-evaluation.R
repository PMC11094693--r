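test_that("micro and macro F1 match the hand-computed example", {
  labels <- c("A", "B")
  truth <- mkTruth(rbind(c(1, 0), c(1, 1)), labels, c("m1", "m2"))
  preds <- mkPreds(list("A", "A"), labels)
  rep <- f1Report(preds, truth)
  expect_equal(microF1(rep), 5 / 6)    # (1 + 2/3) / 2
  expect_equal(macroF1(rep), 0.5)      # (1 + 0) / 2

  # perfect predictions
  perfect <- mkPreds(list("A", c("A", "B")), labels)
  repP <- f1Report(perfect, truth)
  expect_equal(microF1(repP), 1)
  expect_equal(macroF1(repP), 1)

  # all-negative predictions with non-empty truths
  none <- mkPreds(list(character(), character()), labels)
  expect_equal(microF1(f1Report(none, truth)), 0)
})

test_that("macro F1 excludes labels absent from truth and prediction", {
  labels <- c("A", "B", "C")
  truth <- mkTruth(rbind(c(1, 0, 0), c(1, 0, 0)), labels, c("m1", "m2"))
  preds <- mkPreds(list("A", "A"), labels)
  rep <- f1Report(preds, truth)
  expect_identical(rep@excludedLabels, c("B", "C"))
  expect_equal(macroF1(rep), 1)        # only A enters the mean
  expect_true(is.na(perClassF1(rep)["B"]))
})

test_that("pooled micro F1 differs from datapoint-averaged when set sizes vary", {
  labels <- c("A", "B")
  truth <- mkTruth(rbind(c(1, 0), c(1, 1)), labels, c("m1", "m2"))
  preds <- mkPreds(list("A", "A"), labels)
  pooled <- f1Report(preds, truth, micro = "pooled")
  # pooled counts: TP=2, FP=0, FN=1 -> 2*2/(2*2+0+1) = 0.8
  expect_equal(microF1(pooled), 0.8)
  expect_false(isTRUE(all.equal(microF1(pooled), 5 / 6)))
})

test_that("correct non-redundant predictions drop inferable superclasses", {
  g <- toyGraph(list(B = "A", C = "B"))
  expect_identical(correctNonredundant(g, c("A", "B"), c("A", "B", "C")), "B")
  expect_identical(correctNonredundant(g, c("A", "B"), character()), character())
  sib <- toyGraph(list(B = "A", C = "A"))
  expect_setequal(correctNonredundant(sib, c("B", "C"), c("B", "C")), c("B", "C"))
  # never two comparable classes in the output
  for (seed in 1:6) {
    gr <- randomDAG(10, seed)
    pred <- sample(classIds(gr), 5)
    anc <- sample(classIds(gr), 6)
    out <- correctNonredundant(gr, pred, anc)
    for (x in out) expect_length(intersect(transitiveSuperclasses(gr, x), out), 0)
  }
})

test_that("root path histograms accumulate per-molecule correct predictions", {
  g <- toyGraph(list(B = "A", C = "B", m = "C"), smiles = c(m = "CC"))
  labels <- c("B", "C")
  truth <- mkTruth(rbind(c(1, 1)), labels, "m")
  preds <- mkPreds(list(c("B", "C")), labels)
  h <- rootPathHistogram(preds, truth, g, "A")
  # C is the only non-redundant correct prediction; C -> B -> A has 2 edges
  expect_identical(pathCounts(h), c("2" = 1))

  # no correct predictions anywhere -> empty histogram
  predsWrong <- mkPreds(list(character()), labels)
  expect_length(pathCounts(rootPathHistogram(predsWrong, truth, g, "A")), 0)

  # diamond: both diamond arms counted by the DFS oracle
  gd <- toyGraph(list(B = "A", C = "A", D = c("B", "C"), m = "D"),
                 smiles = c(m = "CC"))
  truthD <- mkTruth(rbind(c(1, 1, 1)), c("B", "C", "D"), "m")
  predsD <- mkPreds(list(c("D")), c("B", "C", "D"))
  hD <- pathCounts(rootPathHistogram(predsD, truthD, gd, "A"))
  oracle <- dfsPathOracle(gd, "D", "A")
  expect_identical(hD[order(names(hD))], oracle[order(names(oracle))])
})

test_that("parent distances match a BFS oracle and flag incomparable molecules", {
  skip_if_not_installed("igraph")
  # chain: molecule's asserted parent is C; predicting C gives distance 0,
  # predicting B (C's parent) gives 1
  g <- toyGraph(list(B = "A", C = "B", m = "C"), smiles = c(m = "CC"))
  truth <- mkTruth(rbind(c(1, 1)), c("B", "C"), "m")
  d0 <- parentDistance(mkPreds(list("C"), c("B", "C")), truth, g)
  expect_identical(d0$minDistance, 0)
  d1 <- parentDistance(mkPreds(list("B"), c("B", "C")), truth, g)
  expect_identical(d1$minDistance, 1)
  expect_identical(d1$nComparable, 1L)

  # random fixtures against igraph shortest paths
  for (seed in 1:6) {
    gr <- randomDAG(12, seed, smilesProb = 0)
    ids <- classIds(gr)
    leaves <- ids[!ids %in% unlist(gr@parents)]
    mol <- leaves[length(leaves)]
    anc <- transitiveSuperclasses(gr, mol)
    if (length(anc) < 2) next
    predSet <- sample(anc, min(3, length(anc)))
    labels <- sort(anc)
    truthR <- mkTruth(matrix(1, 1, length(labels)), labels, mol)
    pd <- parentDistance(mkPreds(list(predSet), labels), truthR, gr)
    # oracle: igraph distances from each asserted parent upward
    ig <- asIgraph(gr)
    asserted <- directNonredundantParents(gr, anc)
    dm <- igraph::distances(ig, v = asserted, to = predSet, mode = "out")
    comparable <- dm[is.finite(dm)]
    if (length(comparable)) {
      expect_equal(pd$minDistance, min(comparable))
      expect_equal(pd$meanDistance, mean(comparable))
    } else {
      expect_true(is.na(pd$minDistance))
      expect_identical(attr(pd, "nExcluded"), 1L)
    }
  }
})

test_that("the four-way specificity comparison applies the precedence rules", {
  g <- toyGraph(list(B = "A", C = "B", m = "C"), smiles = c(m = "CC"))
  truth <- mkTruth(rbind(c(1, 1, 1)), c("A", "B", "C"), "m")
  labsA <- c("A", "B", "C")

  # A predicts B, B predicts A (a superclass): A's prediction more specific
  tab <- specificityComparison(mkPreds(list("B"), labsA),
                               mkPreds(list("A"), labsA), truth, g)
  expect_identical(unname(specificityCounts(tab)["more_specific"]), 1)
  expect_identical(tab@nPairs, 1L)

  # identical correct sets -> equally specific
  tab2 <- specificityComparison(mkPreds(list(c("B", "C")), labsA),
                                mkPreds(list(c("B", "C")), labsA), truth, g)
  expect_identical(unname(specificityCounts(tab2)["equally_specific"]), 2)
  expect_equal(unname(specificityPercentages(tab2)["equally_specific"]), 100)

  # B predicts a subclass of A's prediction -> A less specific
  tab3 <- specificityComparison(mkPreds(list("B"), labsA),
                                mkPreds(list("C"), labsA), truth, g)
  expect_identical(unname(specificityCounts(tab3)["less_specific"]), 1)

  # incomparable correct class -> not comparable
  g2 <- toyGraph(list(B = "A", C = "A", m = c("B", "C")), smiles = c(m = "CC"))
  truth2 <- mkTruth(rbind(c(1, 1)), c("B", "C"), "m")
  tab4 <- specificityComparison(mkPreds(list("B"), c("B", "C")),
                                mkPreds(list("C"), c("B", "C")), truth2, g2)
  expect_identical(unname(specificityCounts(tab4)["not_comparable"]), 1)
})

test_that("specificity percentages always sum to one hundred", {
  for (seed in 1:5) {
    b <- smallBenchmark(seed = seed + 20, nMolecules = 80)
    test <- datasetPartition(b$dataset, "test")
    labs <- labelOrder(test)
    tmat <- labelMatrix(test)
    set.seed(seed)
    randSets <- function() lapply(seq_len(nrow(tmat)), function(i)
      sample(labs, sample(0:3, 1)))
    tab <- specificityComparison(mkPreds(randSets(), labs),
                                 mkPreds(randSets(), labs), test, b$graph)
    if (tab@nPairs > 0)
      expect_lt(abs(sum(specificityPercentages(tab)) - 100), 0.05)
  }
})
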