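test_that("label matrices are filled by transitive closure", {
  g <- toyGraph(list(B = "A", mol = "B"), smiles = c(mol = "CCO"))
  sel <- selectLabelClasses(g, "A", 1)
  expect_setequal(labelClasses(sel), c("B"))
  # force both labels via threshold 1 on a richer fixture
  g2 <- toyGraph(list(B = "A", m1 = "B", m2 = "B"),
                 smiles = c(m1 = "C", m2 = "CC"))
  sel2 <- selectLabelClasses(g2, "A", 2)
  ds <- buildLabeledDataset(g2, sel2)
  m <- labelMatrix(ds)
  expect_identical(dim(m), c(2L, 1L))
  expect_true(all(m[, "B"] == 1))
})

test_that("molecules without selected ancestors keep all-zero rows with a warning", {
  g <- toyGraph(list(B = "A", C = "A", m1 = "B", m2 = "B", stray = "C"),
                smiles = c(m1 = "C", m2 = "CC", stray = "CCC"))
  sel <- selectLabelClasses(g, "A", 2)   # only B selected
  expect_warning(ds <- buildLabeledDataset(g, sel), "no selected label")
  expect_identical(ncol(ds), 3L)
  expect_identical(unname(rowSums(labelMatrix(ds))[ "stray" ]), 0)
  dsDrop <- suppressWarnings(buildLabeledDataset(g, sel, dropEmpty = TRUE))
  expect_identical(ncol(dsDrop), 2L)
})

test_that("ancestor label columns dominate descendant columns on random benchmarks", {
  for (seed in c(3, 7)) {
    b <- generateBenchmark(fixtureConfig(nClasses = 19, nLabelClasses = 5,
                                         nMolecules = 150, seed = seed,
                                         subconceptsPerConcept = seed %% 2))
    m <- labelMatrix(b$dataset)
    labs <- colnames(m)
    for (j in labs) {
      for (a in intersect(transitiveSuperclasses(b$graph, j), labs)) {
        expect_true(all(m[, a] >= m[, j]),
                    info = paste("ancestor", a, "descendant", j, "seed", seed))
      }
    }
  }
})

test_that("splitting partitions molecules by largest-remainder fractions", {
  b <- smallBenchmark(seed = 5, nMolecules = 200)
  sp <- splitAssignments(b$dataset)
  expect_false(anyNA(sp))
  tb <- table(sp)
  # 200 * (0.85, 0.0225, 0.1275) = (170, 4.5, 25.5); the remainder tie
  # breaks train > test > validation, so test takes the extra molecule
  expect_identical(as.integer(tb[c("train", "validation", "test")]),
                   c(170L, 4L, 26L))
  # disjoint and exhaustive by construction of a total assignment
  expect_identical(sum(tb), 200L)
})

test_that("splits are deterministic in the seed and refuse double splitting", {
  mols <- paste0("m", 1:10)
  sm <- setNames(strrep("C", 1:10), mols)
  g <- toyGraph(c(list(B = "A"), setNames(rep("B", 10), mols)), smiles = sm)
  sel <- selectLabelClasses(g, "A", 10)
  ds <- buildLabeledDataset(g, sel)
  cfg <- splitConfig(train = 0.5, validation = 0.2, test = 0.3, seed = 42)
  s1 <- splitDataset(ds, cfg)
  s2 <- splitDataset(ds, cfg)
  expect_identical(splitAssignments(s1), splitAssignments(s2))
  s3 <- splitDataset(ds, splitConfig(train = 0.5, validation = 0.2,
                                     test = 0.3, seed = 43))
  expect_false(identical(splitAssignments(s1), splitAssignments(s3)))
  expect_error(splitDataset(s1, splitConfig()), "already has a split")
})

test_that("a single molecule lands in the largest-fraction partition", {
  g <- toyGraph(list(B = "A", m1 = "B"), smiles = c(m1 = "C"))
  sel <- selectLabelClasses(g, "A", 1)
  ds <- splitDataset(buildLabeledDataset(g, sel), splitConfig(seed = 1))
  expect_identical(unname(splitAssignments(ds)), "train")
})

test_that("split config validates fractions", {
  expect_error(splitConfig(train = 0.5, validation = 0.2, test = 0.2), "sum to 1")
  expect_error(splitConfig(train = -0.1, validation = 0.55, test = 0.55), "lie in")
  # zero fractions are allowed (prior-version protocol)
  expect_silent(splitConfig(train = 0.9775, validation = 0.0225, test = 0))
})

test_that("prior-version datasets exclude shared test molecules and relabel to old labels", {
  # new version: two label concepts B, C; old version: C dropped below
  # threshold (one member lost), so old labels are just B
  newG <- toyGraph(list(B = "A", C = "A",
                        m1 = "B", m2 = "B", m3 = "B", m4 = c("B", "C"),
                        m5 = "C", m6 = "C"),
                   smiles = c(m1 = "C", m2 = "CC", m3 = "CCC", m4 = "CCCC",
                              m5 = "CCCCC", m6 = "OC"))
  oldG <- toyGraph(list(B = "A", C = "A",
                        m1 = "B", m2 = "B", m3 = "B", m4 = c("B", "C"),
                        m5 = "C"),
                   smiles = c(m1 = "C", m2 = "CC", m3 = "CCC", m4 = "CCCC",
                              m5 = "CCCCC"))
  newSel <- selectLabelClasses(newG, "A", 2)
  expect_setequal(labelClasses(newSel), c("B", "C"))
  oldSel <- selectLabelClasses(oldG, "A", 3)
  expect_identical(labelClasses(oldSel), "B")

  newDs <- splitDataset(buildLabeledDataset(newG, newSel),
                        splitConfig(0.5, 0.25, 0.25, seed = 3))
  # m5 has no selected ancestor in the old selection: all-zero row warning
  res <- suppressWarnings(derivePriorVersionDataset(oldG, oldSel, newDs, seed = 9))

  testIds <- molecules(datasetPartition(newDs, "test"))$id
  oldIds <- molecules(res$trainval)$id
  expect_length(intersect(oldIds, testIds), 0L)
  expect_true(all(splitAssignments(res$trainval) %in% c("train", "validation")))

  # shared test set relabeled to the old label order; the dropped class's
  # column is absent from both returns
  expect_identical(labelOrder(res$test), labelClasses(oldSel))
  expect_identical(labelOrder(res$trainval), labelClasses(oldSel))
  expect_identical(molecules(res$test)$id, testIds)
  # truth of relabeled rows agrees with old-graph closure
  for (id in intersect(testIds, classIds(oldG))) {
    anc <- transitiveSuperclasses(oldG, id)
    expect_identical(unname(labelMatrix(res$test)[id, "B"]),
                     as.integer("B" %in% anc))
  }
})

test_that("dataset serialization round-trips through the plain-text format", {
  b <- smallBenchmark(seed = 8, nMolecules = 60)
  dir <- withr::local_tempdir()
  writeLabeledDataset(b$dataset, dir)
  back <- readLabeledDataset(dir)
  expect_identical(labelOrder(back), labelOrder(b$dataset))
  expect_identical(molecules(back), molecules(b$dataset))
  expect_identical(unname(labelMatrix(back)), unname(labelMatrix(b$dataset)))
})
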