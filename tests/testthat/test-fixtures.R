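test_that("generated ontologies are rooted DAGs reaching the root", {
  cfg1 <- fixtureConfig(nClasses = 1, nLabelClasses = 1, nMolecules = 1)
  g1 <- generateOntology(cfg1)
  expect_length(g1, 1L)
  expect_length(g1@parents[[1]], 0L)

  for (seed in 1:30) {
    cfg <- fixtureConfig(nClasses = sample(5:40, 1),
                         maxDepth = sample(2:4, 1),
                         multiParentProbability = runif(1, 0, 0.5),
                         nLabelClasses = 2, nMolecules = 10, seed = seed)
    g <- generateOntology(cfg)
    # validity (incl. acyclicity) is enforced at construction; every class
    # must reach the root
    root <- classIds(g)[1]
    for (id in classIds(g)[-1]) {
      expect_true(root %in% transitiveSuperclasses(g, id),
                  info = paste("seed", seed, "id", id))
    }
  }
})

test_that("ontology generation is deterministic in the seed", {
  cfg <- fixtureConfig(seed = 77, nClasses = 25, nLabelClasses = 5,
                       nMolecules = 100)
  g1 <- generateMolecules(generateOntology(cfg), cfg)
  g2 <- generateMolecules(generateOntology(cfg), cfg)
  expect_identical(classIds(g1), classIds(g2))
  expect_identical(g1@parents, g2@parents)
  expect_identical(g1@smiles, g2@smiles)
})

test_that("molecules carry the motifs of all their concept ancestors", {
  cfg <- fixtureConfig(nClasses = 19, nLabelClasses = 6, nMolecules = 120,
                       subconceptsPerConcept = 1L, seed = 13)
  g <- generateMolecules(generateOntology(cfg), cfg)
  motif <- c(g@metadata$conceptMotif, g@metadata$subconceptMotif)
  mols <- grep("^TOY:1", classIds(g), value = TRUE)
  expect_gt(length(mols), 0)
  for (mol in sample(mols, 30)) {
    tks <- tokens(tokenizeSmiles(classSmiles(g)[[mol]]))
    for (anc in transitiveSuperclasses(g, mol)) {
      if (anc %in% names(motif)) {
        motifTok <- tokens(tokenizeSmiles(motif[[anc]]))[1]
        expect_true(motifTok %in% tks,
                    info = paste(mol, "missing motif of", anc))
      }
    }
  }
})

test_that("every generated SMILES tokenizes losslessly", {
  cfg <- fixtureConfig(nClasses = 25, nLabelClasses = 8, nMolecules = 400,
                       motifLength = 2L, seed = 21)
  g <- generateMolecules(generateOntology(cfg), cfg)
  sm <- classSmiles(g)
  sm <- sm[!is.na(sm)]
  expect_length(sm, 400L)
  for (s in sm) expect_identical(paste(tokens(tokenizeSmiles(s)), collapse = ""), s)
})

test_that("benchmarks keep exactly the concept classes as labels", {
  b <- smallBenchmark(seed = 31)
  g <- b$graph
  conceptish <- c(g@metadata$concepts,
                  unlist(g@metadata$subconcepts, use.names = FALSE))
  expect_setequal(labelClasses(b$selection), conceptish)
  # member counts at least the threshold
  expect_true(all(memberCounts(b$selection) >= b$selection@minMembers))
})

test_that("class sizes span at least a tenfold imbalance", {
  for (seed in c(2, 14)) {
    b <- generateBenchmark(fixtureConfig(nClasses = 31, nLabelClasses = 10,
                                         nMolecules = 600, seed = seed))
    counts <- memberCounts(b$selection)
    expect_gte(max(counts) / min(counts), 10)
  }
})

test_that("benchmark serialization is byte-identical under one seed", {
  cfg <- fixtureConfig(nClasses = 19, nLabelClasses = 5, nMolecules = 80,
                       seed = 55)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeLabeledDataset(generateBenchmark(cfg)$dataset, d1)
  writeLabeledDataset(generateBenchmark(cfg)$dataset, d2)
  for (f in c("molecules.tsv", "labels.tsv", "label_order.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("generated benchmarks satisfy the dataset invariants", {
  b <- smallBenchmark(seed = 41)
  m <- labelMatrix(b$dataset)
  sp <- splitAssignments(b$dataset)
  expect_false(anyNA(sp))
  expect_identical(sort(unique(unname(sp))), sort(c("test", "train", "validation")))
  # every molecule's labels equal its ancestor set intersected with labels
  for (id in sample(rownames(m), 20)) {
    anc <- transitiveSuperclasses(b$graph, id)
    expect_setequal(colnames(m)[m[id, ] == 1], intersect(anc, colnames(m)))
  }
})

test_that("a bag-of-tokens baseline decodes the labels almost perfectly", {
  b <- smallBenchmark(seed = 61, nMolecules = 300)
  train <- datasetPartition(b$dataset, "train")
  test <- datasetPartition(b$dataset, "test")
  vocab <- buildVocabulary(lapply(molecules(train)$smiles, tokenizeSmiles))
  bl <- trainTokenBaseline(train, vocab)
  rep <- f1Report(predictBaseline(bl, molecules(test)$smiles), test)
  expect_gte(macroF1(rep), 0.9)
})
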