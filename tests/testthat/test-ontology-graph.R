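test_that("transitive superclasses cover chains, diamonds and roots", {
  chain <- toyGraph(list(B = "A", C = "B"))
  expect_setequal(transitiveSuperclasses(chain, "C"), c("A", "B"))
  expect_identical(transitiveSuperclasses(chain, "A"), character())

  diamond <- toyGraph(list(B = "A", C = "A", D = c("B", "C")))
  expect_setequal(transitiveSuperclasses(diamond, "D"), c("A", "B", "C"))

  expect_error(transitiveSuperclasses(chain, "Z"), "unknown class")
})

test_that("transitive superclasses form a transitively closed relation and match igraph", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    g <- randomDAG(15, seed)
    ig <- asIgraph(g)
    for (id in classIds(g)) {
      anc <- transitiveSuperclasses(g, id)
      oracle <- setdiff(names(igraph::subcomponent(ig, id, mode = "out")), id)
      expect_setequal(anc, oracle)
      for (b in anc) {
        expect_true(all(transitiveSuperclasses(g, b) %in% anc))
      }
    }
  }
})

test_that("member counts tally SMILES-bearing proper subclasses only", {
  g <- toyGraph(list(B = "A", C = "A", D = "A"),
                smiles = c(B = "CC", C = "CCO"))
  expect_identical(memberCount(g, "A"), 2L)
  expect_identical(memberCount(g, "B"), 0L)   # leaf

  # a class's own SMILES never counts toward its member count
  g2 <- toyGraph(list(B = "A"), smiles = c(A = "C", B = "CC"))
  expect_identical(memberCount(g2, "A"), 1L)
  expect_identical(memberCount(g2, "B"), 0L)
})

test_that("adding a SMILES annotation to a descendant never decreases member counts", {
  for (seed in 1:8) {
    g <- randomDAG(12, seed, smilesProb = 0.4)
    before <- vapply(classIds(g), function(i) memberCount(g, i), integer(1))
    bare <- which(is.na(g@smiles))[1]
    if (is.na(bare)) next
    g@smiles[bare] <- "CCC"
    after <- vapply(classIds(g), function(i) memberCount(g, i), integer(1))
    expect_true(all(after >= before))
  }
})

test_that("label-class selection honors the threshold and is antitone in it", {
  g <- toyGraph(list(B = "A", C = "A", b1 = "B", b2 = "B", c1 = "C"),
                smiles = c(b1 = "C", b2 = "CC", c1 = "CCC"))
  sel <- selectLabelClasses(g, "A", 2)
  expect_identical(labelClasses(sel), "B")    # only B has >= 2 members
  expect_identical(unname(memberCounts(sel)["B"]), 2L)

  sel1 <- selectLabelClasses(g, "A", 1)
  expect_true(all(labelClasses(sel) %in% labelClasses(sel1)))
  expect_setequal(labelClasses(sel1), c("B", "C"))
  expect_error(selectLabelClasses(g, "Z", 1), "unknown class")
})

test_that("non-redundant parent reduction removes inferable classes and is idempotent", {
  chain <- toyGraph(list(B = "A", C = "B"))
  expect_identical(directNonredundantParents(chain, c("A", "B")), "B")
  diamond <- toyGraph(list(B = "A", C = "A"))
  expect_setequal(directNonredundantParents(diamond, c("B", "C")), c("B", "C"))
  expect_identical(directNonredundantParents(chain, character()), character())

  for (seed in 1:10) {
    g <- randomDAG(12, seed)
    sub <- sample(classIds(g), 6)
    once <- directNonredundantParents(g, sub)
    expect_identical(directNonredundantParents(g, once), once)
  }
})

test_that("path counting matches the chain and diamond examples", {
  diamond <- toyGraph(list(B = "A", C = "A", D = c("B", "C")))
  expect_identical(pathCounts(countPaths(diamond, "D", "A")), c("2" = 2))
  chain <- toyGraph(list(B = "A", C = "B", D = "C"))
  expect_identical(pathCounts(countPaths(chain, "D", "A")), c("3" = 1))
  # degenerate: source equals target
  expect_identical(pathCounts(countPaths(chain, "A", "A")), c("0" = 1))
  # unreachable target gives an empty histogram
  expect_length(pathCounts(countPaths(chain, "A", "D")), 0)
})

test_that("path counting equals exhaustive DFS enumeration on random DAGs", {
  for (seed in 1:50) {
    n <- sample(4:12, 1)
    g <- randomDAG(n, seed * 31)
    ids <- classIds(g)
    sources <- sample(ids, min(2, n))
    target <- sample(ids, 1)
    got <- pathCounts(countPaths(g, sources, target))
    oracle <- dfsPathOracle(g, sources, target)
    expect_identical(got[order(as.integer(names(got)))],
                     oracle[order(as.integer(names(oracle)))],
                     info = paste("seed", seed))
  }
})

test_that("ontology fragments contain the new class and all root paths", {
  chain <- toyGraph(list(B = "A"))
  fr <- ontologyFragment(chain, "B", "A", "novel")
  expect_setequal(classIds(fr), c("NEW:0000001", "A", "B"))
  expect_identical(fr@parents[[match("NEW:0000001", classIds(fr))]], "B")

  diamond <- toyGraph(list(B = "A", C = "A", D = c("B", "C")))
  fr2 <- ontologyFragment(diamond, c("B", "C"), "A")
  expect_setequal(classIds(fr2), c("NEW:0000001", "A", "B", "C"))
  newIdx <- match("NEW:0000001", classIds(fr2))
  expect_setequal(fr2@parents[[newIdx]], c("B", "C"))

  fr3 <- ontologyFragment(diamond, "A", "A")
  expect_setequal(classIds(fr3), c("NEW:0000001", "A"))

  expect_warning(fr4 <- ontologyFragment(diamond, character(), "A"),
                 "no predicted parents")
  expect_identical(classIds(fr4), "NEW:0000001")

  # off-path classes stay out: D is below the parents, so never included
  expect_false("D" %in% classIds(fr2))
})

test_that("graph validity rejects cycles, duplicate edges and unknown endpoints", {
  expect_error(OntologyGraph(c("A", "B"), parents = list("B", "A")), "cycle")
  expect_error(OntologyGraph(c("A", "B"), parents = list(character(), c("A", "A"))),
               "duplicate")
  expect_error(OntologyGraph(c("A"), parents = list("Z")), "not registered")
})
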