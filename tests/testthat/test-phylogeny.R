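chain2 <- function() {
  # germline -> C1(10) -> C2(11)
  g <- rbind(C1 = c(1L, 0L), C2 = c(1L, 1L))
  cloneTree(g, data.frame(parent = c("germline", "C1"),
                          child = c("C1", "C2")))
}

test_that("hamming distance counts differing loci and checks lengths", {
  expect_equal(hammingDist("00", "00"), 0)
  expect_equal(hammingDist("10", "01"), 2)
  expect_equal(hammingDist("10110", "11010"), 2)
  expect_equal(hammingDist(c(1L, 0L), c(1L, 1L)), 1)
  expect_error(hammingDist("10", "101"), "length mismatch")
})

test_that("parsimony scoring sums edge gains and flags illegal edges", {
  expect_equal(parsimonyScore(chain2()), 2L)
  g <- rbind(C1 = c(1L, 0L), C2 = c(0L, 1L), C3 = c(1L, 1L))
  star <- cloneTree(g, data.frame(parent = rep("germline", 3),
                                  child = c("C1", "C2", "C3")),
                    mode = "free")
  expect_equal(parsimonyScore(star), 4L)
  mixed <- cloneTree(g, data.frame(parent = c("germline", "germline", "C1"),
                                   child = c("C1", "C2", "C3")))
  expect_equal(parsimonyScore(mixed), 3L)
  # an edge losing a mutation is an error in irreversible mode, named
  bad <- cloneTree(g, data.frame(parent = c("germline", "C3", "germline"),
                                 child = c("C3", "C1", "C2")),
                   mode = "free")
  expect_error(parsimonyScore(bad, mode = "irreversible"), "C3->C1")
})

test_that("the search returns the known co-optimal sets on small instances", {
  one <- searchMPTrees(newCloneSet("10"))
  expect_equal(mpScore(one), 1L)
  expect_length(mpTrees(one), 1L)

  # the hand-analysable branching instance: parent of 11 is unresolved
  res <- searchMPTrees(newCloneSet(c("10", "01", "11")))
  expect_equal(mpScore(res), 3L)
  expect_length(mpTrees(res), 2L)
  parents11 <- vapply(mpTrees(res), function(t)
    treeEdges(t)$parent[treeEdges(t)$child == "C3"], character(1L))
  expect_setequal(parents11, c("C1", "C2"))

  chain <- searchMPTrees(newCloneSet(c("100", "110", "111")))
  expect_equal(mpScore(chain), 3L)
  expect_length(mpTrees(chain), 1L)
  expect_equal(treeEdges(mpTrees(chain)[[1L]]),
               data.frame(parent = c("C1", "C2", "germline"),
                          child = c("C2", "C3", "C1"),
                          stringsAsFactors = FALSE))
})

test_that("duplicate genotypes are rejected before the search", {
  g <- rbind(C1 = c(1L, 0L), C2 = c(1L, 0L))
  expect_error(searchMPTrees(g), "duplicate genotypes")
})

test_that("the brute-force oracle enumerates every rooted arborescence", {
  res <- mpBruteForce(newCloneSet(c("10", "01", "11")))
  expect_equal(attr(mpTrees(res), "nCandidates"), 16L)  # 4^(4-2)
  expect_equal(mpScore(res), 3L)
  expect_length(mpTrees(res), 2L)
  single <- mpBruteForce(newCloneSet("1"))
  expect_equal(attr(mpTrees(single), "nCandidates"), 1L)
  big <- matrix(0L, 9, 9); diag(big) <- 1L
  rownames(big) <- sprintf("C%d", 1:9)
  expect_error(mpBruteForce(big), "at most 8 nodes")
})

test_that("search and oracle agree on random clone sets in both modes", {
  for (seed in 1:50) {
    nc <- (seed %% 5L) + 1L
    cs <- randomCloneSet(nc, 3L + (seed %% 5L), seed = seed)
    for (mode in c("irreversible", "free")) {
      a <- searchMPTrees(cs, mode = mode)
      b <- mpBruteForce(cs, mode = mode)
      expect_identical(mpResultKey(a), mpResultKey(b))
    }
  }
})

test_that("the minimum score is bounded below by the mutation union", {
  # equality iff no mutation is gained twice (no homoplasy)
  for (seed in 1:10) {
    tr <- simulateCloneTree((seed %% 4L) + 2L, (seed %% 4L) + 4L,
                            seed = seed)
    g <- treeGenotypes(tr)
    clones <- g[setdiff(rownames(g), "germline"), , drop = FALSE]
    res <- searchMPTrees(clones)
    expect_equal(mpScore(res), sum(colSums(clones) > 0L))
  }
  # planted homoplasy forces the score above the union bound
  trH <- simulateCloneTree(6, 8, allowReiteration = TRUE,
                           reiterationProb = 1, seed = 3)
  gH <- treeGenotypes(trH)
  clonesH <- gH[setdiff(rownames(gH), "germline"), , drop = FALSE]
  resH <- searchMPTrees(clonesH)
  expect_gt(mpScore(resH), sum(colSums(clonesH) > 0L))
})

test_that("irreversible minimum score is never below the free-mode score", {
  for (seed in 1:20) {
    cs <- randomCloneSet((seed %% 4L) + 2L, 4L + (seed %% 3L), seed = seed)
    expect_gte(mpScore(searchMPTrees(cs, mode = "irreversible")),
               mpScore(searchMPTrees(cs, mode = "free")))
  }
})

test_that("branch-and-bound beyond the exhaustive limit stays complete", {
  for (seed in 1:10) {
    cs <- randomCloneSet(5L, 6L, seed = 100L + seed)
    a <- searchMPTrees(cs, exhaustiveLimit = 3L)   # forces B&B
    b <- mpBruteForce(cs)
    expect_equal(a@method, "branch_and_bound")
    expect_identical(mpResultKey(a), mpResultKey(b))
  }
})

test_that("consensus edges are those shared by every co-optimal tree", {
  uniq <- searchMPTrees(newCloneSet(c("100", "110", "111")))
  expect_equal(nrow(consensusEdges(uniq)), 3L)
  res <- searchMPTrees(newCloneSet(c("10", "01", "11")))
  ce <- consensusEdges(res)
  expect_equal(ce, data.frame(parent = c("germline", "germline"),
                              child = c("C1", "C2"),
                              stringsAsFactors = FALSE))
  expect_error(consensusEdges(new("MPResult", score = 0L, trees = list(),
                                  mode = "free", method = "exhaustive")),
               "empty")
})

test_that("newick output round-trips and parses in ape", {
  # chain with internal labels (unifurcations)
  expect_equal(toNewick(chain2()), "((C2)C1)germline;")
  g <- rbind(C1 = c(1L, 0L), C2 = c(0L, 1L), C3 = c(1L, 1L))
  star <- cloneTree(g, data.frame(parent = rep("germline", 3),
                                  child = c("C1", "C2", "C3")),
                    mode = "free")
  expect_equal(toNewick(star), "(C1,C2,C3)germline;")
  ap <- ape::read.tree(text = toNewick(star))
  expect_setequal(ap$tip.label, c("C1", "C2", "C3"))
  expect_equal(ap$node.label, "germline")
  # round-trip property on random simulated trees
  for (seed in 1:30) {
    tr <- simulateCloneTree((seed %% 6L) + 1L, (seed %% 6L) + 3L,
                            seed = seed)
    rt <- readNewick(toNewick(tr))
    expect_equal(rt$root, "germline")
    e <- treeEdges(tr)
    e <- e[order(e$parent, e$child), ]
    rownames(e) <- NULL
    expect_equal(rt$edges, e)
  }
})
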