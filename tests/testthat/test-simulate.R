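test_that("simulated clone trees satisfy the structural invariants", {
  for (seed in 1:25) {
    nc <- (seed %% 6L) + 1L
    tr <- simulateCloneTree(nc, nc + 2L, seed = seed)
    g <- treeGenotypes(tr)
    e <- treeEdges(tr)
    expect_true(all(g["germline", ] == 0L))
    expect_equal(nrow(g), nc + 1L)
    expect_false(anyDuplicated(apply(g, 1L, genoKey)) > 0L)
    # spanning, rooted, irreversible growth
    expect_setequal(e$child, setdiff(rownames(g), "germline"))
    for (i in seq_len(nrow(e)))
      expect_true(all(g[e$parent[i], ] <= g[e$child[i], ]))
  }
})

test_that("founder-first trees make the founder truncal and the secondary late", {
  for (seed in 1:25) {
    nc <- (seed %% 5L) + 2L
    tr <- simulateCloneTree(nc, nc + 2L, founderFirst = TRUE, seed = seed)
    g <- treeGenotypes(tr)
    clones <- setdiff(rownames(g), "germline")
    expect_true(all(g[clones, tr@founderMutation] == 1L))
    expect_true(any(g[clones, tr@secondaryMutation] == 0L))
    expect_true(any(g[clones, tr@secondaryMutation] == 1L))
  }
  # a single clone cannot express the order; the secondary stays unused
  tr1 <- simulateCloneTree(1, 3, founderFirst = TRUE, seed = 4)
  g1 <- treeGenotypes(tr1)
  expect_equal(unname(g1["C1", tr1@founderMutation]), 1L)
  expect_equal(unname(g1["C1", tr1@secondaryMutation]), 0L)
})

test_that("forced reiteration plants a mutation gained on two branches", {
  for (seed in 1:10) {
    tr <- simulateCloneTree(6, 8, allowReiteration = TRUE,
                            reiterationProb = 1, seed = seed)
    expect_length(tr@reiteratedMutation, 1L)
    gains <- unlist(edgeGains(tr)$gained)
    expect_gte(sum(gains == tr@reiteratedMutation), 2L)
  }
})

test_that("infeasible tree parameters raise explicit errors", {
  expect_error(simulateCloneTree(4, 3, seed = 1), "infeasible")
  expect_error(simulateCloneTree(1, 1, founderFirst = TRUE, seed = 1),
               "infeasible")
  expect_error(simulateCloneTree(1, 3, allowReiteration = TRUE, seed = 1),
               "infeasible")
  expect_error(simulateCloneTree(9, 12, seed = 1), "nClones")
})

test_that("population frequencies are simplex vectors with a germline T-cell control", {
  for (seed in 1:15) {
    tr <- simulateCloneTree((seed %% 6L) + 1L, (seed %% 6L) + 3L,
                            seed = seed)
    pop <- simulatePopulation(tr, seed = seed)
    expect_true(all(abs(colSums(pop@freqs) - 1) < 1e-9))
    expect_true(all(pop@freqs >= 0 & pop@freqs <= 1))
    expect_equal(unname(pop@freqs["germline", "tcell"]), 1)
    expect_equal(unname(pop@freqs["germline", "blast"]), 0)
  }
})

test_that("a noise-free single-clone chip calls identically in every well", {
  tr <- simulateCloneTree(1, 3, seed = 2)
  pop <- simulatePopulation(tr, seed = 2)
  chip <- sampleChip(tr, pop, "blast", 48, noiseFree(), seed = 2)
  gm <- callGenotypes(chip, assayPanel(colnames(treeGenotypes(tr))))
  expect_true(all(qcStatus(gm) == "pass"))
  expect_equal(nrow(unique(calls(gm))), 1L)
})

test_that("ado_rate=1 reads every sampled het locus as wild type", {
  tr <- simulateCloneTree(1, 3, seed = 3)
  pop <- simulatePopulation(tr, seed = 3)
  chip <- sampleChip(tr, pop, "blast", 48,
                     noiseModel(adoRate = 1, fpRate = 0, locusFailRate = 0,
                                cellFailRate = 0), seed = 3)
  gm <- callGenotypes(chip, assayPanel(colnames(treeGenotypes(tr))))
  expect_true(all(calls(gm) == "WT"))
})

test_that("observed false-WT fraction matches the binomial dropout model", {
  # Monte-Carlo oracle: dropout is Bernoulli(ado) per het (cell, locus)
  ado <- 0.1
  n <- 20000L
  tr <- simulateCloneTree(1, 2, seed = 5)      # one clone, het everywhere
  pop <- simulatePopulation(tr, seed = 5)
  chip <- sampleChip(tr, pop, "blast", n,
                     noiseModel(adoRate = ado, fpRate = 0,
                                locusFailRate = 0, cellFailRate = 0),
                     seed = 5)
  gm <- callGenotypes(chip, assayPanel(colnames(treeGenotypes(tr))))
  hetCalls <- calls(gm)                        # every locus is truly mutant
  obs <- mean(hetCalls == "WT")
  se <- sqrt(ado * (1 - ado) / length(hetCalls))
  expect_lt(abs(obs - ado), 3 * se)
})

test_that("seeded chips are bit-reproducible and reject bad inputs", {
  tr <- simulateCloneTree(3, 5, seed = 6)
  pop <- simulatePopulation(tr, seed = 6)
  c1 <- sampleChip(tr, pop, "blast", 48, seed = 42)
  c2 <- sampleChip(tr, pop, "blast", 48, seed = 42)
  expect_identical(c1, c2)
  c3 <- sampleChip(tr, pop, "blast", 48, seed = 43)
  expect_false(identical(c1$ct, c3$ct))
  expect_error(sampleChip(tr, pop, "marrow", 48, seed = 1),
               "unknown compartment")
  expect_error(sampleChip(tr, pop, "blast", 0, seed = 1), "nCells")
})

test_that("xenograft bottlenecks reshape frequencies as specified", {
  tr <- simulateCloneTree(3, 5, seed = 8)
  pop <- simulatePopulation(tr, seed = 8)
  # point mass at dominance 1
  g1 <- simulateXenograft(pop, "C2", 1.0, seed = 1)
  expect_equal(unname(g1@freqs["C2", "graft"]), 1)
  expect_equal(sum(g1@freqs[, "graft"]), 1)
  # dominance 0.7 with two permitted clones
  g2 <- simulateXenograft(pop, "C2", 0.7, others = c("C1", "C3"), seed = 1)
  expect_equal(sum(g2@freqs[, "graft"]), 1)
  expect_gte(g2@freqs["C2", "graft"], 0.7)
  expect_true(all(g2@freqs[c("C1", "C3"), "graft"] > 0))
  # a clone absent at diagnosis may engraft
  popx <- addClones(pop, "NOVEL")
  expect_true(all(popx@freqs["NOVEL", ] == 0))
  g3 <- simulateXenograft(popx, "C2", 0.6, others = "NOVEL", seed = 1)
  expect_gt(g3@freqs["NOVEL", "graft"], 0)
  expect_error(simulateXenograft(pop, "C9", 0.5, seed = 1), "unknown clone")
})

test_that("ground truth serialises to JSON for recovery tests", {
  tr <- simulateCloneTree(3, 5, founderFirst = TRUE, seed = 9)
  pop <- simulatePopulation(tr, seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  writeTruth(tr, pop, noiseModel(), 9L, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$seed, 9L)
  expect_equal(obj$founder, "DNMT3A")
  expect_equal(sort(names(obj$nodes)), sort(rownames(treeGenotypes(tr))))
})
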