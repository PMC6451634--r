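test_that("containment forces mutation order; incomparable pairs stay open", {
  # every clone with locus2 also has locus1, and C1 has locus1 alone
  cs <- newCloneSet(c("10", "11"))
  pr <- mutationPrecedence(cs)
  expect_equal(pr$pairs$relation[pr$pairs$a == "M01" & pr$pairs$b == "M02"],
               "a_before_b")
  expect_equal(pr$pairs$relation[pr$pairs$a == "M02" & pr$pairs$b == "M01"],
               "b_before_a")
  # disjoint clones cannot be ordered
  pr2 <- mutationPrecedence(newCloneSet(c("10", "01")))
  expect_true(all(pr2$pairs$relation == "unresolved"))
})

test_that("truncal status means presence in every called clone", {
  cs <- newCloneSet(c("10", "11"))
  st <- mutationPrecedence(cs)$status
  expect_equal(st$status[st$mutation == "M01"], "truncal")
  expect_equal(st$status[st$mutation == "M02"], "sub_clonal")
})

test_that("mutations absent from all clones are excluded with a warning", {
  cs <- newCloneSet(c("100", "110"))
  expect_warning(pr <- mutationPrecedence(cs), "M03")
  expect_false("M03" %in% c(pr$pairs$a, pr$pairs$b))
})

test_that("precedence relations are antisymmetric on random clone sets", {
  for (seed in 1:20) {
    cs <- randomCloneSet((seed %% 5L) + 2L, 4L + (seed %% 4L), seed = seed)
    pr <- suppressWarnings(mutationPrecedence(cs))
    p <- pr$pairs
    for (i in seq_len(nrow(p))) {
      rev <- p$relation[p$a == p$b[i] & p$b == p$a[i]]
      if (p$relation[i] == "a_before_b") expect_equal(rev, "b_before_a")
      if (p$relation[i] == "b_before_a") expect_equal(rev, "a_before_b")
    }
    # truncal mutations precede (or are unresolved with) every other
    st <- pr$status
    for (tm in st$mutation[st$status == "truncal"]) {
      rels <- p$relation[p$a == tm]
      expect_false(any(rels == "b_before_a"))
    }
  }
})

test_that("reiterated gains are reported per co-optimal tree", {
  chain <- searchMPTrees(newCloneSet(c("100", "110", "111")))
  rr <- detectReiterated(chain)
  expect_equal(rr$perTree, list(character(0)))
  expect_length(rr$inAllTrees, 0L)

  # branching instance: each co-optimal tree reiterates a different locus
  res <- searchMPTrees(newCloneSet(c("10", "01", "11")))
  rr2 <- detectReiterated(res)
  expect_setequal(unlist(rr2$perTree), c("M01", "M02"))
  expect_length(rr2$inAllTrees, 0L)
})

test_that("a planted parallel gain is reiterated in all co-optimal trees", {
  for (seed in c(3, 7, 11)) {
    tr <- simulateCloneTree(6, 8, allowReiteration = TRUE,
                            reiterationProb = 1, seed = seed)
    g <- treeGenotypes(tr)
    clones <- g[setdiff(rownames(g), "germline"), , drop = FALSE]
    rr <- detectReiterated(searchMPTrees(clones))
    expect_true(tr@reiteratedMutation %in% rr$inAllTrees)
  }
})

test_that("query clones classify against the reference in precedence order", {
  # diagnostic: DNMT3A+NPM1c and its DNMT3A ancestor-like clone
  ref <- newCloneSet(c(D1 = "1100", D2 = "1000"),
                     panel = assayPanel(c("DNMT3A", "NPM1c", "TET2",
                                          "WT1")))
  qry <- newCloneSet(c(Q1 = "1100",   # identical -> matched
                       Q2 = "1110",   # extra TET2 -> novel_descendant
                       Q3 = "0010"),  # unrelated
                     panel = ref@panel)
  mp <- mapCloneSets(ref, qry)
  expect_equal(mp$mapping$class, c("matched", "novel_descendant",
                                   "unrelated"))
  expect_equal(mp$mapping$match[1:2], c("D1", "D1"))

  # pre-leukaemic read-out: strict subset of a diagnostic clone
  ref2 <- newCloneSet(c(D1 = "111"),
                      panel = assayPanel(c("DNMT3A", "TET2", "NPM1c")))
  qry2 <- newCloneSet(c(Q1 = "100"), panel = ref2@panel)
  expect_equal(mapCloneSets(ref2, qry2)$mapping$class, "ancestral")

  expect_error(mapCloneSets(ref, qry2), "share one assay panel")
})

test_that("classification is exhaustive and mutually exclusive", {
  classes <- c("matched", "novel_descendant", "ancestral", "unrelated")
  for (seed in 1:15) {
    ref <- randomCloneSet(3L, 5L, seed = seed)
    qry <- randomCloneSet(4L, 5L, seed = seed + 1000L)
    mp <- mapCloneSets(ref, qry)
    expect_equal(nrow(mp$mapping), 4L)
    expect_true(all(mp$mapping$class %in% classes))
    # classes re-derived independently from set relations
    rg <- cloneGenotypes(ref)
    qg <- cloneGenotypes(qry)
    for (i in seq_len(nrow(qg))) {
      eqs <- any(apply(rg, 1L, function(r) all(r == qg[i, ])))
      sups <- any(apply(rg, 1L, function(r)
        all(r <= qg[i, ]) && any(r < qg[i, ])))
      subs <- any(apply(rg, 1L, function(r)
        all(qg[i, ] <= r) && any(qg[i, ] < r)))
      want <- if (eqs) "matched" else if (sups) "novel_descendant"
        else if (subs) "ancestral" else "unrelated"
      expect_equal(mp$mapping$class[i], want)
    }
  }
})

test_that("the dominant query clone is the most frequent, ties by id", {
  panel <- assayPanel(c("A", "B"))
  qry <- newCloneSet(c(Q1 = "10", Q2 = "11"),
                     counts = matrix(c(10, 30), 2, 1,
                                     dimnames = list(c("Q1", "Q2"),
                                                     "graft")),
                     panel = panel)
  ref <- newCloneSet(c(D = "10"), panel = panel)
  expect_equal(mapCloneSets(ref, qry)$dominant, "Q2")
  tie <- newCloneSet(c(Q1 = "10", Q2 = "11"),
                     counts = matrix(c(20, 20), 2, 1,
                                     dimnames = list(c("Q1", "Q2"),
                                                     "graft")),
                     panel = panel)
  expect_equal(mapCloneSets(ref, tie)$dominant, "Q1")
})

test_that("cohort summaries count clones, unions and graft genotypes", {
  panel <- assayPanel(c("DNMT3A", "NPM1c", "TET2"))
  single <- list(
    diagnostic = newCloneSet(c(C1 = "110"), panel = panel),
    graft = newCloneSet(c(G1 = "110"),
                        counts = matrix(40, 1, 1,
                                        dimnames = list("G1", "graft")),
                        panel = panel),
    secondary = "NPM1c")
  multi <- list(
    diagnostic = newCloneSet(c(A = "100", B = "110"), panel = panel),
    graft = newCloneSet(c(B = "110", C = "111"),
                        counts = matrix(c(10, 30), 2, 1,
                                        dimnames = list(c("B", "C"),
                                                        "graft")),
                        panel = panel),
    secondary = "NPM1c")
  sm <- cohortSummary(list(p1 = single, p2 = multi))
  expect_equal(sm$total_distinct_clones, c(1L, 3L))
  expect_equal(sm$clones_graft, c(1L, 2L))
  expect_true(all(sm$dominant_graft_has_secondary))
  # determinism
  expect_identical(sm, cohortSummary(list(p1 = single, p2 = multi)))
  expect_error(cohortSummary(list()), "at least one")
})
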