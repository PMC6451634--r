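## profile matrix helper: build a GenotypeMatrix holding given numbers of
## cells per profile string (over 0/1/?)
gmFromProfiles <- function(counts, compartment = "blast") {
  rows <- unlist(mapply(function(p, n) rep(p, n), names(counts), counts))
  m <- matrix(unlist(lapply(rows, function(p) {
    v <- strsplit(p, "")[[1L]]
    ifelse(v == "1", "MUT", ifelse(v == "0", "WT", "MISSING"))
  })), nrow = length(rows), byrow = TRUE)
  makeGM(m, compartment = rep(compartment, nrow(m)))
}

test_that("profiles are tabulated with incomplete ones listed separately", {
  gm <- gmFromProfiles(c("110" = 30, "100" = 15, "1?0" = 3))
  pr <- enumerateProfiles(gm)
  expect_equal(pr$complete$count[pr$complete$profile == "110"], 30)
  expect_equal(pr$complete$count[pr$complete$profile == "100"], 15)
  expect_equal(pr$incomplete$profile, "1?0")
  expect_equal(pr$incomplete$count, 3)

  one <- enumerateProfiles(gmFromProfiles(c("101" = 12)))
  expect_equal(nrow(one$complete), 1L)

  empty <- makeGM(matrix("WT", 2, 3), qc = rep("control_fail", 2))
  expect_error(enumerateProfiles(empty), "no QC-passing cells")
})

test_that("incomplete profiles are assigned only on a unique match", {
  expect_true(is.na(resolveMissing("1?0", c(A = "110", B = "100"))))
  expect_equal(resolveMissing("1?0", c(A = "110")), "A")
  expect_true(is.na(resolveMissing("0?1", c(A = "110", B = "100"))))
})

test_that("clone calling applies the count and frequency thresholds", {
  # 30 + 15 + 2 leukaemic cells + 1 germline cell = 48 informative
  gm <- gmFromProfiles(c("110" = 30, "100" = 15, "010" = 2, "000" = 1))
  cs <- callClones(gm, minCells = 2, minFreq = 0.05)
  g <- cloneGenotypes(cs)
  keys <- apply(g, 1L, genoKey)
  expect_setequal(keys, c("110", "100", "010"))
  f <- cloneFreqs(cs)[, "blast"]
  expect_equal(unname(f[keys == "110"]), 30 / 48)
  expect_equal(unname(f[keys == "100"]), 15 / 48)
  conf <- cloneConfidence(cs)
  expect_equal(unname(conf[keys == "010"]), "low_frequency")
  expect_equal(unname(conf[keys == "110"]), "called")
  expect_equal(unname(cs@germlineCounts), 1)
})

test_that("sub-threshold dropout artefacts merge into their superset clone", {
  gm <- gmFromProfiles(c("110" = 30, "100" = 1))
  cs <- callClones(gm, minCells = 2, maxAdoLoci = 1)
  expect_equal(nrow(cloneGenotypes(cs)), 1L)
  expect_equal(unname(cloneCounts(cs)[1L, "blast"]), 31)
  # distance 2 is beyond the merge radius -> unassigned
  gm2 <- gmFromProfiles(c("111" = 30, "100" = 1))
  cs2 <- callClones(gm2, minCells = 2, maxAdoLoci = 1)
  expect_equal(unname(cloneCounts(cs2)[1L, "blast"]), 30)
  expect_equal(unname(cs2@unassignedCounts), 1)
})

test_that("a single profile yields one clone at frequency 1", {
  cs <- callClones(gmFromProfiles(c("101" = 48)))
  expect_equal(nrow(cloneGenotypes(cs)), 1L)
  expect_equal(unname(cloneFreqs(cs)[1L, "blast"]), 1)
})

test_that("cell accounting is conserved per compartment", {
  for (seed in 1:8) {
    pt <- simulatePatient(seed, nClones = (seed %% 4L) + 2L, ado = 0.1)
    cs <- pt$clones
    assigned <- colSums(cloneCounts(cs))
    expect_identical(
      unname(assigned + cs@germlineCounts + cs@unassignedCounts),
      unname(cs@totals))
    passComp <- compartments(pt$gm)[qcStatus(pt$gm) == "pass"]
    expect_identical(unname(cs@totals),
                     as.numeric(table(passComp)[names(cs@totals)]))
  }
})

test_that("noise-free clone calling recovers the simulation truth exactly", {
  for (seed in 1:10) {
    pt <- simulatePatient(seed, nClones = (seed %% 6L) + 1L, ado = 0)
    expect_identical(cloneKeySet(cloneGenotypes(pt$clones)),
                     cloneKeySet(treeGenotypes(pt$tree)))
  }
})

test_that("detection probability follows 1-(1-f)^n and the Monte-Carlo oracle", {
  expect_equal(detectionProbability(0, 48), 0)
  expect_equal(detectionProbability(1, 1), 1)
  # independent oracle: binomial sampling of carrier cells
  mc <- withr::with_seed(1L, mean(stats::rbinom(1e6, 48, 0.05) > 0))
  se <- sqrt(mc * (1 - mc) / 1e6)
  expect_lt(abs(detectionProbability(0.05, 48) - mc), 3 * se)
  expect_error(detectionProbability(1.2, 48), "f must")
  expect_error(detectionProbability(0.5, 0), "n must")
})

test_that("detection probability is monotone in frequency and cells", {
  fs <- seq(0, 1, length.out = 20)
  ns <- seq(1, 96, length.out = 20)
  p <- outer(fs, ns, detectionProbability)
  expect_true(all(diff(p) >= 0))       # rows: increasing f
  expect_true(all(t(diff(t(p))) >= 0)) # cols: increasing n
})

test_that("Wilson intervals always contain the point frequency", {
  for (seed in 1:5) {
    n <- 48
    x <- withr::with_seed(seed, sample(0:n, 10, replace = TRUE))
    ci <- wilsonInterval(x, n)
    expect_true(all(ci[, "lower"] <= x / n + 1e-12))
    expect_true(all(ci[, "upper"] >= x / n - 1e-12))
  }
})
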