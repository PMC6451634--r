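## Shared fixture builders. Everything is generated in code under fixed
## seeds; no data files.

noiseFree <- function() noiseModel(0, 0, 0, 0)

genoKey <- function(g) paste(as.integer(g), collapse = "")

## sorted genotype-string set of the non-germline nodes
cloneKeySet <- function(genotypes) {
  keep <- setdiff(rownames(genotypes), "germline")
  unname(sort(apply(genotypes[keep, , drop = FALSE], 1L, genoKey)))
}

## tree topology as a set of genotype-labelled edges (robust to node
## relabelling between simulation and clone calling)
edgeKeySet <- function(tree) {
  g <- treeGenotypes(tree)
  e <- treeEdges(tree)
  sort(paste(apply(g[e$parent, , drop = FALSE], 1L, genoKey),
             apply(g[e$child, , drop = FALSE], 1L, genoKey), sep = ">"))
}

## canonical serialisation of an MPResult's co-optimal set, for equality
## checks between the search and the brute-force oracle
mpResultKey <- function(res) {
  keys <- vapply(mpTrees(res), function(t)
    paste(edgeKeySet(t), collapse = "|"), character(1L))
  paste(mpScore(res), paste(sort(keys), collapse = "||"), sep = "@")
}

## hand-built GenotypeMatrix
makeGM <- function(callsMat, compartment = NULL, qc = NULL, panel = NULL) {
  if (is.null(rownames(callsMat)))
    rownames(callsMat) <- sprintf("cell%03d", seq_len(nrow(callsMat)))
  if (is.null(panel))
    panel <- assayPanel(if (is.null(colnames(callsMat)))
      sprintf("M%02d", seq_len(ncol(callsMat))) else colnames(callsMat))
  colnames(callsMat) <- mutationIds(panel)
  if (is.null(compartment)) compartment <- rep("blast", nrow(callsMat))
  if (is.null(qc)) qc <- rep("pass", nrow(callsMat))
  new("GenotypeMatrix", calls = callsMat, compartment = compartment,
      qc = qc, panel = panel)
}

## random distinct clone genotypes for oracle-equivalence properties
randomCloneSet <- function(nClones, nMut, seed) {
  withr::with_seed(seed, {
    seen <- character(0)
    rows <- list()
    while (length(rows) < nClones) {
      g <- stats::rbinom(nMut, 1L, 0.45)
      if (sum(g) == 0L) next
      k <- genoKey(g)
      if (k %in% seen) next
      seen <- c(seen, k)
      rows[[length(rows) + 1L]] <- g
    }
    m <- do.call(rbind, rows)
    rownames(m) <- sprintf("C%d", seq_len(nClones))
    newCloneSet(m)
  })
}

## one synthetic patient: founder-first tree, blast + stem chips at 48
## cells each, genotype calling and clone calling
simulatePatient <- function(seed, nClones, nMutations = nClones + 2L,
                            ado = 0, founderFirst = TRUE, nCells = 48L) {
  tree <- simulateCloneTree(nClones, nMutations, founderFirst = founderFirst,
                            seed = seed)
  pop <- simulatePopulation(tree, seed = seed)
  nm <- noiseModel(adoRate = ado, fpRate = 0, locusFailRate = 0,
                   cellFailRate = 0)
  panel <- assayPanel(colnames(treeGenotypes(tree)))
  gmB <- callGenotypes(sampleChip(tree, pop, "blast", nCells, nm,
                                  panel = panel, seed = seed * 3L + 1L),
                       panel)
  gmS <- callGenotypes(sampleChip(tree, pop, "stem", nCells, nm,
                                  panel = panel, seed = seed * 3L + 2L),
                       panel)
  gm <- combineGenotypes(gmB, gmS)
  list(tree = tree, pop = pop, panel = panel, gm = gm,
       clones = callClones(gm))
}

## xenograft scenario: a dominant NPM1c-like clone, a planted novel
## descendant carrying one extra panel mutation absent from every
## diagnostic clone (below-detection-at-diagnosis pattern), and a planted
## pre-leukaemic ancestral genotype; graft read out at 96 cells
xenograftCase <- function(seed) {
  nClones <- (seed %% 4L) + 2L
  tree <- simulateCloneTree(nClones, nClones + 2L, founderFirst = TRUE,
                            seed = seed)
  g <- treeGenotypes(tree)
  extra <- "TET2x"
  gx <- cbind(g, matrix(0L, nrow(g), 1L, dimnames = list(NULL, extra)))
  sec <- tree@secondaryMutation
  secClones <- rownames(gx)[gx[, sec] == 1L & rownames(gx) != "germline"]
  u <- secClones[order(-rowSums(gx[secClones, , drop = FALSE]),
                       secClones)][1L]
  ## planted ancestral-type genotype: a strict subset of a diagnostic
  ## clone that contains no complete diagnostic clone (so the precedence
  ## order equality > superset > subset lands on "ancestral"): the
  ## founder-only genotype, unless that is itself a clone, in which case
  ## the dominant clone stripped of the founder mutation
  founder <- tree@founderMutation
  anc <- gx[u, ]; anc[] <- 0L; anc[founder] <- 1L
  keys <- apply(gx[setdiff(rownames(gx), "germline"), , drop = FALSE],
                1L, genoKey)
  if (genoKey(anc) %in% keys) {
    anc <- gx[u, ]
    anc[founder] <- 0L
  }
  novel <- gx[u, ]
  novel[extra] <- 1L
  nodes <- rbind(gx, NOVEL = novel, ANC = anc)
  pop <- addClones(simulatePopulation(tree, seed = seed), c("NOVEL", "ANC"))
  graftPop <- simulateXenograft(pop, u, 0.5, others = c("NOVEL", "ANC"),
                                shareFloor = 0.9, seed = seed)
  panel <- assayPanel(colnames(nodes))
  nm <- noiseFree()
  gmDiag <- combineGenotypes(
    callGenotypes(sampleChip(nodes, graftPop, "blast", 48L, nm,
                             panel = panel, seed = seed * 5L + 1L), panel),
    callGenotypes(sampleChip(nodes, graftPop, "stem", 48L, nm,
                             panel = panel, seed = seed * 5L + 2L), panel))
  gmGraft <- callGenotypes(sampleChip(nodes, graftPop, "graft", 96L, nm,
                                      panel = panel, seed = seed * 5L + 3L),
                           panel)
  list(reference = callClones(gmDiag), query = callClones(gmGraft),
       secondary = sec, dominantKey = genoKey(gx[u, ]),
       novelKey = genoKey(novel), ancestralKey = genoKey(anc))
}
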