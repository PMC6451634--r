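## Synthetic-data module: ground-truth clonal structures and noisy chip
## read-outs with the statistical structure the downstream analysis assumes
## (sorted compartments, 48/96-well chips, allele dropout, xenograft
## bottlenecks). Every stochastic draw flows from one explicit integer seed
## per operation, so seeded runs are bit-reproducible.

.defaultMutationNames <- function(n) {
  pool <- c("DNMT3A", "NPM1c", "TET2a", "FLT3-ITD", "WT1", "IDH2",
            "NRAS", "CBL", "TET2b", "GATA2", "PTPN11", "ZRSR2")
  if (n <= length(pool)) pool[seq_len(n)] else
    c(pool, sprintf("MUT%02d", seq_len(n - length(pool))))
}

## one random growth of the tree structure; returns genotypes + edges
.growTree <- function(nClones, muts, founder, secondary, founderFirst) {
  ids <- sprintf("C%d", seq_len(nClones))
  nM <- length(muts)
  # one required fresh gain per edge keeps genotypes distinct
  placeable <- setdiff(muts, c(founder, secondary))
  req <- character(nClones)
  if (founderFirst) {
    req[1L] <- founder
    if (nClones >= 2L) {
      j <- if (nClones == 2L) 2L else sample(2:nClones, 1L)
      req[j] <- secondary
    }
    open <- which(req == "")
    if (length(open))
      req[open] <- sample(placeable, length(open))
  } else {
    req <- sample(muts, nClones)
  }
  leftovers <- setdiff(muts, c(req, secondary))
  gains <- as.list(req)
  for (m in leftovers) {
    e <- sample.int(nClones, 1L)
    gains[[e]] <- c(gains[[e]], m)
  }
  parent <- character(nClones)
  parent[1L] <- "germline"
  if (nClones >= 2L)
    for (i in 2:nClones) {
      cand <- if (founderFirst) ids[seq_len(i - 1L)] else
        c("germline", ids[seq_len(i - 1L)])
      parent[i] <- cand[sample.int(length(cand), 1L)]
    }
  g <- matrix(0L, nClones + 1L, nM,
              dimnames = list(c("germline", ids), muts))
  for (i in seq_len(nClones)) {
    g[ids[i], ] <- g[parent[i], ]
    g[ids[i], gains[[i]]] <- 1L
  }
  list(genotypes = g,
       edges = data.frame(parent = parent, child = ids,
                          stringsAsFactors = FALSE))
}

.descendantsOf <- function(edges, node) {
  out <- character(0)
  frontier <- node
  repeat {
    nxt <- edges$child[edges$parent %in% frontier]
    if (!length(nxt)) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

## try to gain one existing mutation independently on a second branch;
## NULL when no placement works. A placement is accepted only when the
## carriers of the mutation have no common contained carrier clone, so
## every irreversible tree over the resulting genotypes must gain the
## mutation at least twice (forced homoplasy, not merely a second gain in
## the generating topology).
.plantReiteration <- function(res, protected) {
  g <- res$genotypes
  clones <- setdiff(rownames(g), "germline")
  cand <- expand.grid(m = setdiff(colnames(g), protected), v = clones,
                      stringsAsFactors = FALSE)
  cand <- cand[g[cbind(cand$v, cand$m)] == 0L, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  for (i in sample.int(nrow(cand))) {
    m <- cand$m[i]; v <- cand$v[i]
    g2 <- g
    g2[c(v, .descendantsOf(res$edges, v)), m] <- 1L
    if (anyDuplicated(apply(g2, 1L, .genoKey))) next
    carriers <- clones[g2[clones, m] == 1L]
    forced <- !any(vapply(carriers, function(w)
      all(vapply(carriers, function(u)
        .isSubset(g2[w, ], g2[u, ]), logical(1L))), logical(1L)))
    if (forced) {
      res$genotypes <- g2
      res$reiterated <- m
      return(res)
    }
  }
  NULL
}

#' Simulate a ground-truth clonal phylogeny
#'
#' Grows a random rooted clone tree under the irreversible model: each
#' sub-clone gains at least one fresh mutation on the edge from its
#' parent, so genotypes are automatically pairwise distinct and every
#' child genotype contains its parent's. With \code{founderFirst}, the
#' tree reproduces the mutation-order structure seen in NPM1c-mutant AML:
#' a designated founder mutation (DNMT3A/TET2-like, the first mutation
#' name) is carried by every leukaemic clone, and a designated secondary
#' mutation (NPM1c-like, the second name) arises strictly later, on an
#' edge below the founder clone, so at least one clone carries the
#' founder without it. With a single clone the order is not expressible
#' and the secondary mutation stays unused (as in a one-clone patient).
#'
#' With \code{allowReiteration}, with probability \code{reiterationProb}
#' one mutation is additionally gained independently on a second branch
#' (parallel evolution / homoplasy, e.g. two distinct TET2 lesions in
#' separate sub-clones).
#'
#' @param nClones number of sub-clones, 1-8.
#' @param nMutations number of tracked mutations; must be at least
#'   \code{nClones} so each clone can gain a fresh mutation.
#' @param founderFirst logical; impose the founder-first structure.
#' @param allowReiteration logical; permit a planted parallel gain.
#' @param reiterationProb probability the parallel gain is planted when
#'   \code{allowReiteration} is set.
#' @param mutationNames optional mutation ids (defaults to AML-driver-like
#'   names, founder first, NPM1c-like second).
#' @param seed integer seed; all draws flow from it.
#' @return a [TrueCloneTree-class].
#' @examples
#' simulateCloneTree(4, 6, founderFirst = TRUE, seed = 11)
#' @export
simulateCloneTree <- function(nClones, nMutations, founderFirst = FALSE,
                              allowReiteration = FALSE, reiterationProb = 0.5,
                              mutationNames = NULL, seed = 1L) {
  nClones <- as.integer(nClones)
  nMutations <- as.integer(nMutations)
  if (is.na(nClones) || nClones < 1L || nClones > 8L)
    stop("nClones must be an integer in 1..8")
  if (nMutations < nClones)
    stop("infeasible parameter combination: need nMutations >= nClones ",
         "for distinct genotypes")
  if (founderFirst && nMutations < 2L)
    stop("infeasible parameter combination: founderFirst needs at least ",
         "2 mutations (founder and secondary)")
  if (allowReiteration && nClones < 2L)
    stop("infeasible parameter combination: a reiterated gain needs >= 2 clones")
  muts <- if (is.null(mutationNames)) .defaultMutationNames(nMutations) else
    as.character(mutationNames)
  if (length(muts) != nMutations || anyDuplicated(muts))
    stop("mutationNames must be ", nMutations, " unique ids")
  founder <- if (founderFirst) muts[1L] else character(0)
  secondary <- if (founderFirst) muts[2L] else character(0)
  withr::with_seed(seed, {
    doReiterate <- allowReiteration && stats::runif(1L) < reiterationProb
    res <- NULL
    for (attempt in seq_len(100L)) {
      res <- .growTree(nClones, muts, founder, secondary, founderFirst)
      if (!doReiterate) break
      planted <- .plantReiteration(res, protected = founder)
      if (!is.null(planted)) { res <- planted; break }
      if (attempt == 100L)
        stop("infeasible parameter combination: could not place a ",
             "reiterated mutation with distinct genotypes")
    }
    new("TrueCloneTree",
        genotypes = res$genotypes, edges = res$edges, mode = "irreversible",
        founderMutation = founder, secondaryMutation = secondary,
        reiteratedMutation = if (is.null(res$reiterated)) character(0) else
          res$reiterated)
  })
}

#' Simulate per-compartment clone frequencies
#'
#' Generates a [PopulationSpec-class] over the three diagnostic
#' compartments of the study design: the bulk blast fraction
#' (CD33+/CD34-/CD3-, leukaemic clones only), the small putative stem-cell
#' fraction (CD34+/CD33-, which carries a germline/normal admixture and is
#' biased towards ancestral, mutation-poor clones, emulating
#' compartment-restricted pre-leukaemic clones), and the T-cell control
#' (CD3+, germline at frequency 1).
#'
#' Every clone receives at least \code{minCloneFreq} of the blast
#' compartment (and \code{minCloneFreq} of the non-germline stem mass),
#' the remainder being split by random gamma weights. The floor keeps all
#' simulated clones well above the ~5\% detection limit of a 48-cell
#' read-out, so parameter-recovery tests probe the method rather than
#' multinomial sampling noise; sensitivity at the detection limit is
#' modelled separately by [detectionProbability()].
#'
#' @param tree a [CloneTree-class] (or [TrueCloneTree-class]).
#' @param compartments which of \code{"blast"}, \code{"stem"},
#'   \code{"tcell"} to generate.
#' @param minCloneFreq per-clone frequency floor (default 0.15; capped at
#'   \code{0.9 / nClones} when many clones).
#' @param stemGermlineFreq germline (normal HSC) admixture in the stem
#'   compartment.
#' @param seed integer seed.
#' @return a [PopulationSpec-class].
#' @export
simulatePopulation <- function(tree,
                               compartments = c("blast", "stem", "tcell"),
                               minCloneFreq = 0.15, stemGermlineFreq = 0.1,
                               seed = 1L) {
  compartments <- match.arg(compartments, several.ok = TRUE)
  g <- treeGenotypes(tree)
  clones <- setdiff(rownames(g), "germline")
  k <- length(clones)
  floorB <- min(minCloneFreq, 0.9 / k)
  withr::with_seed(seed, {
    f <- matrix(0, nrow = k + 1L, ncol = length(compartments),
                dimnames = list(c("germline", clones), compartments))
    if ("blast" %in% compartments) {
      w <- stats::rgamma(k, shape = 1.5)
      f[clones, "blast"] <- floorB + (1 - k * floorB) * w / sum(w)
    }
    if ("stem" %in% compartments) {
      nm <- rowSums(g)[clones]
      w <- stats::rgamma(k, shape = 1.5) * (1 + max(nm) - nm)
      f[clones, "stem"] <-
        (1 - stemGermlineFreq) * (floorB + (1 - k * floorB) * w / sum(w))
      f["germline", "stem"] <- stemGermlineFreq
    }
    if ("tcell" %in% compartments)
      f["germline", "tcell"] <- 1
    new("PopulationSpec", freqs = f)
  })
}

#' Construct a noise model
#'
#' @param adoRate mutant-allele dropout probability per (cell, locus);
#'   a heterozygous cell then reads falsely wild type.
#' @param fpRate spurious mutant-channel amplification probability.
#' @param locusFailRate probability an assay gives no signal in a well.
#' @param cellFailRate probability the control locus fails (cell
#'   discarded).
#' @return a [NoiseModel-class].
#' @examples
#' noiseModel(adoRate = 0.1)         # study-like defaults
#' noiseModel(0, 0, 0, 0)            # noise-free
#' @export
noiseModel <- function(adoRate = 0.1, fpRate = 0, locusFailRate = 0.05,
                       cellFailRate = 0.05)
  new("NoiseModel", adoRate = adoRate, fpRate = fpRate,
      locusFailRate = locusFailRate, cellFailRate = cellFailRate)

## clamped Ct draw for an amplified channel: always below threshold so a
## noise-free chip calls deterministically
.drawCt <- function(n, threshold) {
  round(pmin(pmax(stats::rnorm(n, mean = threshold - 6, sd = 1),
                  threshold - 12), threshold - 2), 3L)
}

#' Sample a single-cell Q-PCR chip
#'
#' Emulates one sorted compartment loaded on a 48- or 96-well chip: each
#' well draws a clone from the compartment's frequency vector, then emits
#' per-assay Ct signals. Allelic-discrimination assays emit a WT channel
#' (the wild-type allele of a heterozygous cell always amplifies) and a
#' MUT channel subject to allele dropout and false positives; mutant-only
#' assays emit the MUT channel alone; the diploid control locus emits
#' unless the cell fails. "No amplification" is encoded as a missing Ct.
#'
#' @param x a [CloneTree-class] or a plain 0/1 genotype matrix (nodes x
#'   mutations, rownames = node ids including \code{"germline"}).
#' @param pop a [PopulationSpec-class] whose nodes are rows of \code{x}.
#' @param compartment compartment label to sample from.
#' @param nCells number of wells (default 48, the chip format used for
#'   sorted fractions).
#' @param noise a [NoiseModel-class].
#' @param panel optional [AssayPanel-class]; defaults to one inferred from
#'   the mutation ids.
#' @param ctThreshold amplification threshold (Ct below it counts as
#'   amplified; default 30).
#' @param seed integer seed.
#' @return a chip table: data.frame with columns \code{cell_id},
#'   \code{compartment}, \code{assay_id}, \code{channel} (WT/MUT/CTRL) and
#'   \code{ct} (NA = no amplification). The sampled clone per well is kept
#'   in attribute \code{"trueClone"} for parameter-recovery tests.
#' @export
sampleChip <- function(x, pop, compartment, nCells = 48L,
                       noise = noiseModel(), panel = NULL, ctThreshold = 30,
                       seed = 1L) {
  g <- if (is(x, "CloneTree")) treeGenotypes(x) else x
  if (!is.matrix(g)) stop("x must be a CloneTree or a genotype matrix")
  if (!compartment %in% colnames(pop@freqs))
    stop("unknown compartment: ", compartment)
  nCells <- as.integer(nCells)
  if (is.na(nCells) || nCells < 1L) stop("nCells must be >= 1")
  f <- pop@freqs[, compartment]
  if (!all(names(f) %in% rownames(g)))
    stop("population nodes missing from the genotype matrix: ",
         paste(setdiff(names(f), rownames(g)), collapse = ", "))
  if (is.null(panel)) panel <- assayPanel(colnames(g))
  kinds <- assayKinds(panel)
  withr::with_seed(seed, {
    cellId <- sprintf("%s_w%03d", compartment, seq_len(nCells))
    who <- sample(names(f), nCells, replace = TRUE, prob = f)
    rows <- vector("list", length(panel@mutations) + 1L)
    ctrlFail <- stats::runif(nCells) < noise@cellFailRate
    ctrlCt <- .drawCt(nCells, ctThreshold)
    ctrlCt[ctrlFail] <- NA_real_
    rows[[1L]] <- data.frame(cell_id = cellId, compartment = compartment,
                             assay_id = panel@controlLocus, channel = "CTRL",
                             ct = ctrlCt, stringsAsFactors = FALSE)
    for (j in seq_along(panel@mutations)) {
      mut <- panel@mutations[j]
      gj <- if (mut %in% colnames(g)) g[who, mut] else rep(0L, nCells)
      locusFail <- stats::runif(nCells) < noise@locusFailRate
      mutAmp <- ifelse(gj == 1L,
                       stats::runif(nCells) >= noise@adoRate,
                       stats::runif(nCells) < noise@fpRate) & !locusFail
      mutCt <- .drawCt(nCells, ctThreshold)
      mutCt[!mutAmp] <- NA_real_
      block <- data.frame(cell_id = cellId, compartment = compartment,
                          assay_id = mut, channel = "MUT", ct = mutCt,
                          stringsAsFactors = FALSE)
      if (kinds[[mut]] == "allelic_discrimination") {
        wtCt <- .drawCt(nCells, ctThreshold)
        wtCt[locusFail] <- NA_real_
        block <- rbind(data.frame(cell_id = cellId, compartment = compartment,
                                  assay_id = mut, channel = "WT", ct = wtCt,
                                  stringsAsFactors = FALSE), block)
      }
      rows[[j + 1L]] <- block
    }
    chip <- do.call(rbind, rows)
    chip <- chip[order(match(chip$cell_id, cellId),
                       match(chip$assay_id,
                             c(panel@controlLocus, panel@mutations)),
                       chip$channel), , drop = FALSE]
    rownames(chip) <- NULL
    attr(chip, "trueClone") <- stats::setNames(who, cellId)
    chip
  })
}

#' Impose a xenograft bottleneck on a clone population
#'
#' Transplantation into immunodeficient mice reads out leukaemia-
#' propagating activity: typically one sub-clone regenerates dominantly.
#' This returns the population with an added graft compartment in which
#' \code{dominantClone} has frequency at least \code{dominance} and the
#' remaining mass is spread over a permitted subset of other clones --
#' possibly clones at frequency 0 in every diagnostic compartment,
#' emulating a graft clone below the detection limit at diagnosis. The
#' bottleneck is purely a frequency-vector transformation.
#'
#' @param pop a [PopulationSpec-class].
#' @param dominantClone node id of the regenerating dominant clone.
#' @param dominance its graft frequency, in (0, 1].
#' @param others node ids permitted to co-engraft (default none).
#' @param shareFloor fraction of the residual mass \code{1 - dominance}
#'   guaranteed to be split evenly across \code{others} (the rest is
#'   random); keeps each permitted clone detectable.
#' @param compartment name of the new compartment (default
#'   \code{"graft"}).
#' @param seed integer seed.
#' @return a [PopulationSpec-class] with the graft column added.
#' @export
simulateXenograft <- function(pop, dominantClone, dominance,
                              others = character(0), shareFloor = 0.8,
                              compartment = "graft", seed = 1L) {
  ids <- rownames(pop@freqs)
  if (!dominantClone %in% ids)
    stop("unknown clone id: ", dominantClone)
  if (!is.numeric(dominance) || dominance <= 0 || dominance > 1)
    stop("dominance must lie in (0, 1]")
  others <- setdiff(others, dominantClone)
  if (!all(others %in% ids))
    stop("unknown clone id: ", paste(setdiff(others, ids), collapse = ", "))
  withr::with_seed(seed, {
    f <- stats::setNames(numeric(length(ids)), ids)
    rem <- 1 - dominance
    if (length(others) && rem > 0) {
      m <- length(others)
      base <- shareFloor * rem / m
      w <- stats::rgamma(m, shape = 1)
      f[others] <- base + (rem - m * base) * w / sum(w)
      f[dominantClone] <- dominance
    } else {
      f[dominantClone] <- 1
    }
    new("PopulationSpec",
        freqs = cbind(pop@freqs[, setdiff(colnames(pop@freqs), compartment),
                                drop = FALSE],
                      matrix(f, ncol = 1L,
                             dimnames = list(ids, compartment))))
  })
}

#' Extend a population with additional (zero-frequency) clones
#'
#' Adds node ids at frequency 0 in every compartment, so a later
#' [simulateXenograft()] call may let them engraft -- the
#' below-detection-limit scenario where a clone absent from the
#' diagnostic read-out dominates the graft.
#'
#' @param pop a [PopulationSpec-class].
#' @param ids new node ids.
#' @return a [PopulationSpec-class].
#' @export
addClones <- function(pop, ids) {
  ids <- setdiff(ids, rownames(pop@freqs))
  if (!length(ids)) return(pop)
  z <- matrix(0, nrow = length(ids), ncol = ncol(pop@freqs),
              dimnames = list(ids, colnames(pop@freqs)))
  new("PopulationSpec", freqs = rbind(pop@freqs, z))
}

setMethod("show", "PopulationSpec", function(object) {
  cat("PopulationSpec:", nrow(object@freqs) - 1L, "clone(s) + germline,",
      ncol(object@freqs), "compartment(s)\n")
  print(round(object@freqs, 3))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(
    "NoiseModel: ado=%.3g fp=%.3g locus_fail=%.3g cell_fail=%.3g\n",
    object@adoRate, object@fpRate, object@locusFailRate,
    object@cellFailRate))
})

setMethod("show", "TrueCloneTree", function(object) {
  callNextMethod()
  if (length(object@founderMutation))
    cat("  founder:", object@founderMutation,
        " secondary:", object@secondaryMutation, "\n")
  if (length(object@reiteratedMutation))
    cat("  reiterated gain:", object@reiteratedMutation, "\n")
})
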