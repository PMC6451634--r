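#' @import methods
NULL

## Internal genotype helpers used throughout: genotypes are named integer
## 0/1 vectors (or rows of a 0/1 matrix) over the tracked panel mutations.

.genoKey <- function(g) paste(as.integer(g), collapse = "")

.isSubset <- function(a, b) all(a <= b)          # a subset-of b, elementwise 0/1
.isStrictSubset <- function(a, b) all(a <= b) && any(a < b)

# ---------------------------------------------------------------------------
# AssayPanel
# ---------------------------------------------------------------------------

.validAssayPanel <- function(object) {
  msg <- character()
  if (length(object@mutations) < 1L)
    msg <- c(msg, "panel must track at least one mutation")
  if (anyDuplicated(object@mutations))
    msg <- c(msg, "mutation ids must be unique")
  if (length(object@assayKind) != length(object@mutations))
    msg <- c(msg, "assayKind must have one entry per mutation")
  if (!all(object@assayKind %in% c("allelic_discrimination", "mutant_only")))
    msg <- c(msg, "assayKind must be 'allelic_discrimination' or 'mutant_only'")
  if (length(object@controlLocus) != 1L || is.na(object@controlLocus) ||
      !nzchar(object@controlLocus))
    msg <- c(msg, "exactly one control locus id is required")
  if (object@controlLocus %in% object@mutations)
    msg <- c(msg, "control locus cannot also be a tracked mutation")
  if (length(msg)) msg else TRUE
}

#' AssayPanel: the tracked mutations for one patient
#'
#' An \code{AssayPanel} records the patient-specific mutations tracked by
#' single-cell Q-PCR, the assay chemistry per mutation (dual-probe
#' allelic discrimination with WT/MUT channels, or a mutant-only design as
#' used for indels and FLT3-ITDs where no wild-type probe exists), and the
#' diploid control locus (beta-2-microglobulin by default) whose
#' amplification certifies that a well contained amplifiable single-cell
#' DNA.
#'
#' @slot mutations character vector of unique mutation ids
#'   (e.g. \code{"TET2 p.R544*"}).
#' @slot assayKind character vector parallel to \code{mutations}, each
#'   \code{"allelic_discrimination"} or \code{"mutant_only"}.
#' @slot controlLocus id of the diploid control locus.
#'
#' @seealso [assayPanel()] for the user-facing constructor.
#' @exportClass AssayPanel
setClass("AssayPanel",
  slots = c(mutations = "character",
            assayKind = "character",
            controlLocus = "character"),
  prototype = prototype(controlLocus = "B2M"),
  validity = .validAssayPanel)

# ---------------------------------------------------------------------------
# GenotypeMatrix
# ---------------------------------------------------------------------------

.validGenotypeMatrix <- function(object) {
  msg <- character()
  m <- object@calls
  if (!is.matrix(m) || !is.character(m))
    msg <- c(msg, "calls must be a character matrix (cells x mutations)")
  else {
    if (!all(m %in% c("WT", "MUT", "MISSING")))
      msg <- c(msg, "calls must be WT, MUT or MISSING")
    if (nrow(m) > 0L && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
      msg <- c(msg, "cells need unique ids (rownames of calls)")
    if (!identical(colnames(m), object@panel@mutations))
      msg <- c(msg, "call columns must match the panel mutations")
    if (length(object@compartment) != nrow(m))
      msg <- c(msg, "one compartment label per cell required")
    if (length(object@qc) != nrow(m))
      msg <- c(msg, "one qc status per cell required")
  }
  if (!all(object@qc %in% c("pass", "control_fail", "excluded")))
    msg <- c(msg, "qc must be pass, control_fail or excluded")
  if (length(msg)) msg else TRUE
}

#' GenotypeMatrix: per-cell ternary genotype calls
#'
#' Cells-by-mutations matrix of \code{WT}/\code{MUT}/\code{MISSING} calls
#' with a per-cell sorted-compartment label and QC status. Cells whose
#' control locus failed to amplify are flagged \code{control_fail} and are
#' excluded from every downstream denominator; wells listed as doublet or
#' otherwise compromised may be flagged \code{excluded}.
#'
#' @slot calls character matrix, cells (rows) x panel mutations (columns).
#' @slot compartment character vector of compartment labels, one per cell.
#' @slot qc character vector, one of \code{pass}, \code{control_fail},
#'   \code{excluded} per cell.
#' @slot panel the [AssayPanel-class] the calls refer to.
#'
#' @seealso [callGenotypes()], [qcSummary()]
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  slots = c(calls = "matrix",
            compartment = "character",
            qc = "character",
            panel = "AssayPanel"),
  validity = .validGenotypeMatrix)

# ---------------------------------------------------------------------------
# CloneSet
# ---------------------------------------------------------------------------

.validCloneSet <- function(object) {
  msg <- character()
  g <- object@genotypes
  if (!is.matrix(g))
    return("genotypes must be a 0/1 matrix (clones x mutations)")
  if (nrow(g) > 0L) {
    if (!all(g %in% c(0L, 1L)))
      msg <- c(msg, "clone genotypes must be 0/1")
    if (is.null(rownames(g)) || anyDuplicated(rownames(g)))
      msg <- c(msg, "clones need unique ids (rownames)")
    if (anyDuplicated(apply(g, 1L, .genoKey)))
      msg <- c(msg, "clone genotypes must be pairwise distinct")
    if (any(rowSums(g) == 0L))
      msg <- c(msg, "the all-WT genotype is the germline reference, not a clone")
  }
  if (!identical(colnames(g), object@panel@mutations))
    msg <- c(msg, "genotype columns must match the panel mutations")
  cmp <- colnames(object@counts)
  if (!identical(rownames(object@counts), rownames(g)))
    msg <- c(msg, "counts rows must match clone ids")
  for (slotv in list(object@germlineCounts, object@unassignedCounts,
                     object@totals))
    if (!identical(names(slotv), cmp))
      msg <- c(msg, "compartments must agree across counts/germline/unassigned/totals")
  if (!length(msg)) {
    assigned <- if (nrow(object@counts)) colSums(object@counts) else
      stats::setNames(numeric(length(cmp)), cmp)
    if (any(assigned + object@germlineCounts + object@unassignedCounts !=
            object@totals))
      msg <- c(msg, "per compartment, assigned + germline + unassigned must equal informative pass cells")
  }
  cloneIds <- if (is.null(rownames(g))) character(0) else rownames(g)
  confNames <- if (is.null(names(object@confidence))) character(0) else
    names(object@confidence)
  if (!all(object@confidence %in% c("called", "low_frequency")) ||
      !identical(confNames, cloneIds))
    msg <- c(msg, "confidence must be named 'called'/'low_frequency' per clone")
  if (length(msg)) msg else TRUE
}

#' CloneSet: sub-clones with per-compartment counts
#'
#' A set of genetically distinct sub-clones, each a binary genotype over
#' the tracked panel mutations, with per-compartment cell counts.
#' All-wild-type cells are counted against the germline reference (normal
#' contaminating cells), not as a clone; cells whose incomplete profile is
#' compatible with more than one clone stay unassigned. Per compartment,
#' assigned + germline + unassigned cells equal the informative pass cells
#' exactly.
#'
#' @slot genotypes integer 0/1 matrix, clones (rows) x panel mutations.
#' @slot counts integer matrix, clones x compartments, assigned cells.
#' @slot germlineCounts named numeric, all-WT cells per compartment.
#' @slot unassignedCounts named numeric, ambiguous/unmatched cells per
#'   compartment.
#' @slot totals named numeric, informative pass cells per compartment.
#' @slot confidence \code{"called"} or \code{"low_frequency"} per clone;
#'   clones under the frequency floor are flagged, never dropped.
#' @slot panel the [AssayPanel-class].
#'
#' @seealso [callClones()], [cloneFreqs()], [newCloneSet()]
#' @exportClass CloneSet
setClass("CloneSet",
  slots = c(genotypes = "matrix",
            counts = "matrix",
            germlineCounts = "numeric",
            unassignedCounts = "numeric",
            totals = "numeric",
            confidence = "character",
            panel = "AssayPanel"),
  validity = .validCloneSet)

# ---------------------------------------------------------------------------
# CloneTree / TrueCloneTree
# ---------------------------------------------------------------------------

.validCloneTree <- function(object) {
  msg <- character()
  g <- object@genotypes
  if (!is.matrix(g) || is.null(rownames(g)))
    return("genotypes must be a 0/1 matrix with node ids as rownames")
  nodes <- rownames(g)
  if (!"germline" %in% nodes)
    msg <- c(msg, "tree must contain the germline root node")
  else if (any(g["germline", ] != 0L))
    msg <- c(msg, "germline genotype must be all zero")
  if (anyDuplicated(apply(g, 1L, .genoKey)))
    msg <- c(msg, "node genotypes must be pairwise distinct")
  e <- object@edges
  if (!is.data.frame(e) || !all(c("parent", "child") %in% names(e)))
    return(c(msg, "edges must be a data.frame with parent and child columns"))
  if (!all(c(e$parent, e$child) %in% nodes))
    msg <- c(msg, "edges must reference tree nodes")
  nonroot <- setdiff(nodes, "germline")
  if ("germline" %in% e$child)
    msg <- c(msg, "germline cannot have a parent")
  if (!setequal(e$child, nonroot) || anyDuplicated(e$child))
    msg <- c(msg, "every non-root node needs exactly one parent")
  if (!length(msg) && length(nonroot)) {
    # reachability from germline
    reached <- "germline"
    repeat {
      nxt <- e$child[e$parent %in% reached & !(e$child %in% reached)]
      if (!length(nxt)) break
      reached <- c(reached, nxt)
    }
    if (!setequal(reached, nodes))
      msg <- c(msg, "every node must be reachable from germline")
  }
  if (!length(msg) && identical(object@mode, "irreversible")) {
    for (i in seq_len(nrow(e)))
      if (!.isSubset(g[e$parent[i], ], g[e$child[i], ]))
        msg <- c(msg, sprintf(
          "irreversible mode violated on edge %s->%s (child genotype must contain parent's)",
          e$parent[i], e$child[i]))
  }
  if (!object@mode %in% c("irreversible", "free"))
    msg <- c(msg, "mode must be 'irreversible' or 'free'")
  if (length(msg)) msg else TRUE
}

#' CloneTree: a rooted clonal phylogeny
#'
#' Directed spanning tree over \{germline\} and the observed sub-clones;
#' observed clones may be internal (ancestral) nodes. In the default
#' irreversible model every child genotype contains its parent's (somatic
#' point mutations are not lost); free mode permits losses and is kept for
#' sensitivity analysis.
#'
#' @slot genotypes integer 0/1 matrix, nodes x mutations, including the
#'   all-zero \code{germline} row.
#' @slot edges data.frame with \code{parent}, \code{child} columns.
#' @slot mode \code{"irreversible"} or \code{"free"}.
#'
#' @seealso [parsimonyScore()], [searchMPTrees()], [toNewick()]
#' @exportClass CloneTree
setClass("CloneTree",
  slots = c(genotypes = "matrix", edges = "data.frame", mode = "character"),
  prototype = prototype(mode = "irreversible"),
  validity = .validCloneTree)

#' TrueCloneTree: a simulated ground-truth clonal phylogeny
#'
#' A [CloneTree-class] produced by [simulateCloneTree()], annotated with
#' the designated founder (DNMT3A/TET2-like, truncal by construction when
#' \code{founderFirst} is set) and secondary (NPM1c-like) mutations and
#' with any mutation planted as a reiterated (parallel) gain.
#'
#' @slot founderMutation id of the designated founder mutation
#'   (\code{character(0)} when no role was designated).
#' @slot secondaryMutation id of the designated secondary mutation.
#' @slot reiteratedMutation id(s) gained independently on two branches.
#'
#' @exportClass TrueCloneTree
setClass("TrueCloneTree",
  contains = "CloneTree",
  slots = c(founderMutation = "character",
            secondaryMutation = "character",
            reiteratedMutation = "character"),
  prototype = prototype(founderMutation = character(0),
                        secondaryMutation = character(0),
                        reiteratedMutation = character(0)))

# ---------------------------------------------------------------------------
# PopulationSpec
# ---------------------------------------------------------------------------

.validPopulationSpec <- function(object) {
  f <- object@freqs
  msg <- character()
  if (!is.matrix(f) || is.null(rownames(f)) || is.null(colnames(f)))
    return("freqs must be a matrix with node ids as rownames and compartments as colnames")
  if (!"germline" %in% rownames(f))
    msg <- c(msg, "population must include the germline node (may be at frequency 0)")
  if (any(f < 0) || any(f > 1))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (any(abs(colSums(f) - 1) > 1e-9))
    msg <- c(msg, "each compartment's frequencies must sum to 1 (tol 1e-9)")
  if (length(msg)) msg else TRUE
}

#' PopulationSpec: per-compartment clone frequencies
#'
#' Frequency vectors over \{germline\} and the clones for each sorted
#' compartment (e.g. blast CD33+/CD34-/CD3-, stem CD34+/CD33-, the
#' CD3+ T-cell control where germline has frequency 1, and xenograft
#' read-outs). Each column sums to 1; any clone may be absent (frequency
#' 0) from any compartment.
#'
#' @slot freqs numeric matrix, nodes (rows, including \code{germline}) x
#'   compartments (columns).
#'
#' @seealso [simulatePopulation()], [simulateXenograft()], [sampleChip()]
#' @exportClass PopulationSpec
setClass("PopulationSpec",
  slots = c(freqs = "matrix"),
  validity = .validPopulationSpec)

# ---------------------------------------------------------------------------
# NoiseModel
# ---------------------------------------------------------------------------

.validNoiseModel <- function(object) {
  rates <- c(ado = object@adoRate, fp = object@fpRate,
             locus = object@locusFailRate, cell = object@cellFailRate)
  if (length(rates) != 4L || any(is.na(rates)) || any(rates < 0 | rates > 1))
    "all noise rates must be single values in [0, 1]"
  else TRUE
}

#' NoiseModel: stochastic artefacts of single-cell Q-PCR
#'
#' @slot adoRate probability that the mutant allele of a heterozygous cell
#'   fails to amplify (allele dropout; the call reads falsely WT).
#' @slot fpRate probability of a spurious mutant-channel amplification in
#'   a wild-type cell.
#' @slot locusFailRate probability that an assay yields no signal at all
#'   in a well (call MISSING for dual-probe assays).
#' @slot cellFailRate probability that the control locus fails, discarding
#'   the cell.
#'
#' @seealso [noiseModel()], [sampleChip()]
#' @exportClass NoiseModel
setClass("NoiseModel",
  slots = c(adoRate = "numeric", fpRate = "numeric",
            locusFailRate = "numeric", cellFailRate = "numeric"),
  prototype = prototype(adoRate = 0.1, fpRate = 0,
                        locusFailRate = 0.05, cellFailRate = 0.05),
  validity = .validNoiseModel)

# ---------------------------------------------------------------------------
# MPResult
# ---------------------------------------------------------------------------

.validMPResult <- function(object) {
  msg <- character()
  if (!all(vapply(object@trees, is, logical(1L), class2 = "CloneTree")))
    msg <- c(msg, "trees must be CloneTree objects")
  if (!object@mode %in% c("irreversible", "free"))
    msg <- c(msg, "mode must be 'irreversible' or 'free'")
  if (!object@method %in% c("exhaustive", "branch_and_bound"))
    msg <- c(msg, "method must be 'exhaustive' or 'branch_and_bound'")
  if (!length(msg) && length(object@trees)) {
    sc <- vapply(object@trees, parsimonyScore, numeric(1L), mode = object@mode)
    if (any(sc != object@score))
      msg <- c(msg, "all co-optimal trees must share the minimum score")
  }
  if (length(msg)) msg else TRUE
}

#' MPResult: a complete maximum-parsimony search result
#'
#' The minimum parsimony score together with the complete, canonically
#' ordered list of co-optimal rooted spanning trees. Completeness is the
#' contract: no spanning arborescence outside the list has a lower or
#' equal score (the search either enumerates exhaustively or uses a
#' branch-and-bound that prunes only provably suboptimal partial trees).
#'
#' @slot score integer minimum score (total mutation gains, plus losses in
#'   free mode).
#' @slot trees list of co-optimal [CloneTree-class] objects, duplicate-free,
#'   sorted by their canonical edge-list serialisation.
#' @slot mode \code{"irreversible"} or \code{"free"}.
#' @slot method \code{"exhaustive"} or \code{"branch_and_bound"}.
#'
#' @seealso [searchMPTrees()], [mpBruteForce()], [consensusEdges()]
#' @exportClass MPResult
setClass("MPResult",
  slots = c(score = "numeric", trees = "list",
            mode = "character", method = "character"),
  validity = .validMPResult)
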