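#' Accessor generics
#'
#' Small accessor family for the CloneArch S4 classes: tracked mutation
#' ids, assay kinds and control locus of an [AssayPanel-class]; calls,
#' compartments and QC status of a [GenotypeMatrix-class]; genotypes,
#' counts, frequencies and confidence flags of a [CloneSet-class]; edge
#' table and node genotypes of a [CloneTree-class]; score and tree list of
#' an [MPResult-class].
#'
#' @param x an object of the matching class.
#' @param ... passed to methods.
#' @return the slot contents (see each method).
#' @name accessors
#' @aliases mutationIds assayKinds controlLocus calls compartments qcStatus
#'   cloneGenotypes cloneCounts cloneFreqs cloneConfidence treeEdges
#'   treeGenotypes mpScore mpTrees
NULL

#' @rdname accessors
#' @export
setGeneric("mutationIds", function(x) standardGeneric("mutationIds"))

#' @rdname accessors
#' @export
setGeneric("assayKinds", function(x) standardGeneric("assayKinds"))

#' @rdname accessors
#' @export
setGeneric("controlLocus", function(x) standardGeneric("controlLocus"))

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' @rdname accessors
#' @export
setGeneric("qcStatus", function(x) standardGeneric("qcStatus"))

#' @rdname accessors
#' @export
setGeneric("cloneGenotypes", function(x) standardGeneric("cloneGenotypes"))

#' @rdname accessors
#' @export
setGeneric("cloneCounts", function(x) standardGeneric("cloneCounts"))

#' @rdname accessors
#' @export
setGeneric("cloneFreqs", function(x, ...) standardGeneric("cloneFreqs"))

#' @rdname accessors
#' @export
setGeneric("cloneConfidence", function(x) standardGeneric("cloneConfidence"))

#' @rdname accessors
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))

#' @rdname accessors
#' @export
setGeneric("treeGenotypes", function(x) standardGeneric("treeGenotypes"))

#' @rdname accessors
#' @export
setGeneric("mpScore", function(x) standardGeneric("mpScore"))

#' @rdname accessors
#' @export
setGeneric("mpTrees", function(x) standardGeneric("mpTrees"))

#' @rdname searchMPTrees
#' @export
setGeneric("searchMPTrees", function(clones, mode = c("irreversible", "free"),
                                     exhaustiveLimit = 7L)
  standardGeneric("searchMPTrees"))

#' @rdname mpBruteForce
#' @export
setGeneric("mpBruteForce", function(clones, mode = c("irreversible", "free"))
  standardGeneric("mpBruteForce"))

#' @rdname callClones
#' @export
setGeneric("callClones", function(x, minCells = 2L, minFreq = 0.05,
                                  maxAdoLoci = 1L)
  standardGeneric("callClones"))
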