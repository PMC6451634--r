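#' Construct an assay panel
#'
#' Builds the per-patient panel of tracked mutations. Assay chemistry is
#' inferred from the mutation id when not given: ids containing
#' \code{"ITD"} or a frameshift tag (\code{"fs"}) get a mutant-only design
#' (no wild-type probe can be placed across an indel breakpoint), all
#' others a dual-probe allelic-discrimination design.
#'
#' @param mutations character vector of unique mutation ids.
#' @param kinds optional character vector (\code{"allelic_discrimination"}
#'   or \code{"mutant_only"}) parallel to \code{mutations}.
#' @param control id of the diploid control locus (default \code{"B2M"}).
#' @return an [AssayPanel-class].
#' @examples
#' assayPanel(c("DNMT3A", "NPM1c", "FLT3-ITD"))
#' @export
assayPanel <- function(mutations, kinds = NULL, control = "B2M") {
  mutations <- as.character(mutations)
  if (is.null(kinds))
    kinds <- ifelse(grepl("ITD|fs", mutations),
                    "mutant_only", "allelic_discrimination")
  new("AssayPanel", mutations = mutations, assayKind = as.character(kinds),
      controlLocus = control)
}

#' @rdname accessors
setMethod("mutationIds", "AssayPanel", function(x) x@mutations)

#' @rdname accessors
setMethod("assayKinds", "AssayPanel",
          function(x) stats::setNames(x@assayKind, x@mutations))

#' @rdname accessors
setMethod("controlLocus", "AssayPanel", function(x) x@controlLocus)

setMethod("show", "AssayPanel", function(object) {
  cat("AssayPanel with", length(object@mutations), "tracked mutation(s)\n")
  cat("  control locus:", object@controlLocus, "\n")
  k <- table(object@assayKind)
  cat("  chemistry:", paste(sprintf("%s (%d)", names(k), k), collapse = ", "),
      "\n")
  cat("  mutations:", paste(object@mutations, collapse = ", "), "\n")
})

#' @rdname accessors
setMethod("mutationIds", "GenotypeMatrix", function(x) x@panel@mutations)

#' @rdname accessors
setMethod("calls", "GenotypeMatrix", function(x) x@calls)

#' @rdname accessors
setMethod("compartments", "GenotypeMatrix", function(x)
  stats::setNames(x@compartment, rownames(x@calls)))

#' @rdname accessors
setMethod("qcStatus", "GenotypeMatrix", function(x)
  stats::setNames(x@qc, rownames(x@calls)))

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "cells x",
      ncol(object@calls), "mutations\n")
  cat("  compartments:", paste(names(table(object@compartment)),
                               table(object@compartment),
                               sep = "=", collapse = ", "), "\n")
  cat("  qc:", paste(names(table(object@qc)), table(object@qc),
                     sep = "=", collapse = ", "), "\n")
})
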