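## Clone calling: collapse per-cell ternary genotypes into sub-clones with
## per-compartment counts, dropout-aware merging of sub-threshold profiles
## and a binomial detection-limit model.

.profileString <- function(row)
  paste(ifelse(row == "MUT", "1", ifelse(row == "WT", "0", "?")),
        collapse = "")

.profileToGeno <- function(p) {
  v <- strsplit(p, "")[[1L]]
  unname(c("0" = 0L, "1" = 1L)[v])     # "?" maps to NA
}

#' Tabulate per-cell genotype profiles
#'
#' Counts complete (no MISSING call) genotype profiles per compartment
#' among QC-passing cells; incomplete profiles are listed separately for
#' [resolveMissing()].
#'
#' @param gm a [GenotypeMatrix-class] with at least one passing cell.
#' @return list with data.frames \code{complete} and \code{incomplete},
#'   each with columns \code{profile} (string over 0/1/?),
#'   \code{compartment}, \code{count}, plus the panel in attribute
#'   \code{"panel"}.
#' @export
enumerateProfiles <- function(gm) {
  keep <- gm@qc == "pass"
  if (!any(keep)) stop("no QC-passing cells")
  m <- gm@calls[keep, , drop = FALSE]
  comp <- gm@compartment[keep]
  prof <- apply(m, 1L, .profileString)
  df <- as.data.frame(table(profile = prof, compartment = comp),
                      stringsAsFactors = FALSE)
  names(df)[3L] <- "count"
  df <- df[df$count > 0L, , drop = FALSE]
  df <- df[order(df$profile, df$compartment), , drop = FALSE]
  rownames(df) <- NULL
  incomplete <- grepl("?", df$profile, fixed = TRUE)
  out <- list(complete = df[!incomplete, , drop = FALSE],
              incomplete = df[incomplete, , drop = FALSE])
  attr(out, "panel") <- gm@panel
  out
}

#' Assign incomplete profiles to called clones
#'
#' An incomplete cell profile (MISSING at one or more loci) is assigned to
#' a clone genotype iff exactly one candidate genotype agrees with all its
#' non-missing calls; with zero or several compatible candidates the cell
#' stays unassigned (excluded from clone numerators, retained in
#' denominators).
#'
#' @param profiles character vector of profile strings over 0/1/?.
#' @param cloneGenotypes character vector of complete 0/1 genotype
#'   strings (the called clones, optionally plus the germline reference),
#'   optionally named.
#' @return character vector parallel to \code{profiles}: the matched
#'   genotype's name (or string, when unnamed), or \code{NA} when
#'   unassigned.
#' @examples
#' resolveMissing(c("1?0", "0?1"), c(A = "110", B = "100"))
#' @export
resolveMissing <- function(profiles, cloneGenotypes) {
  ids <- if (is.null(names(cloneGenotypes))) cloneGenotypes else
    names(cloneGenotypes)
  gen <- lapply(cloneGenotypes, .profileToGeno)
  vapply(profiles, function(p) {
    v <- .profileToGeno(p)
    obs <- !is.na(v)
    hits <- which(vapply(gen, function(g)
      length(g) == length(v) && all(g[obs] == v[obs]), logical(1L)))
    if (length(hits) == 1L) ids[hits] else NA_character_
  }, character(1L), USE.NAMES = FALSE)
}

#' Call sub-clones from genotype profiles
#'
#' Complete profiles seen in at least \code{minCells} cells (summed over
#' compartments) become clones. A sub-threshold profile whose genotype is
#' a strict subset of exactly one called clone within Hamming distance
#' \code{maxAdoLoci} is merged into that clone as a presumed allele-
#' dropout artefact (mutant alleles read falsely wild type); other
#' sub-threshold cells stay unassigned. All-wild-type cells count against
#' the germline reference. Incomplete profiles are then resolved against
#' the called clones and the germline via [resolveMissing()]. Clones whose
#' frequency stays below \code{minFreq} in every compartment are flagged
#' \code{low_frequency} but never dropped: at 48 cells per compartment,
#' clones under ~5\% are near the sampling detection limit and clonal
#' complexity is more likely under- than over-estimated.
#'
#' @param x a [GenotypeMatrix-class], or the profile list from
#'   [enumerateProfiles()].
#' @param minCells minimum cells for a profile to be called (default 2).
#' @param minFreq frequency floor below which a clone is flagged
#'   (default 0.05, the study's stated sensitivity bound).
#' @param maxAdoLoci dropout-merge radius in loci (default 1).
#' @return a [CloneSet-class].
#' @name callClones
#' @aliases callClones,GenotypeMatrix-method callClones,list-method
NULL

.callClonesFromProfiles <- function(prof, minCells, minFreq, maxAdoLoci) {
  panel <- attr(prof, "panel")
  if (is.null(panel)) stop("profile list lacks its panel attribute")
  muts <- panel@mutations
  comps <- sort(unique(c(prof$complete$compartment,
                         prof$incomplete$compartment)))
  zero <- stats::setNames(numeric(length(comps)), comps)

  cc <- prof$complete
  germKey <- strrep("0", length(muts))
  countsOf <- function(df, profilesKeep) {
    out <- matrix(0, nrow = length(profilesKeep), ncol = length(comps),
                  dimnames = list(profilesKeep, comps))
    sub <- df[df$profile %in% profilesKeep, , drop = FALSE]
    if (nrow(sub)) out[cbind(sub$profile, sub$compartment)] <- sub$count
    out
  }
  totalsAll <- zero
  for (df in prof[c("complete", "incomplete")]) {
    t0 <- tapply(df$count, df$compartment, sum)
    totalsAll[names(t0)] <- totalsAll[names(t0)] + t0
  }

  germCounts <- zero
  gsub0 <- cc[cc$profile == germKey, , drop = FALSE]
  if (nrow(gsub0)) germCounts[gsub0$compartment] <- gsub0$count
  cand <- cc[cc$profile != germKey, , drop = FALSE]
  tot <- tapply(cand$count, cand$profile, sum)
  calledProfiles <- names(tot)[tot >= minCells]
  subProfiles <- names(tot)[tot < minCells]

  counts <- countsOf(cand, calledProfiles)
  unassigned <- zero

  ## dropout-aware merging of sub-threshold profiles
  if (length(calledProfiles)) {
    calledG <- lapply(calledProfiles, .profileToGeno)
    for (p in subProfiles) {
      g <- .profileToGeno(p)
      hits <- which(vapply(calledG, function(q)
        all(g <= q) && any(g < q) && sum(q - g) <= maxAdoLoci, logical(1L)))
      pc <- countsOf(cand, p)[1L, ]
      if (length(hits) == 1L)
        counts[calledProfiles[hits], ] <- counts[calledProfiles[hits], ] + pc
      else
        unassigned <- unassigned + pc
    }
  } else {
    for (p in subProfiles) unassigned <- unassigned + countsOf(cand, p)[1L, ]
  }

  ## incomplete profiles: unique-match assignment, else unassigned
  if (nrow(prof$incomplete)) {
    ref <- stats::setNames(c(calledProfiles, germKey),
                           c(calledProfiles, ".germline"))
    asg <- resolveMissing(prof$incomplete$profile, ref)
    for (i in seq_len(nrow(prof$incomplete))) {
      cmp <- prof$incomplete$compartment[i]
      n <- prof$incomplete$count[i]
      if (is.na(asg[i])) unassigned[cmp] <- unassigned[cmp] + n
      else if (asg[i] == ".germline") germCounts[cmp] <- germCounts[cmp] + n
      else counts[asg[i], cmp] <- counts[asg[i], cmp] + n
    }
  }

  ## assemble, ordered by descending total count then genotype string
  ord <- order(-rowSums(counts), rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  ids <- sprintf("C%d", seq_along(calledProfiles))
  geno <- matrix(unlist(lapply(rownames(counts), .profileToGeno)),
                 ncol = length(muts), nrow = nrow(counts), byrow = TRUE)
  dimnames(geno) <- list(ids, muts)
  rownames(counts) <- ids

  freqs <- sweep(counts, 2L, pmax(totalsAll, 1), "/")
  lowf <- apply(freqs < minFreq | rep(totalsAll == 0, each = nrow(freqs)),
                1L, all)
  confidence <- stats::setNames(ifelse(lowf, "low_frequency", "called"), ids)
  if (!length(ids)) confidence <- stats::setNames(character(0), character(0))

  new("CloneSet", genotypes = geno, counts = counts,
      germlineCounts = germCounts, unassignedCounts = unassigned,
      totals = totalsAll, confidence = confidence, panel = panel)
}

#' @rdname callClones
setMethod("callClones", "GenotypeMatrix",
  function(x, minCells = 2L, minFreq = 0.05, maxAdoLoci = 1L)
    .callClonesFromProfiles(enumerateProfiles(x), minCells, minFreq,
                            maxAdoLoci))

#' @rdname callClones
setMethod("callClones", "list",
  function(x, minCells = 2L, minFreq = 0.05, maxAdoLoci = 1L)
    .callClonesFromProfiles(x, minCells, minFreq, maxAdoLoci))

#' Probability of sampling at least one carrier cell
#'
#' The detection-limit model for single-cell read-outs: a clone at
#' frequency \code{f} is seen at least once among \code{n} assayed cells
#' with probability \eqn{1 - (1 - f)^n}. At the study's 48 cells per
#' compartment a 5\% clone is detected with probability ~0.915, which is
#' why minor clones below 5\% are difficult to detect.
#'
#' @param f clone frequency (vectorised), in \[0, 1\].
#' @param n number of cells assayed, >= 1.
#' @return detection probability.
#' @examples
#' detectionProbability(0.05, 48)
#' @export
detectionProbability <- function(f, n) {
  if (any(is.na(f)) || any(f < 0) || any(f > 1))
    stop("f must lie in [0, 1]")
  if (any(is.na(n)) || any(n < 1))
    stop("n must be >= 1")
  1 - (1 - f)^n
}

#' Wilson score interval for a clone frequency
#'
#' @param x carrier cell count (vectorised).
#' @param n informative cells.
#' @param conf confidence level (default 0.95).
#' @return matrix with columns \code{lower}, \code{upper}; always
#'   contains the point estimate \code{x/n}.
#' @export
wilsonInterval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Build a CloneSet directly
#'
#' Constructor for programmatic use (random clone sets in property tests,
#' hand-built examples). Genotypes may be 0/1 strings or a 0/1 matrix.
#'
#' @param genotypes character vector of 0/1 strings or an integer matrix
#'   (clones x mutations).
#' @param counts optional clones x compartments count matrix (default: one
#'   cell per clone in a single \code{"sample"} compartment).
#' @param germline,unassigned optional per-compartment counts.
#' @param panel optional [AssayPanel-class]; defaults to generic ids.
#' @param confidence optional per-clone flags (default \code{"called"}).
#' @return a [CloneSet-class].
#' @examples
#' newCloneSet(c("10", "01", "11"))
#' @export
newCloneSet <- function(genotypes, counts = NULL, germline = NULL,
                        unassigned = NULL, panel = NULL, confidence = NULL) {
  if (is.character(genotypes)) {
    g <- matrix(unlist(lapply(genotypes, .profileToGeno)),
                nrow = length(genotypes), byrow = TRUE)
    rownames(g) <- if (is.null(names(genotypes)))
      sprintf("C%d", seq_along(genotypes)) else names(genotypes)
  } else {
    g <- genotypes
    if (is.null(rownames(g))) rownames(g) <- sprintf("C%d", seq_len(nrow(g)))
  }
  storage.mode(g) <- "integer"
  if (is.null(panel))
    panel <- assayPanel(if (is.null(colnames(g)))
      sprintf("M%02d", seq_len(ncol(g))) else colnames(g))
  colnames(g) <- panel@mutations
  if (is.null(counts))
    counts <- matrix(1, nrow = nrow(g), ncol = 1L,
                     dimnames = list(rownames(g), "sample"))
  comps <- colnames(counts)
  zero <- stats::setNames(numeric(length(comps)), comps)
  if (is.null(germline)) germline <- zero
  if (is.null(unassigned)) unassigned <- zero
  totals <- colSums(counts) + germline + unassigned
  if (is.null(confidence))
    confidence <- stats::setNames(rep("called", nrow(g)), rownames(g))
  new("CloneSet", genotypes = g, counts = counts, germlineCounts = germline,
      unassignedCounts = unassigned, totals = totals,
      confidence = confidence, panel = panel)
}

#' @rdname accessors
setMethod("cloneGenotypes", "CloneSet", function(x) x@genotypes)

#' @rdname accessors
setMethod("cloneCounts", "CloneSet", function(x) x@counts)

#' @rdname accessors
#' @param interval logical; also return Wilson 95\% bounds.
setMethod("cloneFreqs", "CloneSet", function(x, interval = FALSE) {
  f <- sweep(x@counts, 2L, pmax(x@totals, 1), "/")
  if (!interval) return(f)
  lst <- lapply(colnames(f), function(cmp) {
    ci <- wilsonInterval(x@counts[, cmp], max(x@totals[cmp], 1))
    data.frame(clone_id = rownames(f), compartment = cmp,
               freq = f[, cmp], lower = ci[, "lower"], upper = ci[, "upper"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, lst)
})

#' @rdname accessors
setMethod("cloneConfidence", "CloneSet", function(x) x@confidence)

#' @rdname accessors
setMethod("mutationIds", "CloneSet", function(x) x@panel@mutations)

setMethod("show", "CloneSet", function(object) {
  k <- nrow(object@genotypes)
  cat("CloneSet:", k, "clone(s) over", ncol(object@genotypes),
      "mutation(s);", sum(object@confidence == "low_frequency"),
      "flagged low_frequency\n")
  if (k) {
    df <- data.frame(
      genotype = apply(object@genotypes, 1L, .genoKey),
      round(cloneFreqs(object), 3),
      confidence = object@confidence)
    print(df)
  }
  cat("  informative cells:",
      paste(names(object@totals), object@totals, sep = "=",
            collapse = ", "), "\n")
  cat("  germline:", paste(object@germlineCounts, collapse = ", "),
      " unassigned:", paste(object@unassignedCounts, collapse = ", "), "\n")
})
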