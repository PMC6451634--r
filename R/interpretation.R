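## Biological read-outs derived from clone sets and maximum-parsimony
## results: mutation order and truncal status, reiterated (parallel)
## gains, and mapping of xenograft/relapse clone sets onto diagnostic
## clones. Precedence is argued from genotype containment, which is sound
## under the irreversible model and robust to which co-optimal tree is
## chosen; the trees are consulted only for reiteration (gain-edge)
## analysis.

#' Mutation order and truncal status
#'
#' For every ordered mutation pair (a, b) present in the called clones:
#' \code{a_before_b} iff every clone carrying b also carries a and some
#' clone carries a without b (containment forces a to be acquired first
#' under the irreversible model); \code{parallel} iff the pair cannot be
#' ordered and one of the two mutations is gained on more than one edge
#' in every co-optimal tree; \code{unresolved} otherwise. A mutation is
#' \code{truncal} iff it is present in every non-germline called clone of
#' the sample -- the pattern of DNMT3A/TET2-like founders, whereas
#' NPM1c-like secondary mutations are sub-clonal.
#'
#' Mutations absent from every called clone are excluded with a warning
#' (their order is not expressible from the observed clones).
#'
#' @param clones the [CloneSet-class] used for the parsimony search.
#' @param result optional [MPResult-class] over the same clones, used
#'   only to recognise parallel pairs.
#' @return list with \code{pairs} (data.frame \code{a}, \code{b},
#'   \code{relation}) and \code{status} (data.frame \code{mutation},
#'   \code{status} of \code{truncal}/\code{sub_clonal}).
#' @export
mutationPrecedence <- function(clones, result = NULL) {
  g <- cloneGenotypes(clones)
  present <- colnames(g)[colSums(g) > 0L]
  absent <- setdiff(colnames(g), present)
  if (length(absent))
    warning("mutation(s) absent from all called clones excluded: ",
            paste(absent, collapse = ", "))
  reiterEverywhere <- character(0)
  if (!is.null(result) && length(result@trees))
    reiterEverywhere <- detectReiterated(result)$inAllTrees

  pairs <- list()
  for (a in present) for (b in setdiff(present, a)) {
    hasA <- g[, a] == 1L; hasB <- g[, b] == 1L
    rel <- if (all(hasA[hasB]) && any(hasA & !hasB)) "a_before_b"
    else if (all(hasB[hasA]) && any(hasB & !hasA)) "b_before_a"
    else if (a %in% reiterEverywhere || b %in% reiterEverywhere) "parallel"
    else "unresolved"
    pairs[[length(pairs) + 1L]] <- data.frame(
      a = a, b = b, relation = rel, stringsAsFactors = FALSE)
  }
  status <- data.frame(
    mutation = present,
    status = ifelse(colSums(g[, present, drop = FALSE]) == nrow(g),
                    "truncal", "sub_clonal"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(a = character(0), b = character(0),
                    relation = character(0), stringsAsFactors = FALSE),
       status = status)
}

#' Reiterated (parallel) mutations across co-optimal trees
#'
#' Lists, for each co-optimal tree, the mutations gained on two or more
#' edges (homoplasy: the same driver gene hit independently in separate
#' sub-clones), and separately the mutations reiterated in every
#' co-optimal tree -- the robust calls; mutations reiterated in only some
#' trees are reported per tree and left unadjudicated.
#'
#' @param result an [MPResult-class] with at least one tree.
#' @return list with \code{perTree} (list of character vectors, one per
#'   tree in canonical order) and \code{inAllTrees}.
#' @export
detectReiterated <- function(result) {
  if (!is(result, "MPResult") || length(result@trees) == 0L)
    stop("empty maximum-parsimony result")
  perTree <- lapply(result@trees, function(t) {
    gains <- unlist(edgeGains(t)$gained)
    sort(unique(gains[duplicated(gains)]))
  })
  list(perTree = perTree, inAllTrees = Reduce(intersect, perTree))
}

#' Map a graft/relapse clone set onto a reference clone set
#'
#' Classifies every query clone against the diagnostic reference on the
#' shared panel, checking classes in strict precedence order:
#' \code{matched} (genotype identical to a reference clone),
#' \code{novel_descendant} (strict superset of some reference clone --
#' extra mutations acquired, or a clone below the detection limit at
#' diagnosis), \code{ancestral} (strict subset -- a pre-leukaemic
#' read-out), else \code{unrelated}. The dominant query clone is the one
#' with the highest total frequency, ties broken by clone id.
#'
#' @param reference diagnostic [CloneSet-class].
#' @param query graft or relapse [CloneSet-class] on the same panel.
#' @return list with \code{mapping} (data.frame \code{clone_id},
#'   \code{genotype}, \code{class}, \code{match}: the reference clone
#'   matched/contained, or NA), \code{dominant} (query clone id) and
#'   \code{dominantFreq}.
#' @export
mapCloneSets <- function(reference, query) {
  if (!identical(mutationIds(reference), mutationIds(query)))
    stop("reference and query clone sets must share one assay panel")
  rg <- cloneGenotypes(reference)
  qg <- cloneGenotypes(query)

  classify <- function(v) {
    same <- which(vapply(seq_len(nrow(rg)), function(i)
      all(rg[i, ] == v), logical(1L)))
    if (length(same))
      return(c("matched", rownames(rg)[same[1L]]))
    sup <- which(vapply(seq_len(nrow(rg)), function(i)
      .isStrictSubset(rg[i, ], v), logical(1L)))
    if (length(sup)) {
      ## report the closest contained reference clone (largest overlap)
      best <- sup[order(-rowSums(rg[sup, , drop = FALSE]),
                        rownames(rg)[sup])][1L]
      return(c("novel_descendant", rownames(rg)[best]))
    }
    sub <- which(vapply(seq_len(nrow(rg)), function(i)
      .isStrictSubset(v, rg[i, ]), logical(1L)))
    if (length(sub)) {
      best <- sub[order(rowSums(rg[sub, , drop = FALSE]),
                        rownames(rg)[sub])][1L]
      return(c("ancestral", rownames(rg)[best]))
    }
    c("unrelated", NA_character_)
  }
  cls <- t(vapply(seq_len(nrow(qg)), function(i) classify(qg[i, ]),
                  character(2L)))
  totalFreq <- rowSums(cloneCounts(query)) / max(sum(query@totals), 1)
  dom <- order(-totalFreq, rownames(qg))[1L]
  list(mapping = data.frame(clone_id = rownames(qg),
                            genotype = apply(qg, 1L, .genoKey),
                            class = cls[, 1L], match = cls[, 2L],
                            row.names = NULL, stringsAsFactors = FALSE),
       dominant = rownames(qg)[dom],
       dominantFreq = unname(totalFreq[dom]))
}

#' Cohort summary across patients
#'
#' Mirrors the per-patient tabulation of the study design: clone counts
#' per diagnostic compartment, clones engrafting in the xenograft, total
#' distinct clones (union over all samples by genotype identity), and
#' whether the dominant graft clone carries a designated (NPM1c-like)
#' secondary mutation.
#'
#' @param patients named list; each element a list with components
#'   \code{diagnostic} (a [CloneSet-class]), optional \code{graft}
#'   (a [CloneSet-class]) and optional \code{secondary} (mutation id).
#' @return data.frame, one row per patient.
#' @export
cohortSummary <- function(patients) {
  if (!length(patients)) stop("at least one patient result is required")
  if (is.null(names(patients)))
    names(patients) <- sprintf("patient%d", seq_along(patients))
  rows <- lapply(names(patients), function(nm) {
    p <- patients[[nm]]
    dg <- cloneGenotypes(p$diagnostic)
    comps <- colnames(cloneCounts(p$diagnostic))
    perComp <- vapply(comps, function(cmp)
      sum(cloneCounts(p$diagnostic)[, cmp] > 0), numeric(1L))
    keys <- apply(dg, 1L, .genoKey)
    nGraft <- NA_integer_
    domSecondary <- NA
    if (!is.null(p$graft)) {
      qg <- cloneGenotypes(p$graft)
      nGraft <- nrow(qg)
      keys <- union(keys, apply(qg, 1L, .genoKey))
      if (!is.null(p$secondary) &&
          p$secondary %in% colnames(qg)) {
        dom <- mapCloneSets(p$diagnostic, p$graft)$dominant
        domSecondary <- qg[dom, p$secondary] == 1L
      }
    }
    out <- data.frame(patient = nm, stringsAsFactors = FALSE)
    for (cmp in comps) out[[paste0("clones_", cmp)]] <- perComp[[cmp]]
    out$clones_graft <- nGraft
    out$total_distinct_clones <- length(keys)
    out$dominant_graft_has_secondary <- domSecondary
    out
  })
  ## pad columns across patients with differing compartments
  allCols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cl in setdiff(allCols, names(r))) r[[cl]] <- NA
    r[allCols]
  })
  do.call(rbind, rows)
}
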