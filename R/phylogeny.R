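## Maximum parsimony over observed clone genotypes rooted at germline.
## The search space is the set of rooted spanning arborescences over
## {germline} + clones: observed clones may be internal (ancestral) nodes,
## and no hypothetical unobserved (Steiner) nodes are inferred. The default
## irreversible model permits only mutation gains along an edge
## (child genotype must contain the parent's); free mode scores an edge by
## the full symmetric difference and is kept for sensitivity analysis.

#' Construct a clone tree
#'
#' @param genotypes 0/1 matrix, nodes x mutations, with an all-zero
#'   \code{"germline"} row (added automatically when absent).
#' @param edges data.frame with \code{parent}, \code{child} columns.
#' @param mode \code{"irreversible"} (default) or \code{"free"}.
#' @return a [CloneTree-class].
#' @examples
#' g <- rbind(C1 = c(1L, 0L), C2 = c(1L, 1L))
#' colnames(g) <- c("DNMT3A", "NPM1c")
#' cloneTree(g, data.frame(parent = c("germline", "C1"),
#'                         child = c("C1", "C2")))
#' @export
cloneTree <- function(genotypes, edges, mode = "irreversible") {
  storage.mode(genotypes) <- "integer"
  if (!"germline" %in% rownames(genotypes))
    genotypes <- rbind(germline = rep(0L, ncol(genotypes)), genotypes)
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      stringsAsFactors = FALSE)
  new("CloneTree", genotypes = genotypes, edges = edges, mode = mode)
}

#' @rdname accessors
setMethod("treeEdges", "CloneTree", function(x) x@edges)

#' @rdname accessors
setMethod("treeGenotypes", "CloneTree", function(x) x@genotypes)

#' @rdname accessors
setMethod("mpScore", "MPResult", function(x) x@score)

#' @rdname accessors
setMethod("mpTrees", "MPResult", function(x) x@trees)

setMethod("show", "CloneTree", function(object) {
  cat(class(object), "with", nrow(object@genotypes) - 1L,
      "clone(s), mode", object@mode, "\n")
  e <- object@edges
  gains <- edgeGains(object)
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %s -> %s  [+%s]\n", e$parent[i], e$child[i],
                paste(gains$gained[[i]], collapse = ",")))
})

setMethod("show", "MPResult", function(object) {
  cat("MPResult:", length(object@trees), "co-optimal tree(s), score",
      object@score, sprintf("(%s mode, %s search)\n", object@mode,
                            object@method))
})

#' Hamming distance between genotypes
#'
#' @param g1,g2 0/1 integer vectors of equal length, or single 0/1
#'   strings.
#' @return integer count of differing loci.
#' @examples
#' hammingDist("10110", "11010")  # 2
#' @export
hammingDist <- function(g1, g2) {
  if (is.character(g1)) g1 <- .profileToGeno(g1)
  if (is.character(g2)) g2 <- .profileToGeno(g2)
  if (length(g1) != length(g2))
    stop("genotype length mismatch: ", length(g1), " vs ", length(g2))
  sum(g1 != g2)
}

#' Per-edge gained (and lost) mutations
#'
#' @param tree a [CloneTree-class].
#' @return list with \code{gained} and \code{lost}: per edge (in
#'   \code{treeEdges()} order), the mutation ids gained / lost along it.
#' @export
edgeGains <- function(tree) {
  g <- tree@genotypes
  e <- tree@edges
  muts <- colnames(g)
  gained <- lost <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    d <- g[e$child[i], ] - g[e$parent[i], ]
    gained[[i]] <- muts[d > 0L]
    lost[[i]] <- muts[d < 0L]
  }
  list(gained = gained, lost = lost)
}

#' Parsimony score of a clone tree
#'
#' Sum of per-edge costs: number of mutations gained (irreversible mode,
#' where an edge whose child does not contain its parent's genotype is an
#' error, not an infinite cost) or the symmetric difference (free mode).
#'
#' @param tree a [CloneTree-class].
#' @param mode scoring mode; defaults to the tree's own.
#' @return integer score.
#' @export
parsimonyScore <- function(tree, mode = tree@mode) {
  g <- tree@genotypes
  e <- tree@edges
  total <- 0L
  for (i in seq_len(nrow(e))) {
    p <- g[e$parent[i], ]; cc <- g[e$child[i], ]
    if (mode == "irreversible") {
      if (any(p > cc))
        stop(sprintf("edge %s->%s violates the irreversible model",
                     e$parent[i], e$child[i]))
      total <- total + sum(cc > p)
    } else {
      total <- total + sum(cc != p)
    }
  }
  as.integer(total)
}

## --- shared search plumbing -----------------------------------------------

.nodeMatrixFromClones <- function(clones) {
  g <- if (is(clones, "CloneSet")) cloneGenotypes(clones) else clones
  if (!is.matrix(g)) stop("clones must be a CloneSet or a 0/1 matrix")
  if (nrow(g) < 1L) stop("at least one clone is required")
  storage.mode(g) <- "integer"
  if (is.null(rownames(g))) rownames(g) <- sprintf("C%d", seq_len(nrow(g)))
  if ("germline" %in% rownames(g)) {
    g <- rbind(germline = g["germline", ],
               g[setdiff(rownames(g), "germline"), , drop = FALSE])
  } else {
    g <- rbind(germline = rep(0L, ncol(g)), g)
  }
  if (anyDuplicated(apply(g, 1L, .genoKey)))
    stop("duplicate genotypes must be collapsed before the parsimony search")
  g
}

.edgeCost <- function(g, p, cc, mode) {
  if (mode == "irreversible") {
    if (any(g[p, ] > g[cc, ])) Inf else sum(g[cc, ] > g[p, ])
  } else sum(g[cc, ] != g[p, ])
}

.treeFromParents <- function(g, parentIdx, mode) {
  nodes <- rownames(g)
  e <- data.frame(parent = nodes[parentIdx[-1L]], child = nodes[-1L],
                  stringsAsFactors = FALSE)
  e <- e[order(e$parent, e$child), , drop = FALSE]
  rownames(e) <- NULL
  new("CloneTree", genotypes = g, edges = e, mode = mode)
}

.treeKey <- function(tree) {
  e <- tree@edges
  paste(sort(paste(e$parent, e$child, sep = ">")), collapse = "|")
}

#' Search all maximum-parsimony clone trees
#'
#' Finds the minimum parsimony score over every rooted spanning
#' arborescence on \{germline\} + clones and returns the complete set of
#' co-optimal trees, canonically ordered (edges sorted by parent then
#' child id; trees sorted by their edge-list serialisation). For node
#' counts up to \code{exhaustiveLimit} every arborescence is enumerated;
#' above it a branch-and-bound is used whose bound is the accumulated cost
#' plus, for each unplaced clone, its cheapest possible incoming edge --
#' only provably suboptimal partial trees are pruned, so the returned set
#' is complete in both regimes.
#'
#' @param clones a [CloneSet-class] or 0/1 genotype matrix with distinct
#'   rows (clone ids as rownames; a germline row is added if absent).
#' @param mode \code{"irreversible"} (default; somatic point mutations do
#'   not revert) or \code{"free"}.
#' @param exhaustiveLimit node count up to which plain exhaustive
#'   enumeration is used (default 7).
#' @return an [MPResult-class].
#' @examples
#' res <- searchMPTrees(newCloneSet(c("10", "01", "11")))
#' mpScore(res)           # 3
#' length(mpTrees(res))   # 2: the parent of "11" is unresolved
#' @name searchMPTrees
#' @aliases searchMPTrees,ANY-method
NULL

setMethod("searchMPTrees", "ANY",
  function(clones, mode = c("irreversible", "free"), exhaustiveLimit = 7L) {
  mode <- match.arg(mode)
  g <- .nodeMatrixFromClones(clones)
  n <- nrow(g)
  prune <- n > exhaustiveLimit
  ## assignment order: ascending mutation count (a clone's parents are
  ## then typically already placed in irreversible mode), ties by id
  nonroot <- order(rowSums(g)[-1L], rownames(g)[-1L]) + 1L
  C <- matrix(Inf, n, n)
  for (p in seq_len(n)) for (v in seq_len(n))
    if (p != v) C[p, v] <- .edgeCost(g, p, v, mode)
  minIn <- vapply(nonroot, function(v) min(C[, v]), numeric(1L))
  suffixLB <- rev(cumsum(rev(minIn)))

  best <- Inf
  found <- list()
  parent <- integer(n)
  assigned <- logical(n); assigned[1L] <- TRUE

  recurse <- function(k, cost) {
    if (k > length(nonroot)) {
      if (cost < best) { best <<- cost; found <<- list(parent) }
      else if (cost == best) found[[length(found) + 1L]] <<- parent
      return(invisible())
    }
    if (prune && cost + suffixLB[k] > best) return(invisible())
    v <- nonroot[k]
    for (p in seq_len(n)) {
      w <- C[p, v]
      if (!is.finite(w)) next
      if (prune && cost + w + (if (k < length(nonroot))
        suffixLB[k + 1L] else 0) > best) next
      ## incremental cycle check: walk assigned parents upward from p
      a <- p; cyc <- FALSE
      while (a != 1L && assigned[a]) {
        a <- parent[a]
        if (a == v) { cyc <- TRUE; break }
      }
      if (cyc) next
      parent[v] <<- p; assigned[v] <<- TRUE
      recurse(k + 1L, cost + w)
      assigned[v] <<- FALSE; parent[v] <<- 0L
    }
    invisible()
  }
  recurse(1L, 0)
  if (!is.finite(best)) stop("no valid spanning arborescence exists")
  trees <- lapply(found, .treeFromParents, g = g, mode = mode)
  trees <- trees[order(vapply(trees, .treeKey, character(1L)))]
  new("MPResult", score = as.integer(best), trees = trees, mode = mode,
      method = if (prune) "branch_and_bound" else "exhaustive")
})

#' Brute-force maximum-parsimony oracle
#'
#' Independent reference implementation used to verify
#' [searchMPTrees()]: enumerates every parent-vector assignment over the
#' nodes, filters the acyclic ones (the rooted labelled spanning
#' arborescences; n^(n-2) of them for n nodes), scores each and returns
#' the full co-optimal set. Intended for tests and small instances only.
#'
#' @param clones a [CloneSet-class] or 0/1 genotype matrix, at most 8
#'   nodes including germline.
#' @param mode \code{"irreversible"} or \code{"free"}.
#' @return an [MPResult-class] (method \code{"exhaustive"}); the number of
#'   arborescences enumerated is in attribute \code{"nCandidates"} of the
#'   tree list.
#' @name mpBruteForce
#' @aliases mpBruteForce,ANY-method
NULL

setMethod("mpBruteForce", "ANY",
  function(clones, mode = c("irreversible", "free")) {
  mode <- match.arg(mode)
  g <- .nodeMatrixFromClones(clones)
  n <- nrow(g)
  if (n > 8L) stop("brute-force oracle supports at most 8 nodes")
  ## independent cost computation, straight from the definitions
  cost <- matrix(Inf, n, n)
  for (p in seq_len(n)) for (v in seq_len(n)) {
    if (p == v) next
    if (mode == "free") {
      cost[p, v] <- sum(g[p, ] != g[v, ])
    } else if (all(g[v, ] - g[p, ] >= 0L)) {
      cost[p, v] <- sum(g[v, ] - g[p, ])
    }
  }
  if (n == 1L) {
    tr <- new("CloneTree", genotypes = g,
              edges = data.frame(parent = character(0),
                                 child = character(0)), mode = mode)
    trees <- list(tr)
    attr(trees, "nCandidates") <- 1L
    return(new("MPResult", score = 0L, trees = trees, mode = mode,
               method = "exhaustive"))
  }
  grid <- as.matrix(expand.grid(lapply(2:n, function(v) setdiff(1:n, v)),
                                KEEP.OUT.ATTRS = FALSE))
  V <- nrow(grid)
  ## acyclicity: iterate parent pointers; all chains must reach the root
  P <- cbind(1L, grid)           # column j = parent of node j (root: self)
  cur <- P
  for (s in seq_len(n))
    cur <- matrix(P[cbind(rep(seq_len(V), times = n), as.vector(cur))],
                  nrow = V)
  acyclic <- rowSums(cur == 1L) == n
  sc <- rep(0, V)
  for (j in 2:n) sc <- sc + cost[cbind(grid[, j - 1L], j)]
  ok <- acyclic & is.finite(sc)
  if (!any(ok)) stop("no valid spanning arborescence exists")
  minScore <- min(sc[ok])
  hit <- which(ok & sc == minScore)
  trees <- lapply(hit, function(i)
    .treeFromParents(g, c(1L, grid[i, ]), mode))
  trees <- trees[order(vapply(trees, .treeKey, character(1L)))]
  attr(trees, "nCandidates") <- sum(acyclic)
  new("MPResult", score = as.integer(minScore), trees = trees, mode = mode,
      method = "exhaustive")
})

#' Edges shared by every co-optimal tree
#'
#' The consensus of a complete co-optimal set: an edge is returned iff it
#' appears in every equally parsimonious tree (the solid, resolved part of
#' the clonal phylogeny; edges present in only some co-optimal trees are
#' the alternative, dotted relationships).
#'
#' @param result an [MPResult-class] with at least one tree.
#' @return data.frame with \code{parent}, \code{child} columns (possibly
#'   zero rows).
#' @export
consensusEdges <- function(result) {
  if (!is(result, "MPResult") || length(result@trees) == 0L)
    stop("empty maximum-parsimony result")
  keys <- lapply(result@trees, function(t)
    paste(t@edges$parent, t@edges$child, sep = ">"))
  shared <- Reduce(intersect, keys)
  if (!length(shared))
    return(data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(sort(shared), ">", fixed = TRUE)
  data.frame(parent = vapply(parts, `[`, character(1L), 1L),
             child = vapply(parts, `[`, character(1L), 2L),
             stringsAsFactors = FALSE)
}
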