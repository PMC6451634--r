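#' Newick serialisation of a clone tree
#'
#' Writes the rooted clonal phylogeny as a Newick string with
#' internal-node labels; observed clones are frequently internal
#' (ancestral) nodes, so unifurcations like \code{((C2)C1)germline;} are
#' legal output. Children are emitted in sorted id order, so equal trees
#' serialise identically.
#'
#' @param tree a [CloneTree-class].
#' @return a single Newick string (terminated by \code{";"}).
#' @examples
#' tr <- cloneTree(rbind(C1 = 1L), data.frame(parent = "germline",
#'                                            child = "C1"))
#' toNewick(tr)
#' @export
toNewick <- function(tree) {
  e <- tree@edges
  kids <- split(e$child, e$parent)
  emit <- function(node) {
    ch <- sort(kids[[node]])
    if (is.null(ch) || !length(ch)) node
    else paste0("(", paste(vapply(ch, emit, character(1L)), collapse = ","),
                ")", node)
  }
  paste0(emit("germline"), ";")
}

#' Parse a Newick string with internal-node labels
#'
#' Minimal recursive-descent reader for the grammar produced by
#' [toNewick()] (labels, nesting, unifurcations; branch lengths after
#' \code{":"} are accepted and discarded). Third-party parsers such as
#' \code{ape::read.tree} accept the same strings for multifurcating
#' trees.
#'
#' @param text a Newick string.
#' @return list with \code{root} (label) and \code{edges} (data.frame
#'   \code{parent}, \code{child}).
#' @export
readNewick <- function(text) {
  s <- strsplit(sub(";\\s*$", "", trimws(text)), "")[[1L]]
  pos <- 1L
  edges <- list()
  anon <- 0L
  readLabel <- function() {
    start <- pos
    while (pos <= length(s) && !s[pos] %in% c("(", ")", ",", ";", ":"))
      pos <<- pos + 1L
    lab <- paste(s[start:(pos - 1L)], collapse = "")
    if (pos <= length(s) && s[pos] == ":") {      # discard branch length
      pos <<- pos + 1L
      while (pos <= length(s) && !s[pos] %in% c("(", ")", ",", ";"))
        pos <<- pos + 1L
    }
    lab
  }
  readClade <- function() {
    children <- character(0)
    if (pos <= length(s) && s[pos] == "(") {
      pos <<- pos + 1L
      repeat {
        children <- c(children, readClade())
        if (pos > length(s)) stop("malformed Newick: unbalanced parentheses")
        if (s[pos] == ",") { pos <<- pos + 1L; next }
        if (s[pos] == ")") { pos <<- pos + 1L; break }
        stop("malformed Newick near position ", pos)
      }
    }
    lab <- if (pos <= length(s) && !s[pos] %in% c("(", ")", ",", ";"))
      readLabel() else { anon <<- anon + 1L; sprintf("node%d", anon) }
    for (ch in children)
      edges[[length(edges) + 1L]] <<- c(lab, ch)
    lab
  }
  root <- readClade()
  e <- if (length(edges)) {
    m <- do.call(rbind, edges)
    data.frame(parent = m[, 1L], child = m[, 2L], stringsAsFactors = FALSE)
  } else data.frame(parent = character(0), child = character(0),
                    stringsAsFactors = FALSE)
  e <- e[order(e$parent, e$child), , drop = FALSE]
  rownames(e) <- NULL
  list(root = root, edges = e)
}

#' DOT (Graphviz) export of a clone tree
#'
#' @param tree a [CloneTree-class].
#' @param file optional path; when missing the DOT text is returned.
#' @return the DOT source, invisibly when written to a file.
#' @export
toDot <- function(tree, file = NULL) {
  g <- tree@genotypes
  labels <- vapply(rownames(g), function(nd) {
    muts <- colnames(g)[g[nd, ] == 1L]
    if (length(muts)) sprintf("%s\\n%s", nd, paste(muts, collapse = " "))
    else nd
  }, character(1L))
  lines <- c("digraph clones {",
             "  node [shape=ellipse];",
             sprintf("  \"%s\" [label=\"%s\"];", rownames(g), labels),
             sprintf("  \"%s\" -> \"%s\";", tree@edges$parent,
                     tree@edges$child),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
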