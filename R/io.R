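## Format round-tripping. Every writer's output is accepted by its reader
## with a value-identical round trip; all files are plain text and written
## deterministically (no timestamps), so equal-seed pipeline runs are
## byte-identical.

.checkColumns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
}

#' Read and write chip CSV tables
#'
#' One row per well x assay x channel: columns \code{cell_id},
#' \code{compartment}, \code{assay_id}, \code{channel} (WT/MUT/CTRL) and
#' \code{ct}, with a missing Ct (no amplification) stored as an empty
#' field.
#'
#' @param chip a chip table data.frame ([sampleChip()] output shape).
#' @param file path to a CSV file.
#' @return \code{readChipCsv}: the chip table; \code{writeChipCsv}: the
#'   path, invisibly.
#' @name chipCsv
NULL

#' @rdname chipCsv
#' @export
writeChipCsv <- function(chip, file) {
  .checkColumns(chip, c("cell_id", "compartment", "assay_id", "channel",
                        "ct"), "chip table")
  utils::write.csv(chip[, c("cell_id", "compartment", "assay_id",
                            "channel", "ct")],
                   file, row.names = FALSE, na = "", quote = FALSE)
  invisible(file)
}

#' @rdname chipCsv
#' @export
readChipCsv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "character",
                                       compartment = "character",
                                       assay_id = "character",
                                       channel = "character"))
  .checkColumns(df, c("cell_id", "compartment", "assay_id", "channel",
                      "ct"), "chip CSV")
  if (is.character(df$ct)) {
    ct <- suppressWarnings(as.numeric(ifelse(df$ct == "", NA, df$ct)))
    bad <- which(!is.na(df$ct) & df$ct != "" & is.na(ct))
    if (length(bad))
      stop("malformed ct value at line ", bad[1L] + 1L, ": '",
           df$ct[bad[1L]], "'")
    df$ct <- ct
  }
  badCh <- which(!df$channel %in% c("WT", "MUT", "CTRL"))
  if (length(badCh))
    stop("malformed channel at line ", badCh[1L] + 1L, ": '",
         df$channel[badCh[1L]], "'")
  df
}

#' Read and write genotype matrix CSV
#'
#' Rows are cells; columns \code{cell_id}, \code{compartment}, \code{qc},
#' then one column per tracked mutation with values
#' \code{WT}/\code{MUT}/\code{MISSING}.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param file path to a CSV file.
#' @param panel optional [AssayPanel-class] for the reader; by default a
#'   panel is inferred from the mutation column names.
#' @return \code{readGenotypeCsv}: a [GenotypeMatrix-class];
#'   \code{writeGenotypeCsv}: the path, invisibly.
#' @name genotypeCsv
NULL

#' @rdname genotypeCsv
#' @export
writeGenotypeCsv <- function(gm, file) {
  df <- data.frame(cell_id = rownames(gm@calls),
                   compartment = gm@compartment, qc = gm@qc,
                   gm@calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname genotypeCsv
#' @export
readGenotypeCsv <- function(file, panel = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  .checkColumns(df, c("cell_id", "compartment", "qc"), "genotype CSV")
  muts <- setdiff(names(df), c("cell_id", "compartment", "qc"))
  if (!length(muts)) stop("genotype CSV has no mutation columns")
  if (is.null(panel)) panel <- assayPanel(muts)
  m <- as.matrix(df[, muts, drop = FALSE])
  bad <- which(!m %in% c("WT", "MUT", "MISSING"))
  if (length(bad)) {
    line <- (bad[1L] - 1L) %% nrow(m) + 1L
    stop("malformed genotype call at line ", line + 1L, ": '", m[bad[1L]],
         "'")
  }
  rownames(m) <- df$cell_id
  new("GenotypeMatrix", calls = m, compartment = df$compartment,
      qc = df$qc, panel = panel)
}

#' Read and write clone table CSV
#'
#' Columns \code{clone_id}, \code{genotype} (0/1 string),
#' \code{<compartment>_count} and \code{<compartment>_freq} per
#' compartment, and \code{confidence}. Two bookkeeping rows,
#' \code{germline} and \code{.unassigned}, keep per-compartment cell
#' accounting lossless; an empty clone set writes a header plus those two
#' rows.
#'
#' @param clones a [CloneSet-class].
#' @param file path to a CSV file.
#' @param panel optional [AssayPanel-class] for the reader.
#' @return \code{readCloneTable}: a [CloneSet-class];
#'   \code{writeCloneTable}: the path, invisibly.
#' @name cloneTable
NULL

#' @rdname cloneTable
#' @export
writeCloneTable <- function(clones, file) {
  comps <- colnames(clones@counts)
  freqs <- cloneFreqs(clones)
  genoStr <- if (nrow(clones@genotypes))
    apply(clones@genotypes, 1L, .genoKey) else character(0)
  df <- data.frame(clone_id = c(rownames(clones@genotypes), "germline",
                                ".unassigned"),
                   genotype = c(genoStr,
                                strrep("0", ncol(clones@genotypes)), ""),
                   stringsAsFactors = FALSE)
  for (cmp in comps) {
    df[[paste0(cmp, "_count")]] <- c(clones@counts[, cmp],
                                     clones@germlineCounts[[cmp]],
                                     clones@unassignedCounts[[cmp]])
    df[[paste0(cmp, "_freq")]] <- c(freqs[, cmp],
                                    clones@germlineCounts[[cmp]] /
                                      max(clones@totals[[cmp]], 1),
                                    clones@unassignedCounts[[cmp]] /
                                      max(clones@totals[[cmp]], 1))
  }
  df$confidence <- c(clones@confidence, "reference", "reference")
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname cloneTable
#' @export
readCloneTable <- function(file, panel = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  .checkColumns(df, c("clone_id", "genotype", "confidence"), "clone table")
  comps <- sub("_count$", "",
               grep("_count$", names(df), value = TRUE))
  if (!length(comps)) stop("clone table has no <compartment>_count columns")
  isClone <- !df$clone_id %in% c("germline", ".unassigned")
  nMut <- nchar(df$genotype[df$clone_id == "germline"][1L])
  if (is.null(panel)) panel <- assayPanel(sprintf("M%02d", seq_len(nMut)))
  cn <- function(cmp, rows) as.numeric(df[[paste0(cmp, "_count")]][rows])
  counts <- vapply(comps, function(cmp) cn(cmp, isClone),
                   numeric(sum(isClone)))
  counts <- matrix(counts, ncol = length(comps),
                   dimnames = list(df$clone_id[isClone], comps))
  germ <- vapply(comps, function(cmp) cn(cmp, df$clone_id == "germline"),
                 numeric(1L))
  unas <- vapply(comps, function(cmp) cn(cmp, df$clone_id == ".unassigned"),
                 numeric(1L))
  genoVals <- unlist(lapply(df$genotype[isClone], .profileToGeno))
  geno <- matrix(if (is.null(genoVals)) integer(0) else genoVals,
                 nrow = sum(isClone), ncol = nMut, byrow = TRUE,
                 dimnames = list(if (sum(isClone)) df$clone_id[isClone],
                                 panel@mutations))
  storage.mode(geno) <- "integer"
  new("CloneSet", genotypes = geno, counts = counts, germlineCounts = germ,
      unassignedCounts = unas, totals = colSums(counts) + germ + unas,
      confidence = stats::setNames(df$confidence[isClone],
                                   df$clone_id[isClone]),
      panel = panel)
}

#' Read and write maximum-parsimony results as JSON
#'
#' Serialises the score, mode, search method, node genotypes and every
#' co-optimal tree as an edge list.
#'
#' @param result an [MPResult-class].
#' @param file path to a JSON file.
#' @param mpresult,tree not used directly; see value.
#' @return \code{readMPResult}: an [MPResult-class]; \code{writeMPResult}:
#'   the path, invisibly.
#' @name mpResultJson
NULL

#' @rdname mpResultJson
#' @export
writeMPResult <- function(result, file) {
  g <- if (length(result@trees)) result@trees[[1L]]@genotypes else
    matrix(integer(0), 0L, 0L)
  obj <- list(
    score = result@score,
    mode = result@mode,
    method = result@method,
    mutations = colnames(g),
    nodes = as.list(stats::setNames(apply(g, 1L, .genoKey), rownames(g))),
    trees = lapply(result@trees, function(t)
      lapply(seq_len(nrow(t@edges)), function(i)
        list(parent = t@edges$parent[i], child = t@edges$child[i]))))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname mpResultJson
#' @export
readMPResult <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = FALSE)
  muts <- unlist(obj$mutations)
  nodes <- names(obj$nodes)
  g <- matrix(unlist(lapply(obj$nodes, function(s) .profileToGeno(s))),
              nrow = length(nodes), ncol = length(muts), byrow = TRUE,
              dimnames = list(nodes, muts))
  storage.mode(g) <- "integer"
  trees <- lapply(obj$trees, function(tl) {
    e <- data.frame(
      parent = vapply(tl, function(x) x$parent, character(1L)),
      child = vapply(tl, function(x) x$child, character(1L)),
      stringsAsFactors = FALSE)
    new("CloneTree", genotypes = g, edges = e, mode = obj$mode)
  })
  new("MPResult", score = as.integer(obj$score), trees = trees,
      mode = obj$mode, method = obj$method)
}

#' Write simulation ground truth as JSON
#'
#' Records the true tree (nodes, genotypes, edges), population
#' frequencies, noise parameters and seed of a synthetic run, for
#' consumption by parameter-recovery tests.
#'
#' @param tree a [TrueCloneTree-class] (or [CloneTree-class]).
#' @param pop a [PopulationSpec-class].
#' @param noise a [NoiseModel-class].
#' @param seed the integer seed the run flowed from.
#' @param file path to a JSON file.
#' @return the path, invisibly.
#' @export
writeTruth <- function(tree, pop, noise, seed, file) {
  g <- tree@genotypes
  obj <- list(
    nodes = as.list(stats::setNames(apply(g, 1L, .genoKey), rownames(g))),
    mutations = colnames(g),
    edges = lapply(seq_len(nrow(tree@edges)), function(i)
      list(parent = tree@edges$parent[i], child = tree@edges$child[i])),
    founder = if (is(tree, "TrueCloneTree")) tree@founderMutation else
      character(0),
    secondary = if (is(tree, "TrueCloneTree")) tree@secondaryMutation else
      character(0),
    reiterated = if (is(tree, "TrueCloneTree")) tree@reiteratedMutation else
      character(0),
    frequencies = apply(pop@freqs, 2L, as.list),
    noise = list(ado = noise@adoRate, fp = noise@fpRate,
                 locus_fail = noise@locusFailRate,
                 cell_fail = noise@cellFailRate),
    seed = seed)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}

#' Pipeline run configuration
#'
#' Bundles all paths and thresholds of a pipeline run; serialises
#' losslessly to JSON. All randomness in a run flows from \code{seed}.
#'
#' @param chipCsv path to the input chip CSV (or NULL when starting from
#'   a called genotype matrix).
#' @param genotypeCsv path to a genotype matrix CSV input.
#' @param panelMutations tracked mutation ids (NULL: infer from input).
#' @param panelKinds optional assay kinds per mutation.
#' @param controlLocus control locus id.
#' @param ctThreshold amplification threshold.
#' @param minCells,minFreq,maxAdoLoci clone-calling thresholds.
#' @param mode parsimony mode.
#' @param exhaustiveLimit exhaustive-search node limit.
#' @param graftCompartments compartment labels treated as xenograft
#'   read-outs and mapped onto the diagnostic clones.
#' @param seed integer seed.
#' @param outDir output directory.
#' @return a \code{CloneArchConfig} (validated list).
#' @export
runConfig <- function(chipCsv = NULL, genotypeCsv = NULL,
                      panelMutations = NULL, panelKinds = NULL,
                      controlLocus = "B2M", ctThreshold = 30,
                      minCells = 2L, minFreq = 0.05, maxAdoLoci = 1L,
                      mode = "irreversible", exhaustiveLimit = 7L,
                      graftCompartments = "graft", seed = 1L,
                      outDir = "clonearch_out") {
  cfg <- list(chipCsv = chipCsv, genotypeCsv = genotypeCsv,
              panelMutations = panelMutations, panelKinds = panelKinds,
              controlLocus = controlLocus,
              ctThreshold = as.numeric(ctThreshold),
              minCells = as.integer(minCells),
              minFreq = as.numeric(minFreq),
              maxAdoLoci = as.integer(maxAdoLoci), mode = mode,
              exhaustiveLimit = as.integer(exhaustiveLimit),
              graftCompartments = graftCompartments,
              seed = as.integer(seed), outDir = outDir)
  stopifnot(cfg$ctThreshold > 0, cfg$minCells >= 1L,
            cfg$minFreq >= 0, cfg$minFreq <= 1, cfg$maxAdoLoci >= 0L,
            cfg$mode %in% c("irreversible", "free"),
            cfg$exhaustiveLimit >= 2L)
  structure(cfg, class = "CloneArchConfig")
}

#' @rdname runConfig
#' @param config a \code{CloneArchConfig}.
#' @param file path to a JSON file.
#' @export
writeConfig <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname runConfig
#' @export
readConfig <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(runConfig, obj[!vapply(obj, is.null, logical(1L))])
}
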