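## End-to-end pipeline: call -> clones -> tree -> order -> map, driven by
## a RunConfig. Outputs are deterministic functions of the config (no
## timestamps; all randomness flows from config$seed), so equal-seed runs
## are byte-identical.

# 31-bit polynomial rolling hash; a stable fingerprint for the log, not
# cryptographic
.configHash <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the clonal-architecture pipeline
#'
#' Executes genotype calling, clone calling, maximum-parsimony tree
#' search, mutation-order analysis and (when graft compartments are
#' present) clone-set mapping, writing all result files under
#' \code{config$outDir}: \code{genotypes.csv}, \code{clones.csv} (and
#' \code{graft_clones.csv}), \code{trees.nwk} (all co-optimal trees),
#' \code{mpresult.json}, \code{interpretation.json},
#' \code{mapping.json}, a human-readable \code{report.txt} and a
#' \code{log.txt} recording the package version, a config hash and
#' per-stage counts.
#'
#' @param config a \code{CloneArchConfig} from [runConfig()].
#' @return invisibly, the report bundle: list with \code{genotypes},
#'   \code{diagnostic}, \code{graft}, \code{mp}, \code{precedence},
#'   \code{reiterated}, \code{mapping} and \code{files}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "CloneArchConfig"))
  log <- c(paste("CloneArch", as.character(utils::packageVersion("CloneArch"))),
           paste("config_hash",
                 .configHash(jsonlite::toJSON(
                   unclass(config)[setdiff(names(config), "outDir")],
                   auto_unbox = TRUE, null = "null"))))

  gm <- .stage("genotyping", {
    if (!is.null(config$chipCsv)) {
      if (!file.exists(config$chipCsv))
        stop("input not found: ", config$chipCsv)
      chip <- readChipCsv(config$chipCsv)
      muts <- config$panelMutations
      if (is.null(muts))
        muts <- setdiff(unique(chip$assay_id), config$controlLocus)
      panel <- assayPanel(muts, kinds = config$panelKinds,
                          control = config$controlLocus)
      callGenotypes(chip, panel, ctThreshold = config$ctThreshold)
    } else if (!is.null(config$genotypeCsv)) {
      if (!file.exists(config$genotypeCsv))
        stop("input not found: ", config$genotypeCsv)
      panel <- if (is.null(config$panelMutations)) NULL else
        assayPanel(config$panelMutations, kinds = config$panelKinds,
                   control = config$controlLocus)
      readGenotypeCsv(config$genotypeCsv, panel = panel)
    } else stop("config needs chipCsv or genotypeCsv")
  })
  log <- c(log,
           paste("cells_total", nrow(calls(gm))),
           paste("cells_pass", sum(qcStatus(gm) == "pass")))

  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  outFile <- function(nm) file.path(config$outDir, nm)
  files <- character(0)
  writeGenotypeCsv(gm, outFile("genotypes.csv"))
  files <- c(files, "genotypes.csv")

  isGraft <- gm@compartment %in% config$graftCompartments
  subsetGm <- function(keep) new("GenotypeMatrix",
                                 calls = gm@calls[keep, , drop = FALSE],
                                 compartment = gm@compartment[keep],
                                 qc = gm@qc[keep], panel = gm@panel)
  diagnostic <- .stage("clone_calling",
    callClones(subsetGm(!isGraft), minCells = config$minCells,
               minFreq = config$minFreq, maxAdoLoci = config$maxAdoLoci))
  writeCloneTable(diagnostic, outFile("clones.csv"))
  files <- c(files, "clones.csv")
  log <- c(log, paste("clones_called", nrow(cloneGenotypes(diagnostic))))

  graft <- NULL
  if (any(isGraft)) {
    graft <- .stage("clone_calling",
      callClones(subsetGm(isGraft), minCells = config$minCells,
                 minFreq = config$minFreq,
                 maxAdoLoci = config$maxAdoLoci))
    writeCloneTable(graft, outFile("graft_clones.csv"))
    files <- c(files, "graft_clones.csv")
  }

  mp <- NULL; precedence <- NULL; reiterated <- NULL
  if (nrow(cloneGenotypes(diagnostic)) >= 1L) {
    mp <- .stage("tree_search",
      searchMPTrees(diagnostic, mode = config$mode,
                    exhaustiveLimit = config$exhaustiveLimit))
    writeMPResult(mp, outFile("mpresult.json"))
    writeLines(vapply(mpTrees(mp), toNewick, character(1L)),
               outFile("trees.nwk"))
    files <- c(files, "mpresult.json", "trees.nwk")
    log <- c(log, paste("trees_found", length(mpTrees(mp))),
             paste("parsimony_score", mpScore(mp)))
    precedence <- .stage("mutation_order",
                         suppressWarnings(mutationPrecedence(diagnostic, mp)))
    reiterated <- detectReiterated(mp)
    jsonlite::write_json(
      list(pairs = precedence$pairs, status = precedence$status,
           reiterated_per_tree = reiterated$perTree,
           reiterated_in_all_trees = reiterated$inAllTrees),
      outFile("interpretation.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    files <- c(files, "interpretation.json")
  }

  mapping <- NULL
  if (!is.null(graft) && nrow(cloneGenotypes(graft)) >= 1L) {
    mapping <- .stage("clone_mapping", mapCloneSets(diagnostic, graft))
    jsonlite::write_json(mapping, outFile("mapping.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, "mapping.json")
  }

  report <- c(
    "CloneArch pipeline report",
    "=========================",
    sprintf("cells: %d total, %d pass QC", nrow(calls(gm)),
            sum(qcStatus(gm) == "pass")),
    sprintf("diagnostic clones called: %d (%d flagged low_frequency)",
            nrow(cloneGenotypes(diagnostic)),
            sum(cloneConfidence(diagnostic) == "low_frequency")),
    if (!is.null(mp)) sprintf(
      "maximum parsimony: score %d, %d co-optimal tree(s) [%s mode]",
      mpScore(mp), length(mpTrees(mp)), mp@mode),
    if (!is.null(precedence)) {
      tr <- precedence$status$mutation[precedence$status$status == "truncal"]
      sprintf("truncal mutation(s): %s",
              if (length(tr)) paste(tr, collapse = ", ") else "none")
    },
    if (!is.null(mapping)) sprintf(
      "graft: %d clone(s); dominant %s (freq %.3f); classes: %s",
      nrow(mapping$mapping), mapping$dominant, mapping$dominantFreq,
      paste(mapping$mapping$class, collapse = ", ")))
  writeLines(report, outFile("report.txt"))
  writeLines(log, outFile("log.txt"))
  files <- c(files, "report.txt", "log.txt")

  invisible(list(genotypes = gm, diagnostic = diagnostic, graft = graft,
                 mp = mp, precedence = precedence, reiterated = reiterated,
                 mapping = mapping, files = file.path(config$outDir, files)))
}
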