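#' Call per-cell genotypes from raw chip signals
#'
#' Reproduces allelic-discrimination calling with a diploid control locus.
#' Per cell, the control channel must amplify below \code{ctThreshold} for
#' the cell to pass QC; otherwise the cell is flagged
#' \code{control_fail} and all its calls are excluded downstream. Per
#' passing cell and dual-probe assay: MUT channel amplified (regardless of
#' the WT channel, since dual amplification means heterozygous) gives
#' \code{MUT}; WT channel alone gives \code{WT}; neither gives
#' \code{MISSING}. Mutant-only assays (indels, FLT3-ITDs) have no WT
#' probe: an amplified MUT channel gives \code{MUT}, otherwise the call is
#' \code{WT} when the cell's control locus amplified and \code{MISSING}
#' when it did not. Zygosity is collapsed: \code{MUT} means "mutant allele
#' detected", matching presence/absence clone genotypes.
#'
#' @param chip a chip table as produced by [sampleChip()] or read by
#'   [readChipCsv()].
#' @param panel the [AssayPanel-class]; every assay id in the chip must be
#'   a panel mutation or the control locus.
#' @param ctThreshold amplification threshold (default 30); Ct values at
#'   or above it count as no amplification.
#' @param excludeWells optional cell ids to flag \code{excluded}
#'   (e.g. wells failing single-cell/doublet checks).
#' @return a [GenotypeMatrix-class].
#' @examples
#' tr <- simulateCloneTree(2, 3, seed = 5)
#' pop <- simulatePopulation(tr, seed = 5)
#' chip <- sampleChip(tr, pop, "blast", 48, noiseModel(0, 0, 0, 0), seed = 5)
#' gm <- callGenotypes(chip, assayPanel(colnames(treeGenotypes(tr))))
#' table(qcStatus(gm))
#' @export
callGenotypes <- function(chip, panel, ctThreshold = 30,
                          excludeWells = character(0)) {
  need <- c("cell_id", "assay_id", "channel", "ct")
  if (!all(need %in% names(chip)))
    stop("chip table must have columns cell_id, compartment, assay_id, ",
         "channel, ct")
  known <- c(panel@mutations, panel@controlLocus)
  bad <- setdiff(unique(chip$assay_id), known)
  if (length(bad))
    stop("assay absent from panel: ", paste(bad, collapse = ", "))

  cells <- unique(chip$cell_id)
  comp <- if ("compartment" %in% names(chip))
    chip$compartment[match(cells, chip$cell_id)] else rep("sample", length(cells))
  amp <- !is.na(chip$ct) & chip$ct < ctThreshold

  ## control QC
  ctrlOk <- vapply(cells, function(cl) {
    i <- chip$cell_id == cl & chip$assay_id == panel@controlLocus &
      chip$channel == "CTRL"
    any(amp[i])
  }, logical(1L))
  qc <- ifelse(ctrlOk, "pass", "control_fail")
  qc[cells %in% excludeWells] <- "excluded"

  kinds <- assayKinds(panel)
  callMatrix <- matrix("MISSING", nrow = length(cells),
                       ncol = length(panel@mutations),
                       dimnames = list(cells, panel@mutations))
  ## index signals once: amplified per (cell, assay, channel)
  key <- paste(chip$cell_id, chip$assay_id, chip$channel, sep = "\r")
  ampByKey <- tapply(amp, key, any)
  hasAmp <- function(cl, as, ch) {
    v <- ampByKey[paste(cl, as, ch, sep = "\r")]
    !is.na(v) & v
  }
  for (mut in panel@mutations) {
    mutAmp <- hasAmp(cells, mut, "MUT")
    if (kinds[[mut]] == "allelic_discrimination") {
      wtAmp <- hasAmp(cells, mut, "WT")
      callMatrix[, mut] <- ifelse(mutAmp, "MUT",
                                  ifelse(wtAmp, "WT", "MISSING"))
    } else {
      callMatrix[, mut] <- ifelse(mutAmp, "MUT",
                                  ifelse(ctrlOk, "WT", "MISSING"))
    }
  }
  new("GenotypeMatrix", calls = callMatrix, compartment = as.character(comp),
      qc = qc, panel = panel)
}

#' Reconstruct a chip table from called genotypes
#'
#' Deterministic inverse of [callGenotypes()] up to Ct magnitudes: every
#' amplified channel is written with a nominal Ct, every non-amplified
#' channel with a missing Ct, such that re-calling the reconstructed chip
#' returns the identical matrix (idempotence of the calling rule).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param ct nominal Ct written for amplified channels.
#' @return a chip table data.frame.
#' @export
genotypesToChip <- function(gm, ct = 20) {
  panel <- gm@panel
  kinds <- assayKinds(panel)
  cells <- rownames(gm@calls)
  rows <- list(data.frame(
    cell_id = cells, compartment = gm@compartment,
    assay_id = panel@controlLocus, channel = "CTRL",
    ct = ifelse(gm@qc == "pass", ct, NA_real_), stringsAsFactors = FALSE))
  for (mut in panel@mutations) {
    cl <- gm@calls[, mut]
    mutCt <- ifelse(cl == "MUT", ct, NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cells, compartment = gm@compartment, assay_id = mut,
      channel = "MUT", ct = mutCt, stringsAsFactors = FALSE)
    if (kinds[[mut]] == "allelic_discrimination")
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cells, compartment = gm@compartment, assay_id = mut,
        channel = "WT", ct = ifelse(cl == "MISSING", NA_real_, ct),
        stringsAsFactors = FALSE)
  }
  chip <- do.call(rbind, rows)
  chip <- chip[order(match(chip$cell_id, cells),
                     match(chip$assay_id,
                           c(panel@controlLocus, panel@mutations)),
                     chip$channel), , drop = FALSE]
  rownames(chip) <- NULL
  chip
}

#' Per-compartment QC report for a genotype matrix
#'
#' @param gm a [GenotypeMatrix-class] with at least one cell.
#' @return list with \code{cells} (per-compartment pass/control_fail/
#'   excluded counts) and \code{assays} (per-assay MISSING rate among
#'   passing cells).
#' @export
qcSummary <- function(gm) {
  if (!is(gm, "GenotypeMatrix") || nrow(gm@calls) == 0L)
    stop("empty genotype matrix")
  tab <- table(compartment = gm@compartment,
               qc = factor(gm@qc, levels = c("pass", "control_fail",
                                             "excluded")))
  cellDf <- as.data.frame.matrix(tab)
  cellDf <- cbind(compartment = rownames(cellDf), cellDf)
  rownames(cellDf) <- NULL
  passCalls <- gm@calls[gm@qc == "pass", , drop = FALSE]
  miss <- if (nrow(passCalls))
    colMeans(passCalls == "MISSING") else
    stats::setNames(rep(NA_real_, ncol(gm@calls)), colnames(gm@calls))
  list(cells = cellDf,
       assays = data.frame(assay_id = names(miss),
                           missing_rate = as.numeric(miss),
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Combine genotype matrices from several chips
#'
#' Row-binds matrices sharing one panel (e.g. the blast and stem chips of
#' one patient) so clones can be called jointly across compartments.
#'
#' @param ... [GenotypeMatrix-class] objects on the same panel.
#' @return a [GenotypeMatrix-class].
#' @export
combineGenotypes <- function(...) {
  gms <- list(...)
  if (length(gms) == 1L && is.list(gms[[1L]]) && !is(gms[[1L]], "GenotypeMatrix"))
    gms <- gms[[1L]]
  stopifnot(length(gms) >= 1L)
  p <- gms[[1L]]@panel
  for (g in gms)
    if (!identical(mutationIds(g), mutationIds(p)))
      stop("genotype matrices must share one assay panel")
  new("GenotypeMatrix",
      calls = do.call(rbind, lapply(gms, calls)),
      compartment = unlist(lapply(gms, function(g) g@compartment),
                           use.names = FALSE),
      qc = unlist(lapply(gms, function(g) g@qc), use.names = FALSE),
      panel = p)
}
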