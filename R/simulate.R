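## Synthetic peptide-level data generator. Emulates the statistical structure
## the purge relies on: uniform bead background, anti-tag cross-reactive
## binders enriched on one arm in both genotypes, a core complex enriched in
## the case group of both tags, and per-tag specific interactors. Intensities
## are log-normal around class-and-group-dependent means, censored at a
## detection floor and thinned by a small uniform dropout.

## Which (genotype, arm) groups a truth class is enriched in.
classEnriched <- function(cls, genotype, arm) {
  switch(cls,
    CORE_COMPLEX = genotype == "TURNX" & (arm == "HA" | arm == "V5"),
    HA_SPECIFIC = genotype == "TURNX" & arm == "HA",
    V5_SPECIFIC = genotype == "TURNX" & arm == "V5",
    TAG_CROSS_REACTIVE_HA = arm == "HA",
    TAG_CROSS_REACTIVE_V5 = arm == "V5",
    rep(FALSE, length(arm)))
}

#' Simulate a peptide-level AP-MS dataset with known ground truth
#'
#' Draws a long-format peptide intensity table for every fraction of `design`
#' plus the truth table mapping each simulated accession to its interactor
#' class and realized fold. Identical (design, config) input — the seed lives
#' in the config — reproduces the output bit-for-bit. Only observed
#' measurements are emitted: a (protein, peptide, sample) combination censored
#' below the detection floor or hit by dropout has no row.
#'
#' @param design a [StudyDesign]
#' @param config a [SimulationConfig]
#' @return list with elements `peptides` (data.frame: accession, peptide_id,
#'   sample_id, intensity), `truth` (data.frame: accession, class,
#'   realized_fold) and `samples` (the design's sample sheet)
#' @examples
#' sim <- simulateDataset(StudyDesign(), SimulationConfig(seed = 1))
#' length(unique(sim$peptides$sample_id))  # 96
#' @export
simulateDataset <- function(design, config) {
  stopifnot(is(design, "StudyDesign"), is(config, "SimulationConfig"))
  validObject(design); validObject(config)
  cc <- config@classCounts
  nProt <- sum(cc)
  if (nProt == 0L) stop("empty simulation: all class counts are zero")

  set.seed(config@seed)
  sheet <- sampleSheet(design)
  cls <- rep(names(cc), cc)
  acc <- sprintf("SIM%04d", seq_len(nProt))

  nPep <- 1L + stats::rpois(nProt, config@peptideLambda)
  protOffset <- stats::rnorm(nProt, 0, config@proteinSdLog2)
  pepOffset <- stats::rnorm(sum(nPep), 0, config@peptideSdLog2)

  ## sd of log2 intensity implied by a natural-scale CV
  sigmaLog2 <- sqrt(log(1 + config@biologicalCV^2)) / log(2)
  dLog2 <- log2(config@foldEnrichment)

  pep <- data.table::data.table(
    accession = rep(acc, nPep),
    class = rep(cls, nPep),
    peptide_id = paste0(rep(acc, nPep), "_p",
                        unlist(lapply(nPep, seq_len), use.names = FALSE)),
    base = rep(config@baselineLog2 + protOffset, nPep) + pepOffset)

  nS <- nrow(sheet)
  full <- pep[rep(seq_len(nrow(pep)), each = nS)]
  sidx <- rep(seq_len(nS), times = nrow(pep))
  full[, `:=`(sample_id = sheet$sample_id[sidx],
              genotype = sheet$genotype[sidx], arm = sheet$arm[sidx])]
  full[, enriched := FALSE]
  for (k in setdiff(TRUTH_CLASSES, c("BEAD_BACKGROUND", "ABSENT"))) {
    idx <- full$class == k
    if (any(idx))
      full$enriched[idx] <- classEnriched(k, full$genotype[idx],
                                          full$arm[idx])
  }
  full[, mu := base + enriched * dLog2]
  full[class == "ABSENT", mu := config@detectionFloorLog2 - 8]
  full[, log2i := mu + stats::rnorm(.N, 0, sigmaLog2)]
  full[, keep := log2i >= config@detectionFloorLog2 &
                 stats::runif(.N) >= config@stochasticDropout]

  peptides <- as.data.frame(
    full[keep == TRUE,
         .(accession, peptide_id, sample_id, intensity = 2^log2i)])
  o <- order(peptides$accession, peptides$peptide_id, peptides$sample_id)
  peptides <- peptides[o, , drop = FALSE]
  rownames(peptides) <- NULL

  truth <- data.frame(
    accession = acc, class = cls,
    realized_fold = ifelse(cls %in% c("BEAD_BACKGROUND", "ABSENT"),
                           1, config@foldEnrichment),
    stringsAsFactors = FALSE)
  list(peptides = peptides, truth = truth, samples = sheet)
}

#' Accessions the purge should recover for one tag
#'
#' The truth positives of a tag are the core complex plus that tag's specific
#' interactors; bead background and antibody cross-reactive classes are never
#' members (they are exactly what the three negative controls exist to
#' remove).
#'
#' @param truth truth data.frame from [simulateDataset()]
#' @param tag "HA" or "V5"
#' @return character vector of accessions
#' @export
truthPositiveSet <- function(truth, tag) {
  tag <- match.arg(toupper(tag), TAGS)
  truth$accession[truth$class %in%
                  c("CORE_COMPLEX", paste0(tag, "_SPECIFIC"))]
}

#' Read/write long-format peptide tables
#'
#' TSV with header accession, peptide_id, sample_id, intensity. Rows whose
#' intensity cell is empty (missing measurement) are dropped on read; the
#' in-memory representation holds observed measurements only.
#'
#' @param peptides peptide data.frame
#' @param path file path
#' @return `path` (write) or the peptide data.frame (read)
#' @export
writePeptideTable <- function(peptides, path) {
  stopifnot(all(c("accession", "peptide_id", "sample_id", "intensity") %in%
                names(peptides)))
  out <- peptides[c("accession", "peptide_id", "sample_id", "intensity")]
  out$intensity <- format(out$intensity, digits = 15, trim = TRUE,
                          scientific = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePeptideTable
#' @export
readPeptideTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("peptide table not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "peptide_id", "sample_id", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("peptide table %s is missing column(s): %s", basename(path),
                 paste(missing, collapse = ", ")))
  df$intensity <- suppressWarnings(as.numeric(df$intensity))
  df <- df[!is.na(df$intensity), need]
  if (any(df$intensity <= 0))
    stop("peptide intensities must be strictly positive")
  if (anyDuplicated(df[c("accession", "peptide_id", "sample_id")]))
    stop("duplicate (accession, peptide_id, sample_id) rows in peptide table")
  rownames(df) <- NULL
  df
}

#' Write a truth table as TSV
#'
#' @param truth truth data.frame
#' @param path file path
#' @export
writeTruthTable <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
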