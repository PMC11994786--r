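## Shared fixtures, all built in code.

## long-format peptide table from a named list:
## list(P1 = list(pep1 = c(sampleA = 10, sampleB = 20), ...), ...)
makePeptides <- function(spec) {
  rows <- do.call(rbind, lapply(names(spec), function(acc) {
    do.call(rbind, lapply(names(spec[[acc]]), function(pep) {
      v <- spec[[acc]][[pep]]
      data.frame(accession = acc, peptide_id = pep,
                 sample_id = names(v), intensity = unname(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

## reduced-size simulation config for unit tests (study-condition intensity
## model, fewer proteins)
smallSimConfig <- function(seed, foldEnrichment = 8) {
  SimulationConfig(seed = seed,
                   classCounts = c(BEAD_BACKGROUND = 60L,
                                   TAG_CROSS_REACTIVE_HA = 8L,
                                   TAG_CROSS_REACTIVE_V5 = 8L,
                                   CORE_COMPLEX = 5L,
                                   HA_SPECIFIC = 10L, V5_SPECIFIC = 10L,
                                   ABSENT = 0L),
                   foldEnrichment = foldEnrichment)
}

## deterministic 3-control toy dataset: 4 couples x 1 replicate, one peptide
## per protein, intensities set per (genotype, arm) in log2 units with a tiny
## fixed jitter so variances are nonzero
toySheet <- function() {
  sampleSheet(StudyDesign(nCouples = 4L, replicatesPerArm = 1L))
}

toyPeptides <- function(log2means) {
  ## log2means: named list protein -> function(genotype, arm) -> log2 mean
  sheet <- toySheet()
  jit <- c(-0.02, 0.01, -0.01, 0.02)  # per couple, fixed
  rows <- lapply(names(log2means), function(acc) {
    mu <- mapply(log2means[[acc]], sheet$genotype, sheet$arm)
    keep <- !is.na(mu)
    couple <- as.integer(sub("^C", "", sheet$couple_id))
    data.frame(accession = acc, peptide_id = paste0(acc, "_p1"),
               sample_id = sheet$sample_id[keep],
               intensity = 2^(mu[keep] + jit[couple[keep]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## brute-force oracle for the pairwise-ratio rollup: explicit enumeration of
## all cross-pair log ratios and a sort-based median (independent of the
## implementation's outer/median path)
bruteMedianLog <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

brutePairwiseRatio <- function(case, ctrl) {
  lr <- numeric(0)
  for (a in case) for (b in ctrl) lr <- c(lr, log(a) - log(b))
  exp(bruteMedianLog(lr))
}

bruteProteinRatio <- function(peptides, caseSamples, ctrlSamples) {
  pepIds <- unique(peptides$peptide_id)
  pr <- numeric(0)
  for (p in pepIds) {
    sub <- peptides[peptides$peptide_id == p, ]
    a <- sub$intensity[sub$sample_id %in% caseSamples]
    b <- sub$intensity[sub$sample_id %in% ctrlSamples]
    if (length(a) && length(b)) pr <- c(pr, brutePairwiseRatio(a, b))
  }
  if (!length(pr)) NA_real_ else exp(bruteMedianLog(log(pr)))
}

## random peptide table generator for property tests
randomPeptideTable <- function(nPep, caseSamples, ctrlSamples,
                               dropout = 0.2) {
  rows <- list()
  for (p in seq_len(nPep)) {
    for (s in c(caseSamples, ctrlSamples)) {
      if (stats::runif(1) < dropout) next
      rows[[length(rows) + 1L]] <- data.frame(
        accession = "P1", peptide_id = paste0("pep", p), sample_id = s,
        intensity = 2^stats::rnorm(1, 20, 2), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

## CTLH core-complex rows as printed in the per-tag interactor tables
## (accession, gene symbol); Wdr26 appears as two isoform accessions
ctlhTableRows <- function(tag = c("HA", "V5")) {
  tag <- match.arg(tag)
  ha <- data.frame(
    accession = c("P62700", "Q9D7M1", "A0A0R4J0G4", "A0A494BB75", "G3X920",
                  "O89050", "P69566", "Q80YQ8", "Q4VC33", "E0CYH4",
                  "Q9CPY6", "Q91YQ7"),
    symbol = c("Ypel5", "Gid8", "Ranbp10", "Wdr26", "Armc8", "Mkln1",
               "Ranbp9", "Rmnd5a", "Maea", "Wdr26", "Gid4", "Rmnd5b"),
    stringsAsFactors = FALSE)
  if (tag == "HA") return(ha)
  ha[ha$symbol != "Rmnd5b", ]  # the V5 list lacks Rmnd5b
}
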