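## Significance against each of the three negative-control groups and the
## purge that defines a tag's interactome: a protein is retained only if it
## is enriched (ratio vs the pooled controls) AND significant (two-sided
## Welch t on log2 abundances) against every control group separately.

#' Group-wise log2 protein abundances
#'
#' Builds per-protein log2 abundance observations for one (genotype, arm)
#' group. With `MOUSE_MEAN` the fractions of each mouse are averaged on the
#' log2 scale into one value per animal (missing fractions ignored; a mouse
#' with no detection contributes `NA`); with `FRACTION` every fraction is one
#' observation.
#'
#' @param peptides peptide data.frame
#' @param sheet sample-sheet data.frame
#' @param group character of length 2: (genotype, arm)
#' @param unit "MOUSE_MEAN" or "FRACTION"
#' @return numeric matrix, rows = accessions, columns = replicate units
#' @export
groupAbundances <- function(peptides, sheet, group,
                            unit = c("MOUSE_MEAN", "FRACTION")) {
  unit <- match.arg(unit)
  sub <- sheet[sheet$genotype == toupper(group[1L]) &
               sheet$arm == toupper(group[2L]), , drop = FALSE]
  if (!nrow(sub))
    stop(sprintf("no samples in group (%s, %s)", group[1L], group[2L]))
  m <- log2(abundanceMatrix(peptides, sub$sample_id))
  if (unit == "FRACTION") return(m)
  mice <- unique(sub$mouse_id)
  out <- vapply(mice, function(mm) {
    cols <- sub$sample_id[sub$mouse_id == mm]
    rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(m))
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(rownames(m), mice)
  out
}

#' Two-sided Welch t-test p-value with presence/absence conventions
#'
#' Unequal-variance (Welch) t-test on log2 abundances, floored at `pFloor`.
#' Degenerate rules mirror the saturation conventions of capped AP-MS
#' reports: two constant groups with equal value give p = 1 and with
#' different values give the floor; a protein observed in at least
#' `minPresent` case units but in no control unit is a presence-only call at
#' the floor. Outside these rules a group with fewer than two values is
#' untestable and yields `NA` (insufficient replication).
#'
#' @param caseValues,controlValues numeric vectors (NAs allowed and dropped)
#' @param pFloor lower saturation for the p-value
#' @param minPresent detections required for the presence-only convention
#' @return p-value in `[pFloor, 1]`, or `NA` if untestable
#' @examples
#' welchP(c(5, 5, 5, 5), c(5, 5, 5, 5))  # 1
#' @export
welchP <- function(caseValues, controlValues, pFloor = 1e-17,
                   minPresent = 3L) {
  x <- caseValues[!is.na(caseValues)]
  y <- controlValues[!is.na(controlValues)]
  nx <- length(x); ny <- length(y)
  if (nx >= minPresent && ny == 0L) return(pFloor)
  if (ny >= minPresent && nx == 0L) return(pFloor)
  if (nx >= 1L && ny >= 1L) {
    vx <- if (nx > 1L) stats::var(x) else 0
    vy <- if (ny > 1L) stats::var(y) else 0
    if (vx == 0 && vy == 0)
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else pFloor)
  }
  if (nx < 2L || ny < 2L) return(NA_real_)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1L) + (vy / ny)^2 / (ny - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  min(max(p, pFloor), 1)
}

## Vectorized Welch over matrix rows (case m1, control m2); applies the same
## degenerate rules as welchP. Returns a numeric vector with NA = untestable.
rowWelchP <- function(m1, m2, pFloor, minPresent) {
  n1 <- rowSums(!is.na(m1)); n2 <- rowSums(!is.na(m2))
  mu1 <- rowMeans(m1, na.rm = TRUE); mu2 <- rowMeans(m2, na.rm = TRUE)
  v1 <- apply(m1, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(m2, 1L, stats::var, na.rm = TRUE)
  v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0
  p <- rep(NA_real_, nrow(m1))
  presCase <- n1 >= minPresent & n2 == 0L
  presCtrl <- n2 >= minPresent & n1 == 0L
  p[presCase | presCtrl] <- pFloor
  const <- n1 >= 1L & n2 >= 1L & v1 == 0 & v2 == 0
  p[const] <- ifelse(abs(mu1[const] - mu2[const]) < 1e-12, 1, pFloor)
  todo <- is.na(p) & n1 >= 2L & n2 >= 2L & !const
  if (any(todo)) {
    se2 <- v1[todo] / n1[todo] + v2[todo] / n2[todo]
    tstat <- (mu1[todo] - mu2[todo]) / sqrt(se2)
    df <- se2^2 / ((v1[todo] / n1[todo])^2 / (n1[todo] - 1L) +
                   (v2[todo] / n2[todo])^2 / (n2[todo] - 1L))
    p[todo] <- pmin(pmax(2 * stats::pt(-abs(tstat), df), pFloor), 1)
  }
  p
}

## Vectorized pairwise-ratio rollup for all proteins at once; equivalent to
## proteinRatio() per accession (property-tested). Returns a data.table with
## accession, ratio, capped, n_peptides_used, presence_only.
rollupRatios <- function(peptides, caseSamples, controlSamples, qc) {
  dt <- data.table::as.data.table(peptides)
  caseObs <- dt[sample_id %in% caseSamples]
  ctrlObs <- dt[sample_id %in% controlSamples]
  det <- merge(
    caseObs[, .(n_case_det = data.table::uniqueN(sample_id),
                n_case_pep = data.table::uniqueN(peptide_id)),
            by = accession],
    ctrlObs[, .(n_ctrl_det = data.table::uniqueN(sample_id),
                n_ctrl_pep = data.table::uniqueN(peptide_id)),
            by = accession],
    by = "accession", all = TRUE)
  for (col in c("n_case_det", "n_case_pep", "n_ctrl_det", "n_ctrl_pep"))
    data.table::set(det, which(is.na(det[[col]])), col, 0L)

  pairs <- merge(caseObs[, .(accession, peptide_id, lc = log(intensity))],
                 ctrlObs[, .(accession, peptide_id, lx = log(intensity))],
                 by = c("accession", "peptide_id"), allow.cartesian = TRUE)
  pepR <- pairs[, .(lpr = stats::median(lc - lx)),
                by = .(accession, peptide_id)]
  protR <- pepR[, .(raw = exp(stats::median(lpr)),
                    n_peptides_used = .N), by = accession]

  out <- merge(det, protR, by = "accession", all.x = TRUE)
  out[, presence_only := "NO"]
  out[n_ctrl_det == 0L & n_case_det >= qc@minPresentReplicates,
      presence_only := "CASE_ONLY"]
  out[n_case_det == 0L & n_ctrl_det >= qc@minPresentReplicates,
      presence_only := "CONTROL_ONLY"]
  out[, ratio := pmin(pmax(raw, qc@ratioFloor), qc@ratioCeiling)]
  out[, capped := !is.na(raw) & ratio != raw]
  out[presence_only == "CASE_ONLY",
      `:=`(ratio = qc@ratioCeiling, capped = TRUE,
           n_peptides_used = n_case_pep)]
  out[presence_only == "CONTROL_ONLY",
      `:=`(ratio = qc@ratioFloor, capped = TRUE,
           n_peptides_used = n_ctrl_pep)]
  out[is.na(n_peptides_used), n_peptides_used := 0L]
  out[, .(accession, ratio, capped, n_peptides_used, presence_only,
          n_case_det, n_ctrl_det)]
}

#' Run the three-negative-control purge for one contrast
#'
#' For every protein detected in the contrast's case group: the abundance
#' ratio is computed against the three control groups pooled (the tables'
#' single printed denominator) while significance is assessed against each
#' control group separately; the protein is retained iff the largest of the
#' three Welch p-values is at or below `alpha` and the ratio is at least
#' `minFold`. Output records are sorted by descending ratio, then ascending
#' reported p, then accession, so identical inputs give byte-identical
#' tables. A Benjamini-Hochberg adjusted column is emitted for information
#' only; the retention rule uses raw p-values. The full per-protein table
#' (retained or not) is kept under `provenance(x)$tested` for diagnostics.
#'
#' @param peptides peptide data.frame
#' @param sheet sample-sheet data.frame
#' @param contrast a [ContrastSpec]
#' @param qc a [QuantConfig]
#' @param pc a [PurgeConfig]
#' @param descriptions optional named character (accession -> description)
#' @param annotation optional annotation data.frame (accession, category)
#' @return an [Interactome]
#' @export
runPurge <- function(peptides, sheet, contrast, qc = QuantConfig(),
                     pc = PurgeConfig(), descriptions = NULL,
                     annotation = NULL) {
  stopifnot(is(contrast, "ContrastSpec"), is(qc, "QuantConfig"),
            is(pc, "PurgeConfig"))
  validObject(contrast); validObject(qc); validObject(pc)
  case <- caseGroup(contrast)
  ctrls <- controlGroups(contrast)
  caseSamples <- samplesInGroup(sheet, case[1L], case[2L])
  if (!length(caseSamples))
    stop(sprintf("empty case group (%s, %s)", case[1L], case[2L]))
  ctrlSampleSets <- lapply(seq_len(nrow(ctrls)), function(i) {
    s <- samplesInGroup(sheet, ctrls[i, 1L], ctrls[i, 2L])
    if (!length(s))
      stop(sprintf("empty control group (%s, %s)", ctrls[i, 1L],
                   ctrls[i, 2L]))
    s
  })
  pooledCtrl <- unique(unlist(ctrlSampleSets))

  detected <- unique(peptides$accession[peptides$sample_id %in% caseSamples])
  rr <- rollupRatios(peptides, caseSamples, pooledCtrl, qc)
  rr <- rr[rr$accession %in% detected, ]
  data.table::setkey(rr, accession)
  accs <- rr$accession

  unit <- pc@replicateUnit
  caseM <- groupAbundances(peptides, sheet, case, unit)
  caseM <- padRows(caseM, accs)
  pm <- vapply(seq_len(nrow(ctrls)), function(i) {
    cm <- padRows(groupAbundances(peptides, sheet, ctrls[i, ], unit), accs)
    rowWelchP(caseM, cm, pc@pFloor, qc@minPresentReplicates)
  }, numeric(length(accs)))
  if (!is.matrix(pm)) pm <- matrix(pm, nrow = length(accs))
  colnames(pm) <- sprintf("p_vs_%s_%s", ctrls[, 1L], ctrls[, 2L])

  pReported <- apply(pm, 1L, max)  # NA if any comparison untestable
  testable <- !is.na(pReported)
  significant <- testable & pReported <= pc@alpha & !is.na(rr$ratio) &
    rr$ratio >= pc@minFold

  tab <- data.frame(
    accession = accs,
    description = if (is.null(descriptions)) accs
                  else unname(descriptions[accs]),
    ratio = rr$ratio, capped = rr$capped,
    pm, p_reported = pReported,
    p_adj_bh = NA_real_,
    presence_only = rr$presence_only,
    n_peptides_used = rr$n_peptides_used,
    annotation = if (is.null(annotation)) "" else
      vapply(accs, function(a)
        paste(annotationLookup(annotation, a), collapse = ";"),
        character(1L)),
    stringsAsFactors = FALSE, check.names = FALSE)
  tab$p_adj_bh[testable] <- stats::p.adjust(pReported[testable], "BH")
  tab$description[is.na(tab$description)] <- tab$accession[is.na(tab$description)]

  kept <- tab[significant, , drop = FALSE]
  o <- order(-kept$ratio, kept$p_reported, kept$accession)
  kept <- kept[o, , drop = FALSE]
  rownames(kept) <- NULL

  new("Interactome", tag = tagOf(contrast), records = kept,
      provenance = list(
        contrast = list(tag = tagOf(contrast), case = unname(case),
                        controls = unname(ctrls)),
        tested = tab,
        quantConfig = configSnapshot(qc), purgeConfig = configSnapshot(pc),
        counts = list(n_detected_in_case = length(detected),
                      n_tested = sum(testable),
                      n_excluded_insufficient_replication = sum(!testable),
                      n_significant = nrow(kept))))
}

## align a group-abundance matrix onto a fixed accession set
padRows <- function(m, accs) {
  out <- matrix(NA_real_, nrow = length(accs), ncol = ncol(m),
                dimnames = list(accs, colnames(m)))
  shared <- intersect(rownames(m), accs)
  out[shared, ] <- m[shared, , drop = FALSE]
  out
}

configSnapshot <- function(x) {
  sl <- methods::slotNames(class(x))
  stats::setNames(lapply(sl, function(s) methods::slot(x, s)), sl)
}

#' @rdname accessors
#' @export
setMethod("tagOf", "Interactome", function(x) x@tag)

#' @rdname accessors
#' @export
setMethod("records", "Interactome", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("accessions", "Interactome", function(x) x@records$accession)

#' @rdname accessors
#' @export
setMethod("provenance", "Interactome", function(x) x@provenance)

#' @export
setMethod("length", "Interactome", function(x) nrow(x@records))

setMethod("show", "Interactome", function(object) {
  cnt <- object@provenance$counts
  cat(sprintf("Interactome [%s]: %d significant protein(s)", object@tag,
              nrow(object@records)))
  if (!is.null(cnt))
    cat(sprintf(" (of %d detected in case, %d untestable)",
                cnt$n_detected_in_case,
                cnt$n_excluded_insufficient_replication))
  cat("\n")
})

#' Read/write an interactome table
#'
#' TSV twin of a published per-tag interactor table: Accession, Description,
#' Abundance_ratio, Ratio_capped, three per-control p columns, p_reported,
#' p_adj_BH, Presence_only, N_peptides, Annotation.
#'
#' @param x an [Interactome]
#' @param path file path
#' @param tag tag label for the read object ("HA" or "V5")
#' @return `path` (write) or an [Interactome] (read)
#' @export
writeInteractome <- function(x, path) {
  stopifnot(is(x, "Interactome"))
  r <- records(x)
  pcols <- grep("^p_vs_", names(r), value = TRUE)
  out <- data.frame(Accession = r$accession, Description = r$description,
                    Abundance_ratio = r$ratio, Ratio_capped = r$capped,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pcols)) out[[sprintf("p_vs_ctrl%d", i)]] <- r[[pcols[i]]]
  out$p_reported <- r$p_reported
  out$p_adj_BH <- r$p_adj_bh
  out$Presence_only <- r$presence_only
  out$N_peptides <- r$n_peptides_used
  out$Annotation <- r$annotation
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeInteractome
#' @export
readInteractome <- function(path, tag) {
  if (!file.exists(path)) stop(sprintf("interactome file not found: %s", path))
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop(sprintf("malformed interactome TSV %s: line %d has %d fields, expected %d",
                 basename(path), which(nf != nf[1L])[1L],
                 nf[which(nf != nf[1L])[1L]], nf[1L]))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"Accession" %in% names(df))
    stop(sprintf("interactome TSV %s lacks an Accession column",
                 basename(path)))
  rec <- data.frame(accession = df$Accession,
                    description = if ("Description" %in% names(df))
                      df$Description else df$Accession,
                    stringsAsFactors = FALSE)
  for (col in c("Abundance_ratio", "p_reported")) {
    key <- tolower(sub("Abundance_ratio", "ratio", col))
    if (col %in% names(df)) rec[[key]] <- df[[col]]
  }
  rec$annotation <- if ("Annotation" %in% names(df)) df$Annotation else ""
  new("Interactome", tag = match.arg(toupper(tag), TAGS), records = rec,
      provenance = list(source = path))
}
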