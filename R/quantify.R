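## Protein quantification by the pairwise-ratio method: the protein-level
## abundance ratio is the geometric median of per-peptide ratios, each
## peptide ratio being the geometric median of all cross-pair ratios a_i/b_j
## between its case and control observations. On positive scalars the
## geometric median is the multiplicative-scale median (median of logs); for
## an even count the midpoint of the two central logs, i.e. the geometric
## mean of the two central ratios, which makes inversion symmetry exact.

## median on the log scale, exponentiated; even-count rule = geometric mean
## of the central pair (stats::median of logs does exactly that)
geomedian <- function(x) exp(stats::median(log(x)))

#' Geometric median of all cross-pair peptide ratios
#'
#' Enumerates every ratio a_i/b_j between the case and control observations
#' of one peptide and returns their geometric median. Replicates are unpaired
#' across animals, hence the group-wise cross-pair enumeration rather than
#' index-matched pairs.
#'
#' @param caseIntensities,controlIntensities positive, non-empty numeric
#'   vectors (missing values already removed)
#' @return positive scalar ratio
#' @examples
#' pairwisePeptideRatio(c(8, 8), c(2, 2))  # 4
#' @export
pairwisePeptideRatio <- function(caseIntensities, controlIntensities) {
  if (length(caseIntensities) == 0L || length(controlIntensities) == 0L)
    stop("peptide absent on one side; presence/absence logic must handle ",
         "this before ratio computation")
  if (any(caseIntensities <= 0) || any(controlIntensities <= 0))
    stop("intensities must be strictly positive")
  lr <- as.vector(outer(log(caseIntensities), log(controlIntensities), "-"))
  exp(stats::median(lr))
}

#' Roll one protein's peptides up to a capped abundance ratio
#'
#' Peptides observed in at least one case and one control sample each
#' contribute a pairwise cross-pair ratio; the protein ratio is the geometric
#' median of those peptide ratios, clamped to
#' `[1/ratioCeiling, ratioCeiling]`. A protein detected in at least
#' `minPresentReplicates` case samples and in no control sample is a
#' presence-only call (`CASE_ONLY`) reported at the ceiling; the mirror case
#' (`CONTROL_ONLY`) is reported at the floor.
#'
#' @param peptides peptide data.frame restricted to one accession
#' @param caseSamples,controlSamples disjoint, non-empty sample-id sets
#' @param config a [QuantConfig]
#' @return a [ProteinRatio] object
#' @export
proteinRatio <- function(peptides, caseSamples, controlSamples,
                         config = QuantConfig()) {
  stopifnot(is(config, "QuantConfig"))
  validObject(config)
  if (length(intersect(caseSamples, controlSamples)))
    stop("case and control sample sets must be disjoint")
  if (!length(caseSamples) || !length(controlSamples))
    stop("case and control sample sets must be non-empty")
  acc <- unique(peptides$accession)
  if (length(acc) > 1L)
    stop("proteinRatio expects peptides of a single accession")
  if (length(acc) == 0L) acc <- NA_character_

  caseObs <- peptides[peptides$sample_id %in% caseSamples, , drop = FALSE]
  ctrlObs <- peptides[peptides$sample_id %in% controlSamples, , drop = FALSE]
  nCaseDet <- length(unique(caseObs$sample_id))
  nCtrlDet <- length(unique(ctrlObs$sample_id))

  mk <- function(ratio, capped, nPep, presence, quantifiable = TRUE)
    new("ProteinRatio", accession = acc, ratio = ratio, capped = capped,
        nPeptidesUsed = as.integer(nPep), presenceOnly = presence,
        quantifiable = quantifiable)

  if (nCaseDet == 0L && nCtrlDet == 0L)
    return(mk(NA_real_, FALSE, 0L, "NO", quantifiable = FALSE))
  if (nCtrlDet == 0L && nCaseDet >= config@minPresentReplicates)
    return(mk(config@ratioCeiling, TRUE, length(unique(caseObs$peptide_id)),
              "CASE_ONLY"))
  if (nCaseDet == 0L && nCtrlDet >= config@minPresentReplicates)
    return(mk(config@ratioFloor, TRUE, length(unique(ctrlObs$peptide_id)),
              "CONTROL_ONLY"))

  shared <- intersect(unique(caseObs$peptide_id), unique(ctrlObs$peptide_id))
  if (!length(shared))
    return(mk(NA_real_, FALSE, 0L, "NO", quantifiable = FALSE))
  pepRatios <- vapply(shared, function(p) {
    pairwisePeptideRatio(caseObs$intensity[caseObs$peptide_id == p],
                         ctrlObs$intensity[ctrlObs$peptide_id == p])
  }, numeric(1L))
  raw <- geomedian(pepRatios)
  clamped <- min(max(raw, config@ratioFloor), config@ratioCeiling)
  mk(clamped, clamped != raw, length(shared), "NO")
}

#' Per-sample protein abundance
#'
#' Sum of the observed peptide intensities of one protein in one sample;
#' `NA` when no peptide is observed there.
#'
#' @param peptides peptide data.frame restricted to one accession
#' @param sample a sample id
#' @return nonnegative scalar or `NA`
#' @export
sampleAbundance <- function(peptides, sample) {
  v <- peptides$intensity[peptides$sample_id == sample]
  if (!length(v)) NA_real_ else sum(v)
}

#' Protein-by-sample abundance matrix
#'
#' Sums peptide intensities per (accession, sample); unobserved cells are
#' `NA`. The workhorse behind group abundance aggregation and the purge.
#'
#' @param peptides peptide data.frame (any number of accessions)
#' @param samples sample ids defining the column set and order
#' @return numeric matrix, rows = accessions (sorted), columns = `samples`
#' @export
abundanceMatrix <- function(peptides, samples) {
  dt <- data.table::as.data.table(peptides)
  dt <- dt[sample_id %in% samples,
           .(abundance = sum(intensity)), by = .(accession, sample_id)]
  accs <- sort(unique(dt$accession))
  m <- matrix(NA_real_, nrow = length(accs), ncol = length(samples),
              dimnames = list(accs, samples))
  if (nrow(dt))
    m[cbind(match(dt$accession, accs), match(dt$sample_id, samples))] <-
      dt$abundance
  m
}

setMethod("show", "ProteinRatio", function(object) {
  cat(sprintf(
    "ProteinRatio %s: ratio=%s capped=%s peptides=%d presence=%s%s\n",
    object@accession,
    if (is.na(object@ratio)) "NA" else format(object@ratio, digits = 4),
    object@capped, object@nPeptidesUsed, object@presenceOnly,
    if (object@quantifiable) "" else " (not quantifiable)"))
})
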