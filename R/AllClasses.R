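## Central S4 classes. Validity methods enforce the design vocabulary so that
## downstream stages can trust group labels rather than column order.

#' Known genotype, arm and truth-class vocabularies
#'
#' @name vocabularies
#' @keywords internal
GENOTYPES <- c("WT", "TURNX")

#' @rdname vocabularies
#' @keywords internal
ARMS <- c("HA", "V5", "IG")

#' @rdname vocabularies
#' @keywords internal
TAGS <- c("HA", "V5")

#' @rdname vocabularies
#' @keywords internal
TRUTH_CLASSES <- c("BEAD_BACKGROUND", "TAG_CROSS_REACTIVE_HA",
                   "TAG_CROSS_REACTIVE_V5", "CORE_COMPLEX",
                   "HA_SPECIFIC", "V5_SPECIFIC", "ABSENT")

#' StudyDesign: the couple-based dual-tag IP design
#'
#' Describes the factorial layout of a tag-switch AP-MS study: couples of one
#' wild-type (WT) and one knock-in (TURNX) mouse, each contributing one IP
#' fraction per arm (anti-HA, anti-V5, isotype IgG) per replicate. The default
#' values give the 4 couples x 2 genotypes x 3 arms x 4 replicates = 96-sample
#' layout.
#'
#' @slot nCouples number of WT/TURNX couples
#' @slot replicatesPerArm IP replicates per mouse per arm
#' @slot arms ordered arm labels
#' @slot genotypes ordered genotype labels
#' @export
setClass("StudyDesign",
  representation(nCouples = "integer", replicatesPerArm = "integer",
                 arms = "character", genotypes = "character"),
  prototype(nCouples = 4L, replicatesPerArm = 4L, arms = ARMS,
            genotypes = GENOTYPES))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@nCouples) != 1L || is.na(object@nCouples) ||
      object@nCouples < 1L)
    msg <- c(msg, "nCouples must be a single positive integer")
  if (length(object@replicatesPerArm) != 1L || is.na(object@replicatesPerArm) ||
      object@replicatesPerArm < 1L)
    msg <- c(msg, "replicatesPerArm must be a single positive integer")
  if (!all(object@arms %in% ARMS) || anyDuplicated(object@arms))
    msg <- c(msg, sprintf("arms must be a subset of {%s} without duplicates",
                          paste(ARMS, collapse = ", ")))
  if (!identical(object@genotypes, GENOTYPES))
    msg <- c(msg, "genotypes must be c(\"WT\", \"TURNX\")")
  if (length(msg)) msg else TRUE
})

#' @param nCouples,replicatesPerArm,arms see slots
#' @rdname StudyDesign-class
#' @export
StudyDesign <- function(nCouples = 4L, replicatesPerArm = 4L, arms = ARMS) {
  new("StudyDesign", nCouples = as.integer(nCouples),
      replicatesPerArm = as.integer(replicatesPerArm),
      arms = toupper(arms), genotypes = GENOTYPES)
}

#' ContrastSpec: one tag's case group and its three negative controls
#'
#' The case group is always the knock-in genotype pulled down with the tag's
#' own arm; the controls are the same arm in WT animals (anti-tag antibody
#' background) and the isotype IgG arm in both genotypes (bead background).
#'
#' @slot tag "HA" or "V5"
#' @slot case character of length 2: genotype, arm
#' @slot controls 3 x 2 character matrix (columns genotype, arm)
#' @export
setClass("ContrastSpec",
  representation(tag = "character", case = "character", controls = "matrix"))

setValidity("ContrastSpec", function(object) {
  msg <- character()
  if (!(object@tag %in% TAGS)) msg <- c(msg, "tag must be HA or V5")
  if (!identical(unname(object@case), c("TURNX", object@tag)))
    msg <- c(msg, "case group must be (TURNX, <tag arm>)")
  if (!identical(dim(object@controls), c(3L, 2L)))
    msg <- c(msg, "controls must be a 3 x 2 matrix of (genotype, arm) pairs")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic peptide-level generator
#'
#' Class counts and intensity-model parameters for [simulateDataset()]. The
#' defaults spike a bead background, per-tag antibody cross-reactive binders,
#' a shared core complex and per-tag specific interactors into a log-normal
#' peptide intensity model with detection-floor censoring and a small uniform
#' dropout.
#'
#' @slot seed integer seed governing every draw
#' @slot classCounts named integer vector over the truth classes
#' @slot peptideLambda Poisson rate; peptides per protein = 1 + Pois(lambda)
#' @slot baselineLog2 grand mean log2 intensity of a detected peptide
#' @slot biologicalCV coefficient of variation of intensities (natural scale)
#' @slot foldEnrichment true case/control fold for enriched classes
#' @slot detectionFloorLog2 log2 intensity below which a value is censored
#' @slot stochasticDropout probability that an observation is dropped anyway
#' @slot proteinSdLog2 between-protein spread of baseline abundance (log2)
#' @slot peptideSdLog2 between-peptide ionization spread (log2)
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", classCounts = "integer",
                 peptideLambda = "numeric", baselineLog2 = "numeric",
                 biologicalCV = "numeric", foldEnrichment = "numeric",
                 detectionFloorLog2 = "numeric", stochasticDropout = "numeric",
                 proteinSdLog2 = "numeric", peptideSdLog2 = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cc <- object@classCounts
  if (!identical(sort(names(cc)), sort(TRUTH_CLASSES)))
    msg <- c(msg, "classCounts must be named by the seven truth classes")
  if (any(is.na(cc)) || any(cc < 0L))
    msg <- c(msg, "classCounts must be nonnegative")
  if (object@foldEnrichment <= 0)
    msg <- c(msg, "foldEnrichment must be positive")
  if (object@stochasticDropout < 0 || object@stochasticDropout > 1)
    msg <- c(msg, "stochasticDropout must lie in [0, 1]")
  if (object@biologicalCV <= 0) msg <- c(msg, "biologicalCV must be positive")
  if (length(msg)) msg else TRUE
})

#' @param seed,classCounts,peptideLambda,baselineLog2,biologicalCV see slots
#' @param foldEnrichment,detectionFloorLog2,stochasticDropout see slots
#' @param proteinSdLog2,peptideSdLog2 see slots
#' @rdname SimulationConfig-class
#' @export
SimulationConfig <- function(seed,
                             classCounts = c(BEAD_BACKGROUND = 500L,
                                             TAG_CROSS_REACTIVE_HA = 30L,
                                             TAG_CROSS_REACTIVE_V5 = 30L,
                                             CORE_COMPLEX = 11L,
                                             HA_SPECIFIC = 40L,
                                             V5_SPECIFIC = 40L,
                                             ABSENT = 0L),
                             peptideLambda = 3, baselineLog2 = 20,
                             biologicalCV = 0.25, foldEnrichment = 8,
                             detectionFloorLog2 = 16, stochasticDropout = 0.05,
                             proteinSdLog2 = 1.5, peptideSdLog2 = 1) {
  if (missing(seed))
    stop("an explicit seed is required for reproducible simulation")
  cc <- structure(integer(length(TRUTH_CLASSES)), names = TRUTH_CLASSES)
  cc[names(classCounts)] <- as.integer(classCounts)
  new("SimulationConfig", seed = as.integer(seed), classCounts = cc,
      peptideLambda = peptideLambda, baselineLog2 = baselineLog2,
      biologicalCV = biologicalCV, foldEnrichment = foldEnrichment,
      detectionFloorLog2 = detectionFloorLog2,
      stochasticDropout = stochasticDropout,
      proteinSdLog2 = proteinSdLog2, peptideSdLog2 = peptideSdLog2)
}

#' QuantConfig: saturation constants and presence threshold for quantification
#'
#' Ratio ceiling/floor and p-value floor reproduce the saturation conventions
#' of label-free AP-MS reports (capped ratio 100, floored p 1e-17);
#' `minPresentReplicates` guards presence-only calls against single-replicate
#' contamination.
#'
#' @slot ratioCeiling upper saturation for reported ratios
#' @slot ratioFloor lower saturation; must equal 1/ratioCeiling
#' @slot pFloor lower saturation for reported p-values
#' @slot minPresentReplicates detections required for a presence-only call
#' @slot logBase base of the log scale used throughout (2)
#' @export
setClass("QuantConfig",
  representation(ratioCeiling = "numeric", ratioFloor = "numeric",
                 pFloor = "numeric", minPresentReplicates = "integer",
                 logBase = "numeric"),
  prototype(ratioCeiling = 100, ratioFloor = 0.01, pFloor = 1e-17,
            minPresentReplicates = 3L, logBase = 2))

setValidity("QuantConfig", function(object) {
  msg <- character()
  if (abs(object@ratioFloor * object@ratioCeiling - 1) > 1e-12)
    msg <- c(msg, "ratioFloor must equal 1/ratioCeiling")
  if (object@pFloor <= 0 || object@pFloor >= 1)
    msg <- c(msg, "pFloor must lie in (0, 1)")
  if (object@minPresentReplicates < 1L)
    msg <- c(msg, "minPresentReplicates must be positive")
  if (length(msg)) msg else TRUE
})

#' @param ratioCeiling,pFloor,minPresentReplicates,logBase see slots
#' @rdname QuantConfig-class
#' @export
QuantConfig <- function(ratioCeiling = 100, pFloor = 1e-17,
                        minPresentReplicates = 3L, logBase = 2) {
  new("QuantConfig", ratioCeiling = ratioCeiling, ratioFloor = 1 / ratioCeiling,
      pFloor = pFloor, minPresentReplicates = as.integer(minPresentReplicates),
      logBase = logBase)
}

#' PurgeConfig: significance settings for the three-control purge
#'
#' @slot alpha per-comparison significance threshold
#' @slot minFold minimum case/control ratio (1 = enrichment direction only)
#' @slot replicateUnit "MOUSE_MEAN" (fractions averaged per mouse) or
#'   "FRACTION" (each fraction one observation)
#' @slot pFloor lower saturation for p-values
#' @export
setClass("PurgeConfig",
  representation(alpha = "numeric", minFold = "numeric",
                 replicateUnit = "character", pFloor = "numeric"),
  prototype(alpha = 0.05, minFold = 1, replicateUnit = "MOUSE_MEAN",
            pFloor = 1e-17))

setValidity("PurgeConfig", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (object@minFold < 1) msg <- c(msg, "minFold must be >= 1")
  if (!(object@replicateUnit %in% c("MOUSE_MEAN", "FRACTION")))
    msg <- c(msg, "replicateUnit must be MOUSE_MEAN or FRACTION")
  if (length(msg)) msg else TRUE
})

#' @param alpha,minFold,replicateUnit,pFloor see slots
#' @rdname PurgeConfig-class
#' @export
PurgeConfig <- function(alpha = 0.05, minFold = 1,
                        replicateUnit = c("MOUSE_MEAN", "FRACTION"),
                        pFloor = 1e-17) {
  new("PurgeConfig", alpha = alpha, minFold = minFold,
      replicateUnit = match.arg(replicateUnit), pFloor = pFloor)
}

#' ProteinRatio: one protein's pairwise-ratio rollup
#'
#' @slot accession protein accession
#' @slot ratio capped abundance ratio (NA when not quantifiable)
#' @slot capped TRUE iff saturation or a presence-only call was applied
#' @slot nPeptidesUsed peptides contributing to the rollup (or observed, for
#'   presence-only calls)
#' @slot presenceOnly "NO", "CASE_ONLY" or "CONTROL_ONLY"
#' @slot quantifiable FALSE when the protein is undetected on both sides or
#'   no peptide bridges the two groups
#' @export
setClass("ProteinRatio",
  representation(accession = "character", ratio = "numeric",
                 capped = "logical", nPeptidesUsed = "integer",
                 presenceOnly = "character", quantifiable = "logical"))

#' Interactome: the purged significant-protein list for one tag
#'
#' @slot tag "HA" or "V5"
#' @slot records data.frame of significant enrichment records (one row per
#'   retained protein, ordered by descending ratio then ascending p)
#' @slot provenance list: contrast snapshot, config snapshots, stage counts
#' @export
setClass("Interactome",
  representation(tag = "character", records = "data.frame",
                 provenance = "list"))

setValidity("Interactome", function(object) {
  msg <- character()
  if (!(object@tag %in% TAGS)) msg <- c(msg, "tag must be HA or V5")
  if (nrow(object@records) && anyDuplicated(object@records$accession))
    msg <- c(msg, "record accessions must be unique")
  if (length(msg)) msg else TRUE
})

#' AmpliconModel: genotyping amplicon and restriction-fragment anchors
#'
#' Holds the printed PCR/digest anchors of a knock-in genotyping assay: the
#' wild-type and knock-in amplicon sizes, the enzyme recognition site, and the
#' two digest fragments of the knock-in amplicon. Sizes of the Cre-recombined
#' ("turned") allele are derived from these anchors and the excised cassette
#' length, so they stay independent of the unprinted genomic flanks.
#'
#' @slot wtSize wild-type amplicon (bp)
#' @slot knockinSize unrecombined knock-in amplicon (bp)
#' @slot enzymeSite recognition sequence (TaqaI = TCGA)
#' @slot knockinFragments digest fragments of the knock-in amplicon (bp)
#' @export
setClass("AmpliconModel",
  representation(wtSize = "integer", knockinSize = "integer",
                 enzymeSite = "character", knockinFragments = "integer"),
  prototype(wtSize = 256L, knockinSize = 455L, enzymeSite = "TCGA",
            knockinFragments = c(317L, 138L)))

setValidity("AmpliconModel", function(object) {
  if (sum(object@knockinFragments) != object@knockinSize)
    "knockinFragments must sum to knockinSize" else TRUE
})

#' @param wtSize,knockinSize,enzymeSite,knockinFragments see slots
#' @rdname AmpliconModel-class
#' @export
AmpliconModel <- function(wtSize = 256L, knockinSize = 455L,
                          enzymeSite = "TCGA",
                          knockinFragments = c(317L, 138L)) {
  new("AmpliconModel", wtSize = as.integer(wtSize),
      knockinSize = as.integer(knockinSize), enzymeSite = enzymeSite,
      knockinFragments = as.integer(knockinFragments))
}

#' ComparisonReport: cross-tag interactome comparison
#'
#' @slot nA,nB list sizes
#' @slot nCoreA,nCoreB core-complex entries in each list
#' @slot nCommonNoncore proteins shared by both lists after removing the core
#' @slot specificityA,specificityB percent of each non-core list absent from
#'   the other (half-up, one decimal)
#' @slot commonAccessions the shared non-core accessions
#' @slot categories optional per-category count/percent table
#' @export
setClass("ComparisonReport",
  representation(nA = "integer", nB = "integer", nCoreA = "integer",
                 nCoreB = "integer", nCommonNoncore = "integer",
                 specificityA = "numeric", specificityB = "numeric",
                 commonAccessions = "character", categories = "data.frame"))
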