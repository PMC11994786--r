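## Cross-tag interactome comparison: overlap excluding the shared core
## complex, tag-specificity percentages, annotation-category tallies and the
## previously-reported fraction. All percentages go through one half-up
## rounding routine so every report rounds identically.

#' Round half-up to a fixed number of decimals
#'
#' `round()` in R rounds half to even; published percentage tallies use
#' half-up, so every percentage in this package goes through this routine.
#'
#' @param x numeric
#' @param digits decimals to keep
#' @return rounded numeric
#' @examples
#' roundHalfUp(9.375, 1)  # 9.4
#' @export
roundHalfUp <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Read a two-column annotation map (accession, category)
#'
#' Multiple rows per accession are allowed (multi-category membership);
#' lookups of unknown accessions return the empty set.
#'
#' @param path TSV path with header `accession<TAB>category`
#' @return data.frame with columns accession, category
#' @export
readAnnotationMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (!all(c("accession", "category") %in% names(df)))
    stop("annotation map needs columns accession, category")
  if (any(!nzchar(df$category))) stop("empty category string in annotation map")
  df[c("accession", "category")]
}

#' Categories of one accession
#' @param ann annotation data.frame (accession, category)
#' @param accession one accession
#' @return character vector (possibly empty)
#' @export
annotationLookup <- function(ann, accession) {
  unique(ann$category[ann$accession == accession])
}

## optional isoform merging: collapse accessions to gene symbols so that two
## isoforms of one gene count once. `symbolMap` is a named character
## (accession -> symbol); accessions without a symbol stay verbatim.
mergeBySymbol <- function(accs, symbolMap) {
  if (is.null(symbolMap)) return(unique(accs))
  mapped <- symbolMap[accs]
  mapped[is.na(mapped)] <- accs[is.na(mapped)]
  unique(unname(mapped))
}

#' Compare two interactomes excluding a shared core
#'
#' Computes the overlap of two per-tag interactor lists after removing the
#' core-complex members from both, and the tag-specificity percentages
#' `100 * (1 - common / (n - n_core))` (half-up, one decimal). Accessions are
#' compared verbatim unless `mergeIsoforms = TRUE`, in which case accessions
#' are first collapsed via `symbolMap` so isoforms of one gene count once.
#'
#' @param A,B [Interactome] objects or plain accession character vectors
#' @param core accessions (or symbols, when merging) of the core complex
#' @param mergeIsoforms collapse isoforms to gene symbols first
#' @param symbolMap named character, accession -> gene symbol
#' @return a [ComparisonReport]
#' @export
interactomeOverlap <- function(A, B, core = character(),
                               mergeIsoforms = FALSE, symbolMap = NULL) {
  accA <- if (is(A, "Interactome")) accessions(A) else as.character(A)
  accB <- if (is(B, "Interactome")) accessions(B) else as.character(B)
  if (anyDuplicated(accA) || anyDuplicated(accB))
    stop("accessions must be unique within each interactome")
  if (mergeIsoforms) {
    accA <- mergeBySymbol(accA, symbolMap)
    accB <- mergeBySymbol(accB, symbolMap)
  }
  coreA <- intersect(accA, core); coreB <- intersect(accB, core)
  nonA <- setdiff(accA, core); nonB <- setdiff(accB, core)
  common <- sort(intersect(nonA, nonB))
  spec <- function(n, nCore, nCommon) {
    denom <- n - nCore
    if (denom == 0L) return(NA_real_)
    roundHalfUp(100 * (1 - nCommon / denom), 1L)
  }
  new("ComparisonReport",
      nA = length(accA), nB = length(accB),
      nCoreA = length(coreA), nCoreB = length(coreB),
      nCommonNoncore = length(common),
      specificityA = spec(length(accA), length(coreA), length(common)),
      specificityB = spec(length(accB), length(coreB), length(common)),
      commonAccessions = common,
      categories = data.frame())
}

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf(
    paste0("ComparisonReport: A n=%d (core %d), B n=%d (core %d); ",
           "common non-core %d; specificity A %.1f%%, B %.1f%%\n"),
    object@nA, object@nCoreA, object@nB, object@nCoreB,
    object@nCommonNoncore, object@specificityA, object@specificityB))
  if (nrow(object@categories)) {
    cat("Per-category tallies:\n")
    print(object@categories)
  }
})

#' Count and percentage of a category within one interactome
#'
#' Counts the members of `X` outside the core that carry `category`; the
#' percentage denominator is the list size minus its core members (half-up,
#' one decimal). A zero denominator yields a missing percentage.
#'
#' @param X an [Interactome] or accession vector
#' @param ann annotation data.frame (accession, category)
#' @param category category string
#' @param core core-complex accessions to exclude
#' @return list(count, percentage)
#' @export
categoryFraction <- function(X, ann, category, core = character()) {
  stopifnot(nzchar(category))
  accs <- if (is(X, "Interactome")) accessions(X) else as.character(X)
  n <- length(accs)
  nonCore <- setdiff(accs, core)
  inCat <- ann$accession[ann$category == category]
  count <- length(intersect(nonCore, inCat))
  denom <- n - length(intersect(accs, core))
  pct <- if (denom == 0L) NA_real_ else roundHalfUp(100 * count / denom, 1L)
  list(count = count, percentage = pct)
}

#' Size of a category's union across two interactomes
#'
#' `|cat(A) u cat(B)|` after excluding the core; inclusion-exclusion holds
#' exactly by construction.
#'
#' @inheritParams categoryFraction
#' @param A,B [Interactome] objects or accession vectors
#' @return integer count
#' @export
categoryUnion <- function(A, B, ann, category, core = character()) {
  stopifnot(nzchar(category))
  accA <- if (is(A, "Interactome")) accessions(A) else as.character(A)
  accB <- if (is(B, "Interactome")) accessions(B) else as.character(B)
  inCat <- ann$accession[ann$category == category]
  catA <- intersect(setdiff(accA, core), inCat)
  catB <- intersect(setdiff(accB, core), inCat)
  length(union(catA, catB))
}

#' Fraction of an interactome found in a reference interactor list
#'
#' Percentage of the list's entries (core included) present in the
#' user-supplied reference set, rounded half-up to one decimal. The package
#' ships no interaction database; the reference is an input.
#'
#' @param X an [Interactome] or accession vector
#' @param reference accession character vector
#' @return list(count, percentage)
#' @export
knownFraction <- function(X, reference) {
  accs <- if (is(X, "Interactome")) accessions(X) else as.character(X)
  if (!length(reference)) {
    warning("empty reference list; known fraction is 0")
    return(list(count = 0L, percentage = 0))
  }
  if (!length(accs)) return(list(count = 0L, percentage = NA_real_))
  count <- length(intersect(accs, reference))
  list(count = count,
       percentage = roundHalfUp(100 * count / length(accs), 1L))
}

#' Serialize a ComparisonReport
#'
#' @param report a [ComparisonReport]
#' @return a plain list suitable for JSON serialization
#' @export
comparisonAsList <- function(report) {
  list(n_A = report@nA, n_B = report@nB,
       n_core_A = report@nCoreA, n_core_B = report@nCoreB,
       n_common_noncore = report@nCommonNoncore,
       specificity_A = report@specificityA,
       specificity_B = report@specificityB,
       common_accessions = report@commonAccessions,
       categories = if (nrow(report@categories)) report@categories else NULL)
}
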