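## Study design: sample sheet generation, validation, I/O and the two
## tag contrasts with their three negative-control groups.

SHEET_FIELDS <- c("sample_id", "mouse_id", "couple_id", "genotype", "arm",
                  "replicate")

#' @rdname accessors
#' @export
setMethod("nCouples", "StudyDesign", function(x) x@nCouples)

#' @rdname accessors
#' @export
setMethod("replicatesPerArm", "StudyDesign", function(x) x@replicatesPerArm)

#' @rdname accessors
#' @export
setMethod("arms", "StudyDesign", function(x) x@arms)

#' @rdname accessors
#' @export
setMethod("genotypes", "StudyDesign", function(x) x@genotypes)

#' @rdname accessors
#' @export
setMethod("nSamples", "StudyDesign", function(x)
  x@nCouples * length(x@genotypes) * length(x@arms) * x@replicatesPerArm)

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", nCouples(object), "couple(s) x",
      length(genotypes(object)), "genotypes x", length(arms(object)),
      "IP arms x", replicatesPerArm(object), "replicates =",
      nSamples(object), "samples\n")
})

#' @rdname accessors
#' @export
setMethod("tagOf", "ContrastSpec", function(x) x@tag)

#' @rdname accessors
#' @export
setMethod("caseGroup", "ContrastSpec", function(x) x@case)

#' @rdname accessors
#' @export
setMethod("controlGroups", "ContrastSpec", function(x) x@controls)

setMethod("show", "ContrastSpec", function(object) {
  ctrl <- apply(object@controls, 1L, paste, collapse = ",")
  cat(sprintf("ContrastSpec %s: case (%s) vs controls [%s]\n", object@tag,
              paste(object@case, collapse = ","),
              paste(sprintf("(%s)", ctrl), collapse = " ")))
})

#' Generate the canonical sample sheet of a design
#'
#' Enumerates every IP fraction of the design: couples C1..Cn, each with one
#' WT and one TURNX mouse, each mouse pulled down with every arm in
#' `replicatesPerArm` replicates. Sample ids are deterministic so simulated
#' datasets are diffable.
#'
#' @param design a [StudyDesign]
#' @return data.frame with columns sample_id, mouse_id, couple_id, genotype,
#'   arm, replicate
#' @examples
#' nrow(sampleSheet(StudyDesign()))  # 96
#' @export
sampleSheet <- function(design) {
  stopifnot(is(design, "StudyDesign"))
  grid <- expand.grid(replicate = seq_len(replicatesPerArm(design)),
                      arm = arms(design), genotype = genotypes(design),
                      couple = seq_len(nCouples(design)),
                      stringsAsFactors = FALSE)
  mouse <- sprintf("M%d_%s", grid$couple, grid$genotype)
  data.frame(
    sample_id = sprintf("%s_%s_r%d", mouse, grid$arm, grid$replicate),
    mouse_id = mouse,
    couple_id = sprintf("C%d", grid$couple),
    genotype = grid$genotype,
    arm = grid$arm,
    replicate = as.integer(grid$replicate),
    stringsAsFactors = FALSE)
}

validateSampleSheet <- function(df, origin = "sample sheet") {
  missing <- setdiff(SHEET_FIELDS, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", origin,
                 paste(missing, collapse = ", ")))
  df <- df[SHEET_FIELDS]
  df$genotype <- toupper(trimws(df$genotype))
  df$arm <- toupper(trimws(df$arm))
  badg <- which(!(df$genotype %in% GENOTYPES))
  if (length(badg))
    stop(sprintf("unknown genotype token \"%s\" in %s row %d",
                 df$genotype[badg[1L]], origin, badg[1L]))
  bada <- which(!(df$arm %in% ARMS))
  if (length(bada))
    stop(sprintf("unknown arm token \"%s\" in %s row %d",
                 df$arm[bada[1L]], origin, bada[1L]))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop(sprintf("duplicate sample_id \"%s\" in %s", dup[1L], origin))
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate)) || any(df$replicate < 1L))
    stop(sprintf("replicate must be a positive integer in %s", origin))
  rownames(df) <- NULL
  df
}

#' Read and validate a TSV sample sheet
#'
#' The sheet is tab-separated with a header naming the six fields
#' (sample_id, mouse_id, couple_id, genotype, arm, replicate); lines starting
#' with `#` are ignored and enum fields are case-normalized.
#'
#' @param path file path
#' @return validated data.frame of sample records
#' @export
loadSampleSheet <- function(path) {
  if (!file.exists(path)) stop(sprintf("sample sheet not found: %s", path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  validateSampleSheet(df, origin = basename(path))
}

#' Write a sample sheet as TSV
#'
#' @param sheet a validated sample-sheet data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSampleSheet <- function(sheet, path) {
  sheet <- validateSampleSheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select the sample ids of one (genotype, arm) group
#'
#' @param sheet sample-sheet data.frame
#' @param genotype "WT" or "TURNX"
#' @param arm "HA", "V5" or "IG"
#' @return character vector of sample ids (possibly empty)
#' @export
samplesInGroup <- function(sheet, genotype, arm) {
  sheet$sample_id[sheet$genotype == toupper(genotype) &
                  sheet$arm == toupper(arm)]
}

#' The two tag contrasts with their three negative-control groups
#'
#' For each tag the case group is the knock-in genotype pulled down with that
#' tag's arm; the controls are (i) the same arm in WT animals, which carries
#' the anti-tag antibody's cross-reactive background, and (ii)-(iii) the
#' isotype IgG arm in knock-in and WT animals, which carries the bead
#' background.
#'
#' @return named list of two [ContrastSpec] objects ("HA", "V5")
#' @examples
#' controlGroups(defaultContrasts()$HA)
#' @export
defaultContrasts <- function() {
  mk <- function(tag) {
    new("ContrastSpec", tag = tag, case = c("TURNX", tag),
        controls = matrix(c("WT", tag, "TURNX", "IG", "WT", "IG"),
                          ncol = 2L, byrow = TRUE,
                          dimnames = list(NULL, c("genotype", "arm"))))
  }
  list(HA = mk("HA"), V5 = mk("V5"))
}
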