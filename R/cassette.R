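## In-silico model of the loxP-3xHA-loxP-V5 donor cassette: lox detection,
## Cre excision, epitope translation, and the genotyping amplicon and
## restriction-fragment arithmetic. All sequence work goes through
## Biostrings; coordinates are 1-based inclusive.

LOX_ARM5 <- "ATAACTTCGTATA"
LOX_ARM3 <- "TATACGAAGTTAT"
LOX_LENGTH <- 34L

asDNA <- function(seq) {
  if (is(seq, "DNAString")) return(seq)
  s <- toupper(gsub("\\s", "", as.character(seq)))
  if (!nzchar(s)) stop("empty DNA sequence")
  if (grepl("[^ACGT]", s)) stop("sequence must contain only A, C, G, T")
  Biostrings::DNAString(s)
}

#' The tag-switch donor oligo shipped with the package
#'
#' Returns the 292-nt single-strand oligo donor (ssODN) of the switchable
#' loxP-3xHA-loxP-V5 knock-in cassette: two homology arms flanking a lox
#' site, three tandem HA epitope repeats with a stop codon, a second lox
#' site, a two-base frame linker and the V5 epitope with its stop codon.
#'
#' @return a [Biostrings::DNAString] of length 292
#' @examples
#' length(donorCassette())  # 292
#' @export
donorCassette <- function() {
  fa <- system.file("extdata", "tag_switch_donor_ssodn.fa",
                    package = "RITEproteomics", mustWork = TRUE)
  Biostrings::readDNAStringSet(fa)[[1L]]
}

#' Find lox sites by arm pattern
#'
#' Scans for `arm5 + any 8 bases + arm3` (13 + 8 + 13 = 34 nt). The two
#' 13-bp arms are mutual reverse complements, so the same pattern detects a
#' site regardless of its biological orientation; each position is reported
#' once, labelled FWD for the strand on which the scan reads arm5 -> arm3,
#' with the 8-bp spacer exposed (spacer asymmetry is what defines lox
#' directionality, and [creExcise()] decides direct-vs-inverted from the
#' spacers).
#'
#' @param seq DNA sequence (character or `DNAString`)
#' @return data.frame with columns start, end, orientation, spacer, arm5,
#'   arm3; zero rows when nothing matches
#' @examples
#' findLoxSites(donorCassette())$start  # 51 172
#' @export
findLoxSites <- function(seq) {
  seq <- asDNA(seq)
  pattern <- Biostrings::DNAString(paste0(LOX_ARM5, strrep("N", 8L),
                                          LOX_ARM3))
  hits <- Biostrings::matchPattern(pattern, seq, fixed = FALSE)
  starts <- sort(Biostrings::start(hits))
  if (!length(starts))
    return(data.frame(start = integer(), end = integer(),
                      orientation = character(), spacer = character(),
                      arm5 = character(), arm3 = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    start = starts, end = starts + LOX_LENGTH - 1L,
    orientation = "FWD",
    spacer = vapply(starts, function(s)
      as.character(Biostrings::subseq(seq, s + 13L, s + 20L)), character(1L)),
    arm5 = LOX_ARM5, arm3 = LOX_ARM3, stringsAsFactors = FALSE)
}

#' Excise the segment between two direct-repeat lox sites
#'
#' Removes the sequence from the start of the first site to the base before
#' the start of the second, leaving exactly one lox copy — the product of Cre
#' recombination between direct repeats. Direct vs inverted repeat is decided
#' from the spacers: identical spacers recombine by excision; reverse-
#' complementary spacers form an inverted pair (inversion, not supported);
#' any other spacer pair is incompatible.
#'
#' @param seq DNA sequence (character or `DNAString`)
#' @param sites two-row data.frame from [findLoxSites()]
#' @return the excised `DNAString`; its length is the input length minus the
#'   start-to-start distance of the two sites
#' @export
creExcise <- function(seq, sites) {
  seq <- asDNA(seq)
  if (!is.data.frame(sites) || nrow(sites) != 2L)
    stop("creExcise requires exactly two lox sites")
  sites <- sites[order(sites$start), , drop = FALSE]
  s1 <- sites$start[1L]; s2 <- sites$start[2L]
  if (s2 < s1 + LOX_LENGTH) stop("overlapping lox sites")
  sp1 <- sites$spacer[1L]; sp2 <- sites$spacer[2L]
  rc <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  if (!identical(sp1, sp2)) {
    if (identical(sp1, rc(sp2)))
      stop("inverted lox pair: inversion not supported")
    stop("incompatible lox spacers: ", sp1, " vs ", sp2)
  }
  out <- Biostrings::xscat(Biostrings::subseq(seq, 1L, s1 - 1L),
                           Biostrings::subseq(seq, s2, length(seq)))
  stopifnot(length(out) == length(seq) - (s2 - s1))
  out
}

#' Translate from a frame offset up to the first stop codon
#'
#' Standard genetic code; translation starts at `frameOffset + 1` and stops
#' at (and excludes) the first stop codon. If the reading frame runs off the
#' end without a stop, the translated prefix is returned with `complete =
#' FALSE` (an open reading frame).
#'
#' @param seq DNA sequence (character or `DNAString`)
#' @param frameOffset 0, 1 or 2
#' @return list(peptide = character, complete = logical)
#' @examples
#' translateTag("ATGTAA")$peptide  # "M"
#' @export
translateTag <- function(seq, frameOffset = 0L) {
  stopifnot(frameOffset %in% 0:2)
  seq <- asDNA(seq)
  sub <- Biostrings::subseq(seq, frameOffset + 1L, length(seq))
  n <- (length(sub) %/% 3L) * 3L
  if (n == 0L) return(list(peptide = "", complete = FALSE))
  aa <- as.character(Biostrings::translate(Biostrings::subseq(sub, 1L, n),
                                           no.init.codon = TRUE))
  stop <- regexpr("*", aa, fixed = TRUE)
  if (stop == -1L) list(peptide = aa, complete = FALSE)
  else list(peptide = substr(aa, 1L, stop - 1L), complete = TRUE)
}

#' Amplicon size of the Cre-recombined ("turned") allele
#'
#' The recombined amplicon is the knock-in amplicon minus the excised
#' cassette length — flank-independent arithmetic, so it needs no primer
#' positions.
#'
#' @param model an [AmpliconModel]
#' @param excised excised length in bp (start-to-start lox distance)
#' @return amplicon size in bp
#' @examples
#' turnedAmpliconSize(AmpliconModel(), 121)  # 334
#' @export
turnedAmpliconSize <- function(model = AmpliconModel(), excised) {
  stopifnot(is(model, "AmpliconModel"))
  validObject(model)
  if (excised >= model@knockinSize)
    stop("excised length must be smaller than the knock-in amplicon")
  out <- model@knockinSize - as.integer(excised)
  if (out <= 0L) stop("nonpositive turned amplicon size")
  out
}

#' Digest fragments of the turned amplicon
#'
#' The excised cassette lies inside the larger knock-in digest fragment, so
#' only that fragment shrinks; the pair sums to the turned amplicon size.
#'
#' @inheritParams turnedAmpliconSize
#' @return integer vector of two fragment sizes (bp), larger first
#' @export
turnedFragments <- function(model = AmpliconModel(), excised) {
  stopifnot(is(model, "AmpliconModel"))
  big <- max(model@knockinFragments)
  small <- min(model@knockinFragments)
  turned <- big - as.integer(excised)
  if (turned <= 0L) stop("excised length exceeds the cassette-bearing fragment")
  c(turned, small)
}

#' Restriction digest as fragment lengths
#'
#' Cuts at every occurrence of the recognition sequence; the cut position
#' convention is after `cutAfter` bases of the site (TaqaI: T^CGA, cutAfter =
#' 1). Fragment lengths always sum to the input length.
#'
#' @param seq DNA sequence (character or `DNAString`)
#' @param recognition recognition sequence (>= 4 bases)
#' @param cutAfter bases of the site upstream of the cut
#' @return integer vector of fragment lengths
#' @examples
#' digestFragments(donorCassette(), "TCGA")  # 239 53
#' @export
digestFragments <- function(seq, recognition = "TCGA", cutAfter = 1L) {
  seq <- asDNA(seq)
  if (nchar(recognition) < 4L) stop("recognition site must be >= 4 bases")
  hits <- Biostrings::matchPattern(Biostrings::DNAString(recognition), seq)
  cuts <- sort(Biostrings::start(hits)) + as.integer(cutAfter) - 1L
  cuts <- cuts[cuts >= 1L & cuts < length(seq)]
  bounds <- c(0L, cuts, length(seq))
  frags <- diff(bounds)
  stopifnot(sum(frags) == length(seq))
  frags
}

#' Full cassette report: sites, excision, translation, genotyping arithmetic
#'
#' Convenience wrapper tying the cassette operations together for one donor
#' sequence: lox sites, excised length, recombined sequence, both tag
#' peptides translated from the first lox start (the lox plus the two-base
#' linker is 36 nt = 12 codons, so the downstream tag stays in frame), the
#' turned amplicon and digest-fragment arithmetic, and the donor's own
#' digest.
#'
#' @param seq DNA sequence (defaults to the shipped donor oligo)
#' @param model an [AmpliconModel]
#' @return named list of results
#' @export
cassetteReport <- function(seq = donorCassette(), model = AmpliconModel()) {
  seq <- asDNA(seq)
  sites <- findLoxSites(seq)
  if (nrow(sites) != 2L)
    stop(sprintf("expected 2 lox sites in the cassette, found %d",
                 nrow(sites)))
  excised <- sites$start[2L] - sites$start[1L]
  rec <- creExcise(seq, sites)
  fromLox <- function(s) Biostrings::subseq(s, sites$start[1L], length(s))
  list(
    length = length(seq),
    sites = sites,
    excised_length = excised,
    recombined_length = length(rec),
    tag_peptide_unrecombined = translateTag(fromLox(seq)),
    tag_peptide_recombined = translateTag(fromLox(rec)),
    wt_amplicon = model@wtSize,
    knockin_amplicon = model@knockinSize,
    knockin_fragments = model@knockinFragments,
    turned_amplicon = turnedAmpliconSize(model, excised),
    turned_fragments = turnedFragments(model, excised),
    donor_digest = digestFragments(seq, model@enzymeSite))
}
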