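## fixture lists mirroring the published headline counts: 278 HA entries with
## 11 core members, 202 V5 entries with 10 core, 17 common non-core proteins
printedCountLists <- function() {
  core <- sprintf("CORE%02d", 1:11)
  common <- sprintf("COM%02d", 1:17)
  A <- c(core[1:11], common, sprintf("A%03d", seq_len(278 - 11 - 17)))
  B <- c(core[1:10], common, sprintf("B%03d", seq_len(202 - 10 - 17)))
  list(A = A, B = B, core = core, common = common)
}

test_that("tag specificity reproduces the printed-count arithmetic", {
  fx <- printedCountLists()
  rep <- interactomeOverlap(fx$A, fx$B, core = fx$core)
  expect_equal(rep@nA, 278L); expect_equal(rep@nB, 202L)
  expect_equal(rep@nCoreA, 11L); expect_equal(rep@nCoreB, 10L)
  expect_equal(rep@nCommonNoncore, 17L)
  expect_equal(rep@specificityA, 93.6)
  expect_equal(rep@specificityB, 91.1)
  expect_gte(min(rep@specificityA, rep@specificityB), 90)
})

test_that("overlap handles the degenerate identity and disjoint cases", {
  A <- sprintf("P%02d", 1:20)
  same <- interactomeOverlap(A, A, core = character())
  expect_equal(same@nCommonNoncore, 20L)
  expect_equal(same@specificityA, 0)
  expect_equal(same@specificityB, 0)
  dis <- interactomeOverlap(A, sprintf("Q%02d", 1:10), core = character())
  expect_equal(dis@specificityA, 100)
  expect_equal(dis@specificityB, 100)
  ## symmetry of the common count
  fx <- printedCountLists()
  expect_equal(interactomeOverlap(fx$B, fx$A, core = fx$core)@nCommonNoncore,
               interactomeOverlap(fx$A, fx$B, core = fx$core)@nCommonNoncore)
  expect_error(interactomeOverlap(c("P1", "P1"), A), "unique")
})

test_that("category fractions reproduce the mitochondrial tallies", {
  fx <- printedCountLists()
  mitoA <- c(fx$common[1:2], fx$A[!(fx$A %in% c(fx$core, fx$common))][1:15])
  mitoB <- c(fx$common[1:2], fx$B[!(fx$B %in% c(fx$core, fx$common))][1:16])
  ann <- data.frame(accession = unique(c(mitoA, mitoB)),
                    category = "Mitochondrial", stringsAsFactors = FALSE)
  fa <- categoryFraction(fx$A, ann, "Mitochondrial", fx$core)
  fb <- categoryFraction(fx$B, ann, "Mitochondrial", fx$core)
  expect_equal(fa$count, 17L); expect_equal(fa$percentage, 6.4)  # 17/267
  expect_equal(fb$count, 18L); expect_equal(fb$percentage, 9.4)  # 18/192
  ## union with two shared members: 17 + 18 - 2 = 33
  expect_equal(categoryUnion(fx$A, fx$B, ann, "Mitochondrial", fx$core), 33L)
})

test_that("category union obeys inclusion-exclusion exactly", {
  ann <- data.frame(accession = c("P1", "P2", "P3", "Q1", "Q2", "Q3", "Q4"),
                    category = "cat", stringsAsFactors = FALSE)
  A <- c("P1", "P2", "P3"); B <- c("Q1", "Q2", "Q3", "Q4")
  expect_equal(categoryUnion(A, B, ann, "cat"), 7L)
  expect_equal(categoryUnion(A, A, ann, "cat"), 3L)
  withBoth <- c(A, "Q1")
  cA <- categoryFraction(withBoth, ann, "cat")$count
  cB <- categoryFraction(B, ann, "cat")$count
  inter <- length(intersect(intersect(withBoth, B), ann$accession))
  expect_equal(categoryUnion(withBoth, B, ann, "cat"), cA + cB - inter)
  ## zero members and empty denominators
  expect_equal(categoryFraction(A, ann, "other")$count, 0L)
  expect_equal(categoryFraction(A, ann, "other")$percentage, 0)
  expect_true(is.na(categoryFraction(A, ann, "cat", core = A)$percentage))
})

test_that("known-interactor fractions round half-up to one decimal", {
  X <- sprintf("P%02d", 1:10)
  expect_equal(knownFraction(X, X[1:4])$percentage, 40.0)
  expect_equal(knownFraction(X, c(X, "extra"))$percentage, 100.0)
  expect_warning(kf <- knownFraction(X, character()), "empty reference")
  expect_equal(kf$count, 0L)
  expect_true(is.na(knownFraction(character(), X)$percentage))
  ## half-up rounding is shared and exact at the .x5 boundary
  expect_equal(roundHalfUp(9.375, 1), 9.4)
  expect_equal(roundHalfUp(93.65, 1), 93.7)
  expect_equal(roundHalfUp(0.05, 1), 0.1)
  expect_equal(roundHalfUp(-0.05, 1), -0.1)
})

test_that("isoform merging collapses the two Wdr26 accessions in the core", {
  ha <- ctlhTableRows("HA")   # 12 accessions, 11 gene symbols
  v5 <- ctlhTableRows("V5")   # 11 accessions, 10 gene symbols
  symbolMap <- stats::setNames(c(ha$symbol, v5$symbol),
                               c(ha$accession, v5$accession))
  coreSymbols <- unique(ha$symbol)
  repMerged <- interactomeOverlap(ha$accession, v5$accession,
                                  core = coreSymbols, mergeIsoforms = TRUE,
                                  symbolMap = symbolMap)
  expect_equal(repMerged@nCoreA, 11L)
  expect_equal(repMerged@nCoreB, 10L)
  expect_equal(repMerged@nCommonNoncore, 0L)
  ## verbatim comparison keeps both isoform accessions
  repRaw <- interactomeOverlap(ha$accession, v5$accession,
                               core = ha$accession)
  expect_equal(repRaw@nCoreA, 12L)
})
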