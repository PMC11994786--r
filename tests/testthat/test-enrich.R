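test_that("mouse-mean aggregation averages fractions on the log2 scale", {
  sheet <- sampleSheet(StudyDesign(nCouples = 1L, replicatesPerArm = 4L))
  ids <- samplesInGroup(sheet, "TURNX", "HA")
  tab <- makePeptides(list(P1 = list(
    p1 = stats::setNames(2^c(10, 10, 12, 12), ids))))
  m <- groupAbundances(tab, sheet, c("TURNX", "HA"), "MOUSE_MEAN")
  expect_equal(ncol(m), 1L)       # one mouse
  expect_equal(unname(m["P1", ]), 11)
  f <- groupAbundances(tab, sheet, c("TURNX", "HA"), "FRACTION")
  expect_equal(sort(unname(f["P1", ])), c(10, 10, 12, 12))
})

test_that("each group yields one value per mouse on the study design", {
  sim <- simulateDataset(StudyDesign(), smallSimConfig(seed = 11))
  m <- groupAbundances(sim$peptides, sim$samples, c("WT", "IG"),
                       "MOUSE_MEAN")
  expect_equal(ncol(m), 4L)  # 4 couples -> 4 WT mice
  ## a protein absent from every fraction of a mouse contributes NA
  sheet <- sampleSheet(StudyDesign(nCouples = 2L, replicatesPerArm = 2L))
  ids <- samplesInGroup(sheet, "WT", "IG")
  tab <- makePeptides(list(P1 = list(
    p1 = stats::setNames(c(100, 120), ids[1:2]))))  # mouse 1 only
  g <- groupAbundances(tab, sheet, c("WT", "IG"), "MOUSE_MEAN")
  expect_equal(sum(is.na(g["P1", ])), 1L)
  expect_error(groupAbundances(tab, sheet, c("TURNX", "XX")), "no samples")
})

test_that("welch p-values match the closed-form oracle and conventions", {
  ## identical constant groups
  expect_equal(welchP(c(5, 5, 5, 5), c(5, 5, 5, 5)), 1)
  ## constant but different
  expect_equal(welchP(c(5, 5, 5), c(3, 3, 3)), 1e-17)
  ## presence-only: quantified in 4/4 case units, absent from controls
  expect_equal(welchP(c(20.1, 20.3, 19.9, 20.0), c(NA, NA, NA, NA)), 1e-17)
  ## below the presence threshold it is untestable instead
  expect_true(is.na(welchP(c(20.1, 20.3), rep(NA_real_, 4L))))
  expect_true(is.na(welchP(c(20.1, 20.3, 19.9), 5)))

  ## fixed 4-vs-4 input against stats::t.test (independent Welch oracle)
  x <- c(5.0, 5.2, 4.8, 5.1); y <- c(3.0, 3.1, 2.9, 3.0)
  oracle <- stats::t.test(x, y, var.equal = FALSE)$p.value
  expect_equal(welchP(x, y), oracle, tolerance = 1e-10)

  ## random inputs against t.test, including unequal sizes
  set.seed(1)
  for (i in 1:50) {
    a <- stats::rnorm(sample(2:6, 1L), 0, stats::runif(1, 0.5, 2))
    b <- stats::rnorm(sample(2:6, 1L), stats::runif(1, -1, 1),
                      stats::runif(1, 0.5, 2))
    expect_equal(welchP(a, b),
                 stats::t.test(a, b, var.equal = FALSE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("the purge retains enriched, excludes cross-reactive and depleted", {
  baseline <- function(genotype, arm) 20
  tab <- toyPeptides(list(
    ## enriched only in the case group: retained
    ENR = function(g, a) if (g == "TURNX" && a == "HA") 23 else 20,
    ## enriched on the HA arm in BOTH genotypes (antibody cross-reactive):
    ## passes both Ig comparisons, fails the same-arm WT one -> excluded
    XRE = function(g, a) if (a == "HA") 23 else 20,
    ## depleted protein with clear significance: excluded by direction
    DEP = function(g, a) if (g == "TURNX" && a == "HA") 18.7 else 20,
    ## flat background: excluded by p
    BKG = baseline))
  sheet <- toySheet()
  ia <- runPurge(tab, sheet, defaultContrasts()$HA)
  expect_identical(accessions(ia), "ENR")
  rec <- records(ia)
  expect_true(all(rec$p_reported <= 0.05))
  expect_true(rec$ratio > 1)

  ## the cross-reactive protein fails specifically the same-arm WT control
  tested <- provenance(ia)$tested
  xre <- tested[tested$accession == "XRE", ]
  expect_lt(xre$p_vs_TURNX_IG, 0.05)
  expect_lt(xre$p_vs_WT_IG, 0.05)
  expect_gt(xre$p_vs_WT_HA, 0.05)

  dep <- tested[tested$accession == "DEP", ]
  expect_lt(dep$ratio, 1)  # excluded by the direction rule at any alpha
  expect_true(all(dep[c("p_vs_WT_HA", "p_vs_TURNX_IG", "p_vs_WT_IG")] <
                  0.05))
})

test_that("significance requires every control comparison to pass", {
  ## craft all eight pass/fail combinations of the three control groups
  sheet <- toySheet()
  combos <- expand.grid(c1 = c(TRUE, FALSE), c2 = c(TRUE, FALSE),
                        c3 = c(TRUE, FALSE))
  specs <- list()
  for (i in seq_len(nrow(combos))) {
    pass <- unlist(combos[i, ])
    ## control group mean 20 where the comparison should pass (case at 23),
    ## 23 where it should fail (no difference)
    specs[[sprintf("PR%02d", i)]] <- local({
      pass <- pass
      function(g, a) {
        if (g == "TURNX" && a == "HA") return(23)
        if (g == "WT" && a == "HA") return(if (pass[1L]) 20 else 23)
        if (g == "TURNX" && a == "IG") return(if (pass[2L]) 20 else 23)
        if (g == "WT" && a == "IG") return(if (pass[3L]) 20 else 23)
        NA
      }
    })
  }
  ia <- runPurge(toyPeptides(specs), sheet, defaultContrasts()$HA)
  allPass <- sprintf("PR%02d", which(rowSums(combos) == 3L))
  expect_setequal(accessions(ia), allPass)
})

test_that("alpha and fold thresholds move the interactome monotonically", {
  sim <- simulateDataset(StudyDesign(), smallSimConfig(seed = 21))
  ct <- defaultContrasts()$HA
  sizes <- vapply(c(0.001, 0.05, 0.5), function(a)
    length(runPurge(sim$peptides, sim$samples, ct,
                    pc = PurgeConfig(alpha = a))), numeric(1L))
  expect_true(all(diff(sizes) >= 0))
  folds <- vapply(c(1, 2, 8), function(f)
    length(runPurge(sim$peptides, sim$samples, ct,
                    pc = PurgeConfig(minFold = f))), numeric(1L))
  expect_true(all(diff(folds) <= 0))
})

test_that("the purge is deterministic and a fixed point on its own output", {
  sim <- simulateDataset(StudyDesign(nCouples = 4L, replicatesPerArm = 2L),
                         smallSimConfig(seed = 31))
  ct <- defaultContrasts()$HA
  a <- runPurge(sim$peptides, sim$samples, ct)
  b <- runPurge(sim$peptides, sim$samples, ct)
  expect_identical(records(a), records(b))
  ## output is a subset of what was detected in the case group
  caseIds <- samplesInGroup(sim$samples, "TURNX", "HA")
  detected <- unique(sim$peptides$accession[sim$peptides$sample_id %in%
                                            caseIds])
  expect_true(all(accessions(a) %in% detected))
  ## rerunning on the retained proteins reproduces the list
  sub <- sim$peptides[sim$peptides$accession %in% accessions(a), ]
  again <- runPurge(sub, sim$samples, ct)
  expect_identical(accessions(again), accessions(a))
  ## ordering contract: descending ratio, then ascending p, then accession
  r <- records(a)
  expect_identical(order(-r$ratio, r$p_reported, r$accession),
                   seq_len(nrow(r)))
})

test_that("interactome tables survive a write/read round trip", {
  sim <- simulateDataset(StudyDesign(nCouples = 4L, replicatesPerArm = 2L),
                         smallSimConfig(seed = 41))
  ia <- runPurge(sim$peptides, sim$samples, defaultContrasts()$V5)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeInteractome(ia, path)
  back <- readInteractome(path, "V5")
  expect_identical(accessions(back), accessions(ia))
  expect_equal(records(back)$ratio, records(ia)$ratio, tolerance = 1e-9)
  ## malformed TSV is reported with its line number
  lines <- readLines(path)
  lines[3L] <- paste(lines[3L], "extra", sep = "\t")
  writeLines(lines, path)
  expect_error(readInteractome(path, "V5"), "line 3")
})
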