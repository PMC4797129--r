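test_that("precision is the sample SD per fragment", {
  mk <- function(s) data.frame(locus = "L1", allele = "8", size = s)
  runs <- list(mk(99.9), mk(100.0), mk(100.1))
  rep <- precisionReport(runs)
  expect_equal(rep$perFragment$sd, 0.1)
  expect_equal(rep$maxSd, 0.1)
  expect_true(rep$pass)
  # identical runs -> all zero
  same <- precisionReport(list(mk(100), mk(100)))
  expect_equal(same$maxSd, 0)
  # mismatched fragment sets rejected
  expect_error(precisionReport(list(mk(100),
                                    data.frame(locus = "L1", allele = "9",
                                               size = 100))),
               "different fragment sets")
  expect_error(precisionReport(list(mk(100))), "at least 2")
})

test_that("resolution follows the baseline-width convention", {
  fw <- function(sigma) 2 * sqrt(2 * log(2)) * sigma
  # sigma 0.25 bases: Wb = 1 base, R = 1
  expect_equal(resolutionR(fw(0.25)), 1.0)
  # sigma 1.25 bases: R = 1/(4*1.25) = 0.2
  expect_equal(resolutionR(fw(1.25)), 0.2)
  # coincident pair
  expect_equal(resolutionR(c(fw(0.5), fw(0.5)), sizes = c(200, 200)), 0)
  # pair one base apart equals the single-peak convention
  expect_equal(resolutionR(c(fw(0.25), fw(0.25)), sizes = c(200, 201)),
               resolutionR(fw(0.25)))
  expect_error(resolutionR(0), "positive")
  # R grows without bound as width shrinks
  expect_gt(resolutionR(fw(1e-4)), 1e3)
})

test_that("phrReport aggregates only observed heterozygote ratios", {
  mkProfile <- function(id, phrTable) {
    st <- data.frame(locus = c("TH01", "vWA", "Amelogenin"),
                     status = "called",
                     phr = phrTable, stringsAsFactors = FALSE)
    new("SampleProfile", sampleId = id, calls = forenSTR:::emptyCalls(),
        locusStatus = st, category = "partial", codisLocusCount = 2L)
  }
  # single het locus observation: mean recorded, SD absent
  rep1 <- phrReport(list(mkProfile("a", c(0.7, NA, NA))))
  expect_identical(rep1$locus, "TH01")
  expect_equal(rep1$mean, 0.7)
  expect_true(is.na(rep1$sd))
  # all homozygous -> empty report
  expect_identical(nrow(phrReport(list(mkProfile("b", c(NA, NA, NA))))), 0L)
  # Amelogenin excluded even when a ratio is present
  rep2 <- phrReport(list(mkProfile("c", c(0.8, 0.6, 0.9))))
  expect_setequal(rep2$locus, c("TH01", "vWA"))
})

test_that("concordance tallies match the worked arithmetic", {
  expect_equal(concordanceTally(8094, 8091)$percentConcordant, 99.963)
  expect_equal(concordanceTally(8094, 8091)$nDiscordant, 3L)
  t32 <- concordanceTally(32, 32)
  expect_equal(t32$percentConcordant, 100.000)
  expect_error(concordanceTally(10, 11), "exceed")
  # pooling is order-invariant
  parts <- list(concordanceTally(100, 99, nDropout = 1),
                concordanceTally(50, 50), concordanceTally(20, 19))
  a <- combineTallies(parts)
  b <- combineTallies(rev(parts))
  expect_identical(a$percentConcordant, b$percentConcordant)
  expect_identical(a$nAssessed, 170L)
})

test_that("profile-vs-reference concordance counts dropouts and dropins", {
  panel <- pp16()
  calls <- data.frame(locus = c("TH01", "TH01", "vWA"),
                      designation = c("7", "9.3", "14"),
                      size = c(168, 179, 139), height = 1000,
                      flags = c("", "", "stutter_filtered"),
                      stringsAsFactors = FALSE)
  st <- data.frame(locus = c("TH01", "vWA"), status = c("called", "dropout"),
                   phr = NA_real_, stringsAsFactors = FALSE)
  prof <- new("SampleProfile", sampleId = "s", calls = calls,
              locusStatus = st, category = "partial", codisLocusCount = 1L)
  ref <- list(TH01 = c("7", "8"), vWA = "14")
  tal <- concordance(prof, ref)
  expect_identical(tal$nAssessed, 3L)       # 7, 8, 14
  expect_identical(tal$nConcordant, 1L)     # only TH01 7
  expect_identical(tal$nDropout, 2L)        # 8 missing; vWA 14 flagged away
  expect_identical(tal$nDropin, 1L)         # unflagged 9.3 not in reference
})

test_that("the bundled reproducibility grid tabulates to the printed totals", {
  grid <- system.file("extdata", "table1_status_grid.csv",
                      package = "forenSTR")
  counts <- tabulateStatusGrid(grid)
  expect_identical(counts$nFull, 91L)
  expect_identical(counts$nPartial, 4L)
  expect_identical(counts$nFail, 1L)
  expect_identical(counts$nProfiles, 95L)
  # trivial grids
  allY <- tabulateStatusGrid(matrix("Y", 5, 2))
  expect_identical(allY$nFull, 10L)
  expect_identical(allY$nProfiles, 10L)
  zero <- tabulateStatusGrid(matrix(character(), 0, 0))
  expect_identical(zero$nProfiles, 0L)
  expect_error(tabulateStatusGrid(matrix("Q", 1, 1)), "unknown status code")
})

test_that("sensitivity is monotone in template mass and saturates", {
  panel <- smallPanel()
  params <- smallParams(seed = 1)
  curve <- sensitivityCurve(c(3, 30, 600), nReps = 12L, panel, params,
                            seed = 11)
  expect_true(all(diff(curve$meanCalledLoci) >= 0))
  expect_equal(curve$fracFull[3], 1.0)      # mass >> m50
  expect_gt(curve$fracFail[1], curve$fracFail[3])
})
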