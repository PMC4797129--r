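# Peaks table for the ILS channel at the exact warped positions.
ilsPeakTable <- function(params, sizes, channel = 2L) {
  data.frame(channel = channel,
             apexScan = forenSTR:::warpSize(params, sizes),
             height = 1500, area = 1, fwhmScans = 3, saturated = FALSE)
}

test_that("a clean ILS passes and a deleted fragment fails with its name", {
  panel <- smallPanel()
  params <- smallParams(seed = 1)
  sizes <- ils(panel)@fragmentSizes
  ok <- evaluateIls(ilsPeakTable(params, sizes), ils(panel), channel = 2L)
  expect_identical(ok@status, "pass")
  expect_false(anyNA(ok@matched$apexScan))
  # delete the 130-base fragment
  del <- evaluateIls(ilsPeakTable(params, setdiff(sizes, 130)), ils(panel),
                     channel = 2L)
  expect_identical(del@status, "fail")
  expect_match(del@failureReasons, "missing fragment: 130", all = FALSE)
})

test_that("a spurious peak between fragments is left unmatched", {
  panel <- smallPanel()
  params <- smallParams(seed = 1)
  sizes <- ils(panel)@fragmentSizes
  pk <- ilsPeakTable(params, sizes)
  spur <- forenSTR:::warpSize(params, 145)    # halfway between 130 and 160
  pk <- rbind(pk, data.frame(channel = 2L, apexScan = spur, height = 200,
                             area = 1, fwhmScans = 3, saturated = FALSE))
  out <- evaluateIls(pk, ils(panel), channel = 2L)
  expect_identical(out@status, "pass")
  expect_equal(out@matched$apexScan,
               forenSTR:::warpSize(params, sizes), tolerance = 1e-9)
})

test_that("calibration reproduces an exactly cubic warp", {
  panel <- smallPanel()
  params <- smallParams(seed = 1)
  ok <- evaluateIls(ilsPeakTable(params, ils(panel)@fragmentSizes),
                    ils(panel), channel = 2L)
  cal <- fitCalibration(ok)
  expect_lt(max(abs(cal@residuals)), 1e-6)
  # peak at scan warp(200) sizes to 200.00 and FWHM converts via the slope
  pk <- data.frame(channel = 1L, apexScan = forenSTR:::warpSize(params, 200),
                   height = 1000, area = 1, fwhmScans = 4, saturated = FALSE)
  sized <- sizePeaks(pk, cal, sizingRange = c(90, 230))
  expect_lt(abs(sized$size - 200), 1e-3)
  slope <- forenSTR:::warpSlope(params, 200)
  expect_equal(sized$fwhmBases, 4 / slope, tolerance = 1e-3)
  expect_true(sized$inRange)
  # out-of-range peak flagged, not dropped
  pkOut <- data.frame(channel = 1L, apexScan = forenSTR:::warpSize(params, 70),
                      height = 1000, area = 1, fwhmScans = 4,
                      saturated = FALSE)
  expect_false(sizePeaks(pkOut, cal, sizingRange = c(90, 230))$inRange)
})

test_that("a 4-fragment minimal ILS interpolates exactly", {
  params <- smallParams(seed = 1)
  ilsDef <- ILSDefinition("CXR", c(60, 100, 140, 180))
  ok <- evaluateIls(ilsPeakTable(params, ilsDef@fragmentSizes), ilsDef,
                    channel = 2L)
  cal <- fitCalibration(ok)
  expect_lt(max(abs(cal@residuals)), 1e-8)
})

test_that("calibration refuses a failed assessment", {
  panel <- smallPanel()
  params <- smallParams(seed = 1)
  sizes <- ils(panel)@fragmentSizes
  bad <- evaluateIls(ilsPeakTable(params, sizes[-3]), ils(panel), channel = 2L)
  expect_error(fitCalibration(bad), "cannot calibrate")
})

test_that("local Southern agrees with the cubic fit away from the ends", {
  panel <- smallPanel()
  params <- smallParams(seed = 1)
  ok <- evaluateIls(ilsPeakTable(params, ils(panel)@fragmentSizes),
                    ils(panel), channel = 2L)
  calC <- fitCalibration(ok, "least-squares-cubic")
  calS <- fitCalibration(ok, "local-southern")
  for (s in c(105, 130, 170)) {
    x <- forenSTR:::warpSize(params, s)
    expect_lt(abs(predictSize(calC, x) - s), 1e-6)
    expect_lt(abs(predictSize(calS, x) - s), 0.35)
  }
})

test_that("sized order equals scan order (monotonicity)", {
  panel <- smallPanel()
  params <- smallParams(seed = 6)
  sz <- sizeTrace(simulateLadderRun(panel, params), panel)
  expect_identical(sz$assessment@status, "pass")
  for (ch in unique(sz$peaks$channel)) {
    pk <- sz$peaks[sz$peaks$channel == ch, ]
    expect_identical(order(pk$apexScan), order(pk$size))
  }
})

test_that("a simulated PP16 ladder sizes all 210 fragments within 0.5 base", {
  panel <- pp16()
  sz <- sizeTrace(simulateLadderRun(panel, simulationParams(seed = 21)),
                  panel)
  expect_identical(sz$assessment@status, "pass")
  lt <- forenSTR:::ladderTable(panel)
  err <- vapply(seq_len(nrow(lt)), function(i) {
    cand <- sz$peaks[sz$peaks$channel == lt$channel[i], ]
    min(abs(cand$size - lt$size[i]))
  }, numeric(1))
  expect_lt(max(err), 0.5)
})

test_that("per-fragment size SD shrinks to zero as noise vanishes", {
  panel <- smallPanel()
  sdAt <- function(noise) {
    runs <- lapply(1:4, function(k) {
      params <- smallParams(noiseSd = noise, baselineAmplitude = 0,
                            seed = 300L + k)
      sz <- sizeTrace(simulateLadderRun(panel, params), panel)
      lad <- loci(panel)[[1]]@ladder
      data.frame(locus = "L1", allele = lad$allele,
                 size = vapply(lad$size, function(s)
                   sz$peaks$size[which.min(abs(sz$peaks$size - s))],
                   numeric(1)))
    })
    precisionReport(runs)$maxSd
  }
  expect_lt(sdAt(0), 0.015)
  expect_lt(sdAt(0), sdAt(8) + 0.02)
})
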