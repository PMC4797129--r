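test_that("noise-free ladder calibration recovers nominal bin centres", {
  panel <- pp16()
  bins <- pp16Bins()
  lt <- forenSTR:::ladderTable(panel)
  expect_identical(nrow(bins@bins), 210L)
  m <- merge(bins@bins, lt, by = c("locus", "allele"))
  expect_identical(nrow(m), 210L)
  expect_lt(max(abs(m$center - m$size)), 0.02)
})

test_that("a ladder missing one fragment fails naming the fragment", {
  panel <- pp16()
  sz <- sizeTrace(simulateLadderRun(panel, noiseFreeParams(seed = 5)), panel)
  drop <- sz$peaks[!(sz$peaks$channel == 1 & abs(sz$peaks$size - 168) < 1), ]
  expect_error(calibrateBins(drop, panel), "TH01 allele 7")
})

test_that("alleles are assigned by bin and off-ladder peaks flagged", {
  panel <- pp16()
  bins <- nominalBins(panel)
  mkPeak <- function(channel, size, height = 1000)
    data.frame(channel = channel, apexScan = 0, height = height, area = 1,
               fwhmScans = 3, size = size, fwhmBases = 0.4, inRange = TRUE,
               saturated = FALSE)
  # at a bin centre -> that designation (TH01 9.3 at 179)
  calls <- assignAlleles(mkPeak(1, 179), bins, panel)
  expect_identical(calls$designation, "9.3")
  expect_true(forenSTR:::isUnflagged(calls$flags))
  # 1.7 bases off the nearest tetranucleotide bin -> off-ladder
  calls <- assignAlleles(mkPeak(1, 117.7), bins, panel)   # D3S1358 12 is 115
  expect_identical(calls$designation, "OL")
  expect_true(forenSTR:::hasFlag(calls$flags, "off_ladder"))
  # outside every locus span -> dropped
  calls <- assignAlleles(mkPeak(1, 150), bins, panel)
  expect_identical(nrow(calls), 0L)
})

test_that("computePhr matches the weakest/strongest definition", {
  expect_equal(computePhr(c(700, 1000)), 0.7)
  expect_equal(computePhr(c(1000, 1000)), 1.0)
  expect_equal(computePhr(c(500, 1000)), 0.5)
  expect_true(is.na(computePhr(1000)))
  expect_true(is.na(computePhr(c(1, 2, 3))))
  # scale invariance
  for (k in c(0.01, 3, 1e4))
    expect_equal(computePhr(c(700, 1000) * k), 0.7)
})

test_that("the stutter rule filters by ratio at one repeat unit", {
  panel <- pp16()
  calls <- data.frame(
    locus = c("D3S1358", "D3S1358"),
    designation = c("12", "13"),
    size = c(115, 119), height = c(80, 1000), flags = c("", ""),
    stringsAsFactors = FALSE)
  out <- applyRules(calls, panel)
  expect_true(forenSTR:::hasFlag(out$calls$flags[1], "stutter_filtered"))
  expect_identical(out$locusStatus$status[
    out$locusStatus$locus == "D3S1358"], "called")
  # ratio 0.40 > 0.15 threshold: retained, genuine heterozygote
  calls$height[1] <- 400
  out <- applyRules(calls, panel)
  expect_false(forenSTR:::hasFlag(out$calls$flags[1], "stutter_filtered"))
  st <- out$locusStatus[out$locusStatus$locus == "D3S1358", ]
  expect_equal(st$phr, 0.4)
})

test_that("threshold, PHR and multi-allele rules flag as documented", {
  panel <- pp16()
  # below analytical threshold
  calls <- data.frame(locus = "TH01", designation = "7", size = 168,
                      height = 60, flags = "", stringsAsFactors = FALSE)
  out <- applyRules(calls, panel)
  expect_true(forenSTR:::hasFlag(out$calls$flags, "below_threshold"))
  expect_identical(out$locusStatus$status[out$locusStatus$locus == "TH01"],
                   "flagged_only")
  # severe imbalance: weaker call flagged, PHR absent
  calls <- data.frame(locus = c("vWA", "vWA"), designation = c("14", "17"),
                      size = c(139, 151), height = c(200, 1000),
                      flags = c("", ""), stringsAsFactors = FALSE)
  out <- applyRules(calls, panel)
  expect_true(forenSTR:::hasFlag(out$calls$flags[1], "phr_imbalance"))
  expect_false(forenSTR:::hasFlag(out$calls$flags[2], "phr_imbalance"))
  expect_true(is.na(out$locusStatus$phr[out$locusStatus$locus == "vWA"]))
  # more than two surviving calls: all flagged for review
  calls <- data.frame(locus = "TPOX", designation = c("8", "9", "10"),
                      size = c(270, 274, 278), height = c(900, 950, 1000),
                      flags = "", stringsAsFactors = FALSE)
  out <- applyRules(calls, panel)
  expect_true(all(forenSTR:::hasFlag(out$calls$flags, "phr_imbalance")))
})

test_that("profile categories follow the called-locus rules", {
  panel <- pp16()
  emptyOut <- applyRules(forenSTR:::emptyCalls(), panel)
  expect_identical(profileCategory(assembleProfile(emptyOut, panel)), "fail")
  # a single called locus -> partial
  one <- applyRules(data.frame(locus = "TH01", designation = "7", size = 168,
                               height = 2000, flags = "",
                               stringsAsFactors = FALSE), panel)
  prof <- assembleProfile(one, panel)
  expect_identical(profileCategory(prof), "partial")
  expect_identical(codisLocusCount(prof), 1L)
  # incomplete locus coverage is rejected
  broken <- one
  broken$locusStatus <- broken$locusStatus[-1, ]
  expect_error(assembleProfile(broken, panel), "every panel locus")
})

test_that("low-template runs drop loci and yield sparse partial profiles", {
  panel <- pp16()
  bins <- pp16Bins()
  params <- simulationParams(templateMass = 8, seed = 314)   # far below m50
  g <- sampleGenotype(panel, seed = 314)
  res <- analyzeSample(simulateSample(g, panel, params), bins, panel)
  st <- locusStatus(res$profile)
  expect_gt(sum(st$status == "dropout"), 5)
  expect_true(profileCategory(res$profile) %in% c("partial", "fail"))
  if (profileCategory(res$profile) == "partial")
    expect_lt(codisLocusCount(res$profile), 10L)
})

test_that("noise-free end-to-end calls equal simulated truth (oracle)", {
  panel <- pp16()
  bins <- pp16Bins()
  for (k in 1:20) {
    g <- sampleGenotype(panel, seed = 7000L + k)
    res <- analyzeSample(
      simulateSample(g, panel, noiseFreeParams(seed = 7100L + k)),
      bins, panel)
    expect_identical(profileCategory(res$profile), "full")
    tal <- concordance(res$profile, g)
    expect_identical(tal$nConcordant, tal$nAssessed)
    expect_identical(tal$nDropin, 0L)
  }
})
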