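test_that("noise-free peaks sit at warp(size) with closed-form heights", {
  panel <- smallPanel()
  params <- noiseFreeParams(nChannels = 2L, templateMass = 500, seed = 4,
                            crosstalk = diag(2))
  g <- list(L1 = c("8", "13"))           # sizes 100 and 120
  epg <- simulateSample(g, panel, params)
  v <- traceValues(epg)
  for (size in c(100, 120)) {
    mu <- forenSTR:::warpSize(params, size)
    hExp <- 500 * 10 * exp(-0.002 * size)
    # sample the trace at the integer scan nearest the apex
    i <- round(mu) + 1L
    sigma <- forenSTR:::peakSigmaScans(params, size)
    hAtScan <- hExp * exp(-((round(mu) - mu)^2) / (2 * sigma^2))
    expect_equal(unname(v[i, 1L]), hAtScan, tolerance = 1e-6)
    # local maximum within one scan of the apex
    expect_gte(v[i, 1L], max(v[(i - 3):(i + 3), 1L]) * 0.999)
  }
  # ILS fragments always present in the ILS channel
  for (s in ils(panel)@fragmentSizes) {
    i <- round(forenSTR:::warpSize(params, s)) + 1L
    expect_gt(v[i, 2L], 1000)
  }
})

test_that("simulation is bit-identical under the same seed", {
  panel <- smallPanel()
  params <- smallParams(seed = 77)
  g <- list(L1 = c("9", "12"))
  e1 <- simulateSample(g, panel, params)
  e2 <- simulateSample(g, panel, params)
  expect_identical(traceValues(e1), traceValues(e2))
  l1 <- simulateLadderRun(panel, params)
  l2 <- simulateLadderRun(panel, params)
  expect_identical(traceValues(l1), traceValues(l2))
  e3 <- simulateSample(g, panel, smallParams(seed = 78))
  expect_false(identical(traceValues(e1), traceValues(e3)))
})

test_that("per-allele dropout frequency is ~0.5 at the logistic midpoint", {
  panel <- smallPanel()
  g <- list(L1 = c("8", "13"))
  nSamples <- 1000L                      # 2000 simulated alleles
  muA <- round(forenSTR:::warpSize(smallParams(), 100)) + 1L
  muB <- round(forenSTR:::warpSize(smallParams(), 120)) + 1L
  survived <- 0L
  for (k in seq_len(nSamples)) {
    params <- smallParams(noiseSd = 0, baselineAmplitude = 0,
                          imbalanceDispersion = 0, stutterMean = 0,
                          stutterSd = 0, crosstalk = diag(2),
                          templateMass = 30, dropoutM50 = 30,
                          seed = 5000L + k)
    v <- traceValues(simulateSample(g, panel, params))
    survived <- survived + (v[muA, 1L] > 100) + (v[muB, 1L] > 100)
  }
  pHat <- 1 - survived / (2 * nSamples)
  se <- sqrt(0.25 / (2 * nSamples))
  expect_lt(abs(pHat - 0.5), 3 * se)
})

test_that("identity crosstalk and zero noise keep each dye in its own channel", {
  panel <- smallPanel()
  params <- noiseFreeParams(nChannels = 2L, seed = 2, crosstalk = diag(2))
  g <- list(L1 = c("8", "13"))
  v <- traceValues(simulateSample(g, panel, params))
  # locus channel empty at ILS-only positions, ILS channel empty at
  # allele-only positions (alleles sit at 100 and 120, stutter at 96/116)
  for (s in c(60, 75, 130, 160, 190, 240)) {
    i <- round(forenSTR:::warpSize(params, s)) + 1L
    expect_equal(unname(v[i, 1L]), 0)
  }
  for (s in c(104, 108, 112)) {
    i <- round(forenSTR:::warpSize(params, s)) + 1L
    expect_equal(unname(v[i, 2L]), 0)
  }
})

test_that("Hardy-Weinberg draws have the expected heterozygosity and determinism", {
  panel <- smallPanel()
  ft <- data.frame(locus = "L1", allele = c("8", "13"), freq = c(0.5, 0.5))
  nDraw <- 10000L
  het <- vapply(seq_len(nDraw), function(k)
    length(sampleGenotype(panel, ft, seed = k)$L1) == 2L, logical(1))
  expect_lt(abs(mean(het) - 0.5), 3 * sqrt(0.25 / nDraw))
  # single-allele table -> always homozygous
  ft1 <- data.frame(locus = "L1", allele = "10", freq = 1)
  expect_identical(sampleGenotype(panel, ft1, seed = 1)$L1, "10")
  # determinism
  expect_identical(sampleGenotype(panel, ft, seed = 42),
                   sampleGenotype(panel, ft, seed = 42))
  # frequency-sum violation
  ftBad <- data.frame(locus = "L1", allele = c("8", "13"), freq = c(0.6, 0.5))
  expect_error(sampleGenotype(panel, ftBad, seed = 1), "sum")
})

test_that("genotypes at loci absent from the panel are rejected", {
  expect_error(simulateSample(list(NOPE = "8"), smallPanel(),
                              smallParams(seed = 1)),
               "absent from panel")
})

test_that("simulated PHR mean decreases with imbalance dispersion", {
  panel <- smallPanel()
  g <- list(L1 = c("8", "13"))
  muA <- round(forenSTR:::warpSize(smallParams(), 100)) + 1L
  muB <- round(forenSTR:::warpSize(smallParams(), 120)) + 1L
  meanPhr <- function(disp) {
    phr <- vapply(1:120, function(k) {
      params <- smallParams(noiseSd = 0, baselineAmplitude = 0,
                            stutterMean = 0, stutterSd = 0,
                            crosstalk = diag(2), templateMass = 2000,
                            imbalanceDispersion = disp, seed = 900L + k)
      v <- traceValues(simulateSample(g, panel, params))
      computePhr(c(v[muA, 1L], v[muB, 1L]))
    }, numeric(1))
    mean(phr)
  }
  m <- vapply(c(0.05, 0.20, 0.45), meanPhr, numeric(1))
  expect_true(all(diff(m) < 0))
  # documented default places the mean in the 0.7-0.8 band
  expect_gt(m[2], 0.70)
  expect_lt(m[2], 0.80)
})
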