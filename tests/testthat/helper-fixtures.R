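# Shared fixtures, built in code. Heavy objects are memoised for the test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .cache)) assign(key, fn(), envir = .cache)
  get(key, envir = .cache)
}

# Minimal 1-locus panel on two channels; fast to simulate.
smallPanel <- function() {
  PanelDefinition(
    dyes = list(DyeChannel("FL", 1L), DyeChannel("CXR", 2L)),
    loci = list(LocusDefinition("L1", "FL", 4,
                                data.frame(allele = as.character(8:13),
                                           size = seq(100, 120, by = 4)),
                                stutterThreshold = 0.15, isCodis = TRUE)),
    ils = ILSDefinition("CXR", c(60, 75, 90, 130, 160, 190, 240)),
    analyticalThreshold = 100, phrThreshold = 0.3, binHalfWidth = 0.5,
    sizingRange = c(90, 230))
}

smallParams <- function(...) {
  simulationParams(nChannels = 2L, ...)
}

# All stochastic artifacts off: the oracle conditions.
noiseFreeParams <- function(nChannels = 4L, templateMass = 2000, seed = 1L,
                            ...) {
  simulationParams(noiseSd = 0, baselineAmplitude = 0,
                   imbalanceDispersion = 0, stutterMean = 0, stutterSd = 0,
                   templateMass = templateMass, nChannels = nChannels,
                   seed = seed, ...)
}

pp16 <- function() memo("pp16", pp16Panel)

# Bins calibrated from one noise-free pp16 ladder run.
pp16Bins <- function() memo("pp16Bins", function() {
  calibrateLadder(simulateLadderRun(pp16(), noiseFreeParams(seed = 101)),
                  pp16())
})

# Bins from nominal ladder sizes (no simulation), for rule-level tests.
nominalBins <- function(panel) {
  lt <- forenSTR:::ladderTable(panel)
  new("BinSet",
      bins = data.frame(locus = lt$locus, allele = lt$allele,
                        center = lt$size, halfWidth = panel@binHalfWidth,
                        stringsAsFactors = FALSE),
      ladderRunId = "nominal")
}

# A bare trace containing the given Gaussians (0-based scan mu).
gaussianTrace <- function(nScans, nChannels, peaks,
                          runKind = "sample") {
  v <- matrix(0, nScans, nChannels)
  for (p in peaks)
    v[, p$channel] <- forenSTR:::addGaussian(v[, p$channel], p$mu, p$sigma,
                                             p$height)
  colnames(v) <- paste0("D", seq_len(nChannels))
  Electropherogram(v, runKind = runKind)
}
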