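#' @include AllClasses.R AllGenerics.R utils.R panel.R
NULL

#' Default simulation parameters
#'
#' Constructs a \linkS4class{SimulationParams} object. The defaults emulate a
#' 4-dye, PowerPlex-16-style run on a rapid-DNA instrument at a healthy
#' template input: 500 pg of template at 10 RFU/pg gives main peaks of a few
#' thousand RFU; per-base exponential degradation attenuates large fragments;
#' heterozygote imbalance is log-normal with dispersion chosen so the mean
#' simulated peak height ratio falls in the 0.7-0.8 band; stutter is one
#' repeat unit short at 8 +/- 2 per cent of the parent; dropout is logistic in
#' log template mass with 50 per cent per-allele dropout at 30 pg. The warp
#' maps the 60-600 base interval onto roughly scans 700-6100 with mild
#' cubic nonlinearity, and the width model makes peak SD grow linearly from
#' about 0.16 bases at 140 bases to 0.69 bases at 500 bases (resolution
#' falling from about 1.6 to about 0.36), with a floor of 0.12 bases.
#'
#' @param templateMass Template DNA (pg).
#' @param heightScale RFU per pg at size 0.
#' @param imbalanceDispersion SD of the log-normal per-allele height factor.
#' @param stutterMean,stutterSd Stutter ratio distribution.
#' @param noiseSd White-noise SD (RFU).
#' @param baselineAmplitude Slow baseline drift amplitude (RFU).
#' @param crosstalk Dye-to-detector mixing matrix; default has 5 per cent
#'   bleed between spectrally adjacent dyes.
#' @param saturation Detector ceiling (RFU).
#' @param degradationRate Per-base height decay.
#' @param dropoutM50 Mass (pg) at 50 per cent per-allele dropout.
#' @param dropoutSlope Logistic steepness in log-mass.
#' @param warp Cubic size-to-scan coefficients (intercept, s, s^2, s^3).
#' @param widthModel \code{(floor, b0, b1)}: peak SD in bases is
#'   \code{max(floor, b0 + b1*size)}.
#' @param seed Integer seed.
#' @param nChannels Number of detector channels (sets the default crosstalk
#'   dimension).
#' @return A \linkS4class{SimulationParams}.
#' @export
simulationParams <- function(templateMass = 500, heightScale = 10,
                             imbalanceDispersion = 0.20,
                             stutterMean = 0.08, stutterSd = 0.02,
                             noiseSd = 8, baselineAmplitude = 40,
                             crosstalk = defaultCrosstalk(nChannels),
                             saturation = 30000, degradationRate = 0.002,
                             dropoutM50 = 30, dropoutSlope = 3,
                             warp = c(200, 8.5, 0.0012, 2e-7),
                             widthModel = c(0.12, -0.0525, 0.001486),
                             seed = 1L, nChannels = 4L) {
  new("SimulationParams", templateMass = templateMass,
      heightScale = heightScale, imbalanceDispersion = imbalanceDispersion,
      stutterMean = stutterMean, stutterSd = stutterSd, noiseSd = noiseSd,
      baselineAmplitude = baselineAmplitude, crosstalk = crosstalk,
      saturation = saturation, degradationRate = degradationRate,
      dropoutM50 = dropoutM50, dropoutSlope = dropoutSlope,
      warp = warp, widthModel = widthModel, seed = as.integer(seed))
}

#' Default dye crosstalk matrix
#'
#' Diagonally dominant mixing matrix with 5 per cent bleed between spectrally
#' adjacent dye/detector pairs.
#'
#' @param n Number of channels.
#' @return An \code{n x n} matrix.
#' @export
defaultCrosstalk <- function(n = 4L) {
  m <- diag(n)
  for (i in seq_len(n - 1L)) {
    m[i, i + 1L] <- 0.05
    m[i + 1L, i] <- 0.05
  }
  m
}

## size -> scan under the warp polynomial
warpSize <- function(params, size) {
  w <- params@warp
  w[1] + w[2] * size + w[3] * size^2 + w[4] * size^3
}

## d scan / d size
warpSlope <- function(params, size) {
  w <- params@warp
  w[2] + 2 * w[3] * size + 3 * w[4] * size^2
}

## peak SD in scans at a given size
peakSigmaScans <- function(params, size) {
  wm <- params@widthModel
  sigmaBases <- pmax(wm[1], wm[2] + wm[3] * size)
  sigmaBases * warpSlope(params, size)
}

## per-allele dropout probability at a template mass
dropoutProbability <- function(params, mass = params@templateMass) {
  stats::plogis(-params@dropoutSlope * (log(mass) - log(params@dropoutM50)))
}

## number of scans needed to contain the warped sizing+ILS range
traceLength <- function(params, panel) {
  top <- max(panel@ils@fragmentSizes, panel@sizingRange[2])
  as.integer(ceiling(warpSize(params, top + 20)))
}

## Add one Gaussian peak (RFU apex `height`, SD sigma scans) to a channel.
## `mu` is a 0-based scan position; vector index i holds scan i-1.
addGaussian <- function(channel, mu, sigma, height) {
  lo <- max(1L, floor(mu + 1 - 6 * sigma))
  hi <- min(length(channel), ceiling(mu + 1 + 6 * sigma))
  if (lo > hi) return(channel)
  idx <- lo:hi
  channel[idx] <- channel[idx] +
    height * exp(-(((idx - 1) - mu)^2) / (2 * sigma^2))
  channel
}

## Shared tail of the simulators: pure per-dye signals -> mixed, drifted,
## noisy, clipped detector trace.
finishTrace <- function(pure, params, sampleId, runKind, dyeNames) {
  nScans <- nrow(pure)
  mixed <- pure %*% t(params@crosstalk)
  if (params@baselineAmplitude > 0) {
    phase <- stats::runif(ncol(mixed), 0, 2 * pi)
    for (j in seq_len(ncol(mixed)))
      mixed[, j] <- mixed[, j] + params@baselineAmplitude *
        (1 + sin(2 * pi * seq_len(nScans) / 2000 + phase[j])) / 2
  }
  if (params@noiseSd > 0)
    mixed <- mixed + matrix(stats::rnorm(length(mixed), 0, params@noiseSd),
                            nrow = nScans)
  mixed <- pmin(mixed, params@saturation)
  colnames(mixed) <- dyeNames
  Electropherogram(mixed, sampleId = sampleId, runKind = runKind,
                   crosstalk = params@crosstalk, seed = params@seed)
}

## Pure ILS signal in its own dye column.
addIls <- function(pure, panel, params, height = 1500) {
  idx <- dyeIndex(panel)
  ch <- idx[panel@ils@dye]
  for (s in panel@ils@fragmentSizes) {
    mu <- warpSize(params, s)
    pure[, ch] <- addGaussian(pure[, ch], mu, peakSigmaScans(params, s), height)
  }
  pure
}

#' Simulate a sample electropherogram
#'
#' Generates a synthetic multi-channel trace for a genotype. Each allele that
#' survives dropout contributes a Gaussian peak at scan position
#' \code{warp(size)}; its apex height is
#' \code{heightScale * templateMass * exp(-degradationRate * size)} times a
#' log-normal imbalance factor. One stutter peak per surviving allele is
#' placed one repeat unit short, at a ratio drawn from the stutter
#' distribution. ILS fragments are always present in the ILS channel. Dye
#' signals are mixed through the crosstalk matrix, slow baseline drift and
#' white noise are added, and the trace is clipped at saturation. The whole
#' trace is reproducible from \code{params@seed}.
#'
#' @param genotype Named list mapping locus name to a character vector of one
#'   (homozygous) or two (heterozygous) allele designations present in the
#'   locus ladder.
#' @param panel A \linkS4class{PanelDefinition}.
#' @param params A \linkS4class{SimulationParams}.
#' @param sampleId Identifier stored in the trace metadata.
#' @return An \linkS4class{Electropherogram} (run kind \code{"sample"}).
#' @examples
#' panel <- pp16Panel()
#' params <- simulationParams(seed = 7)
#' g <- sampleGenotype(panel, seed = 7)
#' epg <- simulateSample(g, panel, params)
#' @export
simulateSample <- function(genotype, panel, params, sampleId = "sample") {
  lnames <- vapply(panel@loci, function(l) l@name, character(1))
  unknown <- setdiff(names(genotype), lnames)
  if (length(unknown))
    stop("genotype locus absent from panel: ", paste(unknown, collapse = ", "))
  idx <- dyeIndex(panel)
  nScans <- traceLength(params, panel)
  withSeed(params@seed, {
    pure <- matrix(0, nScans, length(idx))
    pDrop <- dropoutProbability(params)
    for (l in panel@loci) {
      alleles <- genotype[[l@name]]
      if (is.null(alleles)) next
      ch <- idx[l@dye]
      for (a in alleles) {
        row <- match(a, l@ladder$allele)
        if (is.na(row))
          stop(sprintf("allele '%s' not in ladder of locus %s (off-ladder alleles must carry explicit sizes)",
                       a, l@name))
        size <- l@ladder$size[row]
        dropped <- stats::runif(1) < pDrop
        imb <- if (params@imbalanceDispersion > 0)
          exp(stats::rnorm(1, 0, params@imbalanceDispersion)) else 1
        stutterRatio <- if (params@stutterMean > 0 || params@stutterSd > 0)
          max(0, stats::rnorm(1, params@stutterMean, params@stutterSd)) else 0
        if (dropped) next
        h <- params@heightScale * params@templateMass *
          exp(-params@degradationRate * size) * imb
        mu <- warpSize(params, size)
        pure[, ch] <- addGaussian(pure[, ch], mu,
                                  peakSigmaScans(params, size), h)
        if (stutterRatio > 0) {
          sSize <- size - l@repeatUnit
          pure[, ch] <- addGaussian(pure[, ch], warpSize(params, sSize),
                                    peakSigmaScans(params, sSize),
                                    h * stutterRatio)
        }
      }
    }
    pure <- addIls(pure, panel, params)
    finishTrace(pure, params, sampleId, "sample", names(idx))
  })
}

#' Simulate an allelic-ladder electropherogram
#'
#' All ladder fragments of every locus are present at a fixed equal nominal
#' height (no stutter, no dropout), the ILS is included, and the usual
#' crosstalk/drift/noise chain is applied.
#'
#' @param panel A \linkS4class{PanelDefinition}.
#' @param params A \linkS4class{SimulationParams}.
#' @param height Nominal ladder fragment height (RFU).
#' @param sampleId Identifier stored in metadata.
#' @return An \linkS4class{Electropherogram} (run kind \code{"ladder"}).
#' @export
simulateLadderRun <- function(panel, params, height = 2000,
                              sampleId = "ladder") {
  idx <- dyeIndex(panel)
  nScans <- traceLength(params, panel)
  withSeed(params@seed, {
    pure <- matrix(0, nScans, length(idx))
    lt <- ladderTable(panel)
    for (i in seq_len(nrow(lt))) {
      mu <- warpSize(params, lt$size[i])
      pure[, lt$channel[i]] <- addGaussian(pure[, lt$channel[i]], mu,
                                           peakSigmaScans(params, lt$size[i]),
                                           height)
    }
    pure <- addIls(pure, panel, params)
    finishTrace(pure, params, sampleId, "ladder", names(idx))
  })
}

#' Simulate an ILS-only run
#'
#' @param panel A \linkS4class{PanelDefinition}.
#' @param params A \linkS4class{SimulationParams}.
#' @param height ILS fragment height (RFU).
#' @param sampleId Identifier stored in metadata.
#' @return An \linkS4class{Electropherogram} (run kind \code{"ils"}).
#' @export
simulateIlsRun <- function(panel, params, height = 1500, sampleId = "ils") {
  idx <- dyeIndex(panel)
  nScans <- traceLength(params, panel)
  withSeed(params@seed, {
    pure <- addIls(matrix(0, nScans, length(idx)), panel, params, height)
    finishTrace(pure, params, sampleId, "ils", names(idx))
  })
}

#' Uniform allele-frequency table for a panel
#'
#' Convenience table assigning equal frequency to every ladder allele of each
#' locus (including the sex-typing locus, whose designations are drawn like
#' any other alleles).
#'
#' @param panel A \linkS4class{PanelDefinition}.
#' @return \code{data.frame} with columns \code{locus}, \code{allele},
#'   \code{freq}.
#' @export
uniformFrequencyTable <- function(panel) {
  do.call(rbind, lapply(panel@loci, function(l) {
    n <- nrow(l@ladder)
    data.frame(locus = l@name, allele = l@ladder$allele, freq = rep(1 / n, n),
               stringsAsFactors = FALSE)
  }))
}

#' Draw a random genotype under Hardy-Weinberg proportions
#'
#' Samples two allele copies per locus independently from the locus allele
#' frequencies; homozygous draws yield a single designation.
#'
#' @param panel A \linkS4class{PanelDefinition}.
#' @param freqTable \code{data.frame} with columns \code{locus},
#'   \code{allele}, \code{freq}; frequencies must sum to 1 per locus (within
#'   1e-9). Defaults to \code{\link{uniformFrequencyTable}}.
#' @param seed Integer seed.
#' @return Named list: locus -> character vector of 1 or 2 designations,
#'   ordered by nominal size.
#' @export
sampleGenotype <- function(panel, freqTable = uniformFrequencyTable(panel),
                           seed = 1L) {
  withSeed(seed, {
    g <- list()
    for (l in panel@loci) {
      ft <- freqTable[freqTable$locus == l@name, ]
      if (nrow(ft) == 0L) stop("no frequencies for locus ", l@name)
      if (abs(sum(ft$freq) - 1) > 1e-9)
        stop(sprintf("frequencies at locus %s sum to %.12f, not 1", l@name,
                     sum(ft$freq)))
      draw <- sample(ft$allele, 2L, replace = TRUE, prob = ft$freq)
      draw <- unique(draw)
      ord <- order(match(draw, l@ladder$allele))
      g[[l@name]] <- draw[ord]
    }
    g
  })
}
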