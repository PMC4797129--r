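#' @import methods
NULL

#' Dye channel of a multi-colour CE detector
#'
#' A fluorescent dye and its ordinal position in the trace's channel ordering.
#'
#' @slot name Short dye label (e.g. \code{"FL"}, \code{"JOE"}, \code{"TMR"},
#'   \code{"CXR"}).
#' @slot detectorIndex 1-based ordinal position of this dye's channel in the
#'   trace matrix.
#'
#' @exportClass DyeChannel
setClass("DyeChannel",
  representation(name = "character", detectorIndex = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "dye name must be a single non-empty string")
    if (length(object@detectorIndex) != 1L || is.na(object@detectorIndex) ||
        object@detectorIndex < 1L)
      msg <- c(msg, "detectorIndex must be a positive integer")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{DyeChannel}
#' @param name Dye label.
#' @param detectorIndex 1-based channel index.
#' @return A \linkS4class{DyeChannel}.
#' @export
DyeChannel <- function(name, detectorIndex) {
  new("DyeChannel", name = as.character(name),
      detectorIndex = as.integer(detectorIndex))
}

#' STR locus definition
#'
#' One locus of the assay panel: its dye channel, repeat unit, allelic-ladder
#' composition (allele designations with nominal fragment sizes in bases) and
#' per-locus calling thresholds. Microvariant designations (e.g. \code{"9.3"})
#' are carried as character labels with explicit nominal sizes; no arithmetic
#' is ever performed on the labels themselves.
#'
#' @slot name Locus label (e.g. \code{"TH01"}).
#' @slot dye Name of the \linkS4class{DyeChannel} this locus is labelled with.
#' @slot repeatUnit Repeat length in bases (4 for tetranucleotide loci,
#'   5 for the Penta loci).
#' @slot ladder \code{data.frame} with columns \code{allele} (character
#'   designation) and \code{size} (nominal fragment size, bases), sizes
#'   strictly increasing.
#' @slot stutterThreshold Maximum stutter ratio (fraction of the parent peak
#'   height) below which a peak one repeat unit short of a parent allele is
#'   filtered as stutter.
#' @slot isCodis Whether the locus belongs to the CODIS core set.
#'
#' @exportClass LocusDefinition
setClass("LocusDefinition",
  representation(name = "character", dye = "character",
                 repeatUnit = "numeric", ladder = "data.frame",
                 stutterThreshold = "numeric", isCodis = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "locus name must be a single non-empty string")
    if (!all(c("allele", "size") %in% names(object@ladder)))
      msg <- c(msg, "ladder must have columns 'allele' and 'size'")
    else {
      s <- object@ladder$size
      if (nrow(object@ladder) > 1L && any(diff(s) <= 0))
        msg <- c(msg, sprintf("ladder allele sizes must be strictly increasing at locus %s",
                              object@name))
      if (anyDuplicated(object@ladder$allele))
        msg <- c(msg, sprintf("duplicate allele designation at locus %s", object@name))
    }
    if (object@stutterThreshold < 0 || object@stutterThreshold > 1)
      msg <- c(msg, "stutterThreshold must be in [0,1]")
    if (object@repeatUnit < 2)
      msg <- c(msg, "repeatUnit must be >= 2 bases")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{LocusDefinition}
#' @param name Locus label.
#' @param dye Dye name.
#' @param repeatUnit Repeat length in bases.
#' @param ladder data.frame with columns \code{allele}, \code{size}.
#' @param stutterThreshold Stutter filter ratio in [0,1].
#' @param isCodis CODIS core membership.
#' @return A \linkS4class{LocusDefinition}.
#' @export
LocusDefinition <- function(name, dye, repeatUnit, ladder,
                            stutterThreshold = 0.15, isCodis = FALSE) {
  ladder <- data.frame(allele = as.character(ladder$allele),
                       size = as.numeric(ladder$size),
                       stringsAsFactors = FALSE)
  new("LocusDefinition", name = as.character(name), dye = as.character(dye),
      repeatUnit = as.numeric(repeatUnit), ladder = ladder,
      stutterThreshold = as.numeric(stutterThreshold),
      isCodis = as.logical(isCodis))
}

#' Internal lane standard definition
#'
#' The dye-labelled size standard co-injected with every sample, used to map
#' scan positions to fragment sizes in bases.
#'
#' @slot dye Name of the ILS dye channel.
#' @slot fragmentSizes Strictly increasing fragment sizes (bases); at least 4
#'   fragments are required to support the calibration fit.
#'
#' @exportClass ILSDefinition
setClass("ILSDefinition",
  representation(dye = "character", fragmentSizes = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@fragmentSizes) < 4L)
      msg <- c(msg, "ILS needs at least 4 fragments for calibration")
    if (any(diff(object@fragmentSizes) <= 0))
      msg <- c(msg, "ILS fragment sizes must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{ILSDefinition}
#' @param dye ILS dye name.
#' @param fragmentSizes Increasing sizes in bases.
#' @return An \linkS4class{ILSDefinition}.
#' @export
ILSDefinition <- function(dye, fragmentSizes) {
  new("ILSDefinition", dye = as.character(dye),
      fragmentSizes = as.numeric(fragmentSizes))
}

#' Assay panel definition
#'
#' The complete description of an STR assay: loci with their dye channels and
#' allelic-ladder composition, the internal lane standard, and the global
#' calling thresholds.
#'
#' @slot dyes List of \linkS4class{DyeChannel} objects (locus dyes plus the
#'   ILS dye).
#' @slot loci List of \linkS4class{LocusDefinition} objects.
#' @slot ils The \linkS4class{ILSDefinition}.
#' @slot analyticalThreshold Minimum peak height (RFU) for a peak to count as
#'   signal.
#' @slot phrThreshold Minimum acceptable heterozygote peak height ratio.
#' @slot binHalfWidth Allele bin half-width in bases.
#' @slot sizingRange Numeric length-2: (min, max) of the assay sizing range in
#'   bases.
#'
#' @exportClass PanelDefinition
setClass("PanelDefinition",
  representation(dyes = "list", loci = "list", ils = "ILSDefinition",
                 analyticalThreshold = "numeric", phrThreshold = "numeric",
                 binHalfWidth = "numeric", sizingRange = "numeric"),
  validity = function(object) {
    msg <- character()
    dnames <- vapply(object@dyes, function(d) d@name, character(1))
    didx <- vapply(object@dyes, function(d) d@detectorIndex, integer(1))
    if (anyDuplicated(dnames)) msg <- c(msg, "dye names must be unique")
    if (anyDuplicated(didx)) msg <- c(msg, "detector indices must be unique")
    lnames <- vapply(object@loci, function(l) l@name, character(1))
    if (anyDuplicated(lnames)) {
      dup <- lnames[duplicated(lnames)][1L]
      msg <- c(msg, sprintf("duplicated locus name: %s", dup))
    }
    ldyes <- vapply(object@loci, function(l) l@dye, character(1))
    if (!all(ldyes %in% dnames)) msg <- c(msg, "locus dye not among panel dyes")
    if (!(object@ils@dye %in% dnames)) msg <- c(msg, "ILS dye not among panel dyes")
    if (object@ils@dye %in% ldyes)
      msg <- c(msg, "ILS dye must be distinct from locus dyes")
    if (length(object@sizingRange) != 2L ||
        object@sizingRange[1] >= object@sizingRange[2])
      msg <- c(msg, "sizingRange must be (min, max) with min < max")
    else {
      for (l in object@loci) {
        if (nrow(l@ladder) &&
            (min(l@ladder$size) < object@sizingRange[1] ||
             max(l@ladder$size) > object@sizingRange[2]))
          msg <- c(msg, sprintf("ladder alleles of %s outside sizing range", l@name))
      }
    }
    if (object@phrThreshold < 0 || object@phrThreshold > 1)
      msg <- c(msg, "phrThreshold must be in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{PanelDefinition}
#' @param dyes List of \linkS4class{DyeChannel}.
#' @param loci List of \linkS4class{LocusDefinition}.
#' @param ils An \linkS4class{ILSDefinition}.
#' @param analyticalThreshold Analytical threshold in RFU.
#' @param phrThreshold Heterozygote peak-height-ratio threshold in [0,1].
#' @param binHalfWidth Allele bin half-width in bases.
#' @param sizingRange Length-2 numeric (min, max) in bases.
#' @return A \linkS4class{PanelDefinition}.
#' @export
PanelDefinition <- function(dyes, loci, ils, analyticalThreshold = 100,
                            phrThreshold = 0.3, binHalfWidth = 0.5,
                            sizingRange = c(100, 500)) {
  new("PanelDefinition", dyes = dyes, loci = loci, ils = ils,
      analyticalThreshold = as.numeric(analyticalThreshold),
      phrThreshold = as.numeric(phrThreshold),
      binHalfWidth = as.numeric(binHalfWidth),
      sizingRange = as.numeric(sizingRange))
}

#' Simulation parameters for synthetic electropherograms
#'
#' All knobs of the synthetic capillary-electrophoresis trace generator.
#' Peak heights follow \code{heightScale * templateMass * exp(-degradationRate
#' * size)}, modulated per allele by a log-normal imbalance factor. Each
#' allele independently drops out with probability
#' \code{plogis(-dropoutSlope * (log(templateMass) - log(dropoutM50)))}, so
#' dropout is 50\% at \code{templateMass == dropoutM50}. The size-to-scan
#' mapping (electrophoretic mobility) is a monotone cubic \code{warp}; the
#' peak width model is affine in size with a floor.
#'
#' @slot templateMass Template DNA input in pg.
#' @slot heightScale RFU per pg of template at size 0.
#' @slot imbalanceDispersion SD of the per-allele log-normal height factor;
#'   the default places the mean simulated heterozygote peak height ratio in
#'   the 0.7-0.8 band typical of low-DNA-content casework.
#' @slot stutterMean,stutterSd Mean and SD of the per-allele stutter ratio
#'   (one stutter peak per surviving allele, one repeat unit short).
#' @slot noiseSd White-noise SD in RFU.
#' @slot baselineAmplitude Amplitude of the slow sinusoidal baseline drift (RFU).
#' @slot crosstalk Square dye-to-detector mixing matrix (diagonally dominant,
#'   invertible).
#' @slot saturation Detector ceiling in RFU (hard clipping).
#' @slot degradationRate Per-base exponential decay of peak height.
#' @slot dropoutM50 Template mass (pg) at which per-allele dropout is 50\%.
#' @slot dropoutSlope Steepness of the logistic dropout curve in log-mass.
#' @slot warp Length-4 numeric: coefficients (intercept, linear, quadratic,
#'   cubic) of the monotone size-to-scan polynomial.
#' @slot widthModel Length-3 numeric \code{(floor, b0, b1)}: peak SD in
#'   \emph{bases} is \code{max(floor, b0 + b1 * size)}, converted to scans
#'   through the local warp slope.
#' @slot seed Integer seed; all randomness of a simulated run flows from it.
#'
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(templateMass = "numeric", heightScale = "numeric",
                 imbalanceDispersion = "numeric",
                 stutterMean = "numeric", stutterSd = "numeric",
                 noiseSd = "numeric", baselineAmplitude = "numeric",
                 crosstalk = "matrix", saturation = "numeric",
                 degradationRate = "numeric",
                 dropoutM50 = "numeric", dropoutSlope = "numeric",
                 warp = "numeric", widthModel = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    ct <- object@crosstalk
    if (nrow(ct) != ncol(ct)) msg <- c(msg, "crosstalk must be square")
    else {
      dd <- all(2 * abs(diag(ct)) > rowSums(abs(ct)))
      if (!dd) msg <- c(msg, "crosstalk must be diagonally dominant")
      if (abs(det(ct)) < 1e-12) msg <- c(msg, "crosstalk must be invertible")
    }
    nonneg <- c(templateMass = object@templateMass,
                heightScale = object@heightScale,
                imbalanceDispersion = object@imbalanceDispersion,
                stutterMean = object@stutterMean, stutterSd = object@stutterSd,
                noiseSd = object@noiseSd,
                baselineAmplitude = object@baselineAmplitude,
                degradationRate = object@degradationRate,
                dropoutM50 = object@dropoutM50,
                dropoutSlope = object@dropoutSlope)
    if (any(nonneg < 0))
      msg <- c(msg, sprintf("negative rate/scale: %s",
                            paste(names(nonneg)[nonneg < 0], collapse = ", ")))
    if (length(object@warp) != 4L) msg <- c(msg, "warp must have 4 coefficients")
    if (length(object@widthModel) != 3L)
      msg <- c(msg, "widthModel must be (floor, b0, b1)")
    if (length(msg)) msg else TRUE
  })

#' Multi-channel electropherogram
#'
#' A scan-indexed table of fluorescence intensities (RFU), one column per
#' detector channel, with run metadata. Channel columns are named by dye.
#'
#' @slot values Numeric matrix, scans x channels, finite.
#' @slot metadata List with at least \code{sampleId}, \code{panelId} and
#'   \code{runKind} (\code{"sample"}, \code{"ladder"} or \code{"ils"});
#'   simulated traces also carry the \code{crosstalk} matrix used to mix them.
#'
#' @exportClass Electropherogram
setClass("Electropherogram",
  representation(values = "matrix", metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
    else if (!all(is.finite(object@values)))
      msg <- c(msg, "trace values must be finite")
    if (is.null(object@metadata$runKind) ||
        !object@metadata$runKind %in% c("sample", "ladder", "ils"))
      msg <- c(msg, "metadata$runKind must be one of sample/ladder/ils")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{Electropherogram}
#' @param values scans x channels numeric matrix (columns named by dye).
#' @param sampleId,panelId Identifiers stored in metadata.
#' @param runKind One of \code{"sample"}, \code{"ladder"}, \code{"ils"}.
#' @param ... Further metadata entries (e.g. \code{crosstalk}).
#' @return An \linkS4class{Electropherogram}.
#' @export
Electropherogram <- function(values, sampleId = "sample", panelId = "panel",
                             runKind = "sample", ...) {
  new("Electropherogram", values = values,
      metadata = c(list(sampleId = sampleId, panelId = panelId,
                        runKind = runKind), list(...)))
}

#' Internal-lane-standard assessment
#'
#' Result of evaluating the detected ILS peaks against the expected fragment
#' set under the strict pass criteria: every expected fragment matched exactly
#' once, apex scans strictly increasing, and the maximum absolute sizing-fit
#' residual within the configured bound.
#'
#' @slot status \code{"pass"} or \code{"fail"}.
#' @slot matched \code{data.frame} with columns \code{expectedSize} and
#'   \code{apexScan} (NA scan for unmatched fragments).
#' @slot failureReasons Character vector of criterion labels (empty on pass).
#'
#' @exportClass ILSAssessment
setClass("ILSAssessment",
  representation(status = "character", matched = "data.frame",
                 failureReasons = "character"),
  validity = function(object) {
    if (!object@status %in% c("pass", "fail"))
      return("status must be 'pass' or 'fail'")
    if (object@status == "pass" && anyNA(object@matched$apexScan))
      return("pass requires every expected fragment matched")
    TRUE
  })

#' Scan-to-size calibration
#'
#' A monotone mapping from scan position to fragment size in bases, fitted to
#' the matched ILS fragments. The default method is a global least-squares
#' cubic; the classical Local Southern method is available as an alternative.
#'
#' @slot method \code{"least-squares-cubic"} or \code{"local-southern"}.
#' @slot scans Matched ILS apex scans.
#' @slot sizes Matched ILS fragment sizes (bases).
#' @slot coef Cubic coefficients on the standardised scan coordinate
#'   (empty for local-southern).
#' @slot center,scale Standardisation of the scan axis used by the fit.
#' @slot residuals Per-fragment size residuals in bases.
#' @slot range Calibrated size interval (bases).
#'
#' @exportClass SizeCalibration
setClass("SizeCalibration",
  representation(method = "character", scans = "numeric", sizes = "numeric",
                 coef = "numeric", center = "numeric", scale = "numeric",
                 residuals = "numeric", range = "numeric"),
  validity = function(object) {
    if (!object@method %in% c("least-squares-cubic", "local-southern"))
      return("unknown calibration method")
    if (!all(is.finite(object@residuals)))
      return("residuals must be finite")
    TRUE
  })

#' Calibrated allele bin set
#'
#' Per-locus allele bins whose centres are the sizes observed for the
#' corresponding allelic-ladder fragments in a calibration run.
#'
#' @slot bins \code{data.frame} with columns \code{locus}, \code{allele},
#'   \code{center} (bases), \code{halfWidth} (bases).
#' @slot ladderRunId Identifier of the source ladder run.
#'
#' @exportClass BinSet
setClass("BinSet",
  representation(bins = "data.frame", ladderRunId = "character"),
  validity = function(object) {
    b <- object@bins
    if (!all(c("locus", "allele", "center", "halfWidth") %in% names(b)))
      return("bins must have columns locus, allele, center, halfWidth")
    for (loc in unique(b$locus)) {
      x <- b[b$locus == loc, ]
      x <- x[order(x$center), ]
      if (nrow(x) > 1L) {
        lo <- x$center - x$halfWidth
        hi <- x$center + x$halfWidth
        if (any(lo[-1L] < hi[-nrow(x)]))
          return(sprintf("overlapping bins at locus %s", loc))
      }
    }
    TRUE
  })

#' Per-sample STR profile
#'
#' The assembled calling result for one sample: every allele call with its
#' quality flags, one status row per panel locus, and the profile category.
#' A profile is \code{"full"} when every panel locus has at least one
#' unflagged call, \code{"fail"} when no locus does, and \code{"partial"}
#' otherwise. \code{codisLocusCount} counts called CODIS core loci; partial
#' profiles with fewer than 10 called CODIS loci are below the usual database
#' search threshold.
#'
#' @slot sampleId Sample identifier.
#' @slot calls \code{data.frame} of all allele calls (flagged ones included)
#'   with columns \code{locus}, \code{designation}, \code{size}, \code{height},
#'   \code{flags} (';'-separated, possibly empty).
#' @slot locusStatus \code{data.frame} with columns \code{locus},
#'   \code{status} (\code{called}/\code{dropout}/\code{flagged_only}) and
#'   \code{phr} (NA unless exactly two unflagged calls).
#' @slot category \code{"full"}, \code{"partial"} or \code{"fail"}.
#' @slot codisLocusCount Number of CODIS loci with status \code{called}.
#'
#' @exportClass SampleProfile
setClass("SampleProfile",
  representation(sampleId = "character", calls = "data.frame",
                 locusStatus = "data.frame", category = "character",
                 codisLocusCount = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@category %in% c("full", "partial", "fail"))
      msg <- c(msg, "category must be full/partial/fail")
    st <- object@locusStatus$status
    if (object@category == "full" && !all(st == "called"))
      msg <- c(msg, "full requires every locus called")
    if (object@category == "fail" && any(st == "called"))
      msg <- c(msg, "fail requires no locus called")
    if (length(msg)) msg else TRUE
  })
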