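#' @include AllClasses.R AllGenerics.R utils.R panel.R
NULL

## Greedy monotone assignment of detected ILS peak scans to expected
## fragment sizes. Two passes: an order/normalised first pass, then a refit
## of scan ~ cubic(size) on the matched pairs and re-assignment with a
## tolerance of `tolFrac` of the local inter-fragment scan gap.
matchIlsPeaks <- function(scans, sizes, tolFrac = 0.25) {
  n <- length(sizes)
  m <- length(scans)
  scans <- sort(scans)
  if (m == 0L) return(rep(NA_real_, n))
  if (m == n) {
    matched <- scans
  } else {
    u <- (sizes - sizes[1]) / (sizes[n] - sizes[1])
    v <- (scans - scans[1]) / (scans[m] - scans[1] + 1e-12)
    matched <- rep(NA_real_, n)
    used <- rep(FALSE, m)
    lastIdx <- 0L
    gapU <- diff(u)
    for (i in seq_len(n)) {
      tol <- tolFrac * if (i == 1L) gapU[1] else if (i == n) gapU[n - 1L]
             else min(gapU[i - 1L], gapU[i])
      cand <- which(!used & seq_len(m) > lastIdx & abs(v - u[i]) <= tol)
      if (length(cand)) {
        j <- cand[which.min(abs(v[cand] - u[i]))]
        matched[i] <- scans[j]
        used[j] <- TRUE
        lastIdx <- j
      }
    }
  }
  ok <- !is.na(matched)
  if (sum(ok) >= 4L) {
    fit <- stats::lm(y ~ poly(x, 3, raw = TRUE),
                     data = data.frame(x = sizes[ok], y = matched[ok]))
    pred <- as.numeric(stats::predict(fit, data.frame(x = sizes)))
    gap <- diff(pred)
    matched2 <- rep(NA_real_, n)
    used <- rep(FALSE, m)
    for (i in seq_len(n)) {
      tol <- tolFrac * if (i == 1L) gap[1] else if (i == n) gap[n - 1L]
             else min(gap[i - 1L], gap[i])
      cand <- which(!used & abs(scans - pred[i]) <= tol)
      if (length(cand)) {
        j <- cand[which.min(abs(scans[cand] - pred[i]))]
        matched2[i] <- scans[j]
        used[j] <- TRUE
      }
    }
    matched <- matched2
  }
  matched
}

#' Evaluate the internal lane standard against the strict pass criteria
#'
#' Assigns detected ILS-channel peaks to the expected fragment sizes by
#' greedy monotone matching (assignment tolerance 25 per cent of the local
#' inter-fragment scan gap; spurious peaks between fragments remain
#' unmatched). The run passes only if every expected fragment is matched
#' exactly once, the matched scans are strictly increasing, and the maximum
#' absolute residual of a cubic size fit is within \code{residualBound}.
#' Failure is reported as a status with reasons, not an error.
#'
#' @param peaks Peak table (\code{\link{detectPeaks}}) restricted to the ILS
#'   channel, or a full peak table plus \code{channel}.
#' @param ilsDef An \linkS4class{ILSDefinition}.
#' @param channel Optional detector index to filter \code{peaks} by.
#' @param residualBound Maximum tolerated |fit residual| in bases.
#' @param tolFrac Assignment tolerance as a fraction of the local gap.
#' @param heightFrac ILS fragments are equimolar, so candidate peaks shorter
#'   than this fraction of the median height of the tallest n peaks are
#'   excluded before matching (rejects baseline artifacts and minor spurs).
#' @return An \linkS4class{ILSAssessment}.
#' @export
evaluateIls <- function(peaks, ilsDef, channel = NULL, residualBound = 0.25,
                        tolFrac = 0.25, heightFrac = 0.25) {
  if (!is.null(channel)) peaks <- peaks[peaks$channel == channel, , drop = FALSE]
  sizes <- ilsDef@fragmentSizes
  if (nrow(peaks) > length(sizes)) {
    top <- sort(peaks$height, decreasing = TRUE)[seq_len(length(sizes))]
    peaks <- peaks[peaks$height >= heightFrac * stats::median(top), ,
                   drop = FALSE]
  }
  scans <- sort(peaks$apexScan)
  matched <- matchIlsPeaks(scans, sizes, tolFrac)
  reasons <- character()
  if (anyNA(matched)) {
    miss <- sizes[is.na(matched)]
    reasons <- c(reasons, sprintf("missing fragment: %g", miss))
  }
  ok <- !is.na(matched)
  if (sum(ok) >= 2L && any(diff(matched[ok]) <= 0))
    reasons <- c(reasons, "non-monotone fragment order")
  if (!length(reasons) && length(sizes) >= 4L) {
    fit <- stats::lm(y ~ poly(x, 3, raw = TRUE),
                     data = data.frame(x = matched, y = sizes))
    if (max(abs(stats::residuals(fit))) > residualBound)
      reasons <- c(reasons, sprintf("sizing residual exceeds %g bases",
                                    residualBound))
  }
  new("ILSAssessment",
      status = if (length(reasons)) "fail" else "pass",
      matched = data.frame(expectedSize = sizes, apexScan = matched),
      failureReasons = reasons)
}

## Evaluate the cubic mapping and its derivative.
cubicEval <- function(coef, x) {
  coef[1] + coef[2] * x + coef[3] * x^2 + coef[4] * x^3
}
cubicDeriv <- function(coef, x) {
  coef[2] + 2 * coef[3] * x + 3 * coef[4] * x^2
}

## Local Southern size estimate for scan x from matched (scan, size) pairs:
## fit size = a + b/(scan - c) through each of the two bracketing triplets
## and average the two estimates (single triplet at the ends).
southernTriplet <- function(xs, ys, x) {
  r <- (ys[1] - ys[2]) / (ys[2] - ys[3])
  c0 <- (r * (xs[3] - xs[2]) * xs[1] - (xs[2] - xs[1]) * xs[3]) /
        (r * (xs[3] - xs[2]) - (xs[2] - xs[1]))
  b <- (ys[1] - ys[2]) / (1 / (xs[1] - c0) - 1 / (xs[2] - c0))
  a <- ys[1] - b / (xs[1] - c0)
  a + b / (x - c0)
}

localSouthernSize <- function(scans, sizes, x) {
  n <- length(scans)
  vapply(x, function(xi) {
    i <- findInterval(xi, scans, all.inside = TRUE)
    lo <- if (i >= 2L) southernTriplet(scans[(i - 1L):(i + 1L)],
                                       sizes[(i - 1L):(i + 1L)], xi) else NA_real_
    hi <- if (i + 2L <= n) southernTriplet(scans[i:(i + 2L)],
                                           sizes[i:(i + 2L)], xi) else NA_real_
    mean(c(lo, hi), na.rm = TRUE)
  }, numeric(1))
}

#' Fit a scan-to-size calibration from a passed ILS assessment
#'
#' Default method is a global least-squares cubic of size on scan (matching
#' conventional CE sizing software); the classical Local Southern method is
#' available as an alternative. Per-fragment residuals are reported in bases.
#'
#' @param assessment A passed \linkS4class{ILSAssessment}.
#' @param method \code{"least-squares-cubic"} or \code{"local-southern"}.
#' @return A \linkS4class{SizeCalibration}.
#' @export
fitCalibration <- function(assessment, method = c("least-squares-cubic",
                                                  "local-southern")) {
  method <- match.arg(method)
  if (assessment@status != "pass")
    stop("cannot calibrate: ILS assessment failed (",
         paste(assessment@failureReasons, collapse = "; "), ")")
  scans <- assessment@matched$apexScan
  sizes <- assessment@matched$expectedSize
  center <- mean(sizes)
  scale <- stats::sd(sizes)
  if (method == "least-squares-cubic") {
    # electrophoretic mobility is modelled as a cubic in fragment size
    # (the same family the migration follows); sizes are recovered by
    # inverting the monotone fitted curve. The size axis is standardised
    # to keep the cubic well conditioned.
    z <- (sizes - center) / scale
    fit <- stats::lm(y ~ poly(x, 3, raw = TRUE),
                     data = data.frame(x = z, y = scans))
    cf <- as.numeric(stats::coef(fit))
    d <- cubicDeriv(cf, seq(min(z), max(z), length.out = 200))
    if (any(d <= 0))
      stop("fitted calibration is not monotone on the calibrated interval")
    cal <- new("SizeCalibration", method = method, scans = scans,
               sizes = sizes, coef = cf, center = center, scale = scale,
               residuals = numeric(length(sizes)), range = range(sizes))
    cal@residuals <- predictSize(cal, scans) - sizes
    return(cal)
  }
  resid <- localSouthernSize(scans, sizes, scans) - sizes
  resid[!is.finite(resid)] <- 0
  new("SizeCalibration", method = method, scans = scans, sizes = sizes,
      coef = numeric(), center = center, scale = scale, residuals = resid,
      range = range(sizes))
}

#' Convert scan positions to sizes under a calibration
#'
#' @param calibration A \linkS4class{SizeCalibration}.
#' @param scans Numeric scan positions.
#' @return Sizes in bases.
#' @export
predictSize <- function(calibration, scans) {
  if (calibration@method == "least-squares-cubic") {
    cf <- calibration@coef
    zKnots <- (calibration@sizes - calibration@center) / calibration@scale
    # Newton inversion of the monotone scan(size) cubic, started from a
    # linear interpolation of the matched fragments
    z <- stats::approx(calibration@scans, zKnots, xout = scans,
                       rule = 2)$y
    for (k in 1:8) {
      f <- cubicEval(cf, z) - scans
      z <- z - f / cubicDeriv(cf, z)
    }
    z * calibration@scale + calibration@center
  } else {
    localSouthernSize(calibration@scans, calibration@sizes, scans)
  }
}

## d size / d scan of the mapping (numeric for local-southern).
mappingSlope <- function(calibration, scans) {
  if (calibration@method == "least-squares-cubic") {
    z <- (predictSize(calibration, scans) - calibration@center) /
      calibration@scale
    calibration@scale / cubicDeriv(calibration@coef, z)
  } else {
    h <- 0.5
    (predictSize(calibration, scans + h) -
     predictSize(calibration, scans - h)) / (2 * h)
  }
}

#' Size detected peaks
#'
#' Maps each peak's apex scan to a fragment size in bases and converts its
#' FWHM to bases through the local slope of the mapping. Peaks outside the
#' sizing range are kept but marked out-of-range.
#'
#' @param peaks Peak table from \code{\link{detectPeaks}}.
#' @param calibration A \linkS4class{SizeCalibration}.
#' @param sizingRange Length-2 numeric (bases); peaks outside are flagged.
#' @return The peak table with added columns \code{size} (bases, reported to
#'   0.01 base), \code{fwhmBases} and \code{inRange}.
#' @export
sizePeaks <- function(peaks, calibration, sizingRange = calibration@range) {
  if (nrow(peaks) == 0L) {
    peaks$size <- numeric()
    peaks$fwhmBases <- numeric()
    peaks$inRange <- logical()
    return(peaks)
  }
  size <- predictSize(calibration, peaks$apexScan)
  slope <- mappingSlope(calibration, peaks$apexScan)
  peaks$size <- round(size, 2)
  peaks$fwhmBases <- peaks$fwhmScans * slope
  peaks$inRange <- size >= sizingRange[1] & size <= sizingRange[2]
  peaks
}

#' Condition, detect, and size one trace in a single step
#'
#' Runs the standard chain on a raw trace: baseline correction, colour
#' correction, peak detection, ILS evaluation, calibration fit, and peak
#' sizing.
#'
#' @param trace Raw \linkS4class{Electropherogram}.
#' @param panel A \linkS4class{PanelDefinition}.
#' @param crosstalk Optional mixing matrix (defaults to trace metadata).
#' @param method Calibration method, see \code{\link{fitCalibration}}.
#' @param minFwhmScans Peak-width floor passed to \code{\link{detectPeaks}}.
#' @return List with elements \code{trace} (conditioned), \code{peaks}
#'   (sized peak table), \code{assessment} (\linkS4class{ILSAssessment}) and
#'   \code{calibration} (\linkS4class{SizeCalibration}, NULL on ILS fail).
#' @export
sizeTrace <- function(trace, panel, crosstalk = NULL,
                      method = "least-squares-cubic", minFwhmScans = 2) {
  cond <- conditionTrace(trace, crosstalk)
  peaks <- detectPeaks(cond, minHeight = panel@analyticalThreshold / 2,
                       minFwhmScans = minFwhmScans)
  ilsCh <- dyeIndex(panel)[panel@ils@dye]
  assessment <- evaluateIls(peaks, panel@ils, channel = ilsCh)
  if (assessment@status != "pass")
    return(list(trace = cond, peaks = NULL, assessment = assessment,
                calibration = NULL))
  calibration <- fitCalibration(assessment, method)
  sized <- sizePeaks(peaks[peaks$channel != ilsCh, , drop = FALSE],
                     calibration, panel@sizingRange)
  list(trace = cond, peaks = sized, assessment = assessment,
       calibration = calibration)
}
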