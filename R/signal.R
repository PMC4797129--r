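#' @include AllClasses.R AllGenerics.R utils.R
NULL

## Windowed low-percentile baseline estimate for one channel: 10th percentile
## over non-overlapping blocks, linearly interpolated between block centres.
## Robust to sparse peaks (peaks only raise the upper tail of a block).
blockBaseline <- function(x, window = 160L, p = 0.1) {
  n <- length(x)
  half <- max(1L, window %/% 2L)
  starts <- seq(1L, n, by = half)
  centers <- pmin(starts + half / 2, n)
  q <- vapply(starts, function(s)
    stats::quantile(x[s:min(n, s + half - 1L)], p, names = FALSE), numeric(1))
  stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
}

#' Set the trace baseline to zero
#'
#' Estimates a slowly varying per-channel baseline by a windowed
#' 10th-percentile filter (window about 20 times a typical peak FWHM) and
#' subtracts it; a residual median correction then re-centres the non-peak
#' signal at zero. Idempotent within tolerance.
#'
#' @param trace An \linkS4class{Electropherogram}.
#' @param window Baseline window in scans.
#' @return A baseline-corrected \linkS4class{Electropherogram}.
#' @export
correctBaseline <- function(trace, window = 160L) {
  v <- trace@values
  for (j in seq_len(ncol(v))) {
    x <- v[, j] - blockBaseline(v[, j], window)
    v[, j] <- x - stats::median(x)
  }
  new("Electropherogram", values = v, metadata = trace@metadata)
}

#' Spectral colour correction
#'
#' Unmixes dye crosstalk: for each scan the linear system
#' \code{crosstalk \%*\% pure = observed} is solved so that each output
#' channel estimates a single dye's signal.
#'
#' @param trace An \linkS4class{Electropherogram} (observed, mixed channels).
#' @param crosstalk Square dye-to-detector mixing matrix; defaults to the
#'   matrix recorded in the trace metadata, or the identity if none.
#' @return A colour-corrected \linkS4class{Electropherogram}.
#' @export
colorCorrect <- function(trace, crosstalk = NULL) {
  if (is.null(crosstalk)) crosstalk <- trace@metadata$crosstalk
  if (is.null(crosstalk)) crosstalk <- diag(ncol(trace@values))
  if (nrow(crosstalk) != ncol(trace@values))
    stop("crosstalk dimension does not match channel count")
  inv <- tryCatch(solve(crosstalk),
                  error = function(e) stop("singular crosstalk matrix"))
  v <- trace@values %*% t(inv)
  colnames(v) <- colnames(trace@values)
  new("Electropherogram", values = v, metadata = trace@metadata)
}

## Local maxima indices of a vector, with plateau runs collapsed to their
## midpoint. Returns a data.frame idx (integer apex sample), plateauLen.
localMaxima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(data.frame(idx = integer(), plateauLen = integer()))
  inner <- 2:(k - 1L)
  isMax <- r$values[inner] > r$values[inner - 1L] &
           r$values[inner] > r$values[inner + 1L]
  which <- inner[isMax]
  data.frame(idx = as.integer(floor((starts[which] + ends[which]) / 2)),
             plateauLen = r$lengths[which])
}

## Half-height crossing positions around apex i at level h/2, by linear
## interpolation; NA when the trace never falls below half height on a side.
halfCrossings <- function(x, i, half) {
  n <- length(x)
  l <- i
  while (l > 1L && x[l] > half) l <- l - 1L
  r <- i
  while (r < n && x[r] > half) r <- r + 1L
  left <- if (x[l] > half) NA_real_
          else l + (half - x[l]) / (x[l + 1L] - x[l])
  right <- if (x[r] > half) NA_real_
           else (r - 1L) + (half - x[r - 1L]) / (x[r] - x[r - 1L])
  c(left, right)
}

#' Detect peaks in a conditioned trace
#'
#' Finds local maxima above a height threshold in every channel, refines each
#' apex by 3-point parabolic interpolation (plateau maxima use the plateau
#' midpoint), measures FWHM by half-height crossings with linear
#' interpolation, and integrates the area between the bounding valleys.
#' Flat-topped maxima whose plateau exceeds 3 scans are flagged as saturated
#' (clipped).
#'
#' @param trace A baseline- and colour-corrected
#'   \linkS4class{Electropherogram}.
#' @param minHeight Minimum apex height (RFU).
#' @param minFwhmScans Minimum FWHM (scans); narrower maxima (noise spikes)
#'   are discarded.
#' @return \code{data.frame} with columns \code{channel}, \code{apexScan}
#'   (0-based, sub-scan), \code{height}, \code{area}, \code{fwhmScans},
#'   \code{saturated}; empty when nothing qualifies.
#' @export
detectPeaks <- function(trace, minHeight = 50, minFwhmScans = 2) {
  v <- trace@values
  out <- vector("list", ncol(v))
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    lm <- localMaxima(x)
    lm <- lm[x[lm$idx] >= minHeight, , drop = FALSE]
    if (nrow(lm) == 0L) { out[[j]] <- emptyPeaks(); next }
    rows <- lapply(seq_len(nrow(lm)), function(k) {
      i <- lm$idx[k]
      plateau <- lm$plateauLen[k]
      h <- x[i]
      if (plateau == 1L && i > 1L && i < length(x)) {
        denom <- x[i - 1L] - 2 * h + x[i + 1L]
        delta <- if (denom < 0) 0.5 * (x[i - 1L] - x[i + 1L]) / denom else 0
        delta <- max(-0.5, min(0.5, delta))
        apex <- i + delta
        h <- h - 0.25 * (x[i - 1L] - x[i + 1L]) * delta
      } else apex <- i  # plateau midpoint
      hc <- halfCrossings(x, i, h / 2)
      if (anyNA(hc)) return(NULL)
      fwhm <- hc[2] - hc[1]
      lo <- max(1L, floor(hc[1] - 2 * fwhm))
      hi <- min(length(x), ceiling(hc[2] + 2 * fwhm))
      data.frame(channel = j, apexScan = apex - 1, height = h,
                 area = sum(pmax(x[lo:hi], 0)), fwhmScans = fwhm,
                 saturated = plateau > 3L)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    pk <- if (length(rows)) do.call(rbind, rows) else emptyPeaks()
    out[[j]] <- pk[pk$fwhmScans >= minFwhmScans, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Condition a raw trace
#'
#' Convenience chain: \code{\link{correctBaseline}} then
#' \code{\link{colorCorrect}}.
#'
#' @param trace Raw \linkS4class{Electropherogram}.
#' @param crosstalk Optional mixing matrix (defaults to trace metadata).
#' @return Conditioned \linkS4class{Electropherogram}.
#' @export
conditionTrace <- function(trace, crosstalk = NULL) {
  colorCorrect(correctBaseline(trace), crosstalk)
}
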