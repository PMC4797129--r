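#' @include AllClasses.R AllGenerics.R utils.R panel.R sizing.R
NULL

#' Calibrate allele bins from a sized ladder run
#'
#' Matches every expected allelic-ladder fragment to a sized peak in the
#' locus dye channel within \code{binHalfWidth} of its nominal size and sets
#' the bin centre to the observed size. Any expected fragment without a match
#' (or matched twice) fails ladder evaluation with the fragment named.
#'
#' @param ladderPeaks Sized peak table (\code{\link{sizePeaks}}) from a
#'   ladder run whose ILS evaluation passed.
#' @param panel A \linkS4class{PanelDefinition}.
#' @param ladderRunId Identifier recorded in the bin set.
#' @return A \linkS4class{BinSet} with one bin per ladder fragment.
#' @export
calibrateBins <- function(ladderPeaks, panel, ladderRunId = "ladder") {
  lt <- ladderTable(panel)
  centers <- numeric(nrow(lt))
  taken <- rep(FALSE, nrow(ladderPeaks))
  for (i in seq_len(nrow(lt))) {
    cand <- which(!taken & ladderPeaks$channel == lt$channel[i] &
                  abs(ladderPeaks$size - lt$size[i]) <= panel@binHalfWidth)
    if (length(cand) == 0L)
      stop(sprintf("ladder evaluation failed: no peak for %s allele %s (%g bases)",
                   lt$locus[i], lt$allele[i], lt$size[i]))
    j <- cand[which.min(abs(ladderPeaks$size[cand] - lt$size[i]))]
    centers[i] <- ladderPeaks$size[j]
    taken[j] <- TRUE
  }
  new("BinSet",
      bins = data.frame(locus = lt$locus, allele = lt$allele,
                        center = centers, halfWidth = panel@binHalfWidth,
                        stringsAsFactors = FALSE),
      ladderRunId = ladderRunId)
}

#' Assign allele designations to sized sample peaks
#'
#' Locus membership is determined by dye channel and size span (the span of
#' the locus ladder, extended one repeat unit downward to keep stutter with
#' its parent locus). A peak whose size falls inside a calibrated bin gets
#' that bin's designation; a peak inside a locus span but outside every bin
#' is called off-ladder (\code{OL}). Peaks outside all locus spans, or
#' outside the sizing range, are dropped.
#'
#' @param samplePeaks Sized peak table from \code{\link{sizePeaks}}.
#' @param bins A \linkS4class{BinSet}.
#' @param panel A \linkS4class{PanelDefinition}.
#' @return Call table: \code{locus}, \code{designation}, \code{size},
#'   \code{height}, \code{flags} (\code{"off_ladder"} or
#'   \code{"saturated"} may be pre-set; otherwise empty).
#' @export
assignAlleles <- function(samplePeaks, bins, panel) {
  spans <- locusSizeSpans(panel)
  idx <- dyeIndex(panel)
  spans$channel <- unname(idx[spans$dye])
  pk <- samplePeaks[samplePeaks$inRange, , drop = FALSE]
  calls <- emptyCalls()
  for (i in seq_len(nrow(pk))) {
    sp <- spans[spans$channel == pk$channel[i] &
                spans$lower <= pk$size[i] & spans$upper >= pk$size[i], ]
    if (nrow(sp) == 0L) next
    locus <- sp$locus[1L]
    b <- bins@bins[bins@bins$locus == locus, ]
    hit <- which(abs(b$center - pk$size[i]) <= b$halfWidth)
    flags <- if (isTRUE(pk$saturated[i])) "saturated" else ""
    if (length(hit)) {
      desig <- b$allele[hit[which.min(abs(b$center[hit] - pk$size[i]))]]
    } else {
      desig <- "OL"
      flags <- addFlag(flags, "off_ladder")
    }
    calls <- rbind(calls, data.frame(
      locus = locus, designation = desig, size = pk$size[i],
      height = pk$height[i], flags = flags, stringsAsFactors = FALSE))
  }
  rownames(calls) <- NULL
  calls
}

#' Peak height ratio of a heterozygous pair
#'
#' Ratio of the weaker to the stronger allele signal, in (0, 1]. Scale
#' invariant.
#'
#' @param heights Numeric vector of exactly two peak heights.
#' @return The ratio \code{min/max}, or \code{NA} when not given exactly two
#'   heights (not-applicable signal).
#' @examples
#' computePhr(c(700, 1000))  # 0.7
#' @export
computePhr <- function(heights) {
  if (length(heights) != 2L || any(heights <= 0)) return(NA_real_)
  min(heights) / max(heights)
}

#' Fire the expert-system quality rules on assigned calls
#'
#' Rules are applied in a fixed order. (1) Analytical threshold: calls below
#' \code{analyticalThreshold} RFU are flagged \code{below_threshold}.
#' (2) Stutter: a call one repeat unit (within 0.5 bases) below a taller
#' unflagged call of the same locus, at a height ratio at or below the locus
#' stutter threshold, is flagged \code{stutter_filtered}. (3) Peak height
#' ratio: when exactly two unflagged calls remain at a locus and their ratio
#' is below \code{phrThreshold}, the weaker call is flagged
#' \code{phr_imbalance}; when more than two remain, all are flagged
#' \code{phr_imbalance} for review. Loci whose calls are all flagged get
#' status \code{flagged_only}; loci with no calls get status \code{dropout}.
#' The sex-typing locus participates in calling but its PHR is excluded from
#' aggregation by \code{\link{phrReport}}.
#'
#' @param calls Call table from \code{\link{assignAlleles}}.
#' @param panel A \linkS4class{PanelDefinition}.
#' @return List with \code{calls} (flag column updated) and
#'   \code{locusStatus} (\code{data.frame}: \code{locus}, \code{status},
#'   \code{phr}).
#' @export
applyRules <- function(calls, panel) {
  at <- panel@analyticalThreshold
  # (1) analytical threshold
  for (i in seq_len(nrow(calls)))
    if (calls$height[i] < at)
      calls$flags[i] <- addFlag(calls$flags[i], "below_threshold")
  # (2) stutter, judged against the tallest unflagged same-locus call one
  # repeat unit larger
  for (l in panel@loci) {
    li <- which(calls$locus == l@name)
    if (length(li) < 2L) next
    for (i in li) {
      parents <- li[isUnflagged(calls$flags[li]) &
                    abs(calls$size[li] - (calls$size[i] + l@repeatUnit)) <= 0.5 &
                    calls$height[li] > calls$height[i]]
      if (!length(parents)) next
      p <- parents[which.max(calls$height[parents])]
      if (calls$height[i] / calls$height[p] <= l@stutterThreshold)
        calls$flags[i] <- addFlag(calls$flags[i], "stutter_filtered")
    }
  }
  # (3) heterozygote peak height ratio
  lnames <- vapply(panel@loci, function(l) l@name, character(1))
  status <- data.frame(locus = lnames, status = "dropout", phr = NA_real_,
                       stringsAsFactors = FALSE)
  for (k in seq_along(lnames)) {
    li <- which(calls$locus == lnames[k])
    if (!length(li)) next
    surv <- li[isUnflagged(calls$flags[li])]
    if (length(surv) == 2L) {
      phr <- computePhr(calls$height[surv])
      if (phr < panel@phrThreshold) {
        weaker <- surv[which.min(calls$height[surv])]
        calls$flags[weaker] <- addFlag(calls$flags[weaker], "phr_imbalance")
      } else status$phr[k] <- phr
    } else if (length(surv) > 2L) {
      for (i in surv)
        calls$flags[i] <- addFlag(calls$flags[i], "phr_imbalance")
    }
    surv <- li[isUnflagged(calls$flags[li])]
    status$status[k] <- if (length(surv)) "called" else "flagged_only"
  }
  list(calls = calls, locusStatus = status)
}

#' Assemble a sample profile from locus results
#'
#' Applies the profile-category rules: \code{full} when every panel locus has
#' status \code{called}, \code{fail} when none does, \code{partial}
#' otherwise. \code{codisLocusCount} counts CODIS core loci with status
#' \code{called}; partial profiles with fewer than 10 are annotated as below
#' the usual database search threshold.
#'
#' @param ruleResult List from \code{\link{applyRules}}.
#' @param panel A \linkS4class{PanelDefinition}.
#' @param sampleId Sample identifier.
#' @return A \linkS4class{SampleProfile}.
#' @export
assembleProfile <- function(ruleResult, panel, sampleId = "sample") {
  status <- ruleResult$locusStatus
  lnames <- vapply(panel@loci, function(l) l@name, character(1))
  if (!setequal(status$locus, lnames) || nrow(status) != length(lnames))
    stop("locus results must cover every panel locus exactly once")
  called <- status$status == "called"
  category <- if (all(called)) "full" else if (!any(called)) "fail" else "partial"
  codis <- vapply(panel@loci, function(l) l@isCodis, logical(1))
  codisCount <- sum(called[match(lnames[codis], status$locus)])
  new("SampleProfile", sampleId = sampleId, calls = ruleResult$calls,
      locusStatus = status, category = category,
      codisLocusCount = as.integer(codisCount))
}

#' Analyse one sample trace end to end
#'
#' Full expert-system chain for a raw sample trace against a calibrated bin
#' set: condition, detect, evaluate ILS, size, assign alleles, fire the
#' quality rules and assemble the profile.
#'
#' @param trace Raw sample \linkS4class{Electropherogram}.
#' @param bins A \linkS4class{BinSet} from \code{\link{calibrateBins}}.
#' @param panel A \linkS4class{PanelDefinition}.
#' @param crosstalk Optional mixing matrix (defaults to trace metadata).
#' @param sampleId Sample identifier (defaults to the trace metadata).
#' @return List with \code{profile} (\linkS4class{SampleProfile}),
#'   \code{peaks} (sized peak table), \code{assessment} and
#'   \code{calibration}; on ILS failure \code{profile} is \code{NULL}.
#' @export
analyzeSample <- function(trace, bins, panel, crosstalk = NULL,
                          sampleId = traceMetadata(trace)$sampleId) {
  sz <- sizeTrace(trace, panel, crosstalk)
  if (sz$assessment@status != "pass")
    return(c(sz, list(profile = NULL)))
  calls <- assignAlleles(sz$peaks, bins, panel)
  rr <- applyRules(calls, panel)
  profile <- assembleProfile(rr, panel, sampleId)
  c(sz, list(profile = profile))
}

#' Calibrate bins from a raw ladder trace
#'
#' Convenience wrapper: condition, size and bin-calibrate a ladder run.
#'
#' @param ladderTrace Raw ladder \linkS4class{Electropherogram}.
#' @param panel A \linkS4class{PanelDefinition}.
#' @param crosstalk Optional mixing matrix.
#' @return A \linkS4class{BinSet}.
#' @export
calibrateLadder <- function(ladderTrace, panel, crosstalk = NULL) {
  sz <- sizeTrace(ladderTrace, panel, crosstalk)
  if (sz$assessment@status != "pass")
    stop("ladder run failed ILS evaluation: ",
         paste(sz$assessment@failureReasons, collapse = "; "))
  calibrateBins(sz$peaks, panel,
                ladderRunId = traceMetadata(ladderTrace)$sampleId)
}
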