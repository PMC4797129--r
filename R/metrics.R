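#' @include AllClasses.R AllGenerics.R utils.R panel.R calling.R
NULL

#' Sizing precision across repeated ladder injections
#'
#' Precision is the sample standard deviation (n-1 denominator) of the
#' calibrated size of each allelic-ladder fragment across runs. The report
#' passes when the maximum per-fragment SD is below the acceptance bound
#' (default 0.16 bases).
#'
#' @param runs List of per-run fragment tables, each a \code{data.frame} with
#'   columns \code{locus}, \code{allele}, \code{size}; all runs must cover
#'   the identical fragment set.
#' @param bound Acceptance bound in bases.
#' @return List of class \code{"PrecisionReport"}: \code{perFragment}
#'   (\code{locus}, \code{allele}, \code{sd}), \code{maxSd}, \code{bound},
#'   \code{pass}.
#' @seealso \code{\link{ladderPrecision}} to generate and size the runs.
#' @export
precisionReport <- function(runs, bound = 0.16) {
  if (length(runs) < 2L) stop("precision needs at least 2 runs")
  key <- function(r) paste(r$locus, r$allele, sep = "/")
  k0 <- key(runs[[1L]])
  for (r in runs[-1L])
    if (!identical(sort(key(r)), sort(k0)))
      stop("runs cover different fragment sets")
  sizes <- vapply(runs, function(r) r$size[match(k0, key(r))],
                  numeric(length(k0)))
  sizes <- matrix(sizes, nrow = length(k0))
  sds <- apply(sizes, 1L, stats::sd)
  out <- list(perFragment = data.frame(locus = runs[[1L]]$locus,
                                       allele = runs[[1L]]$allele, sd = sds,
                                       stringsAsFactors = FALSE),
              maxSd = max(sds), bound = bound, pass = max(sds) < bound)
  class(out) <- "PrecisionReport"
  out
}

#' @export
print.PrecisionReport <- function(x, ...) {
  cat(sprintf("PrecisionReport: %d fragments, max SD %.4f bases (bound %g) -> %s\n",
              nrow(x$perFragment), x$maxSd, x$bound,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Simulate, size and collect repeated ladder injections
#'
#' Runs \code{nRuns} independent simulated ladder injections (seeds derived
#' from \code{seed}), sizes each through the full conditioning and ILS
#' calibration chain, and returns one fragment-size table per run, suitable
#' for \code{\link{precisionReport}}.
#'
#' @param panel A \linkS4class{PanelDefinition}.
#' @param params A \linkS4class{SimulationParams} (its seed is overridden per
#'   run).
#' @param nRuns Number of injections.
#' @param seed Base seed for the run seeds.
#' @return List of \code{data.frame}s (\code{locus}, \code{allele},
#'   \code{size}).
#' @export
ladderPrecision <- function(panel, params, nRuns = 20L, seed = 1L) {
  lt <- ladderTable(panel)
  lapply(seq_len(nRuns), function(k) {
    params@seed <- deriveSeed(seed, k)
    tr <- simulateLadderRun(panel, params, sampleId = sprintf("ladder%02d", k))
    sz <- sizeTrace(tr, panel)
    if (sz$assessment@status != "pass")
      stop("ladder injection ", k, " failed ILS evaluation")
    obs <- numeric(nrow(lt))
    pk <- sz$peaks
    for (i in seq_len(nrow(lt))) {
      cand <- which(pk$channel == lt$channel[i] &
                    abs(pk$size - lt$size[i]) <= 1.5)
      if (!length(cand))
        stop(sprintf("run %d: fragment %s/%s not recovered", k,
                     lt$locus[i], lt$allele[i]))
      obs[i] <- pk$size[cand[which.min(abs(pk$size[cand] - lt$size[i]))]]
    }
    data.frame(locus = lt$locus, allele = lt$allele, size = obs,
               stringsAsFactors = FALSE)
  })
}

#' Peak resolution R
#'
#' Baseline-width resolution. For two peaks,
#' \code{R = (S2 - S1) / (0.5 * (Wb1 + Wb2))} where the baseline width of a
#' Gaussian is \code{Wb = 2 * FWHM / sqrt(2 ln 2) = 4 sigma}. For a single
#' peak, R is evaluated against a hypothetical twin of equal width one base
#' away: \code{R = 1 / Wb}. R above 0.2 corresponds to single-base
#' resolution under this convention.
#'
#' @param fwhmBases FWHM in bases; one value (single-peak convention) or two.
#' @param sizes Optional two sizes (bases) for the two-peak form.
#' @return The resolution value R.
#' @examples
#' resolutionR(2 * sqrt(2 * log(2)) * 0.25)  # sigma 0.25 bases -> R = 1
#' @export
resolutionR <- function(fwhmBases, sizes = NULL) {
  if (any(fwhmBases <= 0)) stop("peak width must be positive")
  wb <- 2 * fwhmBases / sqrt(2 * log(2))
  if (is.null(sizes)) {
    if (length(fwhmBases) != 1L)
      stop("single-peak form takes one width")
    1 / wb
  } else {
    if (length(sizes) != 2L || length(fwhmBases) != 2L)
      stop("pair form takes two sizes and two widths")
    abs(diff(sizes)) / (0.5 * sum(wb))
  }
}

#' Resolution profile of a sized run
#'
#' Computes the single-peak resolution R for every sized peak inside a size
#' window and reports the per-peak values and the minimum.
#'
#' @param sizedPeaks Sized peak table (\code{\link{sizePeaks}}).
#' @param window Length-2 size window in bases (default 100-500).
#' @return List of class \code{"ResolutionReport"}: \code{perPeak}
#'   (\code{size}, \code{r}), \code{minR}.
#' @export
resolutionReport <- function(sizedPeaks, window = c(100, 500)) {
  pk <- sizedPeaks[sizedPeaks$size >= window[1] &
                   sizedPeaks$size <= window[2] &
                   sizedPeaks$fwhmBases > 0, , drop = FALSE]
  if (nrow(pk) == 0L) stop("no peaks inside the evaluation window")
  r <- vapply(pk$fwhmBases, resolutionR, numeric(1))
  out <- list(perPeak = data.frame(size = pk$size, r = r), minR = min(r))
  class(out) <- "ResolutionReport"
  out
}

#' @export
print.ResolutionReport <- function(x, ...) {
  cat(sprintf("ResolutionReport: %d peaks, min R %.3f\n",
              nrow(x$perPeak), x$minR))
  invisible(x)
}

#' Per-locus peak-height-ratio statistics
#'
#' Aggregates the heterozygote PHR over profiles, by locus, using only loci
#' where a PHR is present (exactly two unflagged calls). The sex-typing
#' locus (\code{Amelogenin}) is excluded because its ratio is sex-dependent.
#'
#' @param profiles List of \linkS4class{SampleProfile} objects.
#' @param excludeLoci Loci excluded from aggregation.
#' @return \code{data.frame}: \code{locus}, \code{n}, \code{mean}, \code{sd}
#'   (SD is NA with a single observation); zero rows when no heterozygous
#'   locus was observed.
#' @export
phrReport <- function(profiles, excludeLoci = "Amelogenin") {
  obs <- do.call(rbind, lapply(profiles, function(p) {
    st <- locusStatus(p)
    st[!is.na(st$phr) & !(st$locus %in% excludeLoci), c("locus", "phr")]
  }))
  if (is.null(obs) || nrow(obs) == 0L)
    return(data.frame(locus = character(), n = integer(), mean = numeric(),
                      sd = numeric(), stringsAsFactors = FALSE))
  agg <- do.call(rbind, lapply(split(obs$phr, obs$locus), function(v)
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_)))
  data.frame(locus = rownames(agg), agg, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Concordance of a called profile against a reference genotype
#'
#' Each reference allele designation is counted as assessed. A matching
#' unflagged call is concordant; a missing one is a dropout and counts as
#' discordant; an unflagged call with no reference counterpart is a drop-in
#' (tracked but not assessed). The percentage is reported to 3 decimals.
#'
#' @param profile A \linkS4class{SampleProfile}.
#' @param reference Genotype (named list locus -> designations) covering the
#'   panel loci.
#' @return A \code{ConcordanceTally} list: \code{nAssessed},
#'   \code{nConcordant}, \code{nDiscordant}, \code{nDropout},
#'   \code{nDropin}, \code{percentConcordant}.
#' @export
concordance <- function(profile, reference) {
  calls <- profileCalls(profile)
  calls <- calls[isUnflagged(calls$flags), , drop = FALSE]
  nA <- 0L; nC <- 0L; nDO <- 0L; nDI <- 0L
  for (locus in names(reference)) {
    ref <- reference[[locus]]
    got <- calls$designation[calls$locus == locus]
    for (a in ref) {
      nA <- nA + 1L
      if (a %in% got) nC <- nC + 1L else nDO <- nDO + 1L
    }
    nDI <- nDI + sum(!(got %in% ref))
  }
  concordanceTally(nA, nC, nDropout = nDO, nDropin = nDI)
}

#' Build a concordance tally from counts
#'
#' Dropouts count as discordant, consistent with the arithmetic
#' \code{assessed = concordant + discordant}; the percentage is
#' \code{100 * concordant / assessed}, reported to 3 decimals.
#'
#' @param nAssessed Total alleles assessed.
#' @param nConcordant Concordant alleles.
#' @param nDropout Dropouts among the discordant.
#' @param nDropin Drop-ins observed (not assessed).
#' @return List of class \code{"ConcordanceTally"}.
#' @examples
#' concordanceTally(8094, 8091)$percentConcordant  # 99.963
#' @export
concordanceTally <- function(nAssessed, nConcordant, nDropout = 0L,
                             nDropin = 0L) {
  if (nConcordant > nAssessed) stop("concordant cannot exceed assessed")
  out <- list(nAssessed = as.integer(nAssessed),
              nConcordant = as.integer(nConcordant),
              nDiscordant = as.integer(nAssessed - nConcordant),
              nDropout = as.integer(nDropout),
              nDropin = as.integer(nDropin),
              percentConcordant = if (nAssessed > 0)
                round(100 * nConcordant / nAssessed, 3) else NA_real_)
  class(out) <- "ConcordanceTally"
  out
}

#' Combine concordance tallies
#'
#' @param tallies List of \code{ConcordanceTally} objects.
#' @return A pooled \code{ConcordanceTally}.
#' @export
combineTallies <- function(tallies) {
  concordanceTally(sum(vapply(tallies, `[[`, integer(1), "nAssessed")),
                   sum(vapply(tallies, `[[`, integer(1), "nConcordant")),
                   sum(vapply(tallies, `[[`, integer(1), "nDropout")),
                   sum(vapply(tallies, `[[`, integer(1), "nDropin")))
}

#' @export
print.ConcordanceTally <- function(x, ...) {
  cat(sprintf("ConcordanceTally: %d/%d concordant (%.3f%%), %d dropout, %d dropin\n",
              x$nConcordant, x$nAssessed, x$percentConcordant,
              x$nDropout, x$nDropin))
  invisible(x)
}

#' Tabulate a reproducibility status grid
#'
#' Collapses a replicate-by-sample-type grid of profile status codes into
#' counts: \code{Y} (full profile) -> full, \code{Y*} (partial, concordant)
#' -> partial, \code{F} (no profile) -> fail. \code{nProfiles} is
#' full + partial.
#'
#' @param grid \code{data.frame} or matrix of status codes (a leading
#'   \code{replicate} column is ignored), or a path to such a CSV.
#' @return List of class \code{"ReproducibilityCounts"}: \code{nFull},
#'   \code{nPartial}, \code{nFail}, \code{nProfiles}.
#' @export
tabulateStatusGrid <- function(grid) {
  if (is.character(grid) && !is.matrix(grid) && length(grid) == 1L)
    grid <- utils::read.csv(grid, check.names = FALSE)
  if (is.data.frame(grid)) {
    grid <- grid[, setdiff(names(grid), "replicate"), drop = FALSE]
    codes <- unlist(grid, use.names = FALSE)
  } else codes <- as.vector(grid)
  codes <- as.character(codes)
  bad <- setdiff(unique(codes), c("Y", "Y*", "F"))
  if (length(bad)) stop("unknown status code: ", paste(bad, collapse = ", "))
  out <- list(nFull = sum(codes == "Y"), nPartial = sum(codes == "Y*"),
              nFail = sum(codes == "F"))
  out$nProfiles <- out$nFull + out$nPartial
  class(out) <- "ReproducibilityCounts"
  out
}

#' @export
print.ReproducibilityCounts <- function(x, ...) {
  cat(sprintf("ReproducibilityCounts: %d full, %d partial, %d fail (%d profiles)\n",
              x$nFull, x$nPartial, x$nFail, x$nProfiles))
  invisible(x)
}

#' Sensitivity curve over template mass
#'
#' Monte-Carlo end-to-end simulation: at each template mass, \code{nReps}
#' random genotypes are simulated, analysed against a calibrated ladder, and
#' summarised as the mean number of called loci and the fractions of
#' full/partial/fail profiles. Reproducible from \code{seed}.
#'
#' @param templateMasses Vector of template masses (pg), all positive.
#' @param nReps Replicates per mass.
#' @param panel A \linkS4class{PanelDefinition}.
#' @param params A \linkS4class{SimulationParams} template (mass and seed are
#'   overridden).
#' @param seed Base seed.
#' @return \code{data.frame}: \code{templateMass}, \code{meanCalledLoci},
#'   \code{meanCodisLoci}, \code{fracFull}, \code{fracPartial},
#'   \code{fracFail}.
#' @export
sensitivityCurve <- function(templateMasses, nReps, panel, params,
                             seed = 1L) {
  stopifnot(all(templateMasses > 0), nReps >= 1L)
  ladderParams <- params
  ladderParams@seed <- deriveSeed(seed, 0L)
  bins <- calibrateLadder(simulateLadderRun(panel, ladderParams), panel)
  rows <- lapply(seq_along(templateMasses), function(mi) {
    mass <- templateMasses[mi]
    cats <- character(nReps)
    nCalled <- integer(nReps)
    nCodis <- integer(nReps)
    for (r in seq_len(nReps)) {
      s <- deriveSeed(seed, mi * 1000L + r)
      g <- sampleGenotype(panel, seed = s)
      p <- params
      p@templateMass <- mass
      p@seed <- deriveSeed(s, 1L)
      res <- analyzeSample(simulateSample(g, panel, p), bins, panel)
      if (is.null(res$profile)) { cats[r] <- "fail"; next }
      cats[r] <- profileCategory(res$profile)
      nCalled[r] <- sum(locusStatus(res$profile)$status == "called")
      nCodis[r] <- codisLocusCount(res$profile)
    }
    data.frame(templateMass = mass, meanCalledLoci = mean(nCalled),
               meanCodisLoci = mean(nCodis),
               fracFull = mean(cats == "full"),
               fracPartial = mean(cats == "partial"),
               fracFail = mean(cats == "fail"))
  })
  do.call(rbind, rows)
}
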