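#' @include AllClasses.R AllGenerics.R
NULL

#' Load an assay panel from a JSON configuration file
#'
#' Reads a panel configuration (loci, dye channels, allelic-ladder
#' composition, internal lane standard and thresholds) and returns a
#' validated \linkS4class{PanelDefinition}. The schema is a JSON object with
#' fields \code{dyes} (array of \code{\{name, detectorIndex\}}), \code{loci}
#' (array of \code{\{name, dye, repeatUnit, stutterThreshold, isCodis,
#' ladder: \{allele: [...], size: [...]\}\}}), \code{ils}
#' (\code{\{dye, fragmentSizes\}}), and scalars \code{analyticalThreshold},
#' \code{phrThreshold}, \code{binHalfWidth} and \code{sizingRange}
#' (length-2 array). The bundled PowerPlex-16-style fixture is available via
#' \code{pp16Panel()}.
#'
#' @param path Path to the JSON panel file.
#' @return A validated \linkS4class{PanelDefinition}.
#' @seealso \code{\link{savePanel}}, \code{\link{pp16Panel}}
#' @examples
#' panel <- pp16Panel()
#' ladderFragmentCount(panel)
#' @export
loadPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed panel file: ", conditionMessage(e)))
  for (field in c("dyes", "loci", "ils"))
    if (is.null(cfg[[field]])) stop("panel file missing field: ", field)
  dyeList <- lapply(seq_len(nrow(cfg$dyes)), function(i)
    DyeChannel(cfg$dyes$name[i], cfg$dyes$detectorIndex[i]))
  lociRaw <- cfg$loci
  locusList <- lapply(seq_len(nrow(lociRaw)), function(i) {
    lad <- lociRaw$ladder
    alleles <- if (is.data.frame(lad)) lad$allele[[i]] else lad[[i]]$allele
    sizes <- if (is.data.frame(lad)) lad$size[[i]] else lad[[i]]$size
    if (is.null(alleles) || is.null(sizes))
      stop("malformed panel file: locus '", lociRaw$name[i],
           "' ladder must have 'allele' and 'size'")
    LocusDefinition(name = lociRaw$name[i], dye = lociRaw$dye[i],
                    repeatUnit = lociRaw$repeatUnit[i],
                    ladder = data.frame(allele = alleles, size = sizes),
                    stutterThreshold = lociRaw$stutterThreshold[i],
                    isCodis = lociRaw$isCodis[i])
  })
  ilsDef <- ILSDefinition(cfg$ils$dye, cfg$ils$fragmentSizes)
  PanelDefinition(dyes = dyeList, loci = locusList, ils = ilsDef,
                  analyticalThreshold = cfg$analyticalThreshold %||% 100,
                  phrThreshold = cfg$phrThreshold %||% 0.6,
                  binHalfWidth = cfg$binHalfWidth %||% 0.5,
                  sizingRange = cfg$sizingRange %||% c(100, 500))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a panel definition to a JSON configuration file
#'
#' Inverse of \code{\link{loadPanel}}: \code{loadPanel(savePanel(p, f))}
#' reproduces \code{p}.
#'
#' @param panel A \linkS4class{PanelDefinition}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
savePanel <- function(panel, path) {
  cfg <- list(
    dyes = data.frame(
      name = vapply(panel@dyes, function(d) d@name, character(1)),
      detectorIndex = vapply(panel@dyes, function(d) d@detectorIndex, integer(1))),
    loci = lapply(panel@loci, function(l) list(
      name = l@name, dye = l@dye, repeatUnit = l@repeatUnit,
      stutterThreshold = l@stutterThreshold, isCodis = l@isCodis,
      ladder = list(allele = l@ladder$allele, size = l@ladder$size))),
    ils = list(dye = panel@ils@dye, fragmentSizes = panel@ils@fragmentSizes),
    analyticalThreshold = panel@analyticalThreshold,
    phrThreshold = panel@phrThreshold,
    binHalfWidth = panel@binHalfWidth,
    sizingRange = panel@sizingRange)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The bundled PowerPlex-16-style panel
#'
#' Loads the canonical fixture shipped with the package: 16 loci across three
#' locus dyes (FL, JOE, TMR) plus a 20-fragment internal lane standard on CXR,
#' with an allelic ladder totalling 210 fragments. Allele lists follow the
#' public PowerPlex 16 ladder composition (FGA trimmed to keep the total at
#' 210); nominal sizes are representative amplicon coordinates, not
#' vendor-exact values.
#'
#' @return A \linkS4class{PanelDefinition}.
#' @export
pp16Panel <- function() {
  loadPanel(system.file("extdata", "pp16_panel.json", package = "forenSTR",
                        mustWork = TRUE))
}

#' Total number of allelic-ladder fragments in a panel
#'
#' Sums the ladder allele counts over all loci; additive over loci by
#' construction.
#'
#' @param panel A \linkS4class{PanelDefinition}.
#' @return Integer fragment count.
#' @examples
#' ladderFragmentCount(pp16Panel())  # 210
#' @export
ladderFragmentCount <- function(panel) {
  if (length(panel@loci) == 0L) return(0L)
  sum(vapply(panel@loci, function(l) nrow(l@ladder), integer(1)))
}

## Per-locus size membership spans: a peak in a locus dye channel belongs to
## the locus whose span contains its size. The lower margin extends one
## repeat unit (plus stutter tolerance) below the smallest ladder allele so
## stutter of the first allele stays attributed to its parent locus; the
## upper margin is the bin half-width.
locusSizeSpans <- function(panel) {
  do.call(rbind, lapply(panel@loci, function(l) {
    data.frame(locus = l@name, dye = l@dye,
               lower = min(l@ladder$size) - l@repeatUnit - 0.6,
               upper = max(l@ladder$size) + panel@binHalfWidth,
               stringsAsFactors = FALSE)
  }))
}

## dye name -> detector index lookup
dyeIndex <- function(panel) {
  idx <- vapply(panel@dyes, function(d) d@detectorIndex, integer(1))
  names(idx) <- vapply(panel@dyes, function(d) d@name, character(1))
  idx
}

## Nominal ladder fragment table: locus, allele, size, dye, channel.
ladderTable <- function(panel) {
  idx <- dyeIndex(panel)
  do.call(rbind, lapply(panel@loci, function(l) {
    data.frame(locus = l@name, allele = l@ladder$allele, size = l@ladder$size,
               dye = l@dye, channel = unname(idx[l@dye]),
               stringsAsFactors = FALSE)
  }))
}
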