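#' @include AllClasses.R AllGenerics.R utils.R calling.R
NULL

#' Write a CODIS CMF-style XML document
#'
#' Serialises a sample profile as a documented subset of the CMF 3.2 exchange
#' schema: a \code{CODISImportFile} root with header fields and one
#' \code{Specimen} holding \code{Locus} elements with \code{Allele} values.
#' Only unflagged allele calls are written; every flagged call (below
#' analytical threshold, stutter-filtered, peak-height-ratio imbalance,
#' off-ladder, saturated) is omitted, exactly as the flagged peaks boxed in
#' the review plot are excluded from database upload. A fail-category
#' profile yields a document with zero locus elements and a
#' \code{profileCategory} attribute.
#'
#' @param profile A \linkS4class{SampleProfile}.
#' @param path Output path.
#' @param kitName Kit name recorded in the document.
#' @param analyst,instrument Placeholder provenance fields.
#' @return \code{path}, invisibly.
#' @export
writeCmf <- function(profile, path, kitName = "PP16-style",
                     analyst = "expert-system", instrument = "simulated") {
  doc <- xml2::xml_new_root("CODISImportFile")
  xml2::xml_add_child(doc, "HeaderVersion", "3.2-subset")
  xml2::xml_add_child(doc, "MessageType", "Import")
  xml2::xml_add_child(doc, "SourceLab", analyst)
  spec <- xml2::xml_add_child(doc, "Specimen")
  xml2::xml_set_attr(spec, "SpecimenId", profile@sampleId)
  xml2::xml_set_attr(spec, "profileCategory", profile@category)
  xml2::xml_add_child(spec, "SpecimenCategory", "Forensic")
  xml2::xml_add_child(spec, "Kit", kitName)
  xml2::xml_add_child(spec, "Instrument", instrument)
  calls <- profile@calls
  calls <- calls[isUnflagged(calls$flags), , drop = FALSE]
  if (profile@category != "fail") {
    for (locus in unique(calls$locus)) {
      ln <- xml2::xml_add_child(spec, "Locus")
      xml2::xml_add_child(ln, "LocusName", locus)
      for (a in calls$designation[calls$locus == locus]) {
        al <- xml2::xml_add_child(ln, "Allele")
        xml2::xml_add_child(al, "AlleleValue", a)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read back the allele values of a CMF-style document
#'
#' Convenience parser for round-trip checks: returns the per-locus allele
#' values contained in a document written by \code{\link{writeCmf}}.
#'
#' @param path Path to the XML document.
#' @return \code{data.frame} with columns \code{locus}, \code{allele}.
#' @export
readCmfAlleles <- function(path) {
  doc <- xml2::read_xml(path)
  lociNodes <- xml2::xml_find_all(doc, ".//Locus")
  rows <- lapply(lociNodes, function(ln) {
    locus <- xml2::xml_text(xml2::xml_find_first(ln, "./LocusName"))
    alleles <- xml2::xml_text(xml2::xml_find_all(ln, "./Allele/AlleleValue"))
    if (!length(alleles)) return(NULL)
    data.frame(locus = locus, allele = alleles, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(locus = character(), allele = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write the allele table CSV
#'
#' One row per allele call, flagged calls included (unlike the CMF export,
#' the allele table is the complete record). RFC-4180 CSV, UTF-8, '.'
#' decimal separator. Columns: \code{sample}, \code{locus}, \code{allele},
#' \code{size}, \code{height}, \code{flags} (';'-separated, empty when
#' unflagged).
#'
#' @param profiles A \linkS4class{SampleProfile} or list of them.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAlleleTable <- function(profiles, path) {
  if (is(profiles, "SampleProfile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    calls <- p@calls
    if (nrow(calls) == 0L) return(NULL)
    data.frame(sample = p@sampleId, locus = calls$locus,
               allele = calls$designation, size = calls$size,
               height = calls$height, flags = calls$flags,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(sample = character(), locus = character(),
                         allele = character(), size = numeric(),
                         height = numeric(), flags = character())
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an allele table CSV
#'
#' @param path Path written by \code{\link{writeAlleleTable}}.
#' @return The call \code{data.frame}.
#' @export
readAlleleTable <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(sample = "character",
                                              locus = "character",
                                              allele = "character",
                                              flags = "character"))
  tab$flags[is.na(tab$flags)] <- ""
  tab
}

#' Plot an electropherogram with called and flagged peaks
#'
#' Draws one panel per dye channel with the trace in the dye's display
#' colour. Called peaks are labelled with their allele designation; flagged
#' peaks are boxed in red (the review convention for peaks excluded from
#' database upload).
#'
#' @param trace A conditioned \linkS4class{Electropherogram}.
#' @param profile Optional \linkS4class{SampleProfile} whose calls are
#'   annotated (requires \code{panel} and \code{calibration}).
#' @param calibration Optional \linkS4class{SizeCalibration}; when given the
#'   x axis is fragment size in bases instead of scans.
#' @param panel Optional \linkS4class{PanelDefinition}, used to place each
#'   locus's calls on its dye channel.
#' @param path Optional PNG output path; when NULL, draws on the current
#'   device.
#' @param width,height PNG size in pixels.
#' @return \code{path} (or NULL), invisibly.
#' @export
plotElectropherogram <- function(trace, profile = NULL, calibration = NULL,
                                 panel = NULL, path = NULL,
                                 width = 1200, height = 800) {
  if (!is.null(path)) {
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  v <- trace@values
  nCh <- ncol(v)
  cols <- c("blue", "darkgreen", "black", "red", "orange", "purple")
  op <- graphics::par(mfrow = c(nCh, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op), add = TRUE)
  xs <- seq_len(nrow(v)) - 1
  xlab <- "scan"
  if (!is.null(calibration)) {
    xs <- predictSize(calibration, xs)
    xlab <- "size (bases)"
  }
  calls <- if (!is.null(profile)) profile@calls else NULL
  locusCh <- NULL
  if (!is.null(panel)) {
    idx <- dyeIndex(panel)
    locusCh <- vapply(panel@loci, function(l) unname(idx[l@dye]), integer(1))
    names(locusCh) <- vapply(panel@loci, function(l) l@name, character(1))
  }
  for (j in seq_len(nCh)) {
    graphics::plot(xs, v[, j], type = "l", col = cols[(j - 1L) %% 6L + 1L],
                   xlab = xlab, ylab = "RFU",
                   main = colnames(v)[j], cex.main = 0.9)
    if (!is.null(calls) && !is.null(calibration) && !is.null(locusCh)) {
      ch <- calls[locusCh[calls$locus] == j, , drop = FALSE]
      for (i in seq_len(nrow(ch))) {
        x0 <- ch$size[i]
        h <- ch$height[i]
        flagged <- nzchar(ch$flags[i])
        graphics::text(x0, h * 1.05, ch$designation[i], cex = 0.7,
                       col = if (flagged) "red" else "grey20")
        if (flagged)
          graphics::rect(x0 - 2, 0, x0 + 2, h * 1.12, border = "red",
                         lwd = 1.5)
      }
    }
  }
  invisible(path)
}
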