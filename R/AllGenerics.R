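#' @include AllClasses.R
NULL

#' Accessors for panel components
#'
#' @param x A \linkS4class{PanelDefinition}.
#' @return \code{loci} returns the list of \linkS4class{LocusDefinition}
#'   objects, \code{dyes} the list of \linkS4class{DyeChannel} objects,
#'   \code{ils} the \linkS4class{ILSDefinition}.
#' @aliases loci,PanelDefinition-method dyes,PanelDefinition-method
#'   ils,PanelDefinition-method
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname loci
#' @export
setGeneric("dyes", function(x) standardGeneric("dyes"))

#' @rdname loci
#' @export
setGeneric("ils", function(x) standardGeneric("ils"))

#' @rdname loci
#' @export
setMethod("loci", "PanelDefinition", function(x) x@loci)

#' @rdname loci
#' @export
setMethod("dyes", "PanelDefinition", function(x) x@dyes)

#' @rdname loci
#' @export
setMethod("ils", "PanelDefinition", function(x) x@ils)

#' Trace matrix and metadata of an electropherogram
#'
#' @param x An \linkS4class{Electropherogram}.
#' @return \code{traceValues} returns the scans x channels RFU matrix;
#'   \code{traceMetadata} the metadata list.
#' @aliases traceValues,Electropherogram-method
#'   traceMetadata,Electropherogram-method
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname traceValues
#' @export
setGeneric("traceMetadata", function(x) standardGeneric("traceMetadata"))

#' @rdname traceValues
#' @export
setMethod("traceValues", "Electropherogram", function(x) x@values)

#' @rdname traceValues
#' @export
setMethod("traceMetadata", "Electropherogram", function(x) x@metadata)

#' Accessors for sample profiles
#'
#' @param x A \linkS4class{SampleProfile}.
#' @return \code{profileCalls} returns the full allele-call table (flagged
#'   calls included); \code{locusStatus} the per-locus status table;
#'   \code{profileCategory} the \code{full}/\code{partial}/\code{fail}
#'   category; \code{codisLocusCount} the number of called CODIS loci.
#' @aliases profileCalls,SampleProfile-method locusStatus,SampleProfile-method
#'   profileCategory,SampleProfile-method codisLocusCount,SampleProfile-method
#' @export
setGeneric("profileCalls", function(x) standardGeneric("profileCalls"))

#' @rdname profileCalls
#' @export
setGeneric("locusStatus", function(x) standardGeneric("locusStatus"))

#' @rdname profileCalls
#' @export
setGeneric("profileCategory", function(x) standardGeneric("profileCategory"))

#' @rdname profileCalls
#' @export
setGeneric("codisLocusCount", function(x) standardGeneric("codisLocusCount"))

#' @rdname profileCalls
#' @export
setMethod("profileCalls", "SampleProfile", function(x) x@calls)

#' @rdname profileCalls
#' @export
setMethod("locusStatus", "SampleProfile", function(x) x@locusStatus)

#' @rdname profileCalls
#' @export
setMethod("profileCategory", "SampleProfile", function(x) x@category)

#' @rdname profileCalls
#' @export
setMethod("codisLocusCount", "SampleProfile", function(x) x@codisLocusCount)

setMethod("show", "PanelDefinition", function(object) {
  cat(sprintf("PanelDefinition: %d loci on %d dyes (+ ILS on %s)\n",
              length(object@loci), length(object@dyes) - 1L, object@ils@dye))
  cat(sprintf("  ladder fragments: %d | ILS fragments: %d\n",
              ladderFragmentCount(object), length(object@ils@fragmentSizes)))
  cat(sprintf("  sizing range: %g-%g bases | AT %g RFU | PHR >= %g | bin +/-%g\n",
              object@sizingRange[1], object@sizingRange[2],
              object@analyticalThreshold, object@phrThreshold,
              object@binHalfWidth))
})

setMethod("show", "Electropherogram", function(object) {
  cat(sprintf("Electropherogram '%s' (%s run): %d scans x %d channels [%s]\n",
              object@metadata$sampleId, object@metadata$runKind,
              nrow(object@values), ncol(object@values),
              paste(colnames(object@values), collapse = ", ")))
})

setMethod("show", "SizeCalibration", function(object) {
  cat(sprintf("SizeCalibration (%s): %d fragments, max |residual| %.4f bases\n",
              object@method, length(object@sizes),
              max(abs(object@residuals))))
})

setMethod("show", "SampleProfile", function(object) {
  cat(sprintf("SampleProfile '%s': %s (%d/%d loci called, %d CODIS)\n",
              object@sampleId, object@category,
              sum(object@locusStatus$status == "called"),
              nrow(object@locusStatus), object@codisLocusCount))
})
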