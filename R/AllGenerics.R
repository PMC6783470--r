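#' @name thermoasr-accessors
#' @title Accessors for thermoasr S4 classes
#' @description Slot accessors for the package's central value classes.
#' @param object a thermoasr S4 object.
#' @return The requested component.
NULL

#' @rdname thermoasr-accessors
#' @export
setGeneric("alignmentIds", function(object) standardGeneric("alignmentIds"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("alignmentMatrix", function(object) standardGeneric("alignmentMatrix"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("nColumns", function(object) standardGeneric("nColumns"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("sequenceStrings", function(object) standardGeneric("sequenceStrings"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("modelSlope", function(object) standardGeneric("modelSlope"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("modelIntercept", function(object) standardGeneric("modelIntercept"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("equilibriumFreqs", function(object) standardGeneric("equilibriumFreqs"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("rateMatrix", function(object) standardGeneric("rateMatrix"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("categoryRates", function(object) standardGeneric("categoryRates"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("profiles", function(object) standardGeneric("profiles"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("mapSequences", function(object) standardGeneric("mapSequences"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("logLikelihood", function(object) standardGeneric("logLikelihood"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))
#' @rdname thermoasr-accessors
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))

setMethod("alignmentIds", "ProteinAlignment", function(object) object@ids)
setMethod("alignmentMatrix", "ProteinAlignment", function(object) object@chars)
setMethod("nColumns", "ProteinAlignment", function(object) ncol(object@chars))
setMethod("sequenceStrings", "ProteinAlignment", function(object) {
  out <- apply(object@chars, 1L, paste0, collapse = "")
  names(out) <- object@ids
  out
})
setMethod("modelSlope", "CalibrationModel", function(object) object@slope)
setMethod("modelIntercept", "CalibrationModel", function(object) object@intercept)
setMethod("rSquared", "CalibrationModel", function(object) object@rSquared)
setMethod("nPoints", "CalibrationModel", function(object) object@nPoints)
setMethod("equilibriumFreqs", "SubstitutionModel", function(object) object@freqs)
setMethod("rateMatrix", "SubstitutionModel", function(object) object@Q)
setMethod("categoryRates", "SubstitutionModel", function(object) object@rates)
setMethod("nodeIds", "AncestralProfiles", function(object) object@nodeIds)
setMethod("profiles", "AncestralProfiles", function(object) object@profiles)
setMethod("mapSequences", "AncestralProfiles", function(object) object@mapSequences)
setMethod("logLikelihood", "AncestralProfiles", function(object) object@logLikelihood)
setMethod("annotations", "OgtPipelineResult", function(object) object@annotations)
setMethod("calibration", "OgtPipelineResult", function(object) object@calibration)
setMethod("profiles", "OgtPipelineResult", function(object) object@profiles)

setMethod("show", "ProteinAlignment", function(object) {
  cat(sprintf("ProteinAlignment: %d sequences x %d columns\n",
              length(object@ids), ncol(object@chars)))
  cat("  ids:", paste(utils::head(object@ids, 5L), collapse = ", "),
      if (length(object@ids) > 5L) "..." else "", "\n")
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: OGT = %.4f * CvP + %.4f\n",
              object@slope, object@intercept))
  cat(sprintf("  R^2 = %.4f, n = %d points (%s)\n",
              object@rSquared, object@nPoints, object@note))
})

setMethod("show", "SubstitutionModel", function(object) {
  cat(sprintf("SubstitutionModel: %s, alpha = %.4g, %d gamma categories\n",
              object@name, object@alpha, object@k))
})

setMethod("show", "AncestralProfiles", function(object) {
  nc <- if (length(object@profiles)) nrow(object@profiles[[1L]]) else 0L
  cat(sprintf("AncestralProfiles: %d internal nodes x %d columns, logL = %.4f\n",
              length(object@nodeIds), nc, object@logLikelihood))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d leaves, %d columns, root OGT %.1f degC\n",
              length(object@tree$tip.label), nColumns(object@alignment),
              unname(object@nodeOgt[ape::Ntip(object@tree) + 1L])))
})

setMethod("show", "OgtPipelineResult", function(object) {
  cat(sprintf("OgtPipelineResult: %d node annotations (%d leaves)\n",
              nrow(object@annotations), sum(object@annotations$is_leaf)))
  ra <- object@annotations[!object@annotations$is_leaf, , drop = FALSE]
  if (nrow(ra))
    cat(sprintf("  internal-node OGT (MAP): %.1f - %.1f degC\n",
                min(ra$ogt_map), max(ra$ogt_map)))
})
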