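#' Discolored-area proportion (PA)
#'
#' @param object a [SegmentationResult-class].
#' @return Numeric proportion in \[0, 1\].
#' @export
setGeneric("pa", function(object) standardGeneric("pa"))

#' Fitted fractal dimension
#'
#' @param object a [BoxCountCurve-class].
#' @return Numeric dimension estimate.
#' @export
setGeneric("fd", function(object) standardGeneric("fd"))

#' Goodness of the log-log box-count fit
#'
#' @param object a [BoxCountCurve-class].
#' @return Numeric R-squared in \[0, 1\].
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' Number of foreground pixels in a mask
#'
#' @param object a [BinaryMask-class].
#' @return Integer count of `TRUE` pixels.
#' @export
setGeneric("foregroundCount", function(object) standardGeneric("foregroundCount"))

#' Surface / discoloration pixel areas
#'
#' @param object a [SegmentationResult-class].
#' @return Integer pixel count.
#' @export
setGeneric("surfaceArea", function(object) standardGeneric("surfaceArea"))

#' @rdname surfaceArea
#' @export
setGeneric("discolorationArea",
           function(object) standardGeneric("discolorationArea"))

#' Feature-axis decision threshold of a single-variable discriminant
#'
#' For a one-variable model `Y = a x + b`, returns the feature value
#' `x = -b / a` at which the score crosses zero, i.e. the cut between
#' preventive and operative treatment on that feature's axis.
#'
#' @param model a [DiscriminantModel-class] with exactly one variable.
#' @return Numeric threshold on the feature axis.
#' @examples
#' decisionThreshold(referenceModel("fd"))   # 1.2047...
#' decisionThreshold(referenceModel("dd"))   # 28.8
#' @export
setGeneric("decisionThreshold", function(model) standardGeneric("decisionThreshold"))

# accessor methods -----------------------------------------------------------

#' @rdname pa
setMethod("pa", "SegmentationResult", function(object) object@pa)

#' @rdname fd
setMethod("fd", "BoxCountCurve", function(object) object@fd)

#' @rdname rSquared
setMethod("rSquared", "BoxCountCurve", function(object) object@rSquared)

#' @rdname foregroundCount
setMethod("foregroundCount", "BinaryMask",
          function(object) sum(object@pixels))

#' @rdname surfaceArea
setMethod("surfaceArea", "SegmentationResult",
          function(object) object@surfaceAreaPx)

#' @rdname surfaceArea
setMethod("discolorationArea", "SegmentationResult",
          function(object) object@discolorationAreaPx)

#' Raster dimensions
#'
#' @param x a [GrayImage-class] or [BinaryMask-class].
#' @return `c(height, width)` in pixels.
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @rdname dim-GrayImage-method
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@pixels))

#' Extract the pixel matrix
#'
#' @param object a [GrayImage-class] or [BinaryMask-class].
#' @return The underlying integer (image) or logical (mask) matrix.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname pixels
setMethod("pixels", "GrayImage", function(object) object@pixels)

#' @rdname pixels
setMethod("pixels", "BinaryMask", function(object) object@pixels)

# show methods ---------------------------------------------------------------

setMethod("show", "GrayImage", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("GrayImage %d x %d, intensity range [%d, %d]\n",
                d[1], d[2], min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryMask", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("BinaryMask %d x %d, %d foreground px", d[1], d[2],
                sum(object@pixels)))
    if (!is.null(object@metadata$threshold))
        cat(sprintf(" (threshold %s)", format(object@metadata$threshold)))
    cat("\n")
})

setMethod("show", "SegmentationResult", function(object) {
    cat(sprintf(
        "SegmentationResult: surface %d px, discoloration %d px, PA = %.3f\n",
        object@surfaceAreaPx, object@discolorationAreaPx, object@pa))
})

setMethod("show", "BoxCountCurve", function(object) {
    cat(sprintf("BoxCountCurve over %d scales (s = %s)\n",
                length(object@boxSizes),
                paste(object@boxSizes, collapse = ", ")))
    cat(sprintf("  FD = %.2f  (R^2 = %.4f%s)\n", object@fd, object@rSquared,
                if (object@lowFit) ", low-fit warning" else ""))
})

setMethod("show", "DiscriminantModel", function(object) {
    terms <- paste(sprintf("%.4g %s", object@coefficients,
                           toupper(object@variables)), collapse = " + ")
    cat(sprintf("DiscriminantModel: Y = %s %+.4g\n", terms, object@intercept))
    cat("  Y > 0 => operative, Y <= 0 => preventive\n")
    if (length(object@variables) == 1L)
        cat(sprintf("  decision threshold on %s: %.4g\n",
                    toupper(object@variables), decisionThreshold(object)))
})

setMethod("show", "ClassificationReport", function(object) {
    cat(sprintf("ClassificationReport (positive = operative): tp=%d fn=%d tn=%d fp=%d\n",
                object@tp, object@fn, object@tn, object@fp))
    cat(sprintf("  sensitivity %.2f  specificity %.2f  accuracy %.2f\n",
                object@sensitivity, object@specificity, object@accuracy))
})
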