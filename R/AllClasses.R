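#' @import methods
NULL

#' 8-bit grayscale tooth image
#'
#' A 2D raster of integer intensities in \[0, 255\], the working
#' representation of an intraoral tooth photograph after conversion to
#' 8-bit grayscale (0 = black, 255 = white).  Rows index image rows
#' (height), columns index image columns (width).
#'
#' @slot pixels integer matrix of intensities in \[0, 255\].
#'
#' @seealso [toGray8()], [readToothImage()]
#' @export
setClass("GrayImage", representation(pixels = "matrix"))

setValidity("GrayImage", function(object) {
    p <- object@pixels
    if (length(p) == 0L || nrow(p) < 1L || ncol(p) < 1L)
        return("empty image")
    if (anyNA(p)) return("NA intensities")
    if (any(p != floor(p)) || min(p) < 0 || max(p) > 255)
        return("intensities must be integers in [0, 255]")
    TRUE
})

#' Construct a GrayImage from a matrix
#'
#' @param pixels numeric or integer matrix with values in \[0, 255\];
#'   non-integer values are an error (use [toGray8()] to convert
#'   arbitrary rasters).
#' @return A [GrayImage-class] object.
#' @examples
#' img <- GrayImage(matrix(0:255, 16, 16))
#' dim(img)
#' @export
GrayImage <- function(pixels) {
    m <- as.matrix(pixels)
    storage.mode(m) <- "integer"
    new("GrayImage", pixels = m)
}

#' Binary raster mask
#'
#' A 2D logical raster with the same shape as its source image.  Used for
#' both the occlusal-surface mask and the pit-and-fissure discoloration
#' mask.  The `metadata` list carries provenance such as the threshold
#' that produced the mask.
#'
#' @slot pixels logical matrix.
#' @slot metadata list of provenance fields (e.g. `threshold`, `method`).
#'
#' @seealso [segmentSurface()], [segmentDiscoloration()]
#' @export
setClass("BinaryMask",
         representation(pixels = "matrix", metadata = "list"),
         prototype(metadata = list()))

setValidity("BinaryMask", function(object) {
    p <- object@pixels
    if (!is.logical(p)) return("mask pixels must be logical")
    if (length(p) == 0L) return("empty mask raster")
    if (anyNA(p)) return("NA mask pixels")
    TRUE
})

#' Construct a BinaryMask
#'
#' @param pixels logical (or 0/1 numeric) matrix.
#' @param metadata optional list of provenance fields.
#' @return A [BinaryMask-class] object.
#' @examples
#' m <- BinaryMask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
#' foregroundCount(m)
#' @export
BinaryMask <- function(pixels, metadata = list()) {
    m <- as.matrix(pixels)
    if (!is.logical(m)) m <- m != 0
    new("BinaryMask", pixels = m, metadata = metadata)
}

#' Segmentation of one occlusal surface
#'
#' Bundles the occlusal-surface mask, the discoloration mask (a subset of
#' the surface), their pixel areas, and PA = discoloration area / surface
#' area.
#'
#' @slot surfaceMask,discolorationMask [BinaryMask-class] objects of equal
#'   shape; every discoloration pixel lies on the surface.
#' @slot surfaceAreaPx,discolorationAreaPx integer pixel counts.
#' @slot pa numeric proportion in \[0, 1\].
#'
#' @seealso [computeSegmentation()], [pa()]
#' @export
setClass("SegmentationResult",
         representation(surfaceMask = "BinaryMask",
                        discolorationMask = "BinaryMask",
                        surfaceAreaPx = "integer",
                        discolorationAreaPx = "integer",
                        pa = "numeric"))

setValidity("SegmentationResult", function(object) {
    s <- object@surfaceMask@pixels
    d <- object@discolorationMask@pixels
    if (!identical(dim(s), dim(d))) return("mask shapes differ")
    if (any(d & !s)) return("mask inconsistency: discoloration outside surface")
    if (object@surfaceAreaPx != sum(s)) return("surface area mismatch")
    if (object@discolorationAreaPx != sum(d)) return("discoloration area mismatch")
    if (object@pa < 0 || object@pa > 1) return("pa outside [0, 1]")
    TRUE
})

#' Box-counting curve and fitted fractal dimension
#'
#' Occupied-box counts N(s) over a ladder of box side lengths s, together
#' with the ordinary-least-squares fit of log N(s) on log s whose negated
#' slope is the box-counting fractal dimension.
#'
#' @slot boxSizes integer vector of box side lengths, strictly increasing.
#' @slot counts integer vector of occupied-box counts, one per size.
#' @slot fd fitted fractal dimension (negated log-log slope).
#' @slot intercept log-log fit intercept.
#' @slot rSquared goodness of the log-log fit in \[0, 1\].
#' @slot lowFit `TRUE` when `rSquared < 0.95`, flagging a poor scaling fit.
#'
#' @seealso [boxCount()], [fitFD()], [estimateFD()]
#' @export
setClass("BoxCountCurve",
         representation(boxSizes = "integer", counts = "integer",
                        fd = "numeric", intercept = "numeric",
                        rSquared = "numeric", lowFit = "logical"))

setValidity("BoxCountCurve", function(object) {
    s <- object@boxSizes; n <- object@counts
    if (length(s) != length(n)) return("sizes/counts length mismatch")
    if (any(diff(s) <= 0)) return("box sizes must be strictly increasing")
    if (any(n < 1L)) return("counts must be >= 1")
    if (any(diff(n) > 0L)) return("counts must be non-increasing in box size")
    if (!is.finite(object@fd) || object@fd < -0.1 || object@fd > 2.1)
        return("fd outside the plausible [0, 2] raster range")
    TRUE
})

#' Linear discriminant treatment model
#'
#' A two-class linear discriminant over any subset of the features FD
#' (fractal dimension), PA (discolored-area proportion) and DD
#' (DIAGNOdent reading).  The score is
#' `Y = sum(coefficients * features) + intercept`; `Y > 0` calls for
#' operative treatment, `Y <= 0` (including the tie `Y = 0`) for
#' preventive treatment.
#'
#' @slot variables ordered character vector of feature names.
#' @slot coefficients numeric weights, one per variable.
#' @slot intercept numeric constant.
#'
#' @seealso [fitDiscriminant()], [referenceModel()], [decisionThreshold()]
#' @export
setClass("DiscriminantModel",
         representation(variables = "character", coefficients = "numeric",
                        intercept = "numeric"))

setValidity("DiscriminantModel", function(object) {
    if (length(object@variables) != length(object@coefficients))
        return("one coefficient per variable required")
    if (length(object@variables) < 1L) return("at least one variable")
    if (anyDuplicated(object@variables)) return("duplicated variable names")
    if (any(!is.finite(object@coefficients)) || !is.finite(object@intercept))
        return("non-finite coefficients")
    TRUE
})

#' Diagnostic performance of treatment predictions
#'
#' Confusion counts and derived metrics for predicted vs. clinician
#' treatment plans.  The positive class is operative treatment:
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp),
#' accuracy = (tp+tn)/n.  A metric is `NA` when its class is absent from
#' the truth labels.
#'
#' @slot tp,fn,tn,fp integer confusion counts.
#' @slot sensitivity,specificity,accuracy numeric proportions (or `NA`).
#'
#' @seealso [evaluateTreatments()]
#' @export
setClass("ClassificationReport",
         representation(tp = "integer", fn = "integer",
                        tn = "integer", fp = "integer",
                        sensitivity = "numeric", specificity = "numeric",
                        accuracy = "numeric"))

setValidity("ClassificationReport", function(object) {
    cnt <- c(object@tp, object@fn, object@tn, object@fp)
    if (any(cnt < 0L)) return("negative confusion counts")
    TRUE
})
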