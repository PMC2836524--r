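# Grayscale conversion, histogram thresholding and mask arithmetic for
# occlusal tooth photographs.

LUMA_WEIGHTS <- c(r = 0.299, g = 0.587, b = 0.114)  # ITU-R 601

#' Convert a raster to an 8-bit grayscale image
#'
#' RGB input is reduced to luminance with fixed ITU-R 601 weights
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel, if present, is
#' dropped.  Values are mapped linearly onto the 8-bit range and rounded
#' half-up: unit-range rasters (`range = "unit"`, all values in \[0, 1\])
#' are multiplied by 255, 8-bit rasters pass through unchanged.  With
#' `range = "auto"` a raster whose values all lie in \[0, 1\] is treated
#' as unit-range.
#'
#' Plain matrices/arrays are interpreted row-major as height x width
#' (x channels); `EBImage::Image` objects (stored width x height) are
#' transposed automatically.
#'
#' @param image matrix (grayscale), height x width x {3,4} array (RGB or
#'   RGBA), or an `EBImage::Image`.
#' @param range `"auto"`, `"unit"` (values in \[0, 1\]) or `"8bit"`
#'   (values in \[0, 255\]).
#' @return A [GrayImage-class].
#' @examples
#' toGray8(array(c(128, 128, 128) / 255, c(1, 1, 3)))  # -> 128
#' @export
toGray8 <- function(image, range = c("auto", "unit", "8bit")) {
    range <- match.arg(range)
    if (inherits(image, "Image")) {
        a <- EBImage::imageData(image)
        # EBImage stores (x, y[, channel]); transpose to (row, col)
        a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
        image <- a
    }
    if (length(image) == 0L) stop("empty image")
    if (anyNA(image)) stop("NA pixel values")
    nd <- length(dim(image))
    if (nd == 2L) {
        g <- image
    } else if (nd == 3L) {
        nc <- dim(image)[3L]
        if (!nc %in% c(3L, 4L))
            stop("unsupported channel count: ", nc)
        g <- LUMA_WEIGHTS["r"] * image[, , 1L] +
             LUMA_WEIGHTS["g"] * image[, , 2L] +
             LUMA_WEIGHTS["b"] * image[, , 3L]
    } else stop("unsupported raster dimensionality")
    if (range == "auto")
        range <- if (max(g) <= 1) "unit" else "8bit"
    if (range == "unit") g <- g * 255
    if (min(g) < 0 || max(g) > 255)
        stop("pixel values outside the declared range")
    GrayImage(matrix(as.integer(floor(g + 0.5)), nrow(g), ncol(g)))
}

#' Automatic histogram threshold by between-class variance
#'
#' Exhaustive Otsu threshold over the 256-bin intensity histogram: the
#' returned integer `t` in 0..255 maximizes the between-class variance of
#' the split into intensities `<= t` and `> t`.  Ties are broken toward
#' the smallest maximizing threshold.
#'
#' @param intensities integer vector (or matrix) of intensities in
#'   \[0, 255\].
#' @return Integer threshold `t`; the dark class is `<= t`, the bright
#'   class `> t`.
#' @examples
#' otsuThreshold(c(rep(10L, 50), rep(200L, 50)))
#' @export
otsuThreshold <- function(intensities) {
    v <- as.integer(intensities)
    h <- tabulate(v + 1L, nbins = 256L)
    n <- sum(h)
    i <- 0:255
    w0 <- cumsum(h)
    w1 <- n - w0
    m  <- cumsum(h * i)
    valid <- w0 > 0 & w1 > 0
    if (!any(valid)) stop("degenerate histogram")
    mu0 <- m / w0
    mu1 <- (m[256L] - m) / w1
    bcv <- as.numeric(w0) * as.numeric(w1) * (mu0 - mu1)^2
    bcv[!valid] <- -Inf
    as.integer(which.max(bcv) - 1L)
}

# Largest 8-connected foreground component of a logical matrix.
# EBImage::bwlabel is 4-connected, so components are taken on the
# 8-neighbour pixel adjacency graph instead.
largestComponent <- function(m) {
    idx <- which(m)
    if (length(idx) == 0L) return(m)
    H <- nrow(m); W <- ncol(m)
    inmask <- logical(H * W); inmask[idx] <- TRUE
    vid <- integer(H * W); vid[idx] <- seq_along(idx)
    r <- ((idx - 1L) %% H) + 1L
    co <- ((idx - 1L) %/% H) + 1L
    edges <- lapply(list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L)),
                    function(d) {
        ok <- r + d[1L] >= 1L & r + d[1L] <= H & co + d[2L] <= W
        nb <- idx[ok] + d[1L] + d[2L] * H
        ok2 <- inmask[nb]
        cbind(vid[idx[ok][ok2]], vid[nb[ok2]])
    })
    e <- do.call(rbind, edges)
    g <- igraph::make_graph(as.vector(t(e)), n = length(idx),
                            directed = FALSE)
    comp <- igraph::components(g)
    keep <- idx[comp$membership == which.max(comp$csize)]
    out <- matrix(FALSE, H, W)
    out[keep] <- TRUE
    out
}

#' Segment the occlusal surface from the image background
#'
#' Marks pixels with intensity strictly above a threshold (the enamel
#' surface is brighter than the intraoral background; set `invert = TRUE`
#' for the opposite polarity).  With `method = "otsu"` the threshold is
#' chosen automatically by between-class-variance maximization over the
#' full-image density histogram ([otsuThreshold()]).  By default only the
#' largest 8-connected foreground component is retained and its interior
#' holes are filled, so that dark fissures do not punch holes in the
#' measured surface area.
#'
#' @param img a [GrayImage-class].
#' @param method `"otsu"` (automatic) or `"manual"`.
#' @param manualThreshold intensity in \[0, 255\], required for
#'   `method = "manual"`.
#' @param invert if `TRUE`, select pixels strictly *below* the threshold.
#' @param keepLargest retain only the largest 8-connected component.
#' @param fillHoles fill interior holes of the retained component.
#' @return A [BinaryMask-class]; `metadata$threshold` records the
#'   threshold used.
#' @export
segmentSurface <- function(img, method = c("otsu", "manual"),
                           manualThreshold = NULL, invert = FALSE,
                           keepLargest = TRUE, fillHoles = TRUE) {
    method <- match.arg(method)
    p <- pixels(img)
    if (method == "manual") {
        if (is.null(manualThreshold) || manualThreshold < 0 ||
            manualThreshold > 255)
            stop("manual threshold must lie in [0, 255]")
        thr <- manualThreshold
    } else {
        thr <- otsuThreshold(p)
    }
    m <- if (invert) p < thr else p > thr
    if (any(m)) {
        if (keepLargest) m <- largestComponent(m)
        if (fillHoles) m <- EBImage::fillHull(m * 1L) != 0
    }
    BinaryMask(m, metadata = list(threshold = thr, method = method,
                                  role = "surface"))
}

#' Segment pit-and-fissure discoloration within the occlusal surface
#'
#' Marks surface pixels with intensity strictly below a threshold
#' (discoloration is darker than the surrounding enamel).  With
#' `method = "otsu"` the density histogram is computed over surface
#' pixels only; the recorded threshold is the smallest intensity of the
#' bright (enamel) class, so the mask is exactly the pixels strictly
#' below it.  The result is always a subset of `surface`.
#'
#' @param img a [GrayImage-class].
#' @param surface the occlusal-surface [BinaryMask-class].
#' @param method `"otsu"` or `"manual"`.
#' @param manualThreshold intensity in \[0, 255\] for `method = "manual"`.
#' @return A [BinaryMask-class] with `metadata$threshold`.
#' @export
segmentDiscoloration <- function(img, surface, method = c("otsu", "manual"),
                                 manualThreshold = NULL) {
    method <- match.arg(method)
    p <- pixels(img)
    s <- pixels(surface)
    if (!identical(dim(p), dim(s))) stop("mask shape differs from image")
    if (!any(s)) stop("empty surface mask")
    if (method == "manual") {
        if (is.null(manualThreshold) || manualThreshold < 0 ||
            manualThreshold > 255)
            stop("manual threshold must lie in [0, 255]")
        thr <- manualThreshold
    } else {
        thr <- otsuThreshold(p[s]) + 1L  # dark class = intensities < thr
    }
    m <- s & p < thr
    BinaryMask(m, metadata = list(threshold = thr, method = method,
                                  role = "discoloration"))
}

#' Assemble a segmentation result and compute PA
#'
#' Validates that the discoloration mask is a subset of the surface mask,
#' counts pixel areas exactly, and computes
#' PA = discoloration area / surface area.
#'
#' @param img the source [GrayImage-class] (shape check only).
#' @param surface,discoloration [BinaryMask-class] objects.
#' @return A [SegmentationResult-class].
#' @examples
#' img <- GrayImage(matrix(200L, 10, 10))
#' s <- BinaryMask(matrix(TRUE, 10, 10))
#' d <- BinaryMask(matrix(c(TRUE, rep(FALSE, 99)), 10, 10))
#' pa(computeSegmentation(img, s, d))   # 0.01
#' @export
computeSegmentation <- function(img, surface, discoloration) {
    s <- pixels(surface); d <- pixels(discoloration)
    if (!identical(dim(pixels(img)), dim(s)))
        stop("surface mask shape differs from image")
    if (!identical(dim(s), dim(d)))
        stop("mask inconsistency: shapes differ")
    if (any(d & !s))
        stop("mask inconsistency: discoloration pixel outside surface")
    sa <- sum(s)
    if (sa == 0L) stop("zero surface area")
    da <- sum(d)
    new("SegmentationResult", surfaceMask = surface,
        discolorationMask = discoloration,
        surfaceAreaPx = sa, discolorationAreaPx = da, pa = da / sa)
}

#' One-call surface + discoloration segmentation
#'
#' Convenience wrapper running [segmentSurface()],
#' [segmentDiscoloration()] and [computeSegmentation()] with a shared
#' configuration.
#'
#' @inheritParams segmentSurface
#' @param surfaceThreshold,discolorationThreshold manual thresholds, used
#'   when `method = "manual"`.
#' @return A [SegmentationResult-class].
#' @export
segmentTooth <- function(img, method = c("otsu", "manual"),
                         surfaceThreshold = NULL,
                         discolorationThreshold = NULL) {
    method <- match.arg(method)
    surf <- segmentSurface(img, method = method,
                           manualThreshold = surfaceThreshold)
    disc <- segmentDiscoloration(img, surf, method = method,
                                 manualThreshold = discolorationThreshold)
    computeSegmentation(img, surf, disc)
}

# image / mask file I/O ------------------------------------------------------

#' Read a tooth photograph from file
#'
#' Reads PNG, TIFF or JPEG via EBImage and converts to 8-bit grayscale
#' with [toGray8()].
#'
#' @param path image file path.
#' @return A [GrayImage-class].
#' @export
readToothImage <- function(path) {
    toGray8(EBImage::readImage(path))
}

#' Write a grayscale image to an 8-bit image file
#'
#' @param img a [GrayImage-class].
#' @param path output path; the extension selects the format (png/tiff/jpeg).
#' @return `path`, invisibly.
#' @export
writeGrayImage <- function(img, path) {
    EBImage::writeImage(EBImage::Image(t(pixels(img)) / 255), path,
                        bits.per.sample = 8L)
    invisible(path)
}

#' Write / read a binary mask as an 8-bit PNG
#'
#' Masks are exported with foreground 0 (black) and background 255
#' (white), the binary-image convention for isolated discoloration.
#'
#' @param mask a [BinaryMask-class].
#' @param path PNG file path.
#' @return `writeMask`: `path` invisibly; `readMask`: a
#'   [BinaryMask-class] (pixels with intensity < 128 are foreground).
#' @export
writeMask <- function(mask, path) {
    v <- ifelse(pixels(mask), 0, 1)
    EBImage::writeImage(EBImage::Image(t(v)), path, bits.per.sample = 8L)
    invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
    g <- toGray8(EBImage::readImage(path))
    BinaryMask(pixels(g) < 128L)
}
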