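# Box-counting fractal dimension of a binary discoloration pattern, with
# a Minkowski (dilation) estimator as an independent cross-check.

#' Count occupied grid boxes at each scale
#'
#' Places a square grid of side `s` anchored at pixel (0, 0) over the
#' mask and counts the grid cells containing at least one foreground
#' pixel.  Partial boxes at the right/bottom edges count.
#'
#' @param mask a [BinaryMask-class] or logical matrix, non-empty.
#' @param boxSizes integer box side lengths, each in
#'   \[1, min(height, width)\].
#' @return Integer vector of occupied-box counts, one per size.
#' @examples
#' m <- matrix(FALSE, 64, 64); m[32, ] <- TRUE
#' boxCount(m, 8)   # 8 boxes along the line
#' @export
boxCount <- function(mask, boxSizes) {
    p <- if (is(mask, "BinaryMask")) pixels(mask) else mask
    w <- which(p, arr.ind = TRUE)
    if (nrow(w) == 0L) stop("empty pattern")
    s <- as.integer(boxSizes)
    if (length(s) == 0L || any(s < 1L)) stop("box size must be >= 1")
    if (any(s > min(dim(p))))
        stop("box size exceeds the smaller raster dimension")
    r0 <- w[, 1L] - 1L
    c0 <- w[, 2L] - 1L
    W <- ncol(p)
    vapply(s, function(si) {
        ncell <- (W + si - 1L) %/% si
        length(unique((r0 %/% si) * ncell + (c0 %/% si)))
    }, integer(1L))
}

#' Fit the fractal dimension from a box-count curve
#'
#' Ordinary least squares of log N(s) on log s over the supplied scales;
#' the fractal dimension is the negated slope, so decreasing counts give
#' FD >= 0.  A constant curve (N(s) = 1 everywhere, e.g. a single point)
#' fits exactly with FD = 0.  `lowFit` is set when the fit's R-squared
#' falls below 0.95, flagging patterns without clean power-law scaling.
#'
#' @param boxSizes integer box side lengths (>= 3 distinct values).
#' @param counts positive occupied-box counts, one per size.
#' @return A [BoxCountCurve-class].
#' @examples
#' fd(fitFD(c(1, 2, 4, 8, 16), 64 / c(1, 2, 4, 8, 16)))   # exactly 1
#' @export
fitFD <- function(boxSizes, counts) {
    s <- as.integer(boxSizes)
    n <- as.integer(counts)
    if (length(unique(s)) < 3L) stop("insufficient scales")
    if (length(n) != length(s)) stop("sizes/counts length mismatch")
    if (any(n < 1L)) stop("counts must be >= 1")
    o <- order(s)
    s <- s[o]; n <- n[o]
    lx <- log(s); ly <- log(n)
    slope <- stats::cov(lx, ly) / stats::var(lx)
    intercept <- mean(ly) - slope * mean(lx)
    sst <- sum((ly - mean(ly))^2)
    r2 <- if (sst == 0) 1 else {
        ssr <- sum((ly - (intercept + slope * lx))^2)
        1 - ssr / sst
    }
    if (r2 < 0.95)
        warning(sprintf("log-log fit R^2 = %.3f < 0.95: weak power-law scaling",
                        r2))
    new("BoxCountCurve", boxSizes = s, counts = n, fd = -slope,
        intercept = intercept, rSquared = r2, lowFit = r2 < 0.95)
}

# Dyadic box-size ladder for a raster of the given dimensions: powers of
# 2 from 2 up to floor(min(H, W) / 4).
defaultBoxSizes <- function(dims, minScales = 4L) {
    smax <- min(dims) %/% 4L
    sizes <- 2L^seq_len(30L)
    sizes <- sizes[sizes <= smax]
    if (length(sizes) < minScales)
        stop("insufficient scales: raster too small for the box-size ladder")
    sizes
}

#' Estimate the box-counting fractal dimension of a pattern
#'
#' Translates the pattern so its bounding-box corner sits at the grid
#' origin, counts occupied boxes over a dyadic ladder of box sizes
#' (powers of 2 from 2 up to `floor(min(height, width) / 4)`, at least
#' `minScales` scales), and fits the log-log regression ([fitFD()]).
#' Deterministic for a given mask and configuration.
#'
#' @param mask a [BinaryMask-class] or logical matrix, non-empty.
#' @param boxSizes optional explicit box-size ladder (>= 3 sizes);
#'   default is the dyadic ladder above.
#' @param minScales minimum number of ladder scales required (default 4).
#' @return A [BoxCountCurve-class].
#' @examples
#' fd(estimateFD(fractalFixture("line")))     # ~1
#' fd(estimateFD(fractalFixture("square")))   # ~2
#' @export
estimateFD <- function(mask, boxSizes = NULL, minScales = 4L) {
    p <- if (is(mask, "BinaryMask")) pixels(mask) else mask
    w <- which(p, arr.ind = TRUE)
    if (nrow(w) == 0L) stop("empty pattern")
    shifted <- matrix(FALSE, nrow(p), ncol(p))
    shifted[cbind(w[, 1L] - min(w[, 1L]) + 1L,
                  w[, 2L] - min(w[, 2L]) + 1L)] <- TRUE
    if (is.null(boxSizes))
        boxSizes <- defaultBoxSizes(dim(p), minScales)
    fitFD(boxSizes, boxCount(shifted, boxSizes))
}

#' Minkowski (dilation) fractal dimension estimate
#'
#' Dilates the pattern by discrete disc structuring elements of each
#' radius r and measures the dilated ("sausage") area A(r).  For a set of
#' Minkowski-Bouligand dimension D, A(r) grows like r^(2 - D) as r
#' shrinks, so D is estimated as `1 + slope` of the ordinary
#' least-squares fit of log(A(r)/r) on log(1/r) (equivalently
#' `2 - dlogA/dlogr`).  The structuring element at radius r is the exact
#' Euclidean disc (offsets with dr^2 + dc^2 <= r^2 + 1/2); it spans
#' 2r + 1 pixels, so an effective radius r + 1/2 is used in the
#' regression.  The raster is padded by the largest radius so dilation is
#' never clipped at the border.
#'
#' This estimator is independent of the box-counting path and serves as
#' its cross-check.
#'
#' @param mask a [BinaryMask-class] or logical matrix, non-empty.
#' @param radii at least 3 positive integer dilation radii; the defaults
#'   stay small because the r -> 0 limit is what is being approximated.
#' @return Numeric dimension estimate.
#' @examples
#' minkowskiFD(fractalFixture("line"))     # ~1
#' @export
minkowskiFD <- function(mask, radii = 1:4) {
    p <- if (is(mask, "BinaryMask")) pixels(mask) else mask
    if (!any(p)) stop("empty pattern")
    radii <- as.integer(radii)
    if (length(radii) < 3L || any(radii < 1L))
        stop("need >= 3 positive dilation radii")
    pad <- max(radii)
    big <- matrix(0L, nrow(p) + 2L * pad, ncol(p) + 2L * pad)
    big[pad + seq_len(nrow(p)), pad + seq_len(ncol(p))] <- p * 1L
    areas <- vapply(radii, function(r) {
        off <- (-r):r
        kern <- matrix(as.integer(outer(off, off, function(a, b)
            a^2 + b^2 <= r^2 + 0.5)), 2L * r + 1L)
        sum(EBImage::dilate(big, kern) != 0)
    }, numeric(1L))
    reff <- radii + 0.5
    x <- log(1 / reff)
    y <- log(areas / reff)
    1 + stats::cov(x, y) / stats::var(x)
}

#' Analytic calibration patterns with known fractal dimension
#'
#' Rasters of shapes whose fractal dimension is known in closed form,
#' used to calibrate and test the estimators: a straight line (D = 1), a
#' filled square (D = 2), a point (D = 0), the Sierpinski triangle
#' (D = log 3 / log 2 ~ 1.585) and the Koch curve
#' (D = log 4 / log 3 ~ 1.262).
#'
#' The Sierpinski raster at depth d is the 2^d x 2^d parity pattern
#' (pixel (r, c) set iff `bitwAnd(r, c) == 0`), which contains exactly
#' 3^d pixels and has exactly collinear dyadic box counts.  The Koch
#' curve is drawn by a turtle over 4^depth unit segments and rasterized
#' into a square canvas.
#'
#' @param shape one of `"line"`, `"square"`, `"point"`, `"sierpinski"`,
#'   `"koch"`.
#' @param depth recursion depth for `"sierpinski"` (default 6) and
#'   `"koch"` (default 5).
#' @param size raster side for `"line"` (default 512), `"square"`
#'   (default 128) and `"point"` (default 128).
#' @return A [BinaryMask-class].
#' @examples
#' foregroundCount(fractalFixture("sierpinski", depth = 6))  # 3^6 = 729
#' @export
fractalFixture <- function(shape = c("line", "square", "point",
                                     "sierpinski", "koch"),
                           depth = NULL, size = NULL) {
    shape <- match.arg(shape)
    if (shape == "line") {
        if (is.null(size)) size <- 512L
        m <- matrix(FALSE, size, size)
        m[size %/% 2L, ] <- TRUE
    } else if (shape == "square") {
        if (is.null(size)) size <- 128L
        m <- matrix(TRUE, size, size)
    } else if (shape == "point") {
        if (is.null(size)) size <- 128L
        m <- matrix(FALSE, size, size)
        m[size %/% 2L, size %/% 2L] <- TRUE
    } else if (shape == "sierpinski") {
        if (is.null(depth)) depth <- 6L
        n <- 2L^depth
        idx <- 0:(n - 1L)
        m <- outer(idx, idx, function(r, c) bitwAnd(r, c) == 0L)
    } else {
        if (is.null(depth)) depth <- 5L
        dirs <- 0
        for (i in seq_len(depth))
            dirs <- as.vector(vapply(dirs, function(d)
                c(d, d + 60, d - 60, d), numeric(4L)))
        x <- cumsum(c(0, cospi(dirs / 180)))
        y <- cumsum(c(0, sinpi(dirs / 180)))
        # sample along each unit segment and rasterize
        tt <- seq(0, 1, by = 0.25)
        px <- as.vector(outer(diff(x), tt)) + rep(x[-length(x)], length(tt))
        py <- as.vector(outer(diff(y), tt)) + rep(y[-length(y)], length(tt))
        pad <- 8L
        side <- ceiling(max(px) - min(px)) + 2L * pad
        rr <- as.integer(round(py - min(py))) + pad + 1L
        cc <- as.integer(round(px - min(px))) + pad + 1L
        m <- matrix(FALSE, side, side)
        m[cbind(rr, cc)] <- TRUE
    }
    BinaryMask(m, metadata = list(shape = shape))
}
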