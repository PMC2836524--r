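# Independent brute-force oracles and fixture builders used across the
# suite.  These deliberately avoid the code paths they check.

# Literal grid scan: iterate over every grid cell and test whether any
# foreground pixel falls inside it.
naiveBoxCount <- function(m, s) {
    H <- nrow(m); W <- ncol(m)
    n <- 0L
    for (r0 in seq(1L, H, by = s)) {
        for (c0 in seq(1L, W, by = s)) {
            cell <- m[r0:min(r0 + s - 1L, H), c0:min(c0 + s - 1L, W)]
            if (any(cell)) n <- n + 1L
        }
    }
    n
}

# Exhaustive threshold search: for every candidate t compute the
# between-class variance of the {<= t} / {> t} split directly from class
# means, and return the smallest maximizing t.
bruteOtsu <- function(v) {
    v <- as.integer(v)
    best <- -Inf; bestT <- NA_integer_
    n <- length(v)
    for (t in 0:255) {
        lo <- v[v <= t]; hi <- v[v > t]
        if (length(lo) == 0L || length(hi) == 0L) next
        bcv <- (length(lo) / n) * (length(hi) / n) *
            (mean(lo) - mean(hi))^2
        if (bcv > best + 1e-12) { best <- bcv; bestT <- t }
    }
    bestT
}

# Closed-form 1-D two-class cutoff: the class-frequency-weighted midpoint
# of the class means, written as scalar arithmetic.
closedFormCutoff <- function(x, operative) {
    m1 <- mean(x[!operative]); m2 <- mean(x[operative])
    n1 <- sum(!operative); n2 <- sum(operative)
    (n1 * m1 + n2 * m2) / (n1 + n2)
}

# Midrank Spearman computed from first principles: ranks by counting,
# then the Pearson product-moment formula written out.
bruteSpearman <- function(x, y) {
    midrank <- function(v) {
        vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2,
               numeric(1))
    }
    rx <- midrank(x); ry <- midrank(y)
    sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
    sxy / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# closed-form mean of a normal truncated to [lo, hi]
truncNormMean <- function(mean, sd, lo, hi) {
    a <- (lo - mean) / sd; b <- (hi - mean) / sd
    mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

randomMask <- function(h, w, p = 0.3) {
    matrix(runif(h * w) < p, h, w)
}

# two-level tooth-like test image: bright disc on dark background with a
# dark line across it
twoLevelDiscImage <- function(size = 64L, bg = 0L, fg = 200L) {
    xs <- matrix(seq_len(size), size, size, byrow = TRUE)
    ys <- matrix(seq_len(size), size, size)
    disc <- (xs - size / 2)^2 + (ys - size / 2)^2 <= (size / 3)^2
    img <- matrix(bg, size, size)
    img[disc] <- fg
    list(image = GrayImage(img), disc = disc)
}
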