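test_that("toGray8 maps the declared range linearly onto [0, 255]", {
    black <- array(0, c(4, 4, 3))
    expect_true(all(pixels(toGray8(black)) == 0L))
    white <- array(1, c(4, 4, 3))
    expect_true(all(pixels(toGray8(white)) == 255L))
    # luminance weights applied by hand to one uniform pixel:
    # (0.299 + 0.587 + 0.114) * 128 = 128
    mid <- array(128 / 255, c(2, 2, 3))
    expect_true(all(pixels(toGray8(mid)) == 128L))
    # 8-bit grayscale passes through unchanged
    g <- matrix(0:255, 16, 16)
    expect_identical(pixels(toGray8(g)), pixels(GrayImage(g)))
    # RGBA: alpha dropped
    rgba <- array(0.5, c(3, 3, 4))
    expect_equal(dim(toGray8(rgba)), c(3L, 3L))
})

test_that("toGray8 rejects empty and unsupported input", {
    expect_error(toGray8(matrix(numeric(0), 0, 0)), "empty image")
    expect_error(toGray8(array(0.5, c(3, 3, 2))), "channel count")
})

test_that("automatic threshold equals the exhaustive-search oracle", {
    set.seed(101)
    for (i in 1:20) {
        # bimodal intensity populations with random separation and mix
        n1 <- sample(50:400, 1); n2 <- sample(50:400, 1)
        v <- as.integer(pmin(pmax(round(c(rnorm(n1, runif(1, 40, 90), 20),
                                          rnorm(n2, runif(1, 150, 220), 25))),
                                  0), 255))
        expect_identical(otsuThreshold(v), bruteOtsu(v))
    }
})

test_that("surface segmentation isolates a bright object", {
    tl <- twoLevelDiscImage()
    m <- segmentSurface(tl$image)
    expect_identical(pixels(m), tl$disc)
    expect_true(m@metadata$threshold >= 0 && m@metadata$threshold < 200)
    # manual threshold: all pixels above it -> full-image mask
    uni <- GrayImage(matrix(150L, 8, 8))
    full <- segmentSurface(uni, method = "manual", manualThreshold = 100)
    expect_true(all(pixels(full)))
    # uniform image with automatic method is degenerate
    expect_error(segmentSurface(uni), "degenerate histogram")
})

test_that("surface segmentation keeps the largest component and fills holes", {
    img <- matrix(0L, 32, 32)
    img[5:20, 5:20] <- 200L     # big blob
    img[10:12, 10:12] <- 30L    # dark fissure inside it
    img[28:30, 28:30] <- 200L   # small separate blob
    m <- pixels(segmentSurface(GrayImage(img)))
    expect_true(all(m[5:20, 5:20]))      # hole filled
    expect_false(any(m[28:30, 28:30]))   # small component dropped
})

test_that("discoloration segmentation marks dark pixels within the surface", {
    img <- matrix(0L, 32, 32)
    img[5:28, 5:28] <- 200L
    img[16, 8:24] <- 30L
    surf <- BinaryMask(img > 0L)
    d <- segmentDiscoloration(GrayImage(img), surf)
    expect_identical(which(pixels(d)), which(img == 30L))
    # surface with nothing below a manual threshold -> empty mask, PA 0
    bright <- GrayImage(matrix(200L, 8, 8))
    all8 <- BinaryMask(matrix(TRUE, 8, 8))
    d0 <- segmentDiscoloration(bright, all8, method = "manual",
                               manualThreshold = 50)
    expect_identical(foregroundCount(d0), 0L)
    expect_error(segmentDiscoloration(bright, BinaryMask(matrix(FALSE, 8, 8))),
                 "empty surface")
})

test_that("discoloration threshold matches the oracle on surface pixels only", {
    set.seed(202)
    for (i in 1:10) {
        img <- matrix(255L, 48, 48)
        surf <- matrix(FALSE, 48, 48); surf[8:40, 8:40] <- TRUE
        vals <- as.integer(pmin(pmax(round(
            c(rnorm(sum(surf) * 0.2, 45, 12),
              rnorm(ceiling(sum(surf) * 0.8), 190, 18))), 0), 255))
        img[surf] <- vals[seq_len(sum(surf))]
        d <- segmentDiscoloration(GrayImage(img), BinaryMask(surf))
        # recorded threshold is the smallest bright-class intensity
        expect_identical(d@metadata$threshold, bruteOtsu(img[surf]) + 1L)
        expect_true(all(pixels(d) <= surf))  # subset of the surface
    }
})

test_that("segmentation areas and PA are exact pixel arithmetic", {
    img <- GrayImage(matrix(100L, 40, 25))
    s <- matrix(FALSE, 40, 25); s[1:40, 1:25] <- TRUE  # 1000 px
    d <- matrix(FALSE, 40, 25); d[1:2, 1:25] <- TRUE   # 50 px
    seg <- computeSegmentation(img, BinaryMask(s), BinaryMask(d))
    expect_identical(surfaceArea(seg), 1000L)
    expect_identical(discolorationArea(seg), 50L)
    expect_equal(pa(seg), 0.05)
    # empty discoloration -> PA 0; discoloration = surface -> PA 1
    seg0 <- computeSegmentation(img, BinaryMask(s),
                                BinaryMask(matrix(FALSE, 40, 25)))
    expect_equal(pa(seg0), 0)
    seg1 <- computeSegmentation(img, BinaryMask(s), BinaryMask(s))
    expect_equal(pa(seg1), 1)
})

test_that("inconsistent masks are rejected", {
    img <- GrayImage(matrix(100L, 10, 10))
    s <- matrix(FALSE, 10, 10); s[2:5, 2:5] <- TRUE
    d <- matrix(FALSE, 10, 10); d[8, 8] <- TRUE  # outside surface
    expect_error(computeSegmentation(img, BinaryMask(s), BinaryMask(d)),
                 "mask inconsistency")
    expect_error(computeSegmentation(img, BinaryMask(matrix(FALSE, 10, 10)),
                                     BinaryMask(matrix(FALSE, 10, 10))),
                 "zero surface area")
})

test_that("PA is invariant under translation, rotation and upscaling", {
    set.seed(303)
    s <- matrix(FALSE, 30, 30); s[5:25, 5:25] <- TRUE
    d <- matrix(FALSE, 30, 30); d[10:12, 10:20] <- TRUE
    img <- GrayImage(matrix(0L, 30, 30))
    p0 <- pa(computeSegmentation(img, BinaryMask(s), BinaryMask(d)))
    # translation by (3, 2)
    shift <- function(m, dr, dc) {
        out <- matrix(FALSE, nrow(m), ncol(m))
        out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
            m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
        out
    }
    expect_equal(pa(computeSegmentation(img, BinaryMask(shift(s, 3, 2)),
                                        BinaryMask(shift(d, 3, 2)))), p0)
    # 90-degree rotation of both masks
    rot <- function(m) t(m[nrow(m):1, ])
    expect_equal(pa(computeSegmentation(img, BinaryMask(rot(s)),
                                        BinaryMask(rot(d)))), p0)
    # pixel replication by factor 3
    up <- function(m, k) m[rep(seq_len(nrow(m)), each = k),
                           rep(seq_len(ncol(m)), each = k)]
    img3 <- GrayImage(matrix(0L, 90, 90))
    expect_equal(pa(computeSegmentation(img3, BinaryMask(up(s, 3)),
                                        BinaryMask(up(d, 3)))), p0)
})

test_that("images and masks round-trip through 8-bit PNG", {
    tl <- twoLevelDiscImage()
    f1 <- tempfile(fileext = ".png")
    writeGrayImage(tl$image, f1)
    expect_identical(pixels(readToothImage(f1)), pixels(tl$image))
    m <- BinaryMask(tl$disc)
    f2 <- tempfile(fileext = ".png")
    writeMask(m, f2)
    expect_identical(pixels(readMask(f2)), tl$disc)
    unlink(c(f1, f2))
})
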