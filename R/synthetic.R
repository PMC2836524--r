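# Synthetic tooth images with ground-truth masks across severity
# classes, and feature tables drawn from per-class reference
# distributions, so every pipeline stage is testable without clinical
# data.

# run expr with a locally pinned RNG state (restored on exit)
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
            get(".Random.seed", globalenv()) else NULL
        set.seed(seed)
        on.exit(if (is.null(old))
            rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, globalenv()))
    }
    expr
}

#' Reference per-class feature distributions
#'
#' Class sizes and marginal mean/SD of FD, PA and DD for each clinical
#' diagnosis, defaulting to the values observed on the original 100-tooth
#' clinical sample: C0 (n = 64) FD 1.09 (0.16), PA 0.005 (0.009), DD
#' 16.9 (15.0); C1 (n = 24) FD 1.34 (0.09), PA 0.012 (0.008), DD 45.2
#' (25.1); C2 (n = 12) FD 1.52 (0.09), PA 0.051 (0.022), DD 57.9 (27.7).
#'
#' @param n named integer vector of class sizes for C0, C1, C2.
#' @return data.frame with one row per class and columns `diagnosis`,
#'   `n`, `fd_mean`, `fd_sd`, `pa_mean`, `pa_sd`, `dd_mean`, `dd_sd`.
#' @examples
#' featurePopulation()
#' featurePopulation(n = c(C0 = 1000, C1 = 500, C2 = 500))
#' @export
featurePopulation <- function(n = c(C0 = 64L, C1 = 24L, C2 = 12L)) {
    stopifnot(all(c("C0", "C1", "C2") %in% names(n)), all(n >= 0))
    data.frame(
        diagnosis = c("C0", "C1", "C2"),
        n = as.integer(n[c("C0", "C1", "C2")]),
        fd_mean = c(1.09, 1.34, 1.52), fd_sd = c(0.16, 0.09, 0.09),
        pa_mean = c(0.005, 0.012, 0.051), pa_sd = c(0.009, 0.008, 0.022),
        dd_mean = c(16.9, 45.2, 57.9), dd_sd = c(15.0, 25.1, 27.7),
        stringsAsFactors = FALSE)
}

# inverse-CDF truncated normal; u in (0,1)
qtruncnorm <- function(u, mean, sd, lo, hi) {
    if (sd == 0) return(rep(mean, length(u)))
    plo <- stats::pnorm(lo, mean, sd)
    phi <- stats::pnorm(hi, mean, sd)
    stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Simulate a labeled feature table
#'
#' Draws per-class features from truncated-Gaussian marginals (FD in
#' \[0, 2.5\], PA in \[0, 1\], DD in \[0, 99\]) with the given class
#' means/SDs, independent across features by default.  Supplying a 3x3
#' `correlation` matrix couples FD/PA/DD within a tooth through a
#' Gaussian copula while preserving the truncated marginals.  Treatment
#' labels follow the clinical rule: C0 is preventive, C1 and C2 are
#' operative.  Deterministic per seed.
#'
#' @param pop a [featurePopulation()] data.frame.
#' @param seed integer RNG seed (or `NULL` to use the current RNG state).
#' @param correlation optional 3x3 positive-definite correlation matrix
#'   for (fd, pa, dd).
#' @return data.frame with columns `tooth_id`, `fd`, `pa`, `dd`,
#'   `diagnosis`, `treatment`.
#' @examples
#' head(simulateFeatureTable(seed = 1))
#' @export
simulateFeatureTable <- function(pop = featurePopulation(), seed = NULL,
                                 correlation = NULL) {
    stopifnot(all(pop$fd_sd >= 0), all(pop$pa_sd >= 0), all(pop$dd_sd >= 0),
              all(pop$n >= 0))
    lims <- list(fd = c(0, 2.5), pa = c(0, 1), dd = c(0, 99))
    withSeed(seed, {
        out <- lapply(seq_len(nrow(pop)), function(i) {
            n <- pop$n[i]
            if (n == 0L) return(NULL)
            if (is.null(correlation)) {
                u <- matrix(stats::runif(n * 3L), n, 3L)
            } else {
                stopifnot(identical(dim(correlation), c(3L, 3L)))
                z <- matrix(stats::rnorm(n * 3L), n, 3L) %*%
                    chol(correlation)
                u <- stats::pnorm(z)
            }
            cl <- pop$diagnosis[i]
            data.frame(
                tooth_id = sprintf("%s_%03d", cl, seq_len(n)),
                fd = qtruncnorm(u[, 1L], pop$fd_mean[i], pop$fd_sd[i],
                                lims$fd[1], lims$fd[2]),
                pa = qtruncnorm(u[, 2L], pop$pa_mean[i], pop$pa_sd[i],
                                lims$pa[1], lims$pa[2]),
                dd = qtruncnorm(u[, 3L], pop$dd_mean[i], pop$dd_sd[i],
                                lims$dd[1], lims$dd[2]),
                diagnosis = cl,
                treatment = if (cl == "C0") "preventive" else "operative",
                stringsAsFactors = FALSE)
        })
        do.call(rbind, out)
    })
}

# --- tooth-image generator --------------------------------------------------

# offsets of a discrete disc of radius r
discOffsets <- function(r) {
    d <- expand.grid(dr = -r:r, dc = -r:r)
    d[d$dr^2 + d$dc^2 <= r^2 + 0.5, , drop = FALSE]
}

#' Simulate a tooth photograph with ground-truth masks
#'
#' Renders an elliptical bright occlusal surface (enamel) on a dark
#' background and draws dark pit-and-fissure discoloration inside it,
#' with a morphology per severity class that mirrors the point-to-line-
#' to-area progression of caries: C0 gets 1-4 isolated point blobs, C1 a
#' single meandering fissure polyline, and C2 a branching fissure tree
#' with widened lesion patches.  Pattern elements are added until the
#' discolored pixel count reaches `targetPA * surface area`, so the
#' realized PA lies within 20% relative of the target.  Per-pixel
#' Gaussian intensity noise of SD `noiseSD` is added (0 = noise-free
#' two-level image).  Deterministic for a fixed seed.
#'
#' Default target PA per class follows the reference per-class means
#' (C0 0.005, C1 0.012, C2 0.051; see [featurePopulation()]).
#'
#' @param severity `"C0"`, `"C1"` or `"C2"`.
#' @param size square raster side in pixels.
#' @param targetPA requested discoloration proportion in (0, 1); default
#'   depends on `severity`.
#' @param noiseSD intensity noise SD in gray levels.
#' @param seed integer RNG seed.
#' @param surfaceIntensity,backgroundIntensity,discolorationIntensity
#'   mean gray levels of the three regions.
#' @return list with `image` ([GrayImage-class]), `surfaceMask` and
#'   `discolorationMask` ([BinaryMask-class], ground truth;
#'   discoloration strictly inside the surface), `severity`, `targetPA`,
#'   `realizedPA`.
#' @examples
#' tooth <- simulateToothImage("C2", seed = 1)
#' tooth$realizedPA
#' @export
simulateToothImage <- function(severity = c("C0", "C1", "C2"), size = 256L,
                               targetPA = NULL, noiseSD = 3, seed = NULL,
                               surfaceIntensity = 205L,
                               backgroundIntensity = 25L,
                               discolorationIntensity = 45L) {
    severity <- match.arg(severity)
    if (is.null(targetPA))
        targetPA <- c(C0 = 0.005, C1 = 0.012, C2 = 0.051)[[severity]]
    if (targetPA <= 0 || targetPA >= 1) stop("target_pa must lie in (0, 1)")
    H <- W <- as.integer(size)
    withSeed(seed, {
        cx <- W / 2 + stats::runif(1, -0.02, 0.02) * W
        cy <- H / 2 + stats::runif(1, -0.02, 0.02) * H
        a <- 0.42 * W * (1 + stats::runif(1, -0.05, 0.05))
        b <- 0.34 * H * (1 + stats::runif(1, -0.05, 0.05))
        xs <- matrix(seq_len(W), H, W, byrow = TRUE)
        ys <- matrix(seq_len(H), H, W)
        surface <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
        inner <- ((xs - cx) / (0.82 * a))^2 + ((ys - cy) / (0.82 * b))^2 <= 1
        surfArea <- sum(surface)
        budget <- round(targetPA * surfArea)
        if (budget < 5L) stop("target_pa infeasible for geometry")
        if (budget > 0.6 * sum(inner)) stop("target_pa infeasible for geometry")

        pattern <- matrix(FALSE, H, W)
        # stamp a disc clipped to the inner ellipse
        stamp <- function(pat, py, px, r) {
            off <- discOffsets(r)
            rr <- round(py) + off$dr; cc <- round(px) + off$dc
            ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
            ij <- cbind(rr[ok], cc[ok])
            ij <- ij[inner[ij], , drop = FALSE]
            pat[ij] <- TRUE
            pat
        }
        randomInner <- function() {
            repeat {
                px <- cx + stats::runif(1, -0.78, 0.78) * a
                py <- cy + stats::runif(1, -0.78, 0.78) * b
                if (py < 1 || py > H || px < 1 || px > W) next
                if (inner[round(py), round(px)]) return(c(py, px))
            }
        }
        # meandering walk stamping a width-3 fissure; returns visited points
        walk <- function(start, heading, maxPx) {
            pos <- start; h <- heading
            pts <- matrix(numeric(0), 0, 2)
            n0 <- sum(pattern)
            for (i in seq_len(5000L)) {
                pattern <<- stamp(pattern, pos[1], pos[2], 1L)
                pts <- rbind(pts, pos)
                if (sum(pattern) - n0 >= maxPx) break
                nxt <- pos + c(sin(h), cos(h)) * 1.2
                if (nxt[1] < 2 || nxt[1] > H - 1 || nxt[2] < 2 ||
                    nxt[2] > W - 1 || !inner[round(nxt[1]), round(nxt[2])]) {
                    h <- atan2(cy - pos[1], cx - pos[2]) +
                        stats::rnorm(1, 0, 0.4)
                    nxt <- pos + c(sin(h), cos(h)) * 1.2
                }
                pos <- nxt
                h <- h + stats::rnorm(1, 0, 0.22)
            }
            pts
        }

        if (severity == "C0") {
            for (i in seq_len(500L)) {
                if (sum(pattern) >= budget) break
                r <- if (budget - sum(pattern) > 12L) sample(1:2, 1L) else 1L
                p <- randomInner()
                pattern <- stamp(pattern, p[1], p[2], r)
            }
        } else if (severity == "C1") {
            start <- c(cy + stats::runif(1, -0.3, 0.3) * b, cx - 0.6 * a)
            heading <- stats::runif(1, -0.4, 0.4)
            for (i in seq_len(50L)) {
                if (sum(pattern) >= budget) break
                walk(start, heading, budget - sum(pattern))
                start <- randomInner()
                heading <- stats::runif(1, 0, 2 * pi)
            }
        } else {
            start <- c(cy + stats::runif(1, -0.3, 0.3) * b, cx - 0.6 * a)
            skel <- walk(start, stats::runif(1, -0.4, 0.4),
                         round(0.35 * budget))
            for (i in seq_len(50L)) {           # branches
                if (sum(pattern) >= 0.7 * budget) break
                at <- skel[sample(nrow(skel), 1L), ]
                skel <- rbind(skel,
                              walk(at, stats::runif(1, 0, 2 * pi),
                                   round(0.12 * budget)))
            }
            for (i in seq_len(500L)) {          # widened lesion patches
                if (sum(pattern) >= budget) break
                rem <- budget - sum(pattern)
                r <- max(1L, min(4L, as.integer(floor(sqrt(rem / 3)))))
                at <- skel[sample(nrow(skel), 1L), ]
                pattern <- stamp(pattern, at[1], at[2], r)
            }
        }
        count <- sum(pattern)
        if (count < 0.8 * budget) stop("target_pa infeasible for geometry")

        img <- matrix(as.numeric(backgroundIntensity), H, W)
        img[surface] <- surfaceIntensity
        img[pattern] <- discolorationIntensity
        if (noiseSD > 0)
            img <- img + stats::rnorm(H * W, 0, noiseSD)
        img <- pmin(pmax(floor(img + 0.5), 0), 255)
        list(image = GrayImage(img),
             surfaceMask = BinaryMask(surface, list(role = "surface")),
             discolorationMask = BinaryMask(pattern,
                                            list(role = "discoloration")),
             severity = severity, targetPA = targetPA,
             realizedPA = count / surfArea)
    })
}

#' Write a batch of simulated tooth images to disk
#'
#' Renders `perClass` images per severity class into `dir` as PNG files
#' and writes `ground_truth.csv` with the true masks' areas, realized PA
#' and severity labels.  Seeds are derived deterministically from `seed`.
#'
#' @param dir output directory (created if needed).
#' @param perClass images per severity class.
#' @param seed base RNG seed.
#' @param noiseSD intensity noise SD passed to [simulateToothImage()].
#' @param size raster side in pixels.
#' @return Invisibly, the ground-truth data.frame.
#' @export
simulateToothImageSet <- function(dir, perClass = 5L, seed = 1L,
                                  noiseSD = 3, size = 256L) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rows <- list()
    k <- 0L
    for (sev in c("C0", "C1", "C2")) {
        for (i in seq_len(perClass)) {
            k <- k + 1L
            tooth <- simulateToothImage(sev, size = size, noiseSD = noiseSD,
                                        seed = seed * 1000L + k)
            id <- sprintf("%s_%03d", sev, i)
            writeGrayImage(tooth$image, file.path(dir, paste0(id, ".png")))
            rows[[k]] <- data.frame(
                tooth_id = id, severity = sev,
                surface_area_px = foregroundCount(tooth$surfaceMask),
                discoloration_area_px = foregroundCount(tooth$discolorationMask),
                true_pa = tooth$realizedPA, stringsAsFactors = FALSE)
        }
    }
    gt <- do.call(rbind, rows)
    utils::write.csv(gt, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
    invisible(gt)
}
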