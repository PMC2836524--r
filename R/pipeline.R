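# Batch orchestration: image directory -> feature table -> summary and
# performance reports, with machine-readable provenance.

FEATURE_COLUMNS <- c("tooth_id", "fd", "pa", "dd", "surface_area_px",
                     "discoloration_area_px", "surface_threshold",
                     "discoloration_threshold", "fd_r_squared", "status")

writeProvenance <- function(outDir, config) {
    jsonlite::write_json(
        list(package = "cariesFD",
             version = as.character(utils::packageVersion("cariesFD")),
             config = config),
        file.path(outDir, "provenance.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
}

#' Extract FD and PA features from a batch of tooth images
#'
#' For each image: load and convert to 8-bit grayscale, segment the
#' occlusal surface and the pit-and-fissure discoloration from the
#' intensity histograms, compute PA, and estimate the box-counting FD of
#' the discoloration mask.  Optional DIAGNOdent readings are merged in by
#' `tooth_id` (the image file stem).  A failure on one image is recorded
#' in that row's `status` and does not abort the batch.
#'
#' @param images character vector of image paths, or a single directory
#'   (all png/tif/tiff/jpg/jpeg files are taken).
#' @param ddTable optional data.frame with columns `tooth_id`, `dd`.  A
#'   tooth without a DD reading gets `dd = NA` and `dd_missing = TRUE`.
#' @param method,surfaceThreshold,discolorationThreshold thresholding
#'   configuration, see [segmentTooth()].
#' @param outDir optional directory; when given, `features.csv` and
#'   `provenance.json` (configuration + package version) are written
#'   there.
#' @return data.frame with one row per image: `tooth_id`, `fd`, `pa`,
#'   `dd`, areas, thresholds, `fd_r_squared`, `status` (`"ok"` or the
#'   error message).
#' @export
runFeatures <- function(images, ddTable = NULL,
                        method = c("otsu", "manual"),
                        surfaceThreshold = NULL,
                        discolorationThreshold = NULL, outDir = NULL) {
    method <- match.arg(method)
    if (length(images) == 1L && dir.exists(images))
        images <- list.files(images, "\\.(png|tiff?|jpe?g)$",
                             full.names = TRUE, ignore.case = TRUE)
    if (length(images) == 0L) {
        warning("no input images")
        empty <- as.data.frame(
            stats::setNames(rep(list(character(0)), length(FEATURE_COLUMNS)),
                            FEATURE_COLUMNS))
        return(empty)
    }
    rows <- lapply(images, function(path) {
        id <- sub("\\.[^.]+$", "", basename(path))
        row <- data.frame(tooth_id = id, fd = NA_real_, pa = NA_real_,
                          dd = NA_real_, surface_area_px = NA_integer_,
                          discoloration_area_px = NA_integer_,
                          surface_threshold = NA_real_,
                          discoloration_threshold = NA_real_,
                          fd_r_squared = NA_real_, status = "ok",
                          stringsAsFactors = FALSE)
        tryCatch({
            img <- readToothImage(path)
            seg <- segmentTooth(img, method = method,
                                surfaceThreshold = surfaceThreshold,
                                discolorationThreshold = discolorationThreshold)
            curve <- estimateFD(seg@discolorationMask)
            row$fd <- fd(curve)
            row$fd_r_squared <- rSquared(curve)
            row$pa <- pa(seg)
            row$surface_area_px <- surfaceArea(seg)
            row$discoloration_area_px <- discolorationArea(seg)
            row$surface_threshold <- seg@surfaceMask@metadata$threshold
            row$discoloration_threshold <-
                seg@discolorationMask@metadata$threshold
        }, error = function(e) row$status <<- conditionMessage(e))
        row
    })
    out <- do.call(rbind, rows)
    if (!is.null(ddTable)) {
        stopifnot(all(c("tooth_id", "dd") %in% names(ddTable)))
        out$dd <- ddTable$dd[match(out$tooth_id, ddTable$tooth_id)]
    }
    out$dd_missing <- is.na(out$dd)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(out, file.path(outDir, "features.csv"),
                         row.names = FALSE)
        writeProvenance(outDir, list(
            command = "features", method = method,
            surfaceThreshold = surfaceThreshold,
            discolorationThreshold = discolorationThreshold,
            nImages = length(images)))
    }
    out
}

resolveModel <- function(model) {
    if (is(model, "DiscriminantModel")) return(model)
    if (is.character(model) && length(model) == 1L) {
        if (file.exists(model)) return(readDiscriminantModel(model))
        return(referenceModel(model))
    }
    stop("model must be a DiscriminantModel, a built-in name, or a JSON path")
}

#' Per-class summary and diagnostic-performance report
#'
#' Produces (i) the per-diagnosis mean (SD) block of FD, PA and DD and
#' (ii) a performance block — sensitivity, specificity, accuracy of the
#' chosen discriminant model against the recorded treatment labels
#' (resubstitution when the model was fitted on the same table).
#' Single-variable models also report their feature-axis decision
#' threshold.  Without treatment labels the evaluation block is dropped
#' with a warning and the features-only summary is still returned.
#'
#' @param features feature data.frame (as from [runFeatures()] or
#'   [simulateFeatureTable()]).
#' @param model a [DiscriminantModel-class], a built-in name accepted by
#'   [referenceModel()], or a path to a model JSON file.
#' @param outDir optional directory for `class_summary.csv`,
#'   `performance.csv` and `provenance.json`.
#' @return list of class `cariesReport`: `classSummary` (data.frame or
#'   `NULL`), `performance` ([ClassificationReport-class] or `NULL`),
#'   `threshold` (numeric or `NULL`), `model`, `predictions`.
#' @export
runReport <- function(features, model = "fd", outDir = NULL) {
    mdl <- resolveModel(model)
    cs <- if ("diagnosis" %in% names(features) &&
              !all(is.na(features$diagnosis)))
        classSummary(features) else NULL
    ok <- stats::complete.cases(features[, mdl@variables, drop = FALSE])
    pred <- rep(NA_character_, nrow(features))
    pred[ok] <- predict(mdl, features[ok, , drop = FALSE])$treatment
    perf <- NULL
    if ("treatment" %in% names(features) &&
        !all(is.na(features$treatment))) {
        use <- ok & !is.na(features$treatment)
        perf <- evaluateTreatments(pred[use], features$treatment[use])
    } else {
        warning("no treatment labels: evaluation block skipped")
    }
    thr <- if (length(mdl@variables) == 1L) decisionThreshold(mdl) else NULL
    rep <- structure(list(classSummary = cs, performance = perf,
                          threshold = thr, model = mdl, predictions = pred),
                     class = "cariesReport")
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        if (!is.null(cs))
            utils::write.csv(cs, file.path(outDir, "class_summary.csv"),
                             row.names = FALSE)
        if (!is.null(perf))
            utils::write.csv(
                data.frame(variables = paste(mdl@variables, collapse = "+"),
                           sensitivity = perf@sensitivity,
                           specificity = perf@specificity,
                           accuracy = perf@accuracy,
                           threshold = if (is.null(thr)) NA_real_ else thr),
                file.path(outDir, "performance.csv"), row.names = FALSE)
        writeProvenance(outDir, list(
            command = "report",
            model = list(variables = mdl@variables,
                         coefficients = unname(mdl@coefficients),
                         intercept = mdl@intercept)))
    }
    rep
}

#' @describeIn runReport Formatted printing: FD to 2 decimals, PA to 3,
#'   DD to 1, metrics to 2.
#' @param x a `cariesReport`.
#' @param ... unused.
#' @export
print.cariesReport <- function(x, ...) {
    if (!is.null(x$classSummary)) {
        cat("Per-class features, mean (SD):\n")
        cs <- x$classSummary
        for (i in seq_len(nrow(cs))) {
            line <- sprintf("  %s (n=%d)", cs$diagnosis[i], cs$n[i])
            if ("fd_mean" %in% names(cs))
                line <- paste0(line, sprintf("  FD %.2f (%.2f)",
                                             cs$fd_mean[i], cs$fd_sd[i]))
            if ("pa_mean" %in% names(cs))
                line <- paste0(line, sprintf("  PA %.3f (%.3f)",
                                             cs$pa_mean[i], cs$pa_sd[i]))
            if ("dd_mean" %in% names(cs))
                line <- paste0(line, sprintf("  DD %.1f (%.1f)",
                                             cs$dd_mean[i], cs$dd_sd[i]))
            cat(line, "\n")
        }
    }
    mdl <- x$model
    terms <- paste(sprintf("%.4g %s", mdl@coefficients,
                           toupper(mdl@variables)), collapse = " + ")
    cat(sprintf("Model: Y = %s %+.4g\n", terms, mdl@intercept))
    if (!is.null(x$threshold)) {
        v <- mdl@variables
        digits <- c(fd = 2L, pa = 3L, dd = 1L)[v]
        if (is.na(digits)) digits <- 3L
        cat(sprintf("Decision threshold (%s): %s\n", toupper(v),
                    formatC(x$threshold, format = "f", digits = digits)))
    }
    if (!is.null(x$performance)) {
        p <- x$performance
        cat(sprintf(
            "Performance: sensitivity %.2f  specificity %.2f  accuracy %.2f\n",
            p@sensitivity, p@specificity, p@accuracy))
    }
    invisible(x)
}

#' Read / write the standard feature-table CSV
#'
#' Columns `tooth_id, fd, pa, dd, diagnosis, treatment` (the last two
#' optional).
#'
#' @param path CSV file path.
#' @param features feature data.frame.
#' @return `readFeatureTable`: data.frame; `writeFeatureTable`: `path`
#'   invisibly.
#' @export
readFeatureTable <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readFeatureTable
#' @export
writeFeatureTable <- function(features, path) {
    utils::write.csv(features, path, row.names = FALSE)
    invisible(path)
}
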