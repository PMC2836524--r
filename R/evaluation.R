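# Diagnostic-performance metrics and rank correlation.

#' Confusion counts and diagnostic metrics for treatment predictions
#'
#' The positive class is operative treatment.  Sensitivity is the
#' fraction of truly operative teeth called operative, specificity the
#' fraction of truly preventive teeth called preventive, and accuracy the
#' overall fraction of teeth on which predicted and clinician treatment
#' plans agree.  When the truth labels lack a class, the corresponding
#' metric is undefined and returned as `NA` with a warning.
#'
#' @param predicted,truth equal-length vectors of `"preventive"` /
#'   `"operative"` labels.
#' @return A [ClassificationReport-class].
#' @examples
#' evaluateTreatments(rep(c("operative", "preventive"), c(9, 11)),
#'                    rep(c("operative", "preventive"), c(10, 10)))
#' @export
evaluateTreatments <- function(predicted, truth) {
    p <- as.character(predicted); t <- as.character(truth)
    if (length(p) != length(t)) stop("length mismatch")
    if (length(p) == 0L) stop("no records")
    if (!all(c(p, t) %in% TREATMENT_LEVELS))
        stop("labels must be 'preventive' or 'operative'")
    tp <- sum(p == "operative" & t == "operative")
    fn <- sum(p == "preventive" & t == "operative")
    tn <- sum(p == "preventive" & t == "preventive")
    fp <- sum(p == "operative" & t == "preventive")
    sens <- if (tp + fn == 0L) {
        warning("sensitivity undefined: no operative teeth in truth")
        NA_real_
    } else tp / (tp + fn)
    spec <- if (tn + fp == 0L) {
        warning("specificity undefined: no preventive teeth in truth")
        NA_real_
    } else tn / (tn + fp)
    new("ClassificationReport", tp = tp, fn = fn, tn = tn, fp = fp,
        sensitivity = sens, specificity = spec,
        accuracy = (tp + tn) / length(p))
}

#' Spearman rank correlation (tie-aware)
#'
#' Pearson correlation of midranks, i.e. `stats::cor(..., method =
#' "spearman")`, with the degenerate constant-sequence case flagged as
#' `NA`.  Clinical severity labels C0/C1/C2 can be passed directly; they
#' are coded ordinally as 0/1/2.
#'
#' @param x,y equal-length (>= 3) numeric vectors, or character/factor
#'   vectors of C0/C1/C2 labels.
#' @return Correlation in \[-1, 1\], or `NA` when either sequence is
#'   constant.
#' @examples
#' spearmanRho(c("C0", "C0", "C1", "C2"), c(10, 14, 40, 60))
#' @export
spearmanRho <- function(x, y) {
    x <- codeOrdinal(x); y <- codeOrdinal(y)
    if (length(x) != length(y)) stop("length mismatch")
    if (length(x) < 3L) stop("need at least 3 pairs")
    if (anyNA(x) || anyNA(y)) stop("missing values")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("correlation undefined for a constant sequence")
        return(NA_real_)
    }
    stats::cor(x, y, method = "spearman")
}

# C0/C1/C2 -> 0/1/2; numeric input passes through.
codeOrdinal <- function(x) {
    if (is.numeric(x)) return(x)
    x <- as.character(x)
    if (all(x %in% c("C0", "C1", "C2")))
        return(match(x, c("C0", "C1", "C2")) - 1)
    suppressWarnings(v <- as.numeric(x))
    if (anyNA(v)) stop("cannot code non-ordinal labels: ",
                       paste(unique(x), collapse = ", "))
    v
}

#' Per-diagnosis feature summary
#'
#' Mean and standard deviation of FD, PA and DD within each clinical
#' diagnosis class (C0/C1/C2), the standard per-class summary layout for
#' this kind of feature table.
#'
#' @param records data.frame with columns `diagnosis` and any of `fd`,
#'   `pa`, `dd`.
#' @return data.frame with one row per diagnosis: `n` and
#'   `<feature>_mean` / `<feature>_sd` columns.
#' @export
classSummary <- function(records) {
    if (!"diagnosis" %in% names(records)) stop("missing diagnosis column")
    feats <- intersect(c("fd", "pa", "dd"), names(records))
    if (length(feats) == 0L) stop("no feature columns found")
    cls <- sort(unique(as.character(records$diagnosis)))
    rows <- lapply(cls, function(cl) {
        sub <- records[records$diagnosis == cl, , drop = FALSE]
        out <- list(diagnosis = cl, n = nrow(sub))
        for (f in feats) {
            out[[paste0(f, "_mean")]] <- mean(sub[[f]], na.rm = TRUE)
            out[[paste0(f, "_sd")]] <- stats::sd(sub[[f]], na.rm = TRUE)
        }
        as.data.frame(out, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
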