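# Two-class linear discriminant functions mapping (FD, PA, DD) features
# to a preventive/operative treatment decision.

TREATMENT_LEVELS <- c("preventive", "operative")

#' Construct a discriminant model from explicit coefficients
#'
#' @param variables character vector of feature names (e.g. `"fd"`,
#'   `"pa"`, `"dd"`).
#' @param coefficients numeric weights, one per variable.
#' @param intercept numeric constant.
#' @return A [DiscriminantModel-class] with score
#'   `Y = sum(coefficients * features) + intercept` and decision
#'   `Y > 0 => operative`.
#' @examples
#' discriminantModel("fd", 6.74, -8.12)
#' @export
discriminantModel <- function(variables, coefficients, intercept) {
    new("DiscriminantModel", variables = as.character(variables),
        coefficients = stats::setNames(as.numeric(coefficients),
                                       as.character(variables)),
        intercept = as.numeric(intercept))
}

#' Built-in reference discriminant formulas
#'
#' The four discriminant formulas estimated on the original 100-tooth
#' clinical sample, usable without refitting:
#'
#' * `"fd"`:    Y = 6.74 FD - 8.12  (threshold FD = 1.20)
#' * `"pa"`:    Y = 63.3 PA - 0.77  (threshold PA = 0.012)
#' * `"dd"`:    Y = 0.05 DD - 1.44  (threshold DD = 28.8)
#' * `"fd-pa"`: Y = 5.68 FD + 17.8 PA - 7.29
#'
#' @param name one of `"fd"`, `"pa"`, `"dd"`, `"fd-pa"`.
#' @return A [DiscriminantModel-class].
#' @examples
#' predict(referenceModel("fd"), data.frame(fd = 1.52))
#' @export
referenceModel <- function(name = c("fd", "pa", "dd", "fd-pa")) {
    name <- match.arg(name)
    switch(name,
           "fd"    = discriminantModel("fd", 6.74, -8.12),
           "pa"    = discriminantModel("pa", 63.3, -0.77),
           "dd"    = discriminantModel("dd", 0.05, -1.44),
           "fd-pa" = discriminantModel(c("fd", "pa"), c(5.68, 17.8), -7.29))
}

#' Fit a two-class linear discriminant for treatment planning
#'
#' Fisher linear discriminant with pooled within-class covariance.  The
#' weight vector is `solve(S_pooled, mu_operative - mu_preventive)`,
#' rescaled so the pooled within-class variance of the score is 1 (which
#' makes coefficients comparable across feature subsets).  The intercept
#' places the zero crossing of the score at the class-frequency-weighted
#' midpoint of the two class score means, i.e. at the grand centroid of
#' the training data, so unequal class sizes shift the cut toward the
#' larger class's side.  Orientation: the operative class mean score is
#' positive.
#'
#' @param records data.frame of feature records with the selected
#'   variable columns and a `treatment` column with values
#'   `"preventive"` / `"operative"` (both classes present, >= 2 records
#'   each, no missing values in the selected variables).
#' @param variables character vector of feature column names to use.
#' @return A [DiscriminantModel-class].
#' @examples
#' tab <- data.frame(fd = c(rnorm(30, 1.1, 0.15), rnorm(30, 1.45, 0.1)),
#'                   treatment = rep(c("preventive", "operative"), each = 30))
#' decisionThreshold(fitDiscriminant(tab, "fd"))
#' @export
fitDiscriminant <- function(records, variables = c("fd", "pa", "dd")) {
    if (!all(variables %in% names(records)))
        stop("missing feature column(s): ",
             paste(setdiff(variables, names(records)), collapse = ", "))
    if (!"treatment" %in% names(records)) stop("missing treatment column")
    tr <- as.character(records$treatment)
    if (!all(tr %in% TREATMENT_LEVELS))
        stop("treatment labels must be 'preventive' or 'operative'")
    X <- as.matrix(records[, variables, drop = FALSE])
    if (anyNA(X)) stop("missing values in the selected variables")
    np <- sum(tr == "preventive"); no <- sum(tr == "operative")
    if (np < 2L || no < 2L)
        stop("both classes must be present with >= 2 records each")
    Xp <- X[tr == "preventive", , drop = FALSE]
    Xo <- X[tr == "operative", , drop = FALSE]
    mup <- colMeans(Xp); muo <- colMeans(Xo)
    Sp <- ((np - 1) * stats::cov(Xp) + (no - 1) * stats::cov(Xo)) /
        (np + no - 2)
    w <- tryCatch(solve(Sp, muo - mup),
                  error = function(e) stop("degenerate features"))
    s2 <- drop(crossprod(w, Sp %*% w))
    if (!is.finite(s2) || s2 <= 0) stop("degenerate features")
    w <- w / sqrt(s2)
    grand <- (np * mup + no * muo) / (np + no)
    discriminantModel(variables, w, -sum(w * grand))
}

#' Predict treatment from a discriminant model
#'
#' Evaluates the linear score `Y` for each record and assigns
#' `"operative"` when `Y > 0`, `"preventive"` otherwise — the tie
#' `Y = 0` is resolved conservatively to preventive care.
#'
#' @param object a [DiscriminantModel-class].
#' @param newdata data.frame (or named vector) supplying every model
#'   variable.
#' @param ... unused.
#' @return data.frame with columns `score` and `treatment`.
#' @examples
#' predict(referenceModel("fd"), data.frame(fd = c(1.09, 1.52)))
#' @export
setMethod("predict", "DiscriminantModel", function(object, newdata, ...) {
    if (!is.data.frame(newdata))
        newdata <- as.data.frame(as.list(newdata))
    miss <- setdiff(object@variables, names(newdata))
    if (length(miss) > 0L)
        stop("missing feature: ", paste(miss, collapse = ", "))
    X <- as.matrix(newdata[, object@variables, drop = FALSE])
    if (anyNA(X)) stop("missing feature value")
    y <- drop(X %*% object@coefficients) + object@intercept
    data.frame(score = y,
               treatment = ifelse(y > 0, "operative", "preventive"),
               stringsAsFactors = FALSE)
})

#' @rdname decisionThreshold
setMethod("decisionThreshold", "DiscriminantModel", function(model) {
    if (length(model@variables) != 1L)
        stop("decision threshold is defined for single-variable models only")
    a <- model@coefficients[[1L]]
    if (a == 0) stop("zero coefficient")
    -model@intercept / a
})

# model JSON round trip ------------------------------------------------------

#' Write / read a discriminant model as JSON
#'
#' Serializes variables, coefficients, intercept and the decision
#' convention.  Besides human-readable decimal numbers, the file carries
#' C99 hexadecimal float renderings (`coefficients_hex`,
#' `intercept_hex`) which the reader prefers, so a write/read round trip
#' is bit-exact.
#'
#' @param model a [DiscriminantModel-class].
#' @param path JSON file path.
#' @return `writeDiscriminantModel`: `path` invisibly;
#'   `readDiscriminantModel`: a [DiscriminantModel-class].
#' @export
writeDiscriminantModel <- function(model, path) {
    jsonlite::write_json(
        list(variables = model@variables,
             coefficients = unname(model@coefficients),
             intercept = model@intercept,
             coefficients_hex = sprintf("%a", unname(model@coefficients)),
             intercept_hex = sprintf("%a", model@intercept),
             convention = "Y = sum(coefficients * features) + intercept; Y > 0 => operative"),
        path, auto_unbox = FALSE, digits = NA)
    invisible(path)
}

#' @rdname writeDiscriminantModel
#' @export
readDiscriminantModel <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    co <- if (!is.null(j$coefficients_hex)) as.numeric(j$coefficients_hex)
          else j$coefficients
    ic <- if (!is.null(j$intercept_hex)) as.numeric(j$intercept_hex)
          else j$intercept
    discriminantModel(j$variables, co, ic)
}
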