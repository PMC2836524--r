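test_that("symmetric 1-D classes put the threshold at the midpoint", {
    set.seed(21)
    x <- c(rnorm(200, -1, 0.5), rnorm(200, 1, 0.5))
    tab <- data.frame(fd = c(x[1:200] - mean(x[1:200]) - 1,
                             x[201:400] - mean(x[201:400]) + 1),
                      treatment = rep(c("preventive", "operative"),
                                      each = 200))
    m <- fitDiscriminant(tab, "fd")
    expect_equal(decisionThreshold(m), 0, tolerance = 1e-10)
})

test_that("the fitted 1-D cutoff equals the closed-form pooled cutoff", {
    set.seed(22)
    for (i in 1:5) {
        n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
        x <- c(rnorm(n1, runif(1, 0.8, 1.2), 0.2),
               rnorm(n2, runif(1, 1.3, 1.7), 0.15))
        op <- rep(c(FALSE, TRUE), c(n1, n2))
        tab <- data.frame(fd = x,
                          treatment = ifelse(op, "operative", "preventive"))
        m <- fitDiscriminant(tab, "fd")
        expect_equal(decisionThreshold(m), closedFormCutoff(x, op),
                     tolerance = 1e-10)
    }
})

test_that("linearly separable 2-D classes are classified perfectly", {
    set.seed(23)
    tab <- data.frame(fd = c(runif(50, 0.8, 1.0), runif(50, 1.4, 1.6)),
                      pa = c(runif(50, 0.001, 0.01), runif(50, 0.04, 0.08)),
                      treatment = rep(c("preventive", "operative"), each = 50))
    m <- fitDiscriminant(tab, c("fd", "pa"))
    rep <- evaluateTreatments(predict(m, tab)$treatment, tab$treatment)
    expect_equal(rep@accuracy, 1)
})

test_that("fitDiscriminant rejects degenerate input", {
    tab1 <- data.frame(fd = rnorm(10), treatment = "operative")
    expect_error(fitDiscriminant(tab1, "fd"), "both classes")
    tab2 <- data.frame(fd = rnorm(20), pa = 0.01,  # constant second feature
                       treatment = rep(c("preventive", "operative"), 10))
    expect_error(fitDiscriminant(tab2, c("fd", "pa")), "degenerate features")
    tab3 <- data.frame(fd = c(NA, rnorm(19)),
                       treatment = rep(c("preventive", "operative"), 10))
    expect_error(fitDiscriminant(tab3, "fd"), "missing values")
})

test_that("reference formula scores evaluate exactly and classify by sign", {
    m <- referenceModel("fd")
    # C2-typical tooth (FD at the operative end of the scale)
    p2 <- predict(m, data.frame(fd = 1.52))
    expect_equal(p2$score, 6.74 * 1.52 - 8.12)   # 2.1248
    expect_identical(p2$treatment, "operative")
    # C0-typical tooth
    p0 <- predict(m, data.frame(fd = 1.09))
    expect_equal(p0$score, 6.74 * 1.09 - 8.12)   # -0.7734
    expect_identical(p0$treatment, "preventive")
    # the tie Y = 0 resolves to preventive
    pt <- predict(m, data.frame(fd = 8.12 / 6.74))
    expect_equal(pt$score, 0)
    expect_identical(pt$treatment, "preventive")
    expect_error(predict(m, data.frame(pa = 0.01)), "missing feature")
})

test_that("reference decision thresholds match their printed values", {
    expect_equal(round(decisionThreshold(referenceModel("fd")), 2), 1.20)
    expect_equal(round(decisionThreshold(referenceModel("pa")), 3), 0.012)
    expect_equal(round(decisionThreshold(referenceModel("dd")), 1), 28.8)
    expect_error(decisionThreshold(referenceModel("fd-pa")),
                 "single-variable")
    expect_error(decisionThreshold(discriminantModel("fd", 0, 1)),
                 "zero coefficient")
})

test_that("scores are invariant under compensating feature rescaling", {
    set.seed(24)
    tab <- data.frame(fd = rnorm(40, 1.2, 0.2), dd = rnorm(40, 30, 10),
                      treatment = rep(c("preventive", "operative"), 20))
    m <- fitDiscriminant(tab, c("fd", "dd"))
    k <- 37.5
    m2 <- discriminantModel(c("fd", "dd"),
                            c(m@coefficients[1] / k, m@coefficients[2]),
                            m@intercept)
    tab2 <- tab; tab2$fd <- tab2$fd * k
    expect_equal(predict(m2, tab2)$score, predict(m, tab)$score)
})

test_that("the 1-D threshold always falls strictly between the class means", {
    set.seed(25)
    for (i in 1:10) {
        m1 <- runif(1, 0.8, 1.2); m2 <- m1 + runif(1, 0.2, 0.6)
        x <- c(rnorm(60, m1, 0.15), rnorm(40, m2, 0.12))
        tab <- data.frame(fd = x, treatment = rep(c("preventive", "operative"),
                                                  c(60, 40)))
        thr <- decisionThreshold(fitDiscriminant(tab, "fd"))
        expect_gt(thr, mean(x[1:60]))
        expect_lt(thr, mean(x[61:100]))
    }
})

test_that("fitted direction agrees with the standard LDA implementation", {
    skip_if_not_installed("MASS")
    set.seed(26)
    tab <- data.frame(fd = c(rnorm(80, 1.1, 0.15), rnorm(80, 1.45, 0.1)),
                      pa = c(rnorm(80, 0.006, 0.005), rnorm(80, 0.03, 0.015)),
                      treatment = rep(c("preventive", "operative"), each = 80))
    m <- fitDiscriminant(tab, c("fd", "pa"))
    ld <- MASS::lda(factor(treatment, levels = c("preventive", "operative"))
                    ~ fd + pa, data = tab)
    ratio <- m@coefficients / drop(ld$scaling)
    expect_equal(ratio[[1]], ratio[[2]], tolerance = 1e-8)
    expect_gt(ratio[[1]], 0)  # same orientation: operative positive
    # with equal class sizes the decision boundaries coincide: predicted
    # classes agree on fresh points
    new <- data.frame(fd = rnorm(200, 1.28, 0.25),
                      pa = rnorm(200, 0.018, 0.02))
    ours <- predict(m, new)$treatment
    theirs <- as.character(predict(ld, new)$class)
    expect_identical(ours, theirs)
})

test_that("models round-trip through JSON bit-exactly", {
    set.seed(27)
    tab <- data.frame(fd = rnorm(40, 1.2, 0.2), pa = rnorm(40, 0.02, 0.01),
                      treatment = rep(c("preventive", "operative"), 20))
    m <- fitDiscriminant(tab, c("fd", "pa"))
    f <- tempfile(fileext = ".json")
    writeDiscriminantModel(m, f)
    m2 <- readDiscriminantModel(f)
    expect_identical(m2@variables, m@variables)
    expect_identical(unname(m2@coefficients), unname(m@coefficients))
    expect_identical(m2@intercept, m@intercept)
    unlink(f)
})

test_that("FD cutoffs fitted on reference-distribution tables sit between the class means", {
    # preventive mean 1.09 vs operative pooled mean 1.43 on the reference
    # per-class parameters
    for (s in 1:5) {
        tab <- simulateFeatureTable(seed = 500 + s)
        thr <- decisionThreshold(fitDiscriminant(tab, "fd"))
        expect_gt(thr, 1.09)
        expect_lt(thr, 1.43)
    }
})
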