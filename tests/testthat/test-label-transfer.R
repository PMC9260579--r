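test_that("LDA fitting recovers class means, priors and permutation invariance", {
    tb <- twoBlobs(n = 150, d = 5, sep = 6, seed = 2)
    model <- fitLDA(tb$x, tb$labels)
    expect_identical(model@classes, c("a", "b"))
    expect_equal(sum(model@priors), 1)
    ## estimator consistency: class means within 3 sd / sqrt(n)
    expect_true(all(abs(model@means["a", 1:2] - 6) < 3 / sqrt(150)))
    expect_true(all(abs(model@means["b", ]) < 3 / sqrt(150)))
    ## permuting cells with labels leaves the model unchanged
    set.seed(5)
    o <- sample(nrow(tb$x))
    m2 <- fitLDA(tb$x[o, ], tb$labels[o])
    expect_equal(model@means, m2@means, tolerance = 1e-12)
    expect_equal(model@sigma, m2@sigma, tolerance = 1e-12)
    ## too-small classes are rejected
    expect_error(fitLDA(tb$x[c(1:3, 151:153), ], tb$labels[c(1:3, 151:153)]),
                 "n_markers")
})

test_that("posteriors match the closed-form 1-D logistic and normalise", {
    ## N(0,1) vs N(4,1), equal priors, x = 0: posterior 1/(1+e^-8)
    model <- new("LDAModel", classes = c("lo", "hi"),
                 means = matrix(c(0, 4), 2, 1,
                                dimnames = list(c("lo", "hi"), "m")),
                 sigma = matrix(1, 1, 1, dimnames = list("m", "m")),
                 priors = c(0.5, 0.5), epsReg = 0, markers = "m")
    x <- matrix(0, 1, 1, dimnames = list(NULL, "m"))
    r95 <- predictWithRejection(model, x, tau = 0.95)
    expect_equal(r95@posterior, 1 / (1 + exp(-8)), tolerance = 1e-12)
    expect_equal(r95@posterior, 0.99966, tolerance = 1e-4)
    expect_identical(r95@predicted, "lo")
    ## the same cell is rejected at tau = 1
    r100 <- predictWithRejection(model, x, tau = 1)
    expect_true(r100@rejected)
    ## equidistant point: posterior 0.5 each, rejected at 0.95
    xm <- matrix(2, 1, 1, dimnames = list(NULL, "m"))
    rm_ <- predictWithRejection(model, xm, tau = 0.95)
    expect_equal(rm_@posterior, 0.5, tolerance = 1e-12)
    expect_true(rm_@rejected)
})

test_that("posteriors equal the quadratic-form oracle and sum to one", {
    tb <- twoBlobs(n = 120, d = 5, sep = 4, seed = 3)
    model <- fitLDA(tb$x, tb$labels)
    set.seed(4)
    xs <- tb$x[sample(nrow(tb$x), 20), , drop = FALSE]
    lp <- cytomodules:::.ldaLogPosterior(model, xs)
    expect_equal(rowSums(exp(lp)), rep(1, 20), tolerance = 1e-12)
    for (i in 1:5) {
        oracle <- ldaPosteriorOracle(model@means, model@sigma,
                                     model@priors, xs[i, ])
        expect_equal(exp(lp[i, ]), oracle, tolerance = 1e-10,
                     ignore_attr = TRUE)
    }
    ## tau -> 0+ equals plain argmax classification (no rejection)
    r <- predictWithRejection(model, tb$x, tau = 1e-9)
    expect_false(any(r@rejected))
    expect_identical(r@predicted,
                     model@classes[max.col(lp2 <-
                         cytomodules:::.ldaLogPosterior(model, tb$x))])
})

test_that("raising tau never increases the matched fraction", {
    tb <- twoBlobs(n = 200, d = 5, sep = 2.5, seed = 6)
    model <- fitLDA(tb$x, tb$labels)
    taus <- c(0.5, 0.8, 0.95, 0.99, 1)
    mf <- vapply(taus, function(tau)
        predictWithRejection(model, tb$x, tau = tau)@matchedFraction, 0)
    expect_true(all(diff(mf) <= 1e-12))
})

test_that("LDA agrees with an independent reference implementation", {
    skip_if_not_installed("MASS")
    tb <- twoBlobs(n = 150, d = 5, sep = 5, seed = 8)
    model <- fitLDA(tb$x, tb$labels, epsReg = 0)
    r <- predictWithRejection(model, tb$x, tau = 1e-9)
    ref <- MASS::lda(tb$x, grouping = tb$labels)
    refPred <- stats::predict(ref, tb$x)
    expect_gt(mean(r@predicted == as.character(refPred$class)), 0.999)
    expect_equal(r@posterior,
                 apply(refPred$posterior, 1L, max), tolerance = 1e-6)
})

test_that("confusion is diagonal-dominant for well-separated classes", {
    set.seed(11)
    d <- 6; K <- 4
    means <- matrix(rnorm(K * d, sd = 4), K, d)
    x <- do.call(rbind, lapply(seq_len(K), function(k)
        sweep(matrix(rnorm(200 * d), 200, d), 2L, means[k, ], "+")))
    colnames(x) <- paste0("m", 1:d)
    labels <- rep(paste0("c", 1:K), each = 200)
    ## keep only pairs with Mahalanobis distance >= 4 (identity covariance)
    dists <- as.matrix(dist(means))
    skip_if(min(dists[upper.tri(dists)]) < 4)
    model <- fitLDA(x, labels)
    r <- predictWithRejection(model, x, tau = 1e-9)
    cm <- table(labels, r@predicted)
    expect_true(all(diag(cm) > 0.9 * rowSums(cm)))
})

test_that("cross-cohort transfer reproduces frequencies on a small study", {
    cfgP <- smallConfig("primary")
    cfgV <- smallConfig("validation")
    stP <- simulateStudy(cfgP, seed = 21, markers = "intestinal")
    stV <- simulateStudy(cfgV, seed = 22, markers = "intestinal")
    model <- fitLDA(cellExprs(stP), cellData(stP)$subset)
    pred <- predictWithRejection(model, stV, tau = 0.95)
    predLab <- pred@predicted
    truthLab <- cellData(stV)$subset
    agree <- mean(predLab[!pred@rejected] == truthLab[!pred@rejected])
    expect_gt(agree, 0.98)
    trueF <- trueFrequencies(stV)
    keep <- sampleData(trueF)$tissue != "blood"
    R <- frequencyConcordance(trueF[, keep], pred@freq)
    expect_gt(R, 0.97)
})

test_that("frequency concordance is 1 on identity and decreases with noise", {
    set.seed(13)
    a <- matrix(runif(60, 0, 10), 10, 6,
                dimnames = list(paste0("s", 1:10), paste0("k", 1:6)))
    expect_equal(frequencyConcordance(a, a), 1)
    sds <- c(0.1, 0.5, 2, 8)
    rs <- vapply(sds, function(s) {
        set.seed(99)
        mean(replicate(30, frequencyConcordance(a, a + matrix(
            rnorm(60, sd = s), 10, 6, dimnames = dimnames(a)))))
    }, 0)
    expect_true(all(diff(rs) < 0))
})

test_that("blood matching finds the IBD-enriched HLA-DR+ EM spike-in", {
    cfg <- smallConfig("primary")
    cfg@nSubjects <- setNames(c(8L, 8L, 8L), names(cfg@nSubjects))
    st <- simulateStudy(cfg, seed = 31)
    intCells <- cellData(st)$sample_id %in%
        sampleData(st)$sample_id[sampleData(st)$tissue != "blood"]
    model <- fitLDA(cellExprs(st)[intCells, ],
                    cellData(st)$subset[intCells])
    mb <- matchBloodToTissue(model, st, tau = 0.95)
    ## cells drawn from the training phenotypes: nearly all match
    expect_gt(mb$matched_fraction, 95)
    f <- freqValues(mb$per_sample)
    sdB <- sampleData(mb$per_sample)
    ibd <- sdB$diagnosis %in% c("CD", "UC") & !sdB$is_internal_control
    w <- stats::wilcox.test(f[ibd, "CD4_T_EM_HLADR_CD38"],
                            f[!ibd, "CD4_T_EM_HLADR_CD38"],
                            alternative = "greater", exact = FALSE)
    expect_lt(w$p.value, 0.05)
})
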