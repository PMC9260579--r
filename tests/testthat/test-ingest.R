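test_that("arcsinh transform matches its closed form and is monotone", {
    expect_identical(arcsinhTransform(0), 0)
    expect_equal(arcsinhTransform(5, cofactor = 5), log(1 + sqrt(2)),
                 tolerance = 1e-12)
    expect_equal(arcsinhTransform(5, cofactor = 5), 0.8814, tolerance = 1e-4)
    x <- sort(runif(50, 0, 100))
    expect_true(all(diff(arcsinhTransform(x)) > 0))
    expect_error(arcsinhTransform(1, cofactor = 0), "positive")
})

test_that("CD45 gate retains by threshold and reports counts", {
    cfg <- smallConfig()
    st <- simulateStudy(cfg, seed = 5)
    g <- gateCD45(st, threshold = 1.0)
    ## generator places every subset's CD45 mean >= 3: near-total retention
    expect_gt(nrow(cellExprs(g)) / nrow(cellExprs(st)), 0.99)
    expect_true(all(cellExprs(g)[, "CD45"] >= 1.0))
    expect_equal(sum(sampleData(g)$n_cells_gated), nrow(cellExprs(g)))
    ## -Inf threshold is the identity
    g0 <- gateCD45(st, threshold = -Inf)
    expect_identical(nrow(cellExprs(g0)), nrow(cellExprs(st)))
    ## all-zero CD45 retains nothing
    st0 <- st
    st0@exprs[, "CD45"] <- 0
    expect_identical(nrow(cellExprs(gateCD45(st0))), 0L)
})

test_that("computeFrequencies counts percentages under both denominators", {
    f <- computeFrequencies(c("a", "a", "a", "b", "b", "b", "b", "b", "b",
                              "b"),
                            rep("s1", 10))
    expect_equal(unname(freqValues(f)[1, ]), c(30, 70))
    ## lineage mode: 10 cells of subset x in a 40-cell lineage -> 25
    lab <- c(rep("x", 10), rep("y", 30), rep("z", 60))
    h <- c(x = "L1", y = "L1", z = "L2")
    fl <- computeFrequencies(lab, rep("s1", 100), mode = "lineage",
                             hierarchy = h)
    expect_equal(unname(freqValues(fl)[1, c("x", "y", "z")]), c(25, 75, 100))
    ## rejected (NA) cells leave numerator and denominator
    fr <- computeFrequencies(c("a", "a", NA, "b"), rep("s1", 4))
    expect_equal(unname(freqValues(fr)[1, ]), c(200 / 3, 100 / 3))
    ## permutation invariance in cell order
    set.seed(1)
    lab2 <- sample(letters[1:3], 60, replace = TRUE)
    sid <- sample(c("s1", "s2"), 60, replace = TRUE)
    o <- sample(60)
    f1 <- computeFrequencies(lab2, sid)
    f2 <- computeFrequencies(lab2[o], sid[o])
    expect_equal(freqValues(f1)[rownames(freqValues(f2)), ],
                 freqValues(f2))
})

test_that("true-label frequencies equal the ground-truth counting oracle", {
    cfg <- smallConfig()
    st <- simulateStudy(cfg, seed = 7)
    truth <- groundTruth(st)
    f <- computeFrequencies(cellData(st)$subset, cellData(st)$sample_id,
                            subsetLevels = colnames(truth$counts))
    oracle <- 100 * truth$counts / rowSums(truth$counts)
    expect_equal(freqValues(f)[rownames(oracle), colnames(oracle)], oracle,
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("preprocessing hits arcsine-sqrt endpoints and degenerate columns", {
    m <- matrix(c(0, 25, 100), 3, 1)
    y <- preprocessFrequencies(m, steps = "arcsine_sqrt")
    expect_equal(as.numeric(y), c(0, asin(0.5), pi / 2), tolerance = 1e-12)
    expect_equal(y[2], 0.5236, tolerance = 1e-4)
    ## constant column z-scores to zeros without error
    cm <- cbind(a = c(5, 5, 5), b = c(1, 2, 3))
    z <- preprocessFrequencies(cm, steps = "zscore_columns")
    expect_identical(unname(z[, 1]), c(0, 0, 0))
    expect_equal(mean(z[, 2]), 0)
    expect_equal(sd(z[, 2]), 1)
    expect_error(preprocessFrequencies(matrix(101, 1, 1)), "0, 100")
})

test_that("Spearman correlations are invariant to the arcsine-sqrt map", {
    set.seed(3)
    x <- matrix(runif(80, 0, 100), 10, 8)
    r1 <- spearmanMatrix(x)
    r2 <- spearmanMatrix(preprocessFrequencies(x, steps = "arcsine_sqrt"))
    expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("a study round-trips through the CSV writer", {
    cfg <- smallConfig()
    cfg@nSubjects <- setNames(c(1L, 1L, 1L), names(cfg@nSubjects))
    cfg@nInternalControls <- 1L
    st <- simulateStudy(cfg, seed = 11)
    dir <- withr::local_tempdir()
    man <- writeStudy(st, dir)
    expect_identical(nrow(man), nrow(sampleData(st)))
    rt <- readStudy(dir)
    expect_equal(dim(cellExprs(rt)), dim(cellExprs(st)))
    expect_lt(max(abs(cellExprs(rt) - cellExprs(st))), 1e-5)
    expect_identical(cellData(rt)$subset, cellData(st)$subset)
    expect_identical(as.data.frame(sampleData(rt))$sample_id,
                     as.data.frame(sampleData(st))$sample_id)
    expect_error(writeStudy(st, dir, format = "fcs"), "FCS")
})
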