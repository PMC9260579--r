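test_that("Spearman matrix matches rank formula and brute-force oracle", {
    ## 1 - 6 * sum(d^2) / (n(n^2-1)) with d^2 = (1,1,1,1) -> 0.6
    m <- cbind(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3), z = 1:4)
    m <- rbind(m, m + 10)  # >= 5 samples
    r <- spearmanMatrix(m)
    m5 <- cbind(x = c(1, 2, 3, 4, 6), y = c(2, 1, 4, 3, 6))
    expect_equal(cor(rank(m5[1:4, 1]), rank(m5[1:4, 2])), 0.6)
    ## monotone transforms: x vs 2x + 3 -> 1; x vs -x -> -1
    set.seed(2)
    v <- rnorm(20)
    mm <- cbind(a = v, b = 2 * v + 3, c = -v, d = rnorm(20),
                e = rnorm(20))
    rr <- spearmanMatrix(mm)
    expect_equal(rr["a", "b"], 1)
    expect_equal(rr["a", "c"], -1)
    ## brute-force rank-then-Pearson equivalence on random matrices
    for (i in 1:5) {
        set.seed(i)
        x <- matrix(rnorm(80), 10, 8)
        colnames(x) <- letters[1:8]
        expect_equal(spearmanMatrix(x), spearmanOracle(x),
                     tolerance = 1e-12)
    }
    ## constant columns warn and zero out
    xc <- cbind(a = rep(1, 6), b = rnorm(6), c = rnorm(6))
    expect_warning(rc <- spearmanMatrix(xc), "constant")
    expect_identical(unname(rc["a", "b"]), 0)
    expect_identical(unname(rc["a", "a"]), 1)
})

test_that("module extraction recovers perfect block structure", {
    ## two perfect blocks of 5: within rho = 1, between 0
    rho <- diag(10)
    rho[1:5, 1:5] <- 1
    rho[6:10, 6:10] <- 1
    dimnames(rho) <- list(letters[1:10], letters[1:10])
    mods <- extractModules(rho)
    st <- moduleStats(mods)
    expect_identical(nrow(st), 2L)
    expect_true(all(st$isNetwork))
    expect_identical(sort(st$size), c(5L, 5L))
    ## identity matrix: nothing qualifies
    id <- diag(8)
    dimnames(id) <- list(letters[1:8], letters[1:8])
    stId <- moduleStats(extractModules(id))
    expect_false(any(stId$isNetwork))
    expect_error(extractModules(diag(2)), "3 subsets")
})

test_that("planted correlation blocks are recovered exactly across seeds", {
    hits <- vapply(1:20, function(s) {
        pb <- plantedBlocks(nSamples = 100, blocks = 3, size = 5,
                            factorSd = 1, noiseSd = 0.7, seed = s)
        rho <- spearmanMatrix(pb$x)
        mods <- extractModules(rho)
        mclust::adjustedRandIndex(moduleAssignments(mods), pb$truth) == 1
    }, NA)
    expect_gte(mean(hits), 0.95)
})

test_that("qualification is monotone in the rho threshold", {
    pb <- plantedBlocks(nSamples = 60, blocks = 4, size = 4,
                        factorSd = 1, noiseSd = 1.2, seed = 3)
    rho <- spearmanMatrix(pb$x)
    qualified <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(t)
        sum(moduleStats(extractModules(rho, rhoMin = t))$isNetwork), 0L)
    expect_true(all(diff(qualified) <= 0))
})

test_that("collective frequencies sum member percentages and conserve mass", {
    x <- matrix(c(30, 70, 20, 80, 50, 50), 3, 2, byrow = TRUE,
                dimnames = list(paste0("s", 1:3), c("a", "b")))
    sdf <- S4Vectors::DataFrame(sample_id = paste0("s", 1:3),
                                subject_id = c("p1", "p1", "p2"),
                                status = c("inflamed", "noninflamed",
                                           "inflamed"),
                                is_internal_control = FALSE)
    f <- cytomodules:::.FrequencyMatrix(x, sdf, "total_CD45")
    rho <- diag(2)
    dimnames(rho) <- list(c("a", "b"), c("a", "b"))
    mods <- new("CorrelationModules", rho = rho,
                tree = hclust(as.dist(1 - rho), "average"),
                modules = c(a = 1L, b = 2L),
                moduleStats = S4Vectors::DataFrame(
                    module = 1:2, size = c(1L, 1L), meanRho = c(1, 1),
                    isNetwork = c(TRUE, TRUE)),
                mMin = 1L, rhoMin = 0.3)
    cf <- collectiveFrequencies(f, mods)
    ## single-member module collective equals that subset's percentage
    expect_equal(cf$module1, x[, "a"], ignore_attr = TRUE)
    ## two disjoint modules covering all subsets sum to 100
    expect_equal(cf$module1 + cf$module2, rep(100, 3), ignore_attr = TRUE)
    ## stratification boundaries
    s0 <- stratifyPatients(cf, "module1", cutoff = 99)
    expect_identical(sum(s0$flagged), 0L + sum(c(FALSE, FALSE)))
    s1 <- stratifyPatients(cf, "module1", cutoff = 1)
    expect_true(all(s1$flagged))
    expect_identical(s1$summary, "2/2")
})

test_that("the default synthetic study stratifies high-network2 patients", {
    ## exaggerated patient-subgroup contrast isolates the mechanism
    cfg <- defaultConfig("primary")
    cfg@deltaHigh <- 2.5
    cfg@sigmaMod <- 0.2
    st <- simulateStudy(cfg, seed = 6, markers = FALSE)
    tf <- trueFrequencies(st)
    sd0 <- sampleData(tf)
    keep <- sd0$tissue != "blood"
    fInt <- tf[, keep]
    da <- ttestInflamedVsRest(fInt)
    mods <- extractModules(spearmanMatrix(fInt), da = da)
    cf <- collectiveFrequencies(fInt, mods)
    expect_true("network2" %in% colnames(cf))
    strat <- stratifyPatients(cf, "network2", cutoff = 50)
    truthHigh <- groundTruth(st)$high_network2_subjects
    flagged <- names(strat$flagged)[strat$flagged]
    ## every designated high-network2 patient is flagged
    expect_true(all(truthHigh %in% flagged))
})
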