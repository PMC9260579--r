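test_that("the default configuration matches the designed study structure", {
    cfg <- defaultConfig("primary")
    subs <- subsetCatalog(cfg)
    expect_identical(nrow(subs), 44L)
    sizes <- table(subs$module)
    expect_identical(as.integer(sizes[c("network1", "network2", "network3",
                                        "none")]),
                     c(11L, 21L, 9L, 3L))
    expect_identical(sum(as.integer(sizes)), 44L)
    expect_identical(sum(subs$module == "network1" &
                         subs$effect == "down_in_inflamed"), 10L)
    expect_identical(sum(subs$module == "network2" &
                         subs$effect == "up_in_inflamed"), 11L)
    ## deterministic construction
    expect_identical(defaultConfig("primary"), defaultConfig("primary"))
    ## validation cohort: 3 extra panel markers, same subsets
    cfgV <- defaultConfig("validation")
    expect_identical(length(markerNames(cfgV)), 39L)
    expect_identical(length(markerNames(cfg)), 36L)
    expect_identical(subsetCatalog(cfgV)$subset_id, subs$subset_id)
    expect_error(defaultConfig("nonsense"))
})

test_that("every pair of subset phenotypes is separable by design", {
    cfg <- defaultConfig("primary")
    bad <- cytomodules:::checkSeparability(cfg@means, minMarkers = 2L,
                                           minDiff = 1.5)
    expect_identical(bad, character(0))
})

test_that("simulation is seed-deterministic and truth is self-consistent", {
    cfg <- smallConfig()
    a <- simulateStudy(cfg, seed = 3)
    b <- simulateStudy(cfg, seed = 3)
    expect_identical(cellExprs(a), cellExprs(b))
    expect_identical(groundTruth(a)$counts, groundTruth(b)$counts)
    c_ <- simulateStudy(cfg, seed = 4)
    expect_false(identical(groundTruth(a)$counts, groundTruth(c_)$counts))
    ## pre-sampling proportions sum to one per sample
    expect_true(all(abs(rowSums(groundTruth(a)$probs) - 1) < 1e-9))
    ## realised counts match per-cell labels
    tab <- table(cellData(a)$sample_id, cellData(a)$subset)
    cnt <- groundTruth(a)$counts
    expect_identical(sum(cnt), nrow(cellExprs(a)))
    ## marker values are nonnegative (zero-truncated draws)
    expect_gte(min(cellExprs(a)), 0)
})

test_that("internal controls share one composition; subjects correlate", {
    cfg <- defaultConfig("primary")
    st <- simulateStudy(cfg, seed = 9, markers = FALSE)
    truth <- groundTruth(st)
    sd0 <- sampleData(st)
    ic <- sd0$is_internal_control
    expect_identical(sum(ic), 7L)
    icP <- truth$probs[ic, , drop = FALSE]
    expect_true(all(abs(sweep(icP, 2L, icP[1L, ])) < 1e-12))
    ## subject random effect: same-subject intestinal samples more rank-
    ## correlated than different-subject samples (>= 20 subjects)
    int <- which(sd0$tissue != "blood" & !ic)
    lp <- log(truth$probs[int, ] + 1e-12)
    subj <- sd0$subject_id[int]
    n <- length(int)
    cors <- cor(t(lp), method = "spearman")
    same <- outer(subj, subj, "==") & upper.tri(cors)
    diff_ <- outer(subj, subj, "!=") & upper.tri(cors)
    expect_gte(length(unique(subj)), 20L)
    expect_gt(mean(cors[same]), mean(cors[diff_]))
})

test_that("module construction yields block-structured co-abundance", {
    cfg <- defaultConfig("primary")
    st <- simulateStudy(cfg, seed = 15, markers = FALSE)
    rho <- spearmanMatrix(trueFrequencies(st))
    subs <- subsetCatalog(st)
    n2 <- subs$subset_id[subs$module == "network2"]
    n1 <- subs$subset_id[subs$module == "network1"]
    within2 <- mean(rho[n2, n2][upper.tri(diag(length(n2)))])
    between <- mean(rho[n2, n1])
    expect_gt(within2, between)
    expect_gt(within2, 0.3)
})

test_that("a null generator has near-independent subsets and uniform p", {
    cfg <- defaultConfig("primary")
    cfg@sigmaMod <- 0
    cfg@deltaEffect <- 0
    cfg@deltaHigh <- 0
    cfg@deltaFactor <- 0
    ## (a) no co-abundance: with subject effects also silenced (they only
    ## shrink the effective sample size), residual correlation comes from
    ## compositional closure and counting noise alone
    cfg0 <- cfg
    cfg0@sigmaSubj <- 0
    st <- simulateStudy(cfg0, seed = 20, markers = FALSE)
    rho <- spearmanMatrix(trueFrequencies(st))
    off <- rho[upper.tri(rho)]
    expect_lt(quantile(abs(off), 0.99), 0.3)
    expect_lt(median(abs(off)), 0.12)
    ## (b) inflamed-vs-rest p-values are uniform across many null studies
    ps <- unlist(lapply(1:25, function(s) {
        sti <- simulateStudy(cfg, seed = 300 + s, markers = FALSE)
        da <- ttestInflamedVsRest(trueFrequencies(sti))
        da$p
    }))
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("unknown cohort tags and invalid configs are rejected", {
    expect_error(defaultConfig("tertiary"))
    cfg <- smallConfig()
    cfg@cellsPerSample <- c(ileum = 10, colon = 10, blood = 10)
    expect_error(simulateStudy(cfg, seed = 1), ">= 100")
    cfg2 <- smallConfig()
    cfg2@sds[1, 1] <- -1
    expect_error(simulateStudy(cfg2, seed = 1), "positive")
})
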