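test_that("lineage scoring follows signatures with a documented tie-break", {
    panel <- defaultPanel()
    m <- matrix(0, 3, length(markerNames(panel)),
                dimnames = list(NULL, markerNames(panel)))
    m[1, c("CD3", "CD4")] <- 4          # CD4 T cell
    m[2, c("CD3", "CD8")] <- 4          # CD8 T cell
    ## row 3 all zero: every score ties at 0 -> first lineage in order
    lin <- assignLineages(m, panel)
    expect_identical(lin, c("CD4T", "CD8T", "CD4T"))
    ## missing signature markers are an error
    expect_error(assignLineages(m[, 1:5], panel), "missing")
})

test_that("lineage assignment on synthetic cells is near-perfect", {
    cfg <- smallConfig()
    st <- simulateStudy(cfg, seed = 12)
    lin <- assignLineages(st)
    expect_gt(mean(lin == cellData(st)$lineage), 0.98)
})

test_that("BIC selects one component for a single Gaussian cloud", {
    hits <- vapply(1:20, function(s) {
        set.seed(s)
        x <- matrix(rnorm(500 * 4), 500, 4)
        colnames(x) <- paste0("m", 1:4)
        lab <- suppressWarnings(
            clusterWithinLineage(x, rep("L", 500), kRange = 1:5,
                                 seed = s))
        lab@fits$L$G == 1L
    }, NA)
    expect_gte(mean(hits), 0.95)
})

test_that("two well-separated Gaussians give k = 2 and accurate labels", {
    tb <- twoBlobs(n = 400, d = 4, sep = 6, seed = 14)
    lab <- clusterWithinLineage(tb$x, rep("L", nrow(tb$x)), kRange = 1:5,
                                seed = 2)
    expect_identical(lab@fits$L$G, 2L)
    acc <- max(mean((lab@subset == "L_1") == (tb$labels == "a")),
               mean((lab@subset == "L_2") == (tb$labels == "a")))
    expect_gte(acc, 0.99)
    ## subset ids are numbered by decreasing size and map to the lineage
    expect_gte(sum(lab@subset == "L_1"), sum(lab@subset == "L_2"))
    expect_identical(unname(lab@hierarchy), rep("L", 2L))
})

test_that("clustering is invariant to cell order and marker offsets", {
    tb <- twoBlobs(n = 200, d = 4, sep = 6, seed = 15)
    lab <- clusterWithinLineage(tb$x, rep("L", nrow(tb$x)), kRange = 1:4,
                                seed = 3)
    ## permutation of cells
    set.seed(4)
    o <- sample(nrow(tb$x))
    labP <- clusterWithinLineage(tb$x[o, ], rep("L", nrow(tb$x)),
                                 kRange = 1:4, seed = 3)
    expect_identical(mclust::adjustedRandIndex(lab@subset[o], labP@subset),
                     1)
    ## adding a constant to all markers
    labC <- clusterWithinLineage(tb$x + 3, rep("L", nrow(tb$x)),
                                 kRange = 1:4, seed = 3)
    expect_identical(mclust::adjustedRandIndex(lab@subset, labC@subset), 1)
})

test_that("tiny lineages reduce the k range with a warning", {
    set.seed(6)
    x <- matrix(rnorm(30 * 3), 30, 3)
    colnames(x) <- paste0("m", 1:3)
    expect_warning(
        lab <- clusterWithinLineage(x, rep("L", 30), kRange = 1:10),
        "reduced k range")
    expect_lte(lab@fits$L$G, 3L)
})

test_that("subset profiles are order-invariant medians with counts", {
    tb <- twoBlobs(n = 50, d = 4, sep = 8, seed = 18)
    pr <- profileSubsets(tb$x, tb$labels)
    expect_identical(unname(pr$counts), c(50L, 50L))
    expect_equal(pr$medians["a", 1], median(tb$x[1:50, 1]))
    o <- sample(100)
    pr2 <- profileSubsets(tb$x[o, ], tb$labels[o])
    expect_equal(pr$medians, pr2$medians)
    ## identical cells: medians equal the common vector
    xid <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
    colnames(xid) <- paste0("m", 1:3)
    prid <- profileSubsets(xid, rep("only", 5))
    expect_equal(unname(prid$medians["only", ]), c(1, 2, 3))
    ## empty subset flagged as NaN with a warning
    expect_warning(pr3 <- profileSubsets(tb$x,
        factor(tb$labels, levels = c("a", "b", "ghost"))), "empty")
})

test_that("recovered medians track the generator's designed phenotypes", {
    cfg <- smallConfig()
    st <- simulateStudy(cfg, seed = 23)
    pr <- profileSubsets(cellExprs(st), cellData(st)$subset)
    big <- names(pr$counts)[pr$counts >= 200]
    dev <- abs(pr$medians[big, markerNames(cfg)] -
               cfg@means[big, markerNames(cfg)])
    ## medians within 0.2 arcsinh units of the design for populous subsets
    ## (low-expression channels are zero-truncated, shifting the median up
    ## by less than that tolerance)
    expect_lt(max(dev), 0.2)
})

test_that("truth matching gives ARI 1 on itself and ~0 for random labels", {
    cfg <- smallConfig()
    st <- simulateStudy(cfg, seed = 25)
    truthLab <- cellData(st)$subset
    self <- matchToTruth(truthLab, truthLab)
    expect_identical(self$ari, 1)
    expect_true(all(self$mapping[names(self$mapping)] == names(self$mapping)))
    set.seed(1)
    rnd <- sample(unique(truthLab), 10000, replace = TRUE)
    r <- matchToTruth(rnd, sample(unique(truthLab), 10000, replace = TRUE))
    expect_lt(abs(r$ari), 0.01)
    ## merging two true subsets strictly decreases ARI (3-subset toy)
    toy <- rep(c("a", "b", "c"), each = 30)
    merged <- ifelse(toy == "b", "a", toy)
    expect_lt(matchToTruth(merged, toy)$ari, 1)
    expect_gt(matchToTruth(merged, toy)$ari, 0)
})

test_that("maximal-overlap matching solves a known assignment exactly", {
    ## recovered labels are a renaming of truth plus asymmetric noise; the
    ## Hungarian solution must recover the planted renaming
    set.seed(33)
    truth <- rep(c("t1", "t2", "t3", "t4"), each = 100)
    ren <- c(t1 = "r3", t2 = "r1", t3 = "r4", t4 = "r2")
    rec <- unname(ren[truth])
    flip <- sample(400, 40)
    rec[flip] <- sample(paste0("r", 1:4), 40, replace = TRUE)
    m <- matchToTruth(rec, truth)
    expect_identical(m$mapping[ren], setNames(names(ren), ren))
})
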