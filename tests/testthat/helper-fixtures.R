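## Shared fixtures and independent oracle implementations.

## A scaled-down generator config for fast cell-level tests: fewer subjects
## and cells, same subset catalogue and composition model.
smallConfig <- function(cohort = "primary") {
    cfg <- defaultConfig(cohort)
    cfg@nSubjects <- setNames(c(4L, 4L, 3L), names(cfg@nSubjects))
    cfg@cellsPerSample <- c(ileum = 600, colon = 400, blood = 800)
    cfg@nInternalControls <- 3L
    validObject(cfg)
    cfg
}

## Brute-force BH step-up: q_i = min over all j with p_j >= p_i of
## m * p_(j) / rank(p_(j)), independent of stats::p.adjust.
bruteForceBH <- function(p) {
    m <- length(p)
    o <- order(p)
    r <- rank(p, ties.method = "first")
    q <- numeric(m)
    ps <- p[o]
    qs <- pmin(1, m * ps / seq_len(m))
    ## step-up: running minimum from the largest p downwards
    for (i in (m - 1):1) if (m > 1) qs[i] <- min(qs[i], qs[i + 1])
    q[o] <- qs
    q
}

## Rank-then-Pearson Spearman oracle.
spearmanOracle <- function(x) {
    r <- apply(x, 2L, rank)
    suppressWarnings(cor(r))
}

## Quadratic-form LDA posterior oracle (no log-sum-exp, direct densities).
ldaPosteriorOracle <- function(means, sigma, priors, x) {
    K <- nrow(means)
    dens <- vapply(seq_len(K), function(k) {
        dv <- x - means[k, ]
        priors[k] * exp(-0.5 * as.numeric(t(dv) %*% solve(sigma) %*% dv))
    }, 0)
    dens / sum(dens)
}

## Deterministic two-cluster toy: two Gaussian blobs `sep` apart in the
## first two of `d` dimensions.
twoBlobs <- function(n = 200, d = 5, sep = 6, seed = 1) {
    set.seed(seed)
    x <- matrix(rnorm(2 * n * d), 2 * n, d)
    x[seq_len(n), 1:2] <- x[seq_len(n), 1:2] + sep
    colnames(x) <- paste0("m", seq_len(d))
    list(x = x, labels = rep(c("a", "b"), each = n))
}

## Planted block-correlation frequency data: `blocks` modules of `size`
## subsets; within-block correlation from a shared factor.
plantedBlocks <- function(nSamples = 100, blocks = 3, size = 5,
                          factorSd = 1, noiseSd = 0.5, seed = 1) {
    set.seed(seed)
    K <- blocks * size
    f <- matrix(rnorm(nSamples * blocks, sd = factorSd), nSamples, blocks)
    x <- f[, rep(seq_len(blocks), each = size)] +
        matrix(rnorm(nSamples * K, sd = noiseSd), nSamples, K)
    colnames(x) <- paste0("s", seq_len(K))
    list(x = x, truth = rep(seq_len(blocks), each = size))
}
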