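#' @importFrom stats pnorm qnorm rnorm runif rpois rmultinom cor dist
#'   prcomp p.adjust pchisq pf kruskal.test t.test sd quantile median setNames
#' @importFrom methods new validObject is slot
#' @importFrom utils write.table read.table packageVersion
NULL

## Run an expression with a private RNG stream, restoring the caller's
## .Random.seed afterwards so library code never perturbs user RNG state.
withPrivateSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

softmax <- function(x) {
    e <- exp(x - max(x))
    e / sum(e)
}

logSumExp <- function(x) {
    m <- apply(x, 1L, max)
    m + log(rowSums(exp(x - m)))
}

## Normal draws truncated below at `lower` (inverse-CDF construction).
rtruncNorm <- function(n, mean, sd, lower = 0) {
    plo <- pnorm((lower - mean) / sd)
    u <- runif(n, min = plo, max = 1)
    ## guard against u == 1 rounding for extreme truncation
    u <- pmin(u, 1 - 1e-12)
    mean + sd * qnorm(u)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
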