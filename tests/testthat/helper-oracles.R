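suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

# Independent oracles, deliberately coded from the verbal rule definitions
# with a different structure than the package implementation.

# Decision-table oracle for one response quad.  Scalar, nested-if style.
oracleTimepointCall <- function(b, p, r, s, theta = 2) {
    primary_fold <- p / b
    residual_fold <- r / b
    secondary_fold <- s / r
    if (primary_fold > theta) {
        # gene is inducible in naive cells
        if (secondary_fold <= theta) return("UNINDUCIBLE")
        rel <- secondary_fold / primary_fold
        if (rel < 1 / theta) return("HYPOINDUCIBLE")
        if (rel > theta) return("HYPERINDUCIBLE")
        return("NORMOINDUCIBLE")
    }
    if (residual_fold > theta) {
        # upregulated only after 24 + 1/4 h
        if (secondary_fold > theta) return("HYPERINDUCIBLE_2")
        return("LATE")
    }
    if (secondary_fold > theta && s / b > theta) return("DE_NOVO")
    "UNRESPONSIVE"
}

# Overall assessment oracle, enumerating the quoted T / NT definitions.
oracleOverall <- function(c1, c4) {
    ntClasses <- c("HYPOINDUCIBLE", "NORMOINDUCIBLE", "HYPERINDUCIBLE",
                   "HYPERINDUCIBLE_2", "DE_NOVO")
    if (c1 %in% ntClasses || c4 %in% ntClasses) return("NT")
    u <- "UNINDUCIBLE"
    if (c1 == u && c4 == u) return("T")
    if (c1 == u && c4 %in% c("UNRESPONSIVE", "LATE")) return("T")
    if (c4 == u && c1 %in% c("UNRESPONSIVE", "LATE")) return("T")
    "UNCLASSIFIED"
}

# Closed-form Pearson chi-square for a 2x2 table, no continuity correction.
chi2ClosedForm <- function(a, b, c, d) {
    a <- as.numeric(a); b <- as.numeric(b)
    c <- as.numeric(c); d <- as.numeric(d)
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Shared simulated dataset: generating it once keeps the suite fast.
simCache <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateToleranceCounts(seed = 20260923)
        cache
    }
})
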