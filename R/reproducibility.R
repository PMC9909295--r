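#' Expected chance overlap of two gene sets
#'
#' For gene sets of sizes \code{n1} and \code{n2} drawn from a universe of
#' \code{N} analysed genes, the probability that a given gene belongs to
#' both sets by chance is \code{p12 = n1 * n2 / N^2}, and the expected
#' number of coincidences is \code{n12 = n1 * n2 / N}, rounded to the
#' nearest integer (ties rounded half-up, away from zero).
#'
#' @param n1,n2 class sizes in experiments 1 and 2.
#' @param N total number of analysed genes.
#' @return List with elements \code{p12} and \code{n12}.
#' @examples
#' expectedOverlap(100, 200, 11964)  # n12 = 2
#' @export
expectedOverlap <- function(n1, n2, N) {
    stopifnot(N > 0, n1 >= 0, n2 >= 0)
    if (n1 > N || n2 > N) stop("class size exceeds the gene universe")
    list(p12 = n1 * n2 / N^2, n12 = floor(n1 * n2 / N + 0.5))
}

#' Reproducibility of a gene class between two experiments
#'
#' Tests whether the observed intersection \code{n3} of a gene class's
#' memberships in two independent experiments exceeds the chance
#' expectation \code{n12}.  When \code{n3 > n12}, the expected and actual
#' coincidence proportions (\code{n12/N} vs \code{n3/N}) are compared by a
#' Pearson chi-square test on the 2x2 table \code{{(n12, N - n12), (n3,
#' N - n3)}} with 1 df and, by default, no continuity correction;
#' membership is called reproducible (nonrandom) at p < 0.05.  When
#' \code{n3 <= n12}, no test is performed and the result records
#' \code{significant = FALSE} with p = 1.
#'
#' @inheritParams expectedOverlap
#' @param n3 observed intersection size.
#' @param correct apply the Yates continuity correction (default
#'   \code{FALSE}).
#' @param alpha significance level (default 0.05).
#' @return One-row \code{data.frame} with columns \code{n1}, \code{n2},
#'   \code{n3}, \code{N}, \code{p12}, \code{n12}, \code{chi2},
#'   \code{p_value}, \code{significant}.
#' @examples
#' overlapSignificance(500, 500, 500, 11964)
#' @export
overlapSignificance <- function(n1, n2, n3, N, correct = FALSE,
                                alpha = 0.05) {
    if (n3 > min(n1, n2)) stop("n3 cannot exceed min(n1, n2)")
    if (n3 < 0) stop("negative intersection size")
    eo <- expectedOverlap(n1, n2, N)
    if (n3 > eo$n12) {
        tab <- matrix(c(eo$n12, N - eo$n12, n3, N - n3), nrow = 2L,
                      byrow = TRUE)
        ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
        chi2 <- unname(ct$statistic)
        p <- unname(ct$p.value)
        sig <- p < alpha
    } else {
        chi2 <- NA_real_; p <- 1; sig <- FALSE
    }
    data.frame(n1 = n1, n2 = n2, n3 = n3, N = N, p12 = eo$p12,
               n12 = eo$n12, chi2 = chi2, p_value = p, significant = sig)
}

#' Per-class overlap report for two classification tables
#'
#' Convenience wrapper: given the \code{\link{classifySequence}} outputs of
#' the same stimulation sequence in two experiments, computes the overlap
#' statistic for each requested class.  Classes \code{"T"}, \code{"NT"}
#' refer to the overall assessment; \code{"SE"} and \code{"NH"} to the NT
#' subcategory.
#'
#' @param calls1,calls2 classification tables from two experiments (same
#'   gene universe).
#' @param classes character vector of class labels.
#' @param correct,alpha passed to \code{\link{overlapSignificance}}.
#' @return \code{data.frame}, one row per class.
#' @export
classOverlap <- function(calls1, calls2, classes = c("T", "NT", "SE", "NH"),
                         correct = FALSE, alpha = 0.05) {
    if (!identical(calls1$gene_id, calls2$gene_id))
        stop("classification tables do not share the same gene universe")
    N <- nrow(calls1)
    members <- function(calls, cls) {
        if (cls %in% c("T", "NT")) calls$gene_id[calls$overall == cls]
        else calls$gene_id[calls$subcategory == cls]
    }
    rows <- lapply(classes, function(cls) {
        s1 <- members(calls1, cls); s2 <- members(calls2, cls)
        res <- overlapSignificance(length(s1), length(s2),
                                   length(intersect(s1, s2)), N,
                                   correct = correct, alpha = alpha)
        cbind(class = cls, res)
    })
    do.call(rbind, rows)
}
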