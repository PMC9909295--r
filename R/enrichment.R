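#' Offset log2 enrichment score between two gene sets
#'
#' \deqn{ES = \log_2\frac{n_1 + 0.5}{N_1 + 0.5} -
#'            \log_2\frac{n_2 + 0.5}{N_2 + 0.5}}
#' where \code{n1} and \code{n2} are the numbers of genes carrying a
#' feature (e.g. a predicted TFBS) in sets 1 and 2, and \code{N1},
#' \code{N2} the set sizes.  The 0.5 offsets keep the score finite at zero
#' counts.  ES is antisymmetric under swapping the two sets.
#'
#' @param n1,N1,n2,N2 non-negative integer counts with \code{n1 <= N1},
#'   \code{n2 <= N2}, \code{N1, N2 >= 1}.
#' @return Numeric enrichment score (log2 units).
#' @examples
#' enrichmentScore(160, 259, 20, 88)  # ~1.417
#' @export
enrichmentScore <- function(n1, N1, n2, N2) {
    if (any(c(n1, N1, n2, N2) < 0)) stop("negative count")
    if (any(n1 > N1) || any(n2 > N2)) stop("feature count exceeds set size")
    stopifnot(all(N1 >= 1), all(N2 >= 1))
    log2((n1 + 0.5) / (N1 + 0.5)) - log2((n2 + 0.5) / (N2 + 0.5))
}

#' Chi-square test for a difference in feature frequency
#'
#' Pearson chi-square (1 df, no continuity correction by default) on the
#' 2x2 table \code{{(n1, N1 - n1), (n2, N2 - n2)}}.  Degenerate tables with
#' a zero margin (e.g. the feature absent from both sets) cannot be tested;
#' they are reported with \code{chi2 = 0}, \code{p = 1} and
#' \code{skipped = TRUE}.
#'
#' @inheritParams enrichmentScore
#' @param correct apply the Yates continuity correction (default
#'   \code{FALSE}).
#' @return List with elements \code{chi2}, \code{p_value}, \code{skipped}.
#' @examples
#' enrichmentTest(160, 259, 20, 88)$p_value  # < 0.0001
#' @export
enrichmentTest <- function(n1, N1, n2, N2, correct = FALSE) {
    if (any(c(n1, N1, n2, N2) < 0)) stop("negative count")
    if (n1 > N1 || n2 > N2) stop("feature count exceeds set size")
    tab <- matrix(c(n1, N1 - n1, n2, N2 - n2), nrow = 2L, byrow = TRUE)
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
        return(list(chi2 = 0, p_value = 1, skipped = TRUE))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(chi2 = unname(ct$statistic), p_value = unname(ct$p.value),
         skipped = FALSE)
}

#' Read a gene x transcription-factor binding-score table
#'
#' Tab-separated layout as exported by promoter-scanning tools: first
#' column gene identifiers, remaining columns one transcription factor
#' each, entries the similarity score in [0, 1] between the best potential
#' binding site and the ideal site sequence (0 = complete mismatch or no
#' site, 1 = exact match).
#'
#' @param path path to the table.
#' @return Numeric matrix (genes x TFs).
#' @export
readBindingTable <- function(path) {
    m <- readCountMatrix(path)
    if (any(m < 0) || any(m > 1))
        stop("binding scores must lie in [0, 1]: ", path)
    m
}

#' Scan binding-score cutoffs for the most significant enrichment
#'
#' For each transcription factor, site presence in a gene is defined as
#' binding score >= cutoff, and the frequency of site-bearing genes in
#' \code{set1} is compared with \code{set2}
#' (\code{\link{enrichmentTest}}).  The cutoff is chosen automatically from
#' \code{grid} (default 0.85 to 1 in steps of 0.01) as the one minimizing
#' the p-value; among ties the largest (most stringent) cutoff is
#' reported.  The conventional reporting filter — site present in at least
#' \code{presenceMin} of one set, \code{ES > esMin} and \code{p < pMax} —
#' is evaluated at the chosen cutoff and returned as a flag rather than
#' used to drop rows.
#'
#' @param binding numeric gene x TF score matrix in [0, 1] (see
#'   \code{\link{readBindingTable}}).
#' @param set1,set2 character vectors of gene identifiers, subsets of
#'   \code{rownames(binding)}.
#' @param grid numeric vector of candidate cutoffs in [0.85, 1].
#' @param presenceMin,esMin,pMax reporting-filter parameters (defaults
#'   0.10, 1, 0.01).
#' @param correct passed to \code{\link{enrichmentTest}}.
#' @return \code{data.frame} with one row per TF: \code{tf},
#'   \code{cutoff}, \code{n1}, \code{N1}, \code{n2}, \code{N2}, \code{ES},
#'   \code{chi2}, \code{p_value}, \code{passes_filter}.
#' @export
scanCutoff <- function(binding, set1, set2, grid = seq(0.85, 1, by = 0.01),
                       presenceMin = 0.10, esMin = 1, pMax = 0.01,
                       correct = FALSE) {
    stopifnot(is.matrix(binding), length(grid) >= 1L)
    if (!length(set1) || !length(set2)) stop("empty gene set")
    missing <- setdiff(c(set1, set2), rownames(binding))
    if (length(missing))
        stop("gene(s) absent from the binding table: ",
             paste(utils::head(missing, 5), collapse = ", "))
    N1 <- length(set1); N2 <- length(set2)
    rows <- lapply(colnames(binding), function(tf) {
        s1 <- binding[set1, tf]; s2 <- binding[set2, tf]
        best <- NULL
        for (cut in sort(grid)) {
            n1 <- sum(s1 >= cut); n2 <- sum(s2 >= cut)
            tst <- enrichmentTest(n1, N1, n2, N2, correct = correct)
            if (is.null(best) || tst$p_value <= best$p_value)
                best <- list(cutoff = cut, n1 = n1, n2 = n2,
                             chi2 = tst$chi2, p_value = tst$p_value)
        }
        es <- enrichmentScore(best$n1, N1, best$n2, N2)
        pass <- (best$n1 / N1 >= presenceMin | best$n2 / N2 >= presenceMin) &
            es > esMin & best$p_value < pMax
        data.frame(tf = tf, cutoff = best$cutoff, n1 = best$n1, N1 = N1,
                   n2 = best$n2, N2 = N2, ES = es, chi2 = best$chi2,
                   p_value = best$p_value, passes_filter = pass)
    })
    do.call(rbind, rows)
}

#' Over-representation of a gene set in one class versus another
#'
#' Compares how often members of \code{geneSet} occur among two disjoint
#' gene classes (typically T versus NT genes) using the same 2x2
#' chi-square machinery and enrichment score as the TFBS analysis.
#'
#' @param geneSet character vector of gene identifiers (e.g. one pathway).
#' @param classA,classB disjoint character vectors of gene identifiers.
#' @param correct passed to \code{\link{enrichmentTest}}.
#' @return One-row \code{data.frame}: \code{n1}, \code{N1}, \code{n2},
#'   \code{N2}, \code{ES}, \code{chi2}, \code{p_value}, \code{skipped}.
#' @export
setOverrepresentation <- function(geneSet, classA, classB, correct = FALSE) {
    if (length(intersect(classA, classB)))
        stop("classes must be disjoint")
    n1 <- length(intersect(geneSet, classA)); N1 <- length(classA)
    n2 <- length(intersect(geneSet, classB)); N2 <- length(classB)
    tst <- enrichmentTest(n1, N1, n2, N2, correct = correct)
    data.frame(n1 = n1, N1 = N1, n2 = n2, N2 = N2,
               ES = enrichmentScore(n1, N1, n2, N2), chi2 = tst$chi2,
               p_value = tst$p_value, skipped = tst$skipped)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member identifiers, all
#' tab-separated.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(vapply(fields, length, 1L) < 3L))
        stop("malformed GMT line (need name, description, >= 1 gene): ", path)
    stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                    vapply(fields, `[`, "", 1L))
}
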