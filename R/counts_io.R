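#' Read a tab-separated count table
#'
#' First column holds gene or transcript identifiers, remaining columns hold
#' one library each.  Lines starting with \code{#} are treated as metadata
#' and skipped.
#'
#' @param path path to the tab-separated file.
#' @return Integer matrix with identifier rownames and library colnames.
#' @export
readCountMatrix <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             comment.char = "#", check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        stop("count table needs an identifier column and >= 1 library: ", path)
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(tab[[1]])
    m
}

#' Read a sample sheet
#'
#' Expected columns: \code{library_id}, \code{experiment_id},
#' \code{first_stimulus}, \code{second_stimulus}, \code{timepoint}.
#'
#' @param path path to the tab-separated sample sheet.
#' @return \code{data.frame}.
#' @export
readSampleSheet <- function(path) {
    ss <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("library_id", "experiment_id", "first_stimulus",
              "second_stimulus", "timepoint")
    missing <- setdiff(need, colnames(ss))
    if (length(missing))
        stop("sample sheet ", path, " lacks column(s): ",
             paste(missing, collapse = ", "))
    ss
}

#' Sum transcript-level counts to gene level
#'
#' Counts of all transcripts (mRNA variants) belonging to the same gene are
#' summed per library.  Transcripts absent from the mapping are dropped with
#' a message; their reads do not contribute to any gene.
#'
#' @param counts numeric matrix of transcript counts (transcripts x
#'   libraries) with transcript identifiers as rownames.
#' @param transcriptToGene two-column \code{data.frame} (transcript id, gene
#'   id), or a named character vector mapping transcript -> gene.
#' @return Numeric matrix of gene counts (genes x libraries).
#' @examples
#' m <- rbind(t1 = c(3, 5), t2 = c(7, 0))
#' aggregateTranscripts(m, data.frame(tx = c("t1", "t2"), gene = "G"))
#' @export
aggregateTranscripts <- function(counts, transcriptToGene) {
    counts <- as.matrix(counts)
    if (is.data.frame(transcriptToGene)) {
        if (ncol(transcriptToGene) < 2L)
            stop("transcript-to-gene mapping needs two columns")
        map <- stats::setNames(as.character(transcriptToGene[[2]]),
                               as.character(transcriptToGene[[1]]))
    } else {
        map <- transcriptToGene
    }
    if (!length(map)) stop("transcript-to-gene mapping is empty")
    gene <- map[rownames(counts)]
    unmapped <- is.na(gene)
    if (any(unmapped))
        message(sum(unmapped), " transcript(s) absent from the mapping ",
                "were dropped")
    counts <- counts[!unmapped, , drop = FALSE]
    gene <- gene[!unmapped]
    if (!nrow(counts)) stop("no transcript could be mapped to a gene")
    rowsum(counts, group = gene, reorder = TRUE)
}

#' Filter genes on raw-count abundance and coding status
#'
#' A gene is retained when, in every experiment (or any, if
#' \code{requireAllExperiments = FALSE}), at least \code{minLibraries}
#' libraries have at least \code{minRawCount} raw counts, and when it is on
#' \code{codingGenes} if such a list is supplied.  The count boundary is
#' inclusive: a maximum of exactly \code{minRawCount} retains the gene.
#'
#' @param countsList a \code{ToleranceExperiment} (split internally by its
#'   \code{experiment} column) or a list of count matrices sharing rownames,
#'   one per experiment.
#' @param minRawCount minimum raw count (default 50).
#' @param minLibraries minimum number of libraries reaching it (default 1).
#' @param requireAllExperiments require the abundance rule in each
#'   experiment (default \code{TRUE}).
#' @param codingGenes optional character vector of protein-coding gene
#'   identifiers used as a whitelist.
#' @return Character vector of retained gene identifiers, in input order.
#' @export
filterGenes <- function(countsList, minRawCount = 50, minLibraries = 1,
                        requireAllExperiments = TRUE, codingGenes = NULL) {
    stopifnot(minRawCount >= 0, minLibraries >= 1)
    if (is(countsList, "ToleranceExperiment")) {
        cnt <- assay(countsList, "counts")
        countsList <- lapply(experimentIds(countsList), function(e)
            cnt[, colData(countsList)$experiment == e, drop = FALSE])
    }
    if (!length(countsList)) stop("no count matrix supplied")
    genes <- rownames(countsList[[1]])
    for (m in countsList)
        if (!identical(rownames(m), genes))
            stop("count matrices do not share the same gene universe")
    ok <- vapply(countsList, function(m)
        rowSums(m >= minRawCount) >= minLibraries,
        logical(length(genes)))
    ok <- if (requireAllExperiments) rowSums(!ok) == 0L else rowSums(ok) > 0L
    if (!is.null(codingGenes)) ok <- ok & genes %in% codingGenes
    genes[ok]
}

#' Normalize counts to reads per million with zero replacement
#'
#' Zero counts are replaced with ones before normalization so that every
#' RPM value is strictly positive and all fold ratios are defined.  Library
#' totals are taken after the replacement, so each RPM column sums exactly
#' to 10^6.  The convention is recorded in \code{metadata()} when applied to
#' a \code{ToleranceExperiment}.
#'
#' @param x a \code{ToleranceExperiment} or a numeric count matrix.
#' @return For a matrix, the RPM matrix.  For a
#'   \code{ToleranceExperiment}, the object with an added \code{"rpm"}
#'   assay.
#' @examples
#' computeRPM(cbind(lib1 = c(0, 1, 999998)))
#' @export
setGeneric("computeRPM", function(x) standardGeneric("computeRPM"))

#' @rdname computeRPM
#' @export
setMethod("computeRPM", "matrix", function(x) {
    if (!length(x)) stop("empty count matrix")
    x[x == 0] <- 1
    totals <- colSums(x)
    if (any(totals <= 0)) stop("non-positive library total")
    sweep(x, 2L, totals, "/") * 1e6
})

#' @rdname computeRPM
#' @export
setMethod("computeRPM", "ToleranceExperiment", function(x) {
    assay(x, "rpm") <- computeRPM(assay(x, "counts"))
    metadata(x)$rpm_convention <-
        "zeros replaced by 1; totals computed after replacement"
    x
})

#' Cross-experiment correlation of synonymous libraries
#'
#' Quality-control statistic: for every condition present in both
#' experiments, the Pearson correlation of log2-RPM values between the two
#' synonymous libraries.
#'
#' @param x a \code{ToleranceExperiment} with exactly two experiments, or a
#'   list of two RPM matrices.
#' @param experiments which two experiment identifiers to compare (defaults
#'   to the first two present).
#' @return Named numeric vector of correlations, one per shared condition.
#' @export
crossExperimentCorrelation <- function(x, experiments = NULL) {
    if (is(x, "ToleranceExperiment")) {
        if (!"rpm" %in% assayNames(x)) x <- computeRPM(x)
        if (is.null(experiments)) experiments <- experimentIds(x)[1:2]
        stopifnot(length(experiments) == 2L)
        lab <- conditionLabels(x)
        expc <- as.character(colData(x)$experiment)
        rpm <- assay(x, "rpm")
        m1 <- rpm[, expc == experiments[1], drop = FALSE]
        m2 <- rpm[, expc == experiments[2], drop = FALSE]
        colnames(m1) <- lab[expc == experiments[1]]
        colnames(m2) <- lab[expc == experiments[2]]
    } else {
        stopifnot(is.list(x), length(x) == 2L)
        m1 <- x[[1]]; m2 <- x[[2]]
        if (!identical(rownames(m1), rownames(m2)))
            stop("RPM matrices do not share the same gene universe")
    }
    shared <- intersect(colnames(m1), colnames(m2))
    if (!length(shared)) stop("no condition is present in both experiments")
    vapply(shared, function(cc)
        stats::cor(log2(m1[, cc]), log2(m2[, cc]), method = "pearson"),
        numeric(1))
}

#' Write a matrix as a tab-separated table
#'
#' Layout matches \code{\link{readCountMatrix}}: identifier column first,
#' one column per library.  Optional \code{header} lines are written
#' prefixed with \code{#}.
#'
#' @param m matrix with rownames.
#' @param path output path.
#' @param idColumn name of the identifier column (default
#'   \code{"gene_id"}).
#' @param header optional character vector of metadata lines.
#' @return Invisibly, \code{path}.
#' @export
writeTable <- function(m, path, idColumn = "gene_id", header = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(paste0("# ", header), con)
    df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE)
    colnames(df)[1] <- idColumn
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
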