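#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.STIMULI    <- c("0", "M", "L")
.TIMEPOINTS <- c("1h", "4h")

#' ToleranceExperiment: container for a two-stimulation RNA-seq design
#'
#' A thin extension of \linkS4class{SummarizedExperiment} for experiments in
#' which cells receive a first (tolerizing, 24 h) stimulus and a second
#' (resolving, 1 h or 4 h) stimulus.  Each library is annotated with the
#' experimental condition it was sampled from: the first stimulus, the second
#' stimulus and the timepoint after the second stimulation.  The full design
#' crosses 3 first stimuli (none/\code{"0"}, the NOD1 agonist M-triDAP
#' \code{"M"}, LPS \code{"L"}) with 3 second stimuli and 2 timepoints,
#' giving 18 conditions per experiment; two independent experiments are held
#' in the same object and distinguished by the \code{experiment} column.
#'
#' Required \code{colData} columns:
#' \describe{
#'   \item{experiment}{experiment identifier (character or factor).}
#'   \item{firstStimulus}{one of \code{"0"}, \code{"M"}, \code{"L"}.}
#'   \item{secondStimulus}{one of \code{"0"}, \code{"M"}, \code{"L"}.}
#'   \item{timepoint}{\code{"1h"} or \code{"4h"} after the second stimulus.}
#' }
#' The \code{"counts"} assay must hold non-negative integer counts.  A
#' \code{"rpm"} assay is added by \code{\link{computeRPM}}.
#'
#' @seealso \code{\link{ToleranceExperiment}}, \code{\link{computeRPM}},
#'   \code{\link{classifySequence}}, \code{\link{simulateToleranceCounts}}
#' @export
setClass("ToleranceExperiment", contains = "SummarizedExperiment")

.validToleranceExperiment <- function(object) {
    msg <- character()
    cd <- colData(object)
    need <- c("experiment", "firstStimulus", "secondStimulus", "timepoint")
    missing <- setdiff(need, colnames(cd))
    if (length(missing))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(missing, collapse = ", ")))
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    if (!length(msg)) {
        if (!all(as.character(cd$firstStimulus) %in% .STIMULI))
            msg <- c(msg, "firstStimulus values must be in {0, M, L}")
        if (!all(as.character(cd$secondStimulus) %in% .STIMULI))
            msg <- c(msg, "secondStimulus values must be in {0, M, L}")
        if (!all(as.character(cd$timepoint) %in% .TIMEPOINTS))
            msg <- c(msg, "timepoint values must be in {1h, 4h}")
        cnt <- assay(object, "counts")
        if (anyNA(cnt) || any(cnt < 0))
            msg <- c(msg, "counts must be non-negative and non-missing")
        else if (any(cnt != round(cnt)))
            msg <- c(msg, "counts must be integers")
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, "gene identifiers (rownames) must be unique")
    }
    if (length(msg)) msg else TRUE
}

setValidity("ToleranceExperiment", .validToleranceExperiment)

#' Construct a ToleranceExperiment
#'
#' @param counts integer matrix of raw counts, genes in rows, libraries in
#'   columns; rownames are gene identifiers, colnames library identifiers.
#' @param sampleSheet \code{data.frame} or \code{DataFrame} with one row per
#'   library and columns \code{library_id}, \code{experiment_id} (or
#'   \code{experiment}), \code{first_stimulus}, \code{second_stimulus},
#'   \code{timepoint}.  Rows are matched to count columns by
#'   \code{library_id}.
#'
#' @return A \linkS4class{ToleranceExperiment}.
#' @examples
#' sim <- simulateToleranceCounts(seed = 1)
#' sim
#' @export
ToleranceExperiment <- function(counts, sampleSheet) {
    counts <- as.matrix(counts)
    ss <- as.data.frame(sampleSheet)
    if (!"library_id" %in% colnames(ss))
        stop("sample sheet lacks column 'library_id'")
    expcol <- intersect(c("experiment_id", "experiment"), colnames(ss))[1]
    if (is.na(expcol))
        stop("sample sheet lacks column 'experiment_id'")
    for (col in c("first_stimulus", "second_stimulus", "timepoint"))
        if (!col %in% colnames(ss))
            stop("sample sheet lacks column '", col, "'")
    idx <- match(colnames(counts), ss$library_id)
    if (anyNA(idx))
        stop("libraries absent from sample sheet: ",
             paste(colnames(counts)[is.na(idx)], collapse = ", "))
    ss <- ss[idx, , drop = FALSE]
    cd <- DataFrame(
        experiment     = as.character(ss[[expcol]]),
        firstStimulus  = as.character(ss$first_stimulus),
        secondStimulus = as.character(ss$second_stimulus),
        timepoint      = as.character(ss$timepoint),
        row.names      = colnames(counts))
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    new("ToleranceExperiment", se)
}

#' @describeIn ToleranceExperiment-class experiment identifiers present in
#'   the object.
#' @param x,object a \code{ToleranceExperiment}.
#' @export
experimentIds <- function(x) unique(as.character(colData(x)$experiment))

#' Encode and decode condition labels
#'
#' Conditions are written \code{"A1->A2@t"}, e.g. \code{"L->0@4h"} for cells
#' tolerized with LPS and recultured without agonists, sampled 4 h after the
#' medium change.  \code{"0"} denotes culture without agonist.  The encoding
#' is bijective over the 18-condition design.
#'
#' @param first,second stimulus codes in \code{c("0","M","L")}.
#' @param timepoint \code{"1h"} or \code{"4h"}.
#' @return \code{encodeCondition}: character vector of labels.
#'   \code{decodeCondition}: \code{data.frame} with columns \code{first},
#'   \code{second}, \code{timepoint}.
#' @examples
#' encodeCondition("L", "0", "4h")
#' decodeCondition("0->M@1h")
#' @export
encodeCondition <- function(first, second, timepoint) {
    stopifnot(all(first %in% .STIMULI), all(second %in% .STIMULI),
              all(timepoint %in% .TIMEPOINTS))
    paste0(first, "->", second, "@", timepoint)
}

#' @rdname encodeCondition
#' @param label character vector of condition labels.
#' @export
decodeCondition <- function(label) {
    m <- regmatches(label, regexec("^(0|M|L)->(0|M|L)@(1h|4h)$", label))
    bad <- vapply(m, length, 1L) != 4L
    if (any(bad))
        stop("malformed condition label(s): ",
             paste(label[bad], collapse = ", "))
    data.frame(first     = vapply(m, `[`, "", 2L),
               second    = vapply(m, `[`, "", 3L),
               timepoint = vapply(m, `[`, "", 4L),
               stringsAsFactors = FALSE)
}

#' Condition labels of the libraries in a ToleranceExperiment
#'
#' @param x a \code{ToleranceExperiment}.
#' @return Character vector, one \code{"A1->A2@t"} label per library.
#' @export
conditionLabels <- function(x) {
    cd <- colData(x)
    encodeCondition(as.character(cd$firstStimulus),
                    as.character(cd$secondStimulus),
                    as.character(cd$timepoint))
}

setMethod("show", "ToleranceExperiment", function(object) {
    callNextMethod()
    cat("experiments:", paste(experimentIds(object), collapse = ", "), "\n")
    cat("conditions per experiment:",
        length(unique(conditionLabels(object))), "\n")
})
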