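#' Classify all four agonist sequences of one experiment
#'
#' Runs \code{\link{classifySequence}} for the homologous (M->M, L->L) and
#' heterologous (M->L, L->M) stimulation sequences.
#'
#' @inheritParams classifySequence
#' @param sequences list of \code{c(a1, a2)} pairs.
#' @return Named list of classification tables (\code{"a1->a2"}).
#' @export
classifyAllSequences <- function(x, experiment = experimentIds(x)[1],
                                 sequences = list(c("M", "M"), c("L", "L"),
                                                  c("L", "M"), c("M", "L")),
                                 theta = 2,
                                 baselineMode = "time_matched",
                                 seRequiresBothAt1h = TRUE) {
    res <- lapply(sequences, function(s)
        classifySequence(x, s[1], s[2], experiment = experiment,
                         theta = theta, baselineMode = baselineMode,
                         seRequiresBothAt1h = seRequiresBothAt1h))
    names(res) <- vapply(sequences, function(s)
        paste0(s[1], "->", s[2]), "")
    res
}

#' Write a classification table with its configuration header
#'
#' Tab-separated output; the classifier configuration is echoed as
#' \code{#}-prefixed header lines so a run can be audited from its output
#' alone.
#'
#' @param calls a table from \code{\link{classifySequence}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeClassification <- function(calls, path) {
    md <- metadata(calls)
    hdr <- c(paste0("theta=", md$theta),
             paste0("baseline_mode=", md$baseline_mode),
             paste0("se_requires_both_1h=", md$se_requires_both_1h),
             paste0("experiment=", md$experiment),
             paste0("boundaries=", md$boundary_convention))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    utils::write.table(as.data.frame(calls), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a classification table written by writeClassification
#'
#' @param path path to the table.
#' @return \code{data.frame}.
#' @export
readClassification <- function(path) {
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
}
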