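.TP_CALLS <- c("UNINDUCIBLE", "HYPOINDUCIBLE", "NORMOINDUCIBLE",
               "HYPERINDUCIBLE", "LATE", "HYPERINDUCIBLE_2", "DE_NOVO",
               "UNRESPONSIVE")
.NT_CALLS <- c("HYPOINDUCIBLE", "NORMOINDUCIBLE", "HYPERINDUCIBLE",
               "HYPERINDUCIBLE_2", "DE_NOVO")

#' The five RPM ratio indices of a response quad
#'
#' A gene's behaviour at one timepoint of one stimulation sequence is
#' summarized by four RPM values (the "response quad"): \code{baseline}
#' (0->0), \code{primary} (0->A2), \code{residual} (A1->0) and
#' \code{secondary} (A1->A2).  Five dimensionless ratios are derived:
#' \describe{
#'   \item{I_primary}{primary / baseline — fold induction in naive cells.}
#'   \item{I_residual}{residual / baseline — residual expression left by
#'     the tolerizing stimulus.}
#'   \item{I_secondary}{secondary / residual — fold induction by the second
#'     stimulus over the residual level, the residual-corrected response.}
#'   \item{I_sec_vs_prim}{secondary / primary.}
#'   \item{I_sec_vs_base}{secondary / baseline.}
#' }
#' \code{I_sec_vs_base == I_secondary * I_residual} holds algebraically.
#'
#' All arguments are recycled to a common length, so the function works on
#' whole gene vectors at once.
#'
#' @param baseline,primary,residual,secondary positive RPM values.
#' @return \code{data.frame} with the five index columns.
#' @examples
#' ratioIndices(10, 50, 12, 13)
#' @export
ratioIndices <- function(baseline, primary, residual, secondary) {
    n <- max(length(baseline), length(primary), length(residual),
             length(secondary))
    baseline  <- rep_len(baseline, n);  primary   <- rep_len(primary, n)
    residual  <- rep_len(residual, n);  secondary <- rep_len(secondary, n)
    if (any(c(baseline, primary, residual, secondary) <= 0) ||
        anyNA(c(baseline, primary, residual, secondary)))
        stop("all four RPM values must be positive (apply zero replacement)")
    data.frame(I_primary     = primary / baseline,
               I_residual    = residual / baseline,
               I_secondary   = secondary / residual,
               I_sec_vs_prim = secondary / primary,
               I_sec_vs_base = secondary / baseline)
}

#' Classify a gene's response at one timepoint
#'
#' Deterministic rule table on the ratio indices, with fold threshold
#' \code{theta} (default 2: more than two-fold RPM differences are
#' biologically significant).  Rules, in order:
#' \enumerate{
#'   \item A gene is \emph{primary-inducible} when \code{I_primary > theta}.
#'   \item Primary-inducible genes: \code{UNINDUCIBLE} when
#'     \code{I_secondary <= theta} (no induction above the residual level
#'     reached in A1->0 cultures); otherwise the secondary fold is compared
#'     with the primary fold through \code{R = I_secondary / I_primary}:
#'     \code{HYPOINDUCIBLE} when \code{R < 1/theta}, \code{HYPERINDUCIBLE}
#'     when \code{R > theta}, else \code{NORMOINDUCIBLE}.
#'   \item Not primary-inducible but \code{I_residual > theta} (upregulated
#'     only after 24 + 1/4 h): \code{HYPERINDUCIBLE_2} when the second
#'     stimulus raises expression further (\code{I_secondary > theta}),
#'     else \code{LATE}.
#'   \item Otherwise: \code{DE_NOVO} when induced only by the full sequence
#'     (\code{I_secondary > theta} and \code{I_sec_vs_base > theta}), else
#'     \code{UNRESPONSIVE}.
#' }
#' The function is total: every positive quad receives exactly one of the
#' eight calls, and the call is invariant to rescaling the quad.
#'
#' @inheritParams ratioIndices
#' @param theta fold threshold, must exceed 1.
#' @return Factor of calls with levels
#'   \code{c("UNINDUCIBLE","HYPOINDUCIBLE","NORMOINDUCIBLE",
#'   "HYPERINDUCIBLE","LATE","HYPERINDUCIBLE_2","DE_NOVO","UNRESPONSIVE")}.
#' @examples
#' classifyTimepoint(10, 50, 12, 13)   # UNINDUCIBLE
#' classifyTimepoint(10, 15, 100, 250) # HYPERINDUCIBLE_2
#' @export
classifyTimepoint <- function(baseline, primary, residual, secondary,
                              theta = 2) {
    stopifnot(length(theta) == 1L, theta > 1)
    idx <- ratioIndices(baseline, primary, residual, secondary)
    out <- character(nrow(idx))
    inducible <- idx$I_primary > theta
    secondaryUp <- idx$I_secondary > theta
    R <- idx$I_secondary / idx$I_primary
    out[inducible & !secondaryUp] <- "UNINDUCIBLE"
    out[inducible & secondaryUp]  <- ifelse(
        R[inducible & secondaryUp] < 1 / theta, "HYPOINDUCIBLE",
        ifelse(R[inducible & secondaryUp] > theta, "HYPERINDUCIBLE",
               "NORMOINDUCIBLE"))
    lateish <- !inducible & idx$I_residual > theta
    out[lateish] <- ifelse(secondaryUp[lateish], "HYPERINDUCIBLE_2", "LATE")
    rest <- !inducible & idx$I_residual <= theta
    out[rest] <- ifelse(secondaryUp[rest] &
                            idx$I_sec_vs_base[rest] > theta,
                        "DE_NOVO", "UNRESPONSIVE")
    factor(out, levels = .TP_CALLS)
}

#' Sustained-expression (SE) criteria
#'
#' An NT gene shows sustained expression when the elevated level left by
#' the tolerizing stimulus decays without agonist but is maintained by
#' restimulation.  Three criteria, all with the same fold threshold
#' \code{theta}:
#' \enumerate{
#'   \item after 24 h with agonist 1 and 1 h of reculture, expression
#'     exceeds \code{theta} times the unstimulated level — by default both
#'     the A1->0 and A1->A2 libraries at 1 h must exceed it (strict reading
#'     of "with or without agonist 2"); set \code{requireBothAt1h = FALSE}
#'     for an either/or reading;
#'   \item expression in A1->0 cultures falls more than \code{theta}-fold
#'     between 1 h and 4 h;
#'   \item expression in A1->A2 cultures at 4 h stays within a
#'     \code{theta}-fold band of the A1->0 level at 1 h.
#' }
#'
#' @param baseline1h,residual1h,secondary1h,residual4h,secondary4h positive
#'   RPM values (vectors are accepted).
#' @param theta fold threshold (> 1).
#' @param requireBothAt1h see above.
#' @return Logical vector.
#' @export
isSustainedExpression <- function(baseline1h, residual1h, secondary1h,
                                  residual4h, secondary4h, theta = 2,
                                  requireBothAt1h = TRUE) {
    stopifnot(theta > 1)
    elevated1h <- if (requireBothAt1h)
        residual1h > theta * baseline1h & secondary1h > theta * baseline1h
    else
        residual1h > theta * baseline1h | secondary1h > theta * baseline1h
    decays <- residual4h < residual1h / theta
    held <- secondary4h / residual1h
    sustained <- held > 1 / theta & held < theta
    elevated1h & decays & sustained
}

#' Overall tolerizeable / non-tolerizeable assessment
#'
#' Combines the two timepoint calls of a gene:
#' \itemize{
#'   \item \code{T} (tolerizeable): \code{UNINDUCIBLE} at both timepoints,
#'     or \code{UNINDUCIBLE} at one and \code{UNRESPONSIVE} or \code{LATE}
#'     at the other.
#'   \item \code{NT} (non-tolerizeable): \code{HYPOINDUCIBLE},
#'     \code{NORMOINDUCIBLE}, \code{HYPERINDUCIBLE},
#'     \code{HYPERINDUCIBLE_2} or \code{DE_NOVO} at at least one timepoint,
#'     irrespective of the other.
#'   \item \code{UNCLASSIFIED}: neither rule matches (e.g. unresponsive at
#'     both timepoints); such genes are excluded from T and NT sets rather
#'     than forced into T.
#' }
#' The two rules are mutually exclusive, so T and NT sets are disjoint.
#'
#' @param call1h,call4h timepoint calls (character or factor, recycled to a
#'   common length).
#' @return Factor with levels \code{c("T", "NT", "UNCLASSIFIED")}.
#' @examples
#' overallCall("UNINDUCIBLE", "LATE")            # T
#' overallCall("UNRESPONSIVE", "HYPOINDUCIBLE")  # NT
#' overallCall("UNRESPONSIVE", "UNRESPONSIVE")   # UNCLASSIFIED
#' @export
overallCall <- function(call1h, call4h) {
    call1h <- as.character(call1h); call4h <- as.character(call4h)
    n <- max(length(call1h), length(call4h))
    call1h <- rep_len(call1h, n); call4h <- rep_len(call4h, n)
    bad <- !(call1h %in% .TP_CALLS) | !(call4h %in% .TP_CALLS)
    if (any(bad)) stop("unknown timepoint call")
    quiet <- c("UNRESPONSIVE", "LATE")
    isT <- (call1h == "UNINDUCIBLE" & call4h == "UNINDUCIBLE") |
        (call1h == "UNINDUCIBLE" & call4h %in% quiet) |
        (call4h == "UNINDUCIBLE" & call1h %in% quiet)
    isNT <- call1h %in% .NT_CALLS | call4h %in% .NT_CALLS
    factor(ifelse(isNT, "NT", ifelse(isT, "T", "UNCLASSIFIED")),
           levels = c("T", "NT", "UNCLASSIFIED"))
}

.pickLibrary <- function(x, experiment, first, second, timepoint) {
    cd <- colData(x)
    hit <- which(as.character(cd$experiment) == experiment &
                 as.character(cd$firstStimulus) == first &
                 as.character(cd$secondStimulus) == second &
                 as.character(cd$timepoint) == timepoint)
    if (length(hit) != 1L)
        stop("experiment ", experiment, " lacks a unique library for ",
             "condition ", encodeCondition(first, second, timepoint))
    hit
}

#' Classify every gene for one stimulation sequence
#'
#' Runs the per-timepoint rule engine and the overall T/NT assessment for
#' one (agonist 1 -> agonist 2) sequence in one experiment, using the eight
#' libraries 0->0, 0->A2, A1->0 and A1->A2 at 1 h and 4 h.  Within the NT
#' category, the SE subcategory is assigned first
#' (\code{\link{isSustainedExpression}}), then NH (normo- or
#' hyperinducible at at least one timepoint), and remaining NT genes are
#' labelled \code{OTHER_NT}.  Genes repressed more than \code{theta}-fold
#' by primary stimulation at either timepoint are flagged \code{repressed}
#' but classified by the same rules.
#'
#' @param x a \code{ToleranceExperiment}; the \code{"rpm"} assay is
#'   computed on the fly if absent.
#' @param a1,a2 first and second stimulus codes (\code{"0"}, \code{"M"},
#'   \code{"L"}).
#' @param experiment experiment identifier (default: the first one).
#' @param theta fold threshold (> 1, default 2).
#' @param baselineMode \code{"time_matched"} (default; the 0->0 library at
#'   the call's own timepoint) or \code{"pooled"} (geometric mean of the
#'   two 0->0 libraries, used at both timepoints).
#' @param seRequiresBothAt1h passed to
#'   \code{\link{isSustainedExpression}}.
#' @return \code{\link[S4Vectors]{DataFrame}} with one row per gene:
#'   \code{gene_id}, \code{sequence}, \code{call_1h}, \code{call_4h},
#'   \code{overall}, \code{subcategory}, the five ratio indices at each
#'   timepoint, and the \code{repressed} flag.  The classified fraction
#'   (genes receiving any explicit call) and the T/NT coverage are stored
#'   in \code{metadata()}.
#' @examples
#' sim <- simulateToleranceCounts(seed = 1)
#' calls <- classifySequence(sim, "L", "L", experiment = "exp1")
#' table(calls$overall)
#' @export
classifySequence <- function(x, a1, a2, experiment = experimentIds(x)[1],
                             theta = 2,
                             baselineMode = c("time_matched", "pooled"),
                             seRequiresBothAt1h = TRUE) {
    stopifnot(is(x, "ToleranceExperiment"),
              a1 %in% .STIMULI, a2 %in% .STIMULI, theta > 1)
    baselineMode <- match.arg(baselineMode)
    if (!"rpm" %in% assayNames(x)) x <- computeRPM(x)
    rpm <- assay(x, "rpm")
    col <- function(first, second, tp)
        rpm[, .pickLibrary(x, experiment, first, second, tp)]
    base1 <- col("0", "0", "1h"); base4 <- col("0", "0", "4h")
    if (baselineMode == "pooled") base1 <- base4 <- sqrt(base1 * base4)
    q <- list(
        `1h` = list(baseline = base1, primary = col("0", a2, "1h"),
                    residual = col(a1, "0", "1h"),
                    secondary = col(a1, a2, "1h")),
        `4h` = list(baseline = base4, primary = col("0", a2, "4h"),
                    residual = col(a1, "0", "4h"),
                    secondary = col(a1, a2, "4h")))
    call1 <- classifyTimepoint(q$`1h`$baseline, q$`1h`$primary,
                               q$`1h`$residual, q$`1h`$secondary, theta)
    call4 <- classifyTimepoint(q$`4h`$baseline, q$`4h`$primary,
                               q$`4h`$residual, q$`4h`$secondary, theta)
    overall <- overallCall(call1, call4)
    se <- isSustainedExpression(q$`1h`$baseline, q$`1h`$residual,
                                q$`1h`$secondary, q$`4h`$residual,
                                q$`4h`$secondary, theta,
                                seRequiresBothAt1h)
    nh <- call1 %in% c("NORMOINDUCIBLE", "HYPERINDUCIBLE") |
          call4 %in% c("NORMOINDUCIBLE", "HYPERINDUCIBLE")
    subcat <- ifelse(overall != "NT", "NONE",
                     ifelse(se, "SE", ifelse(nh, "NH", "OTHER_NT")))
    idx1 <- ratioIndices(q$`1h`$baseline, q$`1h`$primary,
                         q$`1h`$residual, q$`1h`$secondary)
    idx4 <- ratioIndices(q$`4h`$baseline, q$`4h`$primary,
                         q$`4h`$residual, q$`4h`$secondary)
    colnames(idx1) <- paste0(colnames(idx1), "_1h")
    colnames(idx4) <- paste0(colnames(idx4), "_4h")
    repressed <- idx1$I_primary_1h < 1 / theta | idx4$I_primary_4h < 1 / theta
    out <- DataFrame(
        gene_id = rownames(x),
        sequence = paste0(a1, "->", a2),
        call_1h = call1, call_4h = call4, overall = overall,
        subcategory = factor(subcat,
                             levels = c("SE", "NH", "OTHER_NT", "NONE")),
        idx1, idx4, repressed = repressed)
    metadata(out) <- list(
        theta = theta, baseline_mode = baselineMode,
        se_requires_both_1h = seRequiresBothAt1h, experiment = experiment,
        classified_fraction = mean(!is.na(call1) & !is.na(call4)),
        tolerance_coverage = mean(overall != "UNCLASSIFIED"),
        boundary_convention = "induction strict (> theta); complements non-strict")
    out
}

#' Single-ratio NT criterion of earlier tolerance studies
#'
#' For comparison with the residual-corrected classifier, the earlier
#' criterion (Foster-style) calls a gene non-tolerizeable when its
#' expression after secondary stimulation is at least that after primary
#' stimulation (A1->A2 RPM / 0->A2 RPM >= 1), assessed at a single
#' timepoint among the primary-inducible genes.  Because it ignores
#' residual expression, it tends to report a several-fold larger set than
#' the NH subcategory it is meant to capture.
#'
#' @inheritParams classifySequence
#' @param timepoint \code{"4h"} (default, as in the original definition) or
#'   \code{"1h"}.
#' @return Character vector of gene identifiers.
#' @export
fosterNT <- function(x, a1, a2, experiment = experimentIds(x)[1],
                     timepoint = "4h", theta = 2) {
    stopifnot(is(x, "ToleranceExperiment"), timepoint %in% .TIMEPOINTS)
    if (!"rpm" %in% assayNames(x)) x <- computeRPM(x)
    rpm <- assay(x, "rpm")
    col <- function(first, second)
        rpm[, .pickLibrary(x, experiment, first, second, timepoint)]
    baseline <- col("0", "0"); primary <- col("0", a2)
    secondary <- col(a1, a2)
    inducible <- primary / baseline > theta
    rownames(x)[inducible & secondary / primary >= 1]
}
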