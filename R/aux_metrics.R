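#' Relative expression by the 2^-ddCt method
#'
#' \deqn{RE = 2^{-[(Ct_{target,s} - Ct_{hk,s}) -
#'                 (Ct_{target,ref} - Ct_{hk,ref})]}}
#' with the unstimulated sample of each donor as reference and a
#' housekeeping gene (e.g. GAPDH) for normalization.  The reference
#' measured against itself gives RE = 1, and RE is invariant to adding a
#' constant to all four Ct values.
#'
#' @param targetCt,housekeepingCt threshold cycles of the sample (vectors
#'   accepted).
#' @param refTargetCt,refHousekeepingCt threshold cycles of the reference
#'   sample.
#' @return Positive numeric vector of relative expression values.
#' @examples
#' ddctRelativeExpression(24, 18, 25, 18)  # one cycle earlier: RE = 2
#' @export
ddctRelativeExpression <- function(targetCt, housekeepingCt,
                                   refTargetCt, refHousekeepingCt) {
    cts <- c(targetCt, housekeepingCt, refTargetCt, refHousekeepingCt)
    if (anyNA(cts) || any(!is.finite(cts)) || any(cts <= 0))
        stop("Ct values must be finite and positive")
    ddct <- (targetCt - housekeepingCt) - (refTargetCt - refHousekeepingCt)
    2^(-ddct)
}

#' mRNA decay ratio after transcription blockade
#'
#' Ratio of the mRNA level measured 1 h after adding a transcription
#' inhibitor (actinomycin D) to the level at addition.  Values in (0, 1]
#' indicate decay; ratios above 1 are biologically anomalous (synthesis
#' despite the blockade, or measurement noise) and are reported with a
#' message rather than rejected.
#'
#' @param levelAfter,levelBefore positive expression levels (any common
#'   unit; vectors accepted and recycled).
#' @return Numeric vector of ratios.
#' @examples
#' mrnaDecayRatio(5, 10)  # 0.5: half the mRNA decayed within 1 h
#' @export
mrnaDecayRatio <- function(levelAfter, levelBefore) {
    if (any(c(levelAfter, levelBefore) <= 0) ||
        anyNA(c(levelAfter, levelBefore)))
        stop("expression levels must be positive")
    ratio <- levelAfter / levelBefore
    if (any(ratio > 1))
        message(sum(ratio > 1),
                " decay ratio(s) above 1 (apparent synthesis) flagged")
    ratio
}

#' Flag biologically significant fold differences
#'
#' Helper implementing the convention that only differences of
#' \code{theta}-fold or more (default two-fold, in either direction) are
#' biologically significant.
#'
#' @param ratio positive fold ratios.
#' @param theta fold threshold (default 2).
#' @return Logical vector: \code{TRUE} when \code{ratio >= theta} or
#'   \code{ratio <= 1/theta}.
#' @export
isFoldSignificant <- function(ratio, theta = 2) {
    stopifnot(theta > 1, all(ratio > 0))
    ratio >= theta | ratio <= 1 / theta
}
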