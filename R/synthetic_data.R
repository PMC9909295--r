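.ARCHETYPES <- c("TOLERIZED", "SUSTAINED", "NORMO_NT", "HYPER_NT", "LATE",
                 "HYPER2", "DE_NOVO", "CONSTITUTIVE", "LOW_EXPRESSED")

#' The 18-condition, two-experiment stimulation design
#'
#' All combinations of first stimulus (none/M-triDAP/LPS), second stimulus
#' (none/M-triDAP/LPS) and sampling timepoint (1 h or 4 h after the second
#' stimulation), replicated over two independent experiments: 36 libraries.
#'
#' @param experiments character vector of experiment identifiers.
#' @return \code{data.frame} with columns \code{library_id},
#'   \code{experiment_id}, \code{first_stimulus}, \code{second_stimulus},
#'   \code{timepoint}; one row per library.
#' @examples
#' nrow(toleranceDesign())  # 36
#' @export
toleranceDesign <- function(experiments = c("exp1", "exp2")) {
    g <- expand.grid(timepoint = .TIMEPOINTS, second_stimulus = .STIMULI,
                     first_stimulus = .STIMULI,
                     experiment_id = experiments,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g <- g[, c("experiment_id", "first_stimulus", "second_stimulus",
               "timepoint")]
    g$library_id <- paste0(g$experiment_id, ".",
                           g$first_stimulus, g$second_stimulus, g$timepoint)
    g[, c("library_id", "experiment_id", "first_stimulus",
          "second_stimulus", "timepoint")]
}

#' Archetype expression profiles for the simulator
#'
#' Each archetype is a qualitative gene behaviour observed in tolerized
#' macrophages, encoded as expected RPM fold changes over the unstimulated
#' baseline for the four condition patterns (0->0; 0->A2 "primary"; A1->0
#' "residual"; A1->A2 "secondary") at 1 h and 4 h, plus a relative baseline
#' expression scale.  The same profile applies to every agonist pair, so
#' all 18 conditions are covered.  Profiles are placed well inside their
#' intended classification region (at least two-fold away from every
#' \code{theta} boundary, after allowing for the mild compression of RPM
#' ratios caused by library-composition shifts):
#' \describe{
#'   \item{TOLERIZED}{induced by the first stimulus, high stable residual
#'     expression, no response to the second stimulus -> uninducible at
#'     both timepoints (overall T).  Its elevated residual level makes the
#'     single-ratio criterion of \code{\link{fosterNT}} misread it as NT.}
#'   \item{SUSTAINED}{residual expression decays without agonist but is
#'     held up by restimulation -> NT with subcategory SE.}
#'   \item{NORMO_NT / HYPER_NT}{respond to the second stimulus equally /
#'     more strongly than to the first -> NT, subcategory NH.}
#'   \item{LATE}{not induced at 1 or 4 h of primary stimulation, elevated
#'     only after 24 + 1/4 h, no further response.}
#'   \item{HYPER2}{late pattern further upregulated by the second
#'     stimulus.}
#'   \item{DE_NOVO}{induced only by the full first-then-second sequence.}
#'   \item{CONSTITUTIVE}{flat profile, unresponsive.}
#'   \item{LOW_EXPRESSED}{flat and below the abundance filter.}
#' }
#'
#' @param theta fold threshold the profiles are designed against
#'   (default 2; profiles scale their margins relative to it).
#' @return Named list; each element has \code{baselineScale} and a
#'   \code{folds} vector \code{c(prim_1h, prim_4h, resid_1h, resid_4h,
#'   sec_1h, sec_4h)}.
#' @export
defaultArchetypeProfiles <- function(theta = 2) {
    stopifnot(theta > 1)
    s <- theta / 2  # profiles keep their relative margins if theta moves
    prof <- function(scale, p1, p4, r1, r4, s1, s4)
        list(baselineScale = scale,
             folds = c(prim_1h = p1 * s, prim_4h = p4 * s,
                       resid_1h = r1 * s, resid_4h = r4 * s,
                       sec_1h = s1 * s, sec_4h = s4 * s))
    flat <- function(scale)
        list(baselineScale = scale,
             folds = c(prim_1h = 1, prim_4h = 1, resid_1h = 1,
                       resid_4h = 1, sec_1h = 1, sec_4h = 1))
    list(
        TOLERIZED     = prof(0.1,  8,  8, 16, 16,  16,  16),
        SUSTAINED     = prof(0.1, 32, 64, 32,  4,  32,  40),
        NORMO_NT      = prof(0.1, 16, 16,  4,  4,  80,  80),
        HYPER_NT      = prof(0.1,  8,  8,  4,  4, 160, 160),
        LATE          = prof(0.1,  1,  1, 16, 16,  16,  16),
        HYPER2        = prof(0.1,  1,  1, 16, 16,  64,  64),
        DE_NOVO       = prof(0.1,  1,  1,  1,  1,  16,  16),
        CONSTITUTIVE  = flat(1),
        LOW_EXPRESSED = flat(0.01))
}

#' Intended classification outcome of each archetype
#'
#' The call pattern each archetype is constructed to produce under the
#' default rule engine; used to score archetype recovery on simulated
#' data.  \code{LOW_EXPRESSED} genes are expected to be removed by
#' \code{\link{filterGenes}} and carry \code{NA} calls.
#'
#' @return \code{data.frame} with columns \code{archetype},
#'   \code{call_1h}, \code{call_4h}, \code{overall}, \code{subcategory}.
#' @export
archetypeExpectedCalls <- function() {
    data.frame(
        archetype = c("TOLERIZED", "SUSTAINED", "NORMO_NT", "HYPER_NT",
                      "LATE", "HYPER2", "DE_NOVO", "CONSTITUTIVE"),
        call_1h = c("UNINDUCIBLE", "UNINDUCIBLE", "NORMOINDUCIBLE",
                    "HYPERINDUCIBLE", "LATE", "HYPERINDUCIBLE_2",
                    "DE_NOVO", "UNRESPONSIVE"),
        call_4h = c("UNINDUCIBLE", "HYPOINDUCIBLE", "NORMOINDUCIBLE",
                    "HYPERINDUCIBLE", "LATE", "HYPERINDUCIBLE_2",
                    "DE_NOVO", "UNRESPONSIVE"),
        overall = c("T", "NT", "NT", "NT", "UNCLASSIFIED", "NT", "NT",
                    "UNCLASSIFIED"),
        subcategory = c("NONE", "SE", "NH", "NH", "NONE", "OTHER_NT",
                        "OTHER_NT", "NONE"),
        stringsAsFactors = FALSE)
}

.foldFor <- function(folds, first, second, timepoint) {
    if (first == "0" && second == "0") return(1)
    key <- if (first == "0") "prim" else if (second == "0") "resid" else
        "sec"
    unname(folds[paste0(key, "_", timepoint)])
}

#' Simulate two-experiment tolerance RNA-seq counts with truth labels
#'
#' Generates raw counts for the full 18-condition x 2-experiment design
#' under a gamma-Poisson (negative binomial) noise model: counts for gene
#' g in library l are drawn with mean
#' \code{baselineMean * baselineScale[archetype] * fold[archetype,
#' condition] * sizeFactor[l] * 2^eps}, where \code{eps} is a per-gene,
#' per-experiment normal deviate on the log2 scale (sd
#' \code{betweenExperimentSd}) producing strong but imperfect
#' cross-experiment correlations, and variance \code{mu + dispersion *
#' mu^2} (\code{dispersion = 0} degenerates to Poisson).  The archetype of
#' every gene is returned in \code{rowData()} as ground truth.
#'
#' Defaults emulate a deeply sequenced bulk experiment dominated by
#' constitutive genes: 2,000 genes of which 175 responsive (25 per
#' responsive archetype), responsive genes expressed at one tenth of the
#' constitutive baseline so that induction only mildly perturbs library
#' composition, and low technical overdispersion (0.01) appropriate for
#' libraries derived from one macrophage preparation.
#'
#' @param nPerArchetype named integer vector of gene numbers per archetype
#'   (names from \code{names(defaultArchetypeProfiles())}).
#' @param baselineMean expected baseline count of a constitutive gene
#'   (default 1000).
#' @param dispersion negative-binomial overdispersion (default 0.01).
#' @param betweenExperimentSd per-gene between-experiment log2 sd
#'   (default 0.25).
#' @param sizeFactors optional named numeric vector of per-library depth
#'   factors (default: all 1).
#' @param theta fold threshold the archetype profiles target (default 2).
#' @param experiments experiment identifiers (default
#'   \code{c("exp1", "exp2")}).
#' @param seed optional integer seed; a fixed seed makes the output
#'   bitwise reproducible.
#' @return A \code{\link{ToleranceExperiment}} with 36 libraries,
#'   ground-truth \code{rowData()$archetype}, and the simulation
#'   parameters in \code{metadata()}.
#' @examples
#' sim <- simulateToleranceCounts(seed = 7)
#' table(SummarizedExperiment::rowData(sim)$archetype)
#' @export
simulateToleranceCounts <- function(nPerArchetype = c(
        TOLERIZED = 25, SUSTAINED = 25, NORMO_NT = 25, HYPER_NT = 25,
        LATE = 25, HYPER2 = 25, DE_NOVO = 25, CONSTITUTIVE = 1725,
        LOW_EXPRESSED = 100),
    baselineMean = 1000, dispersion = 0.01, betweenExperimentSd = 0.25,
    sizeFactors = NULL, theta = 2, experiments = c("exp1", "exp2"),
    seed = NULL) {
    stopifnot(baselineMean > 0, dispersion >= 0, betweenExperimentSd >= 0)
    if (!length(nPerArchetype) || any(nPerArchetype < 0) ||
        sum(nPerArchetype) == 0)
        stop("invalid gene numbers per archetype")
    unknown <- setdiff(names(nPerArchetype), .ARCHETYPES)
    if (length(unknown))
        stop("unknown archetype(s): ", paste(unknown, collapse = ", "))
    if (!is.null(seed)) set.seed(seed)
    profiles <- defaultArchetypeProfiles(theta)
    design <- toleranceDesign(experiments)
    if (is.null(sizeFactors))
        sizeFactors <- stats::setNames(rep(1, nrow(design)),
                                       design$library_id)
    sf <- sizeFactors[design$library_id]
    if (anyNA(sf) || any(sf <= 0))
        stop("size factors must be positive and cover every library")
    archetype <- rep(names(nPerArchetype), times = nPerArchetype)
    nGenes <- length(archetype)
    geneIds <- sprintf("gene%04d", seq_len(nGenes))
    scale <- vapply(archetype,
                    function(a) profiles[[a]]$baselineScale, numeric(1))
    foldMat <- vapply(seq_len(nrow(design)), function(j)
        vapply(archetype, function(a)
            .foldFor(profiles[[a]]$folds, design$first_stimulus[j],
                     design$second_stimulus[j], design$timepoint[j]),
            numeric(1)),
        numeric(nGenes))
    eps <- matrix(stats::rnorm(nGenes * length(experiments),
                               sd = betweenExperimentSd),
                  nrow = nGenes,
                  dimnames = list(NULL, experiments))
    expFactor <- 2^eps[, design$experiment_id, drop = FALSE]
    mu <- baselineMean * scale * foldMat * expFactor *
        rep(sf, each = nGenes)
    counts <- matrix(0, nrow = nGenes, ncol = nrow(design),
                     dimnames = list(geneIds, design$library_id))
    if (dispersion == 0) {
        counts[] <- stats::rpois(length(mu), lambda = mu)
    } else {
        counts[] <- stats::rnbinom(length(mu), mu = mu,
                                   size = 1 / dispersion)
    }
    te <- ToleranceExperiment(counts, design)
    rowData(te)$archetype <- archetype
    metadata(te) <- list(
        simulation = list(nPerArchetype = nPerArchetype,
                          baselineMean = baselineMean,
                          dispersion = dispersion,
                          betweenExperimentSd = betweenExperimentSd,
                          theta = theta, seed = seed))
    te
}

#' Write a simulated experiment to tab-separated files
#'
#' Emits the same formats \code{\link{readCountMatrix}} and
#' \code{\link{readSampleSheet}} read, plus a two-column truth file of
#' gene archetypes.
#'
#' @param te a \code{ToleranceExperiment} (typically from
#'   \code{\link{simulateToleranceCounts}}).
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (counts, sample sheet, truth).
#' @export
writeToleranceExperiment <- function(te, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cpath <- file.path(dir, "counts.tsv")
    spath <- file.path(dir, "samples.tsv")
    writeTable(assay(te, "counts"), cpath)
    cd <- colData(te)
    ss <- data.frame(library_id = rownames(cd),
                     experiment_id = cd$experiment,
                     first_stimulus = cd$firstStimulus,
                     second_stimulus = cd$secondStimulus,
                     timepoint = cd$timepoint)
    utils::write.table(ss, spath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(counts = cpath, samples = spath)
    if ("archetype" %in% colnames(rowData(te))) {
        tpath <- file.path(dir, "truth.tsv")
        utils::write.table(
            data.frame(gene_id = rownames(te),
                       archetype = rowData(te)$archetype),
            tpath, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, truth = tpath)
    }
    invisible(paths)
}

#' Read a ToleranceExperiment back from tab-separated files
#'
#' @param countsPath,samplesPath paths written by
#'   \code{\link{writeToleranceExperiment}} (or hand-made files in the
#'   same layout).
#' @return A \code{\link{ToleranceExperiment}}.
#' @export
readToleranceExperiment <- function(countsPath, samplesPath) {
    ToleranceExperiment(readCountMatrix(countsPath),
                        readSampleSheet(samplesPath))
}
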