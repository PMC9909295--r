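test_that("transcript aggregation sums variants and conserves totals", {
    m <- rbind(t1 = c(3, 5), t2 = c(7, 0), t3 = c(2, 2))
    map <- data.frame(tx = c("t1", "t2", "t3"), gene = c("G", "G", "H"))
    agg <- aggregateTranscripts(m, map)
    expect_equal(agg["G", ], c(10, 5))
    expect_equal(agg["H", ], c(2, 2))  # single-transcript gene unchanged

    # random transcripts in random genes: brute-force re-summation oracle
    set.seed(11)
    tx <- matrix(rpois(50 * 10, 20), nrow = 50,
                 dimnames = list(paste0("t", 1:50), paste0("lib", 1:10)))
    genes <- sample(paste0("g", 1:10), 50, replace = TRUE)
    agg <- aggregateTranscripts(tx, data.frame(rownames(tx), genes))
    expect_equal(colSums(agg), colSums(tx))
    brute <- t(vapply(sort(unique(genes)), function(g)
        colSums(tx[genes == g, , drop = FALSE]), numeric(10)))
    expect_equal(agg, brute, ignore_attr = TRUE)
})

test_that("aggregation drops unmapped transcripts and rejects empty maps", {
    m <- rbind(t1 = c(1, 1), t9 = c(5, 5))
    expect_message(agg <- aggregateTranscripts(
        m, data.frame(tx = "t1", gene = "G")), "dropped")
    expect_equal(colSums(agg), c(1, 1))
    expect_error(aggregateTranscripts(m, data.frame()), "two columns")
    expect_error(aggregateTranscripts(m, character()), "empty")
})

test_that("gene filter applies the inclusive >=50-in-each-experiment rule", {
    genes <- paste0("g", 1:6)
    mk <- function(mx) matrix(c(mx, rep(0, 6)), ncol = 2,
                              dimnames = list(genes, c("a", "b")))
    # max counts per gene: exp1 then exp2
    e1 <- mk(c(120, 50, 49, 0, 300, 51))
    e2 <- mk(c(130, 50, 50, 0, 250, 49))
    # boundary: max 50 in both experiments -> retained (inclusive)
    expect_true("g2" %in% filterGenes(list(e1, e2)))
    # max 49 in one experiment -> excluded under require-all
    expect_false("g3" %in% filterGenes(list(e1, e2)))
    expect_true("g3" %in% filterGenes(list(e1, e2),
                                      requireAllExperiments = FALSE))
    # g6: 51 in exp1 but 49 in exp2 -> excluded
    coding <- c("g1", "g2", "g3", "g4", "g6")  # g5 non-coding
    expect_identical(filterGenes(list(e1, e2), codingGenes = coding),
                     c("g1", "g2"))
    # monotonicity: raising the threshold never adds genes
    for (thr in c(0, 10, 50, 120, 200)) {
        lo <- filterGenes(list(e1, e2), minRawCount = thr)
        hi <- filterGenes(list(e1, e2), minRawCount = thr + 30)
        expect_true(all(hi %in% lo))
    }
    expect_error(filterGenes(list(e1, e2[6:1, ])), "universe")
})

test_that("RPM normalization replaces zeros and columns sum to one million", {
    m <- cbind(lib1 = c(0, 1, 999998))
    expect_equal(unname(computeRPM(m)[, 1]), c(1, 1, 999998))

    # symmetry: equal counts give equal shares
    eq <- matrix(7, nrow = 10, ncol = 2)
    expect_true(all(computeRPM(eq) == 1e5))

    set.seed(42)
    r <- matrix(rpois(400, 30), nrow = 100)
    rpm <- computeRPM(r)
    expect_equal(colSums(rpm), rep(1e6, 4), tolerance = 1e-9)
    expect_true(all(rpm > 0))
    # scale consistency for entries that were nonzero
    rpm3 <- computeRPM(r * 3L)
    nz <- r > 0
    expect_equal(rpm[nz], rpm3[nz], tolerance = 1e-6)
    expect_error(computeRPM(matrix(numeric(0), 0, 0)), "empty")
})

test_that("cross-experiment correlation behaves at its fixed points", {
    set.seed(5)
    sim <- simCache()
    cors <- crossExperimentCorrelation(sim)
    expect_length(cors, 18)
    expect_true(all(cors >= -1 & cors <= 1))
    expect_true(all(cors > 0.9))  # strong but imperfect replicate agreement

    rpm <- computeRPM(assay(sim, "counts")[, 1:2])
    colnames(rpm) <- c("0->0@1h", "0->0@1h")
    same <- crossExperimentCorrelation(
        list(rpm[, 1, drop = FALSE], rpm[, 1, drop = FALSE]))
    expect_equal(unname(same), 1)
    # log-scale multiplicative shift leaves Pearson r at 1
    shifted <- crossExperimentCorrelation(
        list(rpm[, 1, drop = FALSE], rpm[, 1, drop = FALSE] * 4.2))
    expect_equal(unname(shifted), 1)
    # value permutation destroys correlation on a large gene set
    perm <- rpm[, 1, drop = FALSE]
    perm[, 1] <- sample(perm[, 1])
    scrambled <- crossExperimentCorrelation(
        list(rpm[, 1, drop = FALSE], perm))
    expect_lt(abs(unname(scrambled)), 0.1)
})

test_that("count tables and sample sheets round-trip through disk", {
    sim <- simCache()
    dir <- withr::local_tempdir()
    paths <- writeToleranceExperiment(sim, dir)
    back <- readToleranceExperiment(paths["counts"], paths["samples"])
    expect_equal(assay(back, "counts"), assay(sim, "counts"))
    expect_equal(conditionLabels(back), conditionLabels(sim))
    truth <- read.delim(paths["truth"])
    expect_equal(truth$archetype, rowData(sim)$archetype)
})

test_that("condition encoding round-trips bijectively over the design", {
    d <- toleranceDesign()
    lab <- encodeCondition(d$first_stimulus, d$second_stimulus, d$timepoint)
    expect_equal(length(unique(lab)), 18)  # 3 x 3 x 2 distinct conditions
    dec <- decodeCondition(lab)
    expect_equal(dec$first, d$first_stimulus)
    expect_equal(dec$second, d$second_stimulus)
    expect_equal(dec$timepoint, d$timepoint)
    expect_error(decodeCondition("X->L@1h"), "malformed")
})

test_that("ToleranceExperiment validity rejects malformed input", {
    sim <- simCache()
    d <- toleranceDesign()
    cnt <- assay(sim, "counts")
    bad <- d; bad$first_stimulus[1] <- "Q"
    expect_error(ToleranceExperiment(cnt, bad), "firstStimulus")
    expect_error(ToleranceExperiment(cnt[, 1:3],
                                     d[d$library_id %in% colnames(cnt)[4:6], ]),
                 "absent")
    neg <- cnt; neg[1, 1] <- -1
    expect_error(ToleranceExperiment(neg, d), "non-negative")
})
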