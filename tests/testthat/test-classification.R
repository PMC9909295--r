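test_that("ratio indices reproduce direct arithmetic and their identity", {
    idx <- ratioIndices(10, 50, 12, 13)
    expect_equal(idx$I_primary, 5)
    expect_equal(idx$I_residual, 1.2)
    expect_equal(idx$I_secondary, 13 / 12)
    expect_equal(idx$I_sec_vs_prim, 0.26)
    expect_equal(idx$I_sec_vs_base, 1.3)

    flat <- ratioIndices(7, 7, 7, 7)
    expect_true(all(unlist(flat) == 1))

    set.seed(3)
    q <- matrix(exp(rnorm(400)), ncol = 4)
    idx <- ratioIndices(q[, 1], q[, 2], q[, 3], q[, 4])
    expect_equal(idx$I_sec_vs_base, idx$I_secondary * idx$I_residual,
                 tolerance = 1e-12)
    expect_error(ratioIndices(0, 1, 1, 1), "positive")
})

test_that("timepoint rule engine matches rule-forced examples", {
    expect_equal(as.character(classifyTimepoint(10, 50, 12, 13)),
                 "UNINDUCIBLE")
    expect_equal(as.character(classifyTimepoint(10, 50, 10, 55)),
                 "NORMOINDUCIBLE")
    expect_equal(as.character(classifyTimepoint(10, 15, 100, 250)),
                 "HYPERINDUCIBLE_2")
    expect_equal(as.character(classifyTimepoint(10, 100, 10, 11)),
                 "UNINDUCIBLE")
    expect_equal(as.character(classifyTimepoint(10, 100, 10, 35)),
                 "HYPOINDUCIBLE")
    expect_equal(as.character(classifyTimepoint(10, 40, 10, 900)),
                 "HYPERINDUCIBLE")
    expect_equal(as.character(classifyTimepoint(10, 15, 100, 150)),
                 "LATE")
    expect_equal(as.character(classifyTimepoint(10, 15, 12, 90)),
                 "DE_NOVO")
    expect_equal(as.character(classifyTimepoint(10, 15, 12, 18)),
                 "UNRESPONSIVE")
})

test_that("rule engine is total, scale-invariant and theta-monotone", {
    grid <- expand.grid(b = c(1, 3, 9, 27, 81), p = c(1, 3, 9, 27, 81),
                        r = c(1, 3, 9, 27, 81), s = c(1, 3, 9, 27, 81))
    calls <- classifyTimepoint(grid$b, grid$p, grid$r, grid$s)
    expect_false(anyNA(calls))  # total function on positive quads
    # scale invariance
    calls10 <- classifyTimepoint(grid$b * 10, grid$p * 10, grid$r * 10,
                                 grid$s * 10)
    expect_equal(calls, calls10)
    # raising theta never converts UNINDUCIBLE into an inducible subclass
    calls3 <- classifyTimepoint(grid$b, grid$p, grid$r, grid$s, theta = 3)
    wasUnind <- calls == "UNINDUCIBLE"
    expect_false(any(calls3[wasUnind] %in%
                     c("HYPOINDUCIBLE", "NORMOINDUCIBLE", "HYPERINDUCIBLE")))
})

test_that("overall T/NT assessment follows the definitions for all pairs", {
    expect_equal(as.character(overallCall("UNINDUCIBLE", "LATE")), "T")
    expect_equal(as.character(overallCall("UNRESPONSIVE", "HYPOINDUCIBLE")),
                 "NT")
    expect_equal(as.character(overallCall("UNRESPONSIVE", "UNRESPONSIVE")),
                 "UNCLASSIFIED")
    # exhaustive 64-pair enumeration against the quoted definitions
    lv <- levels(classifyTimepoint(1, 1, 1, 1))
    pairs <- expand.grid(c1 = lv, c4 = lv, stringsAsFactors = FALSE)
    got <- as.character(overallCall(pairs$c1, pairs$c4))
    want <- mapply(oracleOverall, pairs$c1, pairs$c4)
    expect_equal(got, unname(want))
    # T and NT never overlap
    expect_false(any(got == "T" & want == "NT"))
})

test_that("sustained-expression criteria fire and fail one by one", {
    expect_true(isSustainedExpression(10, 100, 110, 20, 95))
    expect_false(isSustainedExpression(10, 100, 110, 60, 95))  # (ii) fails
    expect_false(isSustainedExpression(10, 100, 110, 20, 210)) # (iii) fails
    expect_false(isSustainedExpression(10, 100, 110, 20, 45))  # (iii) low
    expect_false(isSustainedExpression(10, 15, 110, 20, 95))   # (i) fails
    # lenient either/or reading of criterion (i)
    expect_true(isSustainedExpression(10, 100, 15, 20, 95,
                                      requireBothAt1h = FALSE))
    expect_false(isSustainedExpression(10, 100, 15, 20, 95))
})

test_that("sequence classification recovers constructed archetypes", {
    sim <- simCache()
    simf <- sim[filterGenes(sim), ]
    truth <- rowData(simf)$archetype
    want <- archetypeExpectedCalls()
    m <- match(truth, want$archetype)
    calls <- classifySequence(simf, "L", "L", experiment = "exp1")
    agree <- as.character(calls$call_1h) == want$call_1h[m] &
        as.character(calls$call_4h) == want$call_4h[m] &
        as.character(calls$overall) == want$overall[m] &
        as.character(calls$subcategory) == want$subcategory[m]
    expect_gt(mean(agree), 0.95)
    # SE genes are a subset of NT by construction of the rule precedence
    expect_true(all(calls$overall[calls$subcategory == "SE"] == "NT"))
    # T and NT sets are disjoint and coverage is recorded
    expect_equal(sum(calls$overall == "T" & calls$overall == "NT"), 0)
    expect_true(metadata(calls)$tolerance_coverage > 0 &&
                metadata(calls)$tolerance_coverage <= 1)
})

test_that("degenerate 0->0 sequence yields no tolerance classification", {
    sim <- simCache()
    calls <- classifySequence(sim, "0", "0", experiment = "exp1")
    expect_false(any(calls$overall %in% c("T", "NT")))
    expect_true(all(calls$call_1h %in% c("UNRESPONSIVE")))
})

test_that("gene order does not influence per-gene calls", {
    sim <- simCache()[1:300, ]
    calls <- classifySequence(sim, "L", "L", experiment = "exp1")
    perm <- sample(nrow(sim))
    callsPerm <- classifySequence(sim[perm, ], "L", "L",
                                  experiment = "exp1")
    m <- match(calls$gene_id, callsPerm$gene_id)
    expect_equal(as.character(calls$call_1h),
                 as.character(callsPerm$call_1h[m]))
    expect_equal(as.character(calls$overall),
                 as.character(callsPerm$overall[m]))
})

test_that("missing conditions are reported by name", {
    sim <- simCache()
    drop <- conditionLabels(sim) == "L->L@4h" &
        colData(sim)$experiment == "exp1"
    expect_error(classifySequence(sim[, !drop], "L", "L",
                                  experiment = "exp1"),
                 "L->L@4h", fixed = TRUE)
})

test_that("single-ratio NT criterion is inclusive at its boundary", {
    # hand-built experiment: secondary exactly equal to primary (kept),
    # just below (dropped), strongly above (kept), not inducible
    # (excluded).  A filler gene equalizes library totals so RPM ratios
    # equal count ratios exactly and the >= 1 boundary is hit precisely.
    d <- toleranceDesign("e1")
    counts <- matrix(1000L, nrow = 5, ncol = 18,
                     dimnames = list(paste0("g", 1:5), d$library_id))
    prim <- d$first_stimulus == "0" & d$second_stimulus == "L"
    sec <- d$first_stimulus == "L" & d$second_stimulus == "L"
    counts[1, prim] <- 8000L; counts[1, sec] <- 8000L
    counts[2, prim] <- 8000L; counts[2, sec] <- 7920L
    counts[3, prim] <- 8000L; counts[3, sec] <- 16000L
    counts[4, prim] <- 1000L; counts[4, sec] <- 9000L
    counts[5, ] <- 50000L - colSums(counts[1:4, , drop = FALSE])
    te <- ToleranceExperiment(counts, d)
    got <- fosterNT(te, "L", "L", experiment = "e1", timepoint = "4h")
    expect_true("g1" %in% got)     # ratio exactly 1 is included
    expect_false("g2" %in% got)    # 0.99 excluded
    expect_true("g3" %in% got)
    expect_false("g4" %in% got)    # not primary-inducible
})
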