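test_that("the 1% AIC rule reproduces the study's printed acceptance boundaries", {
    # double vs single input: threshold 0.99 * 1415 = 1400.85 (printed >1401)
    expect_true(acceptRule(953, 1415))
    expect_true(acceptRule(1400.85, 1415))
    expect_false(acceptRule(1401, 1415))
    # triple vs best double: threshold 0.99 * 953 = 943.47 (printed >943)
    expect_true(acceptRule(798, 953))
    expect_true(acceptRule(943.4, 953))
    expect_false(acceptRule(944, 953))
    # quadruple vs best triple: threshold 0.99 * 798 = 790.02 (printed <=790)
    expect_true(acceptRule(680, 798))
    expect_true(acceptRule(790, 798))
    expect_false(acceptRule(791, 798))
})

test_that("stagewise candidate enumeration matches the study's counts", {
    sites <- candidateSites(buildBaseModel("simple"))
    s2 <- enumerateCandidates(2, allSites = sites)
    expect_length(s2, 12)
    # nine surviving double-input components -> 36 triples
    surv2 <- lapply(setdiff(sites, c("TSC_pT1462", "p70S6K_pT389",
                                     "PRAS40_pS183")), identity)
    s3 <- enumerateCandidates(3, surv2, sites)
    expect_length(s3, 36)
    expect_true(all(vapply(s3, length, 1L) == 2))
    # seven accepted triples sharing one common component -> C(7,2) = 21
    others <- setdiff(sites, c("IRS_p", "TSC_pT1462", "p70S6K_pT389",
                               "PRAS40_pS183"))[1:7]
    surv3 <- lapply(others, function(x) sort(c("IRS_p", x)))
    s4 <- enumerateCandidates(4, surv3, sites)
    expect_length(s4, 21)
    expect_true(all(vapply(s4, length, 1L) == 3))
    expect_true(all(vapply(s4, function(s) "IRS_p" %in% s, TRUE)))
    # totals across the procedure: 1 + 12 + 36 + 21 = 70
    expect_equal(1 + length(s2) + length(s3) + length(s4), 70)
})

test_that("pair enumeration equals the brute-force C(n, 2) oracle", {
    sites <- candidateSites(buildBaseModel("simple"))
    for (n in 2:12) {
        surv <- lapply(sites[seq_len(n)], identity)
        got <- enumerateCandidates(3, surv, sites)
        # brute force: enumerate all subsets of size 2 by double loop
        brute <- list()
        comps <- sites[seq_len(n)]
        for (i in seq_along(comps)) for (j in seq_along(comps))
            if (i < j) brute[[length(brute) + 1]] <- sort(c(comps[i], comps[j]))
        expect_equal(length(got), length(brute))
        expect_setequal(vapply(got, paste, "", collapse = "+"),
                        vapply(brute, paste, "", collapse = "+"))
    }
    # quadruple unions with four distinct components are discarded
    surv3 <- list(c("Akt_pT308", "Akt_pS473"), c("IRS_p", "TSC_pS1387"))
    expect_length(enumerateCandidates(4, surv3, sites), 0)
    expect_length(enumerateCandidates(3, list(), sites), 0)
})

test_that("a degenerate improvement requirement stops selection at the base model", {
    base <- buildBaseModel("simple")
    tp <- truthParameters()
    base <- setParameters(base, tp[names(tp) %in% parameterTable(base)$id])
    ds <- smallDataset(noiseCV = 0, seed = 1,
                       timeGrid = c(0, 5, 15, 60), nReplicates = 3)
    sel <- runSelection(base, ds, selectionConfig(
        improvementFraction = 1, maxStage = 2,
        fit = fitConfig(nStarts = 1, maxIter = 20, seed = 1),
        candidates = c("IRS_p", "AMPK_pT172")))
    expect_identical(sel@best, character(0))
    expect_equal(unique(selectionTable(sel)$stage[selectionTable(sel)$accepted]), 1)
})
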