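test_that("the shipped ground truth passes the behaviour checklist", {
    ck <- behaviourChecklist(truthModel())
    expect_length(ck, 7)
    expect_true(all(ck))
})

test_that("severing the relevant arms fails the matching checks", {
    m <- truthModel()
    # all-zero amino-acid input rates -> no acute AMPK response at all
    noAa <- setParameters(m, c(k_aa_AMPK_pT172 = 1e-6, k_aa_IRS_p = 1e-6,
                               k_aa_mTORC2_pS2481 = 1e-6,
                               k_mTORC1_act = 1e-6))
    expect_false(behaviourChecklist(noAa)[["ampk_half_max_by_5min"]])
    # severed negative feedback (S6K->IRS and the IRS->AMPK arm):
    # mTORC1 knockdown can no longer raise Akt-S473
    noNfl <- setParameters(m, c(k_IRS_S636_phos = 1e-6, k_AMPK_phos = 1e-6))
    expect_false(behaviourChecklist(noNfl)[["mtorc1_kd_nfl_release"]])
})

test_that("zero noise reproduces the simulated observables exactly", {
    cfg <- synthConfig(timeGrid = c(0, 5, 30, 120), noiseCV = 0, seed = 1)
    ds <- generateTimecourses(truthModel(), cfg)
    d <- datasetTable(ds)
    tr <- simulateModel(truthModel(), cfg$conditions$aa_only,
                        times = c(0, 5, 30, 120))
    d1 <- d[d$condition == "aa_only" & d$observable == "AMPK-pT172" &
            d$replicate == 1, ]
    expect_equal(d1$value, observableValues(tr)[, "AMPK-pT172"])
    # replicates identical when noise-free
    d2 <- d[d$condition == "aa_only" & d$observable == "AMPK-pT172" &
            d$replicate == 2, ]
    expect_identical(d1$value, d2$value)
})

test_that("noise generation honours the RNG contract and the noise law", {
    cfg <- function(s, n = 3, cv = 0.1)
        synthConfig(timeGrid = c(0, 5, 30), nReplicates = n, noiseCV = cv,
                    seed = s)
    a <- generateTimecourses(truthModel(), cfg(1))
    b <- generateTimecourses(truthModel(), cfg(1))
    c <- generateTimecourses(truthModel(), cfg(2))
    expect_identical(datasetTable(a), datasetTable(b))
    expect_false(identical(datasetTable(a), datasetTable(c)))
    expect_true(all(datasetTable(a)$value >= 0))
    # replicate means converge to the noise-free value (law of large numbers)
    many <- generateTimecourses(truthModel(), cfg(3, n = 100))
    d <- datasetTable(many)
    d <- d[d$observable == "AMPK-pT172" & d$condition == "aa_only" &
           d$time == 30, ]
    yhat <- datasetTable(generateTimecourses(truthModel(),
        cfg(1, n = 3, cv = 0)))
    yhat <- yhat$value[yhat$observable == "AMPK-pT172" &
                       yhat$condition == "aa_only" & yhat$time == 30][1]
    expect_lt(abs(mean(d$value) - yhat) / yhat, 3 * 0.1 / sqrt(100))
})

test_that("datasets round-trip bit-exactly through the TSV reader", {
    ds <- smallDataset(seed = 4, timeGrid = c(0, 5, 30))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeDataset(ds, f)
    back <- readDataset(f, protocols(ds))
    expect_equal(datasetTable(back)$value, datasetTable(ds)$value)
    expect_identical(datasetTable(back)$observable, datasetTable(ds)$observable)
})

test_that("generated phosphosite tables behave under the volcano pipeline", {
    # type-I control of the volcano test itself: with independent null
    # ratios the joint FC/p false-call rate stays below alpha
    set.seed(5)
    iid <- matrix(rnorm(2000 * 9, sd = 0.5), 2000, 9,
                  dimnames = list(paste0("N", 1:2000), NULL))
    recI <- attr(volcanoFilter(volcanoRecords(iid, 5), 1.5, 0.05), "records")
    expect_lt(mean(recI$regulated), 0.05)
    expect_lt(abs(mean(recI$p < 0.05) - 0.05), 0.02)
    # on full pipeline nulls the bridged all-vs-all ratios share channel
    # noise, which inflates the nominal t-test; calls must still be rare
    # relative to the planted-effect detection below
    null <- generatePhosphoTable(nSites = 500, nRegulated = 0, seed = 5)
    outN <- runPhosphoPipeline(null, fcCutoffs = 1.5)
    rec <- attr(volcanoFilter(outN$records, 1.5, 0.05), "records")
    nullRate <- mean(rec$regulated)
    # strong planted effects at low noise all pass the twofold filter
    strong <- generatePhosphoTable(nSites = 200, nRegulated = 15,
                                   log2FC = 1.5, channelSD = 0.05,
                                   contaminantFrac = 0, missingRate = 0,
                                   seed = 6)
    outS <- runPhosphoPipeline(strong, fcCutoffs = 2)
    expect_true(all(attr(strong, "regulated") %in% outS$regulated[["2"]]))
    recS <- attr(volcanoFilter(outS$records, 2, 0.05), "records")
    expect_gt(mean(recS$regulated[recS$site %in% attr(strong, "regulated")]),
              nullRate)
    # sub-0.75 localization sites never reach testing
    contam <- generatePhosphoTable(nSites = 100, nRegulated = 0,
                                   contaminantFrac = 0.3, seed = 7)
    low <- contam$Proteins[contam[["Localization prob"]] <= 0.75]
    expect_gt(length(low), 0)
    outC <- runPhosphoPipeline(contam, fcCutoffs = 1.5)
    expect_false(any(low %in% unique(outC$records$site)))
})
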