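test_that("base and variant models carry the expected structure", {
    base <- buildBaseModel("extended")
    expect_equal(nrow(speciesTable(base)), 31)
    expect_equal(nrow(reactionTable(base)), 45)
    expect_equal(length(observableMap(base)), 12)
    expect_equal(nrow(parameterTable(base)), 33)

    quad <- buildVariant(base, c("IRS_p", "AMPK_pT172", "mTORC2_pS2481"))
    expect_equal(nrow(speciesTable(quad)), 31)
    expect_equal(nrow(reactionTable(quad)), 48)
    expect_equal(length(observableMap(quad)), 12)
    expect_equal(nrow(parameterTable(quad)), 36)

    simple <- buildBaseModel("simple")
    expect_equal(nrow(speciesTable(simple)), 29)
    expect_equal(length(observableMap(simple)), 11)
    expect_false("p70S6K-pT229" %in% names(observableMap(simple)))
})

test_that("every reaction interconverts states within one protein pool", {
    for (m in list(buildBaseModel("extended"),
                   buildVariant(buildBaseModel("simple"), candidateSites(NULL)))) {
        sp <- speciesTable(m)
        pool <- setNames(sp$protein, sp$id)
        rx <- reactionTable(m)
        expect_true(all(pool[rx$substrate] == pool[rx$product]))
    }
})

test_that("modified states start at zero and pool totals at one", {
    sp <- speciesTable(buildBaseModel("extended"))
    expect_true(all(sp$initial[sp$phospho != "" | sp$id == "IR_refractory"] == 0))
    expect_true(all(tapply(sp$initial, sp$protein, sum) == 1))
})

test_that("the candidate list has the 12 activatable non-IR sites", {
    sites <- candidateSites(buildBaseModel("simple"))
    expect_length(sites, 12)
    expect_true(all(c("TSC_pT1462", "p70S6K_pT389", "PRAS40_pS183") %in% sites))
    expect_false(any(c("mTORC1_act", "IR", "IR_pY1146", "IR_refractory",
                       "IRS_pS636") %in% sites))
})

test_that("adding inputs grows reactions by precursor pairs and parameters by one per site", {
    base <- buildBaseModel("extended")
    expect_identical(reactionTable(buildVariant(base, character(0))),
                     reactionTable(base))
    # combinatorial-state site: two precursor reactions, one shared parameter
    v <- buildVariant(base, "PRAS40_pT246")
    expect_equal(nrow(reactionTable(v)) - nrow(reactionTable(base)), 2)
    expect_equal(nrow(parameterTable(v)) - nrow(parameterTable(base)), 1)
    aaRx <- reactionTable(v)[reactionTable(v)$param == "k_aa_PRAS40_pT246", ]
    expect_setequal(aaRx$substrate, c("PRAS40", "PRAS40_pS183"))
    # single-state site: one reaction
    v1 <- buildVariant(base, "IRS_p")
    expect_equal(nrow(reactionTable(v1)) - nrow(reactionTable(base)), 1)
    # monotonicity over all sites: species never removed
    for (site in candidateSites(base)) {
        vi <- buildVariant(base, site)
        expect_true(all(speciesTable(base)$id %in% speciesTable(vi)$id))
        expect_gt(nrow(reactionTable(vi)), nrow(reactionTable(base)))
    }
    expect_error(buildVariant(base, "NotASite"), "unknown candidate site")
})

test_that("first/second reaction pairs of combinatorial states share one parameter", {
    quad <- quadModel()
    rx <- reactionTable(quad)
    shared <- names(which(table(rx$param) == 2))
    # Akt (4), PRAS40 (4), p70-S6K (4) combinatorial pairs
    expect_length(shared, 12)
    for (p in shared) {
        pair <- rx[rx$param == p, ]
        sp <- speciesTable(quad)
        expect_equal(length(unique(sp$protein[match(pair$substrate, sp$id)])), 1)
    }
})

test_that("parameter updates are bound-checked and name-checked", {
    m <- buildBaseModel("extended")
    m2 <- setParameters(m, c(k_mTORC1_act = 0.5))
    expect_equal(parameterTable(m2)$value[parameterTable(m2)$id == "k_mTORC1_act"], 0.5)
    expect_error(setParameters(m, c(nope = 1)), "unknown parameter")
    expect_error(setParameters(m, c(k_mTORC1_act = 1e6)), "outside bounds")
})
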