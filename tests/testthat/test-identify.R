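test_that("an exactly anti-correlated parameter pair is flagged", {
    set.seed(21)
    n <- 40
    p1 <- 10^rnorm(n, 0, 0.3)          # CV well above 15%
    ens <- cbind(k_a = p1, k_b = 2 / p1,
                 k_c = 10^rnorm(n, 0, 0.3))
    flags <- motaFlags(ens)
    fa <- flags[flags$parameter == "k_a", ]
    expect_true(fa$flagged)
    expect_equal(fa$tuple, "k_b")
    expect_gt(fa$r2, 0.999)
    expect_false(flags$flagged[flags$parameter == "k_c"])
})

test_that("independent parameters yield no flags and tight parameters are gated out", {
    set.seed(22)
    ens <- matrix(10^rnorm(200, 0, 0.3), 40, 5,
                  dimnames = list(NULL, paste0("k", 1:5)))
    expect_false(any(motaFlags(ens)$flagged))
    # a parameter with ~1% CV is never flagged even when perfectly correlated
    tight <- 10^rnorm(40, 0, 0.004)
    ens2 <- cbind(k_t = tight, k_u = 1 / tight * 10^rnorm(40, 0, 0.2))
    ft <- motaFlags(ens2)
    expect_lt(ft$cv[ft$parameter == "k_t"], 0.05)
    expect_false(ft$flagged[ft$parameter == "k_t"])
})

test_that("flags are invariant to parameter reordering", {
    set.seed(23)
    p1 <- 10^rnorm(30, 0, 0.4)
    ens <- cbind(k_a = p1, k_b = 1 / p1, k_c = 10^rnorm(30, 0, 0.4))
    f1 <- motaFlags(ens)
    f2 <- motaFlags(ens[, c("k_c", "k_b", "k_a")])
    expect_identical(f1[order(f1$parameter), ]$flagged,
                     f2[order(f2$parameter), ]$flagged)
})

test_that("degenerate ensembles warn instead of flagging", {
    ens <- matrix(1, 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    expect_warning(f <- motaFlags(ens), "degenerate")
    expect_false(any(f$flagged))
})

test_that("profile likelihood classifies a constrained rate as identifiable", {
    quad <- quadModel()
    ds0 <- smallDataset(noiseCV = 0, seed = 1,
                        timeGrid = c(0, 2, 5, 10, 20, 40, 80))
    pl <- profileLikelihood(quad, ds0, "k_S6K_T389_phos", nSteps = 7,
                            span = 1.2,
                            free = c("k_S6K_T389_dephos", "k_S6K_T229_phos"))
    expect_equal(pl$class, "identifiable")
    # the profile's centre point is the (perfect-fit) optimum
    mid <- which(pl$grid == truthParameters()[["k_S6K_T389_phos"]])
    expect_lt(pl$chi2[mid], 1e-4)
    expect_true(all(pl$chi2 >= pl$chi2min - 1e-6, na.rm = TRUE))
})

test_that("a parameter with no path to any observable has a flat profile", {
    quad <- quadModel()
    # amino-acid-only data: the insulin receptor module never moves,
    # so its recovery rate cannot influence any residual
    cfg <- synthConfig(timeGrid = c(0, 5, 15, 45), noiseCV = 0, seed = 1,
                       conditions = list(aa_only = Protocol(aa = 1, insulin = 0)))
    ds <- generateTimecourses(quadModel(), cfg)
    pl <- profileLikelihood(quad, ds, "k_IR_recover", nSteps = 5, span = 2,
                            free = character(0))
    expect_equal(pl$class, "structurally non-identifiable")
    expect_lt(diff(range(pl$chi2)), 1e-6)
})

test_that("the identifiability report merges ensemble flags and profile classes", {
    set.seed(30)
    ens <- cbind(k_a = 10^rnorm(20, 0, 0.3), k_b = 10^rnorm(20, 0, 0.3))
    rep <- identifiabilityReport(ens,
        profiles = list(list(param = "k_a", class = "identifiable")))
    expect_equal(rep$class[rep$parameter == "k_a"], "identifiable")
    expect_true(is.na(rep$class[rep$parameter == "k_b"]))
})
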