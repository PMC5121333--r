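test_that("the bridged design yields nine ratios at 5 min and six at 10/15 min", {
    tab <- generatePhosphoTable(nSites = 40, nRegulated = 0, seed = 1,
                                missingRate = 0)
    des <- silacDesign()
    r5 <- computeRatios(tab, des, 5)
    r10 <- computeRatios(tab, des, 10)
    r15 <- computeRatios(tab, des, 15)
    expect_equal(ncol(r5), 9)
    expect_equal(ncol(r10), 6)
    expect_equal(ncol(r15), 6)
    expect_true(all(is.finite(r5)))
})

test_that("ratio combination counts follow the design product rule on arbitrary designs", {
    # brute-force oracle: (#experiments with t) x (#experiments with 0)
    set.seed(5)
    for (rep in 1:10) {
        nexp <- sample(2:6, 1)
        des <- do.call(rbind, lapply(seq_len(nexp), function(e) {
            times <- c(sample(c(0, 5), 1), sample(c(10, 15), 1), 30)
            data.frame(experiment = e, channel = c("L", "M", "H"),
                       time = times)
        }))
        tab <- data.frame(Proteins = paste0("P", 1:5),
                          `Localization prob` = 1, check.names = FALSE)
        for (i in seq_len(nrow(des)))
            tab[[sprintf("Intensity %s %d", des$channel[i], des$experiment[i])]] <-
                runif(5, 1e6, 1e7)
        for (t in intersect(c(5, 10, 15), des$time)) {
            expected <- sum(tapply(des$time, des$experiment, function(x) t %in% x)) *
                sum(tapply(des$time, des$experiment, function(x) 0 %in% x))
            if (expected == 0) next
            expect_equal(ncol(computeRatios(tab, des, t)), expected)
        }
    }
})

test_that("a within-experiment ratio cancels its bridge term", {
    des <- data.frame(experiment = 1, channel = c("L", "M", "H"),
                      time = c(0, 5, 30))
    tab <- data.frame(Proteins = "P1", `Localization prob` = 1,
                      `Intensity L 1` = 200, `Intensity M 1` = 800,
                      `Intensity H 1` = 12345, check.names = FALSE)
    r <- computeRatios(tab, des, 5)
    expect_equal(ncol(r), 1)
    expect_equal(as.numeric(r), log2(800 / 200))
})

test_that("missing bridges drop combinations with a warning and zeros count as missing", {
    des <- silacDesign()
    tab <- generatePhosphoTable(nSites = 10, nRegulated = 0, seed = 2,
                                missingRate = 0)
    tab[["Intensity H 1"]] <- NA   # bridge of experiment 1
    expect_warning(r <- computeRatios(tab, des, 5), "bridge")
    expect_true(all(is.na(r[, grepl("^E1", colnames(r))])))
    tab2 <- generatePhosphoTable(nSites = 10, nRegulated = 0, seed = 2,
                                 missingRate = 0)
    tab2[["Intensity L 1"]][1] <- 0   # zero intensity = missing
    r2 <- computeRatios(tab2, des, 5)
    expect_true(all(is.na(r2[1, grepl("vs.E1$", colnames(r2))])))
})

test_that("median centering zeroes each column median and only shifts", {
    m <- matrix(rnorm(200, mean = 0.3), 20, 10,
                dimnames = list(paste0("P", 1:20), paste0("c", 1:10)))
    cm <- medianCenter(m)
    expect_true(all(abs(apply(cm, 2, median)) < 1e-12))
    expect_equal(cm[, 1], m[, 1] - median(m[, 1]))
})

test_that("volcano filtering applies the n/fold-change/p gates as stated", {
    # hand-checked case: mean 2^1.033 > 2, one-sample t-test p < 0.05
    x <- c(1.0, 1.0, 1.1)
    tt <- t.test(x, mu = 0)
    rec <- volcanoRecords(matrix(c(x, NA), 1, 4,
                                 dimnames = list("S1", NULL)), 5)
    expect_equal(rec$n, 3)
    expect_equal(rec$log2FC, mean(x))
    expect_equal(rec$p, tt$p.value)
    expect_identical(as.character(volcanoFilter(rec, 2, 0.05)), "S1")
    # a single ratio is excluded regardless of magnitude
    rec1 <- volcanoRecords(matrix(c(5, NA), 1, 2, dimnames = list("S2", NULL)))
    expect_equal(nrow(rec1), 0)
    # large mean but high p fails the p gate
    rec2 <- volcanoRecords(matrix(c(2, -1.4, 1.3), 1, 3,
                                  dimnames = list("S3", NULL)))
    expect_length(volcanoFilter(rec2, 1.5, 0.05), 0)
    # zero-variance vector: passes the p gate iff mean is nonzero
    rec3 <- volcanoRecords(matrix(c(1.2, 1.2, 1.2), 1, 3,
                                  dimnames = list("S4", NULL)))
    expect_equal(rec3$p, 0)
})

test_that("localization gate is strict at 0.75", {
    tab <- data.frame(Proteins = c("A", "B", "C"),
                      `Localization prob` = c(0.75, 0.76, NA),
                      check.names = FALSE)
    expect_identical(localizationFilter(tab)$Proteins, "B")
    empty <- tab[0, ]
    expect_equal(nrow(localizationFilter(empty)), 0)
})

test_that("the pipeline is deterministic and cutoffs are nested", {
    tab <- generatePhosphoTable(nSites = 300, nRegulated = 20, log2FC = 1.2,
                                seed = 9)
    out1 <- runPhosphoPipeline(tab)
    out2 <- runPhosphoPipeline(tab)
    expect_identical(out1, out2)
    expect_true(all(out1$regulated[["2"]] %in% out1$regulated[["1.5"]]))
})

test_that("phosphosite tables round-trip through the MaxQuant-dialect reader", {
    tab <- generatePhosphoTable(nSites = 25, nRegulated = 5, seed = 3)
    f <- withr::local_tempfile(fileext = ".txt")
    writePhosphoTable(tab, f)
    back <- readPhosphoTable(f)
    expect_identical(names(back), setdiff(names(tab), character(0)))
    expect_true(all(c("Localization prob", "Intensity L 1", "Intensity H 5")
                    %in% names(back)))
    expect_equal(back[["Intensity M 2"]], tab[["Intensity M 2"]])
})
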