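# Shared fixtures built in code at test time.

quadModel <- function(s6k = "extended") {
    tp <- truthParameters()
    m <- buildVariant(buildBaseModel(s6k),
                      c("IRS_p", "AMPK_pT172", "mTORC2_pS2481"))
    setParameters(m, tp[names(tp) %in% parameterTable(m)$id])
}

irParams <- c("k_IR_phos", "k_IR_refrac", "k_IR_recover")

# small, fast dataset: coarse grid, both stimulation conditions
smallDataset <- function(noiseCV = 0.10, seed = 1, nReplicates = 3,
                         timeGrid = c(0, 1, 3, 5, 10, 15, 30, 60)) {
    generateTimecourses(quadModel(), synthConfig(
        timeGrid = timeGrid, nReplicates = nReplicates,
        noiseCV = noiseCV, seed = seed))
}

# independent naive chi-square oracle: plain loop over rows
chi2Loop <- function(model, dataset, errorFraction = 0.10,
                     sigmaFloorFrac = 0.01) {
    d <- datasetTable(dataset)
    d <- d[d$observable %in% names(observableMap(model)), ]
    floors <- sigmaFloorFrac * vapply(split(d$value, d$observable), max, 1)
    floors[floors == 0] <- sigmaFloorFrac
    total <- 0
    for (cn in unique(d$condition)) {
        dc <- d[d$condition == cn, ]
        tr <- simulateModel(model, protocols(dataset)[[cn]],
                            times = sort(unique(c(0, dc$time))),
                            atol = 1e-8)
        for (i in seq_len(nrow(dc))) {
            yhat <- observableValues(tr)[match(dc$time[i], tr@time),
                                         dc$observable[i]]
            sig <- max(errorFraction * dc$value[i], floors[[dc$observable[i]]])
            total <- total + ((dc$value[i] - yhat) / sig)^2
        }
    }
    as.numeric(total)
}
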