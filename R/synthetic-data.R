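# Ground-truth-based synthetic data: noisy immunoblot-like time courses from
# the quadruple-input network and MaxQuant-style triple-SILAC phosphosite
# tables matching the five-experiment bridged design.

#' Ground-truth rate constants of the synthetic network
#'
#' A hand-calibrated parameterization (1/min, pool totals = 1 arbitrary
#' unit) of the quadruple-amino-acid-input extended model used as the data
#' generating truth. It is calibrated once against [behaviourChecklist()]:
#' acute amino-acid activation of AMPK, delayed p70-S6K-T389, no readout
#' saturation, and the qualitative wortmannin / mTORC1 / mTORC2 / AMPK
#' knockdown responses at the study's residual-activity levels.
#'
#' @return named numeric vector of parameter values.
#' @export
truthParameters <- function() {
    c(
        # insulin receptor: autophosphorylation, refractory cycle
        k_IR_phos = 0.4, k_IR_refrac = 0.1, k_IR_recover = 0.02,
        # IRS and the p70-S6K negative feedback
        k_IRS_phos = 1.0, k_aa_IRS_p = 0.05, k_IRS_dephos = 0.1,
        k_IRS_S636_phos = 2.0, k_IRS_S636_dephos = 0.1,
        # PI3K species (both IRS-activated, both wortmannin-sensitive)
        k_PI3K_PDK1_act = 0.5, k_PI3K_PDK1_inact = 0.3,
        k_PI3K_var_act = 0.7, k_PI3K_var_inact = 0.3,
        # Akt
        k_Akt_T308_phos = 1.0, k_Akt_T308_dephos = 0.6,
        k_Akt_S473_phos = 1.0, k_Akt_S473_dephos = 1.0,
        # TSC1-TSC2
        k_TSC_T1462_phos = 4.0, k_TSC_T1462_dephos = 0.15,
        k_TSC_S1387_phos = 0.2, k_TSC_S1387_dephos = 0.2,
        # mTORC1 (canonical aa input; inactivated by the GAP-active TSC pool)
        k_mTORC1_act = 0.08, k_mTORC1_inact = 2.0,
        # mTORC2
        k_mTORC2_act = 0.7, k_aa_mTORC2_pS2481 = 0.05, k_mTORC2_inact = 1.0,
        # AMPK (fast aa response + insulin-responsive IRS arm)
        k_aa_AMPK_pT172 = 0.8, k_AMPK_phos = 0.1, k_AMPK_dephos = 0.8,
        # PRAS40
        k_PRAS40_T246_phos = 1.0, k_PRAS40_T246_dephos = 0.6,
        k_PRAS40_S183_phos = 1.0, k_PRAS40_S183_dephos = 0.8,
        # p70-S6K (extended module)
        k_S6K_T229_phos = 1.0, k_S6K_T229_dephos = 0.6,
        k_S6K_T389_phos = 1.0, k_S6K_T389_dephos = 1.5
    )
}

#' The synthetic ground-truth model
#'
#' Quadruple-input (mTORC1 + IRS_p + AMPK_pT172 + mTORC2_pS2481) extended
#' model carrying [truthParameters()].
#'
#' @param s6kModule p70-S6K module flavour (default \code{"extended"}).
#' @return a [ModelSpec-class].
#' @export
truthModel <- function(s6kModule = "extended") {
    tp <- truthParameters()
    m <- buildVariant(buildBaseModel(s6kModule),
                      c("IRS_p", "AMPK_pT172", "mTORC2_pS2481"))
    setParameters(m, tp[names(tp) %in% m@parameters$id])
}

.peak <- function(tr, obs) max(tr@observables[, obs])

#' Qualitative behaviour checklist for a candidate ground truth
#'
#' Seven checks a parameterization must pass before serving as the
#' data-generating truth, all under amino-acid-only stimulation:
#' acute AMPK-T172 activation (at least half-maximal by 5 min), later
#' p70-S6K-T389 activation (still rising between 5 and 15 min), no readout
#' saturation (nothing above 0.95 of its pool), and the knockdown
#' signatures at the study's residual levels: PI3K at 10% residual
#' suppresses the Akt-T308 peak by at least half while barely moving
#' AMPK-T172; mTORC1 at 25% suppresses p70-S6K-T389 by at least half and
#' raises Akt-S473 (the negative-feedback release); AMPK at 50% leaves
#' p70-S6K-T389 within 20% of control; mTORC2 at 40% suppresses Akt-S473
#' by at least 30% while p70-S6K-T389 and AMPK-T172 stay within 20%.
#'
#' @param model a [ModelSpec-class] (quadruple extended truth candidate).
#' @param params optional named parameter overrides.
#' @param outputStep simulation output step in minutes (default 0.5; the
#'   checks compare peaks, which are insensitive to the grid).
#' @return named logical vector of the seven checks with attribute
#'   \code{"details"} (the underlying peak ratios).
#' @export
behaviourChecklist <- function(model, params = NULL, outputStep = 0.5) {
    if (!is.null(params))
        model <- setParameters(model, params[names(params) %in% model@parameters$id])
    aaOnly <- Protocol(aa = 1, insulin = 0, outputStep = outputStep)
    run <- function(pert = numeric(0)) {
        p <- aaOnly
        p@perturbations <- pert
        simulateModel(model, p)
    }
    ok <- logical(0)
    details <- list()
    ctrl <- tryCatch(run(), error = function(e) NULL)
    both <- tryCatch(simulateModel(model,
        Protocol(aa = 1, insulin = 1, outputStep = outputStep)),
        error = function(e) NULL)
    if (is.null(ctrl) || is.null(both)) {
        ok <- setNames(rep(FALSE, 7), paste0("check", 1:7))
        attr(ok, "details") <- list(error = "integration failure")
        return(ok)
    }
    ampk <- ctrl@observables[, "AMPK-pT172"]
    at <- function(tr, obs, t) tr@observables[match(t, tr@time), obs]
    # an acute response must exist (amplitude gate) and be half-maximal early
    ok["ampk_half_max_by_5min"] <- max(ampk) >= 0.1 &&
        at(ctrl, "AMPK-pT172", 5) >= 0.5 * max(ampk)
    ok["s6k_t389_rising_5_to_15"] <-
        at(ctrl, "p70S6K-pT389", 15) > at(ctrl, "p70S6K-pT389", 5)
    ok["no_saturation"] <- max(ctrl@observables, both@observables) <= 0.95
    pi3k <- run(c(PI3K_PDK1 = 0.1, PI3K_var = 0.1))
    sup <- function(tr, obs) 1 - .peak(tr, obs) / .peak(ctrl, obs)
    details$pi3k_suppression <- vapply(
        c("Akt-pT308", "Akt-pS473", "p70S6K-pT229", "p70S6K-pT389",
          "AMPK-pT172"), function(o) sup(pi3k, o), 1)
    ok["wortmannin_akt_down_ampk_stable"] <-
        sup(pi3k, "Akt-pT308") >= 0.5 && abs(sup(pi3k, "AMPK-pT172")) <= 0.2
    mt1 <- run(c(mTORC1 = 0.25))
    details$mtorc1_25 <- c(s6k = sup(mt1, "p70S6K-pT389"),
                           akt_s473_gain = -sup(mt1, "Akt-pS473"))
    # the S473 gain must exceed numerical wobble to count as feedback release
    ok["mtorc1_kd_nfl_release"] <-
        sup(mt1, "p70S6K-pT389") >= 0.5 &&
        .peak(mt1, "Akt-pS473") > 1.02 * .peak(ctrl, "Akt-pS473")
    ampk5 <- run(c(AMPK = 0.5))
    details$ampk_50 <- c(s6k = sup(ampk5, "p70S6K-pT389"))
    ok["ampk_kd_mtorc1_stable"] <- abs(sup(ampk5, "p70S6K-pT389")) <= 0.2
    mt2 <- run(c(mTORC2 = 0.4))
    details$mtorc2_40 <- vapply(c("Akt-pS473", "p70S6K-pT389", "AMPK-pT172"),
                                function(o) sup(mt2, o), 1)
    ok["mtorc2_kd_specific"] <- sup(mt2, "Akt-pS473") >= 0.3 &&
        abs(sup(mt2, "p70S6K-pT389")) <= 0.2 &&
        abs(sup(mt2, "AMPK-pT172")) <= 0.2
    attr(ok, "details") <- details
    ok
}

#' Synthetic time-course configuration
#'
#' @param timeGrid sampling times in minutes (default the study-style grid
#'   from 0 to 120 min).
#' @param conditions named list of [Protocol-class]; defaults to
#'   amino-acid-only and amino-acid-plus-insulin stimulation.
#' @param nReplicates biological replicates per point (>= 3).
#' @param noiseCV multiplicative noise coefficient of variation (default
#'   0.10, matching the fitting-side error model).
#' @param seed RNG seed.
#' @export
synthConfig <- function(timeGrid = c(0, 1, 3, 5, 10, 15, 20, 30, 45, 60, 90, 120),
                        conditions = list(
                            aa_only = Protocol(aa = 1, insulin = 0),
                            aa_insulin = Protocol(aa = 1, insulin = 1)),
                        nReplicates = 3, noiseCV = 0.10, seed = 1) {
    stopifnot(nReplicates >= 3 || noiseCV == 0, noiseCV >= 0)
    structure(list(timeGrid = timeGrid, conditions = conditions,
                   nReplicates = nReplicates, noiseCV = noiseCV, seed = seed),
              class = "synthConfig")
}

#' Generate a noisy synthetic time-course dataset
#'
#' Simulates the truth model under every condition and perturbs each
#' replicate value multiplicatively, \eqn{y = \hat y (1 + \epsilon)} with
#' \eqn{\epsilon \sim N(0, CV)} truncated at -0.99 so intensities stay
#' positive. Deterministic given \code{config$seed}.
#'
#' @param truth a [ModelSpec-class] carrying the ground-truth parameters.
#' @param config a [synthConfig()].
#' @return a [TimecourseDataset-class].
#' @export
generateTimecourses <- function(truth = truthModel(), config = synthConfig()) {
    set.seed(config$seed)
    out <- list()
    for (cn in names(config$conditions)) {
        tr <- simulateModel(truth, config$conditions[[cn]],
                            times = sort(unique(c(0, config$timeGrid))))
        obs <- tr@observables
        for (ob in colnames(obs)) {
            yhat <- obs[match(config$timeGrid, tr@time), ob]
            for (r in seq_len(config$nReplicates)) {
                eps <- pmax(rnorm(length(yhat), sd = config$noiseCV), -0.99)
                out[[length(out) + 1L]] <- data.frame(
                    observable = ob, condition = cn, time = config$timeGrid,
                    replicate = r, value = yhat * (1 + eps))
            }
        }
    }
    new("TimecourseDataset", data = do.call(rbind, out),
        protocols = config$conditions)
}

#' The five-experiment triple-SILAC design
#'
#' Experiments 1-3 cover 0/5/30 min, experiments 4-5 cover 10/15/30 min;
#' the 30-min point is present in every experiment and serves as the
#' normalization bridge. Channel-to-time assignment is rotated across
#' experiments to emulate label switches.
#'
#' @return data.frame with columns \code{experiment}, \code{channel}
#'   (L/M/H), \code{time} (min).
#' @export
silacDesign <- function() {
    rbind(
        data.frame(experiment = 1, channel = c("L", "M", "H"), time = c(0, 5, 30)),
        data.frame(experiment = 2, channel = c("M", "H", "L"), time = c(0, 5, 30)),
        data.frame(experiment = 3, channel = c("H", "L", "M"), time = c(0, 5, 30)),
        data.frame(experiment = 4, channel = c("L", "M", "H"), time = c(10, 15, 30)),
        data.frame(experiment = 5, channel = c("M", "H", "L"), time = c(10, 15, 30))
    )
}

#' Generate a MaxQuant-style synthetic phosphosite table
#'
#' Baseline site intensities are log-normal; each experiment/channel value
#' gets independent log-normal measurement noise. Regulated sites are
#' multiplied by \code{2^log2FC} in their stimulated (5/10/15 min)
#' channels; the 30-min bridge is left at baseline so cross-experiment
#' normalization stays neutral. Localization probabilities are drawn from a
#' mixture with a sub-0.75 contaminant fraction, and missing values are
#' injected at a configurable rate.
#'
#' @param nSites number of phosphosites.
#' @param nRegulated number of truly regulated sites (the first rows).
#' @param log2FC planted log2 fold change of regulated sites.
#' @param design a [silacDesign()]-style data.frame.
#' @param channelSD log2-scale s.d. of per-channel measurement noise.
#' @param contaminantFrac fraction of sites with localization probability
#'   below the 0.75 gate.
#' @param missingRate probability that any intensity is missing.
#' @param seed RNG seed.
#' @return data.frame in the MaxQuant Phospho (STY)Sites dialect:
#'   \code{Proteins}, \code{Positions within proteins}, \code{Amino acid},
#'   \code{Localization prob} and one \code{Intensity <channel> <exp>}
#'   column per design row.
#' @export
generatePhosphoTable <- function(nSites = 500, nRegulated = 25, log2FC = 1.5,
                                 design = silacDesign(), channelSD = 0.25,
                                 contaminantFrac = 0.10, missingRate = 0.02,
                                 seed = 1) {
    stopifnot(nRegulated <= nSites)
    set.seed(seed)
    base <- 2^rnorm(nSites, mean = 23, sd = 1.5)
    regulated <- seq_len(nSites) <= nRegulated
    nCont <- round(contaminantFrac * nSites)
    contam <- sample(which(!regulated), min(nCont, sum(!regulated)))
    locProb <- runif(nSites, 0.76, 1)
    locProb[contam] <- runif(length(contam), 0.30, 0.75)
    tab <- data.frame(
        Proteins = sprintf("PROT%04d", seq_len(nSites)),
        `Positions within proteins` = sample(20:900, nSites, replace = TRUE),
        `Amino acid` = sample(c("S", "T", "Y"), nSites, replace = TRUE,
                              prob = c(0.8, 0.15, 0.05)),
        `Localization prob` = round(locProb, 3),
        check.names = FALSE)
    for (i in seq_len(nrow(design))) {
        t <- design$time[i]
        fc <- ifelse(regulated & t %in% c(5, 10, 15), 2^log2FC, 1)
        val <- base * fc * 2^rnorm(nSites, sd = channelSD)
        val[runif(nSites) < missingRate] <- NA
        tab[[sprintf("Intensity %s %d", design$channel[i], design$experiment[i])]] <-
            round(val)
    }
    attr(tab, "regulated") <- tab$Proteins[regulated]
    tab
}
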