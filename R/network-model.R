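# Normative reconstruction of the insulin/amino-acid responsive mTOR-AMPK
# network: phospho-state interconversions of the IR, IRS, PI3K, Akt, AMPK,
# TSC1-TSC2, PRAS40, mTORC1, mTORC2 and p70-S6K modules, strict mass-action
# kinetics, one kinetic rate constant per reaction with first/second pairs
# of combinatorial phospho-states constrained to share a parameter.

.PARAM_LOWER <- 1e-06
.PARAM_UPPER <- 1e+04

.speciesMaster <- function(s6kModule) {
    sp <- rbind(
        data.frame(id = c("IR", "IR_pY1146", "IR_refractory"), protein = "IR"),
        data.frame(id = c("IRS", "IRS_p", "IRS_pS636"), protein = "IRS"),
        data.frame(id = c("PI3K_PDK1", "PI3K_PDK1_act"), protein = "PI3K_PDK1"),
        data.frame(id = c("PI3K_var", "PI3K_var_act"), protein = "PI3K_var"),
        data.frame(id = c("Akt", "Akt_pT308", "Akt_pS473", "Akt_pT308_pS473"),
                   protein = "Akt"),
        data.frame(id = c("TSC", "TSC_pT1462", "TSC_pS1387"), protein = "TSC"),
        data.frame(id = c("mTORC1", "mTORC1_act"), protein = "mTORC1"),
        data.frame(id = c("mTORC2", "mTORC2_pS2481"), protein = "mTORC2"),
        data.frame(id = c("AMPK", "AMPK_pT172"), protein = "AMPK"),
        data.frame(id = c("PRAS40", "PRAS40_pT246", "PRAS40_pS183",
                          "PRAS40_pT246_pS183"), protein = "PRAS40"),
        if (s6kModule == "extended")
            data.frame(id = c("p70S6K", "p70S6K_pT229", "p70S6K_pT389",
                              "p70S6K_pT229_pT389"), protein = "p70S6K")
        else
            data.frame(id = c("p70S6K", "p70S6K_pT389"), protein = "p70S6K")
    )
    # every pool total fixed to 1 arbitrary unit; all modified states (and the
    # refractory IR state) start at 0: cells are starved 16 h before t = 0
    base <- c("IR", "IRS", "PI3K_PDK1", "PI3K_var", "Akt", "TSC", "mTORC1",
              "mTORC2", "AMPK", "PRAS40", "p70S6K")
    sp$phospho <- vapply(strsplit(sp$id, "_"), function(p)
        paste(grep("^p[STY]", p, value = TRUE), collapse = ","), "")
    sp$initial <- ifelse(sp$id %in% base, 1, 0)
    rownames(sp) <- NULL
    sp
}

# Full reaction layout in canonical order. `site` tags the amino-acid-input
# rows of each candidate site; the base model keeps only rows with site NA,
# a variant additionally keeps the rows of its extra input sites.
.reactionMaster <- function(s6kModule) {
    r <- function(sub, prod, cat = "", gate = "none", param, site = NA_character_)
        data.frame(substrate = sub, product = prod, catalysts = cat,
                   gate = gate, param = param, site = site)
    aa <- function(site, sub, prod)
        r(sub, prod, gate = "aa", param = paste0("k_aa_", site), site = site)
    s6k_nfl_cat <- if (s6kModule == "extended") "p70S6K_pT229_pT389" else "p70S6K_pT389"
    tab <- rbind(
        # insulin receptor: autophosphorylation, refractory cycle
        r("IR", "IR_pY1146", gate = "insulin", param = "k_IR_phos"),
        r("IR_pY1146", "IR_refractory", param = "k_IR_refrac"),
        r("IR_refractory", "IR", param = "k_IR_recover"),
        # IRS, with the p70-S6K negative feedback on S636
        r("IRS", "IRS_p", cat = "IR_pY1146", param = "k_IRS_phos"),
        aa("IRS_p", "IRS", "IRS_p"),
        r("IRS_p", "IRS", param = "k_IRS_dephos"),
        r("IRS_p", "IRS_pS636", cat = s6k_nfl_cat, param = "k_IRS_S636_phos"),
        r("IRS_pS636", "IRS", param = "k_IRS_S636_dephos"),
        # two PI3K species, both wortmannin-sensitive, both IRS-activated
        r("PI3K_PDK1", "PI3K_PDK1_act", cat = "IRS_p", param = "k_PI3K_PDK1_act"),
        aa("PI3K_PDK1_act", "PI3K_PDK1", "PI3K_PDK1_act"),
        r("PI3K_PDK1_act", "PI3K_PDK1", param = "k_PI3K_PDK1_inact"),
        r("PI3K_var", "PI3K_var_act", cat = "IRS_p", param = "k_PI3K_var_act"),
        aa("PI3K_var_act", "PI3K_var", "PI3K_var_act"),
        r("PI3K_var_act", "PI3K_var", param = "k_PI3K_var_inact"),
        # Akt: full combinatorial T308/S473 states, first/second shared rates
        r("Akt", "Akt_pT308", cat = "PI3K_PDK1_act", param = "k_Akt_T308_phos"),
        r("Akt_pS473", "Akt_pT308_pS473", cat = "PI3K_PDK1_act", param = "k_Akt_T308_phos"),
        aa("Akt_pT308", "Akt", "Akt_pT308"),
        aa("Akt_pT308", "Akt_pS473", "Akt_pT308_pS473"),
        r("Akt", "Akt_pS473", cat = "mTORC2_pS2481", param = "k_Akt_S473_phos"),
        r("Akt_pT308", "Akt_pT308_pS473", cat = "mTORC2_pS2481", param = "k_Akt_S473_phos"),
        aa("Akt_pS473", "Akt", "Akt_pS473"),
        aa("Akt_pS473", "Akt_pT308", "Akt_pT308_pS473"),
        r("Akt_pT308", "Akt", param = "k_Akt_T308_dephos"),
        r("Akt_pT308_pS473", "Akt_pS473", param = "k_Akt_T308_dephos"),
        r("Akt_pS473", "Akt", param = "k_Akt_S473_dephos"),
        r("Akt_pT308_pS473", "Akt_pT308", param = "k_Akt_S473_dephos"),
        # TSC1-TSC2: inhibited by Akt (T1462), activated by AMPK (S1387)
        r("TSC", "TSC_pT1462", cat = "Akt_pT308,Akt_pT308_pS473",
          param = "k_TSC_T1462_phos"),
        aa("TSC_pT1462", "TSC", "TSC_pT1462"),
        r("TSC_pT1462", "TSC", param = "k_TSC_T1462_dephos"),
        r("TSC", "TSC_pS1387", cat = "AMPK_pT172", param = "k_TSC_S1387_phos"),
        aa("TSC_pS1387", "TSC", "TSC_pS1387"),
        r("TSC_pS1387", "TSC", param = "k_TSC_S1387_dephos"),
        # mTORC1: canonical aa input; GAP-active TSC pool inactivates it
        # (AMPK acts by sequestering TSC away from the Akt-inactivatable state)
        r("mTORC1", "mTORC1_act", gate = "aa", param = "k_mTORC1_act"),
        r("mTORC1_act", "mTORC1", cat = "TSC,TSC_pS1387", param = "k_mTORC1_inact"),
        # mTORC2: activated by the PI3K variant
        r("mTORC2", "mTORC2_pS2481", cat = "PI3K_var_act", param = "k_mTORC2_act"),
        aa("mTORC2_pS2481", "mTORC2", "mTORC2_pS2481"),
        r("mTORC2_pS2481", "mTORC2", param = "k_mTORC2_inact"),
        # AMPK: insulin-responsive arm of the IRS-dependent NFL
        aa("AMPK_pT172", "AMPK", "AMPK_pT172"),
        r("AMPK", "AMPK_pT172", cat = "IRS_p", param = "k_AMPK_phos"),
        r("AMPK_pT172", "AMPK", param = "k_AMPK_dephos"),
        # PRAS40: combinatorial T246 (Akt) / S183 (mTORC1) states
        r("PRAS40", "PRAS40_pT246", cat = "Akt_pT308,Akt_pT308_pS473",
          param = "k_PRAS40_T246_phos"),
        r("PRAS40_pS183", "PRAS40_pT246_pS183", cat = "Akt_pT308,Akt_pT308_pS473",
          param = "k_PRAS40_T246_phos"),
        aa("PRAS40_pT246", "PRAS40", "PRAS40_pT246"),
        aa("PRAS40_pT246", "PRAS40_pS183", "PRAS40_pT246_pS183"),
        r("PRAS40", "PRAS40_pS183", cat = "mTORC1_act", param = "k_PRAS40_S183_phos"),
        r("PRAS40_pT246", "PRAS40_pT246_pS183", cat = "mTORC1_act",
          param = "k_PRAS40_S183_phos"),
        aa("PRAS40_pS183", "PRAS40", "PRAS40_pS183"),
        aa("PRAS40_pS183", "PRAS40_pT246", "PRAS40_pT246_pS183"),
        r("PRAS40_pT246", "PRAS40", param = "k_PRAS40_T246_dephos"),
        r("PRAS40_pT246_pS183", "PRAS40_pS183", param = "k_PRAS40_T246_dephos"),
        r("PRAS40_pS183", "PRAS40", param = "k_PRAS40_S183_dephos"),
        r("PRAS40_pT246_pS183", "PRAS40_pT246", param = "k_PRAS40_S183_dephos"),
        # p70-S6K
        if (s6kModule == "extended") rbind(
            r("p70S6K", "p70S6K_pT229", cat = "PI3K_PDK1_act", param = "k_S6K_T229_phos"),
            r("p70S6K_pT389", "p70S6K_pT229_pT389", cat = "PI3K_PDK1_act",
              param = "k_S6K_T229_phos"),
            r("p70S6K", "p70S6K_pT389", cat = "mTORC1_act", param = "k_S6K_T389_phos"),
            r("p70S6K_pT229", "p70S6K_pT229_pT389", cat = "mTORC1_act",
              param = "k_S6K_T389_phos"),
            aa("p70S6K_pT389", "p70S6K", "p70S6K_pT389"),
            aa("p70S6K_pT389", "p70S6K_pT229", "p70S6K_pT229_pT389"),
            r("p70S6K_pT229", "p70S6K", param = "k_S6K_T229_dephos"),
            r("p70S6K_pT229_pT389", "p70S6K_pT389", param = "k_S6K_T229_dephos"),
            r("p70S6K_pT389", "p70S6K", param = "k_S6K_T389_dephos"),
            r("p70S6K_pT229_pT389", "p70S6K_pT229", param = "k_S6K_T389_dephos")
        ) else rbind(
            r("p70S6K", "p70S6K_pT389", cat = "mTORC1_act", param = "k_S6K_T389_phos"),
            aa("p70S6K_pT389", "p70S6K", "p70S6K_pT389"),
            r("p70S6K_pT389", "p70S6K", param = "k_S6K_T389_dephos")
        )
    )
    rownames(tab) <- NULL
    tab
}

.observableMaster <- function(s6kModule) {
    obs <- list(
        `IR-pY1146` = "IR_pY1146",
        `Akt-pT308` = c("Akt_pT308", "Akt_pT308_pS473"),
        `Akt-pS473` = c("Akt_pS473", "Akt_pT308_pS473"),
        `PRAS40-pT246` = c("PRAS40_pT246", "PRAS40_pT246_pS183"),
        `PRAS40-pS183` = c("PRAS40_pS183", "PRAS40_pT246_pS183"),
        `TSC2-pT1462` = "TSC_pT1462",
        `TSC2-pS1387` = "TSC_pS1387",
        `AMPK-pT172` = "AMPK_pT172",
        `mTOR-pS2448` = "mTORC1_act",
        `mTOR-pS2481` = "mTORC2_pS2481",
        `p70S6K-pT389` = if (s6kModule == "extended")
            c("p70S6K_pT389", "p70S6K_pT229_pT389") else "p70S6K_pT389"
    )
    if (s6kModule == "extended")
        obs$`p70S6K-pT229` <- c("p70S6K_pT229", "p70S6K_pT229_pT389")
    obs
}

.assembleModel <- function(s6kModule, extraInputs, values = NULL) {
    master <- .reactionMaster(s6kModule)
    keep <- is.na(master$site) | master$site %in% extraInputs
    rx <- master[keep, , drop = FALSE]
    rx <- cbind(id = paste0("R", seq_len(nrow(rx))), rx[, setdiff(names(rx), "site")])
    rownames(rx) <- NULL
    pid <- unique(rx$param)
    pa <- data.frame(id = pid, value = 0.1,
                     lower = .PARAM_LOWER, upper = .PARAM_UPPER)
    if (!is.null(values)) {
        i <- match(names(values), pa$id)
        pa$value[i[!is.na(i)]] <- unname(values)[!is.na(i)]
    }
    new("ModelSpec", species = .speciesMaster(s6kModule), reactions = rx,
        parameters = pa, observables = .observableMaster(s6kModule),
        inputSites = sort(extraInputs), s6kModule = s6kModule)
}

#' Build the canonical single-amino-acid-input base model
#'
#' Constructs the mTOR-AMPK network with the amino-acid stimulus gated only
#' through mTORC1 (the canonical Rag-GTPase-mediated input). The extended
#' p70-S6K module tracks the combinatorial T229/T389 phospho-states (31
#' species once the three extra amino-acid inputs of the quadruple variant
#' are added, 12 observables); the simple module collapses p70-S6K to two
#' states (11 observables).
#'
#' @param s6kModule \code{"extended"} (default) or \code{"simple"}.
#' @return a [ModelSpec-class].
#' @examples
#' m <- buildBaseModel("extended")
#' nrow(speciesTable(m))       # 31
#' length(observableMap(m))    # 12
#' @export
buildBaseModel <- function(s6kModule = c("extended", "simple")) {
    s6kModule <- match.arg(s6kModule)
    .assembleModel(s6kModule, character(0))
}

#' Candidate sites for additional amino-acid inputs
#'
#' The activatable phospho/active states at which a further amino-acid input
#' can be attached, besides the canonical input on mTORC1. The insulin
#' receptor states are excluded (IR is the insulin sensor; amino-acid-only
#' protocols have insulin = 0), as is the inhibitory IRS_pS636 state (an
#' "input" there would be a removal, not an activation).
#'
#' @param model a base [ModelSpec-class].
#' @return character vector of 12 site ids.
#' @export
candidateSites <- function(model) {
    c("IRS_p", "PI3K_PDK1_act", "PI3K_var_act", "Akt_pT308", "Akt_pS473",
      "TSC_pT1462", "TSC_pS1387", "AMPK_pT172", "mTORC2_pS2481",
      "PRAS40_pT246", "PRAS40_pS183", "p70S6K_pT389")
}

#' Add amino-acid inputs to a base model
#'
#' For each requested site one amino-acid-gated phosphorylation reaction is
#' added per precursor state (combinatorial sites such as Akt_pT308 gain two
#' reactions, from the unmodified and the singly-modified precursor), all
#' sharing a single new rate parameter \code{k_aa_<site>}; the parameter
#' count therefore grows by exactly one per added site.
#'
#' @param base a base [ModelSpec-class].
#' @param extraInputs character vector of candidate site ids (subset of
#'   [candidateSites()]).
#' @return a [ModelSpec-class] variant; parameter values of the base model
#'   are preserved, new input parameters start at 0.1.
#' @examples
#' m <- buildVariant(buildBaseModel("extended"),
#'                   c("IRS_p", "AMPK_pT172", "mTORC2_pS2481"))
#' nrow(reactionTable(m))   # 48
#' @export
buildVariant <- function(base, extraInputs = character(0)) {
    stopifnot(is(base, "ModelSpec"))
    extraInputs <- unique(c(base@inputSites, extraInputs))
    unknown <- setdiff(extraInputs, candidateSites(base))
    if (length(unknown))
        stop("unknown candidate site(s): ", paste(unknown, collapse = ", "))
    .assembleModel(base@s6kModule, extraInputs,
                   values = setNames(base@parameters$value, base@parameters$id))
}
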