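# SBML Level 2 Version 4 exchange. Kinetic laws are explicit mass-action
# expressions k * gate * (sum of catalysts) * substrate; the two stimulus
# step functions appear as the global parameters stim_aa / stim_insulin and
# observables as non-constant global parameters defined by assignment rules.

.MATHML <- "http://www.w3.org/1998/Math/MathML"
.SBML_NS <- "http://www.sbml.org/sbml/level2/version4"

.ci <- function(parent, id) xml2::xml_add_child(parent, "ci", id, ns = character())

.mathApplyTimes <- function(math, rx) {
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    .ci(ap, rx$param)
    if (rx$gate != "none") .ci(ap, paste0("stim_", rx$gate))
    cats <- strsplit(rx$catalysts, ",")[[1]]
    cats <- cats[nzchar(cats)]
    if (length(cats) > 1) {
        pl <- xml2::xml_add_child(ap, "apply")
        xml2::xml_add_child(pl, "plus")
        for (cc in cats) .ci(pl, cc)
    } else if (length(cats) == 1) .ci(ap, cats)
    .ci(ap, rx$substrate)
    invisible(ap)
}

.numFmt <- function(x) formatC(x, format = "g", digits = 15)

#' Export a model to SBML Level 2 Version 4
#'
#' Species carry their protein pool in the \code{name} attribute; catalysts
#' are listed as modifiers; the kinetic law spells out the mass-action rate
#' with explicit stimulus-gate and catalyst-sum factors; observables are
#' exported as assignment-rule parameters \code{obs_*}.
#'
#' @param model a [ModelSpec-class].
#' @param file path to write; \code{NULL} returns the \code{xml_document}.
#' @return the file path (invisibly) or an \code{xml2::xml_document}.
#' @export
exportSBML <- function(model, file = NULL) {
    stopifnot(is(model, "ModelSpec"))
    validObject(model)
    doc <- xml2::xml_new_root("sbml", xmlns = .SBML_NS,
                              level = "2", version = "4")
    mod <- xml2::xml_add_child(doc, "model",
        id = paste0("mTOR_AMPK_", model@s6kModule,
                    if (length(model@inputSites))
                        paste0("_", length(model@inputSites) + 1L, "aa")
                    else "_1aa"))
    lc <- xml2::xml_add_child(mod, "listOfCompartments")
    xml2::xml_add_child(lc, "compartment", id = "cell", size = "1")
    ls <- xml2::xml_add_child(mod, "listOfSpecies")
    for (i in seq_len(nrow(model@species)))
        xml2::xml_add_child(ls, "species",
            id = model@species$id[i], name = model@species$protein[i],
            compartment = "cell",
            initialAmount = .numFmt(model@species$initial[i]))
    lp <- xml2::xml_add_child(mod, "listOfParameters")
    for (g in c("aa", "insulin"))
        xml2::xml_add_child(lp, "parameter", id = paste0("stim_", g),
                            value = "1", constant = "true")
    for (i in seq_len(nrow(model@parameters)))
        xml2::xml_add_child(lp, "parameter", id = model@parameters$id[i],
                            value = .numFmt(model@parameters$value[i]),
                            constant = "true")
    for (ob in names(model@observables))
        xml2::xml_add_child(lp, "parameter", id = .obsParamId(ob),
                            value = "0", constant = "false")
    lr <- xml2::xml_add_child(mod, "listOfRules")
    for (ob in names(model@observables)) {
        rule <- xml2::xml_add_child(lr, "assignmentRule",
                                    variable = .obsParamId(ob))
        math <- xml2::xml_add_child(rule, "math", xmlns = .MATHML)
        ids <- model@observables[[ob]]
        if (length(ids) > 1) {
            ap <- xml2::xml_add_child(math, "apply")
            xml2::xml_add_child(ap, "plus")
            for (s in ids) .ci(ap, s)
        } else .ci(math, ids)
    }
    lrx <- xml2::xml_add_child(mod, "listOfReactions")
    for (i in seq_len(nrow(model@reactions))) {
        rx <- model@reactions[i, ]
        bad <- setdiff(c(rx$substrate, rx$product), model@species$id)
        if (length(bad))
            stop("cannot serialize reaction ", rx$id, ": unknown species ", bad[1])
        xr <- xml2::xml_add_child(lrx, "reaction", id = rx$id, reversible = "false")
        re <- xml2::xml_add_child(xr, "listOfReactants")
        xml2::xml_add_child(re, "speciesReference", species = rx$substrate)
        pr <- xml2::xml_add_child(xr, "listOfProducts")
        xml2::xml_add_child(pr, "speciesReference", species = rx$product)
        cats <- strsplit(rx$catalysts, ",")[[1]]
        cats <- cats[nzchar(cats)]
        if (length(cats)) {
            lm <- xml2::xml_add_child(xr, "listOfModifiers")
            for (cc in cats)
                xml2::xml_add_child(lm, "modifierSpeciesReference", species = cc)
        }
        kl <- xml2::xml_add_child(xr, "kineticLaw")
        math <- xml2::xml_add_child(kl, "math", xmlns = .MATHML)
        .mathApplyTimes(math, rx)
    }
    if (is.null(file)) return(doc)
    xml2::write_xml(doc, file)
    invisible(file)
}

.obsParamId <- function(ob) paste0("obs_", gsub("-", "_", ob))

#' Import a model from SBML Level 2 Version 4
#'
#' Reads documents written by [exportSBML()] (protein pools in species
#' names, \code{stim_*} gate parameters, \code{obs_*} assignment rules).
#'
#' @param file path or \code{xml2::xml_document}.
#' @return a [ModelSpec-class].
#' @export
importSBML <- function(file) {
    doc <- if (inherits(file, "xml_document")) file else xml2::read_xml(file)
    ns <- c(s = .SBML_NS, m = .MATHML)
    spn <- xml2::xml_find_all(doc, "//s:listOfSpecies/s:species", ns)
    sp <- data.frame(
        id = xml2::xml_attr(spn, "id"),
        protein = xml2::xml_attr(spn, "name"),
        initial = as.numeric(xml2::xml_attr(spn, "initialAmount")))
    sp$phospho <- vapply(strsplit(sp$id, "_"), function(p)
        paste(grep("^p[STY]", p, value = TRUE), collapse = ","), "")
    sp <- sp[, c("id", "protein", "phospho", "initial")]
    pn <- xml2::xml_find_all(doc, "//s:listOfParameters/s:parameter", ns)
    pid <- xml2::xml_attr(pn, "id")
    pval <- as.numeric(xml2::xml_attr(pn, "value"))
    kin <- !grepl("^(stim_|obs_)", pid)
    pa <- data.frame(id = pid[kin], value = pval[kin],
                     lower = .PARAM_LOWER, upper = .PARAM_UPPER)
    rules <- xml2::xml_find_all(doc, "//s:listOfRules/s:assignmentRule", ns)
    obs <- lapply(rules, function(r)
        xml2::xml_text(xml2::xml_find_all(r, ".//m:ci", ns)))
    obsNames <- sub("^obs_", "", xml2::xml_attr(rules, "variable"))
    # readout names use '-' before the phosphosite / complex suffix
    names(obs) <- vapply(obsNames, function(x)
        sub("_", "-", x), "", USE.NAMES = FALSE)
    rxn <- xml2::xml_find_all(doc, "//s:listOfReactions/s:reaction", ns)
    rx <- do.call(rbind, lapply(rxn, function(x) {
        cis <- xml2::xml_text(xml2::xml_find_all(x, ".//s:kineticLaw//m:ci", ns))
        data.frame(
            id = xml2::xml_attr(x, "id"),
            substrate = xml2::xml_attr(xml2::xml_find_first(
                x, ".//s:listOfReactants/s:speciesReference", ns), "species"),
            product = xml2::xml_attr(xml2::xml_find_first(
                x, ".//s:listOfProducts/s:speciesReference", ns), "species"),
            catalysts = paste(xml2::xml_attr(xml2::xml_find_all(
                x, ".//s:listOfModifiers/s:modifierSpeciesReference", ns),
                "species"), collapse = ","),
            gate = if ("stim_aa" %in% cis) "aa"
                   else if ("stim_insulin" %in% cis) "insulin" else "none",
            param = cis[cis %in% pid[kin]][1])
    }))
    inputs <- sort(sub("^k_aa_", "", grep("^k_aa_", rx$param, value = TRUE)))
    new("ModelSpec", species = sp, reactions = rx, parameters = pa,
        observables = obs,
        inputSites = inputs,
        s6kModule = if ("p70S6K_pT229" %in% sp$id) "extended" else "simple")
}
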