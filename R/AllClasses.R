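#' @import methods
#' @importFrom stats median rnorm runif sd setNames coef lm t.test qchisq
#' @importFrom utils combn read.delim write.table head
NULL

#' ModelSpec: a mass-action phospho-state model of the mTOR-AMPK network
#'
#' Container for one model variant: species (phospho-states grouped into
#' protein pools), mass-action state-interconversion reactions with optional
#' catalyst pools and stimulus gates, kinetic parameters with box bounds,
#' and observables mapping readouts to sums of species.
#'
#' @slot species data.frame with columns \code{id}, \code{protein},
#'   \code{phospho} (comma-separated site marks, \code{""} for the
#'   unmodified state), \code{initial}.
#' @slot reactions data.frame with columns \code{id}, \code{substrate},
#'   \code{product}, \code{catalysts} (comma-separated species ids, may be
#'   empty), \code{gate} (one of \code{"none"}, \code{"aa"},
#'   \code{"insulin"}) and \code{param}.
#' @slot parameters data.frame with columns \code{id}, \code{value},
#'   \code{lower}, \code{upper}. Distinct reactions may share a parameter
#'   (the first/second constraint for combinatorial phospho-states).
#' @slot observables named list; each element a character vector of species
#'   ids whose amounts are summed to give the readout.
#' @slot inputSites character; extra amino-acid input sites beyond the
#'   canonical gate on mTORC1.
#' @slot s6kModule \code{"simple"} or \code{"extended"} p70-S6K design.
#'
#' @seealso [buildBaseModel()], [buildVariant()], [exportSBML()]
#' @export
setClass("ModelSpec",
    representation(
        species = "data.frame",
        reactions = "data.frame",
        parameters = "data.frame",
        observables = "list",
        inputSites = "character",
        s6kModule = "character"
    )
)

setValidity("ModelSpec", function(object) {
    sp <- object@species
    rx <- object@reactions
    pa <- object@parameters
    msg <- character(0)
    if (anyDuplicated(sp$id)) msg <- c(msg, "duplicated species ids")
    if (any(sp$initial < 0)) msg <- c(msg, "negative initial amount")
    phos <- sp$phospho != "" | sp$id == "IR_refractory"
    if (any(sp$initial[phos] != 0))
        msg <- c(msg, "modified states must start at amount 0")
    pool <- setNames(sp$protein, sp$id)
    bad <- rx$id[is.na(pool[rx$substrate]) | is.na(pool[rx$product])]
    if (length(bad))
        msg <- c(msg, paste("unknown substrate/product in", bad[1]))
    same <- pool[rx$substrate] == pool[rx$product]
    if (!all(same, na.rm = TRUE))
        msg <- c(msg, "substrate and product must share a protein pool")
    cats <- unlist(strsplit(rx$catalysts[rx$catalysts != ""], ","))
    if (!all(cats %in% sp$id)) {
        off <- rx$id[vapply(strsplit(rx$catalysts, ","), function(cc)
            any(nzchar(cc) & !(cc %in% sp$id)), logical(1))]
        msg <- c(msg, paste("undefined catalyst in reaction", off[1]))
    }
    if (!all(rx$gate %in% c("none", "aa", "insulin")))
        msg <- c(msg, "gate must be none/aa/insulin")
    if (!all(rx$param %in% pa$id)) msg <- c(msg, "reaction with unknown parameter")
    if (!all(pa$value >= pa$lower & pa$value <= pa$upper))
        msg <- c(msg, "parameter value outside bounds")
    obs <- object@observables
    if (length(obs)) {
        if (any(!nzchar(names(obs)))) msg <- c(msg, "unnamed observable")
        if (any(vapply(obs, length, 1L) == 0L)) msg <- c(msg, "empty observable")
        if (!all(unlist(obs) %in% sp$id)) msg <- c(msg, "observable maps to unknown species")
    }
    if (length(msg)) msg else TRUE
})

#' Protocol: one simulated stimulation/perturbation experiment
#'
#' Stimulus step levels (amino acids, insulin; unitless, switched on at
#' t = 0 after 16 h starvation so all modified states start at 0), graded
#' protein-pool perturbations applied to the initial pool totals, and the
#' output time grid.
#'
#' @slot duration numeric, minutes (default 120).
#' @slot outputStep numeric, minutes between output points (default 0.1).
#' @slot aa amino-acid step level in [0, 1].
#' @slot insulin insulin step level in [0, 1].
#' @slot perturbations named numeric; protein pool -> residual fraction in
#'   (0, 1]; 1 is the unperturbed control.
#' @export
setClass("Protocol",
    representation(duration = "numeric", outputStep = "numeric",
        aa = "numeric", insulin = "numeric", perturbations = "numeric")
)

setValidity("Protocol", function(object) {
    msg <- character(0)
    if (object@duration <= 0) msg <- c(msg, "duration must be positive")
    if (object@outputStep <= 0) msg <- c(msg, "outputStep must be positive")
    for (s in c("aa", "insulin")) {
        v <- slot(object, s)
        if (length(v) != 1 || v < 0 || v > 1)
            msg <- c(msg, paste(s, "level must be a scalar in [0, 1]"))
    }
    p <- object@perturbations
    if (length(p)) {
        if (is.null(names(p)) || any(!nzchar(names(p))))
            msg <- c(msg, "perturbations must be named by protein pool")
        if (any(p <= 0 | p > 1))
            msg <- c(msg, "residual fractions must lie in (0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn Protocol-class constructor.
#' @param duration,outputStep,aa,insulin,perturbations see slots.
#' @export
Protocol <- function(duration = 120, outputStep = 0.1, aa = 1, insulin = 0,
                     perturbations = numeric(0)) {
    new("Protocol", duration = duration, outputStep = outputStep,
        aa = aa, insulin = insulin,
        perturbations = unlist(perturbations))
}

#' Trajectory: simulated amounts and observable time courses
#'
#' @slot time numeric grid, minutes.
#' @slot amounts matrix time x species.
#' @slot observables matrix time x observable.
#' @export
setClass("Trajectory",
    representation(time = "numeric", amounts = "matrix", observables = "matrix"))

#' TimecourseDataset: readout x condition x time x replicate values
#'
#' Long-format fitting target emulating quantified immunoblot time courses,
#' together with the stimulation protocol of every condition.
#'
#' @slot data data.frame with columns \code{observable}, \code{condition},
#'   \code{time}, \code{replicate}, \code{value}.
#' @slot protocols named list of [Protocol-class], one per condition id.
#' @export
setClass("TimecourseDataset",
    representation(data = "data.frame", protocols = "list"))

setValidity("TimecourseDataset", function(object) {
    d <- object@data
    need <- c("observable", "condition", "time", "replicate", "value")
    if (!all(need %in% names(d))) return("missing dataset columns")
    if (any(d$value < 0)) return("negative readout value")
    if (!all(unique(d$condition) %in% names(object@protocols)))
        return("condition without a protocol")
    TRUE
})

#' FitResult / FitEnsemble: multi-start estimation output
#'
#' @slot results data.frame, one row per start: \code{start}, \code{chi2},
#'   \code{aic}, \code{converged}, \code{iterations}, then one column per
#'   fitted parameter (linear scale).
#' @slot best named numeric, parameters of the best (lowest chi2) start.
#' @slot chi2 numeric, best chi-square.
#' @slot aic numeric, best AIC (chi2 + 2 k).
#' @slot nData integer, number of residuals.
#' @slot kParams integer, number of fitted (free, distinct) parameters.
#' @slot free character, the fitted parameter ids.
#' @export
setClass("FitEnsemble",
    representation(results = "data.frame", best = "numeric", chi2 = "numeric",
        aic = "numeric", nData = "integer", kParams = "integer",
        free = "character"))

#' SelectionResult: the stagewise amino-acid-input selection table
#'
#' @slot table data.frame with columns \code{stage}, \code{inputs}
#'   (comma-separated extra input sites; empty for the single-input model),
#'   \code{chi2}, \code{aic}, \code{accepted}.
#' @slot survivors list of character vectors, accepted input sets per stage.
#' @slot best character, extra input sites of the selected model.
#' @slot bestAIC numeric.
#' @slot nEvaluated integer, total model variants fitted.
#' @export
setClass("SelectionResult",
    representation(table = "data.frame", survivors = "list",
        best = "character", bestAIC = "numeric", nEvaluated = "integer"))

setMethod("show", "ModelSpec", function(object) {
    cat("ModelSpec:", nrow(object@species), "species,",
        nrow(object@reactions), "mass-action reactions,",
        nrow(object@parameters), "parameters,",
        length(object@observables), "observables\n")
    cat("  p70-S6K module:", object@s6kModule, "\n")
    cat("  aa inputs: mTORC1",
        if (length(object@inputSites)) paste("+", paste(object@inputSites, collapse = ", "))
        else "(canonical only)", "\n")
})

setMethod("show", "Trajectory", function(object) {
    cat("Trajectory:", length(object@time), "time points,",
        ncol(object@amounts), "species,", ncol(object@observables),
        "observables over", max(object@time), "min\n")
})

setMethod("show", "TimecourseDataset", function(object) {
    d <- object@data
    cat("TimecourseDataset:", nrow(d), "values |",
        length(unique(d$observable)), "observables x",
        length(unique(d$condition)), "conditions x",
        length(unique(d$time)), "times x",
        max(d$replicate), "replicates\n")
})

setMethod("show", "FitEnsemble", function(object) {
    cat("FitEnsemble:", nrow(object@results), "starts;",
        "best chi2 =", signif(object@chi2, 5),
        "| AIC =", signif(object@aic, 5),
        "| k =", object@kParams, "| n =", object@nData, "\n")
})

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult:", object@nEvaluated, "models evaluated over",
        length(unique(object@table$stage)), "stages\n")
    cat("  selected extra aa inputs: {",
        paste(object@best, collapse = ", "), "} AIC =",
        signif(object@bestAIC, 6), "\n")
})

# ---- accessor generics ----

#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))
#' @export
setGeneric("reactionTable", function(x) standardGeneric("reactionTable"))
#' @export
setGeneric("parameterTable", function(x) standardGeneric("parameterTable"))
#' @export
setGeneric("observableMap", function(x) standardGeneric("observableMap"))
#' @export
setGeneric("inputSites", function(x) standardGeneric("inputSites"))
#' @export
setGeneric("s6kModule", function(x) standardGeneric("s6kModule"))
#' @export
setGeneric("setParameters", function(x, values) standardGeneric("setParameters"))
#' @export
setGeneric("observableValues", function(x) standardGeneric("observableValues"))
#' @export
setGeneric("datasetTable", function(x) standardGeneric("datasetTable"))
#' @export
setGeneric("protocols", function(x) standardGeneric("protocols"))
#' @export
setGeneric("bestParameters", function(x) standardGeneric("bestParameters"))
#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' @describeIn ModelSpec-class species table accessor.
#' @param x a \code{ModelSpec}.
#' @export
setMethod("speciesTable", "ModelSpec", function(x) x@species)
#' @describeIn ModelSpec-class reaction table accessor.
#' @export
setMethod("reactionTable", "ModelSpec", function(x) x@reactions)
#' @describeIn ModelSpec-class parameter table accessor.
#' @export
setMethod("parameterTable", "ModelSpec", function(x) x@parameters)
#' @describeIn ModelSpec-class observable map accessor.
#' @export
setMethod("observableMap", "ModelSpec", function(x) x@observables)
#' @describeIn ModelSpec-class extra amino-acid input sites.
#' @export
setMethod("inputSites", "ModelSpec", function(x) x@inputSites)
#' @describeIn ModelSpec-class p70-S6K module flavour.
#' @export
setMethod("s6kModule", "ModelSpec", function(x) x@s6kModule)

#' @describeIn ModelSpec-class replace parameter values (named numeric,
#'   partial updates allowed); values are checked against the box bounds.
#' @param values named numeric vector of parameter values.
#' @export
setMethod("setParameters", "ModelSpec", function(x, values) {
    stopifnot(is.numeric(values), !is.null(names(values)))
    unknown <- setdiff(names(values), x@parameters$id)
    if (length(unknown))
        stop("unknown parameter id(s): ", paste(unknown, collapse = ", "))
    i <- match(names(values), x@parameters$id)
    x@parameters$value[i] <- unname(values)
    validObject(x)
    x
})

#' @describeIn Trajectory-class observable matrix (time x observable).
#' @param x a \code{Trajectory}.
#' @export
setMethod("observableValues", "Trajectory", function(x) x@observables)

#' @describeIn TimecourseDataset-class long-format data accessor.
#' @param x a \code{TimecourseDataset}.
#' @export
setMethod("datasetTable", "TimecourseDataset", function(x) x@data)
#' @describeIn TimecourseDataset-class per-condition protocols.
#' @export
setMethod("protocols", "TimecourseDataset", function(x) x@protocols)

#' @describeIn FitEnsemble-class best-fit parameters (linear scale).
#' @param x a \code{FitEnsemble}.
#' @export
setMethod("bestParameters", "FitEnsemble", function(x) x@best)

#' @describeIn SelectionResult-class full per-stage table accessor.
#' @param x a \code{SelectionResult}.
#' @export
setMethod("selectionTable", "SelectionResult", function(x) x@table)
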