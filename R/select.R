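# Stagewise amino-acid-input structure selection: enumerate candidate input
# sets, fit each variant, accept on >= 1% AIC improvement over the best
# model of the previous stage.

#' AIC improvement acceptance rule
#'
#' A model with n inputs improves on the best model with n-1 inputs when
#' its AIC is at least \code{improvementFraction} (default 1\%) less:
#' accepted iff \eqn{AIC_{new} \le (1 - f) \cdot AIC_{prev}}. The 1\%
#' margin guards against spurious improvements from numerical
#' approximation in parameter estimation.
#'
#' @param aicNew AIC of the candidate model.
#' @param aicPrevBest best AIC of the previous stage.
#' @param improvementFraction required relative improvement (default 0.01).
#' @return logical.
#' @export
acceptRule <- function(aicNew, aicPrevBest, improvementFraction = 0.01) {
    stopifnot(is.finite(aicNew), is.finite(aicPrevBest),
              improvementFraction > 0, improvementFraction <= 1)
    aicNew <= (1 - improvementFraction) * aicPrevBest
}

#' Enumerate candidate input sets for one selection stage
#'
#' Stage 2 attaches a second input at every candidate site; stage 3 forms
#' all unordered pairs of the components whose stage-2 model was accepted;
#' stage 4 forms all unions of two accepted stage-3 sets whose union has
#' exactly three components, deduplicated.
#'
#' @param stage 2, 3 or 4.
#' @param survivorsPrev list of accepted input sets (character vectors) of
#'   the previous stage; ignored for stage 2.
#' @param allSites full candidate site list (stage 2).
#' @return list of character vectors (each sorted); empty if the previous
#'   stage had no survivors.
#' @export
enumerateCandidates <- function(stage, survivorsPrev = list(), allSites) {
    stopifnot(stage %in% 2:4)
    if (stage == 2)
        return(lapply(allSites, function(s) s))
    if (!length(survivorsPrev)) return(list())
    if (stage == 3) {
        comps <- sort(unique(unlist(survivorsPrev)))
        if (length(comps) < 2) return(list())
        return(apply(combn(comps, 2), 2, sort, simplify = FALSE))
    }
    # stage 4: three-component unions of pairs of accepted triples
    if (length(survivorsPrev) < 2) return(list())
    pairs <- combn(length(survivorsPrev), 2, simplify = FALSE)
    sets <- lapply(pairs, function(ij)
        sort(unique(c(survivorsPrev[[ij[1]]], survivorsPrev[[ij[2]]]))))
    sets <- sets[vapply(sets, length, 1L) == 3L]
    unique(sets)
}

#' Selection configuration
#'
#' @param improvementFraction required relative AIC improvement (default 0.01).
#' @param maxStage deepest stage (default 4 = quadruple input).
#' @param fit a [fitConfig()] used for every variant fit.
#' @param candidates candidate site list; defaults to [candidateSites()].
#' @param fixed parameter ids held at the base model's values during
#'   fitting (default: the independently calibrated insulin receptor
#'   module).
#' @export
selectionConfig <- function(improvementFraction = 0.01, maxStage = 4,
                            fit = fitConfig(), candidates = NULL,
                            fixed = c("k_IR_phos", "k_IR_refrac",
                                      "k_IR_recover")) {
    stopifnot(improvementFraction > 0, improvementFraction <= 1)
    structure(list(improvementFraction = improvementFraction,
                   maxStage = maxStage, fit = fit, candidates = candidates,
                   fixed = fixed),
              class = "selectionConfig")
}

#' Stagewise amino-acid-input selection
#'
#' Fits the single-input base model, then iterates enumerate / fit / accept
#' over stages until no candidate achieves the required AIC improvement or
#' \code{maxStage} is reached. Every variant is fitted twice: by the
#' multi-start scheme from the base model's parameter values (the bounds
#' midpoint for an uncalibrated base), and by one warm start carried from
#' its best-fitting accepted parent set (shared parameters carried over,
#' each new input rate at the midpoint), whichever ends lower. The warm
#' start makes a nested candidate at least as good as its parent; the cold
#' multi-start keeps candidates from being trapped in the parent's
#' compensation regime. The selected model is the minimum-AIC member of
#' the last stage with acceptances (ties broken toward fewer inputs, then
#' lexicographically).
#'
#' @param baseModel a single-input [ModelSpec-class]; its parameter values
#'   are the stage-1 start point (typically the simple p70-S6K module).
#' @param dataset a [TimecourseDataset-class] covering amino-acid-only and
#'   amino-acid-plus-insulin conditions.
#' @param config a [selectionConfig()].
#' @return a [SelectionResult-class].
#' @export
runSelection <- function(baseModel, dataset, config = selectionConfig()) {
    stopifnot(is(baseModel, "ModelSpec"))
    sites <- if (is.null(config$candidates)) candidateSites(baseModel)
             else config$candidates
    freeOf <- function(model)
        setdiff(model@parameters$id, config$fixed)
    fitOne <- function(model) fitModel(model, dataset, config$fit,
                                       free = freeOf(model))
    warmCfg <- config$fit
    warmCfg$nStarts <- 1
    polishCfg <- warmCfg
    polishCfg$maxIter <- 2 * config$fit$maxIter
    # empty-name list elements cannot be retrieved by name; the base model
    # needs a non-empty sentinel key
    key <- function(set) if (!length(set)) "(base)"
        else paste(sort(set), collapse = ",")
    fitted <- list()   # per input-set best fit (params + aic), for warm starts
    tab <- list()
    base <- fitOne(baseModel)
    fitted[[key(character(0))]] <- list(aic = base@aic,
                                        params = bestParameters(base))
    tab[[1]] <- data.frame(stage = 1L, inputs = "", chi2 = base@chi2,
                           aic = base@aic, accepted = TRUE)
    survivors <- list(character(0))
    bestPrevAIC <- base@aic
    nEval <- 1L
    stage <- 2L
    finalStage <- 1L
    while (stage <= config$maxStage) {
        cand <- enumerateCandidates(stage, survivors, sites)
        if (!length(cand)) break
        fits <- vector("list", length(cand))
        for (i in seq_along(cand)) {
            m <- buildVariant(baseModel, cand[[i]])
            f <- tryCatch(fitOne(m), error = function(e) NULL)
            sub <- survivors[vapply(survivors, function(s)
                all(s %in% cand[[i]]), TRUE)]
            if (!length(sub)) sub <- survivors
            parents <- Filter(Negate(is.null), fitted[vapply(sub, key, "")])
            # two-phase warm start from every accepted parent subset: first
            # let the new input rate(s) find their scale against the parent
            # optimum, then refit everything; different parents unlock
            # different basins (a pair is often reachable from one parent's
            # optimum but trapped in the other's compensation regime)
            for (par in parents) {
                init <- setNames(m@parameters$value, m@parameters$id)
                init[names(par$params)[names(par$params) %in% names(init)]] <-
                    par$params[names(par$params) %in% names(init)]
                newPar <- intersect(setdiff(names(init), names(par$params)),
                                    freeOf(m))
                fw <- tryCatch({
                    mw <- setParameters(m, init)  # parent optimum as background
                    if (length(newPar)) {
                        f1 <- fitModel(mw, dataset, warmCfg, free = newPar)
                        mw <- setParameters(mw, bestParameters(f1)[newPar])
                    }
                    fitModel(mw, dataset, warmCfg, free = freeOf(m))
                }, error = function(e) NULL)
                if (!is.null(fw) && (is.null(f) || fw@chi2 < f@chi2)) f <- fw
            }
            fits[[i]] <- f
        }
        # polish the stage finalists: continue the best few fits from their
        # own optimum so acceptance and ranking compare converged models,
        # not screening-quality ones
        ord <- order(vapply(fits, function(f)
            if (is.null(f)) Inf else f@chi2, 1))
        for (i in head(ord, 5)) {
            if (is.null(fits[[i]])) next
            mp <- setParameters(buildVariant(baseModel, cand[[i]]),
                                bestParameters(fits[[i]]))
            fp <- tryCatch(fitModel(mp, dataset, polishCfg,
                                    free = freeOf(mp)),
                           error = function(e) NULL)
            if (!is.null(fp) && fp@chi2 < fits[[i]]@chi2) fits[[i]] <- fp
        }
        for (i in seq_along(cand))
            if (!is.null(fits[[i]]))
                fitted[[key(cand[[i]])]] <- list(aic = fits[[i]]@aic,
                                                 params = bestParameters(fits[[i]]))
        ok <- !vapply(fits, is.null, TRUE)
        nEval <- nEval + length(cand)
        aics <- vapply(fits, function(f) if (is.null(f)) Inf else f@aic, 1)
        chis <- vapply(fits, function(f) if (is.null(f)) Inf else f@chi2, 1)
        acc <- is.finite(aics) &
            vapply(aics, function(a) is.finite(a) &&
                acceptRule(a, bestPrevAIC, config$improvementFraction), TRUE)
        tab[[stage]] <- data.frame(stage = stage,
            inputs = vapply(cand, paste, "", collapse = ","),
            chi2 = chis, aic = aics, accepted = acc)
        if (!any(acc)) break
        survivors <- cand[acc]
        finalStage <- stage
        bestPrevAIC <- min(aics)
        stage <- stage + 1L
    }
    table <- do.call(rbind, tab)
    rownames(table) <- NULL
    fin <- table[table$stage == finalStage & table$accepted, , drop = FALSE]
    fin <- fin[order(fin$aic,
                     vapply(strsplit(fin$inputs, ","), length, 1L),
                     fin$inputs), , drop = FALSE]
    best <- strsplit(fin$inputs[1], ",")[[1]]
    new("SelectionResult", table = table,
        survivors = split(table$inputs[table$accepted],
                          table$stage[table$accepted]) |>
            lapply(function(x) lapply(strsplit(x, ","), sort)),
        best = sort(best), bestAIC = fin$aic[1],
        nEvaluated = nEval)
}

#' Write a selection report
#'
#' Tab-separated stage table (stage, inputs, chi2, aic, accepted) mirroring
#' the stagewise single/double/triple/quadruple presentation, plus a JSON
#' summary.
#'
#' @param result a [SelectionResult-class].
#' @param file TSV path; a \code{.json} summary is written next to it.
#' @export
writeSelectionReport <- function(result, file) {
    write.table(result@table, file, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(list(
        best = result@best, bestAIC = result@bestAIC,
        nEvaluated = result@nEvaluated),
        sub("\\.tsv$", ".json", file), auto_unbox = TRUE, digits = NA)
    invisible(file)
}
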