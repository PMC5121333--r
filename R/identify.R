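# Identifiability analysis: ensemble-correlation flags over the best fits
# (mean-optimal-transformation style) and profile likelihoods with
# re-optimization of nuisance parameters.

#' Ensemble-correlation (MOTA-style) non-identifiability flags
#'
#' Over the best fraction of a multi-start ensemble, regresses each
#' parameter's log10 value on log10 values of tuples of other parameters
#' (greedy forward selection up to \code{maxTuple} regressors). A
#' parameter is flagged as part of a non-identifiable tuple when the
#' regression r-squared exceeds \code{r2Threshold} and the parameter's
#' coefficient of variation across the ensemble exceeds \code{cvThreshold}
#' (the CV gate keeps tightly determined parameters from being flagged on
#' numerically meaningless correlations).
#'
#' @param ensemble a [FitEnsemble-class], or a numeric matrix of parameter
#'   values (rows = fits, columns = parameters; assumed already restricted
#'   to the fits of interest).
#' @param percentBest percentage of best fits (by chi2) used (default 50).
#' @param r2Threshold r-squared threshold (default 0.9).
#' @param cvThreshold coefficient-of-variation threshold (default 0.15).
#' @param maxTuple maximum tuple size (default 5).
#' @return data.frame: \code{parameter}, \code{tuple} (comma-separated
#'   partners), \code{r2}, \code{cv}, \code{flagged}.
#' @export
motaFlags <- function(ensemble, percentBest = 50, r2Threshold = 0.9,
                      cvThreshold = 0.15, maxTuple = 5) {
    if (is(ensemble, "FitEnsemble")) {
        res <- ensemble@results
        if (nrow(res) < 10)
            stop("ensemble too small for correlation analysis (need >= 10 fits)")
        res <- res[is.finite(res$chi2), , drop = FALSE]
        keep <- seq_len(max(2, ceiling(nrow(res) * percentBest / 100)))
        mat <- as.matrix(res[keep, ensemble@free, drop = FALSE])
    } else {
        mat <- as.matrix(ensemble)
    }
    if (is.null(colnames(mat)))
        colnames(mat) <- paste0("p", seq_len(ncol(mat)))
    cv <- apply(mat, 2, function(x) sd(x) / abs(mean(x)))
    lmat <- log10(mat)
    degenerate <- apply(lmat, 2, sd) < 1e-12
    if (all(degenerate)) {
        warning("degenerate ensemble (all fits identical); no flags")
        return(data.frame(parameter = colnames(mat), tuple = "",
                          r2 = NA_real_, cv = cv, flagged = FALSE))
    }
    out <- lapply(colnames(mat), function(p) {
        others <- setdiff(colnames(mat)[!degenerate], p)
        chosen <- character(0)
        r2 <- 0
        y <- lmat[, p]
        if (sd(y) > 1e-12) {
            repeat {
                if (length(chosen) >= maxTuple || !length(others)) break
                r2try <- vapply(others, function(q) {
                    X <- lmat[, c(chosen, q), drop = FALSE]
                    res <- lm(y ~ X)$residuals
                    1 - sum(res^2) / sum((y - mean(y))^2)
                }, 1)
                b <- which.max(r2try)
                if (r2try[b] <= r2 + 1e-9) break
                r2 <- r2try[b]
                chosen <- c(chosen, others[b])
                others <- others[-b]
                if (r2 > 0.999) break
            }
        }
        data.frame(parameter = p, tuple = paste(chosen, collapse = ","),
                   r2 = r2, cv = cv[[p]],
                   flagged = r2 > r2Threshold && cv[[p]] > cvThreshold)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Profile likelihood of one parameter
#'
#' Steps the parameter over a log10 grid around its best-fit value
#' (default two decades either side), re-optimizing all other free
#' parameters at every step (marching outward from the optimum, each step
#' warm-started from its neighbour). Classification against the 95%
#' one-degree-of-freedom threshold \eqn{\Delta\chi^2 = 3.84}: both profile
#' arms crossing \eqn{\chi^2_{min} + 3.84} means identifiable, one flat arm
#' means practically non-identifiable, two flat arms structurally
#' non-identifiable.
#'
#' @param model a [ModelSpec-class] carrying the best-fit parameters.
#' @param dataset a [TimecourseDataset-class].
#' @param param parameter id to profile.
#' @param nSteps grid points (default 21, odd so the optimum is a grid
#'   point).
#' @param span half-width of the grid in decades (default 2).
#' @param config a [fitConfig()] controlling the re-optimizations
#'   (single-start).
#' @param free parameters re-optimized at each step (default: all others).
#' @param deltaChi2 classification threshold (default
#'   \code{qchisq(0.95, 1)}).
#' @return list with \code{param}, \code{grid} (parameter values),
#'   \code{chi2} (re-optimized profile), \code{chi2min} and \code{class}.
#' @export
profileLikelihood <- function(model, dataset, param, nSteps = 21, span = 2,
                              config = fitConfig(nStarts = 1),
                              free = NULL,
                              deltaChi2 = qchisq(0.95, 1)) {
    pa <- model@parameters
    stopifnot(param %in% pa$id)
    if (is.null(free)) free <- pa$id
    free <- setdiff(free, param)
    center <- log10(pa$value[match(param, pa$id)])
    grid <- seq(center - span, center + span, length.out = nSteps)
    mid <- which.min(abs(grid - center))
    grid[mid] <- center
    chi2 <- rep(NA_real_, nSteps)
    refit <- function(value, startParams) {
        m <- setParameters(model, c(setNames(value, param), startParams))
        if (!length(free)) {
            c2 <- chi2Objective(m, dataset = dataset,
                                errorFraction = config$errorFraction,
                                sigmaFloorFrac = config$sigmaFloorFrac,
                                rtol = config$rtol, atol = config$atol)
            if (!is.finite(c2)) return(NULL)
            return(list(chi2 = c2, params = numeric(0)))
        }
        f <- tryCatch(fitModel(m, dataset, config, free = free),
                      error = function(e) NULL)
        if (is.null(f)) NULL else list(chi2 = f@chi2, params = bestParameters(f)[free])
    }
    start <- setNames(pa$value[match(free, pa$id)], free)
    centerFit <- refit(10^grid[mid], start)
    if (is.null(centerFit)) stop("re-optimization failed at the optimum")
    chi2[mid] <- centerFit$chi2
    for (dir in c(-1, 1)) {
        prev <- centerFit$params
        i <- mid + dir
        while (i >= 1 && i <= nSteps) {
            f <- refit(10^grid[i], prev)
            if (!is.null(f)) {
                chi2[i] <- f$chi2
                prev <- f$params
            }
            i <- i + dir
        }
    }
    thr <- min(chi2, na.rm = TRUE) + deltaChi2
    crossLeft <- any(chi2[seq_len(mid - 1)] > thr, na.rm = TRUE)
    crossRight <- any(chi2[seq(mid + 1, nSteps)] > thr, na.rm = TRUE)
    cls <- if (crossLeft && crossRight) "identifiable"
           else if (crossLeft || crossRight) "practically non-identifiable"
           else "structurally non-identifiable"
    list(param = param, grid = 10^grid, chi2 = chi2,
         chi2min = min(chi2, na.rm = TRUE), class = cls)
}

#' Identifiability report over all fitted parameters
#'
#' Combines the ensemble-correlation flags with (optional) profile
#' likelihood classes into one per-parameter table.
#'
#' @param ensemble a [FitEnsemble-class].
#' @param profiles optional named list of [profileLikelihood()] results.
#' @param ... passed to [motaFlags()].
#' @return data.frame with one row per fitted parameter.
#' @export
identifiabilityReport <- function(ensemble, profiles = NULL, ...) {
    flags <- motaFlags(ensemble, ...)
    flags$class <- NA_character_
    if (!is.null(profiles)) {
        i <- match(vapply(profiles, `[[`, "", "param"), flags$parameter)
        flags$class[i] <- vapply(profiles, `[[`, "", "class")
    }
    flags
}
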