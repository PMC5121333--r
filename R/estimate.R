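# Parameter estimation: weighted least squares with a 10% observation error
# model, multi-start bounded trust-region optimization in log10 parameter
# space, and AIC scoring.

#' Estimation configuration
#'
#' @param nStarts number of independent starts (default 100; large-scale
#'   calibrations would use thousands).
#' @param disturbanceSD start-point disturbance noise, standard deviation of
#'   the multiplicative perturbation in log10 space (default 0.4).
#' @param maxIter maximum optimizer iterations per start (default 250).
#' @param tolerance chi-square and parameter relative tolerance (default 1e-5).
#' @param errorFraction fractional observation error sigma = errorFraction *
#'   y (default 0.10).
#' @param sigmaFloorFrac sigma floor as a fraction of each observable's
#'   maximum over the dataset, preventing zero-variance points at t = 0
#'   (default 0.01).
#' @param rtol,atol integration tolerances used during estimation.
#' @param seed RNG seed making the whole ensemble reproducible.
#' @return a list of class \code{fitConfig}.
#' @export
fitConfig <- function(nStarts = 100, disturbanceSD = 0.4, maxIter = 250,
                      tolerance = 1e-5, errorFraction = 0.10,
                      sigmaFloorFrac = 0.01, rtol = 1e-6, atol = 1e-8,
                      seed = 1) {
    stopifnot(nStarts >= 1, disturbanceSD >= 0, errorFraction >= 0)
    structure(list(nStarts = nStarts, disturbanceSD = disturbanceSD,
                   maxIter = maxIter, tolerance = tolerance,
                   errorFraction = errorFraction,
                   sigmaFloorFrac = sigmaFloorFrac,
                   rtol = rtol, atol = atol, seed = seed),
              class = "fitConfig")
}

# per-row sigma and simulation bookkeeping shared by chi2 and the optimizer
.prepareFit <- function(model, dataset, errorFraction, sigmaFloorFrac) {
    d <- dataset@data
    keep <- d$observable %in% names(model@observables)
    d <- d[keep, , drop = FALSE]
    if (!nrow(d)) stop("dataset has no observables in common with the model")
    # radix = byte-order sort: residual ordering (hence floating-point
    # summation order in the optimizer) must not depend on the locale
    d <- d[order(d$condition, d$observable, d$time, d$replicate,
                 method = "radix"), , drop = FALSE]
    floors <- tapply(d$value, d$observable, max) * sigmaFloorFrac
    # an observable that is identically zero in the dataset still needs a
    # scale: fall back to the pool-total scale (1 arbitrary unit)
    floors[floors == 0] <- sigmaFloorFrac
    sigma <- pmax(errorFraction * d$value, floors[d$observable])
    conds <- lapply(split(seq_len(nrow(d)), d$condition), function(i) {
        times <- sort(unique(c(0, d$time[i])))
        list(rows = i,
             times = times,
             ti = match(d$time[i], times),
             oi = d$observable[i])
    })
    list(d = d, sigma = as.numeric(sigma), conds = conds,
         protocols = dataset@protocols)
}

.simulatedValues <- function(model, prep, rtol, atol) {
    yhat <- numeric(nrow(prep$d))
    for (cn in names(prep$conds)) {
        cc <- prep$conds[[cn]]
        tr <- simulateModel(model, prep$protocols[[cn]], times = cc$times,
                            rtol = rtol, atol = atol)
        obs <- tr@observables
        yhat[cc$rows] <- obs[cbind(cc$ti, match(cc$oi, colnames(obs)))]
    }
    yhat
}

# precompiled fast path for repeated objective evaluations: the network is
# encoded once per condition and only the rate-constant slots are patched
# per call; observables are summed from raw solver output
.compiledSimulator <- function(model, prep, rtol, atol) {
    obsIdx <- lapply(model@observables, function(ids)
        match(ids, model@species$id))
    conds <- lapply(names(prep$conds), function(cn) {
        cc <- prep$conds[[cn]]
        protocol <- prep$protocols[[cn]]
        full <- .encodeModelFull(model, protocol)
        cc$oiIdx <- match(cc$oi, names(obsIdx))
        list(cc = cc, full = full,
             y0 = .initialAmounts(model, protocol))
    })
    n <- nrow(prep$d)
    function(values) {   # named, full parameter vector (linear scale)
        yhat <- numeric(n)
        for (cd in conds) {
            enc <- cd$full$enc
            enc[cd$full$kpos] <- values[cd$full$paramId] * cd$full$gateLevel
            out <- deSolve::lsoda(y = cd$y0, times = cd$cc$times,
                                  func = "mtoraa_derivs", parms = enc,
                                  dllname = "mTORaa",
                                  initfunc = "mtoraa_initmod",
                                  rtol = rtol, atol = atol, maxsteps = 10000)
            if (attr(out, "istate")[1] < 0) return(NULL)
            amounts <- unclass(out)[, -1, drop = FALSE]
            obs <- vapply(obsIdx, function(ix)
                rowSums(amounts[, ix, drop = FALSE]),
                numeric(length(cd$cc$times)))
            yhat[cd$cc$rows] <- obs[cbind(cd$cc$ti, cd$cc$oiIdx)]
        }
        yhat
    }
}

#' Weighted chi-square objective
#'
#' \eqn{\chi^2 = \sum_i ((y_i - \hat y_i)/\sigma_i)^2} with
#' \eqn{\sigma_i = \max(f \cdot y_i, \mathrm{floor})}, the floor being a
#' fraction of the observable's maximum over the dataset.
#'
#' @param model a [ModelSpec-class].
#' @param params optional named parameter values overriding the model's.
#' @param dataset a [TimecourseDataset-class].
#' @param errorFraction,sigmaFloorFrac error model, see [fitConfig()].
#' @param rtol,atol integration tolerances.
#' @return chi-square value; \code{Inf} if the integration fails.
#' @export
chi2Objective <- function(model, params = NULL, dataset,
                          errorFraction = 0.10, sigmaFloorFrac = 0.01,
                          rtol = 1e-6, atol = 1e-8) {
    if (!is.null(params)) model <- setParameters(model, params)
    prep <- .prepareFit(model, dataset, errorFraction, sigmaFloorFrac)
    yhat <- tryCatch(.simulatedValues(model, prep, rtol, atol),
                     error = function(e) NULL)
    if (is.null(yhat)) return(Inf)
    sum(((prep$d$value - yhat) / prep$sigma)^2)
}

#' Akaike information criterion for weighted least squares
#'
#' \eqn{\mathrm{AIC} = \chi^2 + 2k} (Gaussian likelihood with known
#' observation variance, additive constants dropped).
#'
#' @param chi2 chi-square of the fit.
#' @param kParams number of fitted parameters.
#' @return numeric AIC.
#' @export
aicScore <- function(chi2, kParams) {
    stopifnot(chi2 >= 0, kParams >= 0)
    chi2 + 2 * kParams
}

#' Multi-start parameter estimation
#'
#' Each start perturbs the best-known parameter vector multiplicatively by
#' \code{10^N(0, disturbanceSD)} per parameter (the first start is
#' unperturbed), clips to the box bounds \code{[1e-06, 1e+04]}, and runs a
#' bounded Levenberg-Marquardt trust-region least-squares in log10 parameter
#' space. Deterministic given \code{config$seed}.
#'
#' @param model a [ModelSpec-class]; its current parameter values serve as
#'   the best-known start point for the free parameters.
#' @param dataset a [TimecourseDataset-class].
#' @param config a [fitConfig()].
#' @param free ids of parameters to fit (default: all); the rest stay fixed
#'   at the model's values (e.g. the independently calibrated insulin
#'   receptor module).
#' @param init optional named start-point override for free parameters;
#'   \code{"midpoint"} starts from the log10 midpoint of the bounds.
#' @return a [FitEnsemble-class], starts sorted by chi-square.
#' @export
fitModel <- function(model, dataset, config = fitConfig(), free = NULL,
                     init = NULL) {
    stopifnot(is(model, "ModelSpec"), is(dataset, "TimecourseDataset"))
    pa <- model@parameters
    if (is.null(free)) free <- pa$id
    stopifnot(all(free %in% pa$id))
    prep <- .prepareFit(model, dataset, config$errorFraction,
                        config$sigmaFloorFrac)
    n <- nrow(prep$d)
    fi <- match(free, pa$id)
    lower <- log10(pa$lower[fi]); upper <- log10(pa$upper[fi])
    start0 <- log10(pa$value[fi])
    if (identical(init, "midpoint")) {
        start0 <- (lower + upper) / 2
    } else if (!is.null(init)) {
        stopifnot(all(free %in% names(init)))
        start0 <- log10(init[free])
    }
    simulator <- .compiledSimulator(model, prep, config$rtol, config$atol)
    values <- setNames(pa$value, pa$id)
    residFun <- function(logp) {
        values[free] <- 10^logp
        yhat <- tryCatch(simulator(values), error = function(e) NULL)
        if (is.null(yhat)) return(rep(1e6, n))
        (prep$d$value - yhat) / prep$sigma
    }
    set.seed(config$seed)
    disturb <- matrix(rnorm(config$nStarts * length(free),
                            sd = config$disturbanceSD),
                      nrow = config$nStarts)
    disturb[1, ] <- 0
    # forward-difference step matched to the integrator accuracy: residuals
    # carry O(rtol) noise, so the default machine-epsilon step is unusable
    ctrl <- minpack.lm::nls.lm.control(maxiter = config$maxIter,
                                       ftol = config$tolerance,
                                       ptol = config$tolerance,
                                       epsfcn = 1e-6)
    rows <- vector("list", config$nStarts)
    for (s in seq_len(config$nStarts)) {
        p0 <- pmin(pmax(start0 + disturb[s, ], lower), upper)
        fit <- tryCatch(
            withCallingHandlers(
                minpack.lm::nls.lm(par = p0, fn = residFun,
                                   lower = lower, upper = upper,
                                   control = ctrl),
                warning = function(w) {
                    # iteration-budget exhaustion is recorded in `converged`
                    if (grepl("lmdif|lmder|maxiter", conditionMessage(w)))
                        invokeRestart("muffleWarning")
                }),
            error = function(e) NULL)
        if (is.null(fit)) {
            rows[[s]] <- c(start = s, chi2 = Inf, converged = 0,
                           iterations = 0, setNames(10^p0, free))
        } else {
            rows[[s]] <- c(start = s, chi2 = sum(fit$fvec^2),
                           converged = as.numeric(fit$info %in% 1:4),
                           iterations = fit$niter,
                           setNames(10^fit$par, free))
        }
    }
    res <- as.data.frame(do.call(rbind, rows))
    if (all(!is.finite(res$chi2)))
        stop("all ", config$nStarts, " starts failed; see per-start table")
    res <- res[order(res$chi2), , drop = FALSE]
    rownames(res) <- NULL
    k <- length(unique(free))
    res$aic <- res$chi2 + 2 * k
    best <- unlist(res[1, free, drop = FALSE])
    fixedIds <- setdiff(pa$id, free)
    best <- c(best, setNames(pa$value[match(fixedIds, pa$id)], fixedIds))
    new("FitEnsemble", results = res, best = best[pa$id],
        chi2 = res$chi2[1], aic = res$aic[1], nData = as.integer(n),
        kParams = as.integer(k), free = free)
}

#' Read / write the tab-separated time-course dataset dialect
#'
#' Columns: observable, condition, time, replicate, value.
#'
#' @param file path.
#' @param protocols named list of [Protocol-class] per condition id
#'   (required on read).
#' @export
readDataset <- function(file, protocols) {
    d <- read.delim(file, stringsAsFactors = FALSE)
    new("TimecourseDataset", data = d, protocols = protocols)
}

#' @rdname readDataset
#' @param dataset a [TimecourseDataset-class].
#' @export
writeDataset <- function(dataset, file) {
    write.table(dataset@data, file, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(file)
}
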