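# Deterministic simulation of model variants under stimulation protocols and
# graded in-silico protein knockdowns (initial-amount scaling).

.MAX_PARMS <- 1024L

# flatten the reaction network into the fixed-length double vector the
# compiled right-hand side walks; gates are constant for t >= 0 and are
# folded into the effective rate constants. Returns the encoding plus the
# positions of the rate-constant slots so fitting can patch parameter
# values in place without re-encoding.
.encodeModelFull <- function(model, protocol) {
    sp <- model@species
    rx <- model@reactions
    kval <- setNames(model@parameters$value, model@parameters$id)
    gate <- c(none = 1, aa = protocol@aa, insulin = protocol@insulin)
    idx <- setNames(seq_len(nrow(sp)), sp$id)
    enc <- c(nrow(sp), nrow(rx))
    kpos <- integer(nrow(rx))
    for (i in seq_len(nrow(rx))) {
        cats <- strsplit(rx$catalysts[i], ",")[[1]]
        cats <- cats[nzchar(cats)]
        kpos[i] <- length(enc) + 1L
        enc <- c(enc, unname(kval[rx$param[i]] * gate[rx$gate[i]]),
                 idx[[rx$substrate[i]]], idx[[rx$product[i]]],
                 length(cats), unname(idx[cats]))
    }
    if (length(enc) > .MAX_PARMS)
        stop("model too large for the compiled rate evaluator")
    list(enc = c(enc, numeric(.MAX_PARMS - length(enc))),
         kpos = kpos, paramId = rx$param,
         gateLevel = unname(gate[rx$gate]))
}

.encodeModel <- function(model, protocol)
    .encodeModelFull(model, protocol)$enc

.initialAmounts <- function(model, protocol) {
    sp <- model@species
    y0 <- setNames(sp$initial, sp$id)
    pert <- protocol@perturbations
    if (length(pert)) {
        unknown <- setdiff(names(pert), unique(sp$protein))
        if (length(unknown))
            stop("unknown protein pool(s): ", paste(unknown, collapse = ", "))
        for (pool in names(pert))
            y0[sp$protein == pool] <- y0[sp$protein == pool] * pert[[pool]]
    }
    y0
}

#' Simulate a model under a stimulation protocol
#'
#' Integrates the mass-action ODE system with the stiff-capable LSODA
#' solver. Stimuli are unitless step functions switched on at t = 0;
#' perturbations scale the initial amounts of whole protein pools (the
#' phospho-states start at 0, so scaling the unmodified state scales the
#' pool total). Observables are computed as unweighted sums of species
#' amounts (scale 1).
#'
#' @param model a [ModelSpec-class].
#' @param protocol a [Protocol-class].
#' @param times optional explicit output grid (minutes); defaults to
#'   \code{seq(0, duration, by = outputStep)}.
#' @param rtol,atol solver tolerances (defaults 1e-6 / 1e-12).
#' @return a [Trajectory-class].
#' @examples
#' tr <- simulateModel(buildBaseModel("extended"), Protocol(aa = 1, insulin = 1))
#' @export
simulateModel <- function(model, protocol = Protocol(), times = NULL,
                          rtol = 1e-6, atol = 1e-12) {
    stopifnot(is(model, "ModelSpec"), is(protocol, "Protocol"))
    validObject(protocol)
    if (is.null(times))
        times <- seq(0, protocol@duration, by = protocol@outputStep)
    y0 <- .initialAmounts(model, protocol)
    out <- deSolve::lsoda(y = y0, times = times, func = "mtoraa_derivs",
                          parms = .encodeModel(model, protocol),
                          dllname = "mTORaa", initfunc = "mtoraa_initmod",
                          rtol = rtol, atol = atol, maxsteps = 10000)
    if (attr(out, "istate")[1] < 0)
        stop("ODE integration failed (parameter set hash ",
             .parameterHash(model), ")")
    amounts <- unclass(out)[, -1, drop = FALSE]
    if (min(amounts) < -1e-6)
        stop("trajectory left the nonnegative orthant (parameter set hash ",
             .parameterHash(model), ")")
    obs <- vapply(model@observables, function(ids)
        rowSums(amounts[, ids, drop = FALSE]), numeric(length(times)))
    if (length(times) == 1L) obs <- matrix(obs, nrow = 1,
        dimnames = list(NULL, names(model@observables)))
    new("Trajectory", time = times, amounts = amounts, observables = obs)
}

.parameterHash <- function(model) {
    v <- model@parameters$value
    sprintf("%08x", sum(as.integer((abs(v) %% 1000) * 1e4) *
        seq_along(v)) %% .Machine$integer.max)
}

#' Graded in-silico knockdown scan of a protein pool
#'
#' Re-simulates the protocol at 10 residual protein levels (10\% to 100\%
#' of the control total, in steps of 10\%), emulating inhibitor and
#' knockdown titrations. The PI3K scan scales both PI3K species totals
#' together, as both are wortmannin-sensitive.
#'
#' @param model a [ModelSpec-class].
#' @param protocol the base [Protocol-class] (its own perturbations must not
#'   touch the scanned pool).
#' @param pool one of \code{"mTORC1"}, \code{"mTORC2"}, \code{"PI3K"},
#'   \code{"AMPK"}.
#' @param fractions residual fractions (default \code{seq(0.1, 1, 0.1)}).
#' @param times optional output grid passed to [simulateModel()].
#' @return named list of [Trajectory-class], one per residual fraction.
#' @export
perturbationScan <- function(model, protocol = Protocol(), pool,
                             fractions = seq(0.1, 1, by = 0.1),
                             times = NULL) {
    pools <- switch(pool,
        mTORC1 = "mTORC1", mTORC2 = "mTORC2", AMPK = "AMPK",
        PI3K = c("PI3K_PDK1", "PI3K_var"),
        stop("unknown pool '", pool, "'; expected mTORC1, mTORC2, PI3K or AMPK"))
    out <- lapply(fractions, function(f) {
        p <- protocol
        p@perturbations <- c(p@perturbations, setNames(rep(f, length(pools)), pools))
        simulateModel(model, p, times = times)
    })
    names(out) <- format(fractions)
    out
}

#' Tidy export of a trajectory
#'
#' @param trajectory a [Trajectory-class].
#' @param what \code{"observables"} or \code{"species"}.
#' @return long data.frame (id, time, value).
#' @export
trajectoryTable <- function(trajectory, what = c("observables", "species")) {
    what <- match.arg(what)
    m <- if (what == "observables") trajectory@observables else trajectory@amounts
    data.frame(id = rep(colnames(m), each = nrow(m)),
               time = rep(trajectory@time, ncol(m)),
               value = as.vector(m))
}
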