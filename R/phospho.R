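# Post-MaxQuant triple-SILAC ratio pipeline: bridged cross-experiment ratio
# combinatorics via the 30-min channel, per-column median centering,
# one-sample t-tests and fold-change/p-value (volcano) filtering.

.intensityColumn <- function(design, i)
    sprintf("Intensity %s %d", design$channel[i], design$experiment[i])

.channelOf <- function(design, experiment, time) {
    j <- which(design$experiment == experiment & design$time == time)
    if (!length(j)) return(NA_character_)
    .intensityColumn(design, j)
}

#' Read / write MaxQuant-style phosphosite tables
#'
#' Tab-separated 'Phospho (STY)Sites'-dialect tables: identification
#' columns plus one \code{Intensity <channel> <experiment>} column per
#' SILAC channel. Column names are kept verbatim (spaces preserved).
#'
#' @param file path.
#' @param columnMap optional named character vector renaming non-standard
#'   input columns to the dialect names.
#' @return data.frame.
#' @export
readPhosphoTable <- function(file, columnMap = NULL) {
    tab <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
    if (!is.null(columnMap))
        names(tab)[match(names(columnMap), names(tab))] <- unname(columnMap)
    tab
}

#' @rdname readPhosphoTable
#' @param table a phosphosite data.frame.
#' @export
writePhosphoTable <- function(table, file) {
    attr(table, "regulated") <- NULL
    write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Localization-probability filter
#'
#' Retains sites whose phosphorylation is confidently localized:
#' probability strictly greater than 0.75.
#'
#' @param table phosphosite data.frame with a \code{Localization prob}
#'   column.
#' @return the filtered table.
#' @export
localizationFilter <- function(table) {
    table[!is.na(table[["Localization prob"]]) &
          table[["Localization prob"]] > 0.75, , drop = FALSE]
}

#' Bridged cross-experiment SILAC ratios
#'
#' For a stimulated time point t, forms every ordered pair of an experiment
#' containing t and an experiment containing 0 min and computes
#' \deqn{(I_{t,i}/I_{30,i}) / (I_{0,j}/I_{30,j})}
#' normalizing both through the 30-min bridge channel, then takes log2.
#' With three 0/5/30 and two 10/15/30 experiments this yields nine ratios
#' at 5 min and six at 10 and 15 min. Zero intensities are treated as
#' missing; any combination with a missing term is dropped (NA).
#'
#' @param table phosphosite data.frame.
#' @param design a [silacDesign()]-style data.frame.
#' @param timePoint one of the stimulated times present in the design
#'   (5, 10 or 15 for the study design).
#' @return matrix (sites x combinations) of log2 ratios; columns named
#'   \code{E<i>.vs.E<j>}.
#' @export
computeRatios <- function(table, design, timePoint) {
    stopifnot(timePoint %in% design$time, timePoint != 0)
    bridge <- 30
    expT <- unique(design$experiment[design$time == timePoint])
    exp0 <- unique(design$experiment[design$time == 0])
    getI <- function(col) {
        if (is.na(col) || !col %in% names(table))
            return(rep(NA_real_, nrow(table)))
        v <- as.numeric(table[[col]])
        v[!is.na(v) & v == 0] <- NA  # zero intensity = missing
        v
    }
    out <- list()
    for (i in expT) {
        bi <- getI(.channelOf(design, i, bridge))
        ti <- getI(.channelOf(design, i, timePoint))
        if (all(is.na(bi)))
            warning("bridge intensity missing in experiment ", i,
                    "; its combinations are dropped")
        for (j in exp0) {
            bj <- getI(.channelOf(design, j, bridge))
            zj <- getI(.channelOf(design, j, 0))
            out[[sprintf("E%d.vs.E%d", i, j)]] <-
                log2((ti / bi) / (zj / bj))
        }
    }
    m <- do.call(cbind, out)
    rownames(m) <- if ("Proteins" %in% names(table)) table$Proteins else NULL
    m
}

#' Median-center log2 ratio columns
#'
#' Subtracts each column's median across sites, so that the bulk of the
#' phosphoproteome (assumed unregulated) sits at log2 ratio 0.
#'
#' @param ratios matrix of log2 ratios (sites x combinations).
#' @return the centered matrix.
#' @export
medianCenter <- function(ratios) {
    for (j in seq_len(ncol(ratios))) {
        med <- median(ratios[, j], na.rm = TRUE)
        if (is.na(med)) {
            warning("column ", colnames(ratios)[j],
                    " has no finite ratios; left untouched")
            next
        }
        ratios[, j] <- ratios[, j] - med
    }
    ratios
}

#' Per-site volcano statistics at one time point
#'
#' Mean log2 fold change and two-sided one-sample t-test against 0 over the
#' (centered) ratio combinations of each site. Sites with fewer than two
#' finite ratios are excluded. A zero-variance ratio vector leaves the
#' t-test undefined; such a site passes the p-gate iff its mean is nonzero
#' (its p is reported as 0 in that case, 1 otherwise).
#'
#' @param ratios matrix of log2 ratios (sites x combinations).
#' @param timePoint time point label attached to the records.
#' @return data.frame: \code{site}, \code{time}, \code{n}, \code{log2FC},
#'   \code{p}.
#' @export
volcanoRecords <- function(ratios, timePoint = NA) {
    n <- rowSums(is.finite(ratios))
    keep <- which(n >= 2)
    rec <- lapply(keep, function(i) {
        x <- ratios[i, is.finite(ratios[i, ])]
        p <- if (sd(x) == 0) {
            if (mean(x) != 0) 0 else 1
        } else t.test(x, mu = 0)$p.value
        data.frame(site = rownames(ratios)[i], time = timePoint,
                   n = length(x), log2FC = mean(x), p = p)
    })
    if (!length(rec))
        return(data.frame(site = character(), time = numeric(),
                          n = integer(), log2FC = numeric(), p = numeric()))
    out <- do.call(rbind, rec)
    rownames(out) <- NULL
    out
}

#' Fold-change / p-value (volcano) filter
#'
#' A site is regulated at a time point when it has at least two ratios,
#' \eqn{|mean log2 ratio| \ge log2(fcCutoff)} and two-sided one-sample
#' t-test p below \code{pCutoff}, with no multiple-testing correction. A
#' site is regulated overall if it passes at one or more time points.
#'
#' @param records data.frame from [volcanoRecords()] (possibly several time
#'   points row-bound).
#' @param fcCutoff fold-change cutoff on the linear scale (> 1; the study
#'   used 1.5 and 2).
#' @param pCutoff p-value cutoff (default 0.05).
#' @return character vector of regulated site ids; the per-record flags are
#'   attached as attribute \code{"records"}.
#' @export
volcanoFilter <- function(records, fcCutoff = 2, pCutoff = 0.05) {
    stopifnot(fcCutoff > 1, pCutoff > 0, pCutoff < 1)
    pass <- records$n >= 2 & abs(records$log2FC) >= log2(fcCutoff) &
        records$p < pCutoff
    records$regulated <- pass
    out <- sort(unique(records$site[pass]))
    attr(out, "records") <- records
    out
}

#' The full phosphosite processing pipeline
#'
#' Localization filter (> 0.75), bridged ratios per stimulated time point,
#' per-column median centering, volcano statistics and filtering at the
#' requested fold-change cutoffs.
#'
#' @param table phosphosite data.frame.
#' @param design a [silacDesign()]-style data.frame.
#' @param fcCutoffs fold-change cutoffs (default \code{c(1.5, 2)}).
#' @param pCutoff p-value cutoff (default 0.05).
#' @param center median-center ratio columns (default TRUE).
#' @return list with \code{records} (per site x time statistics) and
#'   \code{regulated}, a named list of regulated-site vectors per cutoff.
#' @export
runPhosphoPipeline <- function(table, design = silacDesign(),
                               fcCutoffs = c(1.5, 2), pCutoff = 0.05,
                               center = TRUE) {
    tab <- localizationFilter(table)
    times <- sort(setdiff(unique(design$time), c(0, 30)))
    records <- do.call(rbind, lapply(times, function(t) {
        r <- computeRatios(tab, design, t)
        if (center) r <- medianCenter(r)
        volcanoRecords(r, t)
    }))
    regulated <- lapply(fcCutoffs, function(fc)
        as.character(volcanoFilter(records, fc, pCutoff)))
    names(regulated) <- format(fcCutoffs)
    list(records = records, regulated = regulated)
}
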