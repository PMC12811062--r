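## Brute-force re-implementations of every cascade stage, written as naive
## per-gene loops over the raw records so they share no code path with the
## package's vectorised implementations.

oracleRecords <- function(ft) fitnessRecords(ft)

oracleLookup <- function(rec, gene, cond, col) {
    v <- rec[rec$gene_id == gene & rec$condition == cond, col]
    if (length(v) != 1L) NA_real_ else v
}

oracleComplete <- function(rec, conds) {
    genes <- unique(rec$gene_id)
    keep <- character()
    for (g in genes) {
        ok <- TRUE
        for (cond in conds) {
            row <- rec[rec$gene_id == g & rec$condition == cond, ]
            if (nrow(row) != 1L || row$flag_zero || row$flag_low_t1)
                ok <- FALSE
        }
        if (ok) keep <- c(keep, g)
    }
    keep
}

oracleNeutral <- function(rec, genes, baseline, band) {
    keep <- character()
    for (g in genes) {
        w <- oracleLookup(rec, g, baseline, "mean_w")
        if (!is.na(w) && w >= band[1L] && w <= band[2L])
            keep <- c(keep, g)
    }
    keep
}

oracleConcordant <- function(rec, genes, conds, maxDist) {
    keep <- character()
    for (g in genes) {
        ok <- TRUE
        for (cond in conds) {
            d <- oracleLookup(rec, g, cond, "replicate_distance")
            if (is.na(d) || d >= maxDist) ok <- FALSE
        }
        if (ok) keep <- c(keep, g)
    }
    keep
}

oracleDifferential <- function(rec, genes, baseline, substrates, theta) {
    out <- list()
    for (s in substrates) {
        hits <- character()
        for (g in genes) {
            wb <- oracleLookup(rec, g, baseline, "mean_w")
            ws <- oracleLookup(rec, g, s, "mean_w")
            if (!is.na(wb) && !is.na(ws) && abs(ws - wb) > theta)
                hits <- c(hits, g)
        }
        out[[s]] <- hits
    }
    out
}

oracleSpecific <- function(differential) {
    out <- list()
    for (s in names(differential)) {
        hits <- character()
        for (g in differential[[s]]) {
            elsewhere <- FALSE
            for (s2 in setdiff(names(differential), s))
                if (g %in% differential[[s2]]) elsewhere <- TRUE
            if (!elsewhere) hits <- c(hits, g)
        }
        out[[s]] <- hits
    }
    out
}

## Full cascade oracle, mirroring the declared stage order.
oracleCascade <- function(ft, cfg) {
    rec <- oracleRecords(ft)
    conds <- unique(rec$condition)
    baseline <- cfg@baselineCondition
    subs <- setdiff(conds, baseline)
    complete <- oracleComplete(rec, conds)
    neutral <- oracleNeutral(rec, complete, baseline, cfg@neutralBand)
    concord <- oracleConcordant(rec, complete, subs,
                                cfg@maxReplicateDistance)
    compared <- intersect(neutral, concord)
    diffs <- specs <- list()
    for (t in cfg@differenceThresholds) {
        key <- format(t)
        diffs[[key]] <- oracleDifferential(rec, compared, baseline, subs, t)
        specs[[key]] <- oracleSpecific(diffs[[key]])
    }
    list(complete = complete, neutral = neutral, concordant = concord,
         compared = compared, differential = diffs, specific = specs)
}
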