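#' @include AllClasses.R AllGenerics.R accessors.R
NULL

#' Construct a filter-cascade configuration
#'
#' @param baselineCondition baseline carbon source label (default
#'   \code{"sucrose"}, the diazotrophic sucrose condition).
#' @param neutralBand closed fitness interval on the baseline defining
#'   "loss does not affect growth" (default \code{c(0.9, 1.1)}).
#' @param maxReplicateDistance replicate-concordance cutoff; genes pass
#'   when strictly below it (default 0.2).
#' @param differenceThresholds strictly increasing fitness-difference
#'   thresholds (default \code{c(0.2, 0.3, 0.4)}).
#' @param minT1Count minimum mean t1 count; genes pass when strictly
#'   above it (default 50).
#' @return a \linkS4class{FilterConfig}.
#' @export
filterConfig <- function(baselineCondition = "sucrose",
                         neutralBand = c(0.9, 1.1),
                         maxReplicateDistance = 0.2,
                         differenceThresholds = c(0.2, 0.3, 0.4),
                         minT1Count = 50) {
    obj <- new("FilterConfig",
               baselineCondition = baselineCondition,
               neutralBand = as.numeric(neutralBand),
               maxReplicateDistance = maxReplicateDistance,
               differenceThresholds = as.numeric(differenceThresholds),
               minT1Count = minT1Count)
    validObject(obj)
    obj
}

#' Completeness filter: drop genes with zero values or low t1 counts
#'
#' A gene is retained only if, in every listed condition, it is neither
#' flagged for a zero count in a relevant sample nor flagged for low t1
#' representation. Zero values are treated as categorical, not numeric:
#' when a mutant's reads vanish it is unknown at what point in the growth
#' interval the lineage disappeared, so its fitness is excluded rather
#' than imputed.
#'
#' @param table a \linkS4class{FitnessTable}.
#' @param conditions condition labels that must all be clean.
#' @return character vector of retained gene ids (table order).
#' @export
completenessFilter <- function(table, conditions = NULL) {
    rec <- fitnessRecords(table)
    if (is.null(conditions))
        conditions <- unique(rec$condition)
    miss <- setdiff(conditions, rec$condition)
    if (length(miss))
        stop("condition(s) missing from table: ",
             paste(miss, collapse = ", "))
    rec <- rec[rec$condition %in% conditions, , drop = FALSE]
    bad <- unique(rec$gene_id[rec$flag_zero | rec$flag_low_t1])
    setdiff(unique(rec$gene_id), bad)
}

#' Baseline-neutrality filter
#'
#' Keeps genes whose mean fitness on the baseline condition lies inside
#' the closed neutral band (boundary values are retained).
#'
#' @param table a \linkS4class{FitnessTable}.
#' @param genes gene ids to consider.
#' @param config a \linkS4class{FilterConfig}.
#' @return character vector of retained gene ids.
#' @export
neutralOnBaseline <- function(table, genes, config = filterConfig()) {
    w <- meanW(table, condition = config@baselineCondition)[genes, 1L]
    genes[!is.na(w) & w >= config@neutralBand[1L] &
              w <= config@neutralBand[2L]]
}

#' Replicate-concordance filter
#'
#' Keeps genes whose replicate distance is strictly below the cutoff in
#' every non-baseline condition under comparison.
#'
#' @param table a \linkS4class{FitnessTable}.
#' @param genes gene ids to consider.
#' @param config a \linkS4class{FilterConfig}.
#' @param conditions conditions to check; default all non-baseline
#'   conditions in the table.
#' @return character vector of retained gene ids.
#' @export
concordanceFilter <- function(table, genes, config = filterConfig(),
                              conditions = NULL) {
    if (is.null(conditions))
        conditions <- setdiff(conditions(table), config@baselineCondition)
    d <- replicateDistance(table, condition = conditions)[genes, ,
                                                          drop = FALSE]
    ok <- rowSums(is.na(d)) == 0 &
        rowSums(d < config@maxReplicateDistance) == ncol(d)
    genes[ok]
}

#' Differentially fit genes per substrate
#'
#' A gene is differential on a substrate when the absolute difference
#' between its mean fitness there and on the baseline exceeds the
#' threshold (strictly).
#'
#' @param table a \linkS4class{FitnessTable}.
#' @param genes gene ids to consider.
#' @param config a \linkS4class{FilterConfig}.
#' @param threshold fitness-difference threshold (> 0).
#' @param substrates non-baseline conditions to compare; default all in
#'   the table.
#' @return list with one gene-id vector per substrate plus \code{union},
#'   the across-substrate union.
#' @export
differentialGenes <- function(table, genes, config = filterConfig(),
                              threshold, substrates = NULL) {
    .assertScalarNumeric(threshold, "threshold", lower = 0,
                         strict_lower = TRUE)
    if (is.null(substrates))
        substrates <- setdiff(conditions(table), config@baselineCondition)
    wb <- meanW(table, condition = config@baselineCondition)[genes, 1L]
    ws <- meanW(table, condition = substrates)[genes, , drop = FALSE]
    out <- lapply(substrates, function(s) {
        delta <- abs(ws[, s] - wb)
        genes[!is.na(delta) & delta > threshold]
    })
    names(out) <- substrates
    out$union <- Reduce(union, out[substrates], character())
    out
}

#' Substrate-specific genes
#'
#' A gene is specific to a substrate when it is differential on that
#' substrate and on no other substrate at the same threshold.
#'
#' @param differential per-substrate differential sets (the output of
#'   [differentialGenes()]; a \code{union} element, if present, is
#'   ignored).
#' @return list of per-substrate specific gene-id vectors.
#' @export
substrateSpecific <- function(differential) {
    differential$union <- NULL
    subs <- names(differential)
    out <- lapply(subs, function(s) {
        others <- unlist(differential[setdiff(subs, s)], use.names = FALSE)
        setdiff(differential[[s]], others)
    })
    names(out) <- subs
    out
}

#' Run the full gene-selection cascade
#'
#' Applies, in order: the completeness filter (no zero values, adequate
#' t1 counts, across all listed conditions); the baseline-neutrality and
#' replicate-concordance filters, reported as parallel counts on the
#' complete set with their intersection carried forward; then, on the
#' carried-forward genes, the differential classification against the
#' baseline at each configured threshold and the substrate-specific
#' breakdown.
#'
#' @param x a \linkS4class{FitnessTable}.
#' @param config a \linkS4class{FilterConfig}.
#' @param conditions conditions the completeness filter must cover;
#'   default all in the table.
#' @param ... unused.
#' @return a \linkS4class{CascadeReport}.
#' @export
setMethod("runCascade", signature(x = "FitnessTable"),
          function(x, config = filterConfig(), conditions = NULL, ...) {
    rec <- fitnessRecords(x)
    if (is.null(conditions))
        conditions <- unique(rec$condition)
    if (!config@baselineCondition %in% conditions)
        stop("baseline condition '", config@baselineCondition,
             "' not among the cascade conditions")
    substrates <- setdiff(conditions, config@baselineCondition)
    allGenes <- unique(rec$gene_id)

    complete <- completenessFilter(x, conditions)
    neutral <- neutralOnBaseline(x, complete, config)
    concord <- concordanceFilter(x, complete, config,
                                 conditions = substrates)
    compared <- intersect(neutral, concord)

    th <- config@differenceThresholds
    diffSets <- specSets <- uniSets <- list()
    stage <- c(input = length(allGenes),
               complete = length(complete),
               compared = length(compared))
    for (t in th) {
        key <- format(t)
        dg <- differentialGenes(x, compared, config, threshold = t,
                                substrates = substrates)
        uniSets[[key]] <- dg$union
        dg$union <- NULL
        diffSets[[key]] <- dg
        specSets[[key]] <- substrateSpecific(dg)
        stage[[paste0("differential_", key)]] <- length(uniSets[[key]])
    }
    out <- new("CascadeReport",
               stageCounts = stats::setNames(as.integer(stage), names(stage)),
               parallelCounts = c(neutral_baseline = length(neutral),
                                  replicate_concordant = length(concord)),
               differentialSets = diffSets,
               specificSets = specSets,
               unionSets = uniSets,
               config = config)
    validObject(out)
    out
})

#' Write a cascade report to a directory of TSV files
#'
#' Writes \code{cascade_stages.tsv} (stage table including the parallel
#' counts) and one \code{genes_<substrate>_gt<threshold>.tsv} per
#' (substrate, threshold) pair, each listing the differential genes with
#' a column marking the substrate-specific ones.
#'
#' @param report a \linkS4class{CascadeReport}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCascadeReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sc <- stageCounts(report)
    pc <- parallelCounts(report)
    stages <- data.frame(
        stage = c(names(sc), names(pc)),
        kind = c(rep("ordered", length(sc)), rep("parallel", length(pc))),
        genes = c(as.integer(sc), as.integer(pc)))
    utils::write.table(stages, file.path(dir, "cascade_stages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ds <- differentialSets(report)
    ss <- specificSets(report)
    for (key in names(ds)) {
        for (s in names(ds[[key]])) {
            df <- data.frame(gene_id = ds[[key]][[s]])
            df$specific <- df$gene_id %in% ss[[key]][[s]]
            fn <- sprintf("genes_%s_gt%s.tsv", s, gsub("[.]", "p", key))
            utils::write.table(df, file.path(dir, fn), sep = "\t",
                               quote = FALSE, row.names = FALSE)
        }
    }
    invisible(dir)
}
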