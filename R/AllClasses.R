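#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

#' Ground-truth transposon library
#'
#' A \code{TrueLibrary} holds the simulator's ground truth: one fitness value
#' per gene (1 = neutral, 0 = no growth over the interval) and the relative
#' abundance of each insertion mutant in the pre-grown (t1) pool. The
#' background expansion \code{E} is the fold-expansion a neutral lineage
#' undergoes over the growth interval; over roughly seven generations of a
#' batch culture this is the ~99-155x range an OD600 ratio would report.
#'
#' @slot geneIds character, unique gene identifiers.
#' @slot trueFitness numeric, finite and non-negative, one per gene.
#' @slot t1Abundance numeric, positive relative abundances; interpreted after
#'   normalisation to proportions summing to 1.
#' @slot backgroundExpansion numeric(1), fold-expansion of a neutral lineage,
#'   must exceed 1.
#' @slot seed integer(1), the seed the library was generated from.
#'
#' @seealso [makeLibrary()], [expectedT2Proportions()], [simulateExperiment()]
#' @export
setClass("TrueLibrary",
    slots = c(geneIds = "character",
              trueFitness = "numeric",
              t1Abundance = "numeric",
              backgroundExpansion = "numeric",
              seed = "integer"))

setValidity("TrueLibrary", function(object) {
    n <- length(object@geneIds)
    msg <- character()
    if (n < 1L)
        msg <- c(msg, "library must contain at least one gene")
    if (anyDuplicated(object@geneIds))
        msg <- c(msg, "gene identifiers must be unique")
    if (length(object@trueFitness) != n || length(object@t1Abundance) != n)
        msg <- c(msg, "trueFitness and t1Abundance must match geneIds length")
    if (!all(is.finite(object@trueFitness)) || any(object@trueFitness < 0))
        msg <- c(msg, "trueFitness must be finite and non-negative")
    if (!all(is.finite(object@t1Abundance)) || any(object@t1Abundance <= 0))
        msg <- c(msg, "t1Abundance must be positive and finite")
    if (length(object@backgroundExpansion) != 1L ||
        !is.finite(object@backgroundExpansion) ||
        object@backgroundExpansion <= 1)
        msg <- c(msg, "backgroundExpansion must be a single value > 1")
    if (length(msg)) msg else TRUE
})

#' Tn-seq experiment container
#'
#' Extends \linkS4class{SummarizedExperiment}: a genes x samples matrix in
#' assay \code{"counts"} (integer read counts, or non-negative reals for
#' noise-free simulated data) with per-sample metadata in \code{colData}.
#' Required \code{colData} columns: \code{sample_id}, \code{condition},
#' \code{nitrogen}, \code{replicate}, \code{timepoint} (\code{"t1"} or
#' \code{"t2"}), \code{od_t1}, \code{od_t2}, \code{d} (the expansion factor
#' OD600,t2 / OD600,t1) and \code{mapped_reads}.
#'
#' @export
setClass("TnSeqExperiment", contains = "SummarizedExperiment")

.META_COLS <- c("sample_id", "condition", "nitrogen", "replicate",
                "timepoint", "od_t1", "od_t2", "d", "mapped_reads")

setValidity("TnSeqExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0))
        msg <- c(msg, "counts must be finite and non-negative")
    cd <- SummarizedExperiment::colData(object)
    miss <- setdiff(.META_COLS, colnames(cd))
    if (length(miss))
        return(paste("missing colData columns:", paste(miss, collapse = ", ")))
    if (!all(cd$timepoint %in% c("t1", "t2")))
        msg <- c(msg, "timepoint must be 't1' or 't2'")
    d <- cd$d
    if (any(!is.finite(d)) || any(d <= 0))
        msg <- c(msg, "expansion factor d must be positive")
    ok <- is.finite(cd$od_t1) & is.finite(cd$od_t2) & cd$od_t1 > 0
    if (any(ok)) {
        rel <- abs(cd$od_t2[ok] / cd$od_t1[ok] - d[ok]) / d[ok]
        if (any(rel > 0.005))
            msg <- c(msg, "d must equal od_t2/od_t1 within 0.5%")
    }
    if (length(msg)) msg else TRUE
})

#' Per-gene, per-condition fitness estimates
#'
#' Tabular result of [fitnessTable()]: one row per gene x condition with
#' per-replicate fitness values (\code{w_rep1}, \code{w_rep2}, ...), their
#' mean, the replicate distance (maximum pairwise absolute difference,
#' i.e. |w1 - w2| for duplicates), and the two exclusion flags: low t1
#' representation (mean t1 count at or below the threshold) and zero counts
#' in a relevant sample. Replicates whose computation involved a zero count
#' carry \code{NA} (never a sentinel number); \code{mean_w} and
#' \code{replicate_distance} are \code{NA} unless every replicate is present.
#'
#' @export
setClass("FitnessTable",
    slots = c(records = "data.frame"))

.REC_FIXED <- c("gene_id", "condition", "mean_w", "replicate_distance",
                "flag_low_t1", "flag_zero")

setValidity("FitnessTable", function(object) {
    rec <- object@records
    msg <- character()
    miss <- setdiff(.REC_FIXED, colnames(rec))
    if (length(miss))
        return(paste("missing columns:", paste(miss, collapse = ", ")))
    if (!length(grep("^w_rep[0-9]+$", colnames(rec))))
        msg <- c(msg, "at least one w_rep<k> column is required")
    if (anyDuplicated(rec[, c("gene_id", "condition")]))
        msg <- c(msg, "one row per gene x condition is required")
    dist <- rec$replicate_distance
    if (any(dist[!is.na(dist)] < 0))
        msg <- c(msg, "replicate_distance must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Filter-cascade configuration
#'
#' Parameters of the gene-selection cascade: the baseline condition against
#' which challenge substrates are compared, the neutrality band on the
#' baseline (closed interval, default [0.9, 1.1]), the replicate-concordance
#' cutoff (strict, default < 0.2), the fitness-difference thresholds
#' (default 0.2, 0.3, 0.4 fitness units, strictly increasing) and the
#' minimum mean t1 count (genes are kept when the mean is strictly greater,
#' default 50).
#'
#' @export
setClass("FilterConfig",
    slots = c(baselineCondition = "character",
              neutralBand = "numeric",
              maxReplicateDistance = "numeric",
              differenceThresholds = "numeric",
              minT1Count = "numeric"))

setValidity("FilterConfig", function(object) {
    msg <- character()
    if (length(object@baselineCondition) != 1L)
        msg <- c(msg, "baselineCondition must be a single label")
    if (length(object@neutralBand) != 2L ||
        object@neutralBand[1L] > object@neutralBand[2L])
        msg <- c(msg, "neutralBand must be c(lower, upper) with lower <= upper")
    if (length(object@maxReplicateDistance) != 1L ||
        object@maxReplicateDistance <= 0)
        msg <- c(msg, "maxReplicateDistance must be a single positive value")
    th <- object@differenceThresholds
    if (!length(th) || any(th <= 0) || is.unsorted(th, strictly = TRUE))
        msg <- c(msg, "differenceThresholds must be positive and strictly increasing")
    if (length(object@minT1Count) != 1L || object@minT1Count < 0)
        msg <- c(msg, "minT1Count must be a single non-negative value")
    if (length(msg)) msg else TRUE
})

#' Filter-cascade report
#'
#' Output of [runCascade()]: ordered per-stage surviving-gene counts (never
#' increasing along the stage order), the two parallel counts reported on
#' the complete-gene set (baseline-neutral and replicate-concordant), and
#' the per-substrate differential and substrate-specific gene sets at each
#' configured difference threshold. \code{differentialSets} and
#' \code{specificSets} are nested lists indexed first by threshold (as a
#' character key) then by substrate; \code{unionSets} holds the
#' across-substrate union per threshold.
#'
#' @export
setClass("CascadeReport",
    slots = c(stageCounts = "integer",
              parallelCounts = "integer",
              differentialSets = "list",
              specificSets = "list",
              unionSets = "list",
              config = "FilterConfig"))

setValidity("CascadeReport", function(object) {
    sc <- object@stageCounts
    msg <- character()
    if (is.null(names(sc)))
        msg <- c(msg, "stageCounts must be named")
    if (length(sc) > 1L && any(diff(sc) > 0L))
        msg <- c(msg, "stageCounts must be non-increasing along the stage order")
    th <- names(object@differentialSets)
    for (i in seq_along(th)) {
        ds <- object@differentialSets[[i]]
        ss <- object@specificSets[[i]]
        for (s in names(ss))
            if (!all(ss[[s]] %in% ds[[s]]))
                msg <- c(msg, "specific sets must be subsets of differential sets")
    }
    if (length(msg)) unique(msg) else TRUE
})
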