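#' @include AllClasses.R AllGenerics.R
NULL

#' Culture expansion factor
#'
#' The dimensionless fold-increase of the population over the growth
#' interval, measured as the ratio of harvest to inoculation optical
#' density: d = OD600,t2 / OD600,t1.
#'
#' @param odT1,odT2 optical densities at inoculation and harvest (> 0).
#' @return the expansion factor, a positive real.
#' @examples
#' expansionFactor(0.05, 6.06)  # 121.2
#' @export
expansionFactor <- function(odT1, odT2) {
    if (any(!is.finite(odT1)) || any(odT1 <= 0) ||
        any(!is.finite(odT2)) || any(odT2 <= 0))
        stop("optical densities must be positive")
    odT2 / odT1
}

#' Per-gene read proportions within a sample
#'
#' @param counts non-negative counts for one sample (positive total).
#' @return proportions summing to 1, names preserved.
#' @export
geneProportions <- function(counts) {
    if (any(counts < 0))
        stop("counts must be non-negative")
    total <- sum(counts)
    if (!is.finite(total) || total <= 0)
        stop("sample total must be positive")
    counts / total
}

#' Competitive fitness of a mutant lineage
#'
#' The log-ratio fitness statistic for a pooled competition: the natural
#' log of the lineage's own expansion over the interval divided by the
#' natural log of the expansion of the rest of the population,
#' \deqn{W = \frac{\ln(n_{t2} \, d / n_{t1})}
#'                {\ln((1-n_{t2}) \, d / (1-n_{t1}))}}
#' where \eqn{n_{t1}}, \eqn{n_{t2}} are the gene's read proportions before
#' and after growth and \eqn{d} is the population expansion factor. W = 1
#' is neutral, W = 0 means the lineage did not grow at all, W > 1 an
#' advantage.
#'
#' A zero t2 proportion makes W undefined (the lineage vanished at an
#' unknown point in the interval); callers must flag such genes rather
#' than substitute a number, and this function refuses to compute them.
#'
#' @param nT1,nT2 proportions, each strictly inside (0, 1); vectorised.
#' @param d expansion factor(s) > 0.
#' @return fitness value(s), finite reals.
#' @examples
#' fitnessW(0.001, 0.001, 100)    # 1: neutral
#' fitnessW(0.001, 0.00001, 100)  # 0: lineage did not grow
#' @export
fitnessW <- function(nT1, nT2, d) {
    if (any(!is.finite(nT1)) || any(nT1 <= 0) || any(nT1 >= 1))
        stop("nT1 must lie strictly inside (0, 1)")
    if (any(!is.finite(nT2)) || any(nT2 >= 1))
        stop("nT2 must be < 1")
    if (any(nT2 <= 0))
        stop("undefined fitness: zero t2 proportion must be flagged, ",
             "not computed")
    if (any(!is.finite(d)) || any(d <= 0))
        stop("d must be positive")
    num <- log(nT2 * d / nT1)
    den <- log((1 - nT2) * d / (1 - nT1))
    if (any(den == 0))
        stop("degenerate sample: rest of population unexpanded ",
             "(denominator log is zero)")
    num / den
}

#' Per-gene, per-replicate fitness with exclusion flags
#'
#' Computes the fitness statistic for every gene in every condition and
#' replicate, using each replicate's own expansion factor, and applies the
#' two exclusion flags: \code{flag_low_t1} when the gene's mean t1 count
#' is at or below \code{minT1Count} (genes are kept only when strictly
#' above it), and \code{flag_zero} when any relevant sample (any t1
#' sample, or any t2 replicate of that condition) has a zero count. A
#' replicate involving a zero count gets an \code{NA} fitness, and
#' \code{mean_w} / \code{replicate_distance} are computed only when every
#' replicate is present. With several t1 samples their proportion vectors
#' are averaged.
#'
#' @param t1 genes x t1-samples count matrix (usually one column), gene
#'   rownames required.
#' @param t2 genes x t2-samples count matrix, same genes as \code{t1}.
#' @param meta data.frame with one row per t2 sample: \code{sample_id}
#'   (matching \code{colnames(t2)}), \code{condition}, \code{replicate}
#'   and \code{d}.
#' @param minT1Count exclusion threshold on the mean t1 count (default 50;
#'   genes kept when strictly greater).
#' @param ... unused.
#' @return a \linkS4class{FitnessTable}.
#' @export
setMethod("fitnessTable", signature(t1 = "matrix", t2 = "matrix",
                                    meta = "data.frame"),
          function(t1, t2, meta, minT1Count = 50, ...) {
    if (is.null(rownames(t1)) || is.null(rownames(t2)))
        stop("count matrices must have gene rownames")
    if (!identical(rownames(t1), rownames(t2)))
        stop("t1 and t2 tables must share the same gene_ids in the ",
             "same order")
    need <- c("sample_id", "condition", "replicate", "d")
    miss <- setdiff(need, colnames(meta))
    if (length(miss))
        stop("meta lacks columns: ", paste(miss, collapse = ", "))
    if (!all(colnames(t2) %in% meta$sample_id))
        stop("missing SampleMeta for t2 sample(s): ",
             paste(setdiff(colnames(t2), meta$sample_id), collapse = ", "))
    meta <- meta[match(colnames(t2), meta$sample_id), , drop = FALSE]
    if (any(!is.finite(meta$d)) || any(meta$d <= 0))
        stop("missing or non-positive expansion factor d")

    genes <- rownames(t1)
    t1props <- apply(t1, 2L, geneProportions)
    n1 <- rowMeans(t1props)
    meanT1 <- rowMeans(t1)
    lowT1 <- meanT1 <= minT1Count
    zeroT1 <- apply(t1 == 0, 1L, any)

    conds <- unique(meta$condition)
    recs <- vector("list", length(conds))
    maxRep <- max(table(meta$condition))
    wcols <- sprintf("w_rep%d", seq_len(maxRep))
    for (ci in seq_along(conds)) {
        cond <- conds[ci]
        sel <- which(meta$condition == cond)
        sel <- sel[order(meta$replicate[sel])]
        wm <- matrix(NA_real_, length(genes), maxRep)
        zero <- zeroT1
        for (k in seq_along(sel)) {
            cts <- t2[, sel[k]]
            n2 <- geneProportions(cts)
            d <- meta$d[sel[k]]
            ok <- !zeroT1 & cts > 0 & n1 > 0 & n1 < 1 & n2 < 1
            wm[ok, k] <- fitnessW(n1[ok], n2[ok], d)
            zero <- zero | cts == 0
        }
        used <- seq_along(sel)
        complete <- rowSums(!is.na(wm[, used, drop = FALSE])) ==
            length(used)
        meanw <- ifelse(complete,
                        rowMeans(wm[, used, drop = FALSE]), NA_real_)
        dist <- ifelse(complete, .maxPairwiseDiff(wm[, used, drop = FALSE]),
                       NA_real_)
        df <- data.frame(gene_id = genes, condition = cond,
                         stringsAsFactors = FALSE)
        for (k in seq_len(maxRep)) df[[wcols[k]]] <- wm[, k]
        df$mean_w <- meanw
        df$replicate_distance <- dist
        df$flag_low_t1 <- lowT1
        df$flag_zero <- zero
        recs[[ci]] <- df
    }
    out <- new("FitnessTable", records = do.call(rbind, recs))
    validObject(out)
    out
})

.maxPairwiseDiff <- function(wm) {
    if (ncol(wm) == 1L) return(rep(0, nrow(wm)))
    apply(wm, 1L, function(v) {
        v <- v[!is.na(v)]
        if (length(v) < 2L) 0 else max(v) - min(v)
    })
}

#' @describeIn fitnessTable splits a \linkS4class{TnSeqExperiment} into
#'   its t1 and t2 samples by the \code{timepoint} metadata column and
#'   dispatches to the matrix method; \code{meta} is taken from
#'   \code{colData}.
#' @param experiment a \linkS4class{TnSeqExperiment} (passed as \code{t1}).
#' @export
setMethod("fitnessTable", signature(t1 = "TnSeqExperiment", t2 = "missing",
                                    meta = "missing"),
          function(t1, t2, meta, minT1Count = 50, ...) {
    se <- t1
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    cts <- SummarizedExperiment::assay(se, "counts")
    is1 <- cd$timepoint == "t1"
    if (!any(is1) || all(is1))
        stop("experiment must contain both t1 and t2 samples")
    fitnessTable(cts[, is1, drop = FALSE], cts[, !is1, drop = FALSE],
                 cd[!is1, , drop = FALSE], minT1Count = minT1Count)
})

#' Read and write fitness tables as TSV
#'
#' Columns: gene_id, condition, w_rep1..k, mean_w, replicate_distance,
#' flag_low_t1, flag_zero. W values are written with 6 decimal places;
#' analyses should be run on the in-memory table, which keeps full
#' precision.
#'
#' @param path file path.
#' @return \code{readFitnessTable}: a \linkS4class{FitnessTable}.
#' @export
readFitnessTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    for (col in c("flag_low_t1", "flag_zero"))
        if (col %in% colnames(df)) df[[col]] <- as.logical(df[[col]])
    out <- new("FitnessTable", records = df)
    validObject(out)
    out
}

#' @rdname readFitnessTable
#' @param x a \linkS4class{FitnessTable}.
#' @param digits decimal places for numeric columns (default 6).
#' @export
writeFitnessTable <- function(x, path, digits = 6) {
    rec <- fitnessRecords(x)
    num <- vapply(rec, is.numeric, logical(1L))
    rec[num] <- lapply(rec[num], function(v) round(v, digits))
    utils::write.table(rec, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
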