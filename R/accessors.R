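#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn TrueLibrary-class gene identifiers.
#' @param x,object a \code{TrueLibrary}.
#' @param ... unused.
#' @export
setMethod("geneIds", "TrueLibrary", function(x, ...) x@geneIds)

#' @describeIn TrueLibrary-class per-gene ground-truth fitness.
#' @export
setMethod("trueFitness", "TrueLibrary", function(x, ...) x@trueFitness)

#' @describeIn TrueLibrary-class t1 abundances normalised to proportions
#'   summing to 1.
#' @export
setMethod("t1Proportions", "TrueLibrary",
          function(x, ...) {
              p <- x@t1Abundance / sum(x@t1Abundance)
              names(p) <- x@geneIds
              p
          })

#' @describeIn TrueLibrary-class neutral-lineage fold expansion E.
#' @export
setMethod("backgroundExpansion", "TrueLibrary",
          function(x, ...) x@backgroundExpansion)

setMethod("show", "TrueLibrary", function(object) {
    n <- length(object@geneIds)
    ndel <- sum(object@trueFitness < 1)
    cat("TrueLibrary with", n, "genes\n")
    cat("  non-neutral (W_true < 1):", ndel, "\n")
    cat("  background expansion E:", format(object@backgroundExpansion), "\n")
    cat("  seed:", object@seed, "\n")
})

#' @describeIn FitnessTable-class the underlying records as a base
#'   \code{data.frame} (columns \code{gene_id}, \code{condition},
#'   \code{w_rep1}..., \code{mean_w}, \code{replicate_distance},
#'   \code{flag_low_t1}, \code{flag_zero}).
#' @param x,object a \code{FitnessTable}.
#' @param ... unused.
#' @export
setMethod("fitnessRecords", "FitnessTable", function(x, ...) x@records)

#' @describeIn FitnessTable-class unique gene identifiers, in table order.
#' @export
setMethod("geneIds", "FitnessTable",
          function(x, ...) unique(x@records$gene_id))

#' @describeIn FitnessTable-class condition labels present in the table.
#' @export
setMethod("conditions", "FitnessTable",
          function(x, ...) unique(x@records$condition))

#' @describeIn FitnessTable-class genes x conditions matrix of mean fitness
#'   (\code{NA} where undefined); restricted to \code{condition} when given.
#' @param condition optional condition label(s) to restrict to.
#' @export
setMethod("meanW", "FitnessTable", function(x, condition = NULL, ...) {
    .recordMatrix(x, "mean_w", condition)
})

#' @describeIn FitnessTable-class genes x conditions matrix of replicate
#'   distances.
#' @export
setMethod("replicateDistance", "FitnessTable",
          function(x, condition = NULL, ...) {
    .recordMatrix(x, "replicate_distance", condition)
})

.recordMatrix <- function(x, col, condition = NULL) {
    rec <- x@records
    genes <- unique(rec$gene_id)
    conds <- unique(rec$condition)
    if (!is.null(condition)) {
        bad <- setdiff(condition, conds)
        if (length(bad))
            stop("condition(s) not in table: ", paste(bad, collapse = ", "))
        conds <- condition
    }
    m <- matrix(NA_real_, length(genes), length(conds),
                dimnames = list(genes, conds))
    keep <- rec$condition %in% conds
    m[cbind(match(rec$gene_id[keep], genes),
            match(rec$condition[keep], conds))] <- rec[[col]][keep]
    m
}

setMethod("show", "FitnessTable", function(object) {
    rec <- object@records
    cat("FitnessTable:", length(unique(rec$gene_id)), "genes x",
        length(unique(rec$condition)), "conditions\n")
    nw <- length(grep("^w_rep[0-9]+$", colnames(rec)))
    cat("  replicates per condition:", nw, "\n")
    cat("  flagged low t1:",
        length(unique(rec$gene_id[rec$flag_low_t1])), "genes;",
        "flagged zero:", length(unique(rec$gene_id[rec$flag_zero])),
        "genes\n")
})

#' @describeIn CascadeReport-class ordered per-stage surviving-gene counts.
#' @param x,object a \code{CascadeReport}.
#' @param ... unused.
#' @export
setMethod("stageCounts", "CascadeReport", function(x, ...) x@stageCounts)

#' @describeIn CascadeReport-class the two parallel counts on the complete
#'   set (baseline-neutral and replicate-concordant).
#' @export
setMethod("parallelCounts", "CascadeReport", function(x, ...) x@parallelCounts)

#' @describeIn CascadeReport-class per-substrate differential gene sets;
#'   nested list, threshold key then substrate.
#' @export
setMethod("differentialSets", "CascadeReport",
          function(x, ...) x@differentialSets)

#' @describeIn CascadeReport-class per-substrate substrate-specific gene
#'   sets; nested list, threshold key then substrate.
#' @export
setMethod("specificSets", "CascadeReport", function(x, ...) x@specificSets)

setMethod("show", "CascadeReport", function(object) {
    cat("CascadeReport\n  stages:\n")
    sc <- object@stageCounts
    for (i in seq_along(sc))
        cat(sprintf("    %-22s %d\n", names(sc)[i], sc[i]))
    pc <- object@parallelCounts
    cat("  parallel counts on complete set:\n")
    for (i in seq_along(pc))
        cat(sprintf("    %-22s %d\n", names(pc)[i], pc[i]))
})
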