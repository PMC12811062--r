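## Build a FitnessTable directly from per-condition matrices of replicate
## fitness values; used to hand-craft cascade inputs without running the
## estimator.
makeFitnessFixture <- function(w1, w2, lowT1 = NULL, zero = NULL) {
    genes <- rownames(w1)
    conds <- colnames(w1)
    stopifnot(identical(dim(w1), dim(w2)))
    if (is.null(lowT1)) lowT1 <- matrix(FALSE, nrow(w1), ncol(w1))
    if (is.null(zero)) zero <- matrix(FALSE, nrow(w1), ncol(w1))
    recs <- lapply(seq_along(conds), function(ci) {
        a <- w1[, ci]
        b <- w2[, ci]
        absent <- zero[, ci]
        a[absent] <- NA_real_
        b[absent] <- NA_real_
        data.frame(gene_id = genes, condition = conds[ci],
                   w_rep1 = a, w_rep2 = b,
                   mean_w = ifelse(absent, NA_real_, (a + b) / 2),
                   replicate_distance = ifelse(absent, NA_real_, abs(a - b)),
                   flag_low_t1 = lowT1[, ci], flag_zero = zero[, ci],
                   stringsAsFactors = FALSE)
    })
    new("FitnessTable", records = do.call(rbind, recs))
}

## Random small fitness table for oracle-equivalence testing.
randomFitnessFixture <- function(nGenes, conds = c("sucrose", "acetate",
                                                   "succinate", "glycerol")) {
    genes <- sprintf("g%03d", seq_len(nGenes))
    w1 <- matrix(stats::rnorm(nGenes * length(conds), 1, 0.25),
                 nGenes, length(conds), dimnames = list(genes, conds))
    w2 <- w1 + matrix(stats::rnorm(nGenes * length(conds), 0, 0.12),
                      nGenes, length(conds))
    lowT1 <- matrix(rep(stats::runif(nGenes) < 0.08, length(conds)),
                    nGenes, length(conds))
    zero <- matrix(stats::runif(nGenes * length(conds)) < 0.05,
                   nGenes, length(conds))
    makeFitnessFixture(w1, w2, lowT1, zero)
}

## Minimal GFF3 writer for annotation fixtures.
writeToyGff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
    writeLines(c("##gff-version 3", lines), path)
    path
}
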