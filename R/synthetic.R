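#' @include AllClasses.R AllGenerics.R
NULL

#' Generate a ground-truth transposon library
#'
#' Builds a synthetic insertion-mutant pool with known per-gene fitness.
#' A fraction \code{fracDeleterious} of genes (rounded to the nearest
#' count, chosen uniformly at random under \code{seed}) receive a fitness
#' drawn uniformly from \code{deleteriousFitnessRange}; every other gene is
#' exactly neutral (fitness 1). t1 abundances are drawn log-normally
#' (meanlog 0, sdlog \code{abundanceDispersion}), a right-skewed
#' distribution emulating the uneven insertion representation of real
#' transposon pools; the default dispersion 1.4 places roughly 1-2% of a
#' 5,000-gene pool below 50 reads at a 15M-read sequencing depth.
#'
#' @param nGenes number of genes (>= 2).
#' @param fracDeleterious fraction of genes made non-neutral, in [0, 1).
#' @param deleteriousFitnessRange length-2 numeric, the uniform range
#'   (within [0, 1)) deleterious fitness values are drawn from.
#' @param abundanceDispersion sdlog of the log-normal t1 abundance
#'   distribution; must be positive... 0 is allowed and yields a uniform
#'   pool.
#' @param backgroundExpansion fold-expansion E of a neutral lineage over
#'   the growth interval; must exceed 1. Default 121.1, a typical
#'   seven-generation OD600 ratio.
#' @param seed integer seed; the library is fully reproducible from it.
#'
#' @return a \linkS4class{TrueLibrary}.
#' @examples
#' lib <- makeLibrary(100, fracDeleterious = 0.1, seed = 1)
#' sum(trueFitness(lib) < 1)
#' @export
makeLibrary <- function(nGenes,
                        fracDeleterious = 0.1,
                        deleteriousFitnessRange = c(0, 0.6),
                        abundanceDispersion = 1.4,
                        backgroundExpansion = 121.1,
                        seed = 1L) {
    .assertScalarNumeric(nGenes, "nGenes", lower = 2)
    .assertScalarNumeric(fracDeleterious, "fracDeleterious", lower = 0)
    if (fracDeleterious >= 1)
        stop("fracDeleterious must be < 1")
    if (length(deleteriousFitnessRange) != 2L ||
        any(deleteriousFitnessRange < 0) ||
        deleteriousFitnessRange[1L] > deleteriousFitnessRange[2L])
        stop("deleteriousFitnessRange must be c(lo, hi) with 0 <= lo <= hi")
    .assertScalarNumeric(abundanceDispersion, "abundanceDispersion", lower = 0)
    .assertScalarNumeric(backgroundExpansion, "backgroundExpansion",
                         lower = 1, strict_lower = TRUE)
    nGenes <- as.integer(nGenes)
    nDel <- as.integer(.roundHalfAway(fracDeleterious * nGenes))
    .withSeed(seed, {
        fit <- rep(1, nGenes)
        if (nDel > 0L) {
            idx <- sample.int(nGenes, nDel)
            fit[idx] <- stats::runif(nDel,
                                     deleteriousFitnessRange[1L],
                                     deleteriousFitnessRange[2L])
        }
        ab <- stats::rlnorm(nGenes, meanlog = 0,
                            sdlog = abundanceDispersion)
        new("TrueLibrary",
            geneIds = sprintf("gene_%05d", seq_len(nGenes)),
            trueFitness = fit,
            t1Abundance = ab,
            backgroundExpansion = backgroundExpansion,
            seed = as.integer(seed))
    })
}

#' Construct a TrueLibrary with explicit ground truth
#'
#' Direct constructor for hand-specified libraries (e.g. a single planted
#' non-neutral gene); [makeLibrary()] is the random generator.
#'
#' @param geneIds unique gene identifiers.
#' @param trueFitness per-gene fitness, finite and non-negative.
#' @param t1Abundance per-gene positive relative abundance (normalised to
#'   proportions internally).
#' @param backgroundExpansion neutral-lineage fold expansion, > 1.
#' @param seed integer recorded for provenance (no randomness is used).
#' @return a \linkS4class{TrueLibrary}.
#' @export
trueLibrary <- function(geneIds, trueFitness, t1Abundance,
                        backgroundExpansion = 121.1, seed = 0L) {
    obj <- new("TrueLibrary", geneIds = as.character(geneIds),
               trueFitness = as.numeric(trueFitness),
               t1Abundance = as.numeric(t1Abundance),
               backgroundExpansion = backgroundExpansion,
               seed = as.integer(seed))
    validObject(obj)
    obj
}

#' Expected t2 proportions under the generative growth model
#'
#' Deterministic forward model: over the growth interval gene i's lineage
#' expands by \code{E^W_i}, so its unnormalised t2 mass is its t1
#' proportion times \code{E^W_i}. The realised total expansion (the sum of
#' those masses) is the population-level expansion factor \code{d} that an
#' OD measurement would report; with every gene neutral it equals \code{E}
#' exactly and the proportions are unchanged.
#'
#' @param lib a \linkS4class{TrueLibrary}.
#' @param fitness optional fitness vector overriding the library's ground
#'   truth (used to impose condition-specific effects).
#' @param expansion optional neutral-lineage expansion overriding the
#'   library's \code{backgroundExpansion} (used for replicate jitter).
#'
#' @return list with \code{proportions} (named, summing to 1) and
#'   \code{realizedExpansion}.
#' @export
expectedT2Proportions <- function(lib, fitness = trueFitness(lib),
                                  expansion = backgroundExpansion(lib)) {
    stopifnot(is(lib, "TrueLibrary"))
    validObject(lib)
    if (length(fitness) != length(geneIds(lib)))
        stop("fitness must have one value per gene")
    if (any(!is.finite(fitness)) || any(fitness < 0))
        stop("fitness must be finite and non-negative")
    .assertScalarNumeric(expansion, "expansion", lower = 1,
                         strict_lower = TRUE)
    p1 <- t1Proportions(lib)
    mass <- p1 * expansion^fitness
    total <- sum(mass)
    list(proportions = mass / total, realizedExpansion = total)
}

#' Multinomially sample read counts from proportions
#'
#' @param proportions per-gene proportions summing to 1 (tolerance 1e-8).
#' @param depth total reads to draw (>= 1).
#' @param seed integer seed.
#' @return integer counts, same names as \code{proportions}, summing
#'   exactly to \code{depth}.
#' @export
sampleCounts <- function(proportions, depth, seed = 1L) {
    if (abs(sum(proportions) - 1) > 1e-8)
        stop("proportions must sum to 1")
    if (any(proportions < 0))
        stop("proportions must be non-negative")
    .assertScalarNumeric(depth, "depth", lower = 1)
    cts <- .withSeed(seed,
        stats::rmultinom(1L, size = as.integer(depth), prob = proportions))
    stats::setNames(as.integer(cts[, 1L]), names(proportions))
}

#' Simulate a full carbon-shift Tn-seq experiment
#'
#' Emulates the pooled competition design: one shared t1 sample (the
#' library pre-grown on the isolation medium) and, for each condition x
#' replicate, an independent t2 sample taken after the growth interval.
#' Each replicate's neutral-lineage expansion is jittered multiplicatively
#' (uniform within \code{1 +/- expansionJitter}) and the *realised*
#' population expansion — what an OD600 ratio would report — is recorded as
#' that sample's \code{d}, with a synthetic OD pair (\code{odT1},
#' \code{odT1 * d}) consistent with it.
#'
#' With \code{depth = 0} the simulator runs in noise-free mode: instead of
#' multinomial sampling it emits exact expected proportions scaled to
#' \code{nominalDepth} as real-valued "counts". This mode exists for
#' estimator-inversion testing only and is not a model of sequencing.
#'
#' @param lib a \linkS4class{TrueLibrary}.
#' @param conditions character vector of distinct condition labels.
#' @param replicates replicates per condition (>= 1).
#' @param depth reads per sample (multinomial), or 0 for noise-free mode.
#' @param seed integer seed.
#' @param conditionFitness optional genes x conditions numeric matrix (or
#'   named list of per-gene vectors) of condition-specific true fitness;
#'   defaults to the library's single fitness vector in every condition.
#' @param expansionJitter half-width of the relative jitter on E per
#'   replicate (default 0.05, i.e. +/- 5%).
#' @param nominalDepth scale for noise-free counts (default 1.5e7).
#' @param odT1 synthetic inoculation OD600 (default 0.05).
#' @param nitrogen nitrogen status recorded in the metadata.
#'
#' @return a \linkS4class{TnSeqExperiment} with one t1 column and
#'   \code{length(conditions) * replicates} t2 columns.
#' @export
simulateExperiment <- function(lib,
                               conditions = c("acetate", "succinate",
                                              "glycerol", "sucrose"),
                               replicates = 2L,
                               depth = 15e6,
                               seed = 1L,
                               conditionFitness = NULL,
                               expansionJitter = 0.05,
                               nominalDepth = 1.5e7,
                               odT1 = 0.05,
                               nitrogen = "diazotrophic") {
    stopifnot(is(lib, "TrueLibrary"))
    validObject(lib)
    if (!length(conditions) || anyDuplicated(conditions))
        stop("conditions must be a non-empty set of distinct labels")
    .assertScalarNumeric(replicates, "replicates", lower = 1)
    .assertScalarNumeric(depth, "depth", lower = 0)
    .assertScalarNumeric(expansionJitter, "expansionJitter", lower = 0)
    replicates <- as.integer(replicates)
    genes <- geneIds(lib)
    nG <- length(genes)

    fitMat <- .conditionFitnessMatrix(lib, conditions, conditionFitness)
    noiseFree <- depth == 0
    sampleDepth <- if (noiseFree) nominalDepth else depth

    .withSeed(seed, {
        p1 <- t1Proportions(lib)
        t1cts <- if (noiseFree) p1 * sampleDepth else
            as.numeric(stats::rmultinom(1L, as.integer(depth), p1))
        cols <- list(t1 = t1cts)
        meta <- list(data.frame(
            sample_id = "t1", condition = "library", nitrogen = nitrogen,
            replicate = 1L, timepoint = "t1", od_t1 = odT1, od_t2 = odT1,
            d = 1, mapped_reads = sampleDepth,
            stringsAsFactors = FALSE))
        for (cond in conditions) {
            for (r in seq_len(replicates)) {
                E <- backgroundExpansion(lib) *
                    stats::runif(1L, 1 - expansionJitter, 1 + expansionJitter)
                exp2 <- expectedT2Proportions(lib, fitness = fitMat[, cond],
                                              expansion = E)
                cts <- if (noiseFree) exp2$proportions * sampleDepth else
                    as.numeric(stats::rmultinom(1L, as.integer(depth),
                                                exp2$proportions))
                sid <- sprintf("%s_rep%d", cond, r)
                cols[[sid]] <- cts
                meta[[length(meta) + 1L]] <- data.frame(
                    sample_id = sid, condition = cond, nitrogen = nitrogen,
                    replicate = r, timepoint = "t2", od_t1 = odT1,
                    od_t2 = odT1 * exp2$realizedExpansion,
                    d = exp2$realizedExpansion, mapped_reads = sampleDepth,
                    stringsAsFactors = FALSE)
            }
        }
        counts <- do.call(cbind, cols)
        rownames(counts) <- genes
        cd <- do.call(rbind, meta)
        rownames(cd) <- cd$sample_id
        TnSeqExperiment(counts, cd)
    })
}

.conditionFitnessMatrix <- function(lib, conditions, conditionFitness) {
    genes <- geneIds(lib)
    if (is.null(conditionFitness)) {
        m <- matrix(trueFitness(lib), length(genes), length(conditions),
                    dimnames = list(genes, conditions))
        return(m)
    }
    if (is.list(conditionFitness))
        conditionFitness <- do.call(cbind, conditionFitness)
    if (!is.matrix(conditionFitness) ||
        nrow(conditionFitness) != length(genes))
        stop("conditionFitness must be a genes x conditions matrix")
    miss <- setdiff(conditions, colnames(conditionFitness))
    if (length(miss))
        stop("conditionFitness lacks conditions: ",
             paste(miss, collapse = ", "))
    m <- conditionFitness[, conditions, drop = FALSE]
    rownames(m) <- genes
    m
}

#' Construct a TnSeqExperiment
#'
#' @param counts genes x samples matrix of non-negative counts (real-valued
#'   allowed for noise-free simulated data).
#' @param meta data.frame of per-sample metadata, one row per column of
#'   \code{counts}, with the columns listed in
#'   \linkS4class{TnSeqExperiment}.
#' @return a \linkS4class{TnSeqExperiment}.
#' @export
TnSeqExperiment <- function(counts, meta) {
    if (!is.matrix(counts))
        counts <- as.matrix(counts)
    if (nrow(meta) != ncol(counts))
        stop("meta must have one row per sample column")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
    obj <- new("TnSeqExperiment", se)
    validObject(obj)
    obj
}

#' Write simulator ground truth as TSV
#'
#' Columns: gene_id, true_fitness, t1_proportion.
#' @param lib a \linkS4class{TrueLibrary}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(lib, path) {
    df <- data.frame(gene_id = geneIds(lib),
                     true_fitness = trueFitness(lib),
                     t1_proportion = as.numeric(t1Proportions(lib)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
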