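#' @include AllClasses.R AllGenerics.R
NULL

#' Summarise mapped-read totals across samples
#'
#' @param x numeric vector of per-sample mapped-read totals, or a
#'   data.frame with a \code{mapped_reads} column.
#' @return named numeric \code{c(min, mean, max)}; min and max exact,
#'   the mean rounded to the nearest integer, half away from zero.
#' @examples
#' summarizeReads(c(100, 200, 301))
#' @export
summarizeReads <- function(x) {
    if (is.data.frame(x)) {
        if (!"mapped_reads" %in% colnames(x))
            stop("data.frame input must carry a mapped_reads column")
        x <- x$mapped_reads
    }
    if (!length(x))
        stop("no samples to summarise")
    if (any(!is.finite(x)) || any(x < 0))
        stop("mapped-read totals must be non-negative")
    c(min = min(x), mean = .roundHalfAway(mean(x)), max = max(x))
}

#' Path to the packaged harvest-sample table
#'
#' The six t2 carbon-shift samples (acetate, succinate and glycerol, in
#' duplicate): harvest OD600, expansion factor and mapped-read totals,
#' with the inoculation OD back-computed from the expansion factor.
#'
#' @return file path of the TSV, readable with [readSampleMeta()].
#' @export
table1SamplePath <- function() {
    system.file("extdata", "table1_samples.tsv", package = "tnfit",
                mustWork = TRUE)
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate (or load) -> fitness -> cascade and writes all
#' artifacts plus a run manifest to \code{outDir}. The configuration is a
#' list (or path to a YAML file) with either a \code{simulate} block
#' (\code{genes}, \code{depth}, \code{conditions}, \code{replicates},
#' \code{frac_deleterious}, ...) or an \code{inputs} block (\code{counts},
#' \code{meta}: TSV paths, the count table containing both the t1 and t2
#' samples named in the metadata), plus optional \code{fitness}
#' (\code{min_t1_count}) and \code{cascade} (\code{baseline},
#' \code{neutral_band}, \code{max_replicate_distance}, \code{thresholds})
#' blocks. Outputs are deterministic given the configuration and seed;
#' the manifest is written last so its presence marks a completed run.
#'
#' @param config list or path to a YAML config file.
#' @param outDir output directory (created if needed).
#' @param seed integer seed overriding \code{config$seed} (default 1).
#' @return invisibly, a list with the \linkS4class{FitnessTable}, the
#'   \linkS4class{CascadeReport} and the manifest list.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
    if (is.character(config)) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    if (is.null(seed)) seed <- config$seed
    if (is.null(seed)) seed <- 1L
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    digests <- list()

    if (!is.null(config$simulate)) {
        sim <- config$simulate
        lib <- makeLibrary(
            nGenes = sim$genes %||% 5000,
            fracDeleterious = sim$frac_deleterious %||% 0.1,
            deleteriousFitnessRange =
                unlist(sim$deleterious_fitness_range) %||% c(0, 0.6),
            abundanceDispersion = sim$abundance_dispersion %||% 1.4,
            backgroundExpansion = sim$background_expansion %||% 121.1,
            seed = seed)
        se <- simulateExperiment(
            lib,
            conditions = unlist(sim$conditions) %||%
                c("acetate", "succinate", "glycerol", "sucrose"),
            replicates = sim$replicates %||% 2L,
            depth = sim$depth %||% 15e6,
            seed = seed)
        counts <- SummarizedExperiment::assay(se, "counts")
        meta <- as.data.frame(SummarizedExperiment::colData(se))
        writeGroundTruth(lib, file.path(outDir, "ground_truth.tsv"))
        writeCountTable(counts, file.path(outDir, "counts.tsv"))
        writeSampleMeta(meta, file.path(outDir, "meta.tsv"))
    } else if (!is.null(config$inputs)) {
        for (f in unlist(config$inputs))
            if (!file.exists(f))
                stop("input file not found: ", f)
        counts <- readCountTable(config$inputs$counts)
        meta <- readSampleMeta(config$inputs$meta)
        digests <- as.list(tools::md5sum(unlist(config$inputs)))
    } else {
        stop("config must contain a 'simulate' or an 'inputs' block")
    }

    is1 <- meta$timepoint == "t1"
    if (!any(is1) || all(is1))
        stop("metadata must name both t1 and t2 samples")
    if (!all(meta$sample_id %in% colnames(counts)))
        stop("count table lacks sample(s): ",
             paste(setdiff(meta$sample_id, colnames(counts)),
                   collapse = ", "))
    minT1 <- config$fitness$min_t1_count %||% 50
    ft <- fitnessTable(counts[, meta$sample_id[is1], drop = FALSE],
                       counts[, meta$sample_id[!is1], drop = FALSE],
                       meta[!is1, , drop = FALSE], minT1Count = minT1)
    writeFitnessTable(ft, file.path(outDir, "fitness.tsv"))

    cc <- config$cascade
    cfg <- filterConfig(
        baselineCondition = cc$baseline %||% "sucrose",
        neutralBand = unlist(cc$neutral_band) %||% c(0.9, 1.1),
        maxReplicateDistance = cc$max_replicate_distance %||% 0.2,
        differenceThresholds = unlist(cc$thresholds) %||% c(0.2, 0.3, 0.4),
        minT1Count = minT1)
    report <- runCascade(ft, cfg)
    writeCascadeReport(report, outDir)

    reads <- summarizeReads(meta[!is1, , drop = FALSE])
    manifest <- list(
        tool = "tnfit",
        version = as.character(utils::packageVersion("tnfit")),
        seed = as.integer(seed),
        config = config,
        input_digests = digests,
        mapped_reads = list(min = reads[["min"]], mean = reads[["mean"]],
                            max = reads[["max"]],
                            per_sample = stats::setNames(
                                as.list(meta$mapped_reads[!is1]),
                                meta$sample_id[!is1])),
        stage_counts = as.list(stageCounts(report)),
        parallel_counts = as.list(parallelCounts(report)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(fitness = ft, cascade = report, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
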