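#' @include AllClasses.R
#' @importFrom GenomicRanges GRanges findOverlaps start end width strand
#' @importFrom IRanges IRanges
NULL

#' Read gene models from a GFF3 file
#'
#' Thin wrapper around \code{rtracklayer::import} with a line-level
#' pre-validation pass so that malformed feature lines are reported with
#' their line number. Coordinates are kept 1-based inclusive (the GFF3
#' convention, used throughout this package).
#'
#' @param path path to a GFF3 file.
#' @param featureType feature type(s) to keep (default \code{"gene"}).
#' @param idAttribute attribute(s) tried in order for the gene identifier
#'   (default \code{locus_tag} then \code{ID}).
#' @return a \code{GRanges}, one range per selected feature, with metadata
#'   columns \code{gene_id} and \code{name}.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1;locus_tag=Avin_00010"), gff)
#' readGff3(gff)
#' @export
readGff3 <- function(path, featureType = "gene",
                     idAttribute = c("locus_tag", "ID")) {
    .validateGff3Lines(path)
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) %in% featureType]
    if (!length(gr)) {
        out <- GenomicRanges::GRanges()
        S4Vectors::mcols(out)$gene_id <- character()
        S4Vectors::mcols(out)$name <- character()
        return(out)
    }
    mc <- S4Vectors::mcols(gr)
    ids <- rep(NA_character_, length(gr))
    for (attr in idAttribute) {
        if (attr %in% colnames(mc)) {
            val <- as.character(mc[[attr]])
            ids[is.na(ids) & !is.na(val)] <- val[is.na(ids) & !is.na(val)]
        }
    }
    if (anyNA(ids))
        stop("features without any of the identifier attributes: ",
             paste(idAttribute, collapse = ", "))
    if (anyDuplicated(ids))
        stop("duplicate gene_id in annotation: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    bad <- !as.character(GenomicRanges::strand(gr)) %in% c("+", "-")
    if (any(bad))
        stop("gene feature(s) without +/- strand: ",
             paste(ids[bad], collapse = ", "))
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out)$gene_id <- ids
    nm <- if ("Name" %in% colnames(mc)) as.character(mc$Name)
          else rep(NA_character_, length(gr))
    S4Vectors::mcols(out)$name <- nm
    names(out) <- ids
    out
}

.validateGff3Lines <- function(path) {
    lines <- readLines(path, warn = FALSE)
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (ln == "" || startsWith(ln, "#")) {
            if (startsWith(ln, "##FASTA")) break
            next
        }
        f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        if (length(f) != 9L)
            stop("malformed GFF3 line ", i, ": expected 9 tab-separated ",
                 "fields, found ", length(f))
        st <- suppressWarnings(as.numeric(f[4L]))
        en <- suppressWarnings(as.numeric(f[5L]))
        if (is.na(st) || is.na(en))
            stop("malformed GFF3 line ", i, ": non-numeric coordinates")
        if (st < 1)
            stop("malformed GFF3 line ", i, ": start must be >= 1")
        if (en < st)
            stop("malformed GFF3 line ", i, ": end < start")
    }
    invisible(TRUE)
}

#' Build an insertion-site GRanges
#'
#' Convenience constructor for per-site read counts: width-1 ranges with a
#' \code{count} metadata column.
#'
#' @param seqId replicon identifier(s).
#' @param position 1-based insertion coordinate(s) (>= 1).
#' @param count non-negative read count(s).
#' @param strand site strand; \code{"*"} (unknown) by default, not used
#'   for gene assignment.
#' @return a \code{GRanges} of width-1 sites.
#' @export
siteCounts <- function(seqId, position, count, strand = "*") {
    if (any(position < 1))
        stop("site positions must be >= 1")
    if (any(count < 0))
        stop("site counts must be non-negative")
    GenomicRanges::GRanges(seqId,
                           IRanges::IRanges(position, width = 1L),
                           strand = strand, count = count)
}

#' Aggregate insertion-site counts to per-gene counts
#'
#' Each site is assigned to every gene whose trimmed interval contains its
#' position; a gene's count is the sum of its assigned site counts. The
#' trimmed interval removes \code{edgeTrim} of the gene length from each
#' end, rounded toward the interior (so trimming never under-removes);
#' with the default \code{edgeTrim = 0} the full gene body is used.
#' Strand is ignored for assignment: a transposon insertion disrupts a
#' gene regardless of orientation. Sites contained in no gene are summed
#' into the reported intergenic total. With \code{overlapMode = "first"} a
#' site in several overlapping genes is credited only to the first gene in
#' annotation order.
#'
#' @param sites a \code{GRanges} from [siteCounts()] (metadata column
#'   \code{count}).
#' @param genes a \code{GRanges} from [readGff3()] (metadata column
#'   \code{gene_id}).
#' @param edgeTrim proportion of the gene length trimmed from each end,
#'   in [0, 0.5).
#' @param overlapMode \code{"all"} (default: every containing gene gets
#'   the count) or \code{"first"}.
#' @param sampleId column name for the returned one-sample count matrix.
#' @return list with \code{counts}, a genes x 1 count matrix (rownames
#'   \code{gene_id}), and \code{intergenic}, the total count of unassigned
#'   sites.
#' @export
aggregateSites <- function(sites, genes, edgeTrim = 0,
                           overlapMode = c("all", "first"),
                           sampleId = "sample1") {
    overlapMode <- match.arg(overlapMode)
    .assertScalarNumeric(edgeTrim, "edgeTrim", lower = 0)
    if (edgeTrim >= 0.5)
        stop("edgeTrim must be < 0.5")
    ids <- genes$gene_id
    if (is.null(ids))
        stop("genes must carry a gene_id metadata column")
    ## trim amount rounded toward the interior; the 1e-9 guard keeps exact
    ## products (e.g. 0.45 * 300) from ceiling up through float error
    trim <- ceiling(edgeTrim * GenomicRanges::width(genes) - 1e-9)
    lo <- GenomicRanges::start(genes) + trim
    hi <- GenomicRanges::end(genes) - trim
    keep <- lo <= hi
    trimmed <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(genes)[keep],
        IRanges::IRanges(lo[keep], hi[keep]))
    hits <- GenomicRanges::findOverlaps(sites, trimmed, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- which(keep)[S4Vectors::subjectHits(hits)]
    if (overlapMode == "first" && length(qh)) {
        ord <- order(qh, sh)
        first <- !duplicated(qh[ord])
        qh <- qh[ord][first]
        sh <- sh[ord][first]
    }
    counts <- numeric(length(genes))
    if (length(qh)) {
        agg <- tapply(sites$count[qh], sh, sum)
        counts[as.integer(names(agg))] <- agg
    }
    assigned <- unique(qh)
    intergenic <- sum(sites$count[setdiff(seq_along(sites), assigned)])
    m <- matrix(counts, ncol = 1L, dimnames = list(ids, sampleId))
    list(counts = m, intergenic = intergenic)
}

#' Read and write gene x sample count tables as TSV
#'
#' The on-disk format is UTF-8 tab-delimited text with a header row: first
#' column \code{gene_id}, then one column per sample. \code{readCountTable}
#' validates that all count cells are numeric and non-negative and that
#' gene and sample identifiers are unique; \code{writeCountTable} followed
#' by \code{readCountTable} reproduces the matrix exactly.
#'
#' @param path file path.
#' @return \code{readCountTable}: a numeric matrix with gene rownames and
#'   sample colnames.
#' @export
readCountTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = NA,
                            stringsAsFactors = FALSE, fill = FALSE)
    if (ncol(df) < 2L || colnames(df)[1L] != "gene_id")
        stop("count table must have a gene_id first column and >= 1 sample")
    genes <- as.character(df[[1L]])
    if (anyDuplicated(genes))
        stop("duplicate gene_id in count table")
    if (anyDuplicated(colnames(df)[-1L]))
        stop("duplicate sample identifiers in count table")
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m) || anyNA(m))
        stop("non-numeric count cell in count table")
    if (any(m < 0))
        stop("negative count in count table")
    storage.mode(m) <- "double"
    rownames(m) <- genes
    m
}

#' @rdname readCountTable
#' @param counts genes x samples numeric matrix, non-negative, with
#'   rownames and colnames.
#' @export
writeCountTable <- function(counts, path) {
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have gene rownames and sample colnames")
    if (any(counts < 0))
        stop("negative count")
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read and write per-sample metadata tables as TSV
#'
#' Columns: sample_id, condition, nitrogen, replicate, timepoint, od_t1,
#' od_t2, d, mapped_reads. \code{readSampleMeta} checks that every
#' expansion factor is positive and, where both ODs are present, equals
#' od_t2/od_t1 within 0.5% relative tolerance.
#'
#' @param path file path.
#' @return \code{readSampleMeta}: a data.frame.
#' @export
readSampleMeta <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    miss <- setdiff(.META_COLS, colnames(df))
    if (length(miss))
        stop("sample metadata lacks columns: ", paste(miss, collapse = ", "))
    if (any(!is.finite(df$d)) || any(df$d <= 0))
        stop("expansion factor d must be positive")
    ok <- is.finite(df$od_t1) & is.finite(df$od_t2) & df$od_t1 > 0
    if (any(ok) &&
        any(abs(df$od_t2[ok] / df$od_t1[ok] - df$d[ok]) / df$d[ok] > 0.005))
        stop("d inconsistent with od_t2/od_t1 (> 0.5% relative)")
    df
}

#' @rdname readSampleMeta
#' @param meta data.frame of sample metadata.
#' @export
writeSampleMeta <- function(meta, path) {
    miss <- setdiff(.META_COLS, colnames(meta))
    if (length(miss))
        stop("sample metadata lacks columns: ", paste(miss, collapse = ", "))
    utils::write.table(as.data.frame(meta)[, .META_COLS], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
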