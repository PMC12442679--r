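#' Assemble a screen count container
#'
#' Wraps an integer guide x sample count matrix in a
#' `SummarizedExperiment` with the library's gene map as row annotation.
#'
#' @param counts integer matrix, rows named by guide_id.
#' @param library optional [SgRNALibrary-class]; when given, the row set must
#'   equal the library's guide set (order taken from the library).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"` and rowData columns `gene_id`, `is_control`.
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData colData
screenCounts <- function(counts, library = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts))) stop("counts must have guide_id rownames")
    if (any(counts < 0)) stop("counts must be nonnegative")
    if (any(counts != round(counts))) stop("counts must be integers")
    storage.mode(counts) <- "integer"
    if (!is.null(library)) {
        missing <- setdiff(guideIds(library), rownames(counts))
        extra <- setdiff(rownames(counts), guideIds(library))
        if (length(extra))
            stop("guides absent from library: ",
                 paste(head(extra, 5), collapse = ", "))
        if (length(missing)) {
            # guides dropped from a sample are zero-count, not absent
            pad <- matrix(0L, length(missing), ncol(counts),
                          dimnames = list(missing, colnames(counts)))
            counts <- rbind(counts, pad)
        }
        counts <- counts[guideIds(library), , drop = FALSE]
        rd <- DataFrame(gene_id = geneIds(library),
                        is_control = isControl(library))
    } else {
        rd <- DataFrame(gene_id = rep(NA_character_, nrow(counts)),
                        is_control = rep(NA, nrow(counts)))
    }
    SummarizedExperiment(assays = list(counts = counts), rowData = rd)
}

#' Read / write a guide count table
#'
#' Tab-separated text: first column `guide_id`, one integer column per
#' sample. Writing then reading is the identity.
#'
#' @param path file path.
#' @param se a count `SummarizedExperiment` from [screenCounts()].
#' @param library optional [SgRNALibrary-class] to validate the guide set
#'   against.
#' @return `readCounts`: a `SummarizedExperiment`; `writeCounts`: invisibly,
#'   the path.
#' @export
readCounts <- function(path, library = NULL) {
    df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                            comment.char = "", check.names = FALSE)
    if (colnames(df)[1L] != "guide_id")
        stop("first column must be guide_id")
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (any(m != round(m)) || any(!is.finite(m)))
        stop("non-integer count in ", path)
    rownames(m) <- df$guide_id
    screenCounts(m, library)
}

#' @rdname readCounts
#' @export
writeCounts <- function(se, path) {
    m <- assay(se, "counts")
    df <- data.frame(guide_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Reads-per-million normalization
#'
#' Adds an `"rpm"` assay: `(count + pseudocount) / sum(count + pseudocount)
#' * 1e6` per sample. The pseudocount keeps guides that drop to zero finite
#' on the log scale, which matters because complete dropout is the signal in
#' a negative-selection screen.
#'
#' @param se a count `SummarizedExperiment`.
#' @param pseudocount nonnegative real added to every count (default 1).
#' @return `se` with an added `"rpm"` assay; the pseudocount is recorded in
#'   `metadata(se)$pseudocount`.
#' @export
normalizeRPM <- function(se, pseudocount = 1) {
    stopifnot(pseudocount >= 0)
    m <- assay(se, "counts") + pseudocount
    tot <- colSums(m)
    if (any(tot <= 0)) stop("all-zero sample: ",
                            paste(colnames(m)[tot <= 0], collapse = ", "))
    assay(se, "rpm") <- sweep(m, 2L, tot, "/") * 1e6
    metadata(se)$pseudocount <- pseudocount
    se
}

#' Fraction of guides detected in a sample
#'
#' Library coverage: the fraction of guides whose count strictly exceeds
#' `threshold` (default 1, i.e. "counts exceeding 1"). Coverage declines over
#' passages as selection removes clones.
#'
#' @param se a count `SummarizedExperiment`.
#' @param sample sample (column) name.
#' @param threshold integer count threshold; strict `>` applies.
#' @return a real in `[0, 1]`.
#' @export
coverageFraction <- function(se, sample, threshold = 1L) {
    m <- assay(se, "counts")
    if (!sample %in% colnames(m)) stop("unknown sample: ", sample)
    mean(m[, sample] > threshold)
}

#' Guides completely lost between two samples
#'
#' @param se a count `SummarizedExperiment`.
#' @param reference sample in which the guide must be detected (count > 0).
#' @param query sample in which the guide must be absent (count == 0).
#' @return character vector of guide ids.
#' @export
lostGuides <- function(se, reference, query) {
    m <- assay(se, "counts")
    for (s in c(reference, query))
        if (!s %in% colnames(m)) stop("unknown sample: ", s)
    rownames(m)[m[, reference] > 0 & m[, query] == 0]
}

#' Pearson correlation between two samples on the log2 RPM scale
#'
#' @param se a count `SummarizedExperiment`.
#' @param sampleA,sampleB sample names.
#' @param pseudocount pseudocount used for the RPM normalization.
#' @return Pearson r in `[-1, 1]`.
#' @export
sampleCorrelation <- function(se, sampleA, sampleB, pseudocount = 1) {
    se <- normalizeRPM(se, pseudocount)
    m <- log2(assay(se, "rpm"))
    for (s in c(sampleA, sampleB))
        if (!s %in% colnames(m)) stop("unknown sample: ", s)
    if (nrow(m) < 3L) stop("need at least 3 guides")
    a <- m[, sampleA]; b <- m[, sampleB]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("zero variance in sample")
    stats::cor(a, b)
}

#' Library-health QC report
#'
#' Per-sample depth, coverage and lost-guide counts (versus a reference
#' sample, by default the first column), plus the pairwise log2-RPM Pearson
#' correlation matrix.
#'
#' @param se a count `SummarizedExperiment`.
#' @param reference reference sample for lost-guide counting.
#' @param threshold coverage count threshold (strict `>`).
#' @param pseudocount pseudocount for the correlation log transform.
#' @return a [QCReport-class].
#' @export
qcReport <- function(se, reference = colnames(se)[1L], threshold = 1L,
                     pseudocount = 1) {
    m <- assay(se, "counts")
    samples <- colnames(m)
    cov <- vapply(samples, function(s) coverageFraction(se, s, threshold),
                  numeric(1))
    lost <- vapply(samples, function(s)
        length(lostGuides(se, reference, s)), integer(1))
    lm2 <- log2(assay(normalizeRPM(se, pseudocount), "rpm"))
    new("QCReport",
        depth = colSums(m),
        coverage = cov,
        threshold = as.integer(threshold),
        lost = lost,
        reference = reference,
        correlation = stats::cor(lm2))
}

setMethod("show", "QCReport", function(object) {
    cat("QCReport over", length(object@depth), "samples",
        sprintf("(coverage threshold > %d, reference %s)\n",
                object@threshold, object@reference))
    print(data.frame(depth = object@depth,
                     coverage = round(object@coverage, 4),
                     lost = object@lost))
})

#' Serialize a QC report
#'
#' Writes the per-sample table as TSV and the full report (including the
#' correlation matrix) as JSON.
#'
#' @param qc a [QCReport-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeQCReport <- function(qc, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    df <- data.frame(sample = names(qc@depth), depth = qc@depth,
                     coverage = qc@coverage, lost = qc@lost)
    utils::write.table(df, file.path(dir, "qc_samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(reference = qc@reference, threshold = qc@threshold,
             depth = as.list(qc@depth), coverage = as.list(qc@coverage),
             lost = as.list(qc@lost),
             correlation = qc@correlation),
        file.path(dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
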