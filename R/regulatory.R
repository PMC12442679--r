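#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps pintersect mcols mcols<-
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Overlap helpers that first put query and subject on the union of their
# seqlevels, so comparisons across disjoint chromosome sets are silent
# no-overlaps instead of GenomeInfoDb merge warnings.
.ovAny <- function(q, s, ...) {
    lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
    GenomeInfoDb::seqlevels(q) <- lv
    GenomeInfoDb::seqlevels(s) <- lv
    overlapsAny(q, s, ..., ignore.strand = TRUE)
}

.ovHits <- function(q, s) {
    lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
    GenomeInfoDb::seqlevels(q) <- lv
    GenomeInfoDb::seqlevels(s) <- lv
    findOverlaps(q, s, ignore.strand = TRUE)
}

#' Read / write peak intervals (BED convention)
#'
#' Peaks are exchanged as BED (0-based, half-open) and held in memory as
#' `GRanges` (1-based, closed); the conversion is handled here. Columns 4-5
#' map to `name` and `score` when present.
#'
#' @param path BED file path (3-6 columns, tab-separated, no header).
#' @param gr a `GRanges`.
#' @return `readPeaks`: a `GRanges`; `writePeaks`: invisibly, the path.
#' @export
readPeaks <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                            comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("BED needs at least 3 columns")
    if (any(df[[2L]] < 0) || any(df[[2L]] >= df[[3L]]))
        stop("malformed interval: require 0 <= start < end")
    gr <- GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]))
    if (ncol(df) >= 4L) mcols(gr)$name <- df[[4L]]
    if (ncol(df) >= 5L) mcols(gr)$score <- as.numeric(df[[5L]])
    if (ncol(df) >= 6L) strand(gr) <- df[[6L]]
    gr
}

#' @rdname readPeaks
#' @export
writePeaks <- function(gr, path) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    if (!is.null(mcols(gr)$name)) {
        df$name <- mcols(gr)$name
        if (!is.null(mcols(gr)$score)) df$score <- mcols(gr)$score
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read / write a gene annotation table
#'
#' Tab-separated with header `gene_id, chrom, strand, tss, start, end`;
#' coordinates are BED-convention 0-based (TSS is the 0-based position of
#' the first transcribed base). Returned as a `GRanges` over the gene body
#' with `gene_id` and `tss` metadata.
#'
#' @param path file path.
#' @param genes a gene `GRanges` as returned by `readGeneAnnotation`.
#' @return `readGeneAnnotation`: a `GRanges`; `writeGeneAnnotation`:
#'   invisibly, the path.
#' @export
readGeneAnnotation <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
    req <- c("gene_id", "chrom", "strand", "tss", "start", "end")
    if (!all(req %in% colnames(df)))
        stop("gene annotation needs columns: ", paste(req, collapse = ", "))
    if (any(df$start >= df$end)) stop("gene_start must be < gene_end")
    if (any(df$tss < df$start | df$tss >= df$end))
        stop("tss must lie within the gene body")
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  strand = df$strand)
    mcols(gr)$gene_id <- df$gene_id
    mcols(gr)$tss <- df$tss
    gr
}

#' @rdname readGeneAnnotation
#' @export
writeGeneAnnotation <- function(genes, path) {
    df <- data.frame(gene_id = mcols(genes)$gene_id,
                     chrom = as.character(seqnames(genes)),
                     strand = as.character(strand(genes)),
                     tss = mcols(genes)$tss,
                     start = start(genes) - 1L,
                     end = end(genes))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Promoter windows around TSSs
#'
#' Symmetric window `[tss - halfwidth, tss + halfwidth)` (0-based half-open)
#' around each gene's TSS. Strand determines only where the TSS sits; the
#' window itself is symmetric.
#'
#' @param genes a gene `GRanges` from [readGeneAnnotation()].
#' @param halfwidth window half-width in bp (default 1000, i.e. +/- 1 kb).
#' @return a `GRanges` of promoter windows carrying `gene_id`.
#' @export
promoterWindows <- function(genes, halfwidth = 1000L) {
    tss <- mcols(genes)$tss
    gr <- GRanges(seqnames(genes),
                  IRanges(pmax(tss - halfwidth, 0L) + 1L, tss + halfwidth))
    mcols(gr)$gene_id <- mcols(genes)$gene_id
    gr
}

#' Annotate peaks by genomic context
#'
#' Assigns each peak exactly one category with precedence
#' promoter > gene body > intergenic, using any-overlap (>= 1 bp):
#' a peak overlapping any TSS +/- `promoter_halfwidth` window is a promoter
#' peak; otherwise a peak overlapping any gene body is a gene-body peak;
#' everything else is intergenic. Category fractions sum to one.
#'
#' @param peaks a peak `GRanges`.
#' @param genes a gene `GRanges` from [readGeneAnnotation()].
#' @param promoter_halfwidth promoter window half-width in bp.
#' @return list with `category` (factor per peak, levels promoter /
#'   gene_body / intergenic) and `fractions` (named numeric summing to 1).
#' @export
annotatePeaks <- function(peaks, genes, promoter_halfwidth = 1000L) {
    if (length(peaks) == 0L) stop("no peaks")
    prom <- promoterWindows(genes, promoter_halfwidth)
    in_prom <- .ovAny(peaks, prom)
    in_body <- .ovAny(peaks, genes)
    cat <- ifelse(in_prom, "promoter",
           ifelse(in_body, "gene_body", "intergenic"))
    cat <- factor(cat, levels = c("promoter", "gene_body", "intergenic"))
    frac <- as.numeric(table(cat)) / length(peaks)
    names(frac) <- levels(cat)
    list(category = cat, fractions = frac)
}

#' Fraction of one peak set covered by another
#'
#' Fraction of peaks in `peaksA` that overlap at least one peak in `peaksB`
#' by at least `min_bp` base pairs (co-occupancy, e.g. shared transcription
#' factor binding sites).
#'
#' @param peaksA,peaksB non-empty `GRanges`.
#' @param min_bp minimum overlap in bp (default 1, any overlap).
#' @return list with `fraction` in `[0, 1]` and `matched` (logical per A
#'   peak).
#' @export
overlapFraction <- function(peaksA, peaksB, min_bp = 1L) {
    if (length(peaksA) == 0L) stop("empty peak set A")
    if (length(peaksB) == 0L) stop("empty peak set B")
    matched <- .ovAny(peaksA, peaksB, minoverlap = min_bp)
    list(fraction = mean(matched), matched = matched)
}

#' Call cis-regulatory elements from chromatin marks
#'
#' Active promoters are open-chromatin regions carrying H3K4me3 that overlap
#' a TSS window (+/- `promoter_halfwidth`); they are linked to the gene(s)
#' whose window they hit. Active enhancers are open regions co-marked by
#' H3K4me1 and H3K27ac that are not classified as promoters (promoter
#' precedence: a region satisfying both rules is a promoter only). The two
#' sets are disjoint by construction.
#'
#' @param open_peaks ATAC/accessibility peak `GRanges`.
#' @param k4me3_peaks,k4me1_peaks,k27ac_peaks histone-mark peak `GRanges`.
#' @param genes gene `GRanges` from [readGeneAnnotation()].
#' @param promoter_halfwidth TSS window half-width in bp.
#' @return list with `promoters` (a `GRanges`, one row per region-gene link,
#'   carrying `gene_id`) and `enhancers` (a `GRanges`).
#' @export
callCREs <- function(open_peaks, k4me3_peaks, k4me1_peaks, k27ac_peaks,
                     genes, promoter_halfwidth = 1000L) {
    tracks <- list(open_peaks = open_peaks, k4me3_peaks = k4me3_peaks,
                   k4me1_peaks = k4me1_peaks, k27ac_peaks = k27ac_peaks)
    for (nm in names(tracks))
        if (is.null(tracks[[nm]]) || !is(tracks[[nm]], "GRanges"))
            stop("missing track: ", nm)
    prom_win <- promoterWindows(genes, promoter_halfwidth)
    has_k4me3 <- .ovAny(open_peaks, k4me3_peaks)
    is_prom <- has_k4me3 & .ovAny(open_peaks, prom_win)
    hits <- .ovHits(open_peaks, prom_win)
    keep <- is_prom[queryHits(hits)]
    promoters <- open_peaks[queryHits(hits)[keep]]
    mcols(promoters)$gene_id <-
        mcols(prom_win)$gene_id[subjectHits(hits)[keep]]
    enh <- !is_prom & .ovAny(open_peaks, k4me1_peaks) &
        .ovAny(open_peaks, k27ac_peaks)
    list(promoters = promoters, enhancers = open_peaks[enh])
}

#' Define transcription-factor target genes by multi-omics intersection
#'
#' A gene is called a target when (i) one of its linked cis-regulatory
#' elements overlaps a TF binding peak, (ii) its knockout differential
#' expression shows `log2fc < -lfc_cut` with `p < p_cut` (downregulated on
#' loss of the factor), and (iii) it is likewise downregulated in the
#' differentiation DE table under the same thresholds. Only promoter CREs
#' carry gene links, so condition (i) is evaluated on promoters.
#'
#' @param tf_peaks TF binding peak `GRanges`.
#' @param cres CRE set from [callCREs()].
#' @param ko_de,diff_de data.frames with columns `gene_id`, `log2fc`, `p`
#'   (and optionally `padj`).
#' @param lfc_cut absolute log2 fold-change threshold (default 1).
#' @param p_cut p-value threshold (default 0.05).
#' @return sorted character vector of target gene ids.
#' @export
defineTargets <- function(tf_peaks, cres, ko_de, diff_de,
                          lfc_cut = 1, p_cut = 0.05) {
    bound <- .ovAny(cres$promoters, tf_peaks)
    bound_genes <- unique(mcols(cres$promoters)$gene_id[bound])
    down <- function(de)
        unique(de$gene_id[de$log2fc < -lfc_cut & de$p < p_cut])
    sort(Reduce(intersect, list(bound_genes, down(ko_de), down(diff_de))))
}

#' Mean signal over promoter windows
#'
#' Length-weighted mean of scored-interval signal within each gene's TSS
#' +/- `halfwidth` window; genes with no overlapping interval get 0.
#'
#' @param intervals a `GRanges` with a numeric `score` metadata column.
#' @param genes gene `GRanges` from [readGeneAnnotation()].
#' @param halfwidth promoter window half-width in bp.
#' @return named numeric, one mean signal per gene.
#' @export
promoterSignal <- function(intervals, genes, halfwidth = 1000L) {
    if (is.null(mcols(intervals)$score))
        stop("intervals need a 'score' column")
    win <- promoterWindows(genes, halfwidth)
    out <- stats::setNames(numeric(length(win)), mcols(win)$gene_id)
    hits <- .ovHits(win, intervals)
    if (length(hits)) {
        ov <- width(pintersect(win[queryHits(hits)],
                               intervals[subjectHits(hits)],
                               ignore.strand = TRUE))
        sc <- mcols(intervals)$score[subjectHits(hits)]
        num <- rowsum(ov * sc, queryHits(hits))
        den <- rowsum(ov, queryHits(hits))
        out[as.integer(rownames(num))] <- num[, 1L] / den[, 1L]
    }
    out
}

#' Generate planted-truth regulatory fixtures
#'
#' Builds a small synthetic regulatory landscape with known truth: genes
#' spaced along toy chromosomes; a subset given active-promoter chromatin
#' (open + H3K4me3 at the TSS), a subset given distal enhancers
#' (open + H3K4me1 + H3K27ac), TF binding planted at some promoters, and
#' knockout / differentiation DE tables with planted downregulation. The
#' returned `truth$targets` are exactly the genes satisfying all three
#' target conditions.
#'
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @param frac_promoter fraction of genes with active-promoter chromatin.
#' @param frac_bound fraction of active promoters bound by the TF.
#' @param frac_ko_down,frac_diff_down fractions of genes planted as
#'   downregulated in the two DE tables.
#' @return list with `genes`, `open`, `k4me3`, `k4me1`, `k27ac`, `tf`
#'   (GRanges), `ko_de`, `diff_de` (data.frames), and `truth`.
#' @export
makeRegulatoryFixtures <- function(n_genes = 100L, seed = 1L,
                                   frac_promoter = 0.6, frac_bound = 0.5,
                                   frac_ko_down = 0.4, frac_diff_down = 0.4) {
    withr::with_seed(as.integer(seed), {
        gene_id <- sprintf("G%04d", seq_len(n_genes))
        chrom <- sample(c("chr1", "chr2"), n_genes, replace = TRUE)
        pos <- integer(n_genes)
        for (ch in unique(chrom)) {
            i <- which(chrom == ch)
            pos[i] <- 10000L + (seq_along(i) - 1L) * 20000L
        }
        strand <- sample(c("+", "-"), n_genes, replace = TRUE)
        tss <- pos
        gstart <- ifelse(strand == "+", tss, tss - 8000L)
        gend <- gstart + 8000L
        genes <- GRanges(chrom, IRanges(gstart + 1L, gend), strand = strand)
        mcols(genes)$gene_id <- gene_id
        mcols(genes)$tss <- tss

        has_prom <- stats::runif(n_genes) < frac_promoter
        has_enh <- stats::runif(n_genes) < 0.4
        bound <- has_prom & stats::runif(n_genes) < frac_bound
        ko_down <- stats::runif(n_genes) < frac_ko_down
        diff_down <- stats::runif(n_genes) < frac_diff_down

        mk <- function(sel, lo, hi) {
            if (!any(sel)) return(GRanges())
            s <- tss[sel] + sample(lo:hi, sum(sel), replace = TRUE)
            GRanges(chrom[sel], IRanges(s + 1L, s + 600L))
        }
        open <- c(mk(has_prom, -400L, 100L), mk(has_enh, 4000L, 6000L))
        k4me3 <- mk(has_prom, -300L, 0L)
        k4me1 <- mk(has_enh, 4000L, 6000L)
        k27ac <- mk(has_enh, 4000L, 6000L)
        tf <- mk(bound, -200L, 0L)

        de_table <- function(down_flag) {
            lfc <- ifelse(down_flag, stats::rnorm(n_genes, -2, 0.3),
                          stats::rnorm(n_genes, 0, 0.3))
            p <- ifelse(down_flag, stats::runif(n_genes, 0, 0.01),
                        stats::runif(n_genes, 0.1, 1))
            data.frame(gene_id = gene_id, log2fc = lfc, p = p,
                       padj = pmin(p * 2, 1))
        }
        ko_de <- de_table(ko_down)
        diff_de <- de_table(diff_down)
        truth_targets <- sort(gene_id[has_prom & bound &
            ko_de$log2fc < -1 & ko_de$p < 0.05 &
            diff_de$log2fc < -1 & diff_de$p < 0.05])
        list(genes = genes, open = open, k4me3 = k4me3, k4me1 = k4me1,
             k27ac = k27ac, tf = tf, ko_de = ko_de, diff_de = diff_de,
             truth = list(has_promoter = gene_id[has_prom],
                          bound = gene_id[bound],
                          targets = truth_targets))
    })
}
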