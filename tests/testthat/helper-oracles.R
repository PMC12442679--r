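# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and hand-written arithmetic only.

# End-to-end CRISPR Score from a raw count matrix: RPM+pseudocount
# normalization, per-guide log2 ratio, per-gene arithmetic mean.
oracleCS <- function(counts, gene_id, is_control, initial, final,
                     pseudocount = 1) {
    ci <- counts[, initial] + pseudocount
    cf <- counts[, final] + pseudocount
    ni <- ci / sum(ci) * 1e6
    nf <- cf / sum(cf) * 1e6
    lfc <- log2(nf / ni)
    genes <- sort(unique(gene_id[!is_control]))
    out <- numeric(length(genes))
    for (k in seq_along(genes)) {
        sel <- !is_control & !is.na(gene_id) & gene_id == genes[k]
        out[k] <- sum(lfc[sel]) / sum(sel)
    }
    names(out) <- genes
    out
}

# Overlap length of two 0-based half-open intervals.
ovlBp <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))

# All-pairs peak annotation; peaks/genes are 0-based half-open data.frames.
oracleAnnotate <- function(peaks, genes, hw = 1000L) {
    out <- character(nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
        prom <- FALSE; body <- FALSE
        for (j in seq_len(nrow(genes))) {
            if (peaks$chrom[i] != genes$chrom[j]) next
            t <- genes$tss[j]
            if (ovlBp(peaks$start[i], peaks$end[i], max(t - hw, 0L), t + hw) > 0)
                prom <- TRUE
            if (ovlBp(peaks$start[i], peaks$end[i],
                      genes$start[j], genes$end[j]) > 0)
                body <- TRUE
        }
        out[i] <- if (prom) "promoter" else if (body) "gene_body"
                  else "intergenic"
    }
    out
}

# All-pairs fraction of A peaks with >= min_bp overlap with any B peak.
oracleOverlapFraction <- function(A, B, min_bp = 1L) {
    hit <- logical(nrow(A))
    for (i in seq_len(nrow(A)))
        for (j in seq_len(nrow(B)))
            if (A$chrom[i] == B$chrom[j] &&
                ovlBp(A$start[i], A$end[i], B$start[j], B$end[j]) >= min_bp) {
                hit[i] <- TRUE
                break
            }
    mean(hit)
}

# All-pairs CRE calling on 0-based data.frames; returns per-open-region
# labels "promoter" / "enhancer" / "none".
oracleCRE <- function(open, k4me3, k4me1, k27ac, genes, hw = 1000L) {
    anyOvl <- function(i, set) {
        for (j in seq_len(nrow(set)))
            if (open$chrom[i] == set$chrom[j] &&
                ovlBp(open$start[i], open$end[i],
                      set$start[j], set$end[j]) > 0)
                return(TRUE)
        FALSE
    }
    out <- character(nrow(open))
    for (i in seq_len(nrow(open))) {
        prom <- FALSE
        if (anyOvl(i, k4me3)) {
            for (j in seq_len(nrow(genes))) {
                t <- genes$tss[j]
                if (open$chrom[i] == genes$chrom[j] &&
                    ovlBp(open$start[i], open$end[i],
                          max(t - hw, 0L), t + hw) > 0) {
                    prom <- TRUE
                    break
                }
            }
        }
        out[i] <- if (prom) "promoter"
                  else if (anyOvl(i, k4me1) && anyOvl(i, k27ac)) "enhancer"
                  else "none"
    }
    out
}

# GRanges -> 0-based half-open data.frame (for feeding the oracles).
grToDf <- function(gr) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
    m <- GenomicRanges::mcols(gr)
    if (!is.null(m$tss)) df$tss <- m$tss
    df
}

dfToGr <- function(df) {
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start + 1L, df$end))
}

randomPeaksDf <- function(n, chroms = c("chr1", "chr2"), max_pos = 50000L,
                          max_len = 2000L) {
    s <- sample.int(max_pos, n, replace = TRUE)
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start = s, end = s + sample.int(max_len, n, replace = TRUE))
}
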