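`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a gene GRanges from a 0-based data.frame (gene_id, chrom, tss,
# start, end[, strand]).
mkGenes <- function(df) {
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1L, df$end),
                                 strand = df$strand %||% "+")
    GenomicRanges::mcols(gr)$gene_id <- df$gene_id
    GenomicRanges::mcols(gr)$tss <- df$tss
    gr
}
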