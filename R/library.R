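#' Build a synthetic sgRNA library
#'
#' Construct a knockout library with a fixed number of guides per gene plus a
#' block of non-targeting control (NTC) guides, mirroring the common pooled
#' screen design of several sgRNAs per gene and ~1000 NTCs. Identifiers are
#' deterministic (`G0001_sg1 ... NTC_1 ...`); random 20-mer sequences are
#' attached only when a seed is given.
#'
#' @param n_genes number of targeted genes (>= 0).
#' @param guides_per_gene guides designed per gene (>= 1).
#' @param n_control number of non-targeting control guides (>= 0).
#' @param seed optional integer; when given, random 20-mer sequences are
#'   generated for every guide.
#'
#' @return an [SgRNALibrary-class].
#'
#' @examples
#' lib <- buildLibrary(10, 4, 5)
#' length(lib)            # 45
#' nGenes(lib)            # 10
#' nControls(lib)         # 5
#'
#' @export
buildLibrary <- function(n_genes, guides_per_gene = 4L, n_control = 0L,
                         seed = NULL) {
    n_genes <- as.integer(n_genes)
    guides_per_gene <- as.integer(guides_per_gene)
    n_control <- as.integer(n_control)
    stopifnot(n_genes >= 0L, guides_per_gene >= 1L, n_control >= 0L)
    if (n_genes + n_control == 0L)
        stop("empty library")

    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    guide_id <- character(0)
    gene_id <- character(0)
    if (n_genes > 0L) {
        gene_id <- rep(gene_ids, each = guides_per_gene)
        guide_id <- paste0(gene_id, "_sg", rep(seq_len(guides_per_gene), n_genes))
    }
    if (n_control > 0L) {
        guide_id <- c(guide_id, paste0("NTC_", seq_len(n_control)))
        gene_id <- c(gene_id, rep(NA_character_, n_control))
    }
    guides <- DataFrame(
        guide_id = guide_id,
        gene_id = gene_id,
        is_control = is.na(gene_id)
    )
    if (!is.null(seed)) {
        guides$sequence <- withr::with_seed(as.integer(seed),
            vapply(seq_len(nrow(guides)), function(i)
                paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                      collapse = ""), character(1)))
    }
    new("SgRNALibrary", guides = guides)
}

#' SgRNALibrary accessors
#'
#' @param x an [SgRNALibrary-class].
#' @return `guideIds`, `geneIds`: character vectors (one per guide; `geneIds`
#'   is `NA` for controls); `isControl`: logical per guide; `nGenes`,
#'   `nControls`, `nTargeting`: counts.
#' @name SgRNALibrary-accessors
NULL

#' @rdname SgRNALibrary-accessors
#' @export
setMethod("guideIds", "SgRNALibrary", function(x) x@guides$guide_id)

#' @rdname SgRNALibrary-accessors
#' @export
setMethod("geneIds", "SgRNALibrary", function(x) x@guides$gene_id)

#' @rdname SgRNALibrary-accessors
#' @export
setMethod("isControl", "SgRNALibrary", function(x) x@guides$is_control)

#' @rdname SgRNALibrary-accessors
#' @export
setMethod("nGenes", "SgRNALibrary", function(x)
    length(unique(x@guides$gene_id[!x@guides$is_control])))

#' @rdname SgRNALibrary-accessors
#' @export
setMethod("nControls", "SgRNALibrary", function(x) sum(x@guides$is_control))

#' @rdname SgRNALibrary-accessors
#' @export
setMethod("nTargeting", "SgRNALibrary", function(x) sum(!x@guides$is_control))

#' @describeIn SgRNALibrary-accessors total number of guides.
#' @export
setMethod("length", "SgRNALibrary", function(x) nrow(x@guides))

setMethod("show", "SgRNALibrary", function(object) {
    cat("SgRNALibrary with", length(object), "guides:",
        nTargeting(object), "targeting", nGenes(object), "genes,",
        nControls(object), "non-targeting controls\n")
})

#' Read / write an sgRNA library table
#'
#' Tab-separated text with a mandatory header `guide_id`, `gene_id`,
#' `is_control` and optional `sequence`. Controls have an empty/NA `gene_id`.
#' `writeLibrary` followed by `readLibrary` is the identity; re-serializing
#' a read library is byte-identical (canonical serialization).
#'
#' @param path file path.
#' @param library an [SgRNALibrary-class].
#' @return `readLibrary`: an [SgRNALibrary-class]; `writeLibrary`:
#'   invisibly, the path.
#' @export
readLibrary <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", na.strings = "",
                            quote = "", comment.char = "")
    req <- c("guide_id", "gene_id", "is_control")
    if (!all(req %in% colnames(df)))
        stop("library file must have columns: ", paste(req, collapse = ", "))
    if (anyDuplicated(df$guide_id)) {
        dup <- unique(df$guide_id[duplicated(df$guide_id)])
        stop("duplicate guide_id: ", paste(head(dup, 5), collapse = ", "))
    }
    guides <- DataFrame(
        guide_id = df$guide_id,
        gene_id = df$gene_id,
        is_control = as.logical(df$is_control)
    )
    if ("sequence" %in% colnames(df)) guides$sequence <- df$sequence
    new("SgRNALibrary", guides = guides)
}

#' @rdname readLibrary
#' @export
writeLibrary <- function(library, path) {
    stopifnot(is(library, "SgRNALibrary"))
    df <- as.data.frame(library@guides)
    df$is_control <- ifelse(df$is_control, "TRUE", "FALSE")
    df$gene_id[is.na(df$gene_id)] <- ""
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    invisible(path)
}
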