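#' Per-guide log2 fold-change
#'
#' log2 ratio of normalized (RPM + pseudocount) abundance between a final
#' and an initial sample, per guide — the building block of the CRISPR
#' Score. NTC guides are included (they feed the empirical null).
#'
#' @param se a count `SummarizedExperiment` (the `"rpm"` assay is computed
#'   with `pseudocount` if absent).
#' @param initial,final sample (column) names.
#' @param pseudocount pseudocount used for normalization (default 1).
#' @return `DataFrame` with `guide_id`, `gene_id`, `is_control`, `log2fc`.
#' @export
guideLog2FC <- function(se, initial, final, pseudocount = 1) {
    if (!all(c(initial, final) %in% colnames(se)))
        stop("missing sample: ",
             paste(setdiff(c(initial, final), colnames(se)), collapse = ", "))
    se <- normalizeRPM(se, pseudocount)
    r <- assay(se, "rpm")
    DataFrame(guide_id = rownames(r),
              gene_id = rowData(se)$gene_id,
              is_control = rowData(se)$is_control,
              log2fc = unname(log2(r[, final] / r[, initial])))
}

#' Per-gene CRISPR Score
#'
#' The CRISPR Score (CS) of a gene is the arithmetic mean of the log2
#' fold-changes of all sgRNAs targeting it; non-targeting controls are
#' excluded. Negative CS marks depletion (essential genes in a fitness
#' screen), positive CS enrichment (growth-restricting genes, or
#' pro-pluripotency genes in a sorted reporter-low sample).
#'
#' @param lfc a `DataFrame` from [guideLog2FC()].
#' @return a [GeneScoreTable-class] with `gene_id`, `cs`, `n_guides`, and
#'   rank (1 = most negative CS).
#' @export
crisprScore <- function(lfc) {
    t <- lfc[!lfc$is_control, , drop = FALSE]
    if (nrow(t) == 0L) stop("no targeting guides with LFC values")
    if (any(is.na(t$gene_id))) stop("gene with zero guides / missing gene_id")
    cs <- rowsum(t$log2fc, t$gene_id) / as.vector(table(t$gene_id))
    out <- DataFrame(gene_id = rownames(cs),
                     cs = unname(cs[, 1L]),
                     n_guides = as.vector(table(t$gene_id)))
    out$rank <- rank(out$cs, ties.method = "first")
    rownames(out) <- NULL
    new("GeneScoreTable", out)
}

#' Build the NTC pseudo-gene null model
#'
#' Groups non-targeting control guide LFCs into pseudo-genes of
#' `guides_per_pseudo` guides each (sampled without replacement within a
#' pseudo-gene, with replacement across pseudo-genes) and takes their means,
#' giving an empirical null distribution of CRISPR Scores for neutral genes.
#'
#' @param lfc a `DataFrame` from [guideLog2FC()] (only control rows are used),
#'   or a numeric vector of NTC LFCs.
#' @param guides_per_pseudo guides per pseudo-gene (match the library design).
#' @param n_pseudo number of pseudo-genes to draw.
#' @param seed integer seed.
#' @return a [NullModel-class].
#' @export
buildNtcNull <- function(lfc, guides_per_pseudo = 4L, n_pseudo = 10000L,
                         seed = 1L) {
    x <- if (is.numeric(lfc)) lfc else lfc$log2fc[lfc$is_control]
    guides_per_pseudo <- as.integer(guides_per_pseudo)
    if (length(x) < guides_per_pseudo)
        stop("too few NTC guides (", length(x), ") for pseudo-genes of ",
             guides_per_pseudo)
    cs <- withr::with_seed(as.integer(seed),
        vapply(seq_len(n_pseudo), function(i)
            mean(x[sample.int(length(x), guides_per_pseudo)]), numeric(1)))
    new("NullModel", cs = cs, guides_per_pseudo = guides_per_pseudo,
        seed = as.integer(seed))
}

setMethod("show", "NullModel", function(object) {
    cat("NullModel:", length(object@cs), "pseudo-genes of",
        object@guides_per_pseudo, "NTC guides; CS mean",
        signif(mean(object@cs), 3), "sd", signif(stats::sd(object@cs), 3),
        "\n")
})

#' Classify genes against the NTC null
#'
#' One-sided empirical tail p-values against the pseudo-gene null with the
#' add-one convention `(r + 1) / (n + 1)` per tail (lower tail: essential;
#' upper tail: growth-restricting), Benjamini-Hochberg corrected across all
#' genes within each tail. A gene is classified where its tail q-value is at
#' most `fdr`; everything else is `"other"`. The reported `q` is the q-value
#' of the gene's more extreme tail.
#'
#' @param scores a [GeneScoreTable-class] from [crisprScore()].
#' @param null a [NullModel-class].
#' @param fdr target false discovery rate in (0, 1).
#' @return the score table with added `p_lower`, `p_upper`, `q`, `class`
#'   columns.
#' @export
classifyGenes <- function(scores, null, fdr = 0.05) {
    stopifnot(is(null, "NullModel"), fdr > 0, fdr < 1)
    n0 <- length(null@cs)
    if (n0 == 0L) stop("empty null")
    s <- sort(null@cs)
    # r = number of null values at least as extreme as cs, per tail
    r_lower <- findInterval(scores$cs, s)                 # null <= cs
    r_upper <- n0 - findInterval(scores$cs, s, left.open = TRUE)  # null >= cs
    p_lower <- (r_lower + 1) / (n0 + 1)
    p_upper <- (r_upper + 1) / (n0 + 1)
    q_lower <- stats::p.adjust(p_lower, "BH")
    q_upper <- stats::p.adjust(p_upper, "BH")
    class <- rep("other", nrow(scores))
    class[q_lower <= fdr & p_lower < p_upper] <- "essential"
    class[q_upper <= fdr & p_upper < p_lower] <- "growth_restricting"
    out <- scores
    out$p_lower <- p_lower
    out$p_upper <- p_upper
    out$q <- ifelse(p_lower <= p_upper, q_lower, q_upper)
    out$class <- class
    metadata(out)$fdr <- fdr
    metadata(out)$n_pseudo <- n0
    new("GeneScoreTable", out)
}

#' Welch t-test of a gene class against the NTC pseudo-genes
#'
#' Two-tailed Welch two-sample t-test comparing the CRISPR Scores of one
#' class (e.g. essential or growth-restricting genes) against the NTC
#' pseudo-gene null scores.
#'
#' @param scores a classified [GeneScoreTable-class].
#' @param class class label to test (`"essential"`, `"growth_restricting"`,
#'   or `"other"`).
#' @param null a [NullModel-class] providing the baseline pseudo-gene scores.
#' @return list with `t`, `p`, `df`, and group means.
#' @export
classVsNtcTest <- function(scores, class, null) {
    x <- scores$cs[scores$class == class]
    y <- null@cs
    if (length(x) < 2L || length(y) < 2L)
        stop("need at least 2 scores per group")
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (mean(x) == mean(y))
            return(list(t = 0, p = 1, df = NA_real_,
                        mean_class = mean(x), mean_ntc = mean(y)))
        stop("degenerate groups with zero variance")
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter),
         mean_class = mean(x), mean_ntc = mean(y))
}

#' Intersect the top-k genes of two screens
#'
#' Takes the top `k` genes by CRISPR Score from each table — most negative
#' first for `direction = "depleted"`, most positive first for `"enriched"`
#' — and returns their intersection ordered by mean rank across the two
#' screens (ties broken by gene id). This is the rule used to nominate
#' candidate genes shared between two reporter screens.
#'
#' @param scoresA,scoresB [GeneScoreTable-class] objects.
#' @param k list length per screen.
#' @param direction `"depleted"` or `"enriched"`.
#' @return character vector of gene ids, ordered by mean rank.
#' @export
rankAndIntersect <- function(scoresA, scoresB, k = 20L,
                             direction = c("depleted", "enriched")) {
    direction <- match.arg(direction)
    stopifnot(k <= nrow(scoresA), k <= nrow(scoresB))
    topk <- function(tab) {
        cs <- if (direction == "depleted") tab$cs else -tab$cs
        ord <- order(cs, tab$gene_id)     # ties by gene_id, lexicographic
        stats::setNames(seq_len(k), tab$gene_id[ord[seq_len(k)]])
    }
    ra <- topk(scoresA); rb <- topk(scoresB)
    common <- intersect(names(ra), names(rb))
    mr <- (ra[common] + rb[common]) / 2
    common[order(mr, common)]
}

#' Per-guide abundance trajectory of a gene
#'
#' Normalized (RPM) abundance of every guide targeting a gene across an
#' ordered set of samples — the per-gene dropout/enrichment trajectory plot
#' data.
#'
#' @param se a count `SummarizedExperiment`.
#' @param gene_id gene to extract.
#' @param samples ordered sample names (default: all columns).
#' @param pseudocount pseudocount for normalization.
#' @return numeric matrix, guides x samples, of RPM values.
#' @export
geneTrajectory <- function(se, gene_id, samples = colnames(se),
                           pseudocount = 1) {
    idx <- which(!is.na(rowData(se)$gene_id) &
                 rowData(se)$gene_id == gene_id)
    if (!length(idx)) stop("unknown gene: ", gene_id)
    r <- assay(normalizeRPM(se, pseudocount), "rpm")
    r[idx, samples, drop = FALSE]
}

setMethod("show", "GeneScoreTable", function(object) {
    cat("GeneScoreTable with", nrow(object), "genes\n")
    if ("class" %in% colnames(object)) {
        tab <- table(object$class)
        cat("  classes:",
            paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
            "\n")
    }
    callNextMethod()
})

#' Write / read a gene score table
#'
#' @param scores a [GeneScoreTable-class].
#' @param path file path (TSV).
#' @return `writeGeneScores`: invisibly, the path; `readGeneScores`: a
#'   [GeneScoreTable-class].
#' @export
writeGeneScores <- function(scores, path) {
    df <- as.data.frame(scores)
    num <- vapply(df, is.numeric, logical(1))
    # canonical full-precision serialization so reruns are byte-identical
    df[num] <- lapply(df[num], function(x)
        ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
               sprintf("%.17g", x)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGeneScores
#' @export
readGeneScores <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
    new("GeneScoreTable", DataFrame(df))
}
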