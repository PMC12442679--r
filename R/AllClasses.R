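#' @import methods
#' @importFrom S4Vectors DataFrame DFrame metadata metadata<-
NULL

#' sgRNA library
#'
#' Ordered collection of guide records: the universe over which all counting
#' and scoring happens. Targeting guides carry a `gene_id`; non-targeting
#' controls (NTCs) have `gene_id = NA` and `is_control = TRUE`.
#'
#' @slot guides a `DataFrame` with columns `guide_id` (character, unique),
#'   `gene_id` (character, `NA` for controls), `is_control` (logical) and
#'   optionally `sequence` (20-mer over ACGT).
#'
#' @aliases SgRNALibrary-class
#' @exportClass SgRNALibrary
setClass("SgRNALibrary", slots = c(guides = "DFrame"))

setValidity("SgRNALibrary", function(object) {
    g <- object@guides
    req <- c("guide_id", "gene_id", "is_control")
    if (!all(req %in% colnames(g)))
        return(paste("guides must have columns:", paste(req, collapse = ", ")))
    if (nrow(g) == 0L)
        return("empty library")
    if (anyDuplicated(g$guide_id)) {
        dup <- unique(g$guide_id[duplicated(g$guide_id)])
        return(paste("duplicate guide_id:", paste(head(dup, 5), collapse = ", ")))
    }
    if (any(g$is_control & !is.na(g$gene_id)))
        return("control guides must have gene_id = NA")
    if (any(!g$is_control & is.na(g$gene_id)))
        return("targeting guides must have a gene_id")
    if ("sequence" %in% colnames(g)) {
        s <- g$sequence[!is.na(g$sequence)]
        if (length(s) && any(nchar(s) != 20L | grepl("[^ACGT]", s)))
            return("sequences must be 20-mers over {A,C,G,T}")
    }
    TRUE
})

#' Simulation parameters for a pooled screen
#'
#' Full generative description of one screen arm. Selection coefficients `s`
#' act multiplicatively per passage on edited cells as `(1 + s)`; reporter
#' loss is a per-cell Bernoulli with probability `p_loss` for edited cells
#' and `p_bg` otherwise.
#'
#' @slot library an [SgRNALibrary-class].
#' @slot plasmid_depth mean reads per guide when sequencing the plasmid pool.
#' @slot plasmid_dispersion coefficient of variation of true guide abundance
#'   in the plasmid pool (log-normal representation).
#' @slot n_cells number of cells exposed to virus (finite mode); ignored in
#'   expectation mode.
#' @slot moi expected lentiviral integrations per cell (Poisson).
#' @slot edit_efficiency probability that an integrated guide produces a
#'   functional knockout; unedited integrations behave as neutral carriers.
#' @slot fitness_map named numeric, gene_id -> per-passage selection
#'   coefficient s (> -1). Genes absent from the map are neutral (s = 0).
#' @slot reporter_loss_map named numeric, gene_id -> probability that an
#'   edited cell falls in the reporter-low gate.
#' @slot p_bg background reporter-low rate for unedited / neutral cells.
#' @slot n_passages number of passages to propagate.
#' @slot bottleneck cells kept per passage (finite numeric) or `Inf` for
#'   exact-expectation dynamics.
#' @slot seq_depth reads per sequenced cell sample.
#' @slot sort_fraction fraction of the population gated "reporter-low".
#' @slot seed integer seed controlling all randomness.
#'
#' @aliases SimParams-class
#' @exportClass SimParams
setClass("SimParams", slots = c(
    library = "SgRNALibrary",
    plasmid_depth = "numeric",
    plasmid_dispersion = "numeric",
    n_cells = "numeric",
    moi = "numeric",
    edit_efficiency = "numeric",
    fitness_map = "numeric",
    reporter_loss_map = "numeric",
    p_bg = "numeric",
    n_passages = "integer",
    bottleneck = "numeric",
    seq_depth = "numeric",
    sort_fraction = "numeric",
    seed = "integer"
))

setValidity("SimParams", function(object) {
    if (object@plasmid_depth <= 0) return("plasmid_depth must be > 0")
    if (object@plasmid_dispersion < 0) return("plasmid_dispersion must be >= 0")
    if (object@moi <= 0) return("moi must be > 0")
    if (object@edit_efficiency < 0 || object@edit_efficiency > 1)
        return("edit_efficiency must be in [0, 1]")
    if (length(object@fitness_map) && any(object@fitness_map <= -1))
        return("selection coefficients must satisfy s > -1")
    if (length(object@reporter_loss_map) &&
        (any(object@reporter_loss_map < 0) || any(object@reporter_loss_map > 1)))
        return("reporter loss probabilities must be in [0, 1]")
    if (object@p_bg < 0 || object@p_bg > 1) return("p_bg must be in [0, 1]")
    if (object@n_passages < 0L) return("n_passages must be >= 0")
    if (object@bottleneck <= 0) return("bottleneck must be > 0 (or Inf)")
    if (object@sort_fraction <= 0 || object@sort_fraction > 1)
        return("sort_fraction must be in (0, 1]")
    if (is.finite(object@n_cells) && object@n_cells < 1)
        return("n_cells must be >= 1")
    TRUE
})

#' Cell population carrying integrated guides
#'
#' Integration-level representation of a transduced, selected cell
#' population. Each integration points at a guide and at the clone (cell
#' lineage) carrying it; clones hold a nonnegative weight (cell count, or an
#' expectation in infinite mode) and a per-passage growth multiplier derived
#' from the edited genotypes they carry.
#'
#' @slot guide integer index into the library, one entry per integration.
#' @slot clone integer clone index, one entry per integration.
#' @slot edited logical, one entry per integration.
#' @slot weight numeric clone weights (cells or expected cells).
#' @slot growth numeric per-passage multiplicative growth factor per clone.
#' @slot n_guides library size the guide indices refer to.
#' @slot expectation TRUE when the population is an expectation-mode
#'   (infinite cells) construction.
#'
#' @aliases CellPopulation-class
#' @exportClass CellPopulation
setClass("CellPopulation", slots = c(
    guide = "integer",
    clone = "integer",
    edited = "logical",
    weight = "numeric",
    growth = "numeric",
    n_guides = "integer",
    expectation = "logical"
))

setValidity("CellPopulation", function(object) {
    if (length(object@guide) != length(object@clone) ||
        length(object@guide) != length(object@edited))
        return("guide, clone and edited must be parallel vectors")
    if (length(object@weight) != length(object@growth))
        return("weight and growth must be parallel vectors")
    if (any(!is.finite(object@weight)) || any(object@weight < 0))
        return("clone weights must be finite and nonnegative")
    if (sum(object@weight) <= 0)
        return("total abundance must be > 0")
    TRUE
})

#' Per-gene CRISPR Score table
#'
#' A `DataFrame` subclass holding per-gene results: the CRISPR Score `cs`
#' (mean of the gene's guide-level log2 fold-changes), guide count, class
#' label (`essential`, `growth_restricting`, `other`, or `ntc_pseudo`),
#' empirical q-value and rank (ascending CS). Metadata records the samples
#' compared and the null model used.
#'
#' @aliases GeneScoreTable-class
#' @exportClass GeneScoreTable
setClass("GeneScoreTable", contains = "DFrame")

#' Library-health QC report
#'
#' @slot depth named numeric, per-sample total counts.
#' @slot coverage named numeric, per-sample fraction of guides with counts
#'   exceeding the threshold.
#' @slot threshold integer count threshold used (strict `>`).
#' @slot lost named integer, per-sample count of guides present in the
#'   reference sample but at zero in that sample.
#' @slot reference the reference sample for lost-guide counting.
#' @slot correlation pairwise Pearson correlation matrix of log2 RPM values.
#'
#' @aliases QCReport-class
#' @exportClass QCReport
setClass("QCReport", slots = c(
    depth = "numeric",
    coverage = "numeric",
    threshold = "integer",
    lost = "integer",
    reference = "character",
    correlation = "matrix"
))

setValidity("QCReport", function(object) {
    if (any(object@coverage < 0 | object@coverage > 1))
        return("coverage must be in [0, 1]")
    TRUE
})

#' NTC pseudo-gene null model
#'
#' Empirical null distribution of CRISPR Scores built by grouping
#' non-targeting control guide log2 fold-changes into pseudo-genes.
#'
#' @slot cs numeric vector of pseudo-gene CRISPR Scores.
#' @slot guides_per_pseudo guides averaged per pseudo-gene.
#' @slot seed seed used for the resampling.
#'
#' @aliases NullModel-class
#' @exportClass NullModel
setClass("NullModel", slots = c(
    cs = "numeric",
    guides_per_pseudo = "integer",
    seed = "integer"
))

setValidity("NullModel", function(object) {
    if (length(object@cs) == 0L) return("empty null")
    if (any(!is.finite(object@cs))) return("null CS values must be finite")
    TRUE
})
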