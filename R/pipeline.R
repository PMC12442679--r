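## Allowed configuration keys per block; unknown keys are errors so a typo
## cannot silently fall back to a default.
.config_schema <- list(
    top = c("seed", "library", "sim", "scoring"),
    library = c("n_genes", "guides_per_gene", "n_control"),
    sim = c("plasmid_depth", "plasmid_dispersion", "n_cells", "moi",
            "edit_efficiency", "n_passages", "bottleneck", "seq_depth",
            "sort_fraction", "p_bg", "fitness_map", "reporter_loss_map"),
    scoring = c("pseudocount", "initial", "final", "fdr", "n_pseudo",
                "guides_per_pseudo")
)

checkKeys <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
        stop("unknown config key", if (length(bad) > 1) "s", " in ", where,
             ": ", paste(bad, collapse = ", "))
}

## Expand a fitness/reporter map block. Either an explicit gene_id -> value
## mapping, or a compact planting spec over deterministic gene ids:
##   fitness_map: {n_essential: 10, s_essential: -0.5,
##                 n_growth: 5, s_growth: 0.3}
##   reporter_loss_map: {n_loss: 20, p_loss: 0.8}
expandEffectMap <- function(block, gene_ids, type = c("fitness", "reporter")) {
    type <- match.arg(type)
    if (is.null(block)) return(numeric(0))
    spec_keys <- if (type == "fitness")
        c("n_essential", "s_essential", "n_growth", "s_growth")
    else c("n_loss", "p_loss")
    if (any(names(block) %in% spec_keys)) {
        checkKeys(block, spec_keys, paste0(type, " map spec"))
        m <- numeric(0)
        if (type == "fitness") {
            ne <- block$n_essential %||% 0L
            ng <- block$n_growth %||% 0L
            if (ne + ng > length(gene_ids))
                stop("more planted genes than genes in the library")
            if (ne > 0)
                m <- c(m, stats::setNames(rep(block$s_essential, ne),
                                          gene_ids[seq_len(ne)]))
            if (ng > 0)
                m <- c(m, stats::setNames(rep(block$s_growth, ng),
                                          gene_ids[ne + seq_len(ng)]))
        } else {
            nl <- block$n_loss %||% 0L
            if (nl > length(gene_ids))
                stop("more planted genes than genes in the library")
            if (nl > 0)
                m <- stats::setNames(rep(block$p_loss, nl),
                                     gene_ids[seq_len(nl)])
        }
        return(m)
    }
    v <- unlist(block)
    bad <- setdiff(names(v), gene_ids)
    if (length(bad))
        stop("unknown gene ids in map: ", paste(head(bad, 5), collapse = ", "))
    v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a run configuration
#'
#' YAML configuration with blocks `library`, `sim`, `scoring` and a global
#' `seed`. Unknown keys anywhere are errors. Effect maps may be explicit
#' (`gene_id: value`) or compact planting specs (see
#' `vignette("poolscreen-methods")`).
#'
#' @param path YAML file path.
#' @param arm `"fitness"` or `"facs"`: which effect map is mandatory.
#' @return validated config list with `library` ([SgRNALibrary-class]),
#'   `params` ([SimParams-class]) and `scoring` settings.
#' @export
readRunConfig <- function(path, arm = c("fitness", "facs")) {
    arm <- match.arg(arm)
    cfg <- yaml::read_yaml(path)
    checkKeys(cfg, .config_schema$top, "config")
    if (is.null(cfg$library)) stop("library block required")
    checkKeys(cfg$library, .config_schema$library, "library block")
    checkKeys(cfg$sim %||% list(), .config_schema$sim, "sim block")
    checkKeys(cfg$scoring %||% list(), .config_schema$scoring,
              "scoring block")
    if (arm == "fitness" && is.null(cfg$sim$fitness_map))
        stop("fitness_map required")
    if (arm == "facs" && is.null(cfg$sim$reporter_loss_map))
        stop("reporter_loss_map required")

    lib <- buildLibrary(cfg$library$n_genes %||% stop("n_genes required"),
                        cfg$library$guides_per_gene %||% 4L,
                        cfg$library$n_control %||% 0L)
    gene_ids <- unique(geneIds(lib)[!isControl(lib)])
    s <- cfg$sim %||% list()
    num_inf <- function(x, default) {
        if (is.null(x)) return(default)
        if (identical(x, "infinite") || identical(x, "Inf")) return(Inf)
        as.numeric(x)
    }
    params <- SimParams(
        library = lib,
        plasmid_depth = s$plasmid_depth %||% 500,
        plasmid_dispersion = s$plasmid_dispersion %||% 0.5,
        n_cells = num_inf(s$n_cells, Inf),
        moi = s$moi %||% 0.3,
        edit_efficiency = s$edit_efficiency %||% 0.8,
        fitness_map = expandEffectMap(s$fitness_map, gene_ids, "fitness"),
        reporter_loss_map = expandEffectMap(s$reporter_loss_map, gene_ids,
                                            "reporter"),
        p_bg = s$p_bg %||% 0.02,
        n_passages = s$n_passages %||% 10L,
        bottleneck = num_inf(s$bottleneck, Inf),
        seq_depth = s$seq_depth %||% NULL,
        sort_fraction = s$sort_fraction %||% 0.05,
        seed = cfg$seed %||% 1L)
    sc <- cfg$scoring %||% list()
    scoring <- list(pseudocount = sc$pseudocount %||% 1,
                    initial = sc$initial %||% "P0",
                    final = sc$final %||% NULL,
                    fdr = sc$fdr %||% 0.05,
                    n_pseudo = sc$n_pseudo %||% 10000L,
                    guides_per_pseudo = sc$guides_per_pseudo %||%
                        (cfg$library$guides_per_gene %||% 4L))
    list(path = path, library = lib, params = params, scoring = scoring,
         seed = cfg$seed %||% 1L)
}

writeManifest <- function(dir, config_path, seed, stage_counts) {
    jsonlite::write_json(list(
        package = "poolscreen",
        version = as.character(utils::packageVersion("poolscreen")),
        config_md5 = unname(tools::md5sum(config_path)),
        seed = seed,
        stages = stage_counts
    ), file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

scoreScreen <- function(sim, cfg, initial, final) {
    lfc <- guideLog2FC(sim$counts, initial, final,
                       pseudocount = cfg$scoring$pseudocount)
    scores <- crisprScore(lfc)
    null <- buildNtcNull(lfc, cfg$scoring$guides_per_pseudo,
                         cfg$scoring$n_pseudo, seed = cfg$seed)
    list(scores = classifyGenes(scores, null, cfg$scoring$fdr),
         null = null, lfc = lfc)
}

runPipeline <- function(config_path, out_dir, arm) {
    cfg <- readRunConfig(config_path, arm)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    message("[", arm, "] library: ", length(cfg$library), " guides, ",
            nGenes(cfg$library), " genes, ", nControls(cfg$library), " NTCs")
    sim <- if (arm == "fitness") simulateFitnessScreen(cfg$params)
           else simulateFacsScreen(cfg$params)
    message("[", arm, "] simulated ", ncol(sim$counts), " samples at depth ",
            cfg$params@seq_depth)
    final <- cfg$scoring$final %||%
        colnames(sim$counts)[ncol(sim$counts)]
    res <- scoreScreen(sim, cfg, cfg$scoring$initial, final)
    message("[", arm, "] scored ", nrow(res$scores), " genes (",
            cfg$scoring$initial, " -> ", final, "); classes: ",
            paste(names(table(res$scores$class)),
                  as.integer(table(res$scores$class)),
                  sep = "=", collapse = ", "))
    writeLibrary(cfg$library, file.path(out_dir, "library.tsv"))
    writeCounts(sim$counts, file.path(out_dir, "counts.tsv"))
    utils::write.table(as.data.frame(sim$truth),
                       file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeQCReport(qcReport(sim$counts,
                           pseudocount = cfg$scoring$pseudocount),
                  file.path(out_dir, "qc"))
    writeGeneScores(res$scores, file.path(out_dir, "gene_scores.tsv"))
    writeManifest(out_dir, config_path, cfg$seed,
                  list(guides = length(cfg$library),
                       genes = nGenes(cfg$library),
                       ntc = nControls(cfg$library),
                       samples = ncol(sim$counts),
                       scored_genes = nrow(res$scores),
                       initial = cfg$scoring$initial, final = final))
    invisible(list(dir = out_dir, counts = sim$counts, truth = sim$truth,
                   scores = res$scores, null = res$null))
}

#' Run the fitness (dropout) screen pipeline end to end
#'
#' Chains simulate -> QC -> per-guide log2 fold-change -> CRISPR Score ->
#' NTC-null classification and writes `library.tsv`, `counts.tsv`,
#' `truth.tsv`, `qc/`, `gene_scores.tsv` and a `manifest.json` recording the
#' config hash and seed; a rerun of the same config reproduces identical
#' tables.
#'
#' @param config_path YAML run configuration (see [readRunConfig()]).
#' @param out_dir output directory.
#' @return invisibly, a list with the counts, truth, classified scores and
#'   the null model.
#' @export
runFitnessPipeline <- function(config_path, out_dir) {
    runPipeline(config_path, out_dir, "fitness")
}

#' Run the FACS reporter-loss screen pipeline end to end
#'
#' As [runFitnessPipeline()], but simulating a sorted reporter-low fraction
#' and scoring `sorted` versus `P0`; pro-pluripotency knockouts enrich
#' (positive CRISPR Score) in the sorted sample.
#'
#' @inheritParams runFitnessPipeline
#' @return invisibly, a list with the counts, truth, classified scores and
#'   the null model.
#' @export
runFacsPipeline <- function(config_path, out_dir) {
    runPipeline(config_path, out_dir, "facs")
}
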