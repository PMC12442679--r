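#' Construct simulation parameters
#'
#' Builds a validated [SimParams-class] describing one screen arm. Defaults
#' reflect a typical pooled knockout screen in cultured stem cells: MOI 0.3
#' (so fewer than 30% of cells are transduced and most infected cells carry a
#' single guide), 80% knockout efficiency per integration, a log-normal
#' plasmid pool with CV 0.5, 500x sequencing coverage per guide, ten
#' passages, and a 5% reporter-low sort gate with a 2% background rate.
#'
#' @param library an [SgRNALibrary-class].
#' @param plasmid_depth mean reads per guide for the plasmid sample.
#' @param plasmid_dispersion CV of true plasmid guide abundance.
#' @param n_cells cells exposed to virus; `Inf` selects expectation mode
#'   (exact per-guide expectations instead of sampled cells).
#' @param moi expected integrations per cell.
#' @param edit_efficiency probability an integration yields a knockout.
#' @param fitness_map named numeric of per-passage selection coefficients
#'   (gene_id -> s, s > -1); genes not listed are neutral.
#' @param reporter_loss_map named numeric of reporter-low probabilities for
#'   edited cells (gene_id -> p_loss).
#' @param p_bg background reporter-low probability.
#' @param n_passages passages to propagate.
#' @param bottleneck cells kept at each passage, or `Inf` for deterministic
#'   (exact expectation) propagation.
#' @param seq_depth reads per cell sample; default `500 * length(library)`.
#' @param sort_fraction fraction of cells gated reporter-low.
#' @param seed integer master seed; all stage seeds derive from it.
#'
#' @return a [SimParams-class].
#' @export
SimParams <- function(library,
                      plasmid_depth = 500,
                      plasmid_dispersion = 0.5,
                      n_cells = Inf,
                      moi = 0.3,
                      edit_efficiency = 0.8,
                      fitness_map = numeric(0),
                      reporter_loss_map = numeric(0),
                      p_bg = 0.02,
                      n_passages = 10L,
                      bottleneck = Inf,
                      seq_depth = NULL,
                      sort_fraction = 0.05,
                      seed = 1L) {
    if (is.null(seq_depth)) seq_depth <- 500 * length(library)
    new("SimParams",
        library = library,
        plasmid_depth = plasmid_depth,
        plasmid_dispersion = plasmid_dispersion,
        n_cells = n_cells,
        moi = moi,
        edit_efficiency = edit_efficiency,
        fitness_map = fitness_map,
        reporter_loss_map = reporter_loss_map,
        p_bg = p_bg,
        n_passages = as.integer(n_passages),
        bottleneck = bottleneck,
        seq_depth = seq_depth,
        sort_fraction = sort_fraction,
        seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
    cat("SimParams:", length(object@library), "guides,",
        "MOI", object@moi, "| edit", object@edit_efficiency,
        "| passages", object@n_passages,
        "| depth", object@seq_depth,
        "| bottleneck", object@bottleneck,
        "| seed", object@seed, "\n")
})

## Deterministic per-stage seed expansion from one master seed; kept below
## 2^31 - 1 so it is always a valid R integer.
stageSeed <- function(seed, stage) {
    as.integer((as.numeric(seed) * 48271 + stage * 10007) %% 2147483629)
}

#' Simulate the plasmid guide pool
#'
#' True guide abundances are drawn from a log-normal whose coefficient of
#' variation equals `plasmid_dispersion` and normalized to sum to one; a
#' plasmid sequencing column is then drawn by [sequenceSample()] at
#' `plasmid_depth * length(library)` reads. Dispersion 0 gives an exactly
#' uniform pool.
#'
#' @param params a [SimParams-class].
#' @return list with `abundance` (numeric, sums to 1) and `counts`
#'   (integer vector named by guide).
#' @export
simulatePlasmid <- function(params) {
    stopifnot(is(params, "SimParams"))
    n <- length(params@library)
    d <- params@plasmid_dispersion
    if (d == 0) {
        ab <- rep(1 / n, n)
    } else {
        sdlog <- sqrt(log(1 + d^2))
        ab <- withr::with_seed(stageSeed(params@seed, 1L),
                               stats::rlnorm(n, meanlog = 0, sdlog = sdlog))
        ab <- ab / sum(ab)
    }
    names(ab) <- guideIds(params@library)
    counts <- sequenceSample(ab, round(params@plasmid_depth * n),
                             stageSeed(params@seed, 2L))
    list(abundance = ab, counts = counts)
}

#' Transduce a cell population at low MOI
#'
#' Integrations per cell are Poisson(`moi`); only cells with at least one
#' integration survive selection. Cells with more than one integration keep
#' all their guides (multiplet contamination is retained, as in real screens
#' mitigated only by low MOI). Each integration is edited with probability
#' `edit_efficiency`; unedited integrations make the cell behave as wild
#' type for that gene. With `n_cells = Inf` an expectation-mode population
#' is built instead: one edited and one unedited clone per guide, weighted
#' by plasmid abundance and edit efficiency (multiplet genotypes are a
#' second-order effect and are not represented in this mode).
#'
#' @param abundance normalized plasmid guide abundances.
#' @param params a [SimParams-class].
#' @return a [CellPopulation-class].
#' @export
transduce <- function(abundance, params) {
    stopifnot(is(params, "SimParams"))
    n <- length(params@library)
    stopifnot(length(abundance) == n)
    e <- params@edit_efficiency
    if (!is.finite(params@n_cells)) {
        w <- c(abundance * e, abundance * (1 - e))
        keep <- w > 0
        nclone <- sum(keep)
        return(new("CellPopulation",
                   guide = rep(seq_len(n), 2L)[keep],
                   clone = seq_len(nclone),
                   edited = c(rep(TRUE, n), rep(FALSE, n))[keep],
                   weight = w[keep],
                   growth = rep(1, nclone),
                   n_guides = n,
                   expectation = TRUE))
    }
    m <- params@moi
    withr::with_seed(stageSeed(params@seed, 3L), {
        n_inf <- stats::rbinom(1L, as.integer(params@n_cells), 1 - exp(-m))
        if (n_inf == 0L) stop("no cells transduced; increase n_cells or moi")
        # zero-truncated Poisson integration counts
        k <- stats::qpois(stats::runif(n_inf, stats::ppois(0, m), 1), m)
        total <- sum(k)
        guide <- sample.int(n, total, replace = TRUE, prob = abundance)
        clone <- rep.int(seq_len(n_inf), k)
        edited <- stats::runif(total) < e
    })
    new("CellPopulation",
        guide = guide, clone = clone, edited = edited,
        weight = rep(1, n_inf), growth = rep(1, n_inf),
        n_guides = n, expectation = FALSE)
}

## Per-clone per-passage growth multiplier: the product of (1 + s) over the
## edited genotypes a clone carries. s defaults to 0 for genes absent from
## the map and for non-targeting controls.
cloneGrowth <- function(pop, fitness_map, library) {
    if (length(fitness_map) && any(fitness_map <= -1))
        stop("selection coefficients must satisfy s > -1")
    s <- rep(0, length(library))
    gid <- geneIds(library)
    hit <- !is.na(gid) & gid %in% names(fitness_map)
    s[hit] <- fitness_map[gid[hit]]
    f <- ifelse(pop@edited, 1 + s[pop@guide], 1)
    g <- rep(1, length(pop@weight))
    lg <- rowsum(log(f), pop@clone)
    g[as.integer(rownames(lg))] <- exp(lg[, 1L])
    g
}

#' Propagate a population under selection
#'
#' Each passage multiplies every clone's weight by its growth factor
#' `prod(1 + s)` over its edited genotypes. A finite `bottleneck` then
#' resamples that many cells multinomially; `bottleneck = Inf` keeps the
#' exact (pre-normalization) expected weights, so a single edited gene with
#' coefficient s has weight `(1 + s)^t` after `t` passages.
#'
#' @param pop a [CellPopulation-class].
#' @param fitness_map named numeric gene_id -> s (s > -1).
#' @param library the [SgRNALibrary-class] the population was built from.
#' @param n_passages passages to run (>= 0).
#' @param bottleneck cells kept per passage, or `Inf`.
#' @param seed integer seed for bottleneck resampling.
#' @return list of [CellPopulation-class], of length `n_passages + 1`
#'   (element 1 is the input population).
#' @export
propagate <- function(pop, fitness_map, library, n_passages,
                      bottleneck = Inf, seed = 1L) {
    stopifnot(is(pop, "CellPopulation"), n_passages >= 0)
    pop@growth <- cloneGrowth(pop, fitness_map, library)
    traj <- vector("list", n_passages + 1L)
    traj[[1L]] <- pop
    if (n_passages == 0L) return(traj)
    withr::with_seed(stageSeed(seed, 4L), {
        for (t in seq_len(n_passages)) {
            w <- pop@weight * pop@growth
            if (is.finite(bottleneck)) {
                w <- as.numeric(stats::rmultinom(1L, as.integer(bottleneck),
                                                 w))
            }
            pop@weight <- w
            traj[[t + 1L]] <- pop
        }
    })
    traj
}

#' Per-guide abundance of a population
#'
#' Sums clone weights over every integration of each guide; a multiplet cell
#' contributes its weight to each guide it carries.
#'
#' @param pop a [CellPopulation-class].
#' @return numeric vector of length `n_guides`.
#' @rdname guideAbundance
#' @export
setMethod("guideAbundance", "CellPopulation", function(pop) {
    ab <- numeric(pop@n_guides)
    sums <- rowsum(pop@weight[pop@clone], pop@guide)
    ab[as.integer(rownames(sums))] <- sums[, 1L]
    ab
})

#' Sequence a sample by multinomial sampling
#'
#' Abstraction of library prep + short-read sequencing: `depth` reads are
#' allocated to guides by a multinomial draw on normalized abundances. The
#' returned column always sums exactly to `depth`.
#'
#' @param abundance nonnegative guide abundances, not all zero.
#' @param depth total reads (>= 0).
#' @param seed integer seed.
#' @return integer count vector (names preserved from `abundance`).
#' @export
sequenceSample <- function(abundance, depth, seed = 1L) {
    if (any(abundance < 0) || any(!is.finite(abundance)))
        stop("abundances must be finite and nonnegative")
    if (sum(abundance) <= 0) stop("all-zero abundances")
    stopifnot(depth >= 0)
    if (depth == 0)
        return(stats::setNames(integer(length(abundance)), names(abundance)))
    counts <- withr::with_seed(as.integer(seed),
        stats::rmultinom(1L, as.integer(depth), abundance))[, 1L]
    stats::setNames(as.integer(counts), names(abundance))
}

## Shared plumbing: plasmid -> transduction -> P0 population.
initialPopulation <- function(params) {
    pl <- simulatePlasmid(params)
    pop <- transduce(pl$abundance, params)
    list(plasmid = pl, pop = pop)
}

truthTable <- function(library, fitness_map = numeric(0),
                       reporter_loss_map = numeric(0)) {
    genes <- unique(geneIds(library)[!isControl(library)])
    s <- stats::setNames(rep(0, length(genes)), genes)
    s[names(fitness_map)[names(fitness_map) %in% genes]] <-
        fitness_map[names(fitness_map) %in% genes]
    p <- stats::setNames(rep(0, length(genes)), genes)
    p[names(reporter_loss_map)[names(reporter_loss_map) %in% genes]] <-
        reporter_loss_map[names(reporter_loss_map) %in% genes]
    DataFrame(gene_id = genes, s = unname(s), p_loss = unname(p),
              class_true = ifelse(s < 0, "essential",
                           ifelse(s > 0, "growth_restricting", "neutral")))
}

#' Simulate a fitness (dropout) screen
#'
#' Composes [simulatePlasmid()], [transduce()], [propagate()] and
#' [sequenceSample()] into a full negative/positive selection screen:
#' a plasmid sample, the post-selection starting population P0, and sampled
#' passages thereafter. Knockouts with s < 0 deplete over passages
#' (essential genes); s > 0 enrich (growth-restricting genes).
#'
#' @param params a [SimParams-class]; `fitness_map` supplies the planted
#'   selection coefficients.
#' @param sample_passages integer vector of passages to sequence; default
#'   every second passage plus the final one.
#' @return list with `counts` (a [SummarizedExperiment::SummarizedExperiment]
#'   with columns `plasmid`, `P0`, `P<t>`, built by [screenCounts()]) and
#'   `truth` (per-gene `DataFrame` with `s` and true class).
#' @export
simulateFitnessScreen <- function(params, sample_passages = NULL) {
    stopifnot(is(params, "SimParams"))
    np <- params@n_passages
    if (is.null(sample_passages)) {
        sample_passages <- unique(c(seq(2L, np, by = 2L), np))
        sample_passages <- sample_passages[sample_passages >= 1L]
    }
    ini <- initialPopulation(params)
    traj <- propagate(ini$pop, params@fitness_map, params@library,
                      np, params@bottleneck, params@seed)
    cols <- list(plasmid = ini$plasmid$counts)
    cols$P0 <- sequenceSample(guideAbundance(traj[[1L]]), params@seq_depth,
                              stageSeed(params@seed, 10L))
    for (t in sample_passages) {
        cols[[paste0("P", t)]] <- sequenceSample(
            guideAbundance(traj[[t + 1L]]), params@seq_depth,
            stageSeed(params@seed, 10L + t))
    }
    m <- do.call(cbind, cols)
    rownames(m) <- guideIds(params@library)
    list(counts = screenCounts(m, params@library),
         truth = truthTable(params@library, fitness_map = params@fitness_map))
}

#' Simulate a FACS reporter-loss screen
#'
#' Positive-selection arm: cells carrying knockouts of pro-pluripotency
#' genes lose a fluorescent pluripotency reporter and are collected in a
#' reporter-low sort gate. Each cell is reporter-low with probability
#' `1 - (1 - p_bg) * prod(1 - p_loss)` over its edited genotypes; the sorted
#' sample is drawn from cells conditional on being reporter-low, capped at
#' `sort_fraction` of the population. Returns `P0` and `sorted` count
#' columns plus the planted truth.
#'
#' @param params a [SimParams-class]; `reporter_loss_map` supplies the
#'   planted per-gene reporter-loss probabilities.
#' @return list with `counts` (SummarizedExperiment: `P0`, `sorted`) and
#'   `truth` (per-gene `DataFrame` with `p_loss`).
#' @export
simulateFacsScreen <- function(params) {
    stopifnot(is(params, "SimParams"))
    if (length(params@reporter_loss_map) &&
        params@p_bg >= max(params@reporter_loss_map))
        warning("no contrast: background reporter-low rate >= all planted p_loss")
    ini <- initialPopulation(params)
    pop <- ini$pop
    n <- length(params@library)

    p_loss <- rep(0, n)
    gid <- geneIds(params@library)
    hit <- !is.na(gid) & gid %in% names(params@reporter_loss_map)
    p_loss[hit] <- params@reporter_loss_map[gid[hit]]

    # per-clone probability of falling in the reporter-low gate
    keep_frac <- ifelse(pop@edited, 1 - p_loss[pop@guide], 1)
    lk <- rowsum(log(keep_frac), pop@clone)
    p_keep <- rep(1, length(pop@weight))
    p_keep[as.integer(rownames(lk))] <- exp(lk[, 1L])
    p_low <- 1 - (1 - params@p_bg) * p_keep

    total <- sum(pop@weight)
    f_low <- sum(pop@weight * p_low) / total
    sorted_pop <- pop
    if (pop@expectation) {
        sorted_pop@weight <- pop@weight * p_low
    } else {
        n_sorted <- round(min(f_low, params@sort_fraction) * total)
        sorted_pop@weight <- as.numeric(withr::with_seed(
            stageSeed(params@seed, 5L),
            stats::rmultinom(1L, as.integer(n_sorted), pop@weight * p_low)))
    }
    m <- cbind(
        P0 = sequenceSample(guideAbundance(pop), params@seq_depth,
                            stageSeed(params@seed, 10L)),
        sorted = sequenceSample(guideAbundance(sorted_pop), params@seq_depth,
                                stageSeed(params@seed, 11L)))
    rownames(m) <- guideIds(params@library)
    list(counts = screenCounts(m, params@library),
         truth = truthTable(params@library,
                            reporter_loss_map = params@reporter_loss_map))
}
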