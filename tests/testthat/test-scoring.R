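lfcFrame <- function(log2fc, gene_id, is_control = rep(FALSE, length(log2fc)))
    S4Vectors::DataFrame(guide_id = paste0("g", seq_along(log2fc)),
                         gene_id = gene_id, is_control = is_control,
                         log2fc = log2fc)

test_that("guide log2 fold-changes follow the normalized ratio definition", {
    m <- matrix(c(100L, 999900L, 0L, 1000000L), ncol = 2,
                dimnames = list(c("g1", "g2"), c("P0", "P10")))
    se <- screenCounts(m)
    lfc <- guideLog2FC(se, "P0", "P10", pseudocount = 1)
    # hand formula through the full RPM+1 normalization
    n0 <- (100 + 1) / (100 + 1 + 999900 + 1) * 1e6
    n1 <- (0 + 1) / (0 + 1 + 1000000 + 1) * 1e6
    expect_equal(lfc$log2fc[1], log2(n1 / n0))
    # equal depths: close to log2(1/101)
    expect_lt(abs(lfc$log2fc[1] - log2(1 / 101)), 1e-5)

    same <- guideLog2FC(se, "P0", "P0")
    expect_true(all(same$log2fc == 0))

    m4 <- matrix(c(10L, 90L, 40L, 60L), ncol = 2,
                 dimnames = list(c("g1", "g2"), c("a", "b")))
    # guide 1 normalized value rises 4x (pseudocount 0): +2
    lfc4 <- guideLog2FC(screenCounts(m4), "a", "b", pseudocount = 0)
    expect_equal(lfc4$log2fc[1], 2)

    expect_error(guideLog2FC(se, "P0", "nope"), "missing sample: nope")
})

test_that("CRISPR Score is the per-gene mean of guide log2FCs", {
    lfc <- lfcFrame(c(-1, -1, -3, -3), rep("GA", 4))
    expect_equal(crisprScore(lfc)$cs, -2)

    one <- lfcFrame(0.7, "GB")
    expect_equal(crisprScore(one)$cs, 0.7)

    # NTCs are excluded from gene scores
    mix <- lfcFrame(c(-2, -4, 10), c("GA", "GA", NA),
                    is_control = c(FALSE, FALSE, TRUE))
    expect_equal(crisprScore(mix)$cs, -3)

    # linearity: scaling all guide LFCs by c scales every CS by c
    set.seed(4)
    lfc2 <- lfcFrame(rnorm(40), rep(sprintf("G%02d", 1:10), each = 4))
    cs1 <- crisprScore(lfc2)
    lfc2$log2fc <- lfc2$log2fc * 2.5
    cs2 <- crisprScore(lfc2)
    expect_equal(cs2$cs, 2.5 * cs1$cs)
})

test_that("end-to-end CS matches the brute-force oracle from raw counts", {
    for (seed in 1:3) {
        lib <- buildLibrary(40, 4, 60)
        fm <- stats::setNames(withr::with_seed(seed,
                                  stats::runif(10, -0.6, 0.4)),
                              sprintf("G%04d", 1:10))
        sim <- simulateFitnessScreen(SimParams(lib, fitness_map = fm,
                                               seq_depth = 20000,
                                               seed = seed))
        cs <- crisprScore(guideLog2FC(sim$counts, "P0", "P10"))
        m <- SummarizedExperiment::assay(sim$counts)
        expected <- oracleCS(m, geneIds(lib), isControl(lib), "P0", "P10")
        got <- stats::setNames(cs$cs, cs$gene_id)[names(expected)]
        expect_equal(unname(got), unname(expected), tolerance = 1e-12)
    }
})

test_that("the NTC pseudo-gene null has mean-of-k variance", {
    null0 <- buildNtcNull(rep(0, 100), 4, 500, seed = 1)
    expect_true(all(null0@cs == 0))

    x0 <- withr::with_seed(1, rnorm(100))
    expect_identical(buildNtcNull(x0, 4, 200, seed = 5)@cs,
                     buildNtcNull(x0, 4, 200, seed = 5)@cs)

    x <- withr::with_seed(2, rnorm(1000, sd = 2))
    null <- buildNtcNull(x, 4, 10000, seed = 7)
    expect_lt(abs(stats::var(null@cs) / (stats::var(x) / 4) - 1), 0.15)

    expect_error(buildNtcNull(rnorm(3), 4, 10), "too few NTC")
})

test_that("classification uses add-one empirical tails with BH control", {
    null <- new("NullModel", cs = seq(-1, 1, length.out = 999),
                guides_per_pseudo = 4L, seed = 1L)
    scores <- crisprScore(lfcFrame(c(rep(-5, 4), rep(0.01, 4)),
                                   rep(c("GA", "GB"), each = 4)))
    cls <- classifyGenes(scores, null, 0.05)
    ga <- cls[cls$gene_id == "GA", ]
    # CS below every null value: smallest attainable p = 1/(n+1)
    expect_equal(ga$p_lower, 1 / 1000)
    expect_equal(ga$class, "essential")
    expect_equal(cls[cls$gene_id == "GB", "class"], "other")

    # monotone in CS: no "other" gene scores below the worst essential
    lib <- buildLibrary(100, 4, 200)
    fm <- stats::setNames(rep(-0.5, 15), sprintf("G%04d", 1:15))
    sim <- simulateFitnessScreen(SimParams(lib, fitness_map = fm, seed = 11))
    lfc <- guideLog2FC(sim$counts, "P0", "P10")
    tab <- classifyGenes(crisprScore(lfc), buildNtcNull(lfc, seed = 11), 0.05)
    ess_max <- max(tab$cs[tab$class == "essential"])
    expect_true(all(tab$cs[tab$class == "other"] > ess_max))
})

test_that("class-vs-NTC Welch test matches the textbook formula", {
    x <- c(-2.1, -1.9, -2.3)   # "essential" CS values
    y <- c(0.1, -0.2, 0.05)    # pseudo-gene CS values
    scores <- new("GeneScoreTable", S4Vectors::DataFrame(
        gene_id = paste0("G", 1:3), cs = x, n_guides = 4L,
        class = "essential"))
    null <- new("NullModel", cs = y, guides_per_pseudo = 4L, seed = 1L)
    got <- classVsNtcTest(scores, "essential", null)
    # Welch statistic by hand
    se2 <- stats::var(x) / 3 + stats::var(y) / 3
    t_hand <- (mean(x) - mean(y)) / sqrt(se2)
    df_hand <- se2^2 / ((stats::var(x) / 3)^2 / 2 + (stats::var(y) / 3)^2 / 2)
    expect_equal(got$t, t_hand)
    expect_equal(got$df, df_hand)
    expect_equal(got$p, 2 * stats::pt(-abs(t_hand), df_hand))

    # identical degenerate groups: t = 0, p = 1
    sc0 <- new("GeneScoreTable", S4Vectors::DataFrame(
        gene_id = paste0("G", 1:2), cs = c(1, 1), n_guides = 4L,
        class = "essential"))
    null0 <- new("NullModel", cs = c(1, 1), guides_per_pseudo = 4L,
                 seed = 1L)
    expect_equal(classVsNtcTest(sc0, "essential", null0)[c("t", "p")],
                 list(t = 0, p = 1))

    # groups separated by many pooled SDs
    big <- new("GeneScoreTable", S4Vectors::DataFrame(
        gene_id = paste0("G", 1:100),
        cs = withr::with_seed(1, rnorm(100, -10)), n_guides = 4L,
        class = "essential"))
    nullb <- new("NullModel", cs = withr::with_seed(2, rnorm(100)),
                 guides_per_pseudo = 4L, seed = 1L)
    expect_lt(classVsNtcTest(big, "essential", nullb)$p, 0.001)
})

test_that("top-k intersection follows mean rank with lexicographic ties", {
    mkTab <- function(cs, ids) new("GeneScoreTable",
        S4Vectors::DataFrame(gene_id = ids, cs = cs,
                             n_guides = 4L))
    t1 <- mkTab(seq(-3, 3, length.out = 30), sprintf("G%02d", 1:30))
    expect_length(rankAndIntersect(t1, t1, 20, "depleted"), 20L)

    t2 <- mkTab(seq(-3, 3, length.out = 30), sprintf("H%02d", 1:30))
    expect_length(rankAndIntersect(t1, t2, 10, "depleted"), 0L)

    # brute-force oracle under the stated tie rule
    set.seed(31)
    for (i in 1:10) {
        ids <- sprintf("G%02d", 1:25)
        a <- mkTab(sample(rep(seq(-2, 2, 0.5), length.out = 25)), ids)
        b <- mkTab(sample(rep(seq(-2, 2, 0.5), length.out = 25)), ids)
        k <- 8L
        topOracle <- function(tab, dir) {
            df <- data.frame(id = tab$gene_id, cs = tab$cs)
            df <- if (dir == "depleted") df[order(df$cs, df$id), ]
                  else df[order(-df$cs, df$id), ]
            r <- stats::setNames(seq_len(k), df$id[seq_len(k)])
            r
        }
        for (dir in c("depleted", "enriched")) {
            ra <- topOracle(a, dir); rb <- topOracle(b, dir)
            common <- intersect(names(ra), names(rb))
            mr <- (ra[common] + rb[common]) / 2
            expected <- common[order(mr, common)]
            expect_identical(rankAndIntersect(a, b, k, dir), expected)
        }
    }
})

test_that("gene trajectories mirror the normalized matrix", {
    lib <- buildLibrary(20, 4, 20)
    sim <- simulateFitnessScreen(SimParams(lib,
        fitness_map = c(G0001 = -0.5), seed = 2))
    tr <- geneTrajectory(sim$counts, "G0001")
    expect_equal(dim(tr), c(4L, 7L))
    r <- SummarizedExperiment::assay(normalizeRPM(sim$counts, 1), "rpm")
    expect_equal(tr, r[paste0("G0001_sg", 1:4), ])
    # planted essential declines across passages
    expect_true(all(tr[, "P10"] < tr[, "P0"]))
    expect_error(geneTrajectory(sim$counts, "nope"), "unknown gene")
})
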