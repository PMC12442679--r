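smallLib <- function(n_genes = 50, ntc = 100)
    buildLibrary(n_genes, 4, ntc)

test_that("plasmid pool matches its log-normal parameterization", {
    lib <- smallLib()
    p0 <- SimParams(lib, plasmid_dispersion = 0, seed = 1)
    pl <- simulatePlasmid(p0)
    expect_true(all(abs(pl$abundance - 1 / length(lib)) < 1e-12))
    expect_equal(sum(pl$counts), round(500 * length(lib)))

    # same seed -> identical; different seed -> different
    p1 <- SimParams(lib, seed = 5)
    expect_identical(simulatePlasmid(p1)$counts, simulatePlasmid(p1)$counts)
    expect_false(identical(simulatePlasmid(p1)$counts,
                           simulatePlasmid(SimParams(lib, seed = 6))$counts))

    # empirical CV of true abundances ~ dispersion (moment check)
    big <- buildLibrary(2610, 4, 1000)
    cvs <- vapply(1:20, function(s) {
        ab <- simulatePlasmid(SimParams(big, plasmid_dispersion = 0.5,
                                        seed = s))$abundance
        stats::sd(ab) / mean(ab)
    }, numeric(1))
    expect_lt(abs(mean(cvs) - 0.5), 0.05)
})

test_that("transduction follows the Poisson low-MOI model", {
    lib <- smallLib()
    pl <- simulatePlasmid(SimParams(lib, seed = 1))

    # edit_efficiency = 1: every integration is edited
    p <- SimParams(lib, n_cells = 5e4, edit_efficiency = 1, seed = 2)
    pop <- transduce(pl$abundance, p)
    expect_true(all(pop@edited))

    # multi-integration share among infected at moi = 0.3:
    # (1 - e^-m - m e^-m) / (1 - e^-m)
    m <- 0.3
    expected <- (1 - exp(-m) - m * exp(-m)) / (1 - exp(-m))
    p2 <- SimParams(lib, n_cells = 1e6, moi = m, seed = 3)
    pop2 <- transduce(pl$abundance, p2)
    k <- tabulate(tabulate(pop2@clone))
    share <- 1 - k[1] / sum(k)
    expect_lt(abs(share - expected), 3 * sqrt(expected * (1 - expected) / sum(k)))

    # infected fraction ~ moi for small moi
    p3 <- SimParams(lib, n_cells = 1e6, moi = 0.01, seed = 4)
    pop3 <- transduce(pl$abundance, p3)
    inf_frac <- length(pop3@weight) / 1e6
    expect_lt(abs(inf_frac - (1 - exp(-0.01))), 4e-4)
})

test_that("propagation follows (1+s)^t and is neutral when s = 0", {
    lib <- smallLib()
    pl <- simulatePlasmid(SimParams(lib, seed = 1))
    pop <- transduce(pl$abundance, SimParams(lib, edit_efficiency = 1))

    # neutral dynamics: relative abundances exactly unchanged
    tr <- propagate(pop, numeric(0), lib, 5)
    a0 <- guideAbundance(tr[[1]]); a5 <- guideAbundance(tr[[6]])
    expect_equal(a5 / sum(a5), a0 / sum(a0), tolerance = 1e-12)

    # closed form: s = -0.5 over 3 passages -> weight x 0.125 exactly
    tr2 <- propagate(pop, c(G0001 = -0.5), lib, 3)
    w0 <- guideAbundance(tr2[[1]]); w3 <- guideAbundance(tr2[[4]])
    g1 <- which(geneIds(lib) == "G0001")
    expect_equal(w3[g1] / w0[g1], rep(0.125, 4), tolerance = 1e-12)
    others <- setdiff(which(!isControl(lib)), g1)
    expect_equal(w3[others], w0[others], tolerance = 1e-12)

    expect_error(propagate(pop, c(G0001 = -1), lib, 2), "s > -1")
})

test_that("planted essentials decline monotonically across passages", {
    lib <- buildLibrary(30, 4, 50)
    ess <- sprintf("G%04d", 1:5)
    fm <- stats::setNames(rep(-0.4, 5), ess)
    rel <- matrix(0, 20, 6)
    for (s in 1:20) {
        p <- SimParams(lib, fitness_map = fm, n_cells = 5e4,
                       bottleneck = 5e4, n_passages = 5L, seed = s)
        pl <- simulatePlasmid(p)
        pop <- transduce(pl$abundance, p)
        tr <- propagate(pop, fm, lib, 5, bottleneck = 5e4, seed = s)
        sel <- geneIds(lib) %in% ess
        rel[s, ] <- vapply(tr, function(x) {
            a <- guideAbundance(x)
            sum(a[sel]) / sum(a)
        }, numeric(1))
    }
    expect_true(all(diff(colMeans(rel)) < 0))
})

test_that("sequencing conserves depth and matches multinomial moments", {
    ab <- c(a = 0, b = 1, c = 3)
    expect_identical(sequenceSample(ab, 0, 1), c(a = 0L, b = 0L, c = 0L))
    draws <- t(vapply(1:200, function(s) sequenceSample(ab, 400, s),
                      integer(3)))
    expect_true(all(rowSums(draws) == 400L))
    expect_true(all(draws[, "a"] == 0L))
    # expected count = depth * relative abundance, within 3 SE
    exp_b <- 400 * 1 / 4
    se_b <- sqrt(400 * 0.25 * 0.75) / sqrt(200)
    expect_lt(abs(mean(draws[, "b"]) - exp_b), 3 * se_b)
    expect_error(sequenceSample(c(0, 0), 10, 1), "all-zero")
})

test_that("fitness screens are deterministic and null-centered", {
    lib <- buildLibrary(500, 4, 200)
    p <- SimParams(lib, n_passages = 10L, seed = 42)
    s1 <- simulateFitnessScreen(p)
    s2 <- simulateFitnessScreen(p)
    expect_identical(SummarizedExperiment::assay(s1$counts),
                     SummarizedExperiment::assay(s2$counts))

    # all-neutral: per-guide log2FC (final vs P0) centered at 0
    lfc <- guideLog2FC(s1$counts, "P0", "P10")
    expect_lt(abs(mean(lfc$log2fc)), 0.02)

    # planted essentials occupy the most-negative CS tail
    ess <- sprintf("G%04d", 1:20)
    pe <- SimParams(lib, fitness_map = stats::setNames(rep(-0.5, 20), ess),
                    n_passages = 10L, seed = 7)
    sim <- simulateFitnessScreen(pe)
    cs <- crisprScore(guideLog2FC(sim$counts, "P0", "P10"))
    worst <- cs$gene_id[order(cs$cs)][1:20]
    expect_setequal(worst, ess)
})

test_that("sgRNA coverage decreases over passages under negative selection", {
    lib <- buildLibrary(100, 4, 100)
    ess <- sprintf("G%04d", 1:30)
    # vapply returns a samples x seeds matrix: average across seeds
    cov <- rowMeans(vapply(1:20, function(s) {
        sim <- simulateFitnessScreen(SimParams(lib,
            fitness_map = stats::setNames(rep(-0.6, 30), ess),
            n_cells = 3e4, bottleneck = 2e4, n_passages = 10L,
            seq_depth = 60000, seed = s))
        samples <- paste0("P", c(0, 2, 4, 6, 8, 10))
        vapply(samples, function(x)
            coverageFraction(sim$counts, x), numeric(1))
    }, numeric(6)))
    # non-increasing in expectation; allow Monte-Carlo jitter on the means
    expect_true(all(diff(cov) <= 0.005))
    expect_lt(cov[6], cov[1])
})

test_that("FACS sorting enriches planted reporter-loss genes", {
    lib <- buildLibrary(200, 4, 200)
    planted <- sprintf("G%04d", 1:20)
    rl <- stats::setNames(rep(0.8, 20), planted)

    hits <- vapply(1:20, function(s) {
        sim <- simulateFacsScreen(SimParams(lib, reporter_loss_map = rl,
                                            p_bg = 0.02, seed = s))
        lfc <- guideLog2FC(sim$counts, "P0", "sorted")
        cs <- crisprScore(lfc)
        top <- cs$gene_id[order(-cs$cs)][1:20]
        sum(planted %in% top)
    }, numeric(1))
    expect_gte(sum(hits == 20), 19)

    # null property: with every p_loss = 0 all clones share p_low = p_bg,
    # the sorted composition matches P0 and NTC log2FC is centered at 0
    null_sim <- suppressWarnings(simulateFacsScreen(SimParams(lib,
        reporter_loss_map = stats::setNames(rep(0, 20), planted),
        p_bg = 0.02, seed = 1)))
    null_lfc <- guideLog2FC(null_sim$counts, "P0", "sorted")
    expect_lt(abs(mean(null_lfc$log2fc)), 0.05)
    expect_lt(abs(mean(null_lfc$log2fc[null_lfc$is_control])), 0.05)

    expect_warning(simulateFacsScreen(SimParams(lib,
        reporter_loss_map = stats::setNames(rep(0.1, 5), planted[1:5]),
        p_bg = 0.5, seed = 1)), "no contrast")
})

test_that("mean CS responds monotonically to the selection coefficient", {
    s_grid <- c(-0.6, -0.4, -0.2, 0, 0.2)
    lib <- buildLibrary(50, 4, 200)
    # ten genes per s value
    fm <- stats::setNames(rep(s_grid, each = 10), sprintf("G%04d", 1:50))
    fm <- fm[fm != 0]
    means <- rowMeans(vapply(1:5, function(seed) {
        sim <- simulateFitnessScreen(SimParams(lib, fitness_map = fm,
                                               n_passages = 6L, seed = seed))
        cs <- crisprScore(guideLog2FC(sim$counts, "P0", "P6"))
        cs_by_gene <- stats::setNames(cs$cs, cs$gene_id)
        vapply(seq_along(s_grid), function(k)
            mean(cs_by_gene[sprintf("G%04d", (k - 1) * 10 + 1:10)]),
            numeric(1))
    }, numeric(5)))
    expect_true(all(diff(means) > 0))
})
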