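library(SingleCellExperiment)

normSCE <- function(X) {
    SingleCellExperiment(assays = list(normalized = X))
}

test_that("gene-set scores match a brute-force recomputation at a fixed seed", {
    set.seed(41)
    ng <- 120; nc <- 40
    X <- matrix(rexp(ng * nc, 1), ng,
                dimnames = list(sprintf("g%03d", 1:ng),
                                sprintf("c%02d", 1:nc)))
    markers <- c("g005", "g050", "g100")
    sc <- scoreGeneSet(normSCE(X), markers, n_bins = 10, ctrl_size = 8,
                       seed = 99)

    # oracle: rebuild bins from the sort order, replay the seeded sampling,
    # then score with explicit per-cell loops
    avg <- apply(X, 1, mean)
    r <- rank(avg, ties.method = "first")
    bin <- ceiling(r * 10 / ng)
    names(bin) <- rownames(X)
    ctrl <- local({
        set.seed(99)
        picked <- character(0)
        for (b in unique(bin[markers])) {
            pool <- names(bin)[bin == b]
            picked <- c(picked, sample(pool, min(8, length(pool))))
        }
        unique(picked)
    })
    oracle <- numeric(nc)
    for (j in 1:nc)
        oracle[j] <- mean(X[markers, j]) - mean(X[ctrl, j])
    expect_equal(as.numeric(sc), oracle, tolerance = 1e-12)
    # control genes are drawn from the markers' expression bins
    expect_true(all(bin[attr(sc, "control_genes")] %in% bin[markers]))
})

test_that("a score of a set against its own pool is zero; shifts are recovered", {
    X <- matrix(runif(20 * 15), 20,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("c%02d", 1:15)))
    # single bin, ctrl_size >= all genes, gene_set = all genes
    sc <- scoreGeneSet(normSCE(X), rownames(X), n_bins = 1, ctrl_size = 20,
                       seed = 1)
    expect_lt(max(abs(sc)), 1e-12)

    # markers sit one unit above an otherwise flat background
    set.seed(42)
    ng <- 500
    bg <- matrix(rnorm(ng * 30, 5, 0.1), ng)
    rownames(bg) <- sprintf("g%03d", 1:ng)
    colnames(bg) <- sprintf("c%02d", 1:30)
    mk <- sprintf("g%03d", 1:10)
    bg[mk, ] <- bg[mk, ] + 1
    sc2 <- scoreGeneSet(normSCE(bg), mk, n_bins = 1, ctrl_size = ng,
                        seed = 2)
    expect_true(all(abs(sc2 - 1) < 0.1))

    expect_error(scoreGeneSet(normSCE(X), c("nope1", "nope2")), "missing")
})

test_that("phase assignment follows the two-score rule", {
    expect_identical(assignPhase(c(-0.2, 0.3, 0.1, 0),
                                 c(-0.1, 0.1, 0.3, 0)),
                     c("G1", "S", "G2M", "G1"))
    # equal positive scores resolve to G2M (argmax tie-break)
    expect_identical(assignPhase(0.2, 0.2), "G2M")
    # adding a constant only moves calls through the zero threshold
    s <- c(-0.5, -0.1, 0.4); g <- c(-0.6, -0.3, 0.1)
    shifted <- assignPhase(s + 1, g + 1)
    expect_true(all(shifted %in% c("S", "G2M")))
    expect_identical(assignPhase(s, g)[3], shifted[3])
})

test_that("phase fractions are per-group simplexes and recover simulation", {
    calls <- S4Vectors::DataFrame(
        barcode = sprintf("c%d", 1:4),
        s_score = 0, g2m_score = 0,
        phase = c("G1", "G1", "S", "G2M"))
    ca <- makeAssignment(sprintf("c%d", 1:4), rep("h1", 4), rep("t1", 4),
                         rep("exon_deletion", 4))
    fr <- phaseFractions(calls, ca, level = "guide")
    expect_equal(c(fr$f_G1, fr$f_S, fr$f_G2M), c(0.5, 0.25, 0.25))
    expect_equal(fr$f_G1 + fr$f_S + fr$f_G2M, 1)

    # simulated control cells: fractions within 3 SE of the generating simplex
    lib <- makeLibrary(sprintf("ig_%d", 1:4), rep("intergenic", 4),
                       sprintf("ig_%d", 1:4))
    truth <- simulateTruth(lib, n_genes = 100, seed = 43)
    props <- c(G1 = 0.18, S = 0.52, G2M = 0.30)
    sce <- simulateCells(lib, truth, n_cells_per_guide = 1000,
                         p_detect_cas9 = 1, p_detect_cas12a = 1,
                         doublet_rate = 0, decoupling_rate = 0,
                         phase_proportions = props, lambda_ambient = 0,
                         seed = 44)
    cat <- assignPerturbations(categorizeCapture(detectGuides(sce, lib)), lib)
    truth_calls <- S4Vectors::DataFrame(barcode = colnames(sce),
                                        phase = sce$true_phase)
    fr2 <- phaseFractions(truth_calls, cat, level = "target")
    n <- 1000
    for (ph in names(props)) {
        se <- sqrt(props[ph] * (1 - props[ph]) / n)
        expect_true(all(abs(fr2[[paste0("f_", ph)]] - props[ph]) <= 3 * se))
    }
})

test_that("one-sided Fisher p equals the hypergeometric tail by enumeration", {
    tail_sum <- function(a, b, c_, d) {
        # enumerate P(X >= a) for the 2x2 margins
        kmax <- min(a + b, a + c_)
        sum(vapply(a:kmax, function(k)
            dhyper(k, a + c_, b + d, a + b), numeric(1)))
    }
    # the worked table: 60/200 target vs 170/1000 control, G1 enrichment
    p_pkg <- fisher.test(matrix(c(60, 140, 170, 830), 2, byrow = TRUE),
                         alternative = "greater")$p.value
    expect_equal(p_pkg, tail_sum(60, 140, 170, 830), tolerance = 1e-12)
    set.seed(45)
    for (i in 1:50) {
        a <- rpois(1, 20); b <- rpois(1, 50)
        c_ <- rpois(1, 30); d <- rpois(1, 80)
        if (a + b == 0 || a + c_ == 0) next
        p1 <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                          alternative = "greater")$p.value
        expect_equal(p1, tail_sum(a, b, c_, d), tolerance = 1e-12)
    }
})

test_that("Mann-Whitney normal approximation matches the closed form with ties", {
    mw_oracle <- function(x, y) {
        # one-sided (x > y), tie-corrected z, no continuity correction
        n1 <- length(x); n2 <- length(y)
        r <- rank(c(x, y))
        U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
        mu <- n1 * n2 / 2
        ties <- table(r)
        n <- n1 + n2
        sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        pnorm((U - mu) / sqrt(sigma2), lower.tail = FALSE)
    }
    set.seed(46)
    for (i in 1:20) {
        x <- round(runif(3 + i %% 4), 1)     # coarse values force ties
        y <- round(runif(40), 1)
        p_pkg <- suppressWarnings(wilcox.test(
            x, y, alternative = "greater", exact = FALSE,
            correct = FALSE)$p.value)
        expect_equal(p_pkg, mw_oracle(x, y), tolerance = 1e-10)
    }
})

test_that("the dual gate is calibrated on null exon targets", {
    set.seed(47)
    props <- c(0.17, 0.53, 0.30)
    ctrl <- nullControls()
    n_targets <- 200
    tf <- makeFractions(
        replicate(n_targets * 3, rphase(134, props), simplify = FALSE),
        rep(sprintf("exon_%03d", seq_len(n_targets)), each = 3),
        rep("exon_deletion", n_targets * 3))
    res <- exonPhaseEnrichment(tf, ctrl)
    called <- unique(res$target_id[res$significant])
    expect_lte(length(called) / n_targets, 0.02)
    # identical composition: no phase significant
    same <- makeFractions(replicate(3, rphase(400, props), simplify = FALSE),
                          rep("exon_same", 3), rep("exon_deletion", 3))
    res_same <- exonPhaseEnrichment(same, ctrl)
    expect_false(any(res_same$significant))
})

test_that("a planted G1 shift is called by both gates", {
    set.seed(48)
    ctrl <- nullControls()
    shift_props <- c(0.35, 0.41, 0.24)
    n_t <- 40
    tf <- makeFractions(
        replicate(n_t * 3, rphase(134, shift_props), simplify = FALSE),
        rep(sprintf("exon_s%02d", seq_len(n_t)), each = 3),
        rep("exon_deletion", n_t * 3))
    res <- exonPhaseEnrichment(tf, ctrl)
    g1_called <- vapply(split(res, res$target_id), function(d)
        identical(d$called_phase[1], "G1"), logical(1))
    expect_gte(mean(g1_called), 0.9)

    ko <- knockoutPhaseEnrichment(tf, ctrl)
    ko_called <- vapply(split(ko, ko$target_id), function(d)
        identical(d$called_phase[1], "G1"), logical(1))
    expect_gte(mean(ko_called), 0.9)
})

test_that("every dual-gate call also passes the Fisher-only gate", {
    set.seed(49)
    ctrl <- nullControls()
    mixed <- rbind(
        makeFractions(replicate(60, rphase(134, c(0.17, 0.53, 0.30)),
                                simplify = FALSE),
                      rep(sprintf("exon_n%02d", 1:20), each = 3),
                      rep("exon_deletion", 60)),
        makeFractions(replicate(30, rphase(134, c(0.30, 0.45, 0.25)),
                                simplify = FALSE),
                      rep(sprintf("exon_p%02d", 1:10), each = 3),
                      rep("exon_deletion", 30)))
    dual <- exonPhaseEnrichment(mixed, ctrl)
    single <- knockoutPhaseEnrichment(mixed, ctrl)
    key <- paste(dual$target_id, dual$phase)
    skey <- paste(single$target_id, single$phase)
    passing <- key[dual$significant]
    expect_true(all(passing %in% skey[single$significant]))
})

test_that("single-guide exon targets are unassessable under the dual gate", {
    set.seed(50)
    ctrl <- nullControls(10, 200)
    tf <- makeFractions(list(rphase(200, c(0.5, 0.3, 0.2))),
                        "exon_one", "exon_deletion")
    res <- exonPhaseEnrichment(tf, ctrl)
    expect_true(all(!res$assessable))
    expect_true(all(!res$significant))
})

test_that("Fisher on identical margins and proportions is non-significant", {
    p <- fisher.test(matrix(c(50, 150, 250, 750), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    expect_gte(p, 0.5)
})
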