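lib2 <- makeLibrary(c("h7", "h9", "nt_1"),
                    c("exon_deletion", "exon_deletion", "non_targeting"),
                    c("exon_007", "exon_009", "nt_1"),
                    guide_index = c(1L, 1L, 1L))
feat2 <- paste0(rep(c("h7", "h9", "nt_1"), each = 2), c("|cas9", "|cas12a"))

test_that("guide detection applies the UMI and dominance rules", {
    m <- makeGuideMatrix(list(
        c("h7|cas9" = 25, "h9|cas9" = 0),      # single clear guide
        c("h7|cas9" = 25, "h9|cas9" = 20),     # co-detection: both reported
        c("h7|cas9" = 25, "h9|cas9" = 10),     # 10 >= min_umi: both reported
        c("h7|cas9" = 12, "h9|cas9" = 4),      # dominance met (12 >= 3*4)
        c("h7|cas9" = 11, "h9|cas9" = 4),      # dominance not met
        c("nt_1|cas12a" = 8)                   # cas12a-only
    ), feat2)
    ca <- detectGuides(m, lib2, min_umi = 5, dominance_ratio = 3)
    d9 <- as.list(assignmentTable(ca)$detected_cas9)
    d12 <- as.list(assignmentTable(ca)$detected_cas12a)
    expect_identical(d9[[1]], "h7")
    expect_setequal(d9[[2]], c("h7", "h9"))
    expect_setequal(d9[[3]], c("h7", "h9"))
    expect_identical(d9[[4]], "h7")
    expect_identical(d9[[5]], character(0))
    expect_identical(d9[[6]], character(0))
    expect_identical(d12[[6]], "nt_1")
})

test_that("raising min_umi never increases the detected-guide count", {
    set.seed(99)
    feats <- feat2
    for (rep_i in 1:20) {
        cells <- replicate(15, {
            v <- rpois(length(feats), 4) * rbinom(length(feats), 1, 0.5)
            names(v) <- feats
            v
        }, simplify = FALSE)
        m <- makeGuideMatrix(cells, feats)
        prev <- NULL
        for (mu in c(1, 2, 4, 8, 16)) {
            ca <- detectGuides(m, lib2, min_umi = mu, dominance_ratio = 3)
            n <- lengths(assignmentTable(ca)$detected_cas9) +
                lengths(assignmentTable(ca)$detected_cas12a)
            if (!is.null(prev)) expect_true(all(n <= prev))
            prev <- n
        }
    }
})

test_that("detection on a noise-free simulation recovers truth exactly", {
    fx <- cleanScreen()
    ca <- detectGuides(fx$sce, fx$lib)
    df <- assignmentTable(ca)
    cd <- SummarizedExperiment::colData(fx$sce)
    ok9 <- mapply(function(d, h) identical(d, h),
                  as.list(df$detected_cas9), cd$hgrna_1)
    ok12 <- mapply(function(d, h) identical(d, h),
                   as.list(df$detected_cas12a), cd$hgrna_1)
    expect_true(all(ok9))
    expect_true(all(ok12))
})

test_that("capture categories partition cells, with both normalizations", {
    m <- makeGuideMatrix(list(
        c("h7|cas9" = 25, "h7|cas12a" = 25),  # dual
        c("h7|cas9" = 25),                    # cas9_only
        c("h9|cas12a" = 25),                  # cas12a_only
        c("h7|cas9" = 1)                      # none
    ), feat2)
    ca <- categorizeCapture(detectGuides(m, lib2))
    s <- captureSummary(ca)
    expect_equal(s$n, c(1L, 1L, 1L, 1L))
    expect_equal(s$fraction_all, rep(0.25, 4))
    expect_equal(s$fraction_detected[1:3], rep(1 / 3, 3))
    expect_equal(sum(s$fraction_all), 1)
})

test_that("capture fractions match binomial expectations on simulation", {
    lib <- makeLibrary(sprintf("ig_%d", 1:5), rep("intergenic", 5),
                       sprintf("ig_%d", 1:5))
    truth <- simulateTruth(lib, n_genes = 60, seed = 51)
    p9 <- 0.95; p12 <- 0.9
    sce <- simulateCells(lib, truth, n_cells_per_guide = 2000,
                         p_detect_cas9 = p9, p_detect_cas12a = p12,
                         doublet_rate = 0, decoupling_rate = 0,
                         lambda_ambient = 0, seed = 52)
    n <- ncol(sce)
    ca <- categorizeCapture(detectGuides(sce, lib))
    s <- captureSummary(ca)
    exp_frac <- c(p9 * p12, p9 * (1 - p12), (1 - p9) * p12,
                  (1 - p9) * (1 - p12))
    for (i in 1:4) {
        se <- sqrt(exp_frac[i] * (1 - exp_frac[i]) / n)
        expect_lt(abs(s$fraction_all[i] - exp_frac[i]), 3 * se + 1e-9)
    }
    # p12 = 0 leaves no dual cells at all
    sce0 <- simulateCells(lib, truth, n_cells_per_guide = 200,
                          p_detect_cas9 = 1, p_detect_cas12a = 0,
                          doublet_rate = 0, decoupling_rate = 0,
                          lambda_ambient = 0, seed = 53)
    s0 <- captureSummary(categorizeCapture(detectGuides(sce0, lib)))
    expect_equal(s0$n[s0$category == "dual"], 0L)
})

test_that("perturbation assignment resolves consistent, conflicting and absent evidence", {
    m <- makeGuideMatrix(list(
        c("h7|cas9" = 25, "h7|cas12a" = 30),   # consistent dual -> assigned
        c("h7|cas9" = 25, "h9|cas12a" = 30),   # conflict -> decoupled
        c("h7|cas9" = 25, "h9|cas9" = 20),     # two hgRNAs, one modality -> doublet
        c("h9|cas12a" = 12),                   # single-modality evidence -> assigned
        c("nt_1|cas9" = 25, "nt_1|cas12a" = 8),# non-targeting -> excluded
        c("h7|cas9" = 1)                       # nothing above threshold
    ), feat2)
    ca <- assignPerturbations(categorizeCapture(detectGuides(m, lib2)), lib2)
    df <- assignmentTable(ca)
    expect_identical(df$status,
                     c("assigned", "decoupled", "doublet", "assigned",
                       "excluded_nontargeting", "no_guide"))
    expect_identical(df$assigned_hgrna[1], "h7")
    expect_identical(df$assigned_hgrna[4], "h9")
    expect_identical(df$target_id[1], "exon_007")
    # statuses partition all cells
    expect_equal(sum(table(df$status)), nrow(df))
    # require_dual downgrades single-modality evidence
    ca2 <- assignPerturbations(categorizeCapture(detectGuides(m, lib2)),
                               lib2, require_dual = TRUE)
    expect_identical(assignmentTable(ca2)$status[4], "no_guide")
    # keeping non-targeting cells is possible
    ca3 <- assignPerturbations(categorizeCapture(detectGuides(m, lib2)),
                               lib2, exclude_nontargeting = FALSE)
    expect_identical(assignmentTable(ca3)$status[5], "assigned")
})

test_that("a guide absent from the library is a format error", {
    feats <- c("hX|cas9", "hX|cas12a")
    m <- makeGuideMatrix(list(c("hX|cas9" = 25)), feats)
    expect_error(detectGuides(m, lib2), "not present in the library")
})

test_that("noise-free assignment is 100% accurate and finds all distinguishable doublets", {
    fx <- cleanScreen()
    df <- assignmentTable(fx$ca)
    cd <- SummarizedExperiment::colData(fx$sce)
    nt <- cd$target_class == "non_targeting"
    expect_true(all(df$status[!nt] == "assigned"))
    expect_identical(df$assigned_hgrna[!nt], cd$hgrna_1[!nt])
    expect_true(all(df$status[nt] == "excluded_nontargeting"))

    # doublet recall among cells whose two hgRNAs differ
    lib <- fx$lib
    sce_d <- simulateCells(lib, fx$truth, n_cells_per_guide = 30,
                           p_detect_cas9 = 1, p_detect_cas12a = 1,
                           doublet_rate = 0.1, decoupling_rate = 0,
                           lambda_ambient = 0, seed = 77)
    ca_d <- assignPerturbations(
        categorizeCapture(detectGuides(sce_d, lib)), lib)
    dfd <- assignmentTable(ca_d)
    cdd <- SummarizedExperiment::colData(sce_d)
    distinguishable <- cdd$is_doublet & cdd$hgrna_1 != cdd$hgrna_2
    expect_gt(sum(distinguishable), 10)
    expect_true(all(dfd$status[distinguishable] == "doublet"))
})

test_that("decoupled cells are dropped, not reassigned", {
    fx <- cleanScreen()
    sce_dc <- simulateCells(fx$lib, fx$truth, n_cells_per_guide = 30,
                            p_detect_cas9 = 1, p_detect_cas12a = 1,
                            doublet_rate = 0, decoupling_rate = 0.3,
                            lambda_ambient = 0, seed = 88)
    ca <- assignPerturbations(
        categorizeCapture(detectGuides(sce_dc, fx$lib)), fx$lib)
    df <- assignmentTable(ca)
    cd <- SummarizedExperiment::colData(sce_dc)
    expect_true(all(df$status[cd$is_decoupled] == "decoupled"))
    expect_true(all(is.na(df$assigned_hgrna[cd$is_decoupled])))
})
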