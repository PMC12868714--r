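library(SummarizedExperiment)

test_that("aggregation sums member cells and conserves totals", {
    counts <- matrix(c(1, 2, 3,
                       0, 1, 1,
                       5, 0, 2,
                       1, 1, 1), nrow = 3,
                     dimnames = list(c("gA", "gB", "gC"),
                                     sprintf("c%d", 1:4)))
    ca <- makeAssignment(sprintf("c%d", 1:4),
                         c("h1", "h1", "h2", "ig_1"),
                         c("t1", "t1", "t1", "ig_1"),
                         c("exon_deletion", "exon_deletion",
                           "exon_deletion", "intergenic"))
    pb <- aggregateCells(counts, ca, level = "guide", min_cells = 1)
    expect_equal(unname(assay(pb)[, "h1"]), c(1, 3, 4))
    expect_equal(sum(assay(pb)), sum(counts))
    expect_equal(colData(pb)["h1", "n_cells"], 2L)
    # target level merges a target's guides
    pbt <- aggregateCells(counts, ca, level = "target", min_cells = 1)
    expect_equal(unname(assay(pbt)[, "t1"]),
                 unname(assay(pb)[, "h1"] + assay(pb)[, "h2"]))
    # min_cells drops small groups with a warning
    expect_warning(pb2 <- aggregateCells(counts, ca, level = "guide",
                                         min_cells = 2), "dropping")
    expect_identical(colnames(pb2), "h1")
})

test_that("aggregation can be restricted to perturbed cells", {
    counts <- matrix(1, 2, 4, dimnames = list(c("gA", "gB"),
                                              sprintf("c%d", 1:4)))
    ca <- makeAssignment(sprintf("c%d", 1:4),
                         c("h1", "h1", "h1", "ig_1"),
                         c("t1", "t1", "t1", "ig_1"),
                         c(rep("exon_deletion", 3), "intergenic"))
    fl <- c(c1 = TRUE, c2 = FALSE, c3 = TRUE, c4 = NA)
    pb <- aggregateCells(counts, ca, level = "guide", min_cells = 1,
                         perturbed = fl)
    expect_equal(colData(pb)["h1", "n_cells"], 2L)   # c2 excluded
    expect_equal(colData(pb)["ig_1", "n_cells"], 1L) # controls kept
})

test_that("size factors follow the median-of-ratios definition", {
    m <- matrix(c(10, 20, 30, 10, 20, 30), 3,
                dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
    expect_equal(unname(sizeFactorsMedianRatio(m)), c(1, 1))
    m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
    sf <- sizeFactorsMedianRatio(m2)
    expect_equal(unname(sf[2] / sf[1]), 2)

    # brute-force oracle on a random NB table
    set.seed(31)
    mr <- matrix(rnbinom(200 * 8, mu = 50, size = 5), 200,
                 dimnames = list(sprintf("g%03d", 1:200),
                                 sprintf("s%d", 1:8)))
    sf <- sizeFactorsMedianRatio(mr)
    oracle <- numeric(8)
    ref_ok <- apply(mr, 1, function(r) all(r > 0))
    geo <- exp(rowMeans(log(mr)))
    for (j in 1:8)
        oracle[j] <- median((mr[ref_ok, j] / geo[ref_ok]))
    expect_equal(unname(sf), oracle, tolerance = 1e-12)

    # no gene positive everywhere -> positive-gene fallback with warning
    m3 <- matrix(c(0, 5, 5, 0), 2,
                 dimnames = list(c("gA", "gB"), c("s1", "s2")))
    expect_warning(sizeFactorsMedianRatio(m3), "positive")
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
    set.seed(32)
    ng <- 300
    mu <- exp(rnorm(ng, 4, 1))
    mp <- sapply(1:50, function(j) rpois(ng, mu))
    rownames(mp) <- sprintf("g%03d", 1:ng)
    colnames(mp) <- sprintf("s%02d", 1:50)
    dp <- estimateDispersions(mp)
    expect_lte(median(dp$dispersion, na.rm = TRUE), 0.05)

    mn <- sapply(1:50, function(j) rnbinom(ng, size = 5, mu = mu))
    dimnames(mn) <- dimnames(mp)
    dn <- estimateDispersions(mn)
    expect_lt(abs(median(dn$dispersion_trend, na.rm = TRUE) - 0.2), 0.05)

    # all-zero gene excluded from testing
    mz <- mn; mz[1, ] <- 0
    dz <- estimateDispersions(mz)
    expect_true(is.na(dz$dispersion[1]))
})

test_that("Wald test recovers planted effects with controlled FDR", {
    set.seed(33)
    ng <- 400; n_ctrl <- 40; n_tgt <- 3
    mu <- exp(runif(ng, log(50), log(500)))
    planted <- 1:40
    fc <- rep(1, ng); fc[planted] <- 2
    m <- sapply(seq_len(n_ctrl + n_tgt), function(j) {
        f <- if (j > n_ctrl) fc else rep(1, ng)
        rnbinom(ng, size = 1 / 0.05, mu = mu * f)
    })
    rownames(m) <- sprintf("g%03d", 1:ng)
    colnames(m) <- c(sprintf("ig_%02d", 1:n_ctrl), sprintf("tg_%d", 1:n_tgt))
    de <- deTest(m, sprintf("tg_%d", 1:n_tgt), sprintf("ig_%02d", 1:n_ctrl))
    expect_lt(abs(median(de$log2fc[planted]) - 1), 0.25)
    expect_gte(mean(de$is_deg[planted]), 0.8)
    # empirical FDR among flagged genes
    flagged <- which(de$is_deg)
    fdr <- sum(!flagged %in% planted) / max(1, length(flagged))
    expect_lte(fdr, 0.1)
    # DEG definition invariants
    expect_true(all(de$padj >= de$p - 1e-12, na.rm = TRUE))
    expect_true(all((de$padj < 0.05 & abs(de$log2fc) > 0.5) == de$is_deg,
                    na.rm = TRUE))
})

test_that("identical profiles give null statistics and degenerate fits p = 1", {
    m <- matrix(rep(c(30, 60, 90, 120), 6), 4,
                dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:6)))
    de <- deTest(m, c("s5", "s6"), sprintf("s%d", 1:4))
    expect_true(all(abs(de$log2fc[de$tested]) < 1e-8))
    expect_true(all(de$p[de$tested] > 0.999))
})

test_that("the Wald engine agrees with an established NB DE implementation", {
    set.seed(34)
    ng <- 150
    mu <- exp(runif(ng, log(20), log(400)))
    fc <- rep(1, ng); fc[1:25] <- 2^runif(25, -1.5, 1.5)
    m <- sapply(1:12, function(j) {
        f <- if (j > 8) fc else rep(1, ng)
        rnbinom(ng, size = 10, mu = mu * f)
    })
    rownames(m) <- sprintf("g%03d", 1:ng)
    colnames(m) <- sprintf("s%02d", 1:12)
    de <- deTest(m, sprintf("s%02d", 9:12), sprintf("s%02d", 1:8),
                 min_mean = 0)
    suppressMessages({
        dds <- DESeq2::DESeqDataSetFromMatrix(
            m, S4Vectors::DataFrame(cond = factor(rep(c("c", "t"),
                                                      c(8, 4)))), ~cond)
        dds <- DESeq2::DESeq(dds, quiet = TRUE)
        ref <- DESeq2::results(dds)
    })
    ok <- de$tested & !is.na(ref$log2FoldChange)
    expect_gt(cor(de$log2fc[ok], ref$log2FoldChange[ok]), 0.98)
    expect_gt(cor(-log10(de$p[ok] + 1e-300),
                  -log10(ref$pvalue[ok] + 1e-300)), 0.9)
})

test_that("BH adjustment matches an independent step-up oracle", {
    bh_oracle <- function(p) {
        n <- length(p)
        o <- order(p)
        adj <- p[o] * n / seq_len(n)
        adj <- rev(cummin(rev(adj)))
        out <- numeric(n)
        out[o] <- pmin(adj, 1)
        out
    }
    set.seed(35)
    for (i in 1:5) {
        p <- c(runif(80), runif(20)^4)
        expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-15)
    }
    # monotone step-up: sorted padj is non-decreasing
    p <- runif(50)
    padj <- p.adjust(p, "BH")
    expect_true(all(diff(padj[order(p)]) >= -1e-15))
})

test_that("guide concordance averages pairwise correlations", {
    mkde <- function(lfc) S4Vectors::DataFrame(
        gene = sprintf("g%02d", seq_along(lfc)), log2fc = lfc,
        tested = TRUE)
    set.seed(36)
    x <- rnorm(50)
    expect_equal(guideConcordance(list(a = mkde(x), b = mkde(x)))$mean_r, 1)
    expect_equal(guideConcordance(list(a = mkde(x), b = mkde(-x)))$mean_r, -1)
    y <- x + rnorm(50); z <- rnorm(50)
    got <- guideConcordance(list(a = mkde(x), b = mkde(y), c = mkde(z)))
    expect_equal(got$mean_r,
                 mean(c(cor(x, y), cor(x, z), cor(y, z))))
    expect_true(is.na(guideConcordance(list(a = mkde(x)))$mean_r))
})
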