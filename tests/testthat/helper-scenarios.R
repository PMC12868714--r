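# Scenario builders shared by module tests and the acceptance suite.

# Screen with one exon target (single guide) and six intergenic control
# guides, run through QC, scaling and the perturbation signature.
sigScreen <- function(lfc_scale, escape, seed, n_cells = 200,
                      n_genes = 200) {
    lib <- makeLibrary(c("ex1_g1", sprintf("ig_%d", 1:6)),
                       c("exon_deletion", rep("intergenic", 6)),
                       c("exon_001", sprintf("ig_%d", 1:6)))
    truth <- simulateTruth(lib, n_genes = n_genes,
                           mean_affected_per_target = 25,
                           lfc_scale = lfc_scale, escape_fraction = escape,
                           seed = seed)
    sce <- simulateCells(lib, truth, n_cells_per_guide = n_cells,
                         p_detect_cas9 = 1, p_detect_cas12a = 1,
                         doublet_rate = 0, decoupling_rate = 0,
                         lambda_ambient = 0, seed = seed + 1)
    ca <- assignPerturbations(categorizeCapture(detectGuides(sce, lib)), lib)
    x <- regressAndScale(normalizeLog(
        filterCellsGenes(sce, min_genes = 10, min_cells = 3)))
    sig <- computeSignature(x, ca, n_neighbors = 20, n_pcs = 20,
                            use_hvg = FALSE)
    list(lib = lib, truth = truth, sce = sce, ca = ca, sig = sig)
}

# Simulation where an exon deletion and its host-gene knockout differ only
# through cell-cycle composition: expression depends on phase alone, so any
# exon-versus-knockout DEG is composition-driven and should vanish when the
# comparison is restricted to G1 cells.
phaseScenario <- function() {
    lib <- makeLibrary(
        c(sprintf("ex_g%d", 1:3), sprintf("ko_g%d", 1:2),
          sprintf("ig_%d", 1:6)),
        c(rep("exon_deletion", 3), rep("gene_knockout", 2),
          rep("intergenic", 6)),
        c(rep("exon_001", 3), rep("gene_001", 2), sprintf("ig_%d", 1:6)))
    truth <- simulateTruth(lib, n_genes = 200, lfc_scale = 0,
                           escape_fraction = 0, seed = 55)
    sim1 <- function(sub, props, seed)
        simulateCells(sub, truth, n_cells_per_guide = 120,
                      p_detect_cas9 = 1, p_detect_cas12a = 1,
                      doublet_rate = 0, decoupling_rate = 0,
                      phase_proportions = props, phase_effect_lfc = 3,
                      lambda_ambient = 0, seed = seed)
    rec <- guideRecords(lib)
    subLib <- function(cl) scExonScreen:::GuideLibrary(
        rec[rec$target_class %in% cl, , drop = FALSE])
    sce_ex <- sim1(subLib("exon_deletion"),
                   c(G1 = 0.15, S = 0.55, G2M = 0.30), 56)
    sce_ko <- sim1(subLib("gene_knockout"),
                   c(G1 = 0.70, S = 0.20, G2M = 0.10), 57)
    sce_ig <- sim1(subLib("intergenic"),
                   c(G1 = 0.18, S = 0.52, G2M = 0.30), 58)
    rename <- function(sce, tag) {
        SingleCellExperiment::altExps(sce) <- NULL
        colnames(sce) <- paste0(tag, colnames(sce))
        sce$barcode <- colnames(sce)
        sce
    }
    sce <- do.call(SingleCellExperiment::cbind,
                   list(rename(sce_ex, "e"), rename(sce_ko, "k"),
                        rename(sce_ig, "i")))
    cd <- SummarizedExperiment::colData(sce)
    ca <- makeAssignment(colnames(sce), cd$hgrna_1, cd$target_id,
                         cd$target_class)
    calls <- S4Vectors::DataFrame(barcode = colnames(sce),
                                  phase = cd$true_phase)
    list(sce = sce, ca = ca, calls = calls,
         tg = sprintf("ex_g%d", 1:3), kg = sprintf("ko_g%d", 1:2))
}

# Full-chain differential-expression benchmark: one exon target with three
# guides against 40 intergenic control guides, a block of genes planted at
# log2FC exactly 1 on high-baseline genes, simulated at the cell level and
# carried through assignment and pseudobulk aggregation.
deBenchmark <- function(seed = 91, n_genes = 400, n_planted = 50,
                        n_cells = 200) {
    lib <- makeLibrary(c(sprintf("ex_g%d", 1:3), sprintf("ig_%02d", 1:40)),
                       c(rep("exon_deletion", 3), rep("intergenic", 40)),
                       c(rep("exon_001", 3), sprintf("ig_%02d", 1:40)))
    truth <- simulateTruth(lib, n_genes = n_genes, lfc_scale = 1,
                           escape_fraction = 0, seed = seed)
    planted <- sprintf("g%05d", seq_len(n_planted))
    truth$baseline_mean[planted] <- pmax(truth$baseline_mean[planted], 0.5)
    truth$effects[["exon_001"]] <- list(genes = planted,
                                        log2fc = rep(1, n_planted))
    sce <- simulateCells(lib, truth, n_cells_per_guide = n_cells,
                         p_detect_cas9 = 1, p_detect_cas12a = 1,
                         doublet_rate = 0, decoupling_rate = 0,
                         lambda_ambient = 0, seed = seed + 1)
    ca <- assignPerturbations(categorizeCapture(detectGuides(sce, lib)), lib)
    pb <- aggregateCells(sce, ca, level = "guide", min_cells = 10)
    de <- deTest(pb, sprintf("ex_g%d", 1:3), sprintf("ig_%02d", 1:40))
    list(truth = truth, de = de, planted = planted,
         pseudobulk = pb, n_cells = ncol(sce))
}

# Multinomial phase-count table for one group.
rphase <- function(n, props) {
    k <- as.integer(stats::rmultinom(1, n, props))
    names(k) <- c("G1", "S", "G2M")
    k
}

makeFractions <- function(counts_list, target_ids, classes) {
    do.call(rbind, lapply(seq_along(counts_list), function(i) {
        k <- counts_list[[i]]
        data.frame(group = sprintf("grp_%03d", i), target_id = target_ids[i],
                   target_class = classes[i],
                   n_G1 = k["G1"], n_S = k["S"], n_G2M = k["G2M"],
                   n = sum(k), f_G1 = k["G1"] / sum(k),
                   f_S = k["S"] / sum(k), f_G2M = k["G2M"] / sum(k),
                   row.names = NULL)
    }))
}

nullControls <- function(n_groups = 40, n_cells = 400,
                         props = c(0.17, 0.53, 0.30)) {
    makeFractions(replicate(n_groups, rphase(n_cells, props),
                            simplify = FALSE),
                  sprintf("ig_%02d", seq_len(n_groups)),
                  rep("intergenic", n_groups))
}
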