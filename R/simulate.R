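#' Simulate a dual-nuclease guide library manifest
#'
#' Generates a \code{\link{GuideLibrary}} with the composition of a pooled
#' exon-deletion screen: each targeted exon covered by several independent
#' Cas9/Cas12a guide pairs, gene knockouts by a smaller number of pairs, plus
#' intergenic-cutting and non-targeting negative-control hgRNAs (each control
#' forming its own target group). Spacer sequences are random unique
#' nucleotide strings (20 nt Cas9, 23 nt Cas12a).
#'
#' Defaults mirror the screen design this package models: three guide pairs
#' per exon, two per gene knockout, and 40 + 40 controls.
#'
#' @param n_exon_targets Number of exon-deletion targets.
#' @param guides_per_exon Guide pairs per exon target (default 3).
#' @param n_gene_targets Number of gene-knockout targets.
#' @param guides_per_gene Guide pairs per gene target (default 2).
#' @param n_intergenic Number of intergenic control hgRNAs (default 40).
#' @param n_nontargeting Number of non-targeting control hgRNAs (default 40).
#' @param seed Integer seed; identical seeds give byte-identical manifests.
#' @return A \code{\link{GuideLibrary}}.
#' @examples
#' lib <- simulateGuideLibrary(4, n_gene_targets = 2, n_intergenic = 4,
#'                             n_nontargeting = 2, seed = 1)
#' lib
#' @export
simulateGuideLibrary <- function(n_exon_targets, guides_per_exon = 3L,
                                 n_gene_targets, guides_per_gene = 2L,
                                 n_intergenic = 40L, n_nontargeting = 40L,
                                 seed = 1L) {
    n_exon_targets <- .assertCount(n_exon_targets, "n_exon_targets")
    guides_per_exon <- .assertCount(guides_per_exon, "guides_per_exon")
    n_gene_targets <- .assertCount(n_gene_targets, "n_gene_targets")
    guides_per_gene <- .assertCount(guides_per_gene, "guides_per_gene")
    n_intergenic <- .assertCount(n_intergenic, "n_intergenic")
    n_nontargeting <- .assertCount(n_nontargeting, "n_nontargeting")

    target_id <- c(rep(sprintf("exon_%03d", seq_len(n_exon_targets)),
                       each = guides_per_exon),
                   rep(sprintf("gene_%03d", seq_len(n_gene_targets)),
                       each = guides_per_gene),
                   sprintf("intergenic_%03d", seq_len(n_intergenic)),
                   sprintf("nontargeting_%03d", seq_len(n_nontargeting)))
    target_class <- c(rep("exon_deletion", n_exon_targets * guides_per_exon),
                      rep("gene_knockout", n_gene_targets * guides_per_gene),
                      rep("intergenic", n_intergenic),
                      rep("non_targeting", n_nontargeting))
    guide_index <- c(rep(seq_len(guides_per_exon), n_exon_targets),
                     rep(seq_len(guides_per_gene), n_gene_targets),
                     rep(1L, n_intergenic + n_nontargeting))
    n <- length(target_id)
    ctrl <- target_class %in% c("intergenic", "non_targeting")
    hgrna_id <- ifelse(ctrl, target_id,
                       paste0(target_id, "_g", guide_index))

    .withSeed(seed, {
        cas9 <- .uniqueSpacers(n, 20L)
        cas12a <- .uniqueSpacers(n, 23L)
    })

    GuideLibrary(S4Vectors::DataFrame(
        hgrna_id = hgrna_id, cas9_spacer = cas9, cas12a_spacer = cas12a,
        target_class = target_class, target_id = target_id,
        guide_index = as.integer(guide_index)))
}

.uniqueSpacers <- function(n, width) {
    if (n == 0L) return(character(0))
    draw <- function(k) {
        m <- matrix(sample(c("A", "C", "G", "T"), k * width, replace = TRUE),
                    nrow = k)
        apply(m, 1L, paste0, collapse = "")
    }
    out <- draw(n)
    while (anyDuplicated(out)) {
        dup <- which(duplicated(out))
        out[dup] <- draw(length(dup))
    }
    out
}

#' Simulate the ground-truth perturbation effects of a screen
#'
#' For every non-control target the generator draws a Poisson-sized set of
#' affected genes with log2 fold-changes symmetric about zero at scale
#' \code{lfc_scale} (each effect has magnitude uniform in
#' \code{lfc_scale * [0.5, 1.5]} with a random sign), and records the
#' fraction of that target's cells that will escape the perturbation.
#' Baseline expression means are log-normal across genes; negative-binomial
#' dispersions are constant (or per-gene if a vector is supplied).
#'
#' Control targets (intergenic, non-targeting) have empty affected sets.
#' With \code{lfc_scale = 0} the truth describes a null library.
#'
#' @param library A \code{\link{GuideLibrary}}.
#' @param n_genes Number of genes in the expression universe.
#' @param mean_affected_per_target Poisson mean of the affected-set size.
#' @param lfc_scale Scale of the planted log2 fold-changes.
#' @param escape_fraction Fraction of cells per target that do not respond.
#' @param dispersion NB dispersion (scalar, or one value per gene).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   per-gene mean expression.
#' @param seed Integer seed.
#' @return A list of class \code{"PerturbationTruth"} with elements
#'   \code{genes}, \code{baseline_mean}, \code{dispersion},
#'   \code{escape_fraction} and \code{effects} (named list per target with
#'   \code{genes} and \code{log2fc}).
#' @examples
#' lib <- simulateGuideLibrary(2, n_gene_targets = 0, n_intergenic = 2,
#'                             n_nontargeting = 0, seed = 1)
#' truth <- simulateTruth(lib, n_genes = 100, seed = 1)
#' str(truth$effects[[1]])
#' @export
simulateTruth <- function(library, n_genes, mean_affected_per_target = 20,
                          lfc_scale = 1, escape_fraction = 0.2,
                          dispersion = 0.2, baseline_meanlog = -0.3,
                          baseline_sdlog = 1, seed = 1L) {
    stopifnot(is(library, "GuideLibrary"))
    n_genes <- .assertCount(n_genes, "n_genes", min = 1L)
    escape_fraction <- .assertProb(escape_fraction, "escape_fraction")
    rec <- guideRecords(library)
    genes <- .geneNames(n_genes)
    disp <- rep_len(as.numeric(dispersion), n_genes)
    stopifnot(all(disp > 0))

    targets <- unique(rec$target_id[!rec$target_class %in%
                                    c("intergenic", "non_targeting")])
    .withSeed(seed, {
        baseline <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
        effects <- lapply(targets, function(t) {
            k <- min(stats::rpois(1L, mean_affected_per_target), n_genes)
            gs <- sample(genes, k)
            lfc <- sample(c(-1, 1), k, replace = TRUE) *
                lfc_scale * stats::runif(k, 0.5, 1.5)
            list(genes = gs, log2fc = lfc)
        })
    })
    names(effects) <- targets
    names(baseline) <- names(disp) <- genes
    structure(list(genes = genes, baseline_mean = baseline, dispersion = disp,
                   escape_fraction = escape_fraction, effects = effects),
              class = "PerturbationTruth")
}

#' Simulate guide-capture and expression matrices with ground truth
#'
#' Draws cells for every hgRNA in the library and emulates the statistical
#' structure of a droplet-based dual-guide screen: each modality of a cell's
#' hgRNA is captured independently with its detection probability (detected
#' guides receive \code{1 + Poisson(lambda_guide)} UMIs; a light ambient
#' background adds \code{Poisson(lambda_ambient)} UMIs to at most two random
#' guide features per cell); decoupled cells swap their Cas12a guide for a
#' random other hgRNA; doublets sum the expression of two component cells
#' and emit both hgRNAs. Expression counts are negative binomial with mean
#' \code{baseline * 2^log2fc(target) * 2^(phase effect on own-phase markers)
#' * per-cell log-normal library-size factor}; escaping cells use baseline
#' means.
#'
#' @param library A \code{\link{GuideLibrary}}.
#' @param truth A \code{PerturbationTruth} from \code{\link{simulateTruth}}.
#' @param n_cells_per_guide Cells drawn per hgRNA.
#' @param p_detect_cas9,p_detect_cas12a Per-modality capture probabilities.
#' @param doublet_rate Probability a cell is a doublet.
#' @param decoupling_rate Probability a cell's Cas12a guide is decoupled.
#' @param phase_proportions Named numeric (G1, S, G2M) summing to 1.
#' @param s_markers,g2m_markers Marker gene sets; by default 30 genes each
#'   are taken from the tail of the gene universe.
#' @param phase_effect_lfc Additive log2 effect on a cell's own-phase markers.
#' @param lambda_guide Poisson mean of detected-guide UMI counts (on top of 1).
#' @param lambda_ambient Poisson mean of ambient guide UMIs (0 = noise-free).
#' @param libsize_sdlog Log-normal sd of the per-cell library-size factor.
#' @param seed Integer seed.
#' @return A \code{SingleCellExperiment} with assay \code{counts}
#'   (genes x cells), an \code{altExp "hgRNA"} carrying the guide-capture
#'   matrix (two features per hgRNA: \code{<id>|cas9}, \code{<id>|cas12a}),
#'   and the per-cell truth in \code{colData} (\code{hgrna_1},
#'   \code{hgrna_2}, \code{is_doublet}, \code{is_decoupled},
#'   \code{is_escaping}, \code{true_phase}, \code{target_id},
#'   \code{target_class}).
#' @examples
#' lib <- simulateGuideLibrary(2, n_gene_targets = 0, n_intergenic = 3,
#'                             n_nontargeting = 0, seed = 1)
#' truth <- simulateTruth(lib, n_genes = 60, seed = 1)
#' sce <- simulateCells(lib, truth, n_cells_per_guide = 10, seed = 1)
#' sce
#' @export
simulateCells <- function(library, truth, n_cells_per_guide = 200L,
                          p_detect_cas9 = 0.97, p_detect_cas12a = 0.95,
                          doublet_rate = 0.08, decoupling_rate = 0.05,
                          phase_proportions = c(G1 = 0.18, S = 0.52, G2M = 0.30),
                          s_markers = NULL, g2m_markers = NULL,
                          phase_effect_lfc = 1, lambda_guide = 20,
                          lambda_ambient = 0.1, libsize_sdlog = 0.3,
                          seed = 1L) {
    stopifnot(is(library, "GuideLibrary"),
              inherits(truth, "PerturbationTruth"))
    rec <- guideRecords(library)
    if (nrow(rec) == 0L) stop("empty guide library")
    n_cells_per_guide <- .assertCount(n_cells_per_guide, "n_cells_per_guide", 1L)
    p9 <- .assertProb(p_detect_cas9, "p_detect_cas9")
    p12 <- .assertProb(p_detect_cas12a, "p_detect_cas12a")
    doublet_rate <- .assertProb(doublet_rate, "doublet_rate")
    decoupling_rate <- .assertProb(decoupling_rate, "decoupling_rate")
    if (abs(sum(phase_proportions) - 1) > 1e-8 || length(phase_proportions) != 3L)
        stop("phase_proportions must be a 3-vector summing to 1")
    phases <- c("G1", "S", "G2M")

    genes <- truth$genes
    ng <- length(genes)
    if (is.null(s_markers) || is.null(g2m_markers)) {
        if (ng < 60L)
            stop("default markers need >= 60 genes; supply s_markers/g2m_markers")
        if (is.null(s_markers)) s_markers <- genes[seq(ng - 59L, ng - 30L)]
        if (is.null(g2m_markers)) g2m_markers <- genes[seq(ng - 29L, ng)]
    }
    stopifnot(all(s_markers %in% genes), all(g2m_markers %in% genes))
    s_idx <- match(s_markers, genes)
    g2m_idx <- match(g2m_markers, genes)

    # per-target fold-change vectors (linear scale)
    fc <- lapply(truth$effects, function(e) {
        v <- rep(1, ng)
        v[match(e$genes, genes)] <- 2^e$log2fc
        v
    })

    nrec <- nrow(rec)
    ncell <- nrec * n_cells_per_guide
    hg1 <- rep(rec$hgrna_id, each = n_cells_per_guide)
    is_ctrl <- rec$target_class %in% c("intergenic", "non_targeting")
    names(is_ctrl) <- rec$hgrna_id
    target_of <- rec$target_id; names(target_of) <- rec$hgrna_id
    class_of <- rec$target_class; names(class_of) <- rec$hgrna_id

    .withSeed(seed, {
        is_doublet <- stats::runif(ncell) < doublet_rate
        hg2 <- rep(NA_character_, ncell)
        hg2[is_doublet] <- sample(rec$hgrna_id, sum(is_doublet), replace = TRUE)
        is_decoupled <- stats::runif(ncell) < decoupling_rate
        phase <- sample(phases, ncell, replace = TRUE, prob = phase_proportions)
        esc1 <- !is_ctrl[hg1] & stats::runif(ncell) < truth$escape_fraction
        esc2 <- ifelse(is.na(hg2), FALSE,
                       !is_ctrl[hg2] & stats::runif(ncell) < truth$escape_fraction)

        componentMu <- function(hg, escaping, ph) {
            mu <- truth$baseline_mean
            t <- target_of[[hg]]
            if (!is_ctrl[[hg]] && !escaping && t %in% names(fc))
                mu <- mu * fc[[t]]
            if (ph == "S") mu[s_idx] <- mu[s_idx] * 2^phase_effect_lfc
            if (ph == "G2M") mu[g2m_idx] <- mu[g2m_idx] * 2^phase_effect_lfc
            mu
        }
        size <- 1 / truth$dispersion
        counts <- matrix(0L, nrow = ng, ncol = ncell)
        for (i in seq_len(ncell)) {
            sf <- stats::rlnorm(1L, 0, libsize_sdlog)
            mu <- componentMu(hg1[i], esc1[i], phase[i]) * sf
            ci <- stats::rnbinom(ng, size = size, mu = mu)
            if (is_doublet[i]) {
                sf2 <- stats::rlnorm(1L, 0, libsize_sdlog)
                mu2 <- componentMu(hg2[i], esc2[i], phase[i]) * sf2
                ci <- ci + stats::rnbinom(ng, size = size, mu = mu2)
            }
            counts[, i] <- ci
        }

        # guide-capture matrix: two features per hgRNA
        feat <- paste0(rep(rec$hgrna_id, each = 2L), c("|cas9", "|cas12a"))
        f9 <- function(hg) 2L * match(hg, rec$hgrna_id) - 1L
        f12 <- function(hg) 2L * match(hg, rec$hgrna_id)
        gi <- integer(0); gj <- integer(0); gx <- integer(0)
        emit <- function(rows, cols, vals) {
            gi <<- c(gi, rows); gj <<- c(gj, cols); gx <<- c(gx, vals)
        }
        addComponent <- function(hg, cells, decoupled) {
            det9 <- stats::runif(length(cells)) < p9
            if (any(det9))
                emit(f9(hg)[det9], cells[det9],
                     1L + stats::rpois(sum(det9), lambda_guide))
            hg12 <- hg
            if (any(decoupled) && nrec > 1L) {
                for (k in which(decoupled)) {
                    hg12[k] <- sample(setdiff(rec$hgrna_id, hg[k]), 1L)
                }
            }
            det12 <- stats::runif(length(cells)) < p12
            if (any(det12))
                emit(f12(hg12)[det12], cells[det12],
                     1L + stats::rpois(sum(det12), lambda_guide))
        }
        addComponent(hg1, seq_len(ncell), is_decoupled)
        if (any(is_doublet))
            addComponent(hg2[is_doublet], which(is_doublet),
                         rep(FALSE, sum(is_doublet)))
        if (lambda_ambient > 0) {
            amb_feat <- replicate(ncell, sample.int(2L * nrec, min(2L, 2L * nrec)))
            amb_cnt <- stats::rpois(length(amb_feat), lambda_ambient)
            keep <- amb_cnt > 0L
            if (any(keep))
                emit(as.integer(amb_feat)[keep],
                     rep(seq_len(ncell), each = min(2L, 2L * nrec))[keep],
                     amb_cnt[keep])
        }
        guides <- Matrix::sparseMatrix(i = gi, j = gj, x = as.numeric(gx),
                                       dims = c(2L * nrec, ncell))
    })

    barcodes <- sprintf("cell_%06d", seq_len(ncell))
    rownames(counts) <- genes; colnames(counts) <- barcodes
    rownames(guides) <- feat; colnames(guides) <- barcodes

    cd <- S4Vectors::DataFrame(
        barcode = barcodes, hgrna_1 = hg1, hgrna_2 = hg2,
        is_doublet = is_doublet, is_decoupled = is_decoupled,
        is_escaping = esc1, true_phase = phase,
        target_id = unname(target_of[hg1]),
        target_class = unname(class_of[hg1]),
        row.names = barcodes)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(counts, "CsparseMatrix")),
        colData = cd)
    SingleCellExperiment::altExp(sce, "hgRNA") <-
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = guides))
    S4Vectors::metadata(sce)$markers <- list(S = s_markers, G2M = g2m_markers)
    S4Vectors::metadata(sce)$simulation <- list(
        n_cells_per_guide = n_cells_per_guide, p_detect_cas9 = p9,
        p_detect_cas12a = p12, doublet_rate = doublet_rate,
        decoupling_rate = decoupling_rate,
        phase_proportions = phase_proportions,
        phase_effect_lfc = phase_effect_lfc, lambda_guide = lambda_guide,
        lambda_ambient = lambda_ambient, libsize_sdlog = libsize_sdlog,
        seed = seed)
    sce
}
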