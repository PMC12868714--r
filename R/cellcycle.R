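#' Score a gene program against an expression-matched control set
#'
#' The score of a cell is the mean normalized expression of the gene set
#' minus the mean expression of a control gene pool. The pool is built by
#' binning all genes into \code{n_bins} equal-frequency bins of average
#' expression and sampling \code{ctrl_size} genes (without replacement,
#' seeded) from the bin of each program gene, so that the control matches
#' the program's expression distribution.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{normalized} assay.
#' @param gene_set Character vector of program genes.
#' @param n_bins Number of expression bins (default 25).
#' @param ctrl_size Control genes sampled per program gene's bin (default 50,
#'   capped at bin size).
#' @param seed Integer seed for the control sampling.
#' @return Numeric per-cell score with attribute \code{"control_genes"}.
#' @export
scoreGeneSet <- function(sce, gene_set, n_bins = 25L, ctrl_size = 50L,
                         seed = 0L) {
    X <- SummarizedExperiment::assay(sce, "normalized")
    missing <- setdiff(gene_set, rownames(X))
    gene_set <- intersect(gene_set, rownames(X))
    if (length(gene_set) == 0L)
        stop("no gene-set members in the matrix; missing: ",
             paste(utils::head(missing, 5), collapse = ", "))
    avg <- Matrix::rowMeans(X)
    # equal-frequency bins on average expression (rank-based, ties stable)
    bin <- .rankBins(avg, n_bins)
    names(bin) <- rownames(X)
    ctrl <- .withSeed(seed, {
        picked <- character(0)
        for (b in unique(bin[gene_set])) {
            pool <- names(bin)[bin == b]
            picked <- c(picked, sample(pool, min(ctrl_size, length(pool))))
        }
        unique(picked)
    })
    score <- Matrix::colMeans(X[gene_set, , drop = FALSE]) -
        Matrix::colMeans(X[ctrl, , drop = FALSE])
    attr(score, "control_genes") <- ctrl
    score
}

#' Assign a cell-cycle phase from S and G2/M program scores
#'
#' A cell is in G1 when both scores are non-positive; otherwise the phase
#' with the higher score wins (ties go to G2M). Adding the same constant to
#' both scores of a cell moves calls only through the zero threshold, never
#' between S and G2M.
#'
#' @param s_score,g2m_score Numeric score vectors from
#'   \code{\link{scoreGeneSet}}.
#' @return Character vector with values \code{"G1"}, \code{"S"},
#'   \code{"G2M"}.
#' @export
assignPhase <- function(s_score, g2m_score) {
    stopifnot(length(s_score) == length(g2m_score),
              all(is.finite(s_score)), all(is.finite(g2m_score)))
    ifelse(s_score <= 0 & g2m_score <= 0, "G1",
           ifelse(s_score > g2m_score, "S", "G2M"))
}

#' Score both cell-cycle programs and call phases
#'
#' Convenience wrapper running \code{\link{scoreGeneSet}} for the S and
#' G2/M marker programs and \code{\link{assignPhase}}.
#'
#' @inheritParams scoreGeneSet
#' @param s_genes,g2m_genes Marker gene sets for the S and G2/M programs.
#' @return \code{DataFrame} with \code{s_score}, \code{g2m_score},
#'   \code{phase} per cell.
#' @export
scoreCellCycle <- function(sce, s_genes, g2m_genes, n_bins = 25L,
                           ctrl_size = 50L, seed = 0L) {
    s <- scoreGeneSet(sce, s_genes, n_bins, ctrl_size, seed)
    g <- scoreGeneSet(sce, g2m_genes, n_bins, ctrl_size, seed)
    S4Vectors::DataFrame(barcode = colnames(sce), s_score = as.numeric(s),
                         g2m_score = as.numeric(g),
                         phase = assignPhase(as.numeric(s), as.numeric(g)),
                         row.names = colnames(sce))
}

#' Per-group cell-cycle phase fractions
#'
#' Counts and fractions of G1/S/G2M cells per guide or per target among the
#' supplied cells (typically restricted to perturbation-responsive,
#' "perturbed-passed" cells). Empty groups are dropped with a warning.
#'
#' @param phase_calls \code{DataFrame} from \code{\link{scoreCellCycle}}.
#' @param assignment An assigned \code{\link{CellAssignment}}.
#' @param level \code{"guide"} or \code{"target"}.
#' @param cells Optional barcodes to restrict to (e.g. perturbed cells).
#' @return \code{data.frame} with group, target_id, target_class, phase
#'   counts \code{n_G1,n_S,n_G2M}, total \code{n} and fractions
#'   \code{f_G1,f_S,f_G2M} (summing to 1 per group).
#' @export
phaseFractions <- function(phase_calls, assignment,
                           level = c("guide", "target"), cells = NULL) {
    level <- match.arg(level)
    df <- assignmentTable(assignment)
    df <- df[!is.na(df$status) & df$status == "assigned", , drop = FALSE]
    if (!is.null(cells)) df <- df[df$barcode %in% cells, , drop = FALSE]
    ph <- phase_calls$phase[match(df$barcode, phase_calls$barcode)]
    keep <- !is.na(ph)
    df <- df[keep, , drop = FALSE]; ph <- ph[keep]
    group <- if (level == "guide") df$assigned_hgrna else df$target_id
    if (length(group) == 0L) stop("no cells with phase calls and assignments")
    tab <- table(group, factor(ph, levels = c("G1", "S", "G2M")))
    n <- rowSums(tab)
    if (any(n == 0)) {
        warning("dropping empty groups")
        tab <- tab[n > 0, , drop = FALSE]; n <- n[n > 0]
    }
    meta <- df[match(rownames(tab), group), , drop = FALSE]
    out <- data.frame(group = rownames(tab),
                      target_id = meta$target_id,
                      target_class = meta$target_class,
                      n_G1 = tab[, "G1"], n_S = tab[, "S"], n_G2M = tab[, "G2M"],
                      n = as.integer(n),
                      f_G1 = tab[, "G1"] / n, f_S = tab[, "S"] / n,
                      f_G2M = tab[, "G2M"] / n,
                      row.names = NULL)
    out
}

#' Dual-gate phase-enrichment test for exon targets
#'
#' For every target and phase, tests whether the target's cells are
#' enriched in that phase relative to intergenic controls with two
#' one-sided tests: (i) Fisher's exact test on the 2x2 table of in-phase
#' versus out-of-phase cells, target versus all intergenic cells pooled
#' (cell-level evidence); and (ii) a Mann-Whitney test comparing the
#' target's per-guide phase fractions against the intergenic per-group
#' fractions, using the normal approximation with tie correction and no
#' continuity correction (replicate-level evidence). Each test's p-values
#' are Benjamini-Hochberg adjusted across all (target, phase) pairs of the
#' run. A phase is significant only when \code{fisher_padj < fisher_alpha}
#' AND \code{mw_padj < mw_alpha} (defaults 0.01 and 0.05); the called phase
#' is the significant phase with the lowest adjusted p-value (Fisher
#' adjusted p, ties broken by the Mann-Whitney adjusted p). Targets with
#' fewer than two guides cannot be assessed by the Mann-Whitney gate and
#' are reported as unassessable.
#'
#' @param target_fractions \code{\link{phaseFractions}} at guide level for
#'   the targets under test (exon-deletion guides).
#' @param control_fractions \code{\link{phaseFractions}} at guide level for
#'   the intergenic control groups.
#' @param fisher_alpha,mw_alpha Gate cutoffs on adjusted p-values.
#' @return \code{data.frame}, three rows (phases) per target, with counts,
#'   \code{fisher_p}, \code{fisher_padj}, \code{mw_p}, \code{mw_padj},
#'   \code{significant}, \code{called_phase} (repeated per target; NA when
#'   no phase passes) and \code{assessable}.
#' @export
exonPhaseEnrichment <- function(target_fractions, control_fractions,
                                fisher_alpha = 0.01, mw_alpha = 0.05) {
    .phaseEnrichment(target_fractions, control_fractions,
                     use_mw = TRUE, fisher_alpha = fisher_alpha,
                     mw_alpha = mw_alpha)
}

#' Fisher-only phase-enrichment test for gene knockouts
#'
#' Same cell-level Fisher gate as \code{\link{exonPhaseEnrichment}} but
#' without the replicate-level Mann-Whitney requirement: a phase is
#' significant when its BH-adjusted one-sided Fisher p-value falls below
#' \code{fisher_alpha} (default 0.01). The tie-break for the called phase
#' is unchanged.
#'
#' @inheritParams exonPhaseEnrichment
#' @export
knockoutPhaseEnrichment <- function(target_fractions, control_fractions,
                                    fisher_alpha = 0.01) {
    .phaseEnrichment(target_fractions, control_fractions,
                     use_mw = FALSE, fisher_alpha = fisher_alpha,
                     mw_alpha = NA_real_)
}

.phaseEnrichment <- function(target_fractions, control_fractions, use_mw,
                             fisher_alpha, mw_alpha) {
    phases <- c("G1", "S", "G2M")
    ctrl_in <- c(G1 = sum(control_fractions$n_G1),
                 S = sum(control_fractions$n_S),
                 G2M = sum(control_fractions$n_G2M))
    ctrl_total <- sum(control_fractions$n)

    targets <- unique(target_fractions$target_id)
    rows <- list()
    for (t in targets) {
        tf <- target_fractions[target_fractions$target_id == t, , drop = FALSE]
        n_guides <- nrow(tf)
        t_in <- c(G1 = sum(tf$n_G1), S = sum(tf$n_S), G2M = sum(tf$n_G2M))
        t_total <- sum(tf$n)
        for (ph in phases) {
            a <- t_in[[ph]]; b <- t_total - a
            c_ <- ctrl_in[[ph]]; d <- ctrl_total - c_
            fp <- stats::fisher.test(matrix(c(a, b, c_, d), 2L,
                                            byrow = TRUE),
                                     alternative = "greater")$p.value
            mwp <- NA_real_
            if (use_mw && n_guides >= 2L) {
                fr_t <- tf[[paste0("f_", ph)]]
                fr_c <- control_fractions[[paste0("f_", ph)]]
                mwp <- suppressWarnings(stats::wilcox.test(
                    fr_t, fr_c, alternative = "greater",
                    exact = FALSE, correct = FALSE)$p.value)
            }
            rows[[length(rows) + 1L]] <- data.frame(
                target_id = t, phase = ph, n_guides = n_guides,
                target_in = a, target_out = b,
                control_in = c_, control_out = d,
                fisher_p = fp, mw_p = mwp)
        }
    }
    res <- do.call(rbind, rows)
    res$fisher_padj <- stats::p.adjust(res$fisher_p, method = "BH")
    res$mw_padj <- if (use_mw)
        stats::p.adjust(res$mw_p, method = "BH") else NA_real_
    res$assessable <- if (use_mw) res$n_guides >= 2L else TRUE
    res$significant <- res$assessable &
        res$fisher_padj < fisher_alpha &
        (!use_mw | (!is.na(res$mw_padj) & res$mw_padj < mw_alpha))

    res$called_phase <- NA_character_
    for (t in unique(res$target_id)) {
        ix <- which(res$target_id == t & res$significant)
        if (length(ix)) {
            ord <- ix[order(res$fisher_padj[ix], res$mw_padj[ix])]
            res$called_phase[res$target_id == t] <- res$phase[ord[1L]]
        }
    }
    res
}
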