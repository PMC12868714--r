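#' Matrix of log2 fold-changes over shared differentially expressed genes
#'
#' Collects the genes flagged as differentially expressed in at least
#' \code{min_perturbations} of the supplied perturbation-level DE results
#' and returns their log2 fold-changes across every perturbation (including
#' the non-significant entries for those genes), the input for
#' perturbation-profile correlation and clustering.
#'
#' @param de_list Named list of \code{\link{deTest}} results, one per
#'   perturbation.
#' @param min_perturbations Minimum number of perturbations in which a gene
#'   must be a DEG (default 30).
#' @return Numeric matrix genes x perturbations; zero rows (with a warning)
#'   when no gene qualifies.
#' @export
sharedDegMatrix <- function(de_list, min_perturbations = 30L) {
    stopifnot(length(de_list) >= 1L, !is.null(names(de_list)))
    genes <- de_list[[1L]]$gene
    deg <- vapply(de_list, function(d) {
        stopifnot(identical(d$gene, genes))
        d$is_deg
    }, logical(length(genes)))
    keep <- rowSums(deg) >= min_perturbations
    if (!any(keep)) {
        warning("no gene is a DEG in >= ", min_perturbations, " perturbations")
        return(matrix(numeric(0), 0L, length(de_list),
                      dimnames = list(NULL, names(de_list))))
    }
    lfc <- vapply(de_list, function(d) d$log2fc, numeric(length(genes)))
    rownames(lfc) <- genes
    lfc[keep, , drop = FALSE]
}

#' Correlate and cluster perturbation profiles
#'
#' Pairwise Pearson correlation of log2 fold-change profiles between
#' perturbations (columns of a \code{\link{sharedDegMatrix}}), followed by
#' hierarchical clustering on the distance \code{1 - r} (average linkage by
#' default). Zero-variance profiles yield \code{NA} correlations and are
#' reported.
#'
#' @param mat Genes x perturbations log2 fold-change matrix.
#' @param linkage Hierarchical clustering linkage (default
#'   \code{"average"}).
#' @return List with \code{correlation} (symmetric, unit diagonal),
#'   \code{hclust}, \code{order} (leaf order) and \code{degenerate}
#'   (zero-variance perturbations).
#' @export
correlatePerturbations <- function(mat, linkage = "average") {
    if (ncol(mat) < 2L) stop("need >= 2 perturbations")
    degenerate <- colnames(mat)[apply(mat, 2L, stats::sd, na.rm = TRUE) == 0]
    r <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
    diag(r) <- 1
    d <- stats::as.dist(1 - replace(r, is.na(r), 0))
    hc <- stats::hclust(d, method = linkage)
    list(correlation = r, hclust = hc, order = colnames(mat)[hc$order],
         degenerate = degenerate)
}

#' Exon-versus-knockout phenotype concordance
#'
#' Correlates an exon deletion's transcriptional program with its host
#' gene's knockout program over the union of the two comparisons' DEGs, and
#' classifies the exon as concordant when Pearson \code{r} strictly exceeds
#' \code{r_threshold} (default 0.4; \code{r} equal to the threshold is not
#' concordant). The genes differentially expressed in the direct
#' exon-versus-knockout comparison are returned as the divergent set.
#'
#' @param exon_de \code{\link{deTest}} result, exon deletion vs control.
#' @param ko_de \code{\link{deTest}} result, gene knockout vs control.
#' @param exon_vs_ko_de Optional \code{\link{deTest}} result of the direct
#'   exon-versus-knockout comparison.
#' @param r_threshold Concordance threshold on Pearson r (default 0.4).
#' @return List with \code{r}, \code{concordant}, \code{n_union_degs},
#'   \code{union_genes}, \code{divergent_genes} and
#'   \code{n_degs_exon_vs_ko}.
#' @export
exonVsKnockout <- function(exon_de, ko_de, exon_vs_ko_de = NULL,
                           r_threshold = 0.4) {
    stopifnot(identical(exon_de$gene, ko_de$gene))
    union_genes <- exon_de$gene[exon_de$is_deg | ko_de$is_deg]
    if (length(union_genes) < 3L) {
        warning("empty or tiny DEG union; concordance unassessable")
        return(list(r = NA_real_, concordant = NA,
                    n_union_degs = length(union_genes),
                    union_genes = union_genes,
                    divergent_genes = character(0),
                    n_degs_exon_vs_ko = NA_integer_))
    }
    ix <- match(union_genes, exon_de$gene)
    r <- stats::cor(exon_de$log2fc[ix], ko_de$log2fc[ix],
                    use = "complete.obs")
    divergent <- character(0); n_div <- NA_integer_
    if (!is.null(exon_vs_ko_de)) {
        divergent <- exon_vs_ko_de$gene[exon_vs_ko_de$is_deg]
        n_div <- length(divergent)
    }
    list(r = r, concordant = isTRUE(r > r_threshold),
         n_union_degs = length(union_genes), union_genes = union_genes,
         divergent_genes = divergent, n_degs_exon_vs_ko = n_div)
}

#' Phase-conditioned pseudobulk differential expression
#'
#' Re-runs the pseudobulk DE comparison using only cells assigned to a
#' given cell-cycle phase, the re-analysis that separates genuine
#' exon-specific regulation from differences driven purely by a shifted
#' phase composition. \code{phase = NULL} uses all cells and reproduces the
#' unrestricted result.
#'
#' @param sce \code{SingleCellExperiment} with raw \code{counts}.
#' @param assignment Assigned \code{\link{CellAssignment}}.
#' @param phase_calls \code{\link{scoreCellCycle}} output.
#' @param phase One of \code{"G1"}, \code{"S"}, \code{"G2M"}, or NULL.
#' @param target_groups,control_groups Guide-level groups to compare.
#' @param min_cells Per-group minimum after phase restriction (default 10).
#' @param ... Passed to \code{\link{deTest}}.
#' @return A \code{\link{deTest}} result.
#' @export
phaseConditionedDE <- function(sce, assignment, phase_calls, phase,
                               target_groups, control_groups,
                               min_cells = 10L, ...) {
    cells <- colnames(sce)
    if (!is.null(phase)) {
        stopifnot(phase %in% c("G1", "S", "G2M"))
        in_phase <- phase_calls$barcode[phase_calls$phase == phase]
        cells <- intersect(cells, in_phase)
        if (length(cells) == 0L) stop("no cells in phase ", phase)
    }
    pb <- aggregateCells(sce[, cells], assignment, level = "guide",
                         min_cells = min_cells)
    have <- colnames(pb)
    lost_t <- setdiff(target_groups, have)
    lost_c <- setdiff(control_groups, have)
    if (length(lost_t) || length(lost_c))
        warning("groups lost after phase restriction: ",
                paste(c(lost_t, lost_c), collapse = ", "))
    target_groups <- intersect(target_groups, have)
    control_groups <- intersect(control_groups, have)
    if (length(target_groups) == 0L) stop("no target group survives the phase filter")
    deTest(pb, target_groups, control_groups, ...)
}
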