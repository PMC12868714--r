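#' Per-cell quality-control metrics
#'
#' Computes total UMI count, the number of expressed genes and the percent
#' of counts from mitochondrial genes (identified by a rowname prefix,
#' default \code{"MT-"}) and stores them in \code{colData}.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{counts} assay.
#' @param mito_prefix Rowname prefix identifying mitochondrial genes.
#' @return The \code{SingleCellExperiment} with \code{total_umi},
#'   \code{n_genes_expressed} and \code{pct_mito} in \code{colData}.
#' @export
computeQCMetrics <- function(sce, mito_prefix = "MT-") {
    counts <- SummarizedExperiment::assay(sce, "counts")
    total <- Matrix::colSums(counts)
    mito <- startsWith(rownames(sce), mito_prefix)
    pct <- if (any(mito))
        100 * Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)
    else rep(0, ncol(sce))
    sce$total_umi <- total
    sce$n_genes_expressed <- Matrix::colSums(counts > 0)
    sce$pct_mito <- pct
    sce
}

#' Filter cells and genes on expression breadth
#'
#' Removes cells expressing fewer than \code{min_genes} genes, then genes
#' expressed in fewer than \code{min_cells} of the retained cells (cell
#' filter first, then gene filter, in a single pass). The defaults are the
#' conventional screen thresholds: cells with fewer than 200 expressed genes
#' and genes expressed in fewer than three cells are dropped, so a cell
#' expressing exactly 200 genes and a gene seen in exactly three cells are
#' kept. With \code{iterate = TRUE} the pass is repeated until a fixed point
#' is reached.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{counts} assay.
#' @param min_genes Minimum expressed genes per retained cell (default 200).
#' @param min_cells Minimum cells expressing a retained gene (default 3).
#' @param iterate Repeat to a fixed point (default FALSE: single pass).
#' @param mito_prefix Passed to \code{\link{computeQCMetrics}}.
#' @return The filtered \code{SingleCellExperiment} with refreshed QC
#'   metrics. An empty result is returned with a warning, not an error.
#' @export
filterCellsGenes <- function(sce, min_genes = 200L, min_cells = 3L,
                             iterate = FALSE, mito_prefix = "MT-") {
    min_genes <- .assertCount(min_genes, "min_genes")
    min_cells <- .assertCount(min_cells, "min_cells")
    repeat {
        counts <- SummarizedExperiment::assay(sce, "counts")
        keep_cells <- Matrix::colSums(counts > 0) >= min_genes
        sub <- sce[, keep_cells]
        counts <- SummarizedExperiment::assay(sub, "counts")
        keep_genes <- Matrix::rowSums(counts > 0) >= min_cells
        sub <- sub[keep_genes, ]
        changed <- !all(keep_cells) || !all(keep_genes)
        sce <- sub
        if (!iterate || !changed) break
    }
    if (ncol(sce) == 0L || nrow(sce) == 0L) {
        warning("filtering produced an empty matrix")
        return(sce)
    }
    computeQCMetrics(sce, mito_prefix = mito_prefix)
}

#' Library-size normalization and log transform
#'
#' Scales each cell's counts to sum to \code{target_sum} (default 10,000)
#' and applies \code{log1p}, storing the result as the \code{normalized}
#' assay. Cells with zero total counts are an error: they should have been
#' removed by \code{\link{filterCellsGenes}}.
#'
#' @param sce A filtered \code{SingleCellExperiment}.
#' @param target_sum Per-cell count sum after scaling (default 1e4).
#' @return The \code{SingleCellExperiment} with a \code{normalized} assay.
#' @export
normalizeLog <- function(sce, target_sum = 1e4) {
    counts <- SummarizedExperiment::assay(sce, "counts")
    cs <- Matrix::colSums(counts)
    if (any(cs == 0))
        stop("cells with zero counts present; run filterCellsGenes() first")
    scaled <- counts %*% Matrix::Diagonal(x = target_sum / cs)
    dimnames(scaled) <- dimnames(counts)
    SummarizedExperiment::assay(sce, "normalized") <- log1p(scaled)
    S4Vectors::metadata(sce)$target_sum <- target_sum
    sce
}

#' Flag highly variable genes (dispersion-based)
#'
#' Computes, per gene, the mean and the dispersion (variance/mean) of
#' \code{expm1(normalized)} values, z-normalizes the dispersions within
#' \code{n_bins} equal-frequency bins of the mean, and flags genes whose
#' mean lies strictly inside \code{(min_mean, max_mean)} and whose
#' normalized dispersion exceeds \code{min_disp}. The default thresholds
#' (0.0125, 3, 0.5) are the standard screen settings.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{normalized} assay.
#' @param min_mean,max_mean Open interval for the gene mean.
#' @param min_disp Threshold on the bin-z-scored dispersion.
#' @param n_bins Number of equal-frequency mean bins (default 20; degrades
#'   with a warning when there are fewer genes than bins).
#' @return The \code{SingleCellExperiment} with logical
#'   \code{rowData(sce)$highly_variable} plus the per-gene \code{hvg_mean}
#'   and \code{hvg_dispersion_norm} used for the decision.
#' @export
selectHVG <- function(sce, min_mean = 0.0125, max_mean = 3, min_disp = 0.5,
                      n_bins = 20L) {
    X <- expm1(SummarizedExperiment::assay(sce, "normalized"))
    m <- Matrix::rowMeans(X)
    v <- .rowVars(X)
    disp <- ifelse(m > 0, v / m, 0)
    if (nrow(sce) < n_bins) {
        warning("fewer genes than bins; using ", max(1L, nrow(sce) %/% 2L), " bins")
        n_bins <- max(1L, nrow(sce) %/% 2L)
    }
    z <- .binZScore(m, disp, n_bins)
    hv <- m > min_mean & m < max_mean & z > min_disp
    rd <- SummarizedExperiment::rowData(sce)
    rd$hvg_mean <- m
    rd$hvg_dispersion_norm <- z
    rd$highly_variable <- hv
    SummarizedExperiment::rowData(sce) <- rd
    sce
}

## Equal-frequency bins: rank order split into n_bins consecutive chunks.
.rankBins <- function(by, n_bins) {
    ceiling(rank(by, ties.method = "first") * n_bins / length(by))
}

## z-score of `value` within equal-frequency bins of `by`.
.binZScore <- function(by, value, n_bins) {
    bin <- .rankBins(by, n_bins)
    mu <- tapply(value, bin, mean)
    sd_ <- tapply(value, bin, stats::sd)
    z <- (value - mu[as.character(bin)]) / sd_[as.character(bin)]
    z[!is.finite(z)] <- 0
    as.numeric(z)
}

#' Regress out covariates and scale to unit variance
#'
#' Replaces each gene's normalized values by the residuals of an ordinary
#' least-squares fit on the per-cell covariates (by default total UMI count
#' and mitochondrial percentage) plus an intercept, then centers each gene
#' to mean zero, scales to unit variance, and clips values above
#' \code{max_value} (upper tail only). Genes with zero residual variance
#' are set to zero.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{normalized} assay
#'   and QC metrics in \code{colData}.
#' @param covariates \code{colData} column names to regress out.
#' @param max_value Upper clip for the scaled values (default 10).
#' @return The \code{SingleCellExperiment} with a dense \code{scaled} assay.
#' @export
regressAndScale <- function(sce, covariates = c("total_umi", "pct_mito"),
                            max_value = 10) {
    if (!all(covariates %in% colnames(SummarizedExperiment::colData(sce))))
        stop("missing covariates in colData: ",
             paste(setdiff(covariates, colnames(SummarizedExperiment::colData(sce))),
                   collapse = ", "))
    Y <- as.matrix(SummarizedExperiment::assay(sce, "normalized"))
    D <- cbind(1, as.matrix(as.data.frame(
        SummarizedExperiment::colData(sce)[, covariates, drop = FALSE])))
    Q <- qr.Q(qr(D))
    resid <- Y - (Y %*% Q) %*% t(Q)
    mu <- rowMeans(resid)
    resid <- resid - mu
    sd_ <- sqrt(rowSums(resid^2) / max(1L, ncol(resid) - 1L))
    # genes fully explained by the covariates: numerically zero variance
    tol <- 1e-10 * pmax(1, apply(abs(Y), 1L, max))
    scaled <- resid / ifelse(sd_ > tol, sd_, Inf)
    scaled[scaled > max_value] <- max_value
    SummarizedExperiment::assay(sce, "scaled") <- scaled
    sce
}
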