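#' Aggregate single-cell counts into pseudobulk groups
#'
#' Sums raw UMI counts over the cells of each group — one group per guide
#' (hgRNA) or per target — so that count-based replicate-level testing can
#' be applied, with independent guides serving as biological replicates.
#' Groups with fewer than \code{min_cells} member cells are dropped with a
#' warning. When a perturbed-cell classification is supplied, aggregation
#' is restricted to perturbed cells (controls are always kept).
#'
#' @param sce A \code{SingleCellExperiment} with a \code{counts} assay (or a
#'   genes x cells count matrix).
#' @param assignment An assigned \code{\link{CellAssignment}}.
#' @param level \code{"guide"} (group per hgRNA) or \code{"target"}.
#' @param min_cells Minimum cells per retained group (default 10).
#' @param perturbed Optional per-cell logical (names = barcodes), e.g. the
#'   \code{perturbed} flags from \code{\link{classifyPerturbed}}; control
#'   and \code{NA}-flagged cells are retained.
#' @return A \code{SummarizedExperiment} (genes x groups) with summed
#'   \code{counts} and group metadata \code{target_id}, \code{target_class},
#'   \code{guide}, \code{n_cells} in \code{colData}.
#' @export
aggregateCells <- function(sce, assignment, level = c("guide", "target"),
                           min_cells = 10L, perturbed = NULL) {
    level <- match.arg(level)
    counts <- if (is(sce, "SummarizedExperiment"))
        SummarizedExperiment::assay(sce, "counts") else sce
    df <- assignmentTable(assignment)
    df <- df[match(colnames(counts), df$barcode), , drop = FALSE]
    keep <- !is.na(df$status) & df$status == "assigned"
    if (!is.null(perturbed)) {
        fl <- perturbed[match(df$barcode, names(perturbed))]
        is_ctrl <- df$target_class %in% c("intergenic", "non_targeting")
        keep <- keep & (is_ctrl | is.na(fl) | fl)
    }
    group <- if (level == "guide") df$assigned_hgrna else df$target_id
    keep <- keep & !is.na(group)
    if (!any(keep)) stop("no assigned cells to aggregate")
    group <- group[keep]
    counts <- counts[, keep, drop = FALSE]
    dfk <- df[keep, , drop = FALSE]

    gs <- sort(unique(group))
    n_cells <- as.integer(table(factor(group, levels = gs)))
    small <- n_cells < min_cells
    if (all(small)) stop("no pseudobulk group reaches min_cells")
    if (any(small)) {
        warning(sprintf("dropping %d group(s) under min_cells = %d",
                        sum(small), min_cells))
        gs <- gs[!small]; n_cells <- n_cells[!small]
        sel <- group %in% gs
        group <- group[sel]; counts <- counts[, sel, drop = FALSE]
        dfk <- dfk[sel, , drop = FALSE]
    }
    ind <- Matrix::sparseMatrix(i = seq_along(group),
                                j = match(group, gs), x = 1,
                                dims = c(length(group), length(gs)))
    pb <- as.matrix(counts %*% ind)
    dimnames(pb) <- list(rownames(counts), gs)

    df2 <- dfk[match(gs, group), , drop = FALSE]
    cd <- S4Vectors::DataFrame(
        group = gs,
        guide = if (level == "guide") gs else NA_character_,
        target_id = df2$target_id, target_class = df2$target_class,
        n_cells = n_cells, row.names = gs)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = pb), colData = cd,
        metadata = list(level = level, min_cells = min_cells))
}

#' Median-of-ratios size factors
#'
#' Computes one normalization factor per pseudobulk group as the median,
#' over reference genes, of the ratio of the group's count to the gene's
#' geometric mean across groups. Genes with a zero count in any group are
#' excluded from the reference; if no gene is positive everywhere the
#' ratios fall back to each group's positive-count genes, with a warning.
#'
#' @param pb A \code{SummarizedExperiment} from \code{\link{aggregateCells}}
#'   or a genes x groups count matrix.
#' @return Named numeric vector of size factors (one per group).
#' @export
sizeFactorsMedianRatio <- function(pb) {
    m <- if (is(pb, "SummarizedExperiment"))
        SummarizedExperiment::assay(pb, "counts") else as.matrix(pb)
    if (ncol(m) < 2L) stop("need >= 2 groups")
    logm <- log(m)
    loggeo <- rowMeans(logm)
    ref <- is.finite(loggeo)
    if (!any(ref)) {
        warning("no gene positive in all groups; using positive-count genes per group")
        sf <- apply(m, 2L, function(col) {
            pos <- col > 0
            exp(stats::median(log(col[pos]) - rowMeans(logm, na.rm = TRUE)[pos]))
        })
    } else {
        geo <- exp(loggeo[ref])
        sf <- apply(m[ref, , drop = FALSE], 2L, function(cnt)
            stats::median(cnt / geo))
    }
    names(sf) <- colnames(m)
    sf
}

#' Method-of-moments NB dispersions with a loess trend
#'
#' Estimates a per-gene negative-binomial dispersion from size-factor
#' normalized counts by the method of moments,
#' \eqn{\hat\alpha = (s^2 - \bar q)/\bar q^2}, fits a mean-dispersion trend
#' by loess on the log scale over genes with positive estimates, and shrinks
#' each gene-wise estimate toward the trend (geometric mean of the two;
#' nonpositive gene-wise estimates take the trend). Dispersions are floored
#' at 1e-8. All-zero genes are excluded from testing (\code{NA}).
#'
#' @param pb Pseudobulk \code{SummarizedExperiment} or count matrix.
#' @param sf Size factors (default: \code{\link{sizeFactorsMedianRatio}}).
#' @param span Loess span (default 0.5).
#' @return \code{DataFrame} with per-gene \code{mean}, \code{dispersion_raw},
#'   \code{dispersion_trend} and final \code{dispersion}.
#' @export
estimateDispersions <- function(pb, sf = NULL, span = 0.5) {
    m <- if (is(pb, "SummarizedExperiment"))
        SummarizedExperiment::assay(pb, "counts") else as.matrix(pb)
    if (ncol(m) < 3L) stop("need >= 3 groups to estimate dispersions")
    if (is.null(sf)) sf <- sizeFactorsMedianRatio(m)
    q <- sweep(m, 2L, sf, "/")
    mu <- rowMeans(q)
    v <- apply(q, 1L, stats::var)
    raw <- ifelse(mu > 0, (v - mu) / mu^2, NA_real_)

    ok <- !is.na(raw) & raw > 0 & mu > 0
    trend <- rep(NA_real_, length(mu))
    if (sum(ok) >= 10L) {
        fit <- stats::loess(log(raw[ok]) ~ log(mu[ok]), span = span,
                            family = "symmetric",
                            control = stats::loess.control(surface = "direct"))
        trend[mu > 0] <- exp(stats::predict(fit, log(mu[mu > 0])))
    } else {
        trend[mu > 0] <- stats::median(raw[ok], na.rm = TRUE)
        if (!is.finite(trend[which(mu > 0)[1]])) trend[mu > 0] <- 0.1
    }
    trend <- pmax(trend, 1e-8)
    disp <- ifelse(is.na(raw) | raw <= 0, trend,
                   exp((log(pmax(raw, 1e-8)) + log(trend)) / 2))
    disp <- pmax(disp, 1e-8)
    disp[mu == 0] <- NA_real_
    S4Vectors::DataFrame(mean = mu, dispersion_raw = raw,
                         dispersion_trend = trend, dispersion = disp,
                         row.names = rownames(m))
}

#' Pseudobulk negative-binomial Wald test
#'
#' Tests each gene for differential expression between target and control
#' pseudobulk groups with a negative-binomial log-linear model (condition
#' indicator plus intercept, log size factors as offset, gene-wise
#' dispersion fixed at the shrunken estimate) and a Wald test on the
#' condition coefficient. Genes whose mean normalized count falls below
#' \code{min_mean} are excluded before Benjamini-Hochberg adjustment
#' (independent filtering). A gene is flagged as differentially expressed
#' when \code{padj < alpha} and \code{|log2fc| > lfc_threshold} (defaults
#' 0.05 and 0.5). Degenerate fits report \code{p = 1}.
#'
#' @param pb Pseudobulk \code{SummarizedExperiment} or count matrix.
#' @param target_groups,control_groups Column names of the two conditions.
#' @param sf,disp Optional precomputed size factors / dispersion table for
#'   the full \code{pb}; computed on the selected columns when missing.
#' @param min_mean Independent-filter threshold on mean normalized count
#'   (default 1).
#' @param alpha,lfc_threshold DEG definition thresholds.
#' @return \code{DataFrame} with per-gene \code{base_mean}, \code{log2fc},
#'   \code{se}, \code{stat}, \code{p}, \code{padj}, \code{is_deg},
#'   \code{tested}.
#' @export
deTest <- function(pb, target_groups, control_groups, sf = NULL, disp = NULL,
                   min_mean = 1, alpha = 0.05, lfc_threshold = 0.5) {
    m <- if (is(pb, "SummarizedExperiment"))
        SummarizedExperiment::assay(pb, "counts") else as.matrix(pb)
    if (length(control_groups) < 2L) stop("need >= 2 control groups")
    miss <- setdiff(c(target_groups, control_groups), colnames(m))
    if (length(miss)) stop("unknown groups: ", paste(miss, collapse = ", "))
    sel <- c(control_groups, target_groups)
    msub <- m[, sel, drop = FALSE]
    cond <- rep(c(0, 1), c(length(control_groups), length(target_groups)))
    if (is.null(sf)) sf <- sizeFactorsMedianRatio(msub)
    else sf <- sf[sel]
    if (is.null(disp)) disp <- estimateDispersions(msub, sf = sf)
    dvec <- disp$dispersion

    q <- sweep(msub, 2L, sf, "/")
    base_mean <- rowMeans(q)
    tested <- base_mean >= min_mean & !is.na(dvec)
    off <- log(sf)

    ln2 <- log(2)
    n <- nrow(msub)
    lfc <- se <- stat <- p <- rep(NA_real_, n)
    for (g in which(tested)) {
        y <- msub[g, ]
        res <- tryCatch({
            fam <- MASS::negative.binomial(theta = 1 / max(dvec[g], 1e-8))
            fit <- suppressWarnings(
                stats::glm(y ~ cond, family = fam, offset = off))
            cf <- summary(fit)$coefficients
            if (nrow(cf) < 2L || !is.finite(cf[2L, 2L]) || cf[2L, 2L] <= 0)
                NULL
            else cf[2L, 1:2]
        }, error = function(e) NULL)
        if (is.null(res) || res[2L] < 1e-8) {
            # zero-variance / numerically perfect fits carry no evidence
            lfc[g] <- 0; se[g] <- NA_real_; stat[g] <- 0; p[g] <- 1
        } else {
            lfc[g] <- res[1L] / ln2
            se[g] <- res[2L] / ln2
            stat[g] <- res[1L] / res[2L]
            p[g] <- 2 * stats::pnorm(-abs(stat[g]))
        }
    }
    # identical normalized profiles give p ~ 1 through the model itself
    padj <- rep(NA_real_, n)
    padj[tested] <- stats::p.adjust(p[tested], method = "BH")
    is_deg <- !is.na(padj) & padj < alpha & abs(lfc) > lfc_threshold
    S4Vectors::DataFrame(
        gene = rownames(msub), base_mean = base_mean, log2fc = lfc, se = se,
        stat = stat, p = p, padj = padj, is_deg = is_deg, tested = tested,
        row.names = rownames(msub))
}

#' Mean pairwise guide concordance
#'
#' Pearson correlation of log2 fold-changes between every pair of guides
#' targeting the same feature, averaged — the replicate-consistency summary
#' for a target. Computed over a supplied gene set (typically the highly
#' variable genes).
#'
#' @param de_list Named list of \code{\link{deTest}} results, one per guide.
#' @param genes Genes over which to correlate (default: intersection of all
#'   tested genes).
#' @return List with \code{mean_r} and the per-pair correlation table; with
#'   fewer than two guides \code{mean_r} is \code{NA}.
#' @export
guideConcordance <- function(de_list, genes = NULL) {
    if (length(de_list) < 2L)
        return(list(mean_r = NA_real_, pairs = data.frame()))
    if (is.null(genes)) {
        genes <- Reduce(intersect, lapply(de_list, function(d)
            d$gene[d$tested]))
    }
    lfc <- vapply(de_list, function(d) d$log2fc[match(genes, d$gene)],
                  numeric(length(genes)))
    cmb <- utils::combn(length(de_list), 2L)
    r <- apply(cmb, 2L, function(ix)
        stats::cor(lfc[, ix[1L]], lfc[, ix[2L]], use = "complete.obs"))
    pairs <- data.frame(guide_a = names(de_list)[cmb[1L, ]],
                        guide_b = names(de_list)[cmb[2L, ]], r = r)
    list(mean_r = mean(r), pairs = pairs)
}
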