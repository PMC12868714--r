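#' Local perturbation signature against nearest control cells
#'
#' For every cell, finds its \code{n_neighbors} nearest control cells in
#' PCA space (computed on the scaled layer, by default restricted to highly
#' variable genes) and subtracts their mean expression from the cell's own,
#' yielding a signature layer in which shared technical and cell-state
#' variation cancels and only the perturbation-specific shift remains.
#' Control cells exclude themselves from their own neighbor sets.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{scaled} assay.
#' @param assignment An assigned \code{\link{CellAssignment}} covering the
#'   cells of \code{sce}.
#' @param control_class Target class defining control cells
#'   (default \code{"intergenic"}).
#' @param n_neighbors Number of nearest control cells (default 20).
#' @param n_pcs Number of principal components for the neighbor search
#'   (default 40, capped at the data rank).
#' @param use_hvg Restrict to \code{highly_variable} genes when flagged
#'   (default TRUE).
#' @return The \code{SingleCellExperiment} (subset to the genes used) with a
#'   \code{signature} assay and \code{is_control} in \code{colData}.
#' @export
computeSignature <- function(sce, assignment, control_class = "intergenic",
                             n_neighbors = 20L, n_pcs = 40L, use_hvg = TRUE) {
    df <- assignmentTable(assignment)
    if (!"status" %in% colnames(df)) stop("run assignPerturbations() first")
    df <- df[match(colnames(sce), df$barcode), , drop = FALSE]
    if (anyNA(df$barcode)) stop("assignment does not cover all cells")
    rd <- SummarizedExperiment::rowData(sce)
    if (use_hvg && "highly_variable" %in% colnames(rd)) {
        # a signature space needs enough genes to be meaningful; tiny HVG
        # sets (small gene universes) fall back to all genes
        if (sum(rd$highly_variable) >= 20L) {
            sce <- sce[rd$highly_variable, ]
        } else if (any(rd$highly_variable)) {
            warning("fewer than 20 highly variable genes; using all genes")
        }
    }
    X <- t(as.matrix(SummarizedExperiment::assay(sce, "scaled")))  # cells x genes
    is_ctrl <- !is.na(df$target_class) & df$target_class %in% control_class &
        df$status == "assigned"
    n_ctrl <- sum(is_ctrl)
    if (n_ctrl < n_neighbors)
        stop(sprintf("only %d control cells for n_neighbors = %d",
                     n_ctrl, n_neighbors))

    k <- min(n_pcs, ncol(X), nrow(X) - 1L)
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)$x
    ctrl_idx <- which(is_ctrl)
    d2 <- .crossDist2(pc, pc[ctrl_idx, , drop = FALSE])
    sig <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
    for (i in seq_len(nrow(X))) {
        d <- d2[i, ]
        if (is_ctrl[i]) d[match(i, ctrl_idx)] <- Inf  # exclude self
        nb <- ctrl_idx[order(d)[seq_len(min(n_neighbors, sum(is.finite(d))))]]
        sig[i, ] <- X[i, ] - colMeans(X[nb, , drop = FALSE])
    }
    SummarizedExperiment::assay(sce, "signature") <- t(sig)
    sce$is_control <- is_ctrl
    S4Vectors::metadata(sce)$signature_params <-
        list(control_class = control_class, n_neighbors = n_neighbors,
             n_pcs = k)
    sce
}

## Squared Euclidean distances between rows of A and rows of B.
.crossDist2 <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    d2[d2 < 0] <- 0
    d2
}

#' Classify cells of each target as perturbed or escaping
#'
#' For each non-control target, projects its cells' signatures onto the
#' axis from the mean control signature to the mean target signature
#' (leave-one-out, so no cell is scored against a mean it contributed to),
#' and fits a two-component univariate Gaussian mixture to the projected
#' scores with one component anchored on the control cells' score
#' distribution; component responsibilities are reassigned iteratively
#' until they stabilize (or \code{max_iter}). Cells falling in the
#' control-like component are called escaping; ties go to escaping. A target whose two component means are separated by less
#' than \code{min_separation} pooled standard deviations is declared
#' undetectable and all its cells are called escaping. Control cells are
#' never classified perturbed.
#'
#' @param sce A \code{SingleCellExperiment} from
#'   \code{\link{computeSignature}} (with \code{signature} assay and
#'   \code{is_control}).
#' @param assignment The assigned \code{\link{CellAssignment}}.
#' @param max_iter Maximum label-update iterations (default 100).
#' @param tol EM convergence tolerance on parameters (default 1e-4).
#' @param min_separation Minimum standardized mean separation below which a
#'   target is undetectable (default 0.5).
#' @param min_cells Targets with fewer cells are flagged unclassifiable and
#'   fully retained with a warning (default 10).
#' @return A list with \code{cells} (DataFrame: barcode, target_id,
#'   perturbed) and \code{targets} (DataFrame: target_id, n_cells,
#'   escape_rate, separation, classifiable).
#' @export
classifyPerturbed <- function(sce, assignment, max_iter = 100L, tol = 1e-4,
                              min_separation = 0.5, min_cells = 10L) {
    df <- assignmentTable(assignment)
    df <- df[match(colnames(sce), df$barcode), , drop = FALSE]
    sig <- SummarizedExperiment::assay(sce, "signature")
    is_ctrl <- sce$is_control
    if (is.null(is_ctrl)) stop("run computeSignature() first")
    sig_c <- sig[, is_ctrl, drop = FALSE]
    ctrl_mean <- rowMeans(sig_c)

    targets <- setdiff(unique(df$target_id[df$status == "assigned" &
                                           !is_ctrl]), NA)
    cell_flag <- rep(NA, ncol(sce))
    cell_flag[is_ctrl] <- FALSE
    res <- lapply(targets, function(t) {
        idx <- which(df$target_id == t & df$status == "assigned" & !is_ctrl)
        n <- length(idx)
        if (n < min_cells) {
            warning(sprintf("target %s has %d cells (< %d): unclassifiable, retained",
                            t, n, min_cells))
            cell_flag[idx] <<- TRUE
            return(data.frame(target_id = t, n_cells = n, escape_rate = NA_real_,
                              separation = NA_real_, classifiable = FALSE))
        }
        sig_t <- sig[, idx, drop = FALSE]
        norm2_t <- colSums(sig_t^2)
        norm2_c <- colSums(sig_c^2)
        n_c <- ncol(sig_c)
        # projection axis: mean target signature minus mean control
        # signature, with leave-one-out corrections so that no cell is
        # scored against a mean it contributed to (without the correction
        # every null target would look separated)
        mT <- rowMeans(sig_t)
        raw_tT <- as.numeric(crossprod(sig_t, mT))
        raw_tC <- as.numeric(crossprod(sig_t, ctrl_mean))
        sc_t <- (n * raw_tT - norm2_t) / (n - 1L) - raw_tC
        raw_cT <- as.numeric(crossprod(sig_c, mT))
        raw_cC <- as.numeric(crossprod(sig_c, ctrl_mean))
        sc_c <- raw_cT - (n_c * raw_cC - norm2_c) / (n_c - 1L)
        fit <- .anchoredMixture(sc_t, sc_c, max_iter = max_iter, tol = tol)
        # undetectable targets: the declared minimum separation applies
        # both to the fitted component means and to the standardized
        # target-vs-control score difference (the latter stops the mixture
        # from latching onto a noise tail of a null target)
        sep_group <- abs(mean(sc_t) - mean(sc_c)) /
            sqrt((stats::var(sc_t) + stats::var(sc_c)) / 2)
        sep <- min(fit$separation, sep_group)
        perturbed <- fit$posterior_perturbed > 0.5  # ties -> escaping
        if (!is.finite(sep) || sep < min_separation)
            perturbed <- rep(FALSE, n)
        cell_flag[idx] <<- perturbed
        data.frame(target_id = t, n_cells = n,
                   escape_rate = mean(!perturbed), separation = sep,
                   classifiable = TRUE)
    })
    list(cells = S4Vectors::DataFrame(barcode = colnames(sce),
                                      target_id = df$target_id,
                                      is_control = is_ctrl,
                                      perturbed = cell_flag,
                                      row.names = colnames(sce)),
         targets = S4Vectors::DataFrame(do.call(rbind, res)))
}

## Two-component 1-D Gaussian mixture with the null component anchored on
## the control scores; EM over the target scores only.
.anchoredMixture <- function(sc_t, sc_c, max_iter = 100L, tol = 1e-4) {
    mu1 <- mean(sc_c); sd1 <- max(stats::sd(sc_c), 1e-8)
    if (length(unique(sc_t)) < 2L)
        return(list(posterior_perturbed = rep(0, length(sc_t)),
                    mu_control = mu1, mu_perturbed = mu1, separation = 0))
    km <- suppressWarnings(stats::kmeans(sc_t, centers = 2L, nstart = 3L))
    far <- which.max(abs(km$centers - mu1))
    mu2 <- km$centers[far]
    sd2 <- max(c(stats::sd(sc_t[km$cluster == far]), sd1 / 4, 1e-8),
               na.rm = TRUE)
    pi2 <- mean(km$cluster == far)
    for (it in seq_len(max_iter)) {
        p1 <- (1 - pi2) * stats::dnorm(sc_t, mu1, sd1)
        p2 <- pi2 * stats::dnorm(sc_t, mu2, sd2)
        r <- p2 / pmax(p1 + p2, 1e-300)
        w <- sum(r)
        if (w < 1e-8) { pi2 <- 0; break }
        mu2_new <- sum(r * sc_t) / w
        sd2_new <- max(sqrt(sum(r * (sc_t - mu2_new)^2) / w), 1e-8)
        pi2_new <- w / length(sc_t)
        delta <- max(abs(mu2_new - mu2), abs(sd2_new - sd2), abs(pi2_new - pi2))
        mu2 <- mu2_new; sd2 <- sd2_new; pi2 <- pi2_new
        if (delta < tol) break
    }
    p1 <- (1 - pi2) * stats::dnorm(sc_t, mu1, sd1)
    p2 <- pi2 * stats::dnorm(sc_t, mu2, sd2)
    list(posterior_perturbed = p2 / pmax(p1 + p2, 1e-300),
         mu_control = mu1, mu_perturbed = mu2,
         separation = abs(mu2 - mu1) / sqrt((sd1^2 + sd2^2) / 2))
}
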