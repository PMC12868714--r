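#' Detect guides per cell from the dual-modality capture matrix
#'
#' A guide is called detected in its modality when its UMI count reaches
#' \code{min_umi} and, when it is the only guide above \code{min_umi},
#' additionally dominates the next-highest guide of that modality by
#' \code{dominance_ratio}. When two or more guides of one modality both
#' exceed \code{min_umi} they are all reported, so that doublets remain
#' visible to downstream filtering.
#'
#' @param guides Guide-capture matrix (features x cells) whose rownames are
#'   \code{<hgrna_id>|cas9} / \code{<hgrna_id>|cas12a}, or a
#'   \code{SingleCellExperiment} carrying it as \code{altExp "hgRNA"}.
#' @param library The \code{\link{GuideLibrary}} the features must match.
#' @param min_umi Minimum UMI count for a detection (default 5).
#' @param dominance_ratio Required ratio over the next-highest guide when a
#'   single candidate is present (default 3).
#' @return A \code{\link{CellAssignment}} with per-cell
#'   \code{detected_cas9} / \code{detected_cas12a} hgRNA-id sets.
#' @export
detectGuides <- function(guides, library, min_umi = 5, dominance_ratio = 3) {
    stopifnot(is(library, "GuideLibrary"))
    if (min_umi < 1) stop("min_umi must be >= 1")
    if (dominance_ratio < 1) stop("dominance_ratio must be >= 1")
    if (is(guides, "SingleCellExperiment"))
        guides <- SummarizedExperiment::assay(
            SingleCellExperiment::altExp(guides, "hgRNA"), "counts")
    if (!is(guides, "CsparseMatrix"))
        guides <- methods::as(Matrix::Matrix(guides, sparse = TRUE),
                              "CsparseMatrix")
    feat <- rownames(guides)
    if (is.null(feat)) stop("guide matrix must have feature rownames")
    parts <- strsplit(feat, "|", fixed = TRUE)
    if (any(lengths(parts) != 2L) ||
        !all(vapply(parts, `[`, "", 2L) %in% c("cas9", "cas12a")))
        stop("guide features must be named '<hgrna_id>|cas9' or '<hgrna_id>|cas12a'")
    hg <- vapply(parts, `[`, "", 1L)
    mod <- vapply(parts, `[`, "", 2L)
    rec <- guideRecords(library)
    if (!all(hg %in% rec$hgrna_id))
        stop("guide features not present in the library: ",
             paste(utils::head(setdiff(hg, rec$hgrna_id), 3), collapse = ", "))

    det9 <- .detectModality(guides[mod == "cas9", , drop = FALSE],
                            hg[mod == "cas9"], min_umi, dominance_ratio)
    det12 <- .detectModality(guides[mod == "cas12a", , drop = FALSE],
                             hg[mod == "cas12a"], min_umi, dominance_ratio)
    bc <- colnames(guides)
    if (is.null(bc)) bc <- sprintf("cell_%06d", seq_len(ncol(guides)))
    CellAssignment(S4Vectors::DataFrame(
        barcode = bc,
        detected_cas9 = IRanges::CharacterList(det9),
        detected_cas12a = IRanges::CharacterList(det12),
        row.names = bc))
}

## Per-column detection on one modality's (guides x cells) sparse matrix.
.detectModality <- function(m, hgrna_ids, min_umi, ratio) {
    p <- m@p; i <- m@i; x <- m@x
    lapply(seq_len(ncol(m)), function(j) {
        k <- seq.int(p[j] + 1L, length.out = p[j + 1L] - p[j])
        if (length(k) == 0L) return(character(0))
        vals <- x[k]
        ids <- hgrna_ids[i[k] + 1L]
        cand <- vals >= min_umi
        if (sum(cand) >= 2L) return(ids[cand])
        if (sum(cand) == 1L) {
            next_best <- if (length(vals) > 1L) max(vals[!cand]) else 0
            if (vals[cand] >= ratio * next_best) return(ids[cand])
        }
        character(0)
    })
}

#' Categorize per-cell capture status
#'
#' Assigns each cell to \code{dual}, \code{cas9_only}, \code{cas12a_only}
#' or \code{none} according to which modalities detected at least one guide,
#' and records two summary fraction tables in the object metadata: fractions
#' over all cells, and fractions over cells with at least one detected guide
#' (the normalisation used when reporting detection rates).
#'
#' @param assignment A \code{\link{CellAssignment}} from
#'   \code{\link{detectGuides}}.
#' @return The updated \code{CellAssignment}; retrieve the summaries with
#'   \code{captureSummary()}.
#' @export
categorizeCapture <- function(assignment) {
    df <- assignmentTable(assignment)
    n9 <- lengths(df$detected_cas9)
    n12 <- lengths(df$detected_cas12a)
    cat_ <- ifelse(n9 > 0 & n12 > 0, "dual",
            ifelse(n9 > 0, "cas9_only",
            ifelse(n12 > 0, "cas12a_only", "none")))
    df$capture_category <- cat_
    counts <- table(factor(cat_, levels = CAPTURE_CATEGORIES))
    any_guide <- counts[c("dual", "cas9_only", "cas12a_only")]
    S4Vectors::metadata(df)$capture_summary <- list(
        counts = as.integer(counts),
        categories = CAPTURE_CATEGORIES,
        fraction_all = as.numeric(counts / max(1L, nrow(df))),
        fraction_detected = c(as.numeric(any_guide / max(1L, sum(any_guide))), NA_real_))
    CellAssignment(df)
}

#' @rdname categorizeCapture
#' @param assignment A categorized \code{CellAssignment}.
#' @export
captureSummary <- function(assignment) {
    s <- S4Vectors::metadata(assignmentTable(assignment))$capture_summary
    if (is.null(s)) stop("run categorizeCapture() first")
    data.frame(category = s$categories, n = s$counts,
               fraction_all = s$fraction_all,
               fraction_detected = s$fraction_detected)
}

#' Assign a single hgRNA perturbation identity per cell
#'
#' A cell is \code{assigned} when the hgRNAs implied by its detected Cas9
#' and Cas12a guides are consistent with exactly one library hgRNA (a single
#' modality detecting exactly one guide is acceptable evidence unless
#' \code{require_dual} is set). Cells in which any single modality implies
#' two or more distinct hgRNAs are \code{doublet}s; cells whose Cas9 and
#' Cas12a guides belong to different hgRNAs with no single-hgRNA explanation
#' are \code{decoupled} (their perturbation identity is unknowable and they
#' are dropped rather than reassigned). Cells assigned to a non-targeting
#' control are excluded when \code{exclude_nontargeting} is \code{TRUE}.
#'
#' @param assignment A categorized \code{\link{CellAssignment}}.
#' @param library The \code{\link{GuideLibrary}}.
#' @param exclude_nontargeting Exclude non-targeting assignments (default TRUE).
#' @param require_dual Require evidence from both modalities (default FALSE).
#' @return The \code{CellAssignment} with \code{assigned_hgrna},
#'   \code{target_id}, \code{target_class} and \code{status} columns.
#' @export
assignPerturbations <- function(assignment, library,
                                exclude_nontargeting = TRUE,
                                require_dual = FALSE) {
    df <- assignmentTable(assignment)
    if (!"capture_category" %in% colnames(df))
        df <- assignmentTable(categorizeCapture(assignment))
    rec <- guideRecords(library)
    known <- unique(c(unlist(df$detected_cas9), unlist(df$detected_cas12a)))
    if (!all(known %in% rec$hgrna_id))
        stop("detected guides absent from library: ",
             paste(utils::head(setdiff(known, rec$hgrna_id), 3), collapse = ", "))
    class_of <- rec$target_class; names(class_of) <- rec$hgrna_id
    target_of <- rec$target_id; names(target_of) <- rec$hgrna_id

    d9 <- as.list(df$detected_cas9)
    d12 <- as.list(df$detected_cas12a)
    n <- nrow(df)
    status <- character(n)
    hgrna <- rep(NA_character_, n)
    for (i in seq_len(n)) {
        h9 <- unique(d9[[i]]); h12 <- unique(d12[[i]])
        if (length(h9) == 0L && length(h12) == 0L) {
            status[i] <- "no_guide"
        } else if (length(h9) >= 2L || length(h12) >= 2L) {
            status[i] <- "doublet"
        } else if (length(h9) == 1L && length(h12) == 1L && h9 != h12) {
            status[i] <- "decoupled"
        } else {
            h <- if (length(h9) == 1L) h9 else h12
            if (require_dual && (length(h9) == 0L || length(h12) == 0L)) {
                status[i] <- "no_guide"
            } else if (exclude_nontargeting &&
                       class_of[[h]] == "non_targeting") {
                status[i] <- "excluded_nontargeting"
                hgrna[i] <- h
            } else {
                status[i] <- "assigned"
                hgrna[i] <- h
            }
        }
    }
    df$assigned_hgrna <- hgrna
    df$target_id <- ifelse(is.na(hgrna), NA_character_, unname(target_of[hgrna]))
    df$target_class <- ifelse(is.na(hgrna), NA_character_, unname(class_of[hgrna]))
    df$status <- status
    if (require_dual) S4Vectors::metadata(df)$require_dual <- TRUE
    CellAssignment(df)
}
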