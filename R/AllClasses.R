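#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

GUIDE_CLASSES <- c("exon_deletion", "gene_knockout", "intergenic", "non_targeting")
CAPTURE_CATEGORIES <- c("dual", "cas9_only", "cas12a_only", "none")
ASSIGNMENT_STATUSES <- c("assigned", "doublet", "decoupled", "no_guide",
                         "excluded_nontargeting")

#' GuideLibrary: manifest of hybrid guide RNAs
#'
#' A \code{GuideLibrary} holds the manifest of a dual-nuclease guide library.
#' Each record is one hybrid guide RNA (hgRNA) pairing a 20-nt Cas9 spacer
#' with a 23-nt Cas12a spacer, annotated with its target class
#' (\code{exon_deletion}, \code{gene_knockout}, \code{intergenic} or
#' \code{non_targeting}), target identifier and the 1-based index of the
#' guide within its target.
#'
#' Control records (intergenic and non-targeting) carry their own hgRNA id as
#' target id, so every control guide forms its own group.
#'
#' @slot records A \code{DataFrame} with columns \code{hgrna_id},
#'   \code{cas9_spacer}, \code{cas12a_spacer}, \code{target_class},
#'   \code{target_id}, \code{guide_index}.
#'
#' @seealso \code{\link{simulateGuideLibrary}}, \code{\link{readGuideLibrary}}
#' @aliases GuideLibrary-class
#' @exportClass GuideLibrary
setClass("GuideLibrary", slots = c(records = "DataFrame"))

setValidity("GuideLibrary", function(object) {
    rec <- object@records
    need <- c("hgrna_id", "cas9_spacer", "cas12a_spacer", "target_class",
              "target_id", "guide_index")
    if (!all(need %in% colnames(rec)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(rec$hgrna_id))
        return("hgrna_id values must be unique")
    if (!all(rec$target_class %in% GUIDE_CLASSES))
        return(paste("target_class must be one of:",
                     paste(GUIDE_CLASSES, collapse = ", ")))
    if (nrow(rec) > 0L) {
        if (!all(nchar(rec$cas9_spacer) == 20L))
            return("cas9_spacer must be 20 nt")
        if (!all(nchar(rec$cas12a_spacer) == 23L))
            return("cas12a_spacer must be 23 nt")
        ctrl <- rec$target_class %in% c("intergenic", "non_targeting")
        if (!all(rec$target_id[ctrl] == rec$hgrna_id[ctrl]))
            return("control records must have target_id == hgrna_id")
        # guide_index within each target: 1..k, no gaps
        by_target <- split(rec$guide_index[!ctrl], rec$target_id[!ctrl])
        bad <- vapply(by_target, function(ix)
            !identical(sort(as.integer(ix)), seq_along(ix)), logical(1))
        if (any(bad))
            return(paste("guide_index must be 1..k with no gaps within targets:",
                         paste(utils::head(names(by_target)[bad], 3), collapse = ", ")))
    }
    TRUE
})

#' CellAssignment: per-cell guide detection and perturbation identity
#'
#' Holds, for every cell barcode, the sets of hgRNAs detected through the
#' Cas9 and Cas12a capture modalities, the capture category, the assigned
#' hgRNA (when the detections are consistent with exactly one library
#' hgRNA) and a status flag. Doublets (two or more distinct hgRNAs in one
#' modality), decoupled cells (single but conflicting hgRNAs across
#' modalities) and, optionally, non-targeting assignments are excluded from
#' downstream analysis.
#'
#' @slot cells A \code{DataFrame} with one row per cell; columns grow as the
#'   assignment pipeline runs: \code{barcode}, \code{detected_cas9},
#'   \code{detected_cas12a} (\code{CharacterList}s), then
#'   \code{capture_category}, then \code{assigned_hgrna}, \code{target_id},
#'   \code{target_class}, \code{status}.
#'
#' @seealso \code{\link{detectGuides}}, \code{\link{categorizeCapture}},
#'   \code{\link{assignPerturbations}}
#' @aliases CellAssignment-class
#' @exportClass CellAssignment
setClass("CellAssignment", slots = c(cells = "DataFrame"))

setValidity("CellAssignment", function(object) {
    df <- object@cells
    if (!all(c("barcode", "detected_cas9", "detected_cas12a") %in% colnames(df)))
        return("cells must have columns barcode, detected_cas9, detected_cas12a")
    if (anyDuplicated(df$barcode))
        return("cell barcodes must be unique")
    if ("capture_category" %in% colnames(df) &&
        !all(df$capture_category %in% CAPTURE_CATEGORIES))
        return("invalid capture_category value")
    if ("status" %in% colnames(df)) {
        if (!all(df$status %in% ASSIGNMENT_STATUSES))
            return("invalid status value")
        ok <- df$status == "assigned"
        if (any(ok & (is.na(df$assigned_hgrna) | df$assigned_hgrna == "")))
            return("assigned cells must carry exactly one hgRNA")
        if (any(df$status == "no_guide" & df$capture_category != "none" &
                lengths(df$detected_cas9) + lengths(df$detected_cas12a) > 0 &
                !isTRUE(metadata(df)$require_dual)))
            return("cells with detected guides cannot be no_guide unless require_dual")
    }
    TRUE
})

setMethod("show", "GuideLibrary", function(object) {
    rec <- object@records
    cat("GuideLibrary with", nrow(rec), "hgRNAs\n")
    if (nrow(rec) > 0L) {
        tab <- table(factor(rec$target_class, levels = GUIDE_CLASSES))
        for (cl in names(tab)) {
            nt <- length(unique(rec$target_id[rec$target_class == cl]))
            cat(sprintf("  %-14s %4d guides, %4d targets\n", cl, tab[[cl]], nt))
        }
    }
})

setMethod("show", "CellAssignment", function(object) {
    df <- object@cells
    cat("CellAssignment for", nrow(df), "cells\n")
    if ("capture_category" %in% colnames(df)) {
        tab <- table(factor(df$capture_category, levels = CAPTURE_CATEGORIES))
        cat("  capture:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    }
    if ("status" %in% colnames(df)) {
        tab <- table(factor(df$status, levels = ASSIGNMENT_STATUSES))
        cat("  status: ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    }
})

#' @describeIn GuideLibrary-class Number of guide records.
#' @param x A \code{GuideLibrary}.
#' @export
setMethod("length", "GuideLibrary", function(x) nrow(x@records))

#' Accessors for GuideLibrary and CellAssignment
#'
#' \code{guideRecords} returns the manifest table of a \code{GuideLibrary};
#' \code{targetIds} its unique target identifiers (optionally restricted to a
#' class); \code{assignmentTable} the per-cell table of a
#' \code{CellAssignment}; \code{assignedCells} the subset of cells with
#' status \code{assigned}.
#'
#' @param x A \code{GuideLibrary} or \code{CellAssignment}.
#' @param class Optional target class filter for \code{targetIds}.
#' @return A \code{DataFrame} (or character vector for \code{targetIds}).
#' @export
guideRecords <- function(x) {
    stopifnot(is(x, "GuideLibrary"))
    x@records
}

#' @rdname guideRecords
#' @export
targetIds <- function(x, class = NULL) {
    rec <- guideRecords(x)
    if (!is.null(class)) rec <- rec[rec$target_class %in% class, , drop = FALSE]
    unique(rec$target_id)
}

#' @rdname guideRecords
#' @export
assignmentTable <- function(x) {
    stopifnot(is(x, "CellAssignment"))
    x@cells
}

#' @rdname guideRecords
#' @export
assignedCells <- function(x) {
    df <- assignmentTable(x)
    if (!"status" %in% colnames(df))
        stop("run assignPerturbations() first")
    df[df$status == "assigned", , drop = FALSE]
}

GuideLibrary <- function(records) {
    new("GuideLibrary", records = DataFrame(records))
}

CellAssignment <- function(cells) {
    new("CellAssignment", cells = cells)
}
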