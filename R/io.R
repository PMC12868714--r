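#' Write a counts matrix as MatrixMarket with sidecar tables
#'
#' Writes \code{matrix.mtx}, \code{features.tsv} and \code{barcodes.tsv}
#' (uncompressed, 10x-style layout: features are rows) into \code{dir}.
#'
#' @param m Features x cells matrix (sparse or dense).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
writeMtx <- function(m, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(m, "CsparseMatrix"),
                                "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
    utils::write.table(data.frame(feature = rownames(m)),
                       file.path(dir, "features.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(barcode = colnames(m)),
                       file.path(dir, "barcodes.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(dir)
}

#' @rdname writeMtx
#' @param dir Directory containing \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv}.
#' @export
readMtx <- function(dir) {
    m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                     "CsparseMatrix")
    rownames(m) <- utils::read.table(file.path(dir, "features.tsv"),
                                     sep = "\t")[, 1L]
    colnames(m) <- utils::read.table(file.path(dir, "barcodes.tsv"),
                                     sep = "\t")[, 1L]
    m
}

#' Read / write a guide-library manifest
#'
#' The manifest is a TSV with columns \code{hgrna_id}, \code{cas9_spacer},
#' \code{cas12a_spacer}, \code{target_class}, \code{target_id},
#' \code{guide_index}.
#'
#' @param path TSV file path.
#' @return \code{readGuideLibrary}: a \code{\link{GuideLibrary}}.
#' @export
readGuideLibrary <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    GuideLibrary(df)
}

#' @rdname readGuideLibrary
#' @param library A \code{\link{GuideLibrary}}.
#' @export
writeGuideLibrary <- function(library, path) {
    utils::write.table(as.data.frame(guideRecords(library)), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a marker gene list
#'
#' One gene symbol per line; blank lines and \code{#} comments ignored.
#' The package ships the standard S-phase and G2/M marker lists under
#' \code{inst/extdata} (\code{s_genes.txt}, \code{g2m_genes.txt}).
#'
#' @param path Text file path.
#' @return Character vector of gene names.
#' @examples
#' s <- readMarkerList(system.file("extdata", "s_genes.txt",
#'                                 package = "scExonScreen"))
#' head(s)
#' @export
readMarkerList <- function(path) {
    x <- trimws(readLines(path))
    x[nzchar(x) & !startsWith(x, "#")]
}

#' Write an assignment table to TSV
#'
#' Flattens the list columns (detected guide sets become comma-joined
#' strings) and writes barcode, capture category, assigned hgRNA, target
#' and status.
#'
#' @param assignment A \code{\link{CellAssignment}}.
#' @param path Output TSV path.
#' @export
writeAssignments <- function(assignment, path) {
    df <- assignmentTable(assignment)
    flat <- data.frame(
        barcode = df$barcode,
        detected_cas9 = vapply(as.list(df$detected_cas9),
                               paste, "", collapse = ","),
        detected_cas12a = vapply(as.list(df$detected_cas12a),
                                 paste, "", collapse = ","))
    for (col in c("capture_category", "assigned_hgrna", "target_id",
                  "target_class", "status"))
        if (col %in% colnames(df)) flat[[col]] <- df[[col]]
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
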