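# Shared fixtures, built in code. Heavier objects are created once and
# reused across files via lazy accessors.

.fx <- new.env()

# Small noise-free screen: detections are perfect, no ambient UMIs, no
# doublets or decoupling, no escapers.
cleanScreen <- function() {
    if (is.null(.fx$clean)) {
        lib <- simulateGuideLibrary(3, 3, 2, 2, 6, 2, seed = 11)
        truth <- simulateTruth(lib, n_genes = 300,
                               mean_affected_per_target = 15,
                               lfc_scale = 1.5, escape_fraction = 0,
                               seed = 12)
        sce <- simulateCells(lib, truth, n_cells_per_guide = 40,
                             p_detect_cas9 = 1, p_detect_cas12a = 1,
                             doublet_rate = 0, decoupling_rate = 0,
                             lambda_ambient = 0, seed = 13)
        ca <- assignPerturbations(categorizeCapture(detectGuides(sce, lib)),
                                  lib)
        .fx$clean <- list(lib = lib, truth = truth, sce = sce, ca = ca)
    }
    .fx$clean
}

# Minimal hand-built guide library from explicit records.
makeLibrary <- function(hgrna_id, target_class, target_id,
                        guide_index = NULL) {
    n <- length(hgrna_id)
    if (is.null(guide_index)) {
        guide_index <- stats::ave(seq_len(n), target_id, FUN = seq_along)
    }
    set.seed(7)
    scExonScreen:::GuideLibrary(S4Vectors::DataFrame(
        hgrna_id = hgrna_id,
        cas9_spacer = scExonScreen:::.uniqueSpacers(n, 20L),
        cas12a_spacer = scExonScreen:::.uniqueSpacers(n, 23L),
        target_class = target_class, target_id = target_id,
        guide_index = as.integer(guide_index)))
}

# Guide-capture matrix from a list of per-cell named count vectors, e.g.
# list(c("h1|cas9" = 25, "h1|cas12a" = 30), ...)
makeGuideMatrix <- function(cells, features) {
    m <- matrix(0, length(features), length(cells),
                dimnames = list(features,
                                sprintf("cell_%03d", seq_along(cells))))
    for (j in seq_along(cells)) {
        v <- cells[[j]]
        m[names(v), j] <- v
    }
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

# Hand-built assigned CellAssignment (bypasses detection) for tests that
# exercise downstream modules directly from known cell identities.
makeAssignment <- function(barcode, hgrna, target_id, target_class,
                           status = "assigned") {
    n <- length(barcode)
    empty <- IRanges::CharacterList(rep(list(character(0)), n))
    scExonScreen:::CellAssignment(S4Vectors::DataFrame(
        barcode = barcode, detected_cas9 = empty, detected_cas12a = empty,
        capture_category = rep("dual", n),
        assigned_hgrna = hgrna, target_id = target_id,
        target_class = target_class,
        status = rep_len(status, n), row.names = barcode))
}

# Assignment straight from simulation truth (singlet cells only).
truthAssignment <- function(sce, lib) {
    rec <- guideRecords(lib)
    cd <- SummarizedExperiment::colData(sce)
    makeAssignment(colnames(sce), cd$hgrna_1, cd$target_id, cd$target_class)
}
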