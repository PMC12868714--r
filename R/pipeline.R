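## Default run configuration. Every key is echoed into the run manifest;
## unknown keys in a user config are rejected before any stage runs.
.defaultConfig <- function() {
    list(
        seed = 1L,
        outdir = "screen_run",
        overwrite = FALSE,
        stages = list(simulate = TRUE, assign = TRUE, qc = TRUE,
                      signature = TRUE, de = TRUE, cellcycle = TRUE,
                      compare = TRUE, annotate = FALSE),
        simulate = list(n_exon_targets = 224L, guides_per_exon = 3L,
                        n_gene_targets = 161L, guides_per_gene = 2L,
                        n_intergenic = 40L, n_nontargeting = 40L,
                        n_genes = 2000L, mean_affected_per_target = 20,
                        lfc_scale = 1, escape_fraction = 0.2,
                        dispersion = 0.2, n_cells_per_guide = 200L,
                        p_detect_cas9 = 0.97, p_detect_cas12a = 0.95,
                        doublet_rate = 0.08, decoupling_rate = 0.05,
                        phase_proportions = c(G1 = 0.18, S = 0.52, G2M = 0.30),
                        phase_effect_lfc = 1),
        assign = list(min_umi = 5, dominance_ratio = 3,
                      exclude_nontargeting = TRUE, require_dual = FALSE),
        qc = list(min_genes = 200L, min_cells = 3L, target_sum = 1e4,
                  min_mean = 0.0125, max_mean = 3, min_disp = 0.5,
                  max_value = 10, mito_prefix = "MT-"),
        signature = list(control_class = "intergenic", n_neighbors = 20L,
                         n_pcs = 40L, min_separation = 0.5, min_cells = 10L),
        de = list(level = "guide", min_cells = 10L, min_mean = 1,
                  alpha = 0.05, lfc_threshold = 0.5, perturbed_only = TRUE,
                  max_targets = Inf),
        cellcycle = list(n_bins = 25L, ctrl_size = 50L),
        compare = list(min_perturbations = 30L, r_threshold = 0.4,
                       linkage = "average"),
        annotate = list(gtf = NULL, exons = NULL, genome = NULL)
    )
}

.mergeConfig <- function(base, user, path = "") {
    for (k in names(user)) {
        full <- if (nzchar(path)) paste0(path, ".", k) else k
        if (!k %in% names(base))
            stop("unknown config key: ", full)
        if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
            if (!is.list(user[[k]]))
                stop("config key ", full, " must be a list")
            base[[k]] <- .mergeConfig(base[[k]], user[[k]], full)
        } else {
            base[[k]] <- user[[k]]
        }
    }
    base
}

#' Run the full screen-analysis pipeline
#'
#' Executes the stages in order (simulate -> assign -> qc -> signature ->
#' de -> cellcycle -> compare -> annotate), writing every stage's tables
#' under \code{outdir} and a run manifest JSON (\code{run_manifest.json})
#' that echoes all parameters, the derived per-stage seeds, output file MD5
#' hashes and stage timings. A single global seed is fanned out to
#' per-stage child seeds by a stage-name hash, so toggling one stage does
#' not shift another stage's random stream. Identical configs and seeds
#' give identical manifests and output hashes. Existing non-empty output
#' directories are refused unless \code{overwrite = TRUE}: partial outputs
#' are never silently reused.
#'
#' @param config A (partial) configuration list, or the path to a YAML/JSON
#'   file; unknown keys are rejected before any stage runs. See
#'   \code{scExonScreen:::.defaultConfig()} for all keys and defaults.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config = list()) {
    if (is.character(config)) {
        config <- if (grepl("\\.ya?ml$", config))
            yaml::read_yaml(config) else jsonlite::read_json(config,
                                                             simplifyVector = TRUE)
    }
    cfg <- .mergeConfig(.defaultConfig(), config)
    outdir <- cfg$outdir
    if (dir.exists(outdir) && length(list.files(outdir)) > 0L) {
        if (!isTRUE(cfg$overwrite))
            stop("output directory ", outdir,
                 " is not empty; set overwrite = TRUE to rerun")
        unlink(outdir, recursive = TRUE)
    }
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

    manifest <- list(config = cfg, stage_seeds = list(), timings = list(),
                     output_hashes = list())
    results <- list()
    outputs <- character(0)
    runStage <- function(name, fun) {
        t0 <- Sys.time()
        seed <- .stageSeed(cfg$seed, name)
        manifest$stage_seeds[[name]] <<- seed
        res <- tryCatch(fun(seed), error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        manifest$timings[[name]] <<-
            round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
        res
    }
    addOutput <- function(...) outputs <<- c(outputs, file.path(outdir, ...))

    st <- cfg$stages
    if (isTRUE(st$simulate)) {
        results$sim <- runStage("simulate", function(seed) {
            p <- cfg$simulate
            lib <- simulateGuideLibrary(p$n_exon_targets, p$guides_per_exon,
                                        p$n_gene_targets, p$guides_per_gene,
                                        p$n_intergenic, p$n_nontargeting,
                                        seed = seed)
            truth <- simulateTruth(lib, n_genes = p$n_genes,
                                   mean_affected_per_target = p$mean_affected_per_target,
                                   lfc_scale = p$lfc_scale,
                                   escape_fraction = p$escape_fraction,
                                   dispersion = p$dispersion,
                                   seed = seed + 1L)
            sce <- simulateCells(lib, truth,
                                 n_cells_per_guide = p$n_cells_per_guide,
                                 p_detect_cas9 = p$p_detect_cas9,
                                 p_detect_cas12a = p$p_detect_cas12a,
                                 doublet_rate = p$doublet_rate,
                                 decoupling_rate = p$decoupling_rate,
                                 phase_proportions = unlist(p$phase_proportions),
                                 phase_effect_lfc = p$phase_effect_lfc,
                                 seed = seed + 2L)
            writeGuideLibrary(lib, file.path(outdir, "guide_library.tsv"))
            writeMtx(SummarizedExperiment::assay(sce, "counts"),
                     file.path(outdir, "expression"))
            writeMtx(SummarizedExperiment::assay(
                SingleCellExperiment::altExp(sce, "hgRNA"), "counts"),
                file.path(outdir, "guide_capture"))
            utils::write.table(
                as.data.frame(SummarizedExperiment::colData(sce)),
                file.path(outdir, "cell_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
            addOutput("guide_library.tsv", "cell_truth.tsv",
                      file.path("expression", "matrix.mtx"),
                      file.path("guide_capture", "matrix.mtx"))
            list(library = lib, truth = truth, sce = sce)
        })
    }
    lib <- results$sim$library; sce <- results$sim$sce

    if (isTRUE(st$assign)) {
        results$assign <- runStage("assign", function(seed) {
            p <- cfg$assign
            ca <- detectGuides(sce, lib, min_umi = p$min_umi,
                               dominance_ratio = p$dominance_ratio)
            ca <- categorizeCapture(ca)
            ca <- assignPerturbations(ca, lib,
                                      exclude_nontargeting = p$exclude_nontargeting,
                                      require_dual = p$require_dual)
            writeAssignments(ca, file.path(outdir, "assignments.tsv"))
            jsonlite::write_json(captureSummary(ca),
                                 file.path(outdir, "capture_summary.json"),
                                 auto_unbox = TRUE, digits = NA, pretty = TRUE)
            addOutput("assignments.tsv", "capture_summary.json")
            ca
        })
    }
    ca <- results$assign

    if (isTRUE(st$qc)) {
        results$qc <- runStage("qc", function(seed) {
            p <- cfg$qc
            x <- filterCellsGenes(sce, p$min_genes, p$min_cells,
                                  mito_prefix = p$mito_prefix)
            x <- normalizeLog(x, target_sum = p$target_sum)
            x <- selectHVG(x, p$min_mean, p$max_mean, p$min_disp)
            x <- regressAndScale(x, max_value = p$max_value)
            qc <- as.data.frame(SummarizedExperiment::colData(x)[
                , c("total_umi", "n_genes_expressed", "pct_mito")])
            qc <- cbind(barcode = colnames(x), qc)
            utils::write.table(qc, file.path(outdir, "qc_metrics.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            addOutput("qc_metrics.tsv")
            x
        })
        sce <- results$qc
    }

    if (isTRUE(st$signature)) {
        results$signature <- runStage("signature", function(seed) {
            p <- cfg$signature
            sig <- computeSignature(sce, ca, control_class = p$control_class,
                                    n_neighbors = p$n_neighbors,
                                    n_pcs = p$n_pcs)
            cls <- .withSeed(seed, classifyPerturbed(
                sig, ca, min_separation = p$min_separation,
                min_cells = p$min_cells))
            utils::write.table(as.data.frame(cls$cells),
                               file.path(outdir, "perturbed_cells.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            utils::write.table(as.data.frame(cls$targets),
                               file.path(outdir, "escape_rates.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            addOutput("perturbed_cells.tsv", "escape_rates.tsv")
            list(sce = sig, classification = cls)
        })
    }

    perturbed <- NULL
    if (!is.null(results$signature)) {
        fl <- results$signature$classification$cells
        perturbed <- stats::setNames(fl$perturbed, fl$barcode)
    }

    if (isTRUE(st$de)) {
        results$de <- runStage("de", function(seed) {
            p <- cfg$de
            pb <- aggregateCells(results$sim$sce, ca, level = "guide",
                                 min_cells = p$min_cells,
                                 perturbed = if (isTRUE(p$perturbed_only))
                                     perturbed else NULL)
            cd <- SummarizedExperiment::colData(pb)
            ctrl <- rownames(cd)[cd$target_class == "intergenic"]
            targets <- unique(cd$target_id[
                cd$target_class %in% c("exon_deletion", "gene_knockout")])
            if (is.finite(p$max_targets))
                targets <- utils::head(targets, p$max_targets)
            de <- lapply(targets, function(t) {
                tg <- rownames(cd)[!is.na(cd$target_id) & cd$target_id == t]
                deTest(pb, tg, ctrl, min_mean = p$min_mean,
                       alpha = p$alpha, lfc_threshold = p$lfc_threshold)
            })
            names(de) <- targets
            summ <- data.frame(
                target_id = targets,
                n_deg = vapply(de, function(d) sum(d$is_deg), integer(1)))
            utils::write.table(summ, file.path(outdir, "deg_summary.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            addOutput("deg_summary.tsv")
            list(pseudobulk = pb, results = de, control_groups = ctrl)
        })
    }

    if (isTRUE(st$cellcycle)) {
        results$cellcycle <- runStage("cellcycle", function(seed) {
            p <- cfg$cellcycle
            mk <- S4Vectors::metadata(results$sim$sce)$markers
            calls <- scoreCellCycle(sce, mk$S, mk$G2M, n_bins = p$n_bins,
                                    ctrl_size = p$ctrl_size, seed = seed)
            pass <- if (is.null(perturbed)) NULL else
                names(perturbed)[is.na(perturbed) | perturbed]
            fr <- phaseFractions(calls, ca, level = "guide", cells = pass)
            exon_fr <- fr[fr$target_class == "exon_deletion", , drop = FALSE]
            ko_fr <- fr[fr$target_class == "gene_knockout", , drop = FALSE]
            ctrl_fr <- fr[fr$target_class == "intergenic", , drop = FALSE]
            enr <- list()
            if (nrow(exon_fr) && nrow(ctrl_fr))
                enr$exon <- exonPhaseEnrichment(exon_fr, ctrl_fr)
            if (nrow(ko_fr) && nrow(ctrl_fr))
                enr$knockout <- knockoutPhaseEnrichment(ko_fr, ctrl_fr)
            utils::write.table(as.data.frame(calls),
                               file.path(outdir, "phase_calls.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            if (length(enr))
                utils::write.table(do.call(rbind, enr),
                                   file.path(outdir, "phase_enrichment.tsv"),
                                   sep = "\t", quote = FALSE, row.names = FALSE)
            addOutput("phase_calls.tsv")
            list(calls = calls, fractions = fr, enrichment = enr)
        })
    }

    if (isTRUE(st$compare) && !is.null(results$de)) {
        results$compare <- runStage("compare", function(seed) {
            p <- cfg$compare
            de <- results$de$results
            shared <- suppressWarnings(
                sharedDegMatrix(de, min_perturbations =
                    min(p$min_perturbations, max(1L, length(de) %/% 2L))))
            corr <- if (nrow(shared) >= 2L && ncol(shared) >= 2L)
                correlatePerturbations(shared, linkage = p$linkage) else NULL
            # exon vs matching knockout where both targets were tested
            rows <- list()
            for (ex in grep("^exon_", names(de), value = TRUE)) {
                ko <- sub("^exon_", "gene_", ex)
                if (!ko %in% names(de)) next
                cmp <- exonVsKnockout(de[[ex]], de[[ko]],
                                      r_threshold = p$r_threshold)
                rows[[ex]] <- data.frame(exon = ex, knockout = ko,
                                         r = cmp$r,
                                         n_union_degs = cmp$n_union_degs,
                                         concordant = cmp$concordant)
            }
            div <- if (length(rows)) do.call(rbind, rows) else NULL
            if (!is.null(div)) {
                utils::write.table(div, file.path(outdir, "divergence.tsv"),
                                   sep = "\t", quote = FALSE, row.names = FALSE)
                addOutput("divergence.tsv")
            }
            if (!is.null(corr)) {
                utils::write.table(corr$correlation,
                                   file.path(outdir, "perturbation_correlation.tsv"),
                                   sep = "\t", quote = FALSE)
                jsonlite::write_json(corr$order,
                                     file.path(outdir, "dendrogram_order.json"))
                addOutput("perturbation_correlation.tsv", "dendrogram_order.json")
            }
            list(shared = shared, correlation = corr, divergence = div)
        })
    }

    if (isTRUE(st$annotate) && !is.null(cfg$annotate$gtf)) {
        results$annotate <- runStage("annotate", function(seed) {
            p <- cfg$annotate
            exons <- utils::read.table(p$exons, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)
            ann <- annotateTargetedExons(p$gtf, exons, genome = p$genome)
            utils::write.table(ann, file.path(outdir, "exon_annotation.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            addOutput("exon_annotation.tsv")
            ann
        })
    }

    have <- outputs[file.exists(outputs)]
    manifest$output_hashes <- as.list(tools::md5sum(have))
    names(manifest$output_hashes) <- substring(have, nchar(outdir) + 2L)
    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE, null = "null")
    invisible(c(results, list(manifest = manifest)))
}
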