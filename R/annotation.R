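#' Construct a targeted-exon descriptor
#'
#' Coordinates follow the GTF convention: 1-based, inclusive on both ends.
#' An optional mutually-exclusive-exon (MXE) partner can be attached; for
#' MXE targets, skipping of the targeted exon implies inclusion of the
#' partner.
#'
#' @param chrom Chromosome / sequence name.
#' @param start,end 1-based inclusive coordinates, \code{start <= end}.
#' @param strand \code{"+"} or \code{"-"}.
#' @param gene_id Gene the exon belongs to.
#' @param mxe_partner Optional second \code{targetedExon} (partner exon).
#' @return A \code{GRanges} of length 1 with \code{gene_id} and
#'   \code{mxe_partner} metadata columns.
#' @export
targetedExon <- function(chrom, start, end, strand, gene_id,
                         mxe_partner = NULL) {
    stopifnot(start <= end, strand %in% c("+", "-"))
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start, end = end),
        strand = strand)
    gr$gene_id <- gene_id
    gr$mxe_partner <- if (is.null(mxe_partner)) list(NULL) else list(mxe_partner)
    gr
}

## Split a GTF GRanges into per-transcript exon / CDS GRangesLists for one gene.
.geneModels <- function(gtf, gene_id) {
    g <- gtf[!is.na(gtf$gene_id) & gtf$gene_id == gene_id]
    if (length(g) == 0L) return(NULL)
    ex <- g[g$type == "exon"]
    cds <- g[g$type == "CDS"]
    list(exons = S4Vectors::split(ex, ex$transcript_id),
         cds = S4Vectors::split(cds, cds$transcript_id))
}

#' Map a targeted exon to inclusion and skipping transcripts
#'
#' Inclusion transcripts of the exon's gene contain an exon with exactly
#' the targeted coordinates (identical start and end — overlap with an
#' alternative 5'/3' splice-site variant does not count). Skipping
#' transcripts have an intron spanning the whole targeted exon. Transcripts
#' doing neither (e.g. ending before the exon) belong to neither set, so
#' the two sets are disjoint by construction.
#'
#' @param gtf A \code{GRanges} from \code{rtracklayer::import()} of a GTF,
#'   or the path to a GTF file.
#' @param exon A \code{\link{targetedExon}}.
#' @return List with character vectors \code{inclusion} and \code{skipping}.
#' @export
mapTranscripts <- function(gtf, exon) {
    gtf <- .asGtf(gtf)
    models <- .geneModels(gtf, exon$gene_id)
    if (is.null(models))
        stop(sprintf("exon %s:%d-%d matches no gene '%s' in the annotation",
                     as.character(GenomicRanges::seqnames(exon)),
                     GenomicRanges::start(exon), GenomicRanges::end(exon),
                     exon$gene_id))
    ex_by_tx <- models$exons
    estart <- GenomicRanges::start(exon)
    eend <- GenomicRanges::end(exon)
    estrand <- as.character(GenomicRanges::strand(exon))
    echrom <- as.character(GenomicRanges::seqnames(exon))

    inclusion <- character(0); skipping <- character(0)
    for (tx in names(ex_by_tx)) {
        exs <- ex_by_tx[[tx]]
        if (length(exs) == 0L) next
        if (as.character(GenomicRanges::strand(exs))[1L] != estrand ||
            as.character(GenomicRanges::seqnames(exs))[1L] != echrom) next
        st <- sort(GenomicRanges::start(exs))
        en <- sort(GenomicRanges::end(exs))
        if (any(GenomicRanges::start(exs) == estart &
                GenomicRanges::end(exs) == eend)) {
            inclusion <- c(inclusion, tx)
        } else if (length(st) >= 2L) {
            # introns in genomic order
            int_start <- en[-length(en)] + 1L
            int_end <- st[-1L] - 1L
            if (any(int_start <= estart & int_end >= eend))
                skipping <- c(skipping, tx)
        }
    }
    if (length(inclusion) == 0L && length(skipping) == 0L)
        stop(sprintf(
            "exon %s:%d-%d (%s) matches no transcript of gene '%s' (check strand)",
            echrom, estart, eend, estrand, exon$gene_id))
    list(inclusion = inclusion, skipping = skipping)
}

.asGtf <- function(gtf) {
    if (is.character(gtf)) gtf <- rtracklayer::import(gtf)
    stopifnot(is(gtf, "GRanges"))
    gtf
}

#' Frame preservation of a targeted exon
#'
#' The deleted coding length is the overlap of the exon with the
#' transcript's CDS; skipping preserves the reading frame when that length
#' is a multiple of three, so the resulting protein lacks exactly the
#' residues encoded by the exon. An exon lying entirely in the UTR deletes
#' zero coding nucleotides and is frame-preserving. The result is
#' strand-invariant: only the overlap length matters.
#'
#' @param gtf GTF \code{GRanges} or path.
#' @param exon A \code{\link{targetedExon}}.
#' @param transcript_id An inclusion transcript with CDS records.
#' @return List with \code{frame_preserving} (logical; \code{NA} when the
#'   transcript has no CDS) and \code{deleted_coding_length}.
#' @export
framePreservation <- function(gtf, exon, transcript_id) {
    gtf <- .asGtf(gtf)
    cds <- gtf[gtf$type == "CDS" & !is.na(gtf$transcript_id) &
               gtf$transcript_id == transcript_id]
    if (length(cds) == 0L) {
        return(list(frame_preserving = NA, deleted_coding_length = NA_integer_,
                    reason = "no CDS annotated; unassessable"))
    }
    ov <- GenomicRanges::intersect(
        GenomicRanges::granges(cds),
        GenomicRanges::granges(exon), ignore.strand = TRUE)
    dl <- sum(GenomicRanges::width(ov))
    list(frame_preserving = dl %% 3L == 0L,
         deleted_coding_length = as.integer(dl))
}

## Ordered CDS ranges of a transcript as a plain data.frame (genomic order).
.cdsRanges <- function(gtf, tx) {
    cds <- gtf[gtf$type == "CDS" & !is.na(gtf$transcript_id) &
               gtf$transcript_id == tx]
    if (length(cds) == 0L) return(NULL)
    r <- GenomicRanges::reduce(GenomicRanges::granges(cds))
    r[order(GenomicRanges::start(r))]
}

## Coding sequence of a set of ordered CDS ranges, from a genome
## DNAStringSet; reverse-complemented on the minus strand.
.codingSeq <- function(ranges, strand, chrom, genome) {
    if (is.null(genome)) return(NULL)
    seqs <- lapply(seq_along(ranges), function(i)
        Biostrings::subseq(genome[[chrom]],
                           GenomicRanges::start(ranges)[i],
                           GenomicRanges::end(ranges)[i]))
    s <- do.call(Biostrings::xscat, seqs)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
}

#' Strict and longest skipping transcripts for a targeted exon
#'
#' A skipping transcript is \emph{strict} when its coding sequence equals
#' an inclusion transcript's coding sequence with exactly the targeted
#' exon removed — all other coding regions unchanged (UTR differences do
#' not disqualify). For an MXE target the expected coding sequence instead
#' substitutes the partner exon for the targeted exon. Without a genome
#' FASTA the comparison is made on CDS coordinates (coordinate identity
#' implies sequence identity); with \code{genome} supplied the reconstructed
#' nucleotide sequences are compared. The \emph{longest} skipping
#' transcript is the one with the greatest total exonic (mRNA) length,
#' regardless of other differences.
#'
#' @param gtf GTF \code{GRanges} or path.
#' @param exon A \code{\link{targetedExon}} (with \code{mxe_partner} set
#'   for MXE targets).
#' @param genome Optional \code{DNAStringSet} (or FASTA path) for
#'   sequence-level comparison.
#' @return List of class \code{"SkippingCall"}: \code{inclusion},
#'   \code{skipping}, \code{strict_skipping},
#'   \code{longest_skipping} (single id or \code{NA}), and
#'   \code{frame_preserving} of the first CDS-bearing inclusion transcript.
#' @export
strictAndLongestSkipping <- function(gtf, exon, genome = NULL) {
    gtf <- .asGtf(gtf)
    if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
    if (!is.null(genome))
        names(genome) <- sub("\\s.*$", "", names(genome))
    sets <- mapTranscripts(gtf, exon)
    partner <- exon$mxe_partner[[1L]]
    chrom <- as.character(GenomicRanges::seqnames(exon))
    strand <- as.character(GenomicRanges::strand(exon))

    strict <- character(0)
    fp <- NA
    if (length(sets$skipping) > 0L && length(sets$inclusion) > 0L) {
        exon_gr <- GenomicRanges::granges(exon)
        for (ti in sets$inclusion) {
            cds_i <- .cdsRanges(gtf, ti)
            if (is.null(cds_i)) next
            if (is.na(fp))
                fp <- framePreservation(gtf, exon, ti)$frame_preserving
            expected <- GenomicRanges::setdiff(cds_i, exon_gr,
                                               ignore.strand = TRUE)
            if (!is.null(partner)) {
                expected <- GenomicRanges::reduce(GenomicRanges::union(
                    expected, GenomicRanges::granges(partner),
                    ignore.strand = TRUE))
            }
            expected <- expected[order(GenomicRanges::start(expected))]
            for (ts in setdiff(sets$skipping, strict)) {
                cds_s <- .cdsRanges(gtf, ts)
                if (is.null(cds_s)) next
                same <- if (is.null(genome)) {
                    length(expected) == length(cds_s) &&
                        all(GenomicRanges::start(expected) ==
                            GenomicRanges::start(cds_s)) &&
                        all(GenomicRanges::end(expected) ==
                            GenomicRanges::end(cds_s))
                } else {
                    identical(.codingSeq(expected, strand, chrom, genome),
                              .codingSeq(cds_s, strand, chrom, genome))
                }
                if (isTRUE(same)) strict <- c(strict, ts)
            }
        }
    }

    longest <- NA_character_
    if (length(sets$skipping) > 0L) {
        ex_by_tx <- .geneModels(gtf, exon$gene_id)$exons
        len <- vapply(sets$skipping, function(tx)
            sum(GenomicRanges::width(ex_by_tx[[tx]])), numeric(1))
        longest <- sets$skipping[which.max(len)]
    }
    structure(list(inclusion = sets$inclusion, skipping = sets$skipping,
                   strict_skipping = strict, longest_skipping = longest,
                   frame_preserving = fp),
              class = "SkippingCall")
}

#' Annotate a table of targeted exons
#'
#' Applies \code{\link{mapTranscripts}}, \code{\link{framePreservation}}
#' and \code{\link{strictAndLongestSkipping}} to every row of an exon
#' table, collecting one annotation row per exon.
#'
#' @param gtf GTF \code{GRanges} or path.
#' @param exons \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{gene_id} (and optionally
#'   \code{exon_id}).
#' @param genome Optional genome FASTA path or \code{DNAStringSet}.
#' @return \code{data.frame} with per-exon transcript sets (comma-joined),
#'   frame call and deleted coding length.
#' @export
annotateTargetedExons <- function(gtf, exons, genome = NULL) {
    gtf <- .asGtf(gtf)
    rows <- lapply(seq_len(nrow(exons)), function(i) {
        e <- exons[i, ]
        te <- targetedExon(e$chrom, e$start, e$end, e$strand, e$gene_id)
        call <- strictAndLongestSkipping(gtf, te, genome = genome)
        dl <- NA_integer_
        if (length(call$inclusion)) {
            fp <- framePreservation(gtf, te, call$inclusion[1L])
            dl <- fp$deleted_coding_length
        }
        data.frame(
            exon_id = if ("exon_id" %in% names(exons)) e$exon_id
                      else sprintf("%s:%d-%d", e$chrom, e$start, e$end),
            gene_id = e$gene_id, exon_length = e$end - e$start + 1L,
            frame_preserving = call$frame_preserving,
            deleted_coding_length = dl,
            inclusion = paste(call$inclusion, collapse = ","),
            skipping = paste(call$skipping, collapse = ","),
            strict_skipping = paste(call$strict_skipping, collapse = ","),
            longest_skipping = call$longest_skipping)
    })
    do.call(rbind, rows)
}
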