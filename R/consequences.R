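## pieces: 2-col matrix (start, end) ascending by start; traversal is
## left-to-right on '+' and right-to-left on '-'.
.spliceToGenomic <- function(pieces, strand, ntStart, ntEnd) {
    w <- pieces[, 2L] - pieces[, 1L] + 1L
    ord <- if (strand == "+") seq_len(nrow(pieces)) else rev(seq_len(nrow(pieces)))
    total <- sum(w)
    if (ntStart < 1L || ntEnd > total || ntStart > ntEnd)
        stop("coordinates [", ntStart, ", ", ntEnd,
             "] outside the spliced length ", total)
    out <- NULL
    c0 <- 0L
    for (i in ord) {
        lo <- c0 + 1L
        hi <- c0 + w[i]
        if (ntEnd >= lo && ntStart <= hi) {
            o1 <- max(ntStart, lo) - c0
            o2 <- min(ntEnd, hi) - c0
            gi <- if (strand == "+")
                c(pieces[i, 1L] + o1 - 1L, pieces[i, 1L] + o2 - 1L)
            else
                c(pieces[i, 2L] - o2 + 1L, pieces[i, 2L] - o1 + 1L)
            out <- rbind(out, gi)
        }
        c0 <- hi
    }
    out <- out[order(out[, 1L]), , drop = FALSE]
    IRanges(out[, 1L], out[, 2L])
}

## inverse of .spliceToGenomic for an interval contiguous in the spliced
## molecule; maps a genomic interval inside the pieces back to nt coords
.genomicToSpliced <- function(pieces, strand, gStart, gEnd) {
    w <- pieces[, 2L] - pieces[, 1L] + 1L
    ord <- if (strand == "+") seq_len(nrow(pieces)) else rev(seq_len(nrow(pieces)))
    cum <- c(0L, cumsum(w[ord]))
    ntOf <- function(pos) {
        for (k in seq_along(ord)) {
            i <- ord[k]
            if (pos >= pieces[i, 1L] && pos <= pieces[i, 2L]) {
                off <- if (strand == "+") pos - pieces[i, 1L] + 1L
                       else pieces[i, 2L] - pos + 1L
                return(cum[k] + off)
            }
        }
        stop("genomic position ", pos, " not inside the pieces")
    }
    range(ntOf(gStart), ntOf(gEnd))
}

.txPieces <- function(x, transcript, what = c("exons", "cds")) {
    what <- match.arg(what)
    src <- if (what == "exons") x@exons else x@cds
    if (!transcript %in% names(src))
        stop("unknown transcript: ", transcript)
    gr <- src[[transcript]]
    if (!length(gr)) stop("transcript ", transcript, " has no ", what)
    list(mat = cbind(start(gr), end(gr), deparse.level = 0L),
         chrom = as.character(seqnames(gr))[1L],
         strand = as.character(strand(gr))[1L])
}

#' Project peptide coordinates to the genome
#'
#' Maps a 1-based amino-acid interval of a coding isoform to genomic
#' intervals: peptide \code{[p1, p2]} covers CDS nucleotides
#' \code{[3(p1-1)+1, 3 p2]}, which are walked through the CDS pieces
#' strand-aware, splitting across exon boundaries. The summed genomic width
#' always equals \code{3 (p2 - p1 + 1)}.
#'
#' @param x a [TranscriptModels-class].
#' @param transcript transcript id (must have a CDS).
#' @param pepStart,pepEnd 1-based peptide interval.
#' @return a `GRanges` of genomic intervals, ascending by start.
#' @export
peptideToGenomic <- function(x, transcript, pepStart, pepEnd) {
    p <- .txPieces(x, transcript, "cds")
    ir <- .spliceToGenomic(p$mat, p$strand,
                           3L * (pepStart - 1L) + 1L, 3L * pepEnd)
    GRanges(p$chrom, ir, strand = p$strand)
}

#' Project transcript (spliced mRNA) coordinates to the genome
#'
#' As [peptideToGenomic()] but in nucleotide units over the exons of the
#' isoform rather than codon units over its CDS.
#'
#' @param x a [TranscriptModels-class].
#' @param transcript transcript id.
#' @param txStart,txEnd 1-based positions on the spliced transcript.
#' @return a `GRanges` of genomic intervals, ascending by start.
#' @export
transcriptToGenomic <- function(x, transcript, txStart, txEnd) {
    p <- .txPieces(x, transcript, "exons")
    GRanges(p$chrom, .spliceToGenomic(p$mat, p$strand, txStart, txEnd),
            strand = p$strand)
}

#' Project a genomic interval to transcript or CDS coordinates
#'
#' Inverse of [transcriptToGenomic()] / [peptideToGenomic()] for intervals
#' whose endpoints lie inside the isoform's pieces.
#'
#' @param x a [TranscriptModels-class].
#' @param transcript transcript id.
#' @param gStart,gEnd genomic interval endpoints (must fall in exons/CDS).
#' @param space `"exons"` for spliced-transcript nt, `"cds"` for CDS nt.
#' @return integer vector `c(start, end)` in the requested coordinate
#'   space.
#' @export
genomicToTranscript <- function(x, transcript, gStart, gEnd,
                                space = c("exons", "cds")) {
    space <- match.arg(space)
    p <- .txPieces(x, transcript, space)
    .genomicToSpliced(p$mat, p$strand, gStart, gEnd)
}

#' Select the reference isoform of a gene
#'
#' `longest_coding` picks the isoform with the longest CDS (ties: longest
#' spliced transcript, then lexicographically smallest id); genes with no
#' coding isoform are skipped (`NA`). `major` picks the isoform with the
#' highest median FPKM across all samples (ties: smallest id).
#'
#' @param x a [TranscriptModels-class].
#' @param gene gene id.
#' @param mode `"longest_coding"` or `"major"`.
#' @param se a [SpliceExperiment-class]; required for `mode = "major"`.
#' @return the reference transcript id, or `NA_character_`.
#' @export
selectReferenceIsoform <- function(x, gene,
                                   mode = c("longest_coding", "major"),
                                   se = NULL) {
    mode <- match.arg(mode)
    txs <- x@txData$transcript_id[x@txData$gene_id == gene]
    if (!length(txs)) stop("unknown gene: ", gene)
    txs <- sort(txs)
    if (mode == "longest_coding") {
        cdsLen <- vapply(txs, function(t) sum(width(x@cds[[t]])), numeric(1))
        if (all(cdsLen == 0)) return(NA_character_)
        txLen <- vapply(txs, function(t) sum(width(x@exons[[t]])), numeric(1))
        best <- which(cdsLen == max(cdsLen))
        best <- best[order(-txLen[best], txs[best])]
        txs[best[1L]]
    } else {
        if (is.null(se)) stop("mode 'major' needs expression data")
        m <- fpkm(se)
        idx <- match(txs, rownames(m))
        if (anyNA(idx)) stop("isoform(s) of ", gene, " not in expression")
        med <- apply(m[idx, , drop = FALSE], 1L, stats::median)
        txs[order(-med, txs)[1L]]
    }
}

.fmtIntervals <- function(chrom, ir)
    paste(sprintf("%s:%d-%d", chrom, start(ir), end(ir)), collapse = ";")

.parseIntervals <- function(s) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
    m <- regmatches(parts, regexec("^(.+):(\\d+)-(\\d+)$", parts))
    do.call(rbind, lapply(m, function(x)
        data.frame(chrom = x[2L], start = as.integer(x[3L]),
                   end = as.integer(x[4L]))))
}

## genomic anchoring of one feature table row
.featureGenomic <- function(x, row, kind) {
    if (kind == "domain")
        peptideToGenomic(x, row$transcript_id, row$pep_start, row$pep_end)
    else
        transcriptToGenomic(x, row$transcript_id, row$tx_start, row$tx_end)
}

#' Gain and loss of features between isoforms
#'
#' Compares the feature content of every non-reference isoform of a gene
#' against the reference isoform ([selectReferenceIsoform()]). A feature in
#' the alternative isoform but not the reference is gained; present in the
#' reference but missing from the alternative, lost. Protein domains are
#' compared as accession sets (copies collapse); miRNA sites are identified
#' by (miRNA id, genomic interval), so the same miRNA hitting different
#' genomic regions of two isoforms counts as distinct sites.
#'
#' @param x a [TranscriptModels-class].
#' @param features data.frame; for domains: `transcript_id`, `accession`,
#'   `pep_start`, `pep_end`; for miRNA sites: `transcript_id`, `mirna_id`,
#'   `tx_start`, `tx_end`.
#' @param kind `"domain"` or `"mirna_site"`.
#' @param referenceMode `"longest_coding"` or `"major"`.
#' @param se expression (needed for `referenceMode = "major"`).
#' @param genes optional subset of gene ids.
#' @return data.frame of changes: `gene_id`, `reference_mode`,
#'   `reference_transcript_id`, `alt_transcript_id`, `feature_kind`,
#'   `feature_id`, `direction` (`gained`/`lost`), `intervals`
#'   (`chrom:start-end` joined by `;`, on the isoform carrying the
#'   feature).
#' @export
featureGainLoss <- function(x, features, kind = c("domain", "mirna_site"),
                            referenceMode = c("longest_coding", "major"),
                            se = NULL, genes = NULL) {
    kind <- match.arg(kind)
    referenceMode <- match.arg(referenceMode)
    features <- as.data.frame(features)
    unknown <- setdiff(features$transcript_id, transcriptIds(x))
    if (length(unknown))
        stop("features on unknown transcripts: ",
             paste(unique(unknown), collapse = ", "))
    td <- x@txData
    if (is.null(genes)) genes <- geneIds(x)
    ## per transcript: feature id -> merged genomic interval string
    featsOf <- function(tx) {
        rows <- features[features$transcript_id == tx, , drop = FALSE]
        if (!nrow(rows)) return(list())
        out <- list()
        for (i in seq_len(nrow(rows))) {
            gr <- .featureGenomic(x, rows[i, ], kind)
            id <- if (kind == "domain") rows$accession[i]
                  else sprintf("%s@%s:%d-%d", rows$mirna_id[i],
                               as.character(seqnames(gr))[1L],
                               min(start(gr)), max(end(gr)))
            iv <- .fmtIntervals(as.character(seqnames(gr))[1L], ranges(gr))
            if (is.null(out[[id]])) out[[id]] <- iv
        }
        out
    }
    recs <- list()
    for (g in genes) {
        txs <- sort(td$transcript_id[td$gene_id == g])
        if (length(txs) < 2L) next
        ref <- selectReferenceIsoform(x, g, referenceMode, se)
        if (is.na(ref)) next
        fr <- featsOf(ref)
        for (alt in setdiff(txs, ref)) {
            fa <- featsOf(alt)
            for (id in setdiff(names(fa), names(fr)))
                recs[[length(recs) + 1L]] <- data.frame(
                    gene_id = g, reference_mode = referenceMode,
                    reference_transcript_id = ref, alt_transcript_id = alt,
                    feature_kind = kind, feature_id = id,
                    direction = "gained", intervals = fa[[id]])
            for (id in setdiff(names(fr), names(fa)))
                recs[[length(recs) + 1L]] <- data.frame(
                    gene_id = g, reference_mode = referenceMode,
                    reference_transcript_id = ref, alt_transcript_id = alt,
                    feature_kind = kind, feature_id = id,
                    direction = "lost", intervals = fr[[id]])
        }
    }
    if (!length(recs))
        return(data.frame(gene_id = character(), reference_mode = character(),
                          reference_transcript_id = character(),
                          alt_transcript_id = character(),
                          feature_kind = character(), feature_id = character(),
                          direction = character(), intervals = character()))
    do.call(rbind, recs)
}

#' Attribute feature changes to splicing events
#'
#' An event explains a change when (i) its interval overlaps (>= 1 bp) a
#' genomic interval of the changed feature and (ii) the event separates the
#' alternative isoform from the reference (one is in the event's inclusion
#' set and the other in its exclusion set). Overlap alone over-attributes:
#' an event shared by both isoforms cannot cause a difference between them.
#'
#' @param changes data.frame from [featureGainLoss()].
#' @param events event `GRanges` from [classifyASEvents()].
#' @return `changes` with an `attributed_events` column (event ids joined
#'   by `;`, empty string when nothing is attributable).
#' @export
attributeChangesToEvents <- function(changes, events) {
    if (!nrow(changes)) {
        changes$attributed_events <- character(0)
        return(changes)
    }
    evGene <- events$gene_id
    incl <- strsplit(events$inclusion, ",", fixed = TRUE)
    excl <- strsplit(events$exclusion, ",", fixed = TRUE)
    changes$attributed_events <- vapply(seq_len(nrow(changes)), function(i) {
        iv <- .parseIntervals(changes$intervals[i])
        cand <- which(evGene == changes$gene_id[i])
        if (!length(cand)) return("")
        hits <- cand[vapply(cand, function(e) {
            ov <- any(as.character(seqnames(events))[e] == iv$chrom &
                      start(events)[e] <= iv$end &
                      end(events)[e] >= iv$start)
            if (!ov) return(FALSE)
            a <- changes$alt_transcript_id[i]
            r <- changes$reference_transcript_id[i]
            (a %in% incl[[e]] && r %in% excl[[e]]) ||
                (a %in% excl[[e]] && r %in% incl[[e]])
        }, logical(1))]
        paste(sort(events$event_id[hits]), collapse = ";")
    }, character(1))
    changes
}

#' Gene-level summary of feature changes
#'
#' Counts, per feature kind and reference mode, the genes whose isoforms
#' only gained, only lost, or both gained and lost features, and the
#' overlap of changed-gene sets between the two reference modes.
#'
#' @param changes data.frame from [featureGainLoss()] (both reference
#'   modes may be rbind-ed together).
#' @return list with `by_class` (kind, mode, direction_class, n_genes) and
#'   `mode_overlap` (kind, n_longest, n_major, n_overlap).
#' @export
consequenceSummary <- function(changes) {
    byClass <- NULL
    for (k in unique(changes$feature_kind)) {
        for (m in unique(changes$reference_mode)) {
            sub <- changes[changes$feature_kind == k &
                           changes$reference_mode == m, , drop = FALSE]
            if (!nrow(sub)) next
            gained <- unique(sub$gene_id[sub$direction == "gained"])
            lost <- unique(sub$gene_id[sub$direction == "lost"])
            both <- intersect(gained, lost)
            byClass <- rbind(byClass, data.frame(
                feature_kind = k, reference_mode = m,
                direction_class = c("gained_only", "lost_only", "both"),
                n_genes = c(length(setdiff(gained, both)),
                            length(setdiff(lost, both)), length(both))))
        }
    }
    overlap <- NULL
    for (k in unique(changes$feature_kind)) {
        gl <- unique(changes$gene_id[changes$feature_kind == k &
                                     changes$reference_mode ==
                                     "longest_coding"])
        gm <- unique(changes$gene_id[changes$feature_kind == k &
                                     changes$reference_mode == "major"])
        overlap <- rbind(overlap, data.frame(
            feature_kind = k, n_longest = length(gl), n_major = length(gm),
            n_overlap = length(intersect(gl, gm))))
    }
    list(by_class = byClass, mode_overlap = overlap)
}
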