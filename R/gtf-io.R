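#' Read a transcript annotation from GTF
#'
#' Parses a GTF (2.2 dialect, `gene_id` / `transcript_id` attributes) into a
#' [TranscriptModels-class] object. Only `exon` and `CDS` features are used;
#' `gene` / `transcript` container lines are ignored. Transcripts without
#' exons and unstranded records are rejected: the classifier's donor and
#' acceptor labels are strand-dependent.
#'
#' @param path path to a GTF file.
#' @return a [TranscriptModels-class] object.
#' @seealso [writeGtf()]
#' @export
readGtf <- function(path) {
    if (!file.exists(path)) stop("GTF file not found: ", path)
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                   error = function(e)
                       stop("GTF parse error in '", path, "': ",
                            conditionMessage(e)))
    gr <- gr[gr$type %in% c("exon", "CDS")]
    if (!length(gr)) stop("no exon records in ", path)
    if (any(is.na(gr$transcript_id)) || any(is.na(gr$gene_id)))
        stop("exon/CDS records must carry gene_id and transcript_id")
    if (any(strand(gr) == "*"))
        stop("unstranded exon records are not supported")
    ex <- gr[gr$type == "exon"]
    exl <- split(granges(ex), ex$transcript_id)
    txg <- unique(data.frame(transcript_id = gr$transcript_id,
                             gene_id = gr$gene_id))
    if (anyDuplicated(txg$transcript_id))
        stop("transcript assigned to more than one gene_id")
    noex <- setdiff(txg$transcript_id, names(exl))
    if (length(noex))
        stop("transcripts without exons: ", paste(noex, collapse = ", "))
    cd <- gr[gr$type == "CDS"]
    cdl <- if (length(cd)) split(granges(cd), cd$transcript_id) else NULL
    mod <- TranscriptModels(exl, txg, cdl)
    .checkModelGeometry(mod)
    mod
}

## exons disjoint with >= 1 nt introns, CDS inside exons, shared gene strand
.checkModelGeometry <- function(x) {
    ex <- x@exons
    ok_gap <- vapply(seq_along(ex), function(i) {
        g <- ex[[i]]
        length(g) < 2L || all(start(g)[-1L] > end(g)[-length(g)] + 1L)
    }, logical(1))
    if (!all(ok_gap))
        stop("overlapping or abutting exons in transcript(s): ",
             paste(names(ex)[!ok_gap], collapse = ", "))
    has_cds <- lengths(x@cds) > 0L
    for (i in which(has_cds)) {
        hit <- IRanges::findOverlaps(ranges(x@cds[[i]]), ranges(ex[[i]]),
                                     type = "within")
        if (length(unique(S4Vectors::queryHits(hit))) != length(x@cds[[i]]))
            stop("CDS outside exons in transcript ",
                 x@txData$transcript_id[i])
    }
    gstr <- tapply(
        vapply(seq_along(ex),
               function(i) as.character(strand(ex[[i]])[1L]), ""),
        x@txData$gene_id, function(s) length(unique(s)))
    if (any(gstr > 1L)) stop("isoforms of one gene on different strands")
    gchr <- tapply(
        vapply(seq_along(ex),
               function(i) as.character(seqnames(ex[[i]])[1L]), ""),
        x@txData$gene_id, function(s) length(unique(s)))
    if (any(gchr > 1L)) stop("isoforms of one gene on different chromosomes")
    invisible(TRUE)
}

#' Write a transcript annotation to GTF
#'
#' Emits `exon` (and `CDS` where present) records with 1-based inclusive
#' coordinates and `gene_id` followed by `transcript_id` attributes. Exon
#' lines are written in ascending start order regardless of strand, the
#' usual GTF convention. `readGtf(writeGtf(x))` is coordinate-identical.
#'
#' @param x a [TranscriptModels-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(x, path) {
    fmt <- function(grl, genes, txs, type) {
        g <- unlist(grl, use.names = FALSE)
        n <- lengths(grl)
        data.frame(chrom = as.character(seqnames(g)),
                   source = "PopSplice", type = type,
                   start = start(g), end = end(g), score = ".",
                   strand = as.character(strand(g)), frame = ".",
                   attr = sprintf('gene_id "%s"; transcript_id "%s";',
                                  rep(genes, n), rep(txs, n)))
    }
    df <- fmt(x@exons, x@txData$gene_id, x@txData$transcript_id, "exon")
    keep <- lengths(x@cds) > 0L
    if (any(keep))
        df <- rbind(df, fmt(x@cds[keep], x@txData$gene_id[keep],
                            x@txData$transcript_id[keep], "CDS"))
    df <- df[order(df$chrom, df$start, df$end, df$type, df$attr), ]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(df$chrom, df$source, df$type, df$start, df$end,
                     df$score, df$strand, df$frame, df$attr, sep = "\t"),
               con)
    invisible(path)
}
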