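#' Splice junctions of transcript isoforms
#'
#' A junction is the intron excised between two consecutive exons, identified
#' by (chrom, strand, first intronic base, last intronic base). An isoform
#' with k exons contributes k - 1 junctions; single-exon isoforms none.
#'
#' @param x a [TranscriptModels-class] object.
#' @param transcripts optional character vector restricting to these ids.
#' @return a `GRanges` of introns with mcols `transcript_id`, `gene_id` and
#'   `junction_id` (`chrom:strand:start-end`).
#' @examples
#' # exons 1-100 and 201-300 yield the junction 101-200
#' @export
extractJunctions <- function(x, transcripts = NULL) {
    ids <- transcriptIds(x)
    if (!is.null(transcripts)) ids <- intersect(ids, transcripts)
    ex <- x@exons[ids]
    gene <- x@txData$gene_id[match(ids, x@txData$transcript_id)]
    parts <- lapply(seq_along(ex), function(i) {
        g <- ex[[i]]
        k <- length(g)
        if (k < 2L) return(NULL)
        data.frame(chrom = as.character(seqnames(g))[1L],
                   strand = as.character(strand(g))[1L],
                   start = end(g)[-k] + 1L, end = start(g)[-1L] - 1L,
                   transcript_id = ids[i], gene_id = gene[i])
    })
    df <- do.call(rbind, parts)
    if (is.null(df))
        return(GRanges(junction_id = character(), transcript_id = character(),
                       gene_id = character()))
    GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
            junction_id = .junctionId(df$chrom, df$strand, df$start, df$end),
            transcript_id = df$transcript_id, gene_id = df$gene_id)
}

.junctionId <- function(chrom, strand, start, end)
    sprintf("%s:%s:%d-%d", chrom, strand, as.integer(start), as.integer(end))

## intron matrix (start,end) of an exon matrix sorted by start
.juncMat <- function(m) {
    k <- nrow(m)
    if (k < 2L) return(matrix(integer(), 0L, 2L))
    cbind(m[-k, 2L] + 1L, m[-1L, 1L] - 1L, deparse.level = 0L)
}

.ovl <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

## all pairwise events between two isoforms; A, B are exon matrices
## (columns start, end; rows ascending). Returns a list of records
## list(type, start, end, junc = 2-col matrix, inclFirst = A is the
## inclusion isoform).
.pairEvents <- function(A, B, strand) {
    ev <- list()
    add <- function(type, s, e, junc, inclFirst)
        ev[[length(ev) + 1L]] <<- list(type = type, start = s, end = e,
                                       junc = junc, inclFirst = inclFirst)
    JA <- .juncMat(A); JB <- .juncMat(B)
    ## retained intron: junction in one isoform, a single exon of the other
    ## fully contains [start-1, end+1]
    for (dir in 1:2) {
        JX <- if (dir == 1L) JA else JB
        Y <- if (dir == 1L) B else A
        if (nrow(JX)) for (j in seq_len(nrow(JX))) {
            if (any(Y[, 1L] <= JX[j, 1L] - 1L & Y[, 2L] >= JX[j, 2L] + 1L))
                add("RI", JX[j, 1L], JX[j, 2L], JX[j, , drop = FALSE],
                    inclFirst = (dir == 2L))
        }
    }
    ## skipped exon: internal exon with both flanking junctions in one
    ## isoform, single spanning junction in the other
    for (dir in 1:2) {
        X <- if (dir == 1L) A else B
        JY <- if (dir == 1L) JB else JA
        kX <- nrow(X)
        if (kX >= 3L && nrow(JY)) for (i in 2:(kX - 1L)) {
            j1 <- c(X[i - 1L, 2L] + 1L, X[i, 1L] - 1L)
            j2 <- c(X[i, 2L] + 1L, X[i + 1L, 1L] - 1L)
            if (any(JY[, 1L] == j1[1L] & JY[, 2L] == j2[2L]))
                add("SE", X[i, 1L], X[i, 2L],
                    rbind(j1, j2, c(j1[1L], j2[2L]), deparse.level = 0L),
                    inclFirst = (dir == 1L))
        }
    }
    ## alternative donor/acceptor: junction pairs sharing one coordinate,
    ## with the exons flanking the differing coordinate overlapping each
    ## other (this separates A5/A3 from alternative terminal exons)
    if (nrow(JA) && nrow(JB)) for (a in seq_len(nrow(JA))) {
        for (b in seq_len(nrow(JB))) {
            ja <- JA[a, ]; jb <- JB[b, ]
            if (ja[1L] == jb[1L] && ja[2L] != jb[2L]) {
                ## shared left (intron start), differing right (intron end)
                fa <- A[A[, 1L] == ja[2L] + 1L, , drop = FALSE]
                fb <- B[B[, 1L] == jb[2L] + 1L, , drop = FALSE]
                if (nrow(fa) && nrow(fb) &&
                    .ovl(fa[1L, 1L], fa[1L, 2L], fb[1L, 1L], fb[1L, 2L])) {
                    type <- if (strand == "+") "A3" else "A5"
                    add(type, min(ja[2L], jb[2L]) + 1L, max(ja[2L], jb[2L]),
                        rbind(ja, jb, deparse.level = 0L),
                        inclFirst = ja[2L] < jb[2L])
                }
            } else if (ja[2L] == jb[2L] && ja[1L] != jb[1L]) {
                ## shared right, differing left
                fa <- A[A[, 2L] == ja[1L] - 1L, , drop = FALSE]
                fb <- B[B[, 2L] == jb[1L] - 1L, , drop = FALSE]
                if (nrow(fa) && nrow(fb) &&
                    .ovl(fa[1L, 1L], fa[1L, 2L], fb[1L, 1L], fb[1L, 2L])) {
                    type <- if (strand == "+") "A5" else "A3"
                    add(type, min(ja[1L], jb[1L]), max(ja[1L], jb[1L]) - 1L,
                        rbind(ja, jb, deparse.level = 0L),
                        inclFirst = ja[1L] > jb[1L])
                }
            }
        }
    }
    ## alternative terminal exons: mutually non-overlapping terminal exons
    ## that splice into a shared body (>= 1 shared junction, and the exon
    ## next to each terminal exon overlaps the partner isoform)
    if (nrow(A) >= 2L && nrow(B) >= 2L && nrow(JA) && nrow(JB)) {
        shared <- any(paste(JA[, 1L], JA[, 2L]) %in%
                      paste(JB[, 1L], JB[, 2L]))
        if (shared) {
            kA <- nrow(A); kB <- nrow(B)
            noX <- function(e, M) !any(.ovl(e[1L], e[2L], M[, 1L], M[, 2L]))
            ## left terminal exons
            eA <- A[1L, ]; eB <- B[1L, ]
            if (noX(eA, B) && noX(eB, A) &&
                any(.ovl(A[2L, 1L], A[2L, 2L], B[, 1L], B[, 2L])) &&
                any(.ovl(B[2L, 1L], B[2L, 2L], A[, 1L], A[, 2L])))
                add("AE", min(eA[1L], eB[1L]), max(eA[2L], eB[2L]),
                    rbind(JA[1L, ], JB[1L, ], deparse.level = 0L),
                    inclFirst = eA[1L] < eB[1L])
            ## right terminal exons
            eA <- A[kA, ]; eB <- B[kB, ]
            if (noX(eA, B) && noX(eB, A) &&
                any(.ovl(A[kA - 1L, 1L], A[kA - 1L, 2L], B[, 1L], B[, 2L])) &&
                any(.ovl(B[kB - 1L, 1L], B[kB - 1L, 2L], A[, 1L], A[, 2L])))
                add("AE", min(eA[1L], eB[1L]), max(eA[2L], eB[2L]),
                    rbind(JA[nrow(JA), ], JB[nrow(JB), ], deparse.level = 0L),
                    inclFirst = eA[2L] > eB[2L])
        }
    }
    ev
}

.juncString <- function(junc) {
    junc <- unique(junc)
    o <- order(junc[, 1L], junc[, 2L])
    paste(sprintf("%d-%d", junc[o, 1L], junc[o, 2L]), collapse = ";")
}

#' Classify alternative splicing events within genes
#'
#' Compares every pair of isoforms of each gene and reports the five event
#' types: retained intron (RI), skipped exon (SE), alternative 3' acceptor
#' (A3), alternative 5' donor (A5) and alternative terminal exon (AE).
#' Donor/acceptor labels are strand-aware (the donor is the intron end
#' nearer the transcript 5' end). Events are deduplicated across isoform
#' pairs by (type, interval, junction set); the isoforms on either side of
#' each event are accumulated in `inclusion` (interval exonic / proximal
#' variant) and `exclusion`.
#'
#' @param x a [TranscriptModels-class] object.
#' @param genes optional character vector of gene ids to classify.
#' @return a `GRanges` (the event interval) with mcols `event_id`,
#'   `gene_id`, `event_type`, `junctions` (sorted `start-end` pairs joined
#'   by `;`), `inclusion`, `exclusion` (comma-separated transcript ids).
#'   Single-isoform genes contribute nothing.
#' @export
classifyASEvents <- function(x, genes = NULL) {
    if (is.null(genes)) genes <- geneIds(x)
    td <- x@txData
    recs <- list()
    for (g in genes) {
        txs <- td$transcript_id[td$gene_id == g]
        if (length(txs) < 2L) next
        mats <- lapply(txs, function(tx) {
            gr <- x@exons[[tx]]
            cbind(start(gr), end(gr), deparse.level = 0L)
        })
        gr1 <- x@exons[[txs[1L]]]
        chrom <- as.character(seqnames(gr1))[1L]
        strand <- as.character(strand(gr1))[1L]
        bucket <- new.env(parent = emptyenv())
        for (i in seq_len(length(txs) - 1L)) for (j in (i + 1L):length(txs)) {
            evs <- .pairEvents(mats[[i]], mats[[j]], strand)
            for (e in evs) {
                js <- .juncString(e$junc)
                key <- paste(e$type, e$start, e$end, js, sep = "|")
                incl <- if (e$inclFirst) txs[i] else txs[j]
                excl <- if (e$inclFirst) txs[j] else txs[i]
                cur <- bucket[[key]]
                if (is.null(cur))
                    bucket[[key]] <- list(type = e$type, start = e$start,
                                          end = e$end, junctions = js,
                                          incl = incl, excl = excl)
                else {
                    cur$incl <- union(cur$incl, incl)
                    cur$excl <- union(cur$excl, excl)
                    bucket[[key]] <- cur
                }
            }
        }
        for (key in ls(bucket)) {
            e <- bucket[[key]]
            recs[[length(recs) + 1L]] <- data.frame(
                chrom = chrom, strand = strand, start = e$start, end = e$end,
                gene_id = g, event_type = e$type, junctions = e$junctions,
                inclusion = paste(sort(e$incl), collapse = ","),
                exclusion = paste(sort(e$excl), collapse = ","))
        }
    }
    df <- do.call(rbind, recs)
    if (is.null(df))
        return(GRanges(event_id = character(), gene_id = character(),
                       event_type = character(), junctions = character(),
                       inclusion = character(), exclusion = character()))
    df <- df[order(df$chrom, df$start, df$end, df$event_type, df$junctions), ]
    GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
            event_id = paste(df$gene_id, df$event_type, df$start, df$end,
                             df$junctions, sep = "|"),
            gene_id = df$gene_id, event_type = df$event_type,
            junctions = df$junctions, inclusion = df$inclusion,
            exclusion = df$exclusion)
}

## expand the junctions mcol of an event GRanges into per-event keys
.eventJunctionKeys <- function(events) {
    chrom <- as.character(seqnames(events))
    strand <- as.character(strand(events))
    lapply(seq_along(events), function(i) {
        parts <- strsplit(events$junctions[i], ";", fixed = TRUE)[[1L]]
        se <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
        .junctionId(chrom[i], strand[i],
                    as.integer(se[, 1L]), as.integer(se[, 2L]))
    })
}

#' Junction read-support filter
#'
#' A junction is supported when its spanning-read count reaches `minReads`
#' in at least one sample (`mode = "any"`, the default post-merge rule), or
#' in every sample (`mode = "all"`). Events whose defining junctions all
#' fail are dropped. Retained-intron events are exempt: an RI isoform has no
#' junction at the retained intron, so RI support is governed by
#' [filterRICoverage()] instead. Junctions absent from the count table count
#' as zero.
#'
#' @param events event `GRanges` from [classifyASEvents()].
#' @param junctionCounts data.frame with columns `chrom`, `strand`,
#'   `intron_start`, `intron_end`, `sample`, `reads`.
#' @param minReads minimum spanning reads (default 2).
#' @param mode `"any"` (max over samples) or `"all"` (every sample).
#' @return the retained subset of `events`.
#' @export
filterJunctionSupport <- function(events, junctionCounts, minReads = 2,
                                  mode = c("any", "all")) {
    mode <- match.arg(mode)
    if (minReads <= 0 || length(events) == 0L) return(events)
    stopifnot(all(junctionCounts$reads >= 0))
    key <- .junctionId(junctionCounts$chrom, junctionCounts$strand,
                       junctionCounts$intron_start,
                       junctionCounts$intron_end)
    stat <- if (mode == "any") tapply(junctionCounts$reads, key, max)
            else tapply(junctionCounts$reads, key, min)
    evKeys <- .eventJunctionKeys(events)
    keep <- vapply(seq_along(events), function(i) {
        if (events$event_type[i] == "RI") return(TRUE)
        s <- stat[evKeys[[i]]]
        s[is.na(s)] <- 0
        any(s >= minReads)
    }, logical(1))
    events[keep]
}

#' Retained-intron coverage filter
#'
#' A retained-intron event is kept when the median per-base read depth over
#' the retained intron reaches `minMedian` in at least one sample. Positions
#' missing from the coverage table count as depth zero. Events of other
#' types pass through unchanged.
#'
#' @param events event `GRanges` from [classifyASEvents()].
#' @param coverage data.frame with columns `chrom`, `pos`, `sample`,
#'   `depth`, giving per-base depth over (at least) the RI intervals.
#' @param minMedian minimum median depth (default 2).
#' @return the retained subset of `events`.
#' @export
filterRICoverage <- function(events, coverage, minMedian = 2) {
    if (minMedian <= 0 || length(events) == 0L) return(events)
    isRI <- events$event_type == "RI"
    if (!any(isRI)) return(events)
    if (any(width(events)[isRI] < 1L)) stop("empty retained-intron interval")
    cov <- coverage
    keepRI <- vapply(which(isRI), function(i) {
        chrom <- as.character(seqnames(events))[i]
        s <- start(events)[i]; e <- end(events)[i]
        len <- e - s + 1L
        sub <- cov[cov$chrom == chrom & cov$pos >= s & cov$pos <= e, ,
                   drop = FALSE]
        if (!nrow(sub)) return(FALSE)
        meds <- vapply(split(sub$depth, sub$sample), function(d)
            stats::median(c(d, rep(0, len - length(d)))), numeric(1))
        any(meds >= minMedian)
    }, logical(1))
    keep <- rep(TRUE, length(events))
    keep[which(isRI)] <- keepRI
    events[keep]
}

#' Genomic context of point loci
#'
#' Classifies positions as exonic (inside any exon of any isoform), intronic
#' (inside a gene span but not exonic) or intergenic, with precedence
#' exon > intron > intergenic. Positions on chromosomes absent from the
#' annotation are intergenic.
#'
#' @param chrom,pos character / integer vectors of equal length.
#' @param x a [TranscriptModels-class] object.
#' @return factor with levels `exon`, `intron`, `intergenic`.
#' @export
snpContext <- function(chrom, pos, x) {
    stopifnot(length(chrom) == length(pos), all(pos >= 1))
    q <- GRanges(chrom, IRanges(pos, pos))
    ex <- reduce(unlist(x@exons, use.names = FALSE), ignore.strand = TRUE)
    sp <- geneSpans(x)
    ans <- rep("intergenic", length(q))
    ans[suppressWarnings(overlapsAny(q, sp, ignore.strand = TRUE))] <- "intron"
    ans[suppressWarnings(overlapsAny(q, ex, ignore.strand = TRUE))] <- "exon"
    factor(ans, levels = c("exon", "intron", "intergenic"))
}
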