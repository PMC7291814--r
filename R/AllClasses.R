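#' @import methods GenomicRanges SummarizedExperiment
#' @importFrom S4Vectors DataFrame endoapply runValue queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom stats setNames
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Transcript model container
#'
#' Holds the exon (and optionally CDS) structure of every transcript isoform
#' in an annotation set, together with the transcript-to-gene map. Coordinates
#' are 1-based inclusive genomic intervals, as in GTF. All isoforms of a gene
#' must share a chromosome and strand, and every transcript must be stranded:
#' alternative donor/acceptor labels are meaningless without strand.
#'
#' @slot exons a \linkS4class{GRangesList}, one element per transcript,
#'   exons sorted by start coordinate and non-overlapping.
#' @slot cds a \linkS4class{GRangesList} keyed like \code{exons}; empty
#'   elements mark non-coding isoforms. Each CDS piece must lie inside an
#'   exon of the same transcript.
#' @slot txData a \code{DataFrame} with columns \code{transcript_id} and
#'   \code{gene_id}, one row per transcript, aligned with \code{exons}.
#'
#' @seealso [readGtf()], [classifyASEvents()], [extractJunctions()]
#' @export
setClass("TranscriptModels",
    slots = c(exons = "GRangesList", cds = "GRangesList", txData = "DataFrame"))

setValidity("TranscriptModels", function(object) {
    msg <- character()
    n <- length(object@exons)
    if (length(object@cds) != n)
        msg <- c(msg, "exons and cds must have the same length")
    if (nrow(object@txData) != n)
        msg <- c(msg, "txData must have one row per transcript")
    if (!all(c("transcript_id", "gene_id") %in% colnames(object@txData)))
        msg <- c(msg, "txData needs transcript_id and gene_id columns")
    else {
        ids <- object@txData$transcript_id
        if (anyDuplicated(ids))
            msg <- c(msg, "duplicated transcript_id")
        if (!identical(names(object@exons), ids))
            msg <- c(msg, "names(exons) must equal txData$transcript_id")
    }
    if (n > 0L) {
        st <- unlist(runValue(strand(object@exons)), use.names = FALSE)
        if (any(st == "*"))
            msg <- c(msg, "unstranded transcripts are not allowed")
        nex <- lengths(object@exons)
        if (any(nex == 0L))
            msg <- c(msg, "transcripts without exons are not allowed")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TranscriptModels object
#'
#' @param exons `GRangesList` of exons, one element per transcript, named by
#'   transcript id.
#' @param txGene data.frame with columns `transcript_id`, `gene_id`.
#' @param cds optional `GRangesList` of CDS pieces keyed like `exons`;
#'   transcripts absent from it are treated as non-coding.
#' @return a [TranscriptModels-class] object.
#' @export
TranscriptModels <- function(exons, txGene, cds = NULL) {
    txGene <- as.data.frame(txGene)
    ord <- order(txGene$gene_id, txGene$transcript_id)
    txGene <- txGene[ord, , drop = FALSE]
    exons <- exons[txGene$transcript_id]
    exons <- endoapply(exons, function(gr) sort(gr, ignore.strand = TRUE))
    if (is.null(cds)) {
        cds <- GRangesList(lapply(seq_along(exons), function(i) GRanges()))
    } else {
        miss <- setdiff(txGene$transcript_id, names(cds))
        if (length(miss)) {
            empty <- GRangesList(lapply(miss, function(i) GRanges()))
            names(empty) <- miss
            cds <- c(cds, empty)
        }
        cds <- cds[txGene$transcript_id]
        cds <- endoapply(cds, function(gr) sort(gr, ignore.strand = TRUE))
    }
    names(cds) <- names(exons)
    new("TranscriptModels", exons = exons, cds = cds,
        txData = DataFrame(transcript_id = txGene$transcript_id,
                           gene_id = txGene$gene_id))
}

#' @describeIn TranscriptModels-class number of transcripts
#' @param x,object a `TranscriptModels` object
#' @export
setMethod("length", "TranscriptModels", function(x) length(x@exons))

setMethod("show", "TranscriptModels", function(object) {
    cat("TranscriptModels with", length(object), "transcripts in",
        length(unique(object@txData$gene_id)), "genes\n")
    ncod <- sum(lengths(object@cds) > 0L)
    cat("  coding isoforms:", ncod, "\n")
})

#' Accessors for TranscriptModels
#'
#' `exonsByTx()` and `cdsByTx()` return the exon / CDS structure as a
#' `GRangesList` keyed by transcript id; `txData()` the transcript-to-gene
#' map; `transcriptIds()` and `geneIds()` the id vectors; `geneSpans()` a
#' `GRanges` with one range per gene covering every exon of its isoforms.
#'
#' @param x a [TranscriptModels-class] object
#' @return see the individual descriptions.
#' @export
exonsByTx <- function(x) x@exons

#' @rdname exonsByTx
#' @export
cdsByTx <- function(x) x@cds

#' @rdname exonsByTx
#' @export
txData <- function(x) x@txData

#' @rdname exonsByTx
#' @export
transcriptIds <- function(x) x@txData$transcript_id

#' @rdname exonsByTx
#' @export
geneIds <- function(x) unique(x@txData$gene_id)

#' @rdname exonsByTx
#' @export
geneSpans <- function(x) {
    ugr <- unlist(x@exons, use.names = FALSE)
    gene <- rep(x@txData$gene_id, lengths(x@exons))
    spl <- split(ugr, gene)
    ans <- unlist(range(spl, ignore.strand = FALSE))
    ans[geneIds(x)]
}

#' Population splicing expression container
#'
#' A thin \linkS4class{SummarizedExperiment} subclass for isoform x sample
#' FPKM matrices from a replicated row-column study design. The single assay
#' is named \code{"fpkm"} (non-negative), \code{rowData} carries
#' \code{transcript_id} and \code{gene_id}, and \code{colData} carries the
#' sample design: \code{individual}, \code{replicate}, \code{row},
#' \code{column}, \code{experiment}.
#'
#' @export
setClass("SpliceExperiment", contains = "SummarizedExperiment")

setValidity("SpliceExperiment", function(object) {
    msg <- character()
    if (!"fpkm" %in% assayNames(object))
        msg <- c(msg, "assay 'fpkm' is required")
    else if (any(assay(object, "fpkm") < 0, na.rm = TRUE))
        msg <- c(msg, "FPKM values must be non-negative")
    need <- c("individual", "replicate", "row", "column", "experiment")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste("missing colData columns:",
                            paste(miss, collapse = ", ")))
    else {
        key <- paste(colData(object)$individual, colData(object)$replicate)
        if (anyDuplicated(key))
            msg <- c(msg, "(individual, replicate) pairs must be unique")
    }
    if (!all(c("transcript_id", "gene_id") %in% colnames(rowData(object))))
        msg <- c(msg, "rowData needs transcript_id and gene_id")
    if (length(msg)) msg else TRUE
})

#' Construct a SpliceExperiment
#'
#' @param fpkm numeric matrix, transcripts x samples, rownames = transcript
#'   ids, colnames = sample ids.
#' @param design data.frame keyed by `sample_id` with columns `individual`,
#'   `replicate`, `row`, `column`, `experiment`.
#' @param txGene data.frame mapping `transcript_id` to `gene_id`.
#' @return a [SpliceExperiment-class].
#' @export
SpliceExperiment <- function(fpkm, design, txGene) {
    design <- as.data.frame(design)
    if (!is.null(design$sample_id)) rownames(design) <- design$sample_id
    design <- design[colnames(fpkm), , drop = FALSE]
    txGene <- as.data.frame(txGene)
    rownames(txGene) <- txGene$transcript_id
    rd <- DataFrame(txGene[rownames(fpkm), c("transcript_id", "gene_id")])
    se <- SummarizedExperiment(assays = list(fpkm = fpkm),
                               rowData = rd, colData = DataFrame(design))
    new("SpliceExperiment", se)
}

#' @describeIn SpliceExperiment-class the sample design table
#' @param x a `SpliceExperiment`
#' @export
sampleDesign <- function(x) as.data.frame(colData(x))

#' @describeIn SpliceExperiment-class the FPKM assay matrix
#' @export
fpkm <- function(x) assay(x, "fpkm")

#' Genotype matrix container
#'
#' Additive-coded genotype calls (minor-allele counts 0/1/2, NA = missing)
#' for a SNP panel, with the SNP map and optional per-call sequencing depth
#' and genotype quality matrices used by [filterSnps()].
#'
#' @slot calls integer matrix, SNPs x individuals, values 0/1/2/NA.
#' @slot map `DataFrame` with columns `snp_id`, `chrom`, `pos` aligned with
#'   the rows of `calls`.
#' @slot depth,gq numeric matrices shaped like `calls`, or NULL.
#' @export
setClass("GenotypeData",
    slots = c(calls = "matrix", map = "DataFrame",
              depth = "matrixOrNULL", gq = "matrixOrNULL"))

setValidity("GenotypeData", function(object) {
    msg <- character()
    v <- object@calls
    if (!all(v %in% c(0L, 1L, 2L, NA)))
        msg <- c(msg, "calls must be 0, 1, 2 or NA")
    if (nrow(object@map) != nrow(v))
        msg <- c(msg, "map must have one row per SNP")
    if (!all(c("snp_id", "chrom", "pos") %in% colnames(object@map)))
        msg <- c(msg, "map needs snp_id, chrom, pos")
    else if (any(object@map$pos < 1))
        msg <- c(msg, "positions must be >= 1")
    for (sl in c("depth", "gq")) {
        m <- slot(object, sl)
        if (!is.null(m) && !identical(dim(m), dim(v)))
            msg <- c(msg, paste(sl, "must match the dimensions of calls"))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param calls SNP x individual matrix of minor-allele counts (0/1/2, NA).
#' @param map data.frame with `snp_id`, `chrom`, `pos`.
#' @param depth,gq optional matrices of per-call depth / genotype quality.
#' @return a [GenotypeData-class].
#' @export
GenotypeData <- function(calls, map, depth = NULL, gq = NULL) {
    storage.mode(calls) <- "integer"
    map <- DataFrame(as.data.frame(map))
    rownames(calls) <- map$snp_id
    new("GenotypeData", calls = calls, map = map, depth = depth, gq = gq)
}

setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", nrow(object@calls), "SNPs x",
        ncol(object@calls), "individuals\n")
    cat("  missing calls:",
        sprintf("%.2f%%", 100 * mean(is.na(object@calls))), "\n")
})

#' @describeIn GenotypeData-class the call matrix
#' @param x a `GenotypeData`
#' @export
genotypeCalls <- function(x) x@calls

#' @rdname GenotypeData-class
#' @export
snpMap <- function(x) as.data.frame(x@map)

#' @describeIn TranscriptModels-class number of SNPs / transcripts
#' @export
setMethod("length", "GenotypeData", function(x) nrow(x@calls))
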