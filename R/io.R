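#' @importFrom data.table fread fwrite
NULL

.checkCols <- function(df, need, what) {
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
    invisible(df)
}

#' Read an isoform FPKM matrix with its sample metadata
#'
#' @param exprPath TSV with a `transcript_id` first column and one column
#'   per sample.
#' @param samplesPath TSV with `sample_id`, `individual`, `replicate`,
#'   `row`, `column`, `experiment`.
#' @param models a [TranscriptModels-class] supplying the transcript-to-
#'   gene map.
#' @return a [SpliceExperiment-class].
#' @export
readExpressionMatrix <- function(exprPath, samplesPath, models) {
    ex <- as.data.frame(fread(exprPath))
    .checkCols(ex, "transcript_id", "expression matrix")
    m <- as.matrix(ex[, -1, drop = FALSE])
    rownames(m) <- ex$transcript_id
    samples <- as.data.frame(fread(samplesPath))
    .checkCols(samples, c("sample_id", "individual", "replicate", "row",
                          "column", "experiment"), "sample metadata")
    SpliceExperiment(m, samples, as.data.frame(txData(models)))
}

#' Read junction-count / gene-count / coverage / feature tables
#'
#' Thin validated readers for the plain-TSV interchange formats used by
#' the pipeline: junction spanning-read counts, per-gene read counts,
#' per-base coverage, domain annotations (Pfam-scan-like layout) and miRNA
#' site annotations.
#'
#' @param path TSV file path.
#' @return a data.frame.
#' @export
readJunctionCounts <- function(path)
    .checkCols(as.data.frame(fread(path)),
               c("chrom", "strand", "intron_start", "intron_end", "gene_id",
                 "sample", "reads"), "junction counts")

#' @rdname readJunctionCounts
#' @export
readGeneCounts <- function(path)
    .checkCols(as.data.frame(fread(path)),
               c("gene_id", "sample", "reads"), "gene counts")

#' @rdname readJunctionCounts
#' @export
readCoverage <- function(path)
    .checkCols(as.data.frame(fread(path)),
               c("chrom", "pos", "sample", "depth"), "coverage")

#' @rdname readJunctionCounts
#' @export
readDomainTable <- function(path)
    .checkCols(as.data.frame(fread(path)),
               c("transcript_id", "accession", "pep_start", "pep_end"),
               "domain table")

#' @rdname readJunctionCounts
#' @export
readMirnaTable <- function(path)
    .checkCols(as.data.frame(fread(path)),
               c("transcript_id", "mirna_id", "tx_start", "tx_end"),
               "miRNA site table")

#' Write genotypes as a minimal VCF
#'
#' Emits a plain-text VCFv4.2 with GT:DP:GQ per call (alleles A/G, the ALT
#' allele being the counted minor allele). Readable by [readVcfGenotypes()].
#'
#' @param g a [GenotypeData-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(g, path) {
    calls <- genotypeCalls(g)
    map <- snpMap(g)
    gtStr <- matrix("./.", nrow(calls), ncol(calls))
    gtStr[calls == 0L] <- "0/0"
    gtStr[calls == 1L] <- "0/1"
    gtStr[calls == 2L] <- "1/1"
    dp <- if (is.null(g@depth)) matrix(".", nrow(calls), ncol(calls))
          else format(g@depth, trim = TRUE)
    gq <- if (is.null(g@gq)) matrix(".", nrow(calls), ncol(calls))
          else format(g@gq, trim = TRUE)
    body <- matrix(paste(gtStr, dp, gq, sep = ":"),
                   nrow(calls), ncol(calls))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
                 "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", colnames(calls)),
                       collapse = "\t")), con)
    lines <- apply(cbind(map$chrom, map$pos, map$snp_id, "A", "G", ".",
                         "PASS", ".", "GT:DP:GQ", body), 1L,
                   paste, collapse = "\t")
    writeLines(lines, con)
    invisible(path)
}

#' Write a synthetic study to disk
#'
#' Emits every input file of the pipeline -- GTF, VCF, expression and
#' sample-metadata TSV, junction and gene read-count TSV, RI coverage TSV,
#' domain and miRNA TSV -- plus the ground truth as JSON. Every file
#' parses with the package's own readers.
#'
#' @param study output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    writeGtf(study$models, p("transcriptome.gtf"))
    writeVcfGenotypes(study$genotypes, p("genotypes.vcf"))
    m <- fpkm(study$expression)
    fwrite(data.frame(transcript_id = rownames(m), m,
                      check.names = FALSE),
           p("expression.tsv"), sep = "\t")
    fwrite(study$design, p("samples.tsv"), sep = "\t")
    fwrite(study$junctionCounts, p("junction_counts.tsv"), sep = "\t")
    fwrite(study$geneCounts, p("gene_counts.tsv"), sep = "\t")
    fwrite(study$riCoverage, p("ri_coverage.tsv"), sep = "\t")
    fwrite(study$domains, p("domains.tsv"), sep = "\t")
    fwrite(study$mirnaSites, p("mirna_sites.tsv"), sep = "\t")
    truth <- study$truth
    jsonlite::write_json(truth, p("ground_truth.json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(dir)
}

.headerLines <- function(cfg, extra = character()) {
    c(sprintf("# PopSplice %s",
              as.character(utils::packageVersion("PopSplice"))),
      sprintf("# seed=%d", cfg$seed),
      sprintf(paste0("# thresholds: fpkm=%g min_replicates=%d ",
                     "min_individuals=%d junction_min_reads=%g ",
                     "ri_min_median=%g hwe_alpha=%g maf_min=%g ",
                     "depth_min=%g gq_min=%g missing_max=%g cis_window=%g ",
                     "fdr_target=%g sqtl_nonzero_frac=%g n_perm_h2=%d ",
                     "n_perm_fdr=%d alpha_h2=%g"),
              cfg$fpkm, cfg$min_replicates, cfg$min_individuals,
              cfg$junction_min_reads, cfg$ri_min_median, cfg$hwe_alpha,
              cfg$maf_min, cfg$depth_min, cfg$gq_min, cfg$missing_max,
              cfg$cis_window, cfg$fdr_target, cfg$sqtl_nonzero_frac,
              cfg$n_perm_h2, cfg$n_perm_fdr, cfg$alpha_h2),
      extra)
}

.writeResult <- function(df, path, cfg, extra = character()) {
    con <- file(path, "w")
    writeLines(.headerLines(cfg, extra), con)
    close(con)
    fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
    invisible(path)
}
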