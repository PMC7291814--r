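#' Pipeline configuration
#'
#' Assembles the threshold set of the full analysis with the standard
#' defaults: isoform presence at FPKM >= 3 in >= 2 replicates and >= 3
#' individuals; junctions supported by >= 2 reads; retained introns by
#' median coverage >= 2; SNP filters HWE p >= 0.01, MAF >= 0.05, mean
#' depth >= 8, mean GQ >= 20, missingness <= 0.75; 1 Mb cis window; 5%
#' empirical FDR; sQTL junctions with usage > 0 in >= 5% of individuals.
#' The heritability permutation count defaults to 1000 (pooled null);
#' 10000 per-trait permutations give the most stable thresholds when
#' runtime allows.
#'
#' @param seed root seed for every random stage.
#' @param outDir output directory for the result tables.
#' @param synthetic generate inputs with [simulateStudy()] (TRUE) or read
#'   them from `inputs`.
#' @param simulation named list of overrides passed to
#'   [simulationConfig()] when `synthetic` is TRUE.
#' @param inputs named list of file paths (`gtf`, `vcf`, `expression`,
#'   `samples`, `junction_counts`, `gene_counts`, `ri_coverage`,
#'   `domains`, `mirna_sites`) when `synthetic` is FALSE.
#' @param fpkm,min_replicates,min_individuals presence/expression filter.
#' @param junction_min_reads,ri_min_median junction/RI support filters.
#' @param hwe_alpha,maf_min,depth_min,gq_min,missing_max SNP filters.
#' @param cis_window,fdr_target,sqtl_nonzero_frac QTL scan settings.
#' @param n_perm_h2,alpha_h2,h2_null_mode heritability permutation null.
#' @param n_perm_fdr phenotype permutations for the empirical FDR.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1, outDir = "popsplice-results",
                           synthetic = TRUE, simulation = list(),
                           inputs = list(),
                           fpkm = 3, min_replicates = 2L,
                           min_individuals = 3L, junction_min_reads = 2,
                           ri_min_median = 2, hwe_alpha = 0.01,
                           maf_min = 0.05, depth_min = 8, gq_min = 20,
                           missing_max = 0.75, cis_window = 1e6,
                           fdr_target = 0.05, sqtl_nonzero_frac = 0.05,
                           n_perm_h2 = 1000L, alpha_h2 = 0.01,
                           h2_null_mode = "pooled", n_perm_fdr = 10L) {
    cfg <- as.list(environment())
    stopifnot(fpkm >= 0, min_replicates >= 1, min_individuals >= 0,
              hwe_alpha >= 0, hwe_alpha <= 1, maf_min >= 0, maf_min <= 0.5,
              missing_max >= 0, missing_max <= 1, cis_window >= 0,
              fdr_target > 0, fdr_target <= 1, n_perm_h2 >= 1,
              n_perm_fdr >= 1)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override the [pipelineConfig()] defaults; a `simulation`
#' mapping overrides [simulationConfig()] fields.
#'
#' @param path YAML file.
#' @return list of class `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(pipelineConfig, y)
}

.stage <- function(log, name, nIn, nOut) {
    message(sprintf("[%s] in=%d out=%d", name, nIn, nOut))
    rbind(log, data.frame(stage = name, n_in = nIn, n_out = nOut))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- transcriptome and event
#' classification with junction/RI support filters, presence/absence and
#' expression filtering, major-isoform statistics and gene-feature
#' correlations, heritability with permutation null, domain/miRNA
#' gain-loss with event attribution, SNP filtering, iso-eQTL and sQTL
#' scans with empirical FDR and cis/trans classification, and the
#' regulated-gene summary. Each result table is written under
#' `cfg$outDir` with a header recording version, seed and thresholds.
#' Reruns with the same configuration are byte-identical.
#'
#' @param cfg a [pipelineConfig()] list (or path to a YAML accepted by
#'   [readPipelineConfig()]).
#' @return invisibly, a list with every intermediate result and the stage
#'   log.
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
    if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    log <- NULL
    ## ---- inputs
    if (isTRUE(cfg$synthetic)) {
        simCfg <- do.call(simulationConfig,
                          utils::modifyList(list(seed = cfg$seed),
                                            cfg$simulation))
        study <- simulateStudy(simCfg)
    } else {
        req <- c("gtf", "expression", "samples", "junction_counts",
                 "gene_counts")
        miss <- setdiff(req, names(cfg$inputs))
        if (length(miss))
            stop("input stage: missing input file entries: ",
                 paste(miss, collapse = ", "))
        for (f in unlist(cfg$inputs)) if (!file.exists(f))
            stop("input stage: file not found: ", f)
        models <- readGtf(cfg$inputs$gtf)
        study <- list(
            models = models,
            genotypes = if (!is.null(cfg$inputs$vcf))
                readVcfGenotypes(cfg$inputs$vcf) else NULL,
            expression = readExpressionMatrix(cfg$inputs$expression,
                                              cfg$inputs$samples, models),
            junctionCounts = readJunctionCounts(
                cfg$inputs$junction_counts),
            geneCounts = readGeneCounts(cfg$inputs$gene_counts),
            riCoverage = if (!is.null(cfg$inputs$ri_coverage))
                readCoverage(cfg$inputs$ri_coverage) else NULL,
            domains = if (!is.null(cfg$inputs$domains))
                readDomainTable(cfg$inputs$domains) else NULL,
            mirnaSites = if (!is.null(cfg$inputs$mirna_sites))
                readMirnaTable(cfg$inputs$mirna_sites) else NULL,
            design = NULL, truth = NULL)
        study$design <- as.data.frame(colData(study$expression))
        study$design$sample_id <- rownames(study$design)
    }
    models <- study$models
    se <- study$expression
    design <- study$design
    ## ---- event classification and support filters
    events <- classifyASEvents(models)
    ev <- filterJunctionSupport(events, study$junctionCounts,
                                cfg$junction_min_reads)
    if (!is.null(study$riCoverage))
        ev <- filterRICoverage(ev, study$riCoverage, cfg$ri_min_median)
    log <- .stage(log, "classify_events", length(events), length(ev))
    evDf <- data.frame(event_id = ev$event_id, gene_id = ev$gene_id,
                       event_type = ev$event_type,
                       chrom = as.character(seqnames(ev)),
                       strand = as.character(strand(ev)),
                       event_start = start(ev), event_end = end(ev),
                       junctions = ev$junctions,
                       inclusion_isoforms = ev$inclusion,
                       exclusion_isoforms = ev$exclusion)
    .writeResult(evDf, file.path(cfg$outDir, "as_events.tsv"), cfg)
    ## ---- presence / expression filter / major isoform
    presence <- presenceCalls(se, cfg$fpkm, cfg$min_replicates)
    retained <- populationExpressionFilter(presence, cfg$min_individuals)
    log <- .stage(log, "expression_filter", nrow(presence),
                  length(retained))
    pav <- pavSummary(presence)
    maj <- majorIsoformFrequency(se)
    corr <- geneFeatureCorrelations(models, se)
    .writeResult(data.frame(transcript_id = retained),
                 file.path(cfg$outDir, "retained_isoforms.tsv"), cfg)
    .writeResult(pav, file.path(cfg$outDir, "pav_histogram.tsv"), cfg)
    .writeResult(maj, file.path(cfg$outDir, "major_isoform.tsv"), cfg)
    .writeResult(corr,
                 file.path(cfg$outDir, "gene_feature_correlations.tsv"),
                 cfg)
    ## ---- heritability
    traits <- fpkm(se)[retained, , drop = FALSE]
    herit <- estimateHeritability(traits, design, nPerm = cfg$n_perm_h2,
                                  alpha = cfg$alpha_h2,
                                  nullMode = cfg$h2_null_mode,
                                  seed = cfg$seed + 100L)
    log <- .stage(log, "heritability", nrow(herit), sum(herit$heritable))
    .writeResult(herit, file.path(cfg$outDir, "heritability.tsv"), cfg,
                 sprintf("# h2_null_mode=%s", cfg$h2_null_mode))
    ## ---- functional consequences
    changes <- NULL
    if (!is.null(study$domains) && nrow(study$domains))
        for (mode in c("longest_coding", "major"))
            changes <- rbind(changes,
                             featureGainLoss(models, study$domains,
                                             "domain", mode, se))
    if (!is.null(study$mirnaSites) && nrow(study$mirnaSites))
        for (mode in c("longest_coding", "major"))
            changes <- rbind(changes,
                             featureGainLoss(models, study$mirnaSites,
                                             "mirna_site", mode, se))
    if (!is.null(changes) && nrow(changes)) {
        changes <- attributeChangesToEvents(changes, ev)
        csum <- consequenceSummary(changes)
        .writeResult(changes,
                     file.path(cfg$outDir, "feature_changes.tsv"), cfg)
        .writeResult(csum$by_class,
                     file.path(cfg$outDir, "consequence_summary.tsv"), cfg)
        .writeResult(csum$mode_overlap,
                     file.path(cfg$outDir, "consequence_overlap.tsv"), cfg)
        log <- .stage(log, "consequences", nrow(changes),
                      nrow(csum$by_class))
    }
    ## ---- QTL mapping
    isoEqtl <- NULL; sqtl <- NULL
    if (!is.null(study$genotypes)) {
        snps <- filterSnps(study$genotypes, cfg$hwe_alpha, cfg$maf_min,
                           cfg$depth_min, cfg$gq_min, cfg$missing_max)
        log <- .stage(log, "filter_snps", length(study$genotypes),
                      length(snps))
        td <- as.data.frame(txData(models))
        multi <- names(which(table(td$gene_id) >= 2L))
        herTx <- intersect(heritableSet(herit, herit),
                           td$transcript_id[td$gene_id %in% multi])
        indMeans <- individualMeans(se)
        spans <- geneSpans(models)
        map <- snpMap(snps)
        if (length(herTx)) {
            phen <- indMeans[herTx, , drop = FALSE]
            isoEqtl <- mapQtl(phen, snps, cfg$fdr_target, cfg$n_perm_fdr,
                              seed = cfg$seed + 200L)
            txLoc <- data.frame(
                trait_id = transcriptIds(models),
                chrom = vapply(exonsByTx(models), function(g)
                    as.character(seqnames(g))[1L], ""),
                start = vapply(exonsByTx(models), function(g)
                    min(start(g)), numeric(1)),
                end = vapply(exonsByTx(models), function(g)
                    max(end(g)), numeric(1)))
            isoEqtl <- classifyCisTrans(isoEqtl, txLoc, map,
                                        cfg$cis_window)
            if (nrow(isoEqtl))
                isoEqtl$snp_context <- as.character(snpContext(
                    map$chrom[match(isoEqtl$snp_id, map$snp_id)],
                    map$pos[match(isoEqtl$snp_id, map$snp_id)], models))
            log <- .stage(log, "iso_eqtl", length(herTx), nrow(isoEqtl))
            .writeResult(isoEqtl, file.path(cfg$outDir, "iso_eqtl.tsv"),
                         cfg)
        }
        ## splice-junction usage QTL
        ju <- junctionUsage(study$junctionCounts, study$geneCounts,
                            design)
        keepJ <- sqtlJunctionFilter(ju$usage, ev, cfg$sqtl_nonzero_frac)
        if (length(keepJ)) {
            u <- ju$usage[keepJ, , drop = FALSE]
            if (anyNA(u)) {  # individuals with no informative replicate
                rm <- rowMeans(u, na.rm = TRUE)
                idx <- which(is.na(u))
                u[idx] <- rm[(idx - 1L) %% nrow(u) + 1L]
            }
            sqtl <- mapQtl(u, snps, cfg$fdr_target, cfg$n_perm_fdr,
                           seed = cfg$seed + 300L)
            jLoc <- data.frame(
                trait_id = ju$junctions$junction_id,
                chrom = as.character(seqnames(spans))[
                    match(ju$junctions$gene_id, names(spans))],
                start = start(spans)[match(ju$junctions$gene_id,
                                           names(spans))],
                end = end(spans)[match(ju$junctions$gene_id,
                                       names(spans))])
            sqtl <- classifyCisTrans(sqtl, jLoc, map, cfg$cis_window)
            log <- .stage(log, "sqtl", length(keepJ), nrow(sqtl))
            .writeResult(sqtl, file.path(cfg$outDir, "sqtl.tsv"), cfg)
            ## regulated-gene summary (Table-1-style)
            jGene <- setNames(ju$junctions$gene_id,
                              ju$junctions$junction_id)
            herCount <- table(factor(
                td$gene_id[td$transcript_id %in% heritableSet(herit,
                                                              herit)],
                levels = geneIds(models)))
            herCount <- setNames(as.numeric(herCount), geneIds(models))
            snpGene <- rep(NA_character_, nrow(map))
            hit <- suppressWarnings(GenomicRanges::findOverlaps(
                GRanges(map$chrom, IRanges(map$pos, map$pos)), spans,
                ignore.strand = TRUE))
            snpGene[S4Vectors::queryHits(hit)] <-
                names(spans)[S4Vectors::subjectHits(hit)]
            names(snpGene) <- map$snp_id
            classes <- list(
                cis_regulated = unique(jGene[
                    sqtl$trait_id[sqtl$regulation %in% "cis"]]),
                trans_regulated = unique(jGene[
                    sqtl$trait_id[sqtl$regulation %in% "trans"]]),
                cis_regulator = unique(stats::na.omit(snpGene[
                    sqtl$snp_id[sqtl$regulation %in% "cis"]])),
                trans_regulator = unique(stats::na.omit(snpGene[
                    sqtl$snp_id[sqtl$regulation %in% "trans"]])))
            regSum <- regulatedGeneSummary(classes, herCount)
            .writeResult(regSum,
                         file.path(cfg$outDir,
                                   "regulated_gene_summary.tsv"), cfg)
        }
    }
    .writeResult(log, file.path(cfg$outDir, "stage_log.tsv"), cfg)
    invisible(list(config = cfg, study = study, events = events,
                   filteredEvents = ev, presence = presence,
                   retained = retained, pav = pav, majorIsoform = maj,
                   correlations = corr, heritability = herit,
                   changes = changes, isoEqtl = isoEqtl, sqtl = sqtl,
                   log = log))
}
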