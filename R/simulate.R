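#' Configuration of a synthetic splicing study
#'
#' Collects every knob of the synthetic-study generator with defaults that
#' define the desk-scale preset: 50 individuals with 3 clonal replicates in
#' a row-column greenhouse layout, 200 genes, 500 SNPs. Event-type
#' proportions follow the ordering typical of plant transcriptomes
#' (retained introns most frequent, skipped exons least). Expression is
#' log-normal FPKM built from genotype, row, column and residual variance
#' components plus planted cis/trans QTL effects.
#'
#' @param nIndividuals,nReplicates,nGenes,nSnps study dimensions.
#' @param nChromosomes chromosomes over which genes and SNPs are placed.
#' @param nExperiments experiments (fixed effect); row/column factors are
#'   nested within experiment.
#' @param isoformNumberProbs probabilities of a gene carrying 1, 2, 3, ...
#'   isoforms.
#' @param eventMix named proportions over RI, A3, A5, AE, SE used when
#'   drawing the event realized by each extra isoform.
#' @param mafRange minor-allele-frequency range of well-behaved SNPs.
#' @param meanDepth,meanGq,missingRate sequencing-quality parameters of
#'   well-behaved SNPs.
#' @param badSnpFraction fraction of SNPs deliberately failing one of the
#'   five marker filters (split evenly across failure classes, recorded in
#'   the ground truth).
#' @param sigma2_r,sigma2_c,sigma2_e row, column and residual variances of
#'   log-expression.
#' @param sigma2_g prior of the genotype variance: a point mass at zero
#'   with probability `zero_prob`, otherwise Gamma(`shape`, `scale`).
#' @param nCisQtl,nTransQtl,qtlR2 planted isoform-expression QTL: counts
#'   and fraction of trait variance explained.
#' @param nSqtl,sqtlEffect planted junction-usage QTL: count and logit-
#'   scale effect per standardized allele.
#' @param readScale expected gene read count per FPKM unit.
#' @param domainChangeProb,mirnaChangeProb per AS gene, probability of
#'   planting a protein-domain / miRNA-site change straddling one of its
#'   events.
#' @param seed mandatory integer root seed.
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nIndividuals = 50, nReplicates = 3,
                             nGenes = 200, nSnps = 500, nChromosomes = 5,
                             nExperiments = 1,
                             isoformNumberProbs = c(0.35, 0.40, 0.20, 0.05),
                             eventMix = c(RI = 0.30, A3 = 0.24, A5 = 0.20,
                                          AE = 0.15, SE = 0.11),
                             mafRange = c(0.05, 0.5), meanDepth = 20,
                             meanGq = 60, missingRate = 0.02,
                             badSnpFraction = 0.10,
                             sigma2_r = 0.25, sigma2_c = 0.25, sigma2_e = 1,
                             sigma2_g = list(zero_prob = 0.3, shape = 2,
                                             scale = 0.5),
                             nCisQtl = 10, nTransQtl = 10, qtlR2 = 0.3,
                             nSqtl = 8, sqtlEffect = 1.5, readScale = 30,
                             domainChangeProb = 0.5, mirnaChangeProb = 0.5,
                             seed = 1) {
    cfg <- as.list(environment())
    stopifnot(nIndividuals >= 2, nReplicates >= 1, nGenes >= 1, nSnps >= 1,
              !is.null(seed), abs(sum(eventMix) - 1) < 1e-8,
              all(sort(names(eventMix)) == c("A3", "A5", "AE", "RI", "SE")),
              qtlR2 > 0, qtlR2 < 1)
    class(cfg) <- "SimulationConfig"
    cfg
}

## edit kinds realizing each event type, resolved by gene strand:
## shifting an exon's right edge moves the intron donor on '+' (A5) and
## the acceptor on '-' (A3); shifting a left edge is the mirror case.
.editFor <- function(type, strand) {
    switch(type,
           RI = "merge", SE = "skip", AE = "alt_first",
           A5 = if (strand == "+") "shift_right_of_exon" else
                                   "shift_left_of_exon",
           A3 = if (strand == "+") "shift_left_of_exon" else
                                   "shift_right_of_exon")
}

#' Generate a synthetic transcriptome with planted splicing events
#'
#' Builds gene models in which every extra isoform realizes exactly one
#' planted event of a requested type through an explicit exon-structure
#' edit (intron merged for RI, internal exon dropped for SE, splice-site
#' boundary shifted for A5/A3, first exon replaced by a non-overlapping
#' upstream exon for AE). Edits of one gene touch disjoint exons, so the
#' planted list is the complete event set of the gene. A CDS is assigned to
#' every isoform long enough to carry one.
#'
#' @param cfg a [simulationConfig()] list.
#' @return list with `models` (a [TranscriptModels-class]), `truthEvents`
#'   (data.frame: gene_id, event_type, chrom, strand, start, end,
#'   junctions, inclusion, exclusion) and `chromLengths`.
#' @export
generateTranscriptome <- function(cfg) {
    .withSeed(cfg$seed + 11L, .generateTranscriptome(cfg))
}

.generateTranscriptome <- function(cfg) {
    cursor <- rep(1000L, cfg$nChromosomes)
    exl <- list(); cdl <- list(); txg <- list(); truth <- list()
    for (g in seq_len(cfg$nGenes)) {
        gid <- sprintf("G%04d", g)
        ci <- ((g - 1L) %% cfg$nChromosomes) + 1L
        chrom <- paste0("chr", ci)
        strand <- sample(c("+", "-"), 1L)
        k <- sample(4:8, 1L)
        wid <- sample(60:240, k, replace = TRUE)
        gaps <- sample(80:400, k - 1L, replace = TRUE)
        gStart <- cursor[ci] + 400L          # margin for upstream alt exon
        starts <- integer(k); ends <- integer(k)
        pos <- gStart
        for (i in seq_len(k)) {
            starts[i] <- pos
            ends[i] <- pos + wid[i] - 1L
            pos <- ends[i] + 1L + if (i < k) gaps[i] else 0L
        }
        cursor[ci] <- ends[k] + sample(500:1500, 1L)
        nIso <- sample(seq_along(cfg$isoformNumberProbs), 1L,
                       prob = cfg$isoformNumberProbs)
        nEv <- nIso - 1L
        base <- cbind(starts, ends, deparse.level = 0L)
        mats <- list(base)
        usedEx <- integer(0)                 # exon indices already edited
        usedJn <- integer(0)                 # junction indices already edited
        evTypes <- if (nEv > 0L)
            sample(names(cfg$eventMix), nEv, replace = TRUE,
                   prob = cfg$eventMix) else character(0)
        for (type in evTypes) {
            edit <- .editFor(type, strand)
            ## each edit's footprint: the exons it reshapes and the
            ## junctions it creates/destroys; footprints of one gene's
            ## edits must be disjoint so the planted list is complete
            exOf <- function(i) switch(edit,
                merge = c(i, i + 1L), skip = i, alt_first = 1L,
                shift_right_of_exon = i, shift_left_of_exon = i + 1L)
            jnOf <- function(i) switch(edit,
                merge = i, skip = c(i - 1L, i), alt_first = 1L,
                shift_right_of_exon = i, shift_left_of_exon = i)
            cand <- switch(edit,
                merge = seq_len(k - 1L),
                skip = if (k >= 3L) 2:(k - 1L) else integer(0),
                alt_first = if (k >= 3L) 1L else integer(0),
                shift_right_of_exon = seq_len(k - 1L),
                shift_left_of_exon = seq_len(k - 1L))
            cand <- cand[vapply(cand, function(i)
                !any(exOf(i) %in% usedEx) && !any(jnOf(i) %in% usedJn),
                logical(1))]
            if (!length(cand)) next
            slot <- sample(rep(cand, 2L), 1L)[1L]
            usedEx <- c(usedEx, exOf(slot))
            usedJn <- c(usedJn, jnOf(slot))
            alt <- base
            tid_alt <- sprintf("%s.%d", gid, length(mats) + 1L)
            tid_base <- sprintf("%s.1", gid)
            if (edit == "merge") {
                i <- slot
                alt <- rbind(base[seq_len(i - 1L), , drop = FALSE],
                             c(base[i, 1L], base[i + 1L, 2L]),
                             base[seq_len(k)[-seq_len(i + 1L)], ,
                                  drop = FALSE])
                js <- base[i, 2L] + 1L; je <- base[i + 1L, 1L] - 1L
                truth[[length(truth) + 1L]] <- data.frame(
                    gene_id = gid, event_type = "RI", chrom = chrom,
                    strand = strand, start = js, end = je,
                    junctions = sprintf("%d-%d", js, je),
                    inclusion = tid_alt, exclusion = tid_base)
            } else if (edit == "skip") {
                i <- slot
                alt <- base[-i, , drop = FALSE]
                j1 <- c(base[i - 1L, 2L] + 1L, base[i, 1L] - 1L)
                j2 <- c(base[i, 2L] + 1L, base[i + 1L, 1L] - 1L)
                jset <- rbind(j1, j2, c(j1[1L], j2[2L]))
                truth[[length(truth) + 1L]] <- data.frame(
                    gene_id = gid, event_type = "SE", chrom = chrom,
                    strand = strand, start = base[i, 1L], end = base[i, 2L],
                    junctions = .juncString(jset),
                    inclusion = tid_base, exclusion = tid_alt)
            } else if (edit == "shift_right_of_exon") {
                i <- slot  # shorten exon i from the right
                d <- sample(15:min(40L, base[i, 2L] - base[i, 1L] - 19L), 1L)
                alt[i, 2L] <- base[i, 2L] - d
                jA <- c(base[i, 2L] + 1L, base[i + 1L, 1L] - 1L)
                jB <- c(alt[i, 2L] + 1L, base[i + 1L, 1L] - 1L)
                truth[[length(truth) + 1L]] <- data.frame(
                    gene_id = gid, event_type = type, chrom = chrom,
                    strand = strand, start = alt[i, 2L] + 1L,
                    end = base[i, 2L],
                    junctions = .juncString(rbind(jA, jB)),
                    inclusion = tid_base, exclusion = tid_alt)
            } else if (edit == "shift_left_of_exon") {
                i <- slot  # shorten exon i+1 from the left
                d <- sample(15:min(40L, base[i + 1L, 2L] -
                                        base[i + 1L, 1L] - 19L), 1L)
                alt[i + 1L, 1L] <- base[i + 1L, 1L] + d
                jA <- c(base[i, 2L] + 1L, base[i + 1L, 1L] - 1L)
                jB <- c(base[i, 2L] + 1L, alt[i + 1L, 1L] - 1L)
                truth[[length(truth) + 1L]] <- data.frame(
                    gene_id = gid, event_type = type, chrom = chrom,
                    strand = strand, start = base[i + 1L, 1L],
                    end = alt[i + 1L, 1L] - 1L,
                    junctions = .juncString(rbind(jA, jB)),
                    inclusion = tid_base, exclusion = tid_alt)
            } else if (edit == "alt_first") {
                w2 <- sample(60:160, 1L)
                gap <- sample(100:300, 1L)
                ne <- base[1L, 1L] - gap
                ns <- ne - w2 + 1L
                alt[1L, ] <- c(ns, ne)
                jA <- c(base[1L, 2L] + 1L, base[2L, 1L] - 1L)
                jB <- c(ne + 1L, base[2L, 1L] - 1L)
                truth[[length(truth) + 1L]] <- data.frame(
                    gene_id = gid, event_type = "AE", chrom = chrom,
                    strand = strand, start = ns, end = base[1L, 2L],
                    junctions = .juncString(rbind(jA, jB)),
                    inclusion = tid_alt, exclusion = tid_base)
            }
            mats[[length(mats) + 1L]] <- alt
        }
        for (m in seq_along(mats)) {
            tid <- sprintf("%s.%d", gid, m)
            exm <- mats[[m]]
            exl[[tid]] <- GRanges(chrom, IRanges(exm[, 1L], exm[, 2L]),
                                  strand = strand)
            txg[[length(txg) + 1L]] <- data.frame(transcript_id = tid,
                                                  gene_id = gid)
            L <- sum(exm[, 2L] - exm[, 1L] + 1L)
            cdsLen <- (L - 60L) %/% 3L * 3L
            if (cdsLen >= 60L) {
                ir <- .spliceToGenomic(exm, strand, 31L, 30L + cdsLen)
                cdl[[tid]] <- GRanges(chrom, ir, strand = strand)
            }
        }
    }
    models <- TranscriptModels(GRangesList(exl), do.call(rbind, txg),
                               if (length(cdl)) GRangesList(cdl) else NULL)
    truthEvents <- if (length(truth)) do.call(rbind, truth) else
        data.frame(gene_id = character(), event_type = character(),
                   chrom = character(), strand = character(),
                   start = integer(), end = integer(),
                   junctions = character(), inclusion = character(),
                   exclusion = character())
    rownames(truthEvents) <- NULL
    list(models = models, truthEvents = truthEvents,
         chromLengths = setNames(cursor + 10000L,
                                 paste0("chr", seq_len(cfg$nChromosomes))))
}

#' Generate synthetic genotypes
#'
#' Draws biallelic SNPs at Hardy-Weinberg proportions with uniform minor
#' allele frequencies, Poisson per-call depth and Gaussian genotype
#' quality, plus a configured fraction of deliberately failing SNPs (low
#' MAF, HWE violation via excess homozygosity, low depth, low GQ, high
#' missingness), labelled in the ground truth.
#'
#' @param cfg a [simulationConfig()] list.
#' @param chromLengths named chromosome lengths (from
#'   [generateTranscriptome()]).
#' @return list with `genotypes` (a [GenotypeData-class]) and `truthSnps`
#'   (data.frame snp_id, fail_class, maf).
#' @export
generateGenotypes <- function(cfg, chromLengths) {
    .withSeed(cfg$seed + 22L, .generateGenotypes(cfg, chromLengths))
}

.generateGenotypes <- function(cfg, chromLengths) {
    nS <- cfg$nSnps; nI <- cfg$nIndividuals
    inds <- sprintf("I%03d", seq_len(nI))
    chrom <- sample(names(chromLengths), nS, replace = TRUE,
                    prob = chromLengths / sum(chromLengths))
    pos <- vapply(chrom, function(ch)
        sample.int(chromLengths[[ch]], 1L), integer(1))
    ord <- order(chrom, pos)
    chrom <- chrom[ord]; pos <- pos[ord]
    ids <- sprintf("SNP%05d", seq_len(nS))
    nBad <- round(cfg$badSnpFraction * nS)
    classes <- c("low_maf", "hwe", "low_depth", "low_gq", "high_missing")
    failClass <- rep("none", nS)
    if (nBad > 0L)
        failClass[sample.int(nS, nBad)] <-
            rep_len(classes, nBad)[sample.int(nBad)]
    maf <- stats::runif(nS, cfg$mafRange[1L], cfg$mafRange[2L])
    maf[failClass == "low_maf"] <- stats::runif(sum(failClass == "low_maf"),
                                                0.002, 0.03)
    calls <- matrix(NA_integer_, nS, nI, dimnames = list(ids, inds))
    depth <- matrix(0, nS, nI, dimnames = list(ids, inds))
    gq <- matrix(0, nS, nI, dimnames = list(ids, inds))
    for (s in seq_len(nS)) {
        p <- maf[s]
        if (failClass[s] == "hwe") {
            p <- stats::runif(1L, 0.25, 0.5)
            f <- 0.9  # strong excess homozygosity
            pr <- c((1 - p)^2 + f * p * (1 - p),
                    2 * p * (1 - p) * (1 - f),
                    p^2 + f * p * (1 - p))
        } else pr <- c((1 - p)^2, 2 * p * (1 - p), p^2)
        calls[s, ] <- sample(0:2, nI, replace = TRUE, prob = pr)
        dMean <- if (failClass[s] == "low_depth")
            stats::runif(1L, 2, 5) else
            stats::runif(1L, 0.7 * cfg$meanDepth, 1.3 * cfg$meanDepth)
        depth[s, ] <- stats::rpois(nI, dMean)
        gMean <- if (failClass[s] == "low_gq")
            stats::runif(1L, 5, 12) else
            stats::runif(1L, 0.7 * cfg$meanGq, 1.2 * cfg$meanGq)
        gq[s, ] <- pmin(99, pmax(0, round(stats::rnorm(nI, gMean, 8))))
        mr <- if (failClass[s] == "high_missing")
            stats::runif(1L, 0.80, 0.95) else cfg$missingRate
        miss <- stats::runif(nI) < mr
        calls[s, miss] <- NA_integer_
    }
    g <- GenotypeData(calls,
                      data.frame(snp_id = ids, chrom = chrom, pos = pos),
                      depth = depth, gq = gq)
    list(genotypes = g,
         truthSnps = data.frame(snp_id = ids, fail_class = failClass,
                                maf = maf))
}

## row-column layout of samples within experiments
.makeDesign <- function(cfg) {
    inds <- sprintf("I%03d", seq_len(cfg$nIndividuals))
    d <- expand.grid(replicate = seq_len(cfg$nReplicates),
                     individual = inds, stringsAsFactors = FALSE)
    d <- d[, c("individual", "replicate")]
    d$sample_id <- sprintf("%s_r%d", d$individual, d$replicate)
    d$experiment <- paste0("E", rep_len(seq_len(cfg$nExperiments),
                                        cfg$nIndividuals))[
        match(d$individual, inds)]
    d$row <- NA_integer_; d$column <- NA_integer_
    for (e in unique(d$experiment)) {
        idx <- which(d$experiment == e)
        nR <- ceiling(sqrt(length(idx)))
        slots <- sample(seq_along(idx))
        d$row[idx] <- ((slots - 1L) %/% nR) + 1L
        d$column[idx] <- ((slots - 1L) %% nR) + 1L
    }
    rownames(d) <- d$sample_id
    d
}

#' Generate synthetic expression and read counts
#'
#' Draws per-isoform log-FPKM from an intercept plus experiment, genotype
#' (individual), row, column, planted-QTL and residual terms, exponentiates
#' to FPKM, and derives gene read counts (Poisson in expression) and
#' junction-spanning read counts (binomial in the gene reads with success
#' probability proportional to the junction's isoform share, shifted on the
#' logit scale for planted sQTL). Per-base coverage over retained introns
#' is emitted for a handful of samples to drive the RI support filter.
#'
#' @param cfg a [simulationConfig()] list.
#' @param transcriptome output of [generateTranscriptome()].
#' @param genotypes output of [generateGenotypes()].
#' @return list with `expression` (a [SpliceExperiment-class]), `design`,
#'   `junctionCounts`, `geneCounts`, `riCoverage` (data.frames) and
#'   `truthTraits`, `truthQtl`, `truthSqtl`.
#' @export
generateExpression <- function(cfg, transcriptome, genotypes) {
    .withSeed(cfg$seed + 33L,
              .generateExpression(cfg, transcriptome, genotypes))
}

.generateExpression <- function(cfg, transcriptome, genotypes) {
    models <- transcriptome$models
    design <- .makeDesign(cfg)
    inds <- unique(design$individual)
    nI <- length(inds); nSamp <- nrow(design)
    txs <- transcriptIds(models)
    gene <- txData(models)$gene_id
    nT <- length(txs)
    ## per-trait variance components
    sg <- ifelse(stats::runif(nT) < cfg$sigma2_g$zero_prob, 0,
                 stats::rgamma(nT, shape = cfg$sigma2_g$shape,
                               scale = cfg$sigma2_g$scale))
    mu <- stats::runif(nT, 0.5, 3)
    expEff <- stats::rnorm(cfg$nExperiments, 0, 0.5)
    names(expEff) <- paste0("E", seq_len(cfg$nExperiments))
    rowLev <- unique(paste(design$experiment, design$row, sep = ":"))
    colLev <- unique(paste(design$experiment, design$column, sep = ":"))
    indIdx <- match(design$individual, inds)
    rowIdx <- match(paste(design$experiment, design$row, sep = ":"), rowLev)
    colIdx <- match(paste(design$experiment, design$column, sep = ":"),
                    colLev)
    expIdx <- design$experiment
    ## planted expression QTL on AS-gene isoforms where possible
    calls <- genotypeCalls(genotypes)
    smap <- snpMap(genotypes)
    spans <- geneSpans(models)
    geneChrom <- as.character(seqnames(spans))
    names(geneChrom) <- names(spans)
    gStart <- setNames(start(spans), names(spans))
    gEnd <- setNames(end(spans), names(spans))
    nQtl <- cfg$nCisQtl + cfg$nTransQtl
    qtlTraits <- if (nQtl > 0L) sample(txs, min(nQtl, nT)) else character(0)
    truthQtl <- NULL
    qtlEffect <- matrix(0, nT, nI)          # individual-level QTL term
    zOf <- function(snpRow) {
        z <- calls[snpRow, inds]
        z[is.na(z)] <- mean(z, na.rm = TRUE)
        if (stats::sd(z) == 0) return(NULL)
        as.numeric(scale(z)[, 1L])
    }
    for (qi in seq_along(qtlTraits)) {
        tx <- qtlTraits[qi]
        gId <- gene[match(tx, txs)]
        wantCis <- qi <= cfg$nCisQtl
        if (wantCis) {
            cand <- which(smap$chrom == geneChrom[gId] &
                          smap$pos >= gStart[gId] - 5e5 &
                          smap$pos <= gEnd[gId] + 5e5)
        } else {
            cand <- which(smap$chrom != geneChrom[gId])
        }
        if (!length(cand)) next
        snpRow <- sample(rep(cand, 2L), 1L)[1L]
        z <- zOf(snpRow)
        if (is.null(z)) next
        i <- match(tx, txs)
        baseVar <- sg[i] + cfg$sigma2_r + cfg$sigma2_c + cfg$sigma2_e
        beta <- sqrt(cfg$qtlR2 / (1 - cfg$qtlR2) * baseVar)
        qtlEffect[i, ] <- beta * z
        truthQtl <- rbind(truthQtl, data.frame(
            snp_id = smap$snp_id[snpRow], trait_id = tx, gene_id = gId,
            beta = beta, r2 = cfg$qtlR2,
            regulation = if (wantCis) "cis" else "trans"))
    }
    ## sample-level matrix
    y <- matrix(0, nT, nSamp, dimnames = list(txs, design$sample_id))
    uG <- matrix(stats::rnorm(nT * nI), nT, nI) * sqrt(sg)
    uR <- matrix(stats::rnorm(nT * length(rowLev)), nT) *
        sqrt(cfg$sigma2_r)
    uC <- matrix(stats::rnorm(nT * length(colLev)), nT) *
        sqrt(cfg$sigma2_c)
    eps <- matrix(stats::rnorm(nT * nSamp), nT, nSamp) *
        sqrt(cfg$sigma2_e)
    y <- mu + uG[, indIdx, drop = FALSE] + qtlEffect[, indIdx, drop = FALSE] +
        uR[, rowIdx, drop = FALSE] + uC[, colIdx, drop = FALSE] +
        matrix(expEff[expIdx], nT, nSamp, byrow = TRUE) + eps
    dimnames(y) <- list(txs, design$sample_id)
    fpkmMat <- exp(y)
    se <- SpliceExperiment(fpkmMat, design,
                           data.frame(transcript_id = txs, gene_id = gene))
    gvar <- sg + vapply(seq_len(nT), function(i)
        if (any(qtlEffect[i, ] != 0)) stats::var(qtlEffect[i, ]) else 0,
        numeric(1))
    truthTraits <- data.frame(
        trait_id = txs, gene_id = gene, sigma2_g = sg,
        sigma2_r = cfg$sigma2_r, sigma2_c = cfg$sigma2_c,
        sigma2_e = cfg$sigma2_e,
        h2 = gvar / (gvar + cfg$sigma2_r + cfg$sigma2_c + cfg$sigma2_e))
    ## read counts
    juncGr <- extractJunctions(models)
    jdf <- data.frame(chrom = as.character(seqnames(juncGr)),
                      strand = as.character(strand(juncGr)),
                      intron_start = start(juncGr), end = end(juncGr),
                      transcript_id = juncGr$transcript_id,
                      gene_id = juncGr$gene_id,
                      junction_id = juncGr$junction_id)
    names(jdf)[names(jdf) == "end"] <- "intron_end"
    ujunc <- unique(jdf[, c("chrom", "strand", "intron_start", "intron_end",
                            "gene_id", "junction_id")])
    geneFpkm <- rowsum(fpkmMat, gene)
    geneReads <- matrix(stats::rpois(length(geneFpkm),
                                     cfg$readScale * geneFpkm),
                        nrow(geneFpkm), ncol(geneFpkm),
                        dimnames = dimnames(geneFpkm))
    ## planted sQTL on event-linked junctions
    evj <- unique(unlist(lapply(seq_len(nrow(transcriptome$truthEvents)),
        function(i) {
            tr <- transcriptome$truthEvents[i, ]
            parts <- strsplit(tr$junctions, ";", fixed = TRUE)[[1L]]
            se2 <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
            .junctionId(tr$chrom, tr$strand, as.integer(se2[, 1L]),
                        as.integer(se2[, 2L]))
        })))
    sqtlJ <- intersect(ujunc$junction_id, evj)
    sqtlJ <- if (length(sqtlJ) && cfg$nSqtl > 0L)
        sample(sqtlJ, min(cfg$nSqtl, length(sqtlJ))) else character(0)
    truthSqtl <- NULL
    sqtlShift <- matrix(0, nrow(ujunc), nI,
                        dimnames = list(ujunc$junction_id, inds))
    for (j in sqtlJ) {
        gId <- ujunc$gene_id[ujunc$junction_id == j][1L]
        half <- stats::runif(1L) < 0.5
        cand <- if (half)
            which(smap$chrom == geneChrom[gId] &
                  abs(smap$pos - gStart[gId]) < 5e5)
        else which(smap$chrom != geneChrom[gId])
        if (!length(cand)) next
        snpRow <- sample(rep(cand, 2L), 1L)[1L]
        z <- zOf(snpRow)
        if (is.null(z)) next
        sqtlShift[j, ] <- cfg$sqtlEffect * z
        truthSqtl <- rbind(truthSqtl, data.frame(
            snp_id = smap$snp_id[snpRow], junction_id = j, gene_id = gId,
            regulation = if (half) "cis" else "trans"))
    }
    ## junction reads: binomial share of gene reads
    carrierF <- rowsum(fpkmMat[jdf$transcript_id, , drop = FALSE],
                       jdf$junction_id)
    carrierF <- carrierF[ujunc$junction_id, , drop = FALSE]
    gReadsJ <- geneReads[ujunc$gene_id, , drop = FALSE]
    shareBase <- pmin(0.98, pmax(0.02,
        0.8 * carrierF / pmax(geneFpkm[ujunc$gene_id, , drop = FALSE],
                              1e-9)))
    logit <- stats::qlogis(shareBase) +
        sqtlShift[, indIdx, drop = FALSE]
    share <- stats::plogis(logit)
    jReads <- matrix(stats::rbinom(length(gReadsJ), as.vector(gReadsJ),
                                   as.vector(share)),
                     nrow(gReadsJ), ncol(gReadsJ))
    junctionCounts <- data.frame(
        chrom = rep(ujunc$chrom, nSamp),
        strand = rep(ujunc$strand, nSamp),
        intron_start = rep(ujunc$intron_start, nSamp),
        intron_end = rep(ujunc$intron_end, nSamp),
        gene_id = rep(ujunc$gene_id, nSamp),
        sample = rep(design$sample_id, each = nrow(ujunc)),
        reads = as.vector(jReads))
    geneCounts <- data.frame(
        gene_id = rep(rownames(geneReads), nSamp),
        sample = rep(design$sample_id, each = nrow(geneReads)),
        reads = as.vector(geneReads))
    ## RI per-base coverage for a few samples
    riCoverage <- NULL
    tev <- transcriptome$truthEvents
    ri <- tev[tev$event_type == "RI", , drop = FALSE]
    covSamples <- design$sample_id[seq_len(min(6L, nSamp))]
    if (nrow(ri)) {
        parts <- lapply(seq_len(nrow(ri)), function(i) {
            posv <- ri$start[i]:ri$end[i]
            carrier <- ri$inclusion[i]
            do.call(rbind, lapply(covSamples, function(s) {
                lam <- 0.5 + fpkmMat[carrier, s] / 2
                data.frame(chrom = ri$chrom[i], pos = posv, sample = s,
                           depth = stats::rpois(length(posv), lam))
            }))
        })
        riCoverage <- do.call(rbind, parts)
    } else {
        riCoverage <- data.frame(chrom = character(), pos = integer(),
                                 sample = character(), depth = integer())
    }
    list(expression = se, design = design,
         junctionCounts = junctionCounts, geneCounts = geneCounts,
         riCoverage = riCoverage, truthTraits = truthTraits,
         truthQtl = truthQtl, truthSqtl = truthSqtl)
}

## longest-CDS reference, ties by transcript length then id (generator-side
## computation, kept inline so ground truth is independent of the analysis
## functions)
.truthLongestRef <- function(models, txs) {
    cdsLen <- vapply(txs, function(t) sum(width(cdsByTx(models)[[t]])),
                     numeric(1))
    if (all(cdsLen == 0)) return(NA_character_)
    txLen <- vapply(txs, function(t) sum(width(exonsByTx(models)[[t]])),
                    numeric(1))
    o <- order(-cdsLen, -txLen, txs)
    txs[o[1L]]
}

.truthMajorRef <- function(fpkmMat, txs) {
    med <- apply(fpkmMat[txs, , drop = FALSE], 1L, stats::median)
    txs[order(-med, txs)[1L]]
}

## which side of a planted event an isoform (exon matrix) falls on:
## "incl" (interval exonic / proximal variant), "excl", or NA (isoform not
## structurally involved). Mirrors the classifier's side assignment on the
## generator's constructions.
.eventSide <- function(m, ev) {
    J <- do.call(rbind, lapply(
        strsplit(strsplit(ev$junctions, ";", fixed = TRUE)[[1L]],
                 "-", fixed = TRUE), as.integer))
    juncs <- .juncMat(m)
    has <- function(j) nrow(juncs) > 0L &&
        any(juncs[, 1L] == j[1L] & juncs[, 2L] == j[2L])
    s <- ev$start; e <- ev$end
    if (ev$event_type == "RI") {
        if (has(J[1L, ])) return("excl")
        if (any(m[, 1L] <= s - 1L & m[, 2L] >= e + 1L)) return("incl")
    } else if (ev$event_type == "SE") {
        skip <- c(min(J[, 1L]), max(J[, 2L]))
        flanks <- J[!(J[, 1L] == skip[1L] & J[, 2L] == skip[2L]), ,
                    drop = FALSE]
        if (has(skip)) return("excl")
        if (nrow(flanks) && all(apply(flanks, 1L, has)) &&
            any(m[, 1L] == s & m[, 2L] == e)) return("incl")
    } else if (ev$event_type %in% c("A3", "A5")) {
        isLong <- J[, 1L] <= s & J[, 2L] >= e
        if (any(isLong) && has(J[which(isLong)[1L], ])) return("excl")
        if (any(!isLong) && has(J[which(!isLong)[1L], ]) &&
            any(m[, 1L] <= s & m[, 2L] >= e)) return("incl")
    } else if (ev$event_type == "AE") {
        ## left-side AE: inclusion owns the leftmost terminal exon, whose
        ## junction starts earlier
        if (has(J[which.min(J[, 1L]), ])) return("incl")
        if (has(J[which.max(J[, 1L]), ])) return("excl")
    }
    NA_character_
}

#' Generate domain and miRNA-site annotations with planted changes
#'
#' Places protein domains (peptide coordinates) and miRNA binding sites
#' (transcript coordinates) on isoforms such that a configured fraction of
#' AS genes carries a feature straddling one of its planted events on
#' exactly one side of the event (guaranteeing a gain or loss with known
#' event attribution), plus isoform-invariant control features. Expected
#' gains/losses under both reference modes are recorded in the ground
#' truth.
#'
#' @param cfg a [simulationConfig()] list.
#' @param transcriptome output of [generateTranscriptome()].
#' @param expression output of [generateExpression()].
#' @return list with `domains`, `mirnaSites` (input-format data.frames)
#'   and `truthChanges` (expected [featureGainLoss()] rows with an
#'   `expected_events` column).
#' @export
generateFunctionalAnnotations <- function(cfg, transcriptome, expression) {
    .withSeed(cfg$seed + 44L,
              .generateFunctionalAnnotations(cfg, transcriptome, expression))
}

.generateFunctionalAnnotations <- function(cfg, transcriptome, expression) {
    models <- transcriptome$models
    tev <- transcriptome$truthEvents
    fpkmMat <- fpkm(expression$expression)
    td <- as.data.frame(txData(models))
    domains <- NULL; sites <- NULL; truthChanges <- NULL
    pfCounter <- 0L; miCounter <- 0L
    matOf <- function(tx) {
        gr <- exonsByTx(models)[[tx]]
        cbind(start(gr), end(gr), deparse.level = 0L)
    }
    addChangeRows <- function(gene, carrier, fid, kind, ivStr, evRow) {
        txs <- sort(td$transcript_id[td$gene_id == gene])
        refs <- c(longest_coding = .truthLongestRef(models, txs),
                  major = .truthMajorRef(fpkmMat, txs))
        rows <- NULL
        for (mode in names(refs)) {
            ref <- refs[[mode]]
            if (is.na(ref)) next
            for (alt in setdiff(txs, ref)) {
                hasAlt <- alt == carrier
                hasRef <- ref == carrier
                if (hasAlt == hasRef) next
                dirn <- if (hasAlt) "gained" else "lost"
                ## expected attribution: planted events of the gene that
                ## overlap the feature and put alt and ref on opposite
                ## sides (side derived from each isoform's own structure)
                evs <- tev[tev$gene_id == gene, , drop = FALSE]
                iv <- .parseIntervals(ivStr)
                expEv <- character(0)
                if (nrow(evs)) for (k in seq_len(nrow(evs))) {
                    ov <- any(evs$chrom[k] == iv$chrom &
                              evs$start[k] <= iv$end &
                              evs$end[k] >= iv$start)
                    if (!ov) next
                    sa <- .eventSide(matOf(alt), evs[k, ])
                    sr <- .eventSide(matOf(ref), evs[k, ])
                    disc <- !is.na(sa) && !is.na(sr) && sa != sr
                    if (disc)
                        expEv <- c(expEv, paste(evs$gene_id[k],
                                                evs$event_type[k],
                                                evs$start[k], evs$end[k],
                                                evs$junctions[k],
                                                sep = "|"))
                }
                rows <- rbind(rows, data.frame(
                    gene_id = gene, reference_mode = mode,
                    reference_transcript_id = ref, alt_transcript_id = alt,
                    feature_kind = kind, feature_id = fid, direction = dirn,
                    expected_events = paste(sort(expEv), collapse = ";")))
            }
        }
        rows
    }
    for (gene in unique(tev$gene_id)) {
        evs <- tev[tev$gene_id == gene, , drop = FALSE]
        ev <- evs[1L, ]
        carrier <- ev$inclusion        # isoform holding the event interval
        txs <- sort(td$transcript_id[td$gene_id == gene])
        ## ---- protein domain straddling the event
        if (stats::runif(1L) < cfg$domainChangeProb &&
            length(cdsByTx(models)[[carrier]]) > 0L) {
            cdsGr <- cdsByTx(models)[[carrier]]
            ovl <- IRanges::intersect(ranges(cdsGr),
                                      IRanges(ev$start, ev$end))
            if (length(ovl) && sum(width(ovl)) >= 9L) {
                gs <- min(start(ovl)); ge <- max(end(ovl))
                nt <- genomicToTranscript(models, carrier, gs, ge, "cds")
                pep1 <- ceiling(nt[1L] / 3); pep2 <- nt[2L] %/% 3
                pepLen <- sum(width(cdsGr)) %/% 3
                if (pep2 >= pep1 && pep2 <= pepLen && pep1 >= 1L) {
                    pfCounter <- pfCounter + 1L
                    acc <- sprintf("PF%05d", pfCounter)
                    domains <- rbind(domains, data.frame(
                        transcript_id = carrier, accession = acc,
                        name = paste0("dom", pfCounter),
                        pep_start = pep1, pep_end = pep2, evalue = 1e-10))
                    gr <- peptideToGenomic(models, carrier, pep1, pep2)
                    ivStr <- .fmtIntervals(
                        as.character(seqnames(gr))[1L], ranges(gr))
                    truthChanges <- rbind(truthChanges,
                        addChangeRows(gene, carrier, acc, "domain", ivStr,
                                      ev))
                }
            }
        }
        ## ---- shared (isoform-invariant) domain control on coding pair
        coding <- txs[lengths(cdsByTx(models)[txs]) > 0L]
        if (length(coding) >= 2L) {
            pfCounter <- pfCounter + 1L
            acc <- sprintf("PF%05d", pfCounter)
            for (t in coding) {
                pepLen <- sum(width(cdsByTx(models)[[t]])) %/% 3L
                p2 <- min(10L, pepLen)
                domains <- rbind(domains, data.frame(
                    transcript_id = t, accession = acc,
                    name = paste0("dom", pfCounter),
                    pep_start = 1L, pep_end = p2, evalue = 1e-8))
            }
        }
        ## ---- miRNA site straddling the event
        if (stats::runif(1L) < cfg$mirnaChangeProb) {
            exGr <- exonsByTx(models)[[carrier]]
            ovl <- IRanges::intersect(ranges(exGr),
                                      IRanges(ev$start, ev$end))
            if (length(ovl) && sum(width(ovl)) >= 15L) {
                gs <- min(start(ovl))
                ge <- min(max(end(ovl)), gs + 20L)
                nt <- genomicToTranscript(models, carrier, gs, ge, "exons")
                miCounter <- miCounter + 1L
                mid <- sprintf("miR%03d", miCounter)
                sites <- rbind(sites, data.frame(
                    transcript_id = carrier, mirna_id = mid,
                    tx_start = nt[1L], tx_end = nt[2L]))
                gr <- transcriptToGenomic(models, carrier, nt[1L], nt[2L])
                fid <- sprintf("%s@%s:%d-%d", mid,
                               as.character(seqnames(gr))[1L],
                               min(start(gr)), max(end(gr)))
                ivStr <- .fmtIntervals(as.character(seqnames(gr))[1L],
                                       ranges(gr))
                truthChanges <- rbind(truthChanges,
                    addChangeRows(gene, carrier, fid, "mirna_site", ivStr,
                                  ev))
            }
        }
    }
    list(domains = if (is.null(domains)) data.frame(
             transcript_id = character(), accession = character(),
             name = character(), pep_start = integer(),
             pep_end = integer(), evalue = numeric()) else domains,
         mirnaSites = if (is.null(sites)) data.frame(
             transcript_id = character(), mirna_id = character(),
             tx_start = integer(), tx_end = integer()) else sites,
         truthChanges = if (is.null(truthChanges)) data.frame(
             gene_id = character(), reference_mode = character(),
             reference_transcript_id = character(),
             alt_transcript_id = character(), feature_kind = character(),
             feature_id = character(), direction = character(),
             expected_events = character()) else truthChanges)
}

#' Generate a complete synthetic splicing study
#'
#' Runs the four generators in order (transcriptome, genotypes, expression
#' and read counts, functional annotations), each on a seed derived from
#' the root seed, and bundles their outputs with the full ground truth.
#' Regeneration with the same configuration is deterministic.
#'
#' @param cfg a [simulationConfig()] list.
#' @return list with `models`, `genotypes`, `expression`, `design`,
#'   `junctionCounts`, `geneCounts`, `riCoverage`, `domains`,
#'   `mirnaSites`, `truth` (events, snps, traits, qtl, sqtl, changes) and
#'   `config`.
#' @export
simulateStudy <- function(cfg = simulationConfig()) {
    tr <- generateTranscriptome(cfg)
    gt <- generateGenotypes(cfg, tr$chromLengths)
    ex <- generateExpression(cfg, tr, gt$genotypes)
    fn <- generateFunctionalAnnotations(cfg, tr, ex)
    list(models = tr$models, genotypes = gt$genotypes,
         expression = ex$expression, design = ex$design,
         junctionCounts = ex$junctionCounts, geneCounts = ex$geneCounts,
         riCoverage = ex$riCoverage, domains = fn$domains,
         mirnaSites = fn$mirnaSites,
         truth = list(events = tr$truthEvents, snps = gt$truthSnps,
                      traits = ex$truthTraits, qtl = ex$truthQtl,
                      sqtl = ex$truthSqtl, changes = fn$truthChanges),
         config = cfg)
}

#' Simulate Gaussian traits from a replicated variance-component design
#'
#' Draws traits directly from the variance-component model (genotype, row,
#' column, residual) on a balanced design of `nGenotypes` individuals with
#' `nReplicates` replicates each, without the log-normal transformation
#' used for FPKM. Intended for estimator calibration.
#'
#' @param nGenotypes,nReplicates design size.
#' @param sigma2_g,sigma2_r,sigma2_c,sigma2_e variance components.
#' @param nTraits number of independent traits.
#' @param seed optional integer seed.
#' @return list with `traits` (nTraits x samples matrix), `design` and
#'   `h2` (the true heritability).
#' @export
simulateTraits <- function(nGenotypes, nReplicates = 3, sigma2_g = 1,
                           sigma2_r = 0, sigma2_c = 0, sigma2_e = 1,
                           nTraits = 1, seed = NULL) {
    .withSeed(seed, {
        inds <- sprintf("I%03d", seq_len(nGenotypes))
        design <- expand.grid(replicate = seq_len(nReplicates),
                              individual = inds,
                              stringsAsFactors = FALSE)[, 2:1]
        n <- nrow(design)
        design$sample_id <- sprintf("%s_r%d", design$individual,
                                    design$replicate)
        nR <- ceiling(sqrt(n))
        slots <- sample(n)
        design$row <- ((slots - 1L) %/% nR) + 1L
        design$column <- ((slots - 1L) %% nR) + 1L
        design$experiment <- "E1"
        idx <- match(design$individual, inds)
        rl <- sort(unique(design$row)); cl <- sort(unique(design$column))
        y <- matrix(stats::rnorm(nTraits * n, sd = sqrt(sigma2_e)),
                    nTraits, n)
        y <- y + matrix(stats::rnorm(nTraits * nGenotypes,
                                     sd = sqrt(sigma2_g)),
                        nTraits)[, idx, drop = FALSE]
        if (sigma2_r > 0)
            y <- y + matrix(stats::rnorm(nTraits * length(rl),
                                         sd = sqrt(sigma2_r)),
                            nTraits)[, match(design$row, rl), drop = FALSE]
        if (sigma2_c > 0)
            y <- y + matrix(stats::rnorm(nTraits * length(cl),
                                         sd = sqrt(sigma2_c)),
                            nTraits)[, match(design$column, cl),
                                     drop = FALSE]
        colnames(y) <- design$sample_id
        rownames(y) <- paste0("trait", seq_len(nTraits))
        if (sigma2_r == 0) design$row <- NULL
        if (sigma2_c == 0) design$column <- NULL
        list(traits = y, design = design,
             h2 = sigma2_g / (sigma2_g + sigma2_r + sigma2_c + sigma2_e))
    })
}
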