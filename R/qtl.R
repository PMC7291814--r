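#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the p^2 / 2pq / q^2 expectation at the sample allele frequency,
#' without continuity correction. Monomorphic SNPs return statistic 0 and
#' p-value 1.
#'
#' @param nAA,nAa,naa genotype counts (major hom, het, minor hom).
#' @return list with `chisq` and `p_value`.
#' @examples
#' hweTest(25, 50, 25)  # exact HWE proportions: chisq 0, p 1
#' hweTest(50, 0, 50)   # chisq 100
#' @export
hweTest <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    stopifnot(n > 0)
    p <- (2 * nAA + nAa) / (2 * n)
    q <- 1 - p
    if (p == 0 || q == 0) return(list(chisq = 0, p_value = 1))
    expd <- c(p^2, 2 * p * q, q^2) * n
    chisq <- sum((c(nAA, nAa, naa) - expd)^2 / expd)
    list(chisq = chisq, p_value = stats::pchisq(chisq, df = 1,
                                                lower.tail = FALSE))
}

#' Read genotypes from a VCF file
#'
#' Reads GT (additive minor-allele coding), DP and GQ fields from a
#' biallelic VCF into a [GenotypeData-class] object.
#'
#' @param path path to a VCF (plain text or gzipped).
#' @return a [GenotypeData-class].
#' @export
readVcfGenotypes <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    calls <- matrix(NA_integer_, nrow(gt), ncol(gt),
                    dimnames = dimnames(gt))
    clean <- gsub("|", "/", gt, fixed = TRUE)
    calls[clean == "0/0"] <- 0L
    calls[clean %in% c("0/1", "1/0")] <- 1L
    calls[clean == "1/1"] <- 2L
    dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                   error = function(e) NULL)
    gq <- tryCatch(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE),
                   error = function(e) NULL)
    fix <- vcfR::getFIX(v)
    id <- fix[, "ID"]
    noid <- is.na(id) | id == "."
    id[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
    GenotypeData(calls,
                 map = data.frame(snp_id = id, chrom = fix[, "CHROM"],
                                  pos = as.integer(fix[, "POS"])),
                 depth = dp, gq = gq)
}

#' SNP quality filters
#'
#' Applies the five marker filters jointly (order-independent): a SNP is
#' kept iff its HWE chi-square p-value is at least `hweAlpha`, minor allele
#' frequency at least `mafMin`, mean sequencing depth at least `depthMin`,
#' mean genotype quality at least `gqMin`, and missing-call fraction at
#' most `missingMax`. Depth and GQ rules are skipped when the matrices are
#' absent. The filter is idempotent.
#'
#' @param g a [GenotypeData-class].
#' @param hweAlpha HWE p-value floor (default 0.01).
#' @param mafMin minor allele frequency floor (default 0.05).
#' @param depthMin mean depth floor (default 8).
#' @param gqMin mean genotype-quality floor (default 20).
#' @param missingMax maximum missing fraction (default 0.75).
#' @return the filtered [GenotypeData-class].
#' @export
filterSnps <- function(g, hweAlpha = 0.01, mafMin = 0.05, depthMin = 8,
                       gqMin = 20, missingMax = 0.75) {
    calls <- g@calls
    n0 <- rowSums(calls == 0L, na.rm = TRUE)
    n1 <- rowSums(calls == 1L, na.rm = TRUE)
    n2 <- rowSums(calls == 2L, na.rm = TRUE)
    nObs <- n0 + n1 + n2
    hweP <- vapply(seq_len(nrow(calls)), function(i) {
        if (nObs[i] == 0) return(1)
        hweTest(n0[i], n1[i], n2[i])$p_value
    }, numeric(1))
    af <- ifelse(nObs > 0, (n1 + 2 * n2) / (2 * nObs), 0)
    maf <- pmin(af, 1 - af)
    missFrac <- rowMeans(is.na(calls))
    keep <- hweP >= hweAlpha & maf >= mafMin & missFrac <= missingMax
    if (!is.null(g@depth))
        keep <- keep & rowMeans(g@depth, na.rm = TRUE) >= depthMin
    if (!is.null(g@gq))
        keep <- keep & rowMeans(g@gq, na.rm = TRUE) >= gqMin
    keep[is.na(keep)] <- FALSE
    GenotypeData(calls[keep, , drop = FALSE],
                 as.data.frame(g@map)[keep, , drop = FALSE],
                 depth = if (is.null(g@depth)) NULL
                         else g@depth[keep, , drop = FALSE],
                 gq = if (is.null(g@gq)) NULL
                      else g@gq[keep, , drop = FALSE])
}

#' Splice-junction usage phenotypes
#'
#' Per sample, a junction's usage is its spanning-read count divided by the
#' reads mapping to the host gene (undefined when the gene has zero reads);
#' per individual, usage is the mean over replicates with defined usage.
#' The statistic is invariant to scaling all of an individual's replicate
#' counts by a common factor.
#'
#' @param junctionCounts data.frame with `chrom`, `strand`, `intron_start`,
#'   `intron_end`, `gene_id`, `sample`, `reads`.
#' @param geneCounts data.frame with `gene_id`, `sample`, `reads`.
#' @param design data.frame with `sample_id` and `individual`.
#' @return list with `usage` (junction x individual matrix, NA where no
#'   replicate had gene reads) and `junctions` (data.frame mapping
#'   `junction_id` to `gene_id`).
#' @export
junctionUsage <- function(junctionCounts, geneCounts, design) {
    stopifnot(all(geneCounts$reads >= 0))
    jid <- .junctionId(junctionCounts$chrom, junctionCounts$strand,
                       junctionCounts$intron_start,
                       junctionCounts$intron_end)
    gkey <- paste(geneCounts$gene_id, geneCounts$sample)
    greads <- setNames(geneCounts$reads, gkey)
    denom <- greads[paste(junctionCounts$gene_id, junctionCounts$sample)]
    use <- ifelse(!is.na(denom) & denom > 0,
                  junctionCounts$reads / denom, NA_real_)
    ind <- design$individual[match(junctionCounts$sample,
                                   design$sample_id)]
    jset <- unique(data.frame(junction_id = jid,
                              gene_id = junctionCounts$gene_id))
    inds <- unique(as.character(design$individual))
    usage <- matrix(NA_real_, nrow(jset), length(inds),
                    dimnames = list(jset$junction_id, inds))
    ok <- !is.na(use)
    agg <- tapply(use[ok], list(jid[ok], as.character(ind)[ok]), mean)
    usage[rownames(agg), colnames(agg)] <- agg
    list(usage = usage, junctions = jset)
}

#' Junction filter for splicing-QTL analysis
#'
#' A junction becomes an sQTL phenotype when it belongs to the junction set
#' of at least one classified splicing event and its usage is above zero in
#' at least `ceiling(minNonzeroFrac * n_individuals)` individuals.
#'
#' @param usage junction x individual usage matrix (from
#'   [junctionUsage()]).
#' @param events event `GRanges` from [classifyASEvents()].
#' @param minNonzeroFrac minimum fraction of individuals with usage > 0
#'   (default 0.05).
#' @return character vector of retained junction ids.
#' @export
sqtlJunctionFilter <- function(usage, events, minNonzeroFrac = 0.05) {
    evj <- unique(unlist(.eventJunctionKeys(events)))
    need <- ceiling(minNonzeroFrac * ncol(usage))
    nz <- rowSums(usage > 0, na.rm = TRUE)
    rownames(usage)[rownames(usage) %in% evj & nz >= need]
}

#' Genome-wide SNP-trait association scan
#'
#' Regresses every trait on every SNP (additive coding, missing genotypes
#' mean-imputed per SNP) with per-pair simple linear regression computed in
#' matrix form; p-values are the two-sided t-tests and equal per-pair
#' `lm()` fits. Significance is controlled either by a permutation-based
#' empirical FDR (default) -- individuals of the whole phenotype matrix are
#' permuted jointly `nPerm` times and FDR(t) is the mean number of null
#' p-values at or below t (with a one-count pseudo-observation, as in
#' permutation p-values) divided by the observed count, monotonized -- or
#' by Benjamini-Hochberg on the observed p-values. More permutations give
#' a finer-grained FDR; with `nPerm` permutations the smallest reportable
#' FDR at rank r is `1 / (nPerm * r)`.
#'
#' @param phenotypes numeric matrix, traits x individuals.
#' @param genotypes a [GenotypeData-class] or SNP x individual matrix.
#' @param fdrTarget reported FDR level (default 0.05).
#' @param nPerm phenotype permutations for the empirical FDR (default 10).
#' @param seed optional integer seed.
#' @param method `"permutation"` or `"BH"`.
#' @return data.frame of associations passing `fdrTarget`: `snp_id`,
#'   `trait_id`, `beta`, `t_stat`, `p_value`, `fdr`. Attributes `n_tests`
#'   and `n_individuals` record the scan size. Zero-variance traits and
#'   SNPs are dropped from testing.
#' @export
mapQtl <- function(phenotypes, genotypes, fdrTarget = 0.05, nPerm = 10,
                   seed = NULL, method = c("permutation", "BH")) {
    method <- match.arg(method)
    G <- if (is(genotypes, "GenotypeData")) genotypeCalls(genotypes)
         else genotypes
    P <- as.matrix(phenotypes)
    common <- intersect(colnames(G), colnames(P))
    if (length(common) < 3L) stop("need >= 3 shared individuals")
    G <- G[, common, drop = FALSE]
    P <- P[, common, drop = FALSE]
    n <- length(common)
    ## mean-impute missing genotypes per SNP
    if (anyNA(G)) {
        mu <- rowMeans(G, na.rm = TRUE)
        idx <- which(is.na(G))
        G[idx] <- mu[(idx - 1L) %% nrow(G) + 1L]
    }
    sdG <- apply(G, 1L, stats::sd)
    sdP <- apply(P, 1L, stats::sd)
    G <- G[sdG > 0, , drop = FALSE]
    P <- P[sdP > 0, , drop = FALSE]
    sdG <- sdG[sdG > 0]; sdP <- sdP[sdP > 0]
    if (!nrow(G) || !nrow(P))
        return(.emptyAssoc(n, 0L))
    Gs <- (G - rowMeans(G)) / sdG
    Ps <- (P - rowMeans(P)) / sdP
    corP <- function(Pmat) tcrossprod(Gs, Pmat) / (n - 1)
    pFromR <- function(r) {
        r2 <- pmin(r * r, 1 - 1e-15)
        t <- r * sqrt((n - 2) / (1 - r2))
        2 * stats::pt(-abs(t), df = n - 2)
    }
    r <- corP(Ps)
    r2 <- pmin(r * r, 1 - 1e-15)
    tstat <- r * sqrt((n - 2) / (1 - r2))
    pobs <- 2 * stats::pt(-abs(tstat), df = n - 2)
    beta <- r * outer(1 / sdG, sdP)
    obs <- data.frame(snp_id = rep(rownames(G), ncol(pobs)),
                      trait_id = rep(rownames(P), each = nrow(G)))
    obs$beta <- as.vector(beta)
    obs$t_stat <- as.vector(tstat)
    obs$p_value <- as.vector(pobs)
    ord <- order(obs$p_value)
    obs <- obs[ord, ]
    m <- nrow(obs)
    if (method == "BH") {
        obs$fdr <- stats::p.adjust(obs$p_value, "BH")
    } else {
        sortedObs <- obs$p_value
        nullCounts <- numeric(m)
        .withSeed(seed, {
            for (b in seq_len(nPerm)) {
                Pp <- Ps[, sample.int(n), drop = FALSE]
                pnull <- sort(as.vector(pFromR(corP(Pp))))
                nullCounts <- nullCounts +
                    findInterval(sortedObs, pnull)
            }
        })
        ## +1 pseudo-count (the observed scan counts as one more draw from
        ## the null): guards the estimate against downward noise when few
        ## permutations are run, as in permutation p-values
        rawFdr <- ((nullCounts + 1) / nPerm) / seq_len(m)
        obs$fdr <- rev(cummin(rev(pmin(rawFdr, 1))))
    }
    out <- obs[obs$fdr <= fdrTarget, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_tests") <- m
    attr(out, "n_individuals") <- n
    attr(out, "method") <- method
    attr(out, "n_perm") <- if (method == "permutation") nPerm else NA_integer_
    out
}

.emptyAssoc <- function(n, m) {
    out <- data.frame(snp_id = character(), trait_id = character(),
                      beta = numeric(), t_stat = numeric(),
                      p_value = numeric(), fdr = numeric())
    attr(out, "n_tests") <- m
    attr(out, "n_individuals") <- n
    out
}

#' Classify associations as cis or trans
#'
#' An association is cis when the SNP lies on the trait's chromosome within
#' `window` bases of the trait's span (up to 1 Mb upstream of the start or
#' downstream of the end by default, or inside it); otherwise trans. Traits
#' without a genomic location are flagged `NA`.
#'
#' @param assoc association data.frame with `snp_id` and `trait_id`.
#' @param traitLoc data.frame with `trait_id`, `chrom`, `start`, `end` (for
#'   junction traits, the host gene span).
#' @param snpMap data.frame with `snp_id`, `chrom`, `pos`.
#' @param window cis window in bases (default 1e6).
#' @return `assoc` with a `regulation` factor column (`cis`/`trans`, NA
#'   when the trait has no location).
#' @export
classifyCisTrans <- function(assoc, traitLoc, snpMap, window = 1e6) {
    ti <- match(assoc$trait_id, traitLoc$trait_id)
    si <- match(assoc$snp_id, snpMap$snp_id)
    if (anyNA(si)) stop("SNPs missing from snpMap")
    sameChr <- !is.na(ti) &
        as.character(traitLoc$chrom[ti]) == as.character(snpMap$chrom[si])
    inWin <- sameChr &
        snpMap$pos[si] >= traitLoc$start[ti] - window &
        snpMap$pos[si] <= traitLoc$end[ti] + window
    reg <- ifelse(is.na(ti), NA_character_,
                  ifelse(inWin, "cis", "trans"))
    assoc$regulation <- factor(reg, levels = c("cis", "trans"))
    assoc
}

#' Heritable-isoform load of sQTL-regulated and regulator genes
#'
#' For each class of genes -- regulated by a cis sQTL, regulated by a trans
#' sQTL, harboring a cis sQTL (regulator), harboring a trans sQTL --
#' compares the number of significantly heritable isoforms per gene inside
#' versus outside the class with a Wilcoxon rank-sum test.
#'
#' @param geneClasses named list of character vectors of gene ids (the
#'   classes).
#' @param heritableCounts named numeric vector: heritable isoforms per gene
#'   for every gene in the analysis.
#' @return data.frame with `class`, `n_genes`, `mean_in`, `mean_out`,
#'   `p_value`, `flag` (`"empty"` or `"singleton"` when the test cannot
#'   run).
#' @export
regulatedGeneSummary <- function(geneClasses, heritableCounts) {
    all_genes <- names(heritableCounts)
    rows <- lapply(names(geneClasses), function(cl) {
        g <- intersect(geneClasses[[cl]], all_genes)
        out <- setdiff(all_genes, g)
        if (length(g) == 0L)
            return(data.frame(class = cl, n_genes = 0L, mean_in = NA_real_,
                              mean_out = mean(heritableCounts[out]),
                              p_value = NA_real_, flag = "empty"))
        if (length(g) < 2L || length(out) < 2L)
            return(data.frame(class = cl, n_genes = length(g),
                              mean_in = mean(heritableCounts[g]),
                              mean_out = mean(heritableCounts[out]),
                              p_value = NA_real_, flag = "singleton"))
        p <- if (length(unique(heritableCounts[c(g, out)])) == 1L) 1
             else suppressWarnings(
                 stats::wilcox.test(heritableCounts[g],
                                    heritableCounts[out]))$p.value
        data.frame(class = cl, n_genes = length(g),
                   mean_in = mean(heritableCounts[g]),
                   mean_out = mean(heritableCounts[out]),
                   p_value = p, flag = "")
    })
    do.call(rbind, rows)
}
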