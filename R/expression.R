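#' Per-individual replicate-averaged expression
#'
#' Collapses the sample columns of a [SpliceExperiment-class] to one column
#' per individual by taking the arithmetic mean of that individual's
#' replicate FPKMs.
#'
#' @param se a [SpliceExperiment-class].
#' @return numeric matrix, transcripts x individuals.
#' @export
individualMeans <- function(se) {
    ind <- as.character(colData(se)$individual)
    m <- fpkm(se)
    grp <- factor(ind, levels = unique(ind))
    sums <- t(rowsum(t(m), grp))[, levels(grp), drop = FALSE]
    sweep(sums, 2L, as.numeric(table(grp)[levels(grp)]), "/")
}

#' Presence/absence calls for isoforms
#'
#' An isoform is present in an individual when its FPKM reaches
#' `fpkmThreshold` in at least `minReplicates` of that individual's
#' replicates. Individuals with fewer than `minReplicates` replicates are
#' excluded with a warning.
#'
#' @param se a [SpliceExperiment-class].
#' @param fpkmThreshold FPKM cutoff (default 3).
#' @param minReplicates replicates required at or above the cutoff
#'   (default 2).
#' @return logical matrix, transcripts x individuals.
#' @export
presenceCalls <- function(se, fpkmThreshold = 3, minReplicates = 2) {
    ind <- as.character(colData(se)$individual)
    grp <- factor(ind, levels = unique(ind))
    nrep <- table(grp)[levels(grp)]
    bad <- names(nrep)[nrep < minReplicates]
    if (length(bad))
        warning("excluding individuals with < ", minReplicates,
                " replicates: ", paste(bad, collapse = ", "))
    keep <- levels(grp)[!(levels(grp) %in% bad)]
    hits <- (fpkm(se) >= fpkmThreshold) + 0
    counts <- t(rowsum(t(hits), grp))[, levels(grp), drop = FALSE]
    counts[, keep, drop = FALSE] >= minReplicates
}

#' Population-level expression filter
#'
#' Retains isoforms present (per [presenceCalls()]) in at least
#' `minIndividuals` individuals. The filter is idempotent, and with
#' `minIndividuals = 0` it retains everything.
#'
#' @param presence logical transcripts x individuals matrix.
#' @param minIndividuals minimum number of presences (default 3).
#' @return character vector of retained transcript ids.
#' @export
populationExpressionFilter <- function(presence, minIndividuals = 3) {
    rownames(presence)[rowSums(presence) >= minIndividuals]
}

#' Presence/absence variation histogram
#'
#' Counts, for each number of individuals `k`, how many isoforms are present
#' in exactly `k` individuals. The histogram totals the number of isoforms.
#'
#' @param presence logical transcripts x individuals matrix.
#' @return data.frame with columns `n_individuals`, `n_isoforms`.
#' @export
pavSummary <- function(presence) {
    if (nrow(presence) == 0L)
        return(data.frame(n_individuals = integer(), n_isoforms = integer()))
    tab <- table(rowSums(presence))
    data.frame(n_individuals = as.integer(names(tab)),
               n_isoforms = as.integer(tab))
}

#' Major-isoform frequency
#'
#' For each gene and individual, credits the single most highly expressed
#' isoform (replicate-mean FPKM; ties broken by lexicographically smallest
#' transcript id). An individual expresses a gene when the mean summed FPKM
#' of its isoforms is > 0; individuals not expressing the gene credit no
#' isoform, so a gene's frequencies sum to its number of expressing
#' individuals.
#'
#' @param se a [SpliceExperiment-class].
#' @return data.frame with `transcript_id`, `gene_id`, `frequency` (number
#'   of individuals in which the isoform is the gene's most expressed) and
#'   `fraction` (frequency over the number of individuals expressing the
#'   gene; NA when no individual expresses it).
#' @export
majorIsoformFrequency <- function(se) {
    m <- individualMeans(se)
    gene <- as.character(rowData(se)$gene_id)
    tx <- as.character(rowData(se)$transcript_id)
    ord <- order(tx)
    freq <- setNames(integer(length(tx)), tx)
    nexpr <- setNames(integer(length(tx)), tx)
    for (g in unique(gene)) {
        rows <- which(gene == g)
        rows <- rows[order(tx[rows])]        # tie-break: smallest id wins
        sub <- m[rows, , drop = FALSE]
        tot <- colSums(sub)
        expressing <- tot > 0
        if (any(expressing)) {
            best <- apply(sub[, expressing, drop = FALSE], 2L, which.max)
            cnt <- tabulate(best, nbins = length(rows))
            freq[tx[rows]] <- cnt
        }
        nexpr[tx[rows]] <- sum(expressing)
    }
    data.frame(transcript_id = tx, gene_id = gene,
               frequency = as.integer(freq[tx]),
               fraction = ifelse(nexpr[tx] > 0, freq[tx] / nexpr[tx], NA_real_),
               row.names = NULL)
}

#' Gene-feature / isoform-count correlations
#'
#' Correlates the number of isoforms per gene with gene length (span of all
#' exons), exon count (maximum over isoforms) and median gene expression
#' (median across samples of the summed isoform FPKM). Both Pearson (r, r^2)
#' and Spearman statistics are reported; a zero-variance feature yields NA
#' with `flag = "zero_variance"`.
#'
#' @param x a [TranscriptModels-class].
#' @param se a [SpliceExperiment-class] quantifying the same transcripts.
#' @return data.frame with one row per feature pair: `feature`, `pearson_r`,
#'   `pearson_r2`, `pearson_p`, `spearman_rho`, `spearman_p`, `flag`.
#' @export
geneFeatureCorrelations <- function(x, se) {
    genes <- geneIds(x)
    if (length(genes) < 3L) stop("need at least 3 genes")
    td <- x@txData
    nIso <- as.integer(table(factor(td$gene_id, levels = genes)))
    sp <- geneSpans(x)
    glen <- width(sp)[match(genes, names(sp))]
    nex <- vapply(genes, function(g) {
        max(lengths(x@exons[td$transcript_id[td$gene_id == g]]))
    }, integer(1))
    gene <- as.character(rowData(se)$gene_id)
    gm <- rowsum(fpkm(se), gene)
    med <- apply(gm, 1L, stats::median)
    med <- med[genes]
    med[is.na(med)] <- 0
    one <- function(name, feat) {
        if (stats::sd(feat) == 0 || stats::sd(nIso) == 0)
            return(data.frame(feature = name, pearson_r = NA_real_,
                              pearson_r2 = NA_real_, pearson_p = NA_real_,
                              spearman_rho = NA_real_, spearman_p = NA_real_,
                              flag = "zero_variance"))
        pt <- stats::cor.test(feat, nIso, method = "pearson")
        st <- suppressWarnings(
            stats::cor.test(feat, nIso, method = "spearman"))
        data.frame(feature = name,
                   pearson_r = unname(pt$estimate),
                   pearson_r2 = unname(pt$estimate)^2,
                   pearson_p = pt$p.value,
                   spearman_rho = unname(st$estimate),
                   spearman_p = st$p.value, flag = "")
    }
    rbind(one("gene_length", glen),
          one("n_exons", as.numeric(nex)),
          one("median_expression", med))
}
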