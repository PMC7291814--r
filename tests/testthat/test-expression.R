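# helper: SpliceExperiment from a per-replicate FPKM list
makeSE <- function(fpkmByInd, txGene) {
  inds <- names(fpkmByInd)
  nrep <- ncol(fpkmByInd[[1]])
  m <- do.call(cbind, fpkmByInd)
  rownames(m) <- txGene$transcript_id
  colnames(m) <- unlist(lapply(inds, function(i) paste0(i, "_r", 1:nrep)))
  design <- data.frame(sample_id = colnames(m),
                       individual = rep(inds, each = nrep),
                       replicate = rep(1:nrep, length(inds)),
                       row = 1, column = seq_len(ncol(m)),
                       experiment = "E1")
  SpliceExperiment(m, design, txGene)
}

test_that("presence calls need the FPKM threshold in enough replicates", {
  tx <- data.frame(transcript_id = "iso1", gene_id = "g1")
  se <- makeSE(list(A = matrix(c(3.0, 2.9, 5.0), 1),
                    B = matrix(c(2.9, 2.9, 100), 1),
                    C = matrix(c(0, 0, 0), 1)), tx)
  p <- presenceCalls(se, fpkmThreshold = 3, minReplicates = 2)
  expect_identical(p["iso1", ], c(A = TRUE, B = FALSE, C = FALSE))
  # threshold 0 marks everything present
  expect_true(all(presenceCalls(se, 0, 2)))
  # monotone in both threshold and replicate requirement
  expect_true(all(presenceCalls(se, 5, 2) <= presenceCalls(se, 3, 2)))
  expect_true(all(presenceCalls(se, 3, 3) <= presenceCalls(se, 3, 2)))
})

test_that("population filter keeps isoforms present in enough individuals", {
  set.seed(1)
  # 10 isoforms with presence in exactly 0..9 of 9 individuals
  pres <- matrix(FALSE, 10, 9,
                 dimnames = list(paste0("iso", 1:10), paste0("I", 1:9)))
  for (i in 1:10) if (i > 1) pres[i, seq_len(i - 1)] <- TRUE
  # by hand: isoforms 4..10 have >= 3 presences (7 survivors)
  expect_identical(populationExpressionFilter(pres, 3), paste0("iso", 4:10))
  # minIndividuals = 0 retains everything; the filter is idempotent
  expect_identical(populationExpressionFilter(pres, 0), rownames(pres))
  kept <- populationExpressionFilter(pres, 3)
  expect_identical(populationExpressionFilter(pres[kept, ], 3), kept)
})

test_that("PAV histogram counts isoforms by the individuals they appear in", {
  pres <- matrix(c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("I1", "I2")))
  h <- pavSummary(pres)
  expect_equal(sum(h$n_isoforms), nrow(pres))
  expect_equal(h$n_isoforms[h$n_individuals == 1], 2L)
  expect_equal(h$n_isoforms[h$n_individuals == 2], 1L)
  all1 <- matrix(TRUE, 4, 5, dimnames = list(letters[1:4], LETTERS[1:5]))
  h <- pavSummary(all1)
  expect_equal(h, data.frame(n_individuals = 5L, n_isoforms = 4L))
  expect_equal(nrow(pavSummary(pres[0, , drop = FALSE])), 0L)
})

test_that("major-isoform frequency credits one isoform per expressing individual", {
  tx <- data.frame(transcript_id = c("I1", "I2"), gene_id = "g1")
  # individual replicate-means: (10,2), (1,5), (7,7) -> I1 twice (tie to
  # the lexicographically smaller id), I2 once
  se <- makeSE(list(A = rbind(c(10, 10, 10), c(2, 2, 2)),
                    B = rbind(c(1, 1, 1), c(5, 5, 5)),
                    C = rbind(c(7, 7, 7), c(7, 7, 7))), tx)
  f <- majorIsoformFrequency(se)
  expect_equal(f$frequency[f$transcript_id == "I1"], 2L)
  expect_equal(f$frequency[f$transcript_id == "I2"], 1L)
  expect_equal(sum(f$frequency), 3L)  # all individuals express the gene
  # single-isoform gene: frequency = number of expressing individuals
  tx1 <- data.frame(transcript_id = "solo", gene_id = "g2")
  se1 <- makeSE(list(A = matrix(c(1, 1, 1), 1), B = matrix(0, 1, 3)), tx1)
  f1 <- majorIsoformFrequency(se1)
  expect_equal(f1$frequency, 1L)
  # gene unexpressed everywhere
  se0 <- makeSE(list(A = matrix(0, 1, 3)), tx1)
  expect_equal(majorIsoformFrequency(se0)$frequency, 0L)
  expect_true(is.na(majorIsoformFrequency(se0)$fraction))
})

test_that("gene-feature correlations report Pearson and Spearman statistics", {
  # five genes whose isoform count grows linearly with their length
  isoforms <- list()
  txg <- NULL
  for (g in 1:5) {
    len <- 1000 * g
    for (i in seq_len(g)) {
      id <- sprintf("g%d.t%d", g, i)
      isoforms[[id]] <- rbind(c((g - 1) * 20000 + 1,
                                (g - 1) * 20000 + len))
      txg <- rbind(txg, data.frame(transcript_id = id,
                                   gene_id = paste0("g", g)))
    }
  }
  models <- TranscriptModels(
    GenomicRanges::GRangesList(lapply(isoforms, function(m)
      GenomicRanges::GRanges("chr1", IRanges::IRanges(m[, 1], m[, 2]),
                             strand = "+"))), txg)
  m <- matrix(5, length(isoforms), 6,
              dimnames = list(names(isoforms), paste0("s", 1:6)))
  design <- data.frame(sample_id = paste0("s", 1:6),
                       individual = rep(c("A", "B"), each = 3),
                       replicate = rep(1:3, 2), row = 1, column = 1:6,
                       experiment = "E1")
  se <- SpliceExperiment(m, design, txg)
  rep <- geneFeatureCorrelations(models, se)
  glRow <- rep[rep$feature == "gene_length", ]
  expect_equal(glRow$pearson_r2, 1, tolerance = 1e-12)
  # Spearman agrees with the brute-force rank formula on exact ranks
  nIso <- 1:5; len <- 1000 * (1:5)
  d <- rank(len) - rank(nIso)
  rsBrute <- 1 - 6 * sum(d^2) / (5 * (5^2 - 1))
  expect_equal(glRow$spearman_rho, rsBrute)
  # constant features are flagged, not silently dropped (every isoform is
  # single-exon here, so the exon count never varies)
  expect_equal(rep$flag[rep$feature == "n_exons"], "zero_variance")
  expect_true(is.na(rep$pearson_r[rep$feature == "n_exons"]))
})
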