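test_that("HWE chi-square matches hand-computed cases", {
  expect_equal(hweTest(25, 50, 25)$chisq, 0)
  expect_equal(hweTest(25, 50, 25)$p_value, 1)
  expect_equal(hweTest(81, 18, 1)$chisq, 0)  # p = 0.9 gives exact fit
  # (50, 0, 50): expected 25/50/25 -> 25 + 50 + 25 = 100
  expect_equal(hweTest(50, 0, 50)$chisq, 100)
  # monomorphic SNPs are not penalized
  expect_equal(hweTest(80, 0, 0)$p_value, 1)
})

test_that("the five SNP filters return the exact hand-enumerated survivors", {
  nI <- 40
  mk <- function(p) {
    g <- rep(0:2, round(nI * c((1 - p)^2, 2 * p * (1 - p), p^2)))
    rep_len(g, nI)
  }
  calls <- rbind(
    ok1 = mk(0.5), ok2 = mk(0.3),
    lowmaf = c(rep(0L, 39), 1L),                # MAF 0.0125
    badhwe = rep(c(0L, 2L), 20),                # no heterozygotes
    lowdepth = mk(0.4), lowgq = mk(0.4),
    miss = {x <- mk(0.4); x[1:32] <- NA; x},    # 80% missing
    ok3 = mk(0.25))
  colnames(calls) <- paste0("I", seq_len(nI))
  depth <- matrix(20, nrow(calls), nI, dimnames = dimnames(calls))
  depth["lowdepth", ] <- 4
  gq <- matrix(60, nrow(calls), nI, dimnames = dimnames(calls))
  gq["lowgq", ] <- 10
  g <- GenotypeData(calls,
                    data.frame(snp_id = rownames(calls), chrom = "chr1",
                               pos = seq_len(nrow(calls)) * 100),
                    depth = depth, gq = gq)
  kept <- filterSnps(g)
  expect_identical(snpMap(kept)$snp_id, c("ok1", "ok2", "ok3"))
  # order-independence / idempotence
  kept2 <- filterSnps(kept)
  expect_identical(snpMap(kept2)$snp_id, snpMap(kept)$snp_id)
  # single-rule failures
  expect_false("lowmaf" %in% snpMap(filterSnps(g, mafMin = 0.05))$snp_id)
  expect_true("lowdepth" %in%
    snpMap(filterSnps(g, depthMin = 0))$snp_id)
})

test_that("junction usage is the replicate-averaged read-share of the gene", {
  jc <- data.frame(chrom = "chr1", strand = "+", intron_start = 101,
                   intron_end = 200, gene_id = "g1",
                   sample = c("A_r1", "A_r2", "A_r3", "B_r1", "B_r2"),
                   reads = c(12, 30, 30, 5, 5))
  gc <- data.frame(gene_id = "g1",
                   sample = c("A_r1", "A_r2", "A_r3", "B_r1", "B_r2"),
                   reads = c(120, 100, 150, 0, 0))
  design <- data.frame(sample_id = c("A_r1", "A_r2", "A_r3", "B_r1",
                                     "B_r2"),
                       individual = c("A", "A", "A", "B", "B"))
  u <- junctionUsage(jc, gc, design)
  expect_equal(u$usage["chr1:+:101-200", "A"], mean(c(0.1, 0.3, 0.2)))
  # all replicates with zero gene reads: usage undefined for B
  expect_true(is.na(u$usage["chr1:+:101-200", "B"]))
  # invariance to scaling an individual's replicate counts
  jc2 <- jc; gc2 <- gc
  jc2$reads[1:3] <- jc$reads[1:3] * 7
  gc2$reads[1:3] <- gc$reads[1:3] * 7
  u2 <- junctionUsage(jc2, gc2, design)
  expect_equal(u2$usage[, "A"], u$usage[, "A"])
})

test_that("sQTL junction filter needs an AS event and enough nonzero usage", {
  m <- toyModels(list(T1 = rbind(c(1, 100), c(201, 300)),
                      T2 = rbind(c(1, 300))))
  ev <- classifyASEvents(m)
  usage <- matrix(0, 2, 40,
                  dimnames = list(c("chr1:+:101-200", "chr1:+:401-500"),
                                  paste0("I", 1:40)))
  usage[1, 1:3] <- 0.2      # AS junction, nonzero in 3/40 (7.5%)
  usage[2, ] <- 0.5         # non-AS junction, nonzero everywhere
  expect_identical(sqtlJunctionFilter(usage, ev, 0.05), "chr1:+:101-200")
  # below the ceiling(5% of 40) = 2 threshold
  usage[1, ] <- 0; usage[1, 1] <- 0.2
  expect_identical(sqtlJunctionFilter(usage, ev, 0.05), character(0))
})

test_that("scan p-values equal per-pair least-squares t-tests", {
  set.seed(101)
  n <- 30
  G <- matrix(rbinom(25 * n, 2, 0.4), 25,
              dimnames = list(paste0("S", 1:25), paste0("I", 1:n)))
  G[sample(length(G), 20)] <- NA     # exercise mean imputation
  P <- matrix(rnorm(8 * n), 8,
              dimnames = list(paste0("T", 1:8), paste0("I", 1:n)))
  res <- mapQtl(P, G, fdrTarget = 1, nPerm = 2, seed = 3, method = "BH")
  Gimp <- G
  for (s in rownames(G)) {
    x <- G[s, ]; x[is.na(x)] <- mean(x, na.rm = TRUE); Gimp[s, ] <- x
  }
  for (k in sample(nrow(res), 12)) {
    f <- summary(lm(P[res$trait_id[k], ] ~ Gimp[res$snp_id[k], ]))
    expect_equal(res$p_value[k], f$coefficients[2, 4], tolerance = 1e-12)
    expect_equal(res$beta[k], f$coefficients[2, 1], tolerance = 1e-10)
  }
})

test_that("empirical-FDR mode is deterministic and controls strong signals", {
  set.seed(55)
  n <- 120
  G <- matrix(rbinom(40 * n, 2, 0.3), 40,
              dimnames = list(paste0("S", 1:40), paste0("I", 1:n)))
  P <- matrix(rnorm(10 * n), 10,
              dimnames = list(paste0("T", 1:10), paste0("I", 1:n)))
  z <- scale(G["S1", ])[, 1]
  P["T1", ] <- sqrt(0.3 / 0.7) * z + rnorm(n)   # planted, R2 ~ 0.3
  r1 <- mapQtl(P, G, fdrTarget = 0.05, nPerm = 40, seed = 4)
  r2 <- mapQtl(P, G, fdrTarget = 0.05, nPerm = 40, seed = 4)
  expect_identical(r1, r2)
  expect_true(any(r1$snp_id == "S1" & r1$trait_id == "T1"))
  expect_true(all(r1$fdr <= 0.05))
})

test_that("cis/trans classification applies the 1 Mb window rule", {
  traitLoc <- data.frame(trait_id = "t1", chrom = "chr1",
                         start = 2e6, end = 2.1e6)
  snps <- data.frame(snp_id = c("a", "b", "c", "d"),
                     chrom = c("chr1", "chr1", "chr1", "chr2"),
                     pos = c(1.5e6, 3.6e6, 2.05e6, 2e6))
  assoc <- data.frame(snp_id = c("a", "b", "c", "d"), trait_id = "t1")
  out <- classifyCisTrans(assoc, traitLoc, snps)
  # 0.5 Mb upstream -> cis; 1.5 Mb downstream -> trans; inside -> cis;
  # other chromosome -> trans
  expect_equal(as.character(out$regulation),
               c("cis", "trans", "cis", "trans"))
  # traits without a location are flagged NA
  out2 <- classifyCisTrans(data.frame(snp_id = "a", trait_id = "t9"),
                           traitLoc, snps)
  expect_true(is.na(out2$regulation))
})

test_that("regulated-gene summary compares classes with a rank-sum test", {
  counts <- setNames(c(2, 2, 2, 1, 1, 1, 1, 1), paste0("g", 1:8))
  out <- regulatedGeneSummary(list(cls = paste0("g", 1:3)), counts)
  expect_equal(out$mean_in, 2)
  expect_equal(out$mean_out, 1)
  expect_equal(out$p_value,
               suppressWarnings(wilcox.test(c(2, 2, 2),
                                            rep(1, 5))$p.value))
  # identical groups: p near 1
  outSame <- regulatedGeneSummary(list(cls = paste0("g", 4:6)),
                                  counts[4:8])
  expect_gt(outSame$p_value, 0.9)
  # empty and singleton classes are flagged
  outE <- regulatedGeneSummary(list(none = character(0),
                                    one = "g1"), counts)
  expect_equal(outE$flag, c("empty", "singleton"))
})
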