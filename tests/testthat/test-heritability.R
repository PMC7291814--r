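oneWayDesign <- function(nG, r) {
  data.frame(individual = rep(sprintf("I%03d", seq_len(nG)), each = r),
             replicate = rep(seq_len(r), nG))
}

test_that("broad-sense heritability is the genotypic variance fraction", {
  expect_equal(broadSenseH2(1, 1, 1, 1), 0.25)
  expect_equal(broadSenseH2(0, 2, 3, 5), 0)
  expect_equal(broadSenseH2(3, 0, 0, 1), 0.75)
  expect_equal(broadSenseH2(0, 0, 0, 0), 0)  # zero total variance
  expect_error(broadSenseH2(-1, 0, 0, 1), "non-negative")
})

test_that("REML matches the balanced one-way ANOVA closed form", {
  set.seed(7)
  for (rep in 1:10) {
    nG <- 40; r <- 3
    d <- oneWayDesign(nG, r)
    y <- rnorm(nG, sd = 1)[rep(seq_len(nG), each = r)] +
      rnorm(nG * r, sd = 1)
    vc <- fitVarianceComponents(y, d)
    grp <- d$individual
    msb <- sum(r * (tapply(y, grp, mean) - mean(y))^2) / (nG - 1)
    msw <- sum((y - ave(y, grp))^2) / (nG * r - nG)
    sgA <- max(0, (msb - msw) / r)
    expect_equal(vc$sigma2_g, sgA, tolerance = 1e-6)
    h2A <- if (sgA + msw > 0 && sgA > 0) sgA / (sgA + msw) else
      broadSenseH2(0, 0, 0, 1) * 0
    if (sgA > 0) expect_equal(vc$h2, sgA / (sgA + msw), tolerance = 1e-6)
    # and agrees with lme4 on the same data
    vcL <- fitVarianceComponents(y, d, engine = "lmer")
    expect_equal(vc$sigma2_g, vcL$sigma2_g, tolerance = 1e-5)
    expect_equal(vc$sigma2_e, vcL$sigma2_e, tolerance = 1e-5)
  }
})

test_that("degenerate traits and designs return zero components with a flag", {
  d <- oneWayDesign(10, 3)
  vc <- fitVarianceComponents(rep(2.5, 30), d)
  expect_equal(vc$h2, 0)
  expect_equal(vc$flag, "degenerate")
  d1 <- data.frame(individual = rep("I1", 6), replicate = 1:6)
  vc <- fitVarianceComponents(rnorm(6), d1)
  expect_equal(vc$flag, "degenerate")
})

test_that("h2 is invariant to trait location and positive scaling", {
  set.seed(11)
  s <- simulateTraits(50, 3, sigma2_g = 1, sigma2_e = 1, seed = 2)
  y <- s$traits[1, ]
  d <- s$design
  h0 <- fitVarianceComponents(y, d)$h2
  expect_equal(fitVarianceComponents(y + 100, d)$h2, h0, tolerance = 1e-6)
  expect_equal(fitVarianceComponents(y * 7, d)$h2, h0, tolerance = 1e-6)
  expect_gte(h0, 0); expect_lte(h0, 1)
})

test_that("the full model recovers row and column variance when present", {
  set.seed(3)
  s <- simulateTraits(80, 3, sigma2_g = 1, sigma2_r = 0.5, sigma2_c = 0.5,
                      sigma2_e = 1, nTraits = 30, seed = 4)
  fits <- t(vapply(seq_len(30), function(i)
    unlist(fitVarianceComponents(s$traits[i, ], s$design)[1:5]),
    numeric(5)))
  means <- colMeans(fits)
  expect_equal(unname(means["sigma2_g"]), 1, tolerance = 0.25)
  expect_equal(unname(means["sigma2_r"]), 0.5, tolerance = 0.3)
  expect_equal(unname(means["sigma2_c"]), 0.5, tolerance = 0.3)
  expect_equal(unname(means["h2"]), s$h2, tolerance = 0.07)
})

test_that("permutation threshold is reproducible and its fast path is exact", {
  s <- simulateTraits(40, 3, sigma2_g = 0.5, sigma2_e = 1, seed = 6)
  y <- s$traits[1, ]
  d <- s$design[, c("individual", "replicate")]
  p1 <- permutationThreshold(y, d, nPerm = 200, seed = 99)
  p2 <- permutationThreshold(y, d, nPerm = 200, seed = 99)
  expect_identical(p1$null_h2, p2$null_h2)
  # closed-form permutation H2 equals the numeric one-way REML refit
  set.seed(5)
  for (k in 1:5) {
    d2 <- d
    d2$individual <- d$individual[sample.int(nrow(d))]
    h2ref <- fitVarianceComponents(y, d2)$h2
    grp <- d2$individual
    msb <- sum(3 * (tapply(y, grp, mean) - mean(y))^2) / 39
    msw <- sum((y - ave(y, grp))^2) / (120 - 40)
    sg <- max(0, (msb - msw) / 3)
    h2cf <- if (sg + msw > 0) sg / (sg + msw) else 0
    expect_equal(h2cf, h2ref, tolerance = 1e-6)
  }
})

test_that("heritableSet applies a strict threshold and reports missing nulls", {
  h2 <- data.frame(trait_id = c("a", "b", "c"), h2 = c(0.5, 0.4, 0.2))
  nulls <- data.frame(trait_id = c("a", "b"),
                      null_threshold = c(0.4, 0.4))
  expect_warning(kept <- heritableSet(h2, nulls), "without a permutation")
  expect_identical(kept, "a")        # 0.4 == threshold is dropped
  expect_identical(heritableSet(h2[0, ], nulls), character(0))
})

test_that("estimateHeritability returns calibrated empirical p-values", {
  s <- simulateTraits(60, 3, sigma2_g = 2, sigma2_e = 1, nTraits = 3,
                      seed = 13)
  d <- s$design[, c("individual", "replicate")]
  out <- estimateHeritability(s$traits, d, nPerm = 300, seed = 17)
  expect_true(all(out$heritable))    # h2 = 2/3, trivially detectable
  expect_true(all(out$p_perm <= 1 / 301 + 1e-12))
  pooled <- estimateHeritability(s$traits, d, nPerm = 300,
                                 nullMode = "pooled", seed = 17)
  expect_equal(length(unique(pooled$null_threshold)), 1L)
  expect_true(all(pooled$heritable))
})
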