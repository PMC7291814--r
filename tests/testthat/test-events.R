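test_that("definition cases: RI, SE, A3 are classified with exact intervals", {
  # retained intron
  m <- toyModels(list(T1 = rbind(c(1, 100), c(201, 300)),
                      T2 = rbind(c(1, 300))))
  ev <- classifyASEvents(m)
  expect_equal(length(ev), 1L)
  expect_equal(ev$event_type, "RI")
  expect_equal(c(start(ev), end(ev)), c(101, 200))
  expect_equal(ev$inclusion, "T2")   # T2 retains the intron
  expect_equal(ev$exclusion, "T1")

  # skipped exon
  m <- toyModels(list(T1 = rbind(c(1, 100), c(201, 250), c(301, 400)),
                      T2 = rbind(c(1, 100), c(301, 400))))
  ev <- classifyASEvents(m)
  expect_equal(length(ev), 1L)
  expect_equal(ev$event_type, "SE")
  expect_equal(c(start(ev), end(ev)), c(201, 250))
  expect_equal(ev$inclusion, "T1")

  # alternative acceptor on the plus strand (shared donor at 101)
  m <- toyModels(list(T1 = rbind(c(1, 100), c(201, 300)),
                      T2 = rbind(c(1, 100), c(231, 300))))
  ev <- classifyASEvents(m)
  expect_equal(length(ev), 1L)
  expect_equal(ev$event_type, "A3")
  expect_equal(c(start(ev), end(ev)), c(201, 230))
})

test_that("identical exon sets on the minus strand flip A3 to A5", {
  iso <- list(T1 = rbind(c(1, 100), c(201, 300)),
              T2 = rbind(c(1, 100), c(231, 300)))
  evPlus <- classifyASEvents(toyModels(iso, strand = "+"))
  evMinus <- classifyASEvents(toyModels(iso, strand = "-"))
  expect_equal(evPlus$event_type, "A3")
  expect_equal(evMinus$event_type, "A5")
  expect_equal(ranges(evPlus), ranges(evMinus))
})

test_that("a gene whose isoforms jointly realize all five types yields five events", {
  # hand-enumerated fixture: 6-exon base isoform plus one edited isoform
  # per event type, each edit on its own exon slot
  base <- rbind(c(501, 600), c(701, 800), c(901, 1000), c(1101, 1200),
                c(1301, 1400), c(1501, 1600))
  ri <- rbind(c(501, 600), c(701, 1000), c(1101, 1200), c(1301, 1400),
              c(1501, 1600))                         # retains intron 2
  se <- base[-4, ]                                   # skips exon 4
  a5 <- base; a5[5, 2] <- 1380                       # donor shift, exon 5
  ae <- base; ae[1, ] <- c(301, 380)                 # new first exon
  m <- toyModels(list(T1 = base, T2 = ri, T3 = se, T4 = a5, T5 = ae))
  ev <- classifyASEvents(m)
  expect_setequal(ev$event_type, c("RI", "SE", "A5", "AE"))
  expect_equal(length(ev), 4L)
  expect_equal(c(start(ev[ev$event_type == "RI"]),
                 end(ev[ev$event_type == "RI"])), c(801, 900))
  expect_equal(c(start(ev[ev$event_type == "A5"]),
                 end(ev[ev$event_type == "A5"])), c(1381, 1400))
  # adding an acceptor-shifted isoform (exon 6) completes the set
  a3 <- base; a3[6, 1] <- 1531
  m <- toyModels(list(T1 = base, T2 = ri, T3 = se, T4 = a5, T5 = ae,
                      T6 = a3))
  ev <- classifyASEvents(m)
  expect_setequal(ev$event_type, c("RI", "SE", "A5", "A3", "AE"))
  expect_equal(length(ev), 5L)
  # deduplication: the RI is found by several isoform pairs but reported
  # once, with all skipping isoforms accumulated in its exclusion set
  expect_equal(sum(ev$event_type == "RI"), 1L)
  expect_true(all(c("T1", "T3") %in%
    strsplit(ev$exclusion[ev$event_type == "RI"], ",")[[1]]))
})

test_that("classifier matches the brute-force oracle on random gene pairs", {
  set.seed(20)
  for (rep in 1:150) {
    g <- randomGenePair()
    m <- toyModels(list(TA = g$A, TB = g$B), strand = g$strand)
    got <- eventKeysOf(classifyASEvents(m))
    want <- oracleEventKeys(oracleEvents(g$A, g$B, g$strand))
    expect_identical(got, want)
  }
})

test_that("mirroring coordinates and flipping strand maps A3 to A5 and back", {
  set.seed(33)
  M <- 5000L
  for (rep in 1:40) {
    g <- randomGenePair()
    mirror <- function(m) {
      out <- cbind(M - m[, 2], M - m[, 1])
      out[rev(seq_len(nrow(out))), , drop = FALSE]
    }
    flip <- c("+" = "-", "-" = "+")[g$strand]
    ev1 <- classifyASEvents(toyModels(list(TA = g$A, TB = g$B),
                                      strand = g$strand))
    ev2 <- classifyASEvents(toyModels(list(TA = mirror(g$A),
                                           TB = mirror(g$B)),
                                      strand = unname(flip)))
    t1 <- table(factor(ev1$event_type,
                       levels = c("RI", "SE", "A3", "A5", "AE")))
    t2 <- table(factor(ev2$event_type,
                       levels = c("RI", "SE", "A3", "A5", "AE")))
    expect_equal(unname(t1[c("RI", "SE", "AE")]),
                 unname(t2[c("RI", "SE", "AE")]))
    expect_equal(unname(t1["A3"]), unname(t2["A3"]))
    expect_equal(unname(t1["A5"]), unname(t2["A5"]))
  }
})

test_that("junction-support filter keeps junctions by max read count and exempts RI", {
  m <- toyModels(list(T1 = rbind(c(1, 100), c(201, 300)),
                      T2 = rbind(c(1, 300)),
                      T3 = rbind(c(1, 100), c(231, 300))))
  ev <- classifyASEvents(m)  # T2 retains both introns: two RI, one A3
  expect_equal(sort(ev$event_type), c("A3", "RI", "RI"))
  counts <- data.frame(chrom = "chr1", strand = "+",
                       intron_start = c(101, 101, 101, 101),
                       intron_end = c(200, 200, 230, 230),
                       sample = c("s1", "s2", "s1", "s2"),
                       reads = c(5, 0, 1, 1))
  # A3 junction (101-230) max support 1 < 2 but the (101-200) junction of
  # the same event has support 5, so the event survives
  kept <- filterJunctionSupport(ev, counts, minReads = 2)
  expect_equal(sort(kept$event_type), c("A3", "RI", "RI"))
  # with both junctions unsupported the A3 falls, RI is exempt
  counts$reads <- c(1, 1, 1, 1)
  kept <- filterJunctionSupport(ev, counts, minReads = 2)
  expect_equal(sort(kept$event_type), c("RI", "RI"))
  # absent junctions count as zero support
  kept <- filterJunctionSupport(ev, counts[0, ], minReads = 2)
  expect_equal(sort(kept$event_type), c("RI", "RI"))
  # minReads = 0 is the identity
  expect_equal(length(filterJunctionSupport(ev, counts, 0)), length(ev))
})

test_that("RI coverage filter uses the per-sample median over the intron", {
  m <- toyModels(list(T1 = rbind(c(1, 10), c(15, 24)),
                      T2 = rbind(c(1, 24))))
  ev <- classifyASEvents(m)  # RI over 11..14
  covOf <- function(depths) data.frame(chrom = "chr1", pos = 11:14,
                                       sample = "s1", depth = depths)
  expect_equal(length(filterRICoverage(ev, covOf(c(2, 2, 2, 3)), 2)), 1L)
  expect_equal(length(filterRICoverage(ev, covOf(c(0, 0, 10, 10)), 2)), 1L)
  expect_equal(length(filterRICoverage(ev, covOf(c(0, 0, 0, 9)), 2)), 0L)
  # positions absent from the table are depth 0
  part <- data.frame(chrom = "chr1", pos = 13, sample = "s1", depth = 9)
  expect_equal(length(filterRICoverage(ev, part, 2)), 0L)
  # minMedian = 0 is the identity
  expect_equal(length(filterRICoverage(ev, covOf(c(0, 0, 0, 0)), 0)), 1L)
})

test_that("support filters are monotone in their thresholds", {
  set.seed(41)
  st <- generateTranscriptome(simulationConfig(nGenes = 25, seed = 9))
  m <- st$models
  ev <- classifyASEvents(m)
  j <- extractJunctions(m)
  counts <- data.frame(chrom = as.character(seqnames(j)),
                       strand = as.character(strand(j)),
                       intron_start = start(j), intron_end = end(j),
                       sample = "s1",
                       reads = rpois(length(j), 2))
  sizes <- vapply(0:5, function(thr)
    length(filterJunctionSupport(ev, counts, thr)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})
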