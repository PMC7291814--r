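# two-exon coding gene used across projection tests
projModels <- function(strand = "+") {
  toyModels(list(TP = rbind(c(101, 200), c(301, 400))), strand = strand,
            cds = list(TP = rbind(c(101, 200), c(301, 400))))
}

test_that("peptide projection walks the CDS strand-aware and splits on introns", {
  m <- projModels("+")
  gr <- peptideToGenomic(m, "TP", 1, 10)     # CDS nt 1..30
  expect_equal(as.vector(start(gr)), 101)
  expect_equal(as.vector(end(gr)), 130)
  # peptide 30..40 -> CDS nt 88..120, crossing the exon boundary
  gr <- peptideToGenomic(m, "TP", 30, 40)
  expect_equal(as.vector(start(gr)), c(188, 301))
  expect_equal(as.vector(end(gr)), c(200, 320))
  expect_equal(sum(width(gr)), 3 * (40 - 30 + 1))
  # minus strand: the first codons sit at the right-hand genomic end
  mm <- projModels("-")
  gr <- peptideToGenomic(mm, "TP", 1, 10)
  expect_equal(as.vector(start(gr)), 371)
  expect_equal(as.vector(end(gr)), 400)
  # inverse projection recovers the peptide interval
  nt <- genomicToTranscript(mm, "TP", 371, 400, space = "cds")
  expect_equal(ceiling(nt[1] / 3), 1)
  expect_equal(nt[2] / 3, 10)
})

test_that("transcript projection length-conserves and round-trips", {
  m <- toyModels(list(TX = rbind(c(1, 100), c(201, 300))),
                 cds = NULL)
  gr <- transcriptToGenomic(m, "TX", 95, 110)
  expect_equal(as.vector(start(gr)), c(95, 201))
  expect_equal(as.vector(end(gr)), c(100, 210))
  # single-exon site: one interval, length preserved
  gr1 <- transcriptToGenomic(m, "TX", 10, 30)
  expect_equal(length(gr1), 1L)
  expect_equal(width(gr1), 21L)
  # random round trips conserve length and invert exactly
  set.seed(12)
  for (k in 1:25) {
    ex <- randomIsoform(sample(2:5, 1))
    strand <- sample(c("+", "-"), 1)
    mod <- toyModels(list(R = ex), strand = strand)
    L <- sum(ex[, 2] - ex[, 1] + 1)
    a <- sample(L, 1); b <- sample(rep(a:L, 2), 1)
    gr <- transcriptToGenomic(mod, "R", a, b)
    expect_equal(sum(width(gr)), b - a + 1)
    nt <- genomicToTranscript(mod, "R", min(start(gr)), max(end(gr)))
    expect_equal(unname(nt), c(a, b))
  }
})

test_that("reference isoform selection follows CDS length, then tie-breaks", {
  m <- toyModels(list(T1 = rbind(c(1, 800)), T2 = rbind(c(1, 900)),
                      T3 = rbind(c(1, 500))),
                 cds = list(T1 = rbind(c(1, 300)), T2 = rbind(c(1, 450)),
                            T3 = rbind(c(1, 150))))
  expect_equal(selectReferenceIsoform(m, "gene1", "longest_coding"), "T2")
  # equal CDS: longest transcript wins
  m2 <- toyModels(list(T1 = rbind(c(1, 800)), T2 = rbind(c(1, 900))),
                  cds = list(T1 = rbind(c(1, 300)), T2 = rbind(c(1, 300))))
  expect_equal(selectReferenceIsoform(m2, "gene1", "longest_coding"), "T2")
  # no coding isoform: NA (gene skipped upstream)
  m3 <- toyModels(list(T1 = rbind(c(1, 800))))
  expect_true(is.na(selectReferenceIsoform(m3, "gene1", "longest_coding")))
  # major mode: highest median FPKM, lexicographic tie-break
  fp <- matrix(c(5, 5, 5, 5, 5, 5), 2, 3,
               dimnames = list(c("T2", "T1"), paste0("s", 1:3)))
  design <- data.frame(sample_id = paste0("s", 1:3), individual = "A",
                       replicate = 1:3, row = 1, column = 1:3,
                       experiment = "E1")
  se <- SpliceExperiment(fp, design,
                         data.frame(transcript_id = c("T2", "T1"),
                                    gene_id = "gene1"))
  expect_equal(selectReferenceIsoform(m2, "gene1", "major", se), "T1")
})

test_that("feature gain/loss is the set difference against the reference", {
  m <- toyModels(list(T1 = rbind(c(1, 300), c(401, 700)),
                      T2 = rbind(c(1, 300), c(401, 700))),
                 cds = list(T1 = rbind(c(1, 300), c(401, 700)),
                            T2 = rbind(c(1, 300), c(401, 700))))
  # T1 is the reference (equal CDS, equal length, smaller id)
  doms <- data.frame(transcript_id = c("T1", "T2", "T2"),
                     accession = c("PF00076", "PF00076", "PF00515"),
                     pep_start = c(1, 1, 120), pep_end = c(50, 50, 180))
  ch <- featureGainLoss(m, doms, "domain", "longest_coding")
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$direction, "gained")
  expect_equal(ch$feature_id, "PF00515")
  # reference loses a domain the alternative lacks
  doms2 <- data.frame(transcript_id = "T1", accession = "PF00076",
                      pep_start = 1, pep_end = 50)
  ch2 <- featureGainLoss(m, doms2, "domain", "longest_coding")
  expect_equal(ch2$direction, "lost")
  expect_equal(ch2$alt_transcript_id, "T2")
  # features on unknown transcripts are a validation error
  expect_error(featureGainLoss(m, data.frame(transcript_id = "TX",
                                             accession = "PF1",
                                             pep_start = 1, pep_end = 2),
                               "domain", "longest_coding"), "unknown")
})

test_that("gain/loss is antisymmetric under reference swap", {
  m <- toyModels(list(T1 = rbind(c(1, 300), c(401, 700)),
                      T2 = rbind(c(1, 300), c(401, 700))),
                 cds = list(T1 = rbind(c(1, 300), c(401, 700)),
                            T2 = rbind(c(1, 300), c(401, 700))))
  doms <- data.frame(transcript_id = c("T1", "T1", "T2"),
                     accession = c("PFA", "PFB", "PFC"),
                     pep_start = c(1, 60, 10), pep_end = c(50, 90, 40))
  # force the opposite reference through the major mode
  fp <- matrix(c(1, 1, 1, 9, 9, 9), 2, 3, byrow = TRUE,
               dimnames = list(c("T1", "T2"), paste0("s", 1:3)))
  design <- data.frame(sample_id = paste0("s", 1:3), individual = "A",
                       replicate = 1:3, row = 1, column = 1:3,
                       experiment = "E1")
  se <- SpliceExperiment(fp, design,
                         data.frame(transcript_id = c("T1", "T2"),
                                    gene_id = "gene1"))
  chL <- featureGainLoss(m, doms, "domain", "longest_coding")  # ref T1
  chM <- featureGainLoss(m, doms, "domain", "major", se)       # ref T2
  expect_equal(sort(chL$feature_id[chL$direction == "lost"]),
               sort(chM$feature_id[chM$direction == "gained"]))
  expect_equal(sort(chL$feature_id[chL$direction == "gained"]),
               sort(chM$feature_id[chM$direction == "lost"]))
  # a reference isoform never reports changes against itself
  expect_false(any(chL$alt_transcript_id == chL$reference_transcript_id))
})

test_that("event attribution requires overlap and isoform discrimination", {
  # skipped exon whose loss removes a domain
  base <- rbind(c(1, 300), c(401, 500), c(601, 900))
  skip <- base[-2, ]
  m <- toyModels(list(T1 = base, T2 = skip),
                 cds = list(T1 = rbind(c(1, 300), c(401, 500),
                                       c(601, 900)),
                            T2 = rbind(c(1, 300), c(601, 900))))
  ev <- classifyASEvents(m)
  expect_equal(ev$event_type, "SE")
  doms <- data.frame(transcript_id = "T1", accession = "PFX",
                     pep_start = 120, pep_end = 160)  # nt 358..480
  ch <- featureGainLoss(m, doms, "domain", "longest_coding")
  expect_equal(ch$direction, "lost")
  ch <- attributeChangesToEvents(ch, ev)
  expect_equal(ch$attributed_events, ev$event_id)
  # a domain clear of the event is not attributed
  doms2 <- data.frame(transcript_id = "T1", accession = "PFY",
                      pep_start = 1, pep_end = 30)
  ch2 <- attributeChangesToEvents(
    featureGainLoss(m, doms2, "domain", "longest_coding"), ev)
  expect_equal(ch2$attributed_events, "")
  # retained intron inside a domain's intron-spanning projection
  mRI <- toyModels(list(T1 = rbind(c(1, 300), c(401, 700)),
                        T2 = rbind(c(1, 700))),
                   cds = list(T1 = rbind(c(1, 300), c(401, 700)),
                              T2 = rbind(c(1, 699))))
  evRI <- classifyASEvents(mRI)
  expect_equal(evRI$event_type, "RI")
  domsRI <- data.frame(transcript_id = "T2", accession = "PFZ",
                       pep_start = 95, pep_end = 140)  # spans 283..420
  chRI <- attributeChangesToEvents(
    featureGainLoss(mRI, domsRI, "domain", "longest_coding"), evRI)
  expect_equal(nrow(chRI), 1L)
  expect_equal(chRI$attributed_events, evRI$event_id)
})

test_that("consequence summary partitions genes and reports mode overlap", {
  ch <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g1", "g4"),
    reference_mode = c(rep("longest_coding", 4), "major", "major"),
    feature_kind = "domain",
    direction = c("gained", "lost", "gained", "lost", "lost", "gained"))
  out <- consequenceSummary(ch)
  lc <- out$by_class[out$by_class$reference_mode == "longest_coding", ]
  expect_equal(lc$n_genes[lc$direction_class == "both"], 1L)       # g1
  expect_equal(lc$n_genes[lc$direction_class == "gained_only"], 1L) # g2
  expect_equal(lc$n_genes[lc$direction_class == "lost_only"], 1L)   # g3
  expect_equal(out$mode_overlap$n_overlap, 1L)                      # g1
  # the direction classes partition the changed genes
  expect_equal(sum(lc$n_genes), 3L)
})
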