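# Independent brute-force oracles and fixture builders shared by the tests.

# Build a TranscriptModels object from plain exon tables.
# isoforms: named list of data.frames / matrices with columns start, end.
toyModels <- function(isoforms, strand = "+", chrom = "chr1",
                      gene = "gene1", cds = NULL) {
  exl <- lapply(isoforms, function(m) {
    m <- as.matrix(m)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(m[, 1], m[, 2]),
                           strand = strand)
  })
  cdl <- NULL
  if (!is.null(cds)) {
    cdl <- lapply(cds, function(m) {
      m <- as.matrix(m)
      GenomicRanges::GRanges(chrom, IRanges::IRanges(m[, 1], m[, 2]),
                             strand = strand)
    })
    cdl <- GenomicRanges::GRangesList(cdl)
  }
  TranscriptModels(GenomicRanges::GRangesList(exl),
                   data.frame(transcript_id = names(isoforms),
                              gene_id = gene),
                   cdl)
}

# Introns of an exon table, as a data.frame.
oracleIntrons <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) return(data.frame(s = integer(), e = integer()))
  data.frame(s = m[-nrow(m), 2] + 1, e = m[-1, 1] - 1)
}

oracleJuncKey <- function(df) {
  df <- unique(df)
  df <- df[order(df$s, df$e), , drop = FALSE]
  paste(paste0(df$s, "-", df$e), collapse = ";")
}

# Brute-force enumeration of the five event types between two isoforms.
# Deliberately written as plain scans over exon/junction tables, not
# shared with the package implementation.
oracleEvents <- function(A, B, strand) {
  A <- as.matrix(A); B <- as.matrix(B)
  JA <- oracleIntrons(A); JB <- oracleIntrons(B)
  res <- list()
  push <- function(type, s, e, jdf) {
    res[[length(res) + 1]] <<- data.frame(type = type, start = s, end = e,
                                          junctions = oracleJuncKey(jdf))
  }
  overlaps <- function(a1, a2, b1, b2) max(a1, b1) <= min(a2, b2)
  # retained introns, both directions
  for (swap in c(FALSE, TRUE)) {
    J <- if (swap) JB else JA
    other <- if (swap) A else B
    if (nrow(J)) for (r in seq_len(nrow(J))) {
      found <- FALSE
      for (x in seq_len(nrow(other)))
        if (other[x, 1] <= J$s[r] - 1 && other[x, 2] >= J$e[r] + 1)
          found <- TRUE
      if (found) push("RI", J$s[r], J$e[r],
                      data.frame(s = J$s[r], e = J$e[r]))
    }
  }
  # skipped exons, both directions
  for (swap in c(FALSE, TRUE)) {
    X <- if (swap) B else A
    JY <- if (swap) JA else JB
    if (nrow(X) >= 3 && nrow(JY)) for (i in 2:(nrow(X) - 1)) {
      l1 <- X[i - 1, 2] + 1; l2 <- X[i, 1] - 1
      r1 <- X[i, 2] + 1; r2 <- X[i + 1, 1] - 1
      hasSkip <- FALSE
      for (r in seq_len(nrow(JY)))
        if (JY$s[r] == l1 && JY$e[r] == r2) hasSkip <- TRUE
      if (hasSkip)
        push("SE", X[i, 1], X[i, 2],
             data.frame(s = c(l1, r1, l1), e = c(l2, r2, r2)))
    }
  }
  # alternative donors/acceptors: cross pairs of junctions sharing exactly
  # one boundary, with the exons flanking the other boundary overlapping
  if (nrow(JA) && nrow(JB)) for (ra in seq_len(nrow(JA))) {
    for (rb in seq_len(nrow(JB))) {
      sa <- JA$s[ra]; ea <- JA$e[ra]; sb <- JB$s[rb]; eb <- JB$e[rb]
      if (sa == sb && ea != eb) {
        fa <- which(A[, 1] == ea + 1); fb <- which(B[, 1] == eb + 1)
        if (length(fa) && length(fb) &&
            overlaps(A[fa[1], 1], A[fa[1], 2], B[fb[1], 1], B[fb[1], 2])) {
          type <- if (strand == "+") "A3" else "A5"
          push(type, min(ea, eb) + 1, max(ea, eb),
               data.frame(s = c(sa, sb), e = c(ea, eb)))
        }
      }
      if (ea == eb && sa != sb) {
        fa <- which(A[, 2] == sa - 1); fb <- which(B[, 2] == sb - 1)
        if (length(fa) && length(fb) &&
            overlaps(A[fa[1], 1], A[fa[1], 2], B[fb[1], 1], B[fb[1], 2])) {
          type <- if (strand == "+") "A5" else "A3"
          push(type, min(sa, sb), max(sa, sb) - 1,
               data.frame(s = c(sa, sb), e = c(ea, eb)))
        }
      }
    }
  }
  # alternative terminal exons
  if (nrow(A) >= 2 && nrow(B) >= 2 && nrow(JA) && nrow(JB)) {
    sharedJ <- FALSE
    for (ra in seq_len(nrow(JA))) for (rb in seq_len(nrow(JB)))
      if (JA$s[ra] == JB$s[rb] && JA$e[ra] == JB$e[rb]) sharedJ <- TRUE
    clearOf <- function(ex, M) {
      for (x in seq_len(nrow(M)))
        if (overlaps(ex[1], ex[2], M[x, 1], M[x, 2])) return(FALSE)
      TRUE
    }
    touches <- function(ex, M) !clearOf(ex, M)
    if (sharedJ) {
      # left side
      if (clearOf(A[1, ], B) && clearOf(B[1, ], A) &&
          touches(A[2, ], B) && touches(B[2, ], A))
        push("AE", min(A[1, 1], B[1, 1]), max(A[1, 2], B[1, 2]),
             data.frame(s = c(JA$s[1], JB$s[1]), e = c(JA$e[1], JB$e[1])))
      # right side
      ka <- nrow(A); kb <- nrow(B)
      if (clearOf(A[ka, ], B) && clearOf(B[kb, ], A) &&
          touches(A[ka - 1, ], B) && touches(B[kb - 1, ], A))
        push("AE", min(A[ka, 1], B[kb, 1]), max(A[ka, 2], B[kb, 2]),
             data.frame(s = c(JA$s[nrow(JA)], JB$s[nrow(JB)]),
                        e = c(JA$e[nrow(JA)], JB$e[nrow(JB)])))
    }
  }
  if (!length(res))
    return(data.frame(type = character(), start = integer(),
                      end = integer(), junctions = character()))
  unique(do.call(rbind, res))
}

oracleEventKeys <- function(df)
  sort(paste(df$type, df$start, df$end, df$junctions, sep = "|"))

eventKeysOf <- function(events)
  sort(paste(events$event_type, GenomicRanges::start(events),
             GenomicRanges::end(events), events$junctions, sep = "|"))

# Random isoform: k non-overlapping exons with introns of at least 2 nt.
randomIsoform <- function(k, lo = 1, hi = 1500) {
  repeat {
    b <- sort(sample(seq(lo, hi), 2 * k))
    st <- b[seq(1, 2 * k, 2)]
    en <- b[seq(2, 2 * k, 2)]
    if (k < 2 || all(st[-1] > en[-k] + 1)) return(cbind(st, en, deparse.level = 0))
  }
}

# Random 2-isoform gene: second isoform is either an edited copy of the
# first (merge / skip / boundary shift / new terminal exon) or independent.
randomGenePair <- function() {
  kA <- sample(2:6, 1)
  A <- randomIsoform(kA)
  mode <- sample(c("edit", "free"), 1, prob = c(0.6, 0.4))
  if (mode == "free") {
    B <- randomIsoform(sample(1:6, 1))
  } else {
    B <- A
    op <- sample(c("merge", "skip", "shiftL", "shiftR", "newFirst"), 1)
    k <- nrow(B)
    if (op == "merge" && k >= 2) {
      i <- sample(k - 1, 1)
      B <- rbind(B[seq_len(i - 1), , drop = FALSE],
                 c(B[i, 1], B[i + 1, 2]),
                 B[setdiff(seq_len(k), seq_len(i + 1)), , drop = FALSE])
    } else if (op == "skip" && k >= 3) {
      B <- B[-sample(2:(k - 1), 1), , drop = FALSE]
    } else if (op == "shiftL" && k >= 2) {
      i <- sample(2:k, 1)
      room <- B[i, 2] - B[i, 1]
      if (room >= 2) B[i, 1] <- B[i, 1] + sample(room - 1, 1)
    } else if (op == "shiftR" && k >= 2) {
      i <- sample(k - 1, 1)
      room <- B[i, 2] - B[i, 1]
      if (room >= 2) B[i, 2] <- B[i, 2] - sample(room - 1, 1)
    } else if (op == "newFirst" && k >= 3 && B[1, 1] > 30) {
      w <- sample(5:20, 1)
      ne <- B[1, 1] - sample(3:10, 1)
      B[1, ] <- c(max(1, ne - w), ne)
    }
  }
  strand <- sample(c("+", "-"), 1)
  list(A = A, B = B, strand = strand)
}
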