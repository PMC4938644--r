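# Independent brute-force oracles. These re-derive, by exhaustive dynamic
# programming or enumeration, the quantities the package computes with
# seeded/accelerated algorithms; they share no code with the implementation.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# all maximal-scoring ungapped segment pairs on every diagonal, found by
# recursive best-subarray decomposition (no seeding, no x-drop)
oracle_hsps <- function(query, subject, match = 1L, mismatch = -2L,
                        min_score = 22L) {
  one_strand <- function(q, strand) {
    qv <- strsplit(q, "")[[1]]
    sv <- strsplit(subject, "")[[1]]
    nq <- length(qv); ns <- length(sv)
    out <- list()
    for (d in (-(nq - 1L)):(ns - 1L)) {
      qi <- max(1L, 1L - d):min(nq, ns - d)   # query 1-based indices
      if (length(qi) == 0L) next
      si <- qi + d
      sc <- ifelse(qv[qi] == sv[si] & qv[qi] %in% c("A", "C", "G", "T"),
                   match, mismatch)
      segs <- list()
      rec <- function(lo, hi) {
        if (lo > hi) return()
        # Kadane with positions
        best <- -Inf; bi <- lo; bj <- lo
        cur <- 0; ci <- lo
        for (k in lo:hi) {
          if (cur <= 0) { cur <- sc[k]; ci <- k } else cur <- cur + sc[k]
          if (cur > best) { best <- cur; bi <- ci; bj <- k }
        }
        if (best >= min_score)
          segs[[length(segs) + 1L]] <<- c(bi, bj, best)
        if (best > 0) {
          rec(lo, bi - 1L)
          rec(bj + 1L, hi)
        }
      }
      rec(1L, length(sc))
      for (s in segs) {
        i1 <- qi[s[1]]; i2 <- qi[s[2]]
        out[[length(out) + 1L]] <- data.frame(
          q_start = i1 - 1L, q_end = i2, s_start = i1 + d - 1L,
          s_end = i2 + d, score = s[3], strand = strand)
      }
    }
    out
  }
  plus <- one_strand(query, "+")
  minus <- one_strand(oracle_revcomp(query), "-")
  minus <- lapply(minus, function(h) {
    n <- nchar(query)
    qs <- n - h$q_end
    h$q_end <- n - h$q_start
    h$q_start <- qs
    h
  })
  res <- do.call(rbind, c(plus, minus))
  if (is.null(res))
    return(data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      score = integer(), strand = character()))
  res <- unique(res)
  res[order(-res$score, res$q_start, res$s_start), , drop = FALSE]
}

# affine-gap local Smith-Waterman on peptides, score only
oracle_sw_protein <- function(a, b, gap_open = 11, gap_extend = 1,
                              mat = NULL) {
  if (is.null(mat)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  if (n == 0L || m == 0L) return(0)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)   # gap in a (up)
  F_ <- matrix(-Inf, n + 1L, m + 1L)  # gap in b (left)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i - 1L, j] - gap_open - gap_extend,
                     E[i - 1L, j] - gap_extend)
      F_[i, j] <- max(H[i, j - 1L] - gap_open - gap_extend,
                      F_[i, j - 1L] - gap_extend)
      s <- mat[av[i - 1L], bv[j - 1L]]
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# codon-table translation (stops '*', any non-ACGT in a codon 'X')
oracle_translate <- function(nt, frame) {
  s <- if (frame > 0) nt else oracle_revcomp(nt)
  s <- substr(s, abs(frame), nchar(s))
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  codons <- substring(s, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  gc <- Biostrings::GENETIC_CODE
  aa <- ifelse(grepl("[^ACGT]", codons), "X", unname(gc[codons]))
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_translated_best <- function(nt, pep, gap_open = 11, gap_extend = 1) {
  best <- 0; best_frame <- NA_integer_
  for (f in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    aa <- oracle_translate(nt, f)
    if (nchar(aa) == 0L) next
    sc <- oracle_sw_protein(aa, pep, gap_open, gap_extend)
    if (sc > best) { best <- sc; best_frame <- f }
  }
  list(score = best, frame = best_frame)
}

# back-translate a peptide with fixed (arbitrary but valid) codons
oracle_backtranslate <- function(pep) {
  gc <- Biostrings::GENETIC_CODE
  pick <- vapply(split(names(gc), unname(gc)), `[[`, character(1), 1L)
  paste(pick[strsplit(pep, "")[[1]]], collapse = "")
}

random_nt <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# pairs of sequences sharing conserved blocks at low divergence (mutations
# spaced so no long mismatch runs arise), the regime the bridge test targets
random_hsp_instance <- function(n_blocks = 2L, block_len = 60L,
                                spacer = 30L, gc = 0.65) {
  blocks <- replicate(n_blocks, random_nt(block_len, gc))
  subject <- paste(blocks, collapse = "")
  mutate_block <- function(b) {
    ch <- strsplit(b, "")[[1]]
    k <- sample(0:2, 1L)
    if (k > 0) {
      pos <- sort(sample(seq(5L, length(ch) - 5L, by = 7L), min(k, 3L)))
      ch[pos] <- vapply(ch[pos], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
    }
    paste(ch, collapse = "")
  }
  query <- paste(vapply(blocks, mutate_block, character(1)),
                 collapse = random_nt(spacer, gc))
  list(query = query, subject = subject)
}

CANONICAL_AA <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
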