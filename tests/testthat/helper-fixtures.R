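# Small deterministic fixtures built in code.

# an intron whose terminal windows follow the simulator's splice consensus
plant_intron <- function(len, gc = 0.65) {
  cons <- default_splice_consensus()
  w <- cons$windows
  draw <- function(profile) {
    paste(vapply(seq_len(ncol(profile)), function(i)
      sample(c("A", "C", "G", "T"), 1L, prob = profile[, i]), character(1)),
      collapse = "")
  }
  don <- draw(cons$donor[, (w$donor_exon + 1L):ncol(cons$donor),
                         drop = FALSE])
  acc <- draw(cons$acceptor[, seq_len(w$acceptor_intron), drop = FALSE])
  paste0(don, random_nt(len - nchar(don) - nchar(acc), gc), acc)
}

# consensus-drawn donor/acceptor window sequences (full windows)
draw_windows <- function(n, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  cons <- default_splice_consensus()
  profile <- cons[[side]]
  vapply(seq_len(n), function(i)
    paste(vapply(seq_len(ncol(profile)), function(j)
      sample(c("A", "C", "G", "T"), 1L, prob = profile[, j]), character(1)),
      collapse = ""), character(1))
}

# a two-exon gene on a small genome; returns genome, model, and the pieces
two_exon_fixture <- function(e1 = 120L, e2 = 120L, intron = 200L,
                             with_n = FALSE, seed = 42L) {
  withr::with_seed(seed, {
    u <- random_nt(50, 0.65)
    x1 <- random_nt(e1, 0.65)
    i1 <- plant_intron(intron)
    if (with_n) {
      mid <- nchar(i1) %/% 2L
      i1 <- paste0(substr(i1, 1, mid - 10L), strrep("N", 20L),
                   substr(i1, mid + 11L, nchar(i1)))
    }
    x2 <- random_nt(e2, 0.65)
    d <- random_nt(50, 0.65)
    g <- as_genome_assembly(c(chr = paste0(u, x1, i1, x2, d)))
    ex <- data.frame(start = c(50L, 50L + e1 + nchar(i1)),
                     end = c(50L + e1, 50L + e1 + nchar(i1) + e2))
    m <- transcript_model("t1", "chr", "+", ex, g)
    list(genome = g, model = m, e1 = x1, e2 = x2, intron = i1)
  })
}

# hand-built consensus island covering template [core_start, core_end) with
# given tails (island coordinates == template coordinates)
fake_island <- function(template, core_start, core_end, left_tail = "",
                        right_tail = "") {
  cons <- paste0(left_tail,
                 substr(template, core_start + 1L, core_end),
                 right_tail)
  structure(list(core_start = core_start, core_end = core_end,
                 ext_start = core_start - nchar(left_tail),
                 ext_end = core_end + nchar(right_tail),
                 consensus = cons, left_tail = left_tail,
                 right_tail = right_tail,
                 depth = rep(1L, nchar(cons)),
                 agreement = rep(1, nchar(cons)), n_reads = 10L,
                 read_ids = character(), read_rows = integer(),
                 seed = list(position = core_start, side = "start"),
                 low_confidence = FALSE),
            class = "consensus_island")
}

# uniform error-free read tibble tiling a source sequence
tile_reads <- function(source, read_len, depth, prefix = "r",
                       error_rate = 0) {
  n <- ceiling(depth * nchar(source) / read_len)
  start <- sample(nchar(source) - read_len + 1L, n, replace = TRUE)
  seqs <- substring(source, start, start + read_len - 1L)
  flip <- runif(n) < 0.5
  seqs[flip] <- vapply(seqs[flip], oracle_revcomp, character(1))
  if (error_rate > 0) {
    k <- rbinom(n, read_len, error_rate)
    for (i in which(k > 0)) {
      ch <- strsplit(seqs[i], "")[[1]]
      pos <- sample(read_len, k[i])
      ch[pos] <- vapply(ch[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  out <- tibble::tibble(read_id = sprintf("%s%05d", prefix, seq_len(n)),
                        seq = unname(seqs))
  attr(out, "read_length") <- as.integer(read_len)
  out
}

pwm_from_consensus <- function(n = 600L, seed = 11L, cutoff = 11) {
  withr::with_seed(seed, {
    build_pwm(draw_windows(n, "donor"), draw_windows(n, "acceptor"),
              score_cutoff = cutoff)
  })
}
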