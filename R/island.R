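# Local alignment of genomic reads to a transcript object, the start/finish
# boundary signature, and iterative majority-consensus island growth.
# Because alignments are ungapped, island coordinates coincide with template
# coordinates across the whole island, tails included; tail positions simply
# lie outside the aligned (core) interval.

#' Locally align genomic reads to a template
#'
#' Every read is aligned on both strands (ungapped seed-and-extend local
#' alignment) and the best alignment with aligned length at least
#' `min_local_length` and mismatch fraction at most `max_mismatch_frac` is
#' kept. Read coordinates refer to the strand-oriented read; `oriented_seq`
#' holds the full read in template orientation, which is what consensus
#' growth consumes.
#'
#' @param reads tibble with `read_id` and `seq` (e.g. from [load_reads()] or
#'   [simulate_reads()]).
#' @param template nucleotide string (a transcript object).
#' @param min_local_length minimum aligned length to call a local alignment.
#' @param max_mismatch_frac maximum mismatch fraction of the aligned part.
#' @param word_size seed word length for the read aligner.
#' @return tibble with columns `read_id`, `strand`, `read_start`, `read_end`,
#'   `tmpl_start`, `tmpl_end`, `score`, `mismatches`, `oriented_seq`;
#'   attribute `template_length`.
#' @export
local_align_reads <- function(reads, template, min_local_length = 20L,
                              max_mismatch_frac = 0.05, word_size = 12L) {
  stopifnot(nzchar(template))
  df <- as_tibble(cpp_align_reads(reads$seq, template, word_size, 1L, -2L,
                                  12L, as.integer(min_local_length),
                                  max_mismatch_frac))
  out <- tibble(read_id = reads$read_id[df$read],
                strand = df$strand,
                read_start = df$read_start, read_end = df$read_end,
                tmpl_start = df$tmpl_start, tmpl_end = df$tmpl_end,
                score = df$score, mismatches = df$mismatches)
  seqs <- reads$seq[df$read]
  flip <- df$strand == "-"
  seqs[flip] <- revcomp(seqs[flip])
  out$oriented_seq <- seqs
  attr(out, "template_length") <- nchar(template)
  out
}

#' Detect segment boundaries from alignment start/finish pileups
#'
#' Per-position histograms of local-alignment starts and finishes; a position
#' whose count exceeds `seed_enrichment_threshold` times the mean count at
#' interior positions (template termini excluded from the mean) is reported
#' as a boundary signal. At a true junction between discontiguous genomic
#' segments the enrichment approaches `read_length - min_local_length + 1`.
#'
#' @param alignments tibble from [local_align_reads()].
#' @param template_length template length in nt (taken from the alignments
#'   attribute when omitted).
#' @param seed_enrichment_threshold fold-enrichment needed to report a seed.
#' @return tibble of class `boundary_signals` with `position`, `side`,
#'   `count`, `enrichment`; start and finish histograms are attached as
#'   attributes `start_counts` / `finish_counts` (positions 0..L).
#' @export
detect_boundaries <- function(alignments,
                              template_length = attr(alignments,
                                                     "template_length"),
                              seed_enrichment_threshold = 10) {
  stopifnot(nrow(alignments) >= 1L)
  L <- template_length
  starts <- tabulate(alignments$tmpl_start + 1L, nbins = L + 1L)
  finishes <- tabulate(alignments$tmpl_end + 1L, nbins = L + 1L)
  interior <- 2:L                              # positions 1..L-1, 0-based
  mean_start <- mean(starts[interior])
  mean_finish <- mean(finishes[interior])
  enr_start <- if (mean_start > 0) starts / mean_start else
    ifelse(starts > 0, Inf, 0)
  enr_finish <- if (mean_finish > 0) finishes / mean_finish else
    ifelse(finishes > 0, Inf, 0)
  ms <- enr_start >= seed_enrichment_threshold & starts > 0
  mf <- enr_finish >= seed_enrichment_threshold & finishes > 0
  sig <- bind_rows(
    tibble(position = which(ms) - 1L, side = "start", count = starts[ms],
           enrichment = enr_start[ms]),
    tibble(position = which(mf) - 1L, side = "finish",
           count = finishes[mf], enrichment = enr_finish[mf]))
  sig <- arrange(sig, .data$position, .data$side)
  attr(sig, "start_counts") <- starts
  attr(sig, "finish_counts") <- finishes
  attr(sig, "interior_mean") <- c(start = mean_start, finish = mean_finish)
  attr(sig, "template_length") <- L
  class(sig) <- c("boundary_signals", class(sig))
  sig
}

#' Start/finish pileup plot
#'
#' @param object a `boundary_signals` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.boundary_signals <- function(object, ...) {
  L <- attr(object, "template_length")
  df <- bind_rows(
    tibble(position = 0:L, count = attr(object, "start_counts"),
           side = "start"),
    tibble(position = 0:L, count = attr(object, "finish_counts"),
           side = "finish"))
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$count,
                                   colour = .data$side)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::labs(x = "template position", y = "alignment ends") +
    ggplot2::theme_minimal()
}

# Placement offset: template coordinate of the first base of the oriented
# read (may be negative; overhangs simply extend past the core).
.placement <- function(alignments) {
  alignments$tmpl_start - alignments$read_start
}

# Majority consensus over a set of placed reads. Returns extent coordinates,
# consensus string, per-position depth, agreement fraction and, where the
# extent intersects the template, agreement with the template sequence.
.consensus_from_reads <- function(rows, template, consensus_majority) {
  off <- .placement(rows)
  lens <- nchar(rows$oriented_seq)
  ext1 <- min(off)
  ext2 <- max(off + lens)
  W <- ext2 - ext1
  counts <- matrix(0L, nrow = 5L, ncol = W)  # A C G T other
  for (i in seq_len(nrow(rows))) {
    b <- utf8ToInt(rows$oriented_seq[i])
    code <- match(b, utf8ToInt("ACGT"))
    code[is.na(code)] <- 5L
    pos <- off[i] - ext1 + seq_along(code)
    counts[cbind(code, pos)] <- counts[cbind(code, pos)] + 1L
  }
  depth <- colSums(counts)
  # majority with deterministic tie-break: template base inside the template
  # frame, else alphabetically first
  tmpl_codes <- rep(NA_integer_, W)
  tlo <- max(ext1, 0L)
  thi <- min(ext2 - 1L, nchar(template) - 1L)
  if (tlo <= thi) {
    tb <- utf8ToInt(substr(template, tlo + 1L, thi + 1L))
    tmpl_codes[(tlo:thi) - ext1 + 1L] <- match(tb, utf8ToInt("ACGT"))
  }
  maxc <- apply(counts[1:4, , drop = FALSE], 2L, max)
  cons_code <- integer(W)
  for (j in seq_len(W)) {
    if (depth[j] == 0L) { cons_code[j] <- 5L; next }
    tied <- which(counts[1:4, j] == maxc[j])
    if (length(tied) > 1L && !is.na(tmpl_codes[j]) && tmpl_codes[j] %in% tied)
      cons_code[j] <- tmpl_codes[j]
    else cons_code[j] <- tied[1]
  }
  cons <- paste(c("A", "C", "G", "T", "N")[cons_code], collapse = "")
  agree <- ifelse(depth > 0,
                  counts[cbind(pmin(cons_code, 4L), seq_len(W))] / depth, 0)
  agree[cons_code == 5L] <- 0
  list(ext_start = ext1, ext_end = ext2, consensus = cons, depth = depth,
       agreement = agree, counts = counts)
}

# Fraction of a read's placed positions (within the consensus extent) that
# disagree with the consensus; also the overlap width.
.read_vs_consensus <- function(row_seq, row_off, cons) {
  len <- nchar(row_seq)
  lo <- max(row_off, cons$ext_start)
  hi <- min(row_off + len, cons$ext_end)
  if (hi <= lo) return(c(overlap = 0, disagree = 0))
  r <- substr(row_seq, lo - row_off + 1L, hi - row_off)
  cc <- substr(cons$consensus, lo - cons$ext_start + 1L, hi - cons$ext_start)
  mis <- sum(utf8ToInt(r) != utf8ToInt(cc))
  c(overlap = hi - lo, disagree = mis)
}

#' Grow a consensus island from a boundary seed
#'
#' Implements the iterative majority-consensus loop: reads whose alignment
#' boundary sits at the seed are recruited; a per-position majority consensus
#' is called over the placed reads (tails included); recruited reads
#' disagreeing with the consensus at more than `max_mismatch_frac` of their
#' overlapping positions are discarded; unrecruited template-aligned reads
#' that agree with (and possibly extend) the consensus over at least
#' `min_agree_overlap` positions are recruited; and the loop repeats until
#' the recruited set is stable or `max_rounds` is reached. Reads that align
#' to the template only through an internal repeat disagree with the growing
#' tails and are discarded by this loop.
#'
#' @param seed a row of [detect_boundaries()] output (or a list with
#'   `position` and `side`).
#' @param alignments tibble from [local_align_reads()].
#' @param template the template nucleotide string.
#' @param consensus_majority agreement fraction below which a consensus
#'   position is considered unsupported.
#' @param min_agree_overlap minimum overlap with the consensus to judge (and
#'   recruit) a read.
#' @param max_mismatch_frac disagreement fraction above which a read "fits
#'   poorly" and is discarded.
#' @param max_rounds iteration cap.
#' @return a `consensus_island` (list with `core_start`, `core_end`,
#'   `ext_start`, `ext_end`, `consensus`, `left_tail`, `right_tail`, `depth`,
#'   `agreement`, `n_reads`, `read_ids`, `seed`, `low_confidence`) or `NULL`
#'   when no read touches the seed.
#' @export
grow_island <- function(seed, alignments, template,
                        consensus_majority = 0.75, min_agree_overlap = 20L,
                        max_mismatch_frac = 0.05, max_rounds = 50L) {
  if (seed$side == "start")
    rec <- which(alignments$tmpl_start == seed$position)
  else rec <- which(alignments$tmpl_end == seed$position)
  if (length(rec) == 0L) return(NULL)
  banned <- integer()
  off_all <- .placement(alignments)
  for (round in seq_len(max_rounds)) {
    cons <- .consensus_from_reads(alignments[rec, , drop = FALSE], template,
                                  consensus_majority)
    # discard poor fits
    keep <- vapply(rec, function(i) {
      v <- .read_vs_consensus(alignments$oriented_seq[i], off_all[i], cons)
      v["overlap"] == 0 || v["disagree"] <= max_mismatch_frac * v["overlap"]
    }, logical(1))
    banned <- union(banned, rec[!keep])
    rec2 <- rec[keep]
    if (length(rec2) == 0L) return(NULL)
    if (length(rec2) < length(rec)) {
      cons <- .consensus_from_reads(alignments[rec2, , drop = FALSE],
                                    template, consensus_majority)
    }
    # recruit agreeing reads
    cand <- setdiff(seq_len(nrow(alignments)), union(rec2, banned))
    newly <- cand[vapply(cand, function(i) {
      v <- .read_vs_consensus(alignments$oriented_seq[i], off_all[i], cons)
      v["overlap"] >= min_agree_overlap &&
        v["disagree"] <= max_mismatch_frac * v["overlap"]
    }, logical(1))]
    if (length(newly) == 0L && length(rec2) == length(rec)) {
      rec <- rec2
      break
    }
    rec <- c(rec2, newly)
  }
  cons <- .consensus_from_reads(alignments[rec, , drop = FALSE], template,
                                consensus_majority)
  .finish_island(cons, rec, alignments, template, seed, consensus_majority)
}

# Core = maximal run of template-agreeing consensus positions containing the
# aligned footprint of the recruited reads; everything outside is tail.
.finish_island <- function(cons, rec, alignments, template, seed,
                           consensus_majority) {
  L <- nchar(template)
  t1 <- max(cons$ext_start, 0L)
  t2 <- min(cons$ext_end, L)
  anchor <- min(alignments$tmpl_start[rec])      # leftmost aligned position
  anchor2 <- max(alignments$tmpl_end[rec])
  if (t2 <= t1) return(NULL)
  cseg <- substr(cons$consensus, t1 - cons$ext_start + 1L,
                 t2 - cons$ext_start)
  tseg <- substr(template, t1 + 1L, t2)
  match_vec <- utf8ToInt(cseg) == utf8ToInt(tseg)
  # maximal template-matching run containing the aligned footprint midpoint
  mid <- (max(anchor, t1) + min(anchor2, t2) - 1L) %/% 2L - t1 + 1L
  mid <- min(max(mid, 1L), length(match_vec))
  if (!match_vec[mid]) {
    ok <- which(match_vec)
    if (length(ok) == 0L) return(NULL)
    mid <- ok[which.min(abs(ok - mid))]
  }
  lo <- mid; while (lo > 1L && match_vec[lo - 1L]) lo <- lo - 1L
  hi <- mid; while (hi < length(match_vec) && match_vec[hi + 1L]) hi <- hi + 1L
  core_start <- t1 + lo - 1L
  core_end <- t1 + hi
  left_tail <- substr(cons$consensus, 1L, core_start - cons$ext_start)
  right_tail <- substr(cons$consensus, core_end - cons$ext_start + 1L,
                       cons$ext_end - cons$ext_start)
  core_agree <- cons$agreement[(core_start - cons$ext_start + 1L):
                                 (core_end - cons$ext_start)]
  structure(list(core_start = core_start, core_end = core_end,
                 ext_start = cons$ext_start, ext_end = cons$ext_end,
                 consensus = cons$consensus,
                 left_tail = left_tail, right_tail = right_tail,
                 depth = cons$depth, agreement = cons$agreement,
                 n_reads = length(rec), read_ids = alignments$read_id[rec],
                 read_rows = rec,
                 seed = list(position = seed$position, side = seed$side),
                 low_confidence = length(rec) < 3L ||
                   min(core_agree) < consensus_majority),
            class = "consensus_island")
}

#' @export
print.consensus_island <- function(x, ...) {
  cat("<consensus_island> core [", x$core_start, ",", x$core_end,
      ") tails ", nchar(x$left_tail), "/", nchar(x$right_tail),
      " nt, ", x$n_reads, " reads",
      if (x$low_confidence) " (low confidence)", "\n", sep = "")
  invisible(x)
}

#' Grow, merge and order all consensus islands of one template
#'
#' Boundary detection seeds island growth; the template termini act as
#' implicit seeds so terminal segments also produce islands; islands whose
#' cores overlap on the template are merged by re-calling the consensus over
#' the union of their reads.
#'
#' @param reads tibble of genomic reads, or `NULL` when `alignments` given.
#' @param template template nucleotide string.
#' @param alignments optional precomputed [local_align_reads()] result.
#' @param min_local_length,max_mismatch_frac,word_size passed to
#'   [local_align_reads()].
#' @param seed_enrichment_threshold passed to [detect_boundaries()].
#' @param consensus_majority,min_agree_overlap,max_rounds passed to
#'   [grow_island()].
#' @return list of `consensus_island` objects ordered by core start, class
#'   `island_set`, with the alignments attached as attribute.
#' @export
islands_for_template <- function(reads, template, alignments = NULL,
                                 min_local_length = 20L,
                                 max_mismatch_frac = 0.05, word_size = 12L,
                                 seed_enrichment_threshold = 10,
                                 consensus_majority = 0.75,
                                 min_agree_overlap = 20L, max_rounds = 50L) {
  if (is.null(alignments))
    alignments <- local_align_reads(reads, template, min_local_length,
                                    max_mismatch_frac, word_size)
  L <- nchar(template)
  if (nrow(alignments) == 0L) {
    out <- structure(list(), class = "island_set")
    attr(out, "alignments") <- alignments
    attr(out, "template_length") <- L
    return(out)
  }
  sig <- detect_boundaries(alignments, L, seed_enrichment_threshold)
  seeds <- bind_rows(as_tibble(sig)[, c("position", "side")],
                     tibble(position = c(0L, L),
                            side = c("start", "finish")))
  seeds <- distinct(seeds, .data$position, .data$side)
  islands <- list()
  for (i in seq_len(nrow(seeds))) {
    sd <- seeds[i, ]
    # a segment grown from its start seed need not be regrown from its
    # finish seed (and vice versa); repeat jitter shifts core edges by a few
    # nt, hence the tolerance
    dup <- any(vapply(islands, function(x) {
      if (sd$side == "start")
        abs(x$core_start - sd$position) <= 15L && x$core_end > sd$position
      else abs(x$core_end - sd$position) <= 15L && x$core_start < sd$position
    }, logical(1)))
    if (dup) next
    isl <- grow_island(sd, alignments, template, consensus_majority,
                       min_agree_overlap, max_mismatch_frac, max_rounds)
    if (!is.null(isl)) islands[[length(islands) + 1L]] <- isl
  }
  # merge islands with overlapping cores (start- and finish-seeded growth of
  # the same genomic segment converge on the same interval)
  if (length(islands) > 1L) {
    repeat {
      merged <- FALSE
      for (a in seq_along(islands)) {
        for (b in seq_along(islands)) {
          if (b <= a) next
          ia <- islands[[a]]; ib <- islands[[b]]
          ov <- min(ia$core_end, ib$core_end) -
            max(ia$core_start, ib$core_start)
          # substantial core overlap only: distinct adjacent segments can
          # share a few nt of chance direct repeat at the junction
          if (ov >= max(16L, 0.5 * min(ia$core_end - ia$core_start,
                                       ib$core_end - ib$core_start))) {
            rec <- union(ia$read_rows, ib$read_rows)
            cons <- .consensus_from_reads(alignments[rec, , drop = FALSE],
                                          template, consensus_majority)
            mi <- .finish_island(cons, rec, alignments, template,
                                 ia$seed, consensus_majority)
            islands[[a]] <- mi
            islands[[b]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  ord <- order(vapply(islands, `[[`, integer(1), "core_start"))
  out <- structure(islands[ord], class = "island_set")
  attr(out, "alignments") <- alignments
  attr(out, "template_length") <- L
  out
}

#' @export
tidy.island_set <- function(x, ...) {
  if (length(x) == 0L)
    return(tibble(island = integer(), core_start = integer(),
                  core_end = integer(), left_tail_len = integer(),
                  right_tail_len = integer(), n_reads = integer(),
                  mean_depth = double(), low_confidence = logical()))
  bind_rows(lapply(seq_along(x), function(i) {
    isl <- x[[i]]
    tibble(island = i, core_start = isl$core_start, core_end = isl$core_end,
           left_tail_len = nchar(isl$left_tail),
           right_tail_len = nchar(isl$right_tail),
           n_reads = isl$n_reads, mean_depth = mean(isl$depth),
           low_confidence = isl$low_confidence)
  }))
}

#' Island span plot for one template
#'
#' Cores are drawn as thick bars (sequence identical to the template), tails
#' as thin extensions — the per-object diagram style used for diagnosing
#' fused assemblies.
#'
#' @param object an `island_set`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.island_set <- function(object, ...) {
  df <- tidy(object)
  df$ext_start <- df$core_start - df$left_tail_len
  df$ext_end <- df$core_end + df$right_tail_len
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ext_start,
                                       xend = .data$ext_end,
                                       y = .data$island,
                                       yend = .data$island),
                          linewidth = 1, colour = "grey40") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$core_start,
                                       xend = .data$core_end,
                                       y = .data$island,
                                       yend = .data$island),
                          linewidth = 4, colour = "firebrick") +
    ggplot2::labs(x = "template position", y = "island") +
    ggplot2::theme_minimal()
}
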