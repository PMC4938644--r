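# Donor/acceptor position-weight model over annotated splice junctions.
# Scores are "letter heights" in bits: the observed base's frequency times
# the position's information content (2 - Shannon entropy), summed over all
# window positions. Under this convention four invariant dinucleotide
# positions contribute exactly 8 bits.

.BASES <- c("A", "C", "G", "T")

#' Splice-site window extents
#'
#' The donor window covers the exon/intron boundary (`donor_exon` exonic nt
#' then `donor_intron` intronic nt, including the GT); the acceptor window is
#' `acceptor_intron` intronic nt (including the AG) then `acceptor_exon`
#' exonic nt. All sequences are in mRNA (strand) orientation.
#'
#' @param donor_exon,donor_intron,acceptor_intron,acceptor_exon window side
#'   lengths in nt; the intronic sides must cover the terminal dinucleotides.
#' @return list of class `splice_windows`.
#' @export
splice_windows <- function(donor_exon = 3L, donor_intron = 6L,
                           acceptor_intron = 6L, acceptor_exon = 3L) {
  stopifnot(donor_intron >= 2L, acceptor_intron >= 2L,
            donor_exon >= 0L, acceptor_exon >= 0L)
  structure(list(donor_exon = as.integer(donor_exon),
                 donor_intron = as.integer(donor_intron),
                 acceptor_intron = as.integer(acceptor_intron),
                 acceptor_exon = as.integer(acceptor_exon)),
            class = "splice_windows")
}

#' Collect donor and acceptor training windows from annotated junctions
#'
#' Windows are strand-oriented; sites whose windows leave the contig, contain
#' N, or whose intron is shorter than the two intronic sides are skipped and
#' counted.
#'
#' @param models named list of [transcript_model()] objects.
#' @param genome a `genome_assembly`.
#' @param windows a [splice_windows()] object.
#' @param include_n_flagged keep junctions that splice out an N-island
#'   (excluded by default: those are the junctions under test).
#' @return list with character vectors `donor` and `acceptor` and the
#'   `skipped` count.
#' @export
extract_training_junctions <- function(models, genome,
                                       windows = splice_windows(),
                                       include_n_flagged = FALSE) {
  w <- windows
  donors <- character(); acceptors <- character(); skipped <- 0L
  for (m in models) {
    jx <- m$junctions
    if (!include_n_flagged) jx <- jx[!jx$n_flag, , drop = FALSE]
    if (nrow(jx) == 0L) next
    contig <- genome[[m$contig]]
    for (k in seq_len(nrow(jx))) {
      is <- jx$intron_start[k]; ie <- jx$intron_end[k]
      if (ie - is < w$donor_intron + w$acceptor_intron) {
        skipped <- skipped + 1L; next
      }
      if (m$strand == "+") {
        d1 <- is - w$donor_exon; d2 <- is + w$donor_intron
        a1 <- ie - w$acceptor_intron; a2 <- ie + w$acceptor_exon
        if (d1 < 0L || a2 > nchar(contig)) { skipped <- skipped + 1L; next }
        don <- substr(contig, d1 + 1L, d2)
        acc <- substr(contig, a1 + 1L, a2)
      } else {
        d1 <- ie - w$donor_intron; d2 <- ie + w$donor_exon
        a1 <- is - w$acceptor_exon; a2 <- is + w$acceptor_intron
        if (a1 < 0L || d2 > nchar(contig)) { skipped <- skipped + 1L; next }
        don <- revcomp(substr(contig, d1 + 1L, d2))
        acc <- revcomp(substr(contig, a1 + 1L, a2))
      }
      if (grepl("N", don, fixed = TRUE) || grepl("N", acc, fixed = TRUE)) {
        skipped <- skipped + 1L; next
      }
      donors <- c(donors, don); acceptors <- c(acceptors, acc)
    }
  }
  list(donor = donors, acceptor = acceptors, skipped = skipped)
}

.freq_matrix <- function(seqs, len, pseudocount) {
  stopifnot(all(nchar(seqs) == len))
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = len)
  counts <- vapply(seq_len(len), function(i)
    tabulate(factor(chars[i, ], levels = .BASES), nbins = 4L), integer(4))
  counts <- counts + pseudocount
  sweep(counts, 2L, colSums(counts), "/") # 4 x len, rows A C G T
}

.ic <- function(freq) {
  h <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  2 - h
}

#' Build the splice position-weight model
#'
#' @param donor_seqs,acceptor_seqs training windows from
#'   [extract_training_junctions()] (at least 10 each).
#' @param windows the [splice_windows()] the sequences follow.
#' @param pseudocount added to every base count before normalising (default 0
#'   so invariant columns score exactly 2 bits).
#' @param score_cutoff high-confidence cutoff in bits.
#' @return list of class `splice_pwm` with frequency matrices, per-position
#'   information content, `max_score` and the cutoff.
#' @export
build_pwm <- function(donor_seqs, acceptor_seqs, windows = splice_windows(),
                      pseudocount = 0, score_cutoff = 11) {
  if (length(donor_seqs) < 10L || length(acceptor_seqs) < 10L)
    stop("need at least 10 donor and 10 acceptor training sites")
  dlen <- windows$donor_exon + windows$donor_intron
  alen <- windows$acceptor_intron + windows$acceptor_exon
  dfreq <- .freq_matrix(donor_seqs, dlen, pseudocount)
  afreq <- .freq_matrix(acceptor_seqs, alen, pseudocount)
  rownames(dfreq) <- rownames(afreq) <- .BASES
  dic <- .ic(dfreq); aic <- .ic(afreq)
  max_score <- sum(apply(dfreq, 2, max) * dic) + sum(apply(afreq, 2, max) * aic)
  structure(list(windows = windows, donor_freq = dfreq, acceptor_freq = afreq,
                 donor_ic = dic, acceptor_ic = aic,
                 training_count = c(donor = length(donor_seqs),
                                    acceptor = length(acceptor_seqs)),
                 pseudocount = pseudocount, score_cutoff = score_cutoff,
                 max_score = max_score),
            class = "splice_pwm")
}

.score_side <- function(seqs, freq, ic) {
  len <- nrow(freq) * 0 + ncol(freq)
  if (any(nchar(seqs) != len))
    stop("window length mismatch: expected ", len, " nt")
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = len)
  sc <- numeric(length(seqs))
  for (i in seq_len(len)) {
    b <- match(chars[i, ], .BASES)           # N -> NA -> contributes 0
    contrib <- ifelse(is.na(b), 0, freq[cbind(b, i)] * ic[i])
    sc <- sc + contrib
  }
  sc
}

#' Score candidate junctions in bits
#'
#' Vectorised over candidates: `score = sum_i p_i(b_i) * IC_i` over all donor
#' and acceptor window positions; an observed N contributes 0 at its
#' position.
#'
#' @param donor_seq,acceptor_seq character vectors of candidate windows
#'   (equal length, matching the model's window extents).
#' @param pwm a [build_pwm()] model.
#' @return numeric vector of scores in bits.
#' @export
score_junction <- function(donor_seq, acceptor_seq, pwm) {
  stopifnot(length(donor_seq) == length(acceptor_seq))
  if (length(donor_seq) == 0L) return(numeric())
  .score_side(toupper(donor_seq), pwm$donor_freq, pwm$donor_ic) +
    .score_side(toupper(acceptor_seq), pwm$acceptor_freq, pwm$acceptor_ic)
}

#' Two-step high-confidence splice test
#'
#' TRUE iff the intron-terminal dinucleotides are literally GT (donor) and AG
#' (acceptor) *and* the information-content score reaches the model's cutoff.
#'
#' @inheritParams score_junction
#' @return logical vector.
#' @export
high_confidence <- function(donor_seq, acceptor_seq, pwm) {
  w <- pwm$windows
  donor_seq <- toupper(donor_seq); acceptor_seq <- toupper(acceptor_seq)
  gt <- substr(donor_seq, w$donor_exon + 1L, w$donor_exon + 2L) == "GT"
  ag <- substr(acceptor_seq, w$acceptor_intron - 1L, w$acceptor_intron) == "AG"
  sc <- score_junction(donor_seq, acceptor_seq, pwm)
  gt & ag & sc >= pwm$score_cutoff
}

#' Summed score contribution of the GT/AG dinucleotide positions
#'
#' @param pwm a [build_pwm()] model.
#' @return the score in bits a GT..AG candidate collects from the four
#'   intron-terminal dinucleotide positions alone.
#' @export
dinucleotide_score <- function(pwm) {
  w <- pwm$windows
  dpos <- w$donor_exon + 1:2
  apos <- c(w$acceptor_intron - 1L, w$acceptor_intron)
  sum(pwm$donor_freq[cbind(match(c("G", "T"), .BASES), dpos)] *
        pwm$donor_ic[dpos]) +
    sum(pwm$acceptor_freq[cbind(match(c("A", "G"), .BASES), apos)] *
          pwm$acceptor_ic[apos])
}

#' @export
print.splice_pwm <- function(x, ...) {
  cat("<splice_pwm> trained on", x$training_count[["donor"]], "donor /",
      x$training_count[["acceptor"]], "acceptor sites; total IC",
      round(sum(x$donor_ic) + sum(x$acceptor_ic), 2), "bits; max score",
      round(x$max_score, 2), "bits; cutoff", x$score_cutoff, "bits\n")
  invisible(x)
}

#' @export
tidy.splice_pwm <- function(x, ...) {
  side_tbl <- function(freq, ic, side) {
    df <- as.data.frame(as.table(freq))
    names(df) <- c("base", "position", "prob")
    df$position <- as.integer(df$position)
    df$side <- side
    df$ic <- ic[df$position]
    df$height <- df$prob * df$ic
    as_tibble(df[, c("side", "position", "base", "prob", "ic", "height")])
  }
  bind_rows(side_tbl(x$donor_freq, x$donor_ic, "donor"),
            side_tbl(x$acceptor_freq, x$acceptor_ic, "acceptor"))
}

#' @export
glance.splice_pwm <- function(x, ...) {
  tibble(n_donor = x$training_count[["donor"]],
         n_acceptor = x$training_count[["acceptor"]],
         total_ic = sum(x$donor_ic) + sum(x$acceptor_ic),
         max_score = x$max_score,
         dinucleotide_score = dinucleotide_score(x),
         score_cutoff = x$score_cutoff, pseudocount = x$pseudocount)
}

#' Logo-style plot of a splice model
#'
#' Stacked letter heights (frequency times information content, in bits) per
#' window position for donor and acceptor sides.
#'
#' @param object a `splice_pwm`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.splice_pwm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$height,
                                   fill = .data$base)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::facet_wrap(~side, scales = "free_x") +
    ggplot2::labs(x = "window position", y = "letter height (bits)") +
    ggplot2::theme_minimal()
}

#' Export a splice model as JSON
#'
#' Stores windows, frequencies, information content, cutoff and the policy
#' assumptions (window extents and pseudocount are package defaults, not
#' values fixed by any annotation standard).
#'
#' @param pwm a `splice_pwm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm_json <- function(pwm, path) {
  obj <- list(windows = unclass(pwm$windows),
              donor_freq = pwm$donor_freq, acceptor_freq = pwm$acceptor_freq,
              donor_ic = pwm$donor_ic, acceptor_ic = pwm$acceptor_ic,
              training_count = as.list(pwm$training_count),
              pseudocount = pwm$pseudocount,
              score_cutoff = pwm$score_cutoff, max_score = pwm$max_score,
              assumptions = list(
                window_extents = "package default, tunable",
                pseudocount_policy = "default 0 so invariant columns score 2 bits"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export the position-weight matrix as TSV (for external logo plotting)
#'
#' @param pwm a `splice_pwm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm_tsv <- function(pwm, path) {
  utils::write.table(tidy(pwm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
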