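# Translated-alignment improvement test with scrambled-insert control:
# does the insert of a bridge improve the protein alignment of the flanks to
# a pre-selected homologous peptide, beyond what scrambling can do?

#' Parameters for gapped protein local alignment
#'
#' @param matrix substitution matrix name (a matrix shipped with Biostrings).
#' @param gap_open,gap_extend non-negative gap penalties.
#' @param min_anchor_score minimum flanks-only bit score required to accept
#'   that query and subject share a common peptide.
#' @param x_drop extension drop-off in raw score units: gapped extension
#'   from an ungapped diagonal anchor is pruned wherever its running score
#'   falls this far below the best so far, as in seeded translated
#'   aligners. Long non-matching stretches therefore terminate an alignment
#'   instead of being bridged, which is what keeps the scrambled-insert
#'   control flat. The default 11 sits just below the cost of any gap move
#'   (open 11 + extend 1 = 12), so default extensions are effectively
#'   ungapped: gap ladders that stitch composition-matched residues of a
#'   scrambled insert together are impossible. Raising x_drop above 12
#'   admits short indels at the price of a noisier scrambled null.
#' @return list of class `protein_align_params`.
#' @export
protein_align_params <- function(matrix = "BLOSUM62", gap_open = 11,
                                 gap_extend = 1, min_anchor_score = 40,
                                 x_drop = 11) {
  stopifnot(gap_open >= 0, gap_extend >= 0, x_drop > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend,
                 min_anchor_score = min_anchor_score, x_drop = x_drop),
            class = "protein_align_params")
}

# Karlin-Altschul parameters for gapped BLOSUM62 with gap 11/1; raw scores
# convert to the bit scores reported by translated-search tools, the scale
# on which the improvement threshold is defined (a single coincidental
# high-scoring residue pair is ~+11 raw but only ~4 bits, which is why a
# 10-bit increase is a meaningful ceiling for scrambled controls).
.KA_LAMBDA <- 0.267
.KA_LOGK <- log(0.041)

#' Convert a raw translated-alignment score to BLAST-style bits
#'
#' Uses the standard Karlin-Altschul parameters of gapped BLOSUM62 with gap
#' penalties 11/1 (lambda 0.267, K 0.041); non-positive raw scores map to 0.
#'
#' @param raw numeric raw score(s).
#' @return numeric bit score(s).
#' @export
bit_score <- function(raw) {
  ifelse(raw <= 0, 0, (.KA_LAMBDA * raw - .KA_LOGK) / log(2))
}

.blosum_cache <- new.env(parent = emptyenv())

.get_matrix <- function(name) {
  if (is.null(.blosum_cache[[name]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .blosum_cache[[name]] <- e[[name]]
  }
  .blosum_cache[[name]]
}

# Six-frame translation; stop codons stay as '*' (scores the matrix minimum
# against every residue), codons containing N (or anything non-ACGT) become
# 'X'. Plain codon-table lookup over the standard genetic code.
.translate_one <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  codons <- substring(s, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.translate_frames <- function(nt) {
  frames <- list()
  rc <- revcomp(nt)
  for (f in 1:3) {
    for (src in c(1L, -1L)) {
      s <- if (src == 1L) nt else rc
      frames[[as.character(src * f)]] <-
        .translate_one(substr(s, f, nchar(s)))
    }
  }
  frames
}

#' Best translated local alignment of a nucleotide query to one peptide
#'
#' Scores all six reading frames of `query` against the single subject
#' peptide under HSP semantics: every maximal ungapped diagonal segment
#' anchors a gapped extension that is pruned at the x-drop bound, and the
#' best anchored alignment wins. Unconstrained local alignment would
#' instead bridge long non-matching stretches (banking composition-driven
#' chains), which destroys the scrambled-insert null the conservation test
#' relies on.
#'
#' @param query nucleotide string (length >= 3).
#' @param subject_pep peptide string.
#' @param params a [protein_align_params()] object.
#' @return list with `score` (0 when nothing aligns) and `frame` (+1..+3,
#'   -1..-3).
#' @export
translated_best_score <- function(query, subject_pep,
                                  params = protein_align_params()) {
  if (nchar(query) < 3L) stop("query shorter than one codon")
  frames <- .translate_frames(query)
  mat <- .get_matrix(params$matrix)
  enc <- function(x) {
    i <- match(strsplit(x, "", fixed = TRUE)[[1]], rownames(mat))
    i[is.na(i)] <- match("X", rownames(mat))
    i - 1L
  }
  s_enc <- enc(toupper(subject_pep))
  best <- list(score = 0, frame = 1L)
  for (f in names(frames)) {
    aa <- frames[[f]]
    if (nchar(aa) == 0L) next
    sc <- cpp_translated_hsp_score(enc(aa), s_enc, mat, params$gap_open,
                                   params$gap_extend, params$x_drop,
                                   8)
    if (sc > best$score) best <- list(score = sc, frame = as.integer(f))
  }
  best
}

# Permute the codons of `insert` in reading frame `frame` (amino acids are
# permuted and their original codons travel with them).
.scramble_insert <- function(insert, frame) {
  s <- if (frame > 0) insert else revcomp(insert)
  off <- abs(frame) - 1L
  head_nt <- substr(s, 1L, off)
  body <- substr(s, off + 1L, nchar(s))
  ncod <- nchar(body) %/% 3L
  tail_nt <- substr(body, 3L * ncod + 1L, nchar(body))
  if (ncod > 1L) {
    codons <- substring(body, 3L * (seq_len(ncod) - 1L) + 1L,
                        3L * seq_len(ncod))
    body <- paste(c(sample(codons), tail_nt), collapse = "")
  } else body <- paste0(body)
  out <- paste0(head_nt, body)
  if (frame > 0) out else revcomp(out)
}

#' Translated-alignment improvement test with scrambled control
#'
#' Builds the extended query `flank_left + insert + flank_right` (S1) and the
#' flanks-only query (S2) and compares their best translated scores against
#' one pre-selected subject peptide. As a control the insert's amino acids
#' are randomly permuted (codons carried along, in the insert's best reading
#' frame) `n_scrambles` times (S3). All scores are reported in BLAST-style
#' bits (see [bit_score()]), the scale on which the 10-point improvement
#' threshold is defined. The verdict is `conserved` when
#' `S1 - S2 > improvement_threshold` while no scrambled replicate improves by
#' more than the threshold; `no_common_subject` when the flanks alone fail
#' the anchor score.
#'
#' @param flank_left,flank_right the two HSP query segments, in object order.
#' @param insert the object sequence strictly between the HSPs (non-empty).
#' @param subject_pep the pre-selected homologous peptide.
#' @param params a [protein_align_params()] object.
#' @param n_scrambles number of scrambled replicates.
#' @param improvement_threshold bit-score increase that counts as
#'   significant.
#' @param seed optional integer; fixes the scramble permutations.
#' @return list of class `improvement_result` with elements `s1`, `s2`, `s3`
#'   (vector), `delta`, `max_scrambled_delta`, `verdict`, `frame`.
#' @export
improvement_test <- function(flank_left, flank_right, insert, subject_pep,
                             params = protein_align_params(),
                             n_scrambles = 20L, improvement_threshold = 10,
                             seed = NULL) {
  if (nchar(insert) == 0L) stop("empty insert")
  extended <- paste0(flank_left, insert, flank_right)
  flanks <- paste0(flank_left, flank_right)
  s1 <- bit_score(translated_best_score(extended, subject_pep,
                                        params)$score)
  s2 <- bit_score(translated_best_score(flanks, subject_pep,
                                        params)$score)
  ins_frame <- translated_best_score(insert, subject_pep, params)
  frame <- if (ins_frame$score > 0) ins_frame$frame else 1L
  run <- function() {
    vapply(seq_len(n_scrambles), function(i) {
      scr <- .scramble_insert(insert, frame)
      bit_score(translated_best_score(paste0(flank_left, scr, flank_right),
                                      subject_pep, params)$score)
    }, numeric(1))
  }
  s3 <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  delta <- s1 - s2
  max_sd <- if (length(s3)) max(s3) - s2 else NA_real_
  verdict <- if (s2 < params$min_anchor_score) "no_common_subject"
  else if (delta > improvement_threshold &&
           isTRUE(max_sd <= improvement_threshold)) "conserved"
  else "not_conserved"
  structure(list(s1 = s1, s2 = s2, s3 = s3, delta = delta,
                 max_scrambled_delta = max_sd, verdict = verdict,
                 frame = frame,
                 improvement_threshold = improvement_threshold),
            class = "improvement_result")
}

#' @export
print.improvement_result <- function(x, ...) {
  cat("<improvement_result> S1=", x$s1, " S2=", x$s2, " delta=", x$delta,
      " max scrambled delta=", round(x$max_scrambled_delta, 1),
      " -> ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.improvement_result <- function(x, ...) {
  tibble(replicate = seq_along(x$s3), s3 = x$s3,
         scrambled_delta = x$s3 - x$s2)
}

#' @export
glance.improvement_result <- function(x, ...) {
  tibble(s1 = x$s1, s2 = x$s2, delta = x$delta,
         max_scrambled_delta = x$max_scrambled_delta,
         n_scrambles = length(x$s3), verdict = x$verdict)
}

#' Pick the proteome peptide anchored by the flanks
#'
#' Runs [translated_best_score()] of the flanks-only query against every
#' peptide and returns the id of the best hit (or `NA` when none reaches the
#' anchor score).
#'
#' @param flanks_nt nucleotide string of the concatenated HSP segments.
#' @param proteome named character vector of peptides.
#' @param params a [protein_align_params()] object.
#' @return list with `subject_id` (or `NA`) and `score`.
#' @export
select_subject_peptide <- function(flanks_nt, proteome,
                                   params = protein_align_params()) {
  if (length(proteome) == 0L)
    return(list(subject_id = NA_character_, score = 0))
  scores <- vapply(proteome, function(p)
    bit_score(translated_best_score(flanks_nt, p, params)$score),
    numeric(1))
  i <- which.max(scores)
  if (scores[i] < params$min_anchor_score)
    list(subject_id = NA_character_, score = scores[i])
  else list(subject_id = names(proteome)[i], score = scores[i])
}
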