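# Ungapped local alignment of transcript objects to reference spliced
# transcripts, and the separated-HSP bridge / half-bridge test.

#' Parameters for ungapped nucleotide alignment
#'
#' BLASTN-like defaults. `word_size` is the exact-match seed length,
#' `x_drop` the two-sided extension drop-off and `min_score` the HSP
#' reporting threshold under the `match`/`mismatch` scores.
#'
#' @param match,mismatch per-column scores (`match > 0 > mismatch`).
#' @param word_size exact seed word length (>= 4).
#' @param x_drop extension drop-off in score units.
#' @param min_score minimum HSP score reported.
#' @return a list of class `align_params`.
#' @export
align_params <- function(match = 1L, mismatch = -2L, word_size = 11L,
                         x_drop = 10L, min_score = 22L) {
  stopifnot(match > 0, mismatch < 0, word_size >= 4)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 word_size = as.integer(word_size),
                 x_drop = as.integer(x_drop),
                 min_score = as.integer(min_score)),
            class = "align_params")
}

#' Ungapped local alignment (all maximal HSPs, both query strands)
#'
#' Exact word seeding followed by two-sided x-drop extension on each seeded
#' diagonal; every maximal-scoring ungapped segment pair with score at or
#' above `params$min_score` is reported once. Coordinates are 0-based
#' half-open on the *original* query and on the subject; `strand == "-"`
#' means the reverse complement of `query[q_start, q_end)` aligns to
#' `subject[s_start, s_end)`.
#'
#' @param query,subject nucleotide strings (non-empty).
#' @param params an [align_params()] object.
#' @return tibble with columns `q_start`, `q_end`, `s_start`, `s_end`,
#'   `strand`, `score`, `length`, `mismatches`, `identity`, sorted by
#'   descending score.
#' @export
ungapped_local_align <- function(query, subject, params = align_params()) {
  stopifnot(nzchar(query), nzchar(subject))
  one <- function(q, strand) {
    df <- cpp_ungapped_hsps(q, subject, params$word_size, params$match,
                            params$mismatch, params$x_drop, params$min_score)
    df <- as_tibble(df)
    if (strand == "-" && nrow(df) > 0L) {
      n <- nchar(query)
      qs <- n - df$q_end
      df$q_end <- n - df$q_start
      df$q_start <- qs
    }
    df$strand <- strand
    df
  }
  out <- bind_rows(one(query, "+"), one(revcomp(query), "-"))
  out <- distinct(out, .data$q_start, .data$q_end, .data$s_start,
                  .data$s_end, .data$strand, .keep_all = TRUE)
  out$length <- out$q_end - out$q_start
  out$identity <- ifelse(out$length > 0,
                         (out$length - out$mismatches) / out$length, NA_real_)
  arrange(out, desc(.data$score), .data$q_start)
}

#' Align many transcript objects to many reference transcripts
#'
#' Convenience wrapper over [ungapped_local_align()] producing one HSP table
#' with `object_id` and `transcript_id` columns.
#'
#' @param objects named character vector of transcript-object sequences.
#' @param models named list of [transcript_model()] objects (their spliced
#'   sequences are the subjects).
#' @param params an [align_params()] object.
#' @return tibble of HSPs.
#' @export
align_objects <- function(objects, models, params = align_params()) {
  rows <- list()
  for (oid in names(objects)) {
    for (m in models) {
      h <- ungapped_local_align(objects[[oid]], m$spliced, params)
      if (nrow(h) > 0L) {
        h$object_id <- oid
        h$transcript_id <- m$transcript_id
        rows[[length(rows) + 1L]] <- h
      }
    }
  }
  if (length(rows) == 0L)
    return(tibble(q_start = integer(), q_end = integer(), s_start = integer(),
                  s_end = integer(), strand = character(), score = integer(),
                  length = integer(), mismatches = integer(),
                  identity = double(), object_id = character(),
                  transcript_id = character()))
  bind_rows(rows)
}

# Best bridge pair for one junction from one object's same-strand HSPs.
# Chance direct repeats at the junction let the flanking HSPs extend a few
# nt past the spliced position, so the two HSPs may overlap slightly on the
# subject (and, mirrored, on the query); `trim_overlap` trims the
# lower-scoring HSP back to non-overlap before re-testing. Pairs still
# overlapping after trimming, or with an empty query insert, are rejected:
# a bridge needs extra object sequence strictly between its HSPs.
# Maximise summed score; ties broken by smaller query insert, then position.
.best_bridge <- function(h, p, strand, slack = 10L, trim_overlap = TRUE) {
  left <- h[h$s_start <= p - 1L & h$s_end <= p + slack, , drop = FALSE]
  right <- h[h$s_end >= p + 1L & h$s_start >= p - slack, , drop = FALSE]
  if (nrow(left) == 0L || nrow(right) == 0L) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(left))) for (j in seq_len(nrow(right))) {
    a <- left[i, ]; b <- right[j, ]
    ov <- a$s_end - b$s_start
    if (ov > 0L) {
      if (!trim_overlap) next
      if (a$score <= b$score) {               # trim a's junction-facing end
        a$s_end <- a$s_end - ov
        if (strand == "+") a$q_end <- a$q_end - ov
        else a$q_start <- a$q_start + ov
        a$score <- a$score - ov
      } else {
        b$s_start <- b$s_start + ov
        if (strand == "+") b$q_start <- b$q_start + ov
        else b$q_end <- b$q_end - ov
        b$score <- b$score - ov
      }
      if (a$s_end - a$s_start < 1L || b$s_end - b$s_start < 1L) next
    }
    if (strand == "+") {
      if (b$q_start <= a$q_end) next        # query overlap or empty insert
      ins <- c(a$q_end, b$q_start)
    } else {
      if (a$q_start <= b$q_end) next
      ins <- c(b$q_end, a$q_start)
    }
    cand <- list(left = a, right = b, insert = ins,
                 score = a$score + b$score, ins_len = ins[2] - ins[1])
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score && cand$ins_len < best$ins_len) ||
        (cand$score == best$score && cand$ins_len == best$ins_len &&
         cand$left$q_start < best$left$q_start))
      best <- cand
  }
  best
}

#' Classify the junctions of one reference transcript against object HSPs
#'
#' Implements the separated-HSP test. Per transcript object (in its best
#' orientation against this subject) each junction receives one status:
#'
#' * `covered` — one HSP strictly contains the junction's spliced position
#'   with at least one aligned nt on each side;
#' * `bridged` — two HSPs, non-overlapping in query and subject, one ending
#'   at/before and one starting at/after the junction, with at least 1 nt of
#'   object sequence strictly between them (the insert);
#' * `half_bridged` — only at N-flagged junctions: a single HSP ending within
#'   `half_bridge_max_gap` of the junction whose unaligned object tail on the
#'   junction side exceeds `half_bridge_min_tail_frac` of the object length;
#' * `no_information` otherwise (such rows are not emitted here; see
#'   [aggregate_junction_table()]).
#'
#' @param hsps tibble from [align_objects()] (any subset; rows for other
#'   transcripts are ignored).
#' @param model the subject [transcript_model()].
#' @param objects named character vector of object sequences (used for insert
#'   extraction and tail fractions).
#' @param half_bridge_max_gap max distance (nt, spliced coordinates) between
#'   HSP end and junction for a half-bridge.
#' @param half_bridge_min_tail_frac minimum unaligned tail fraction of the
#'   object for a half-bridge.
#' @param bridge_overlap_slack how far (nt) an HSP may extend past the
#'   junction through a chance direct repeat and still count as flanking.
#' @param trim_overlap trim the lower-scoring HSP of a subject-overlapping
#'   pair back to non-overlap and re-test (direct-repeat guard); with
#'   `FALSE` such pairs are rejected outright.
#' @return tibble of per-object junction calls; `insert_seq` is reported in
#'   mRNA (subject) orientation, `insert_q_start`/`insert_q_end` on the
#'   original object.
#' @export
classify_junctions <- function(hsps, model, objects,
                               half_bridge_max_gap = 50L,
                               half_bridge_min_tail_frac = 0.6,
                               bridge_overlap_slack = 10L,
                               trim_overlap = TRUE) {
  if ("transcript_id" %in% names(hsps))
    hsps <- hsps[hsps$transcript_id == model$transcript_id, , drop = FALSE]
  jx <- model$junctions
  out <- list()
  if (nrow(jx) == 0L || nrow(hsps) == 0L) return(.empty_calls())
  for (oid in unique(hsps$object_id)) {
    h_all <- hsps[hsps$object_id == oid, , drop = FALSE]
    totals <- tapply(h_all$score, h_all$strand, sum)
    strand <- names(totals)[which.max(totals)]          # best orientation
    h <- h_all[h_all$strand == strand, , drop = FALSE]
    olen <- nchar(objects[[oid]])
    for (k in seq_len(nrow(jx))) {
      p <- jx$spliced_pos[k]
      status <- "no_information"
      ins_seq <- NA_character_; ins_q <- c(NA_integer_, NA_integer_)
      sup_score <- NA_integer_
      hl <- list(NA_integer_, NA_integer_, NA_integer_, NA_integer_)
      hr <- hl
      br <- .best_bridge(h, p, strand, bridge_overlap_slack, trim_overlap)
      cov <- h[h$s_start <= p - 1L & h$s_end >= p + 1L, , drop = FALSE]
      if (!is.null(br)) {
        status <- "bridged"
        raw <- substr(objects[[oid]], br$insert[1] + 1L, br$insert[2])
        ins_seq <- if (strand == "+") raw else revcomp(raw)
        ins_q <- br$insert
        sup_score <- br$score
        hl <- list(br$left$q_start, br$left$q_end, br$left$s_start,
                   br$left$s_end)
        hr <- list(br$right$q_start, br$right$q_end, br$right$s_start,
                   br$right$s_end)
      } else if (nrow(cov) > 0L) {
        status <- "covered"
        b <- cov[which.max(cov$score), ]
        sup_score <- b$score
        hl <- list(b$q_start, b$q_end, b$s_start, b$s_end)
      } else if (jx$n_flag[k]) {
        # half-bridge: one HSP near the junction, long tail toward the island
        tails <- numeric(0); scores <- integer(0); idx <- integer(0)
        for (i in seq_len(nrow(h))) {
          a <- h[i, ]
          if (p - a$s_end >= 0L && p - a$s_end <= half_bridge_max_gap) {
            tl <- if (strand == "+") olen - a$q_end else a$q_start
          } else if (a$s_start - p >= 0L &&
                     a$s_start - p <= half_bridge_max_gap) {
            tl <- if (strand == "+") a$q_start else olen - a$q_end
          } else next
          tails <- c(tails, tl / olen); scores <- c(scores, a$score)
          idx <- c(idx, i)
        }
        ok <- which(tails > half_bridge_min_tail_frac)
        if (length(ok) > 0L) {
          status <- "half_bridged"
          b <- h[idx[ok[which.max(scores[ok])]], ]
          sup_score <- b$score
          hl <- list(b$q_start, b$q_end, b$s_start, b$s_end)
        }
      }
      if (status != "no_information")
        out[[length(out) + 1L]] <- tibble(
          transcript_id = model$transcript_id, junction_index = k,
          spliced_pos = p, n_flag = jx$n_flag[k], object_id = oid,
          status = status, strand = strand, score = sup_score,
          insert_len = if (is.na(ins_q[1])) NA_integer_ else
            as.integer(ins_q[2] - ins_q[1]),
          insert_seq = ins_seq,
          insert_q_start = as.integer(ins_q[1]),
          insert_q_end = as.integer(ins_q[2]),
          l_q_start = hl[[1]], l_q_end = hl[[2]],
          l_s_start = hl[[3]], l_s_end = hl[[4]],
          r_q_start = hr[[1]], r_q_end = hr[[2]],
          r_s_start = hr[[3]], r_s_end = hr[[4]])
    }
  }
  if (length(out) == 0L) .empty_calls() else bind_rows(out)
}

.empty_calls <- function() {
  tibble(transcript_id = character(), junction_index = integer(),
         spliced_pos = integer(), n_flag = logical(), object_id = character(),
         status = character(), strand = character(), score = integer(),
         insert_len = integer(), insert_seq = character(),
         insert_q_start = integer(), insert_q_end = integer(),
         l_q_start = integer(), l_q_end = integer(), l_s_start = integer(),
         l_s_end = integer(), r_q_start = integer(), r_q_end = integer(),
         r_s_start = integer(), r_s_end = integer())
}

.status_levels <- c("bridged", "covered", "half_bridged", "no_information")

#' Aggregate junction calls across objects into a per-junction table
#'
#' One row per junction of every model; conflicting calls from different
#' objects resolve by the precedence `bridged > covered > half_bridged >
#' no_information` (ties by supporting score), and disagreement is flagged in
#' `conflict`. Summary counts by N-flag and status are attached as attribute
#' `"summary"` and available through [glance()].
#'
#' @param calls tibble from [classify_junctions()] (possibly several models).
#' @param models named list of the models the calls refer to.
#' @return tibble of class `junction_table`.
#' @export
aggregate_junction_table <- function(calls, models) {
  base <- bind_rows(lapply(models, function(m) {
    if (nrow(m$junctions) == 0L) return(NULL)
    tibble(transcript_id = m$transcript_id,
           junction_index = m$junctions$junction_index,
           spliced_pos = m$junctions$spliced_pos,
           n_flag = m$junctions$n_flag)
  }))
  if (is.null(base) || nrow(base) == 0L)
    base <- tibble(transcript_id = character(), junction_index = integer(),
                   spliced_pos = integer(), n_flag = logical())
  picked <- NULL
  if (nrow(calls) > 0L) {
    calls$.rank <- match(calls$status, .status_levels)
    picked <- calls %>%
      group_by(.data$transcript_id, .data$junction_index) %>%
      mutate(conflict = length(unique(.data$status)) > 1L) %>%
      arrange(.data$.rank, desc(.data$score)) %>%
      slice(1) %>%
      ungroup() %>%
      select("transcript_id", "junction_index", "status", "object_id",
             "strand", "score", "insert_len", "insert_seq",
             "insert_q_start", "insert_q_end", "l_q_start", "l_q_end",
             "l_s_start", "l_s_end", "r_q_start", "r_q_end", "r_s_start",
             "r_s_end", "conflict")
  }
  out <- base
  if (!is.null(picked)) out <- left_join(base, picked,
                                         by = c("transcript_id",
                                                "junction_index"))
  if (!"status" %in% names(out)) out$status <- NA_character_
  out$status[is.na(out$status)] <- "no_information"
  if (!"conflict" %in% names(out)) out$conflict <- FALSE
  out$conflict[is.na(out$conflict)] <- FALSE
  smry <- out %>% count(.data$n_flag, .data$status, name = "n_junctions")
  attr(out, "summary") <- smry
  class(out) <- c("junction_table", class(out))
  out
}

#' @export
glance.junction_table <- function(x, ...) {
  s <- attr(x, "summary")
  tidyr::pivot_wider(s, names_from = "status", values_from = "n_junctions",
                     values_fill = 0L)
}
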