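# The splicing test: enumerate the constrained join positions between
# sequential consensus islands, score splice-site consensus in the island
# tails on both strands, and assemble same-strand connected islands.

# Island sequence over template coordinates [start, end), N-padded where the
# island's consensus does not reach.
.island_substr <- function(island, start, end) {
  if (end <= start) return("")
  lo <- max(start, island$ext_start)
  hi <- min(end, island$ext_end)
  mid <- if (hi > lo)
    substr(island$consensus, lo - island$ext_start + 1L,
           hi - island$ext_start) else ""
  paste0(strrep("N", max(0L, lo - start)), mid,
         strrep("N", max(0L, end - max(hi, start))))
}

#' Enumerate candidate join positions between two sequential islands
#'
#' Because sequential islands share no sequence outside the template frame,
#' the position where their genomic segments must be joined to reconstitute
#' the template is fixed to a single nucleotide — unless a direct repeat
#' spans the junction, in which case a k-nt repeat admits k+1 offsets (the
#' template-matching cores of the two islands overlap by exactly k).
#'
#' @param left,right `consensus_island` objects adjacent in template order
#'   (`left$core_start <= right$core_start`).
#' @param template the template string (unused beyond validation; the cores
#'   already encode template agreement).
#' @return list of class `join_candidate` with `offsets` (template
#'   positions), `ambiguity`, `direct_repeat_len`, `gap` (TRUE when the cores
#'   do not meet) and `truncated` (repeat window clipped by an island edge).
#' @export
find_join_offsets <- function(left, right, template = NULL) {
  if (left$core_start > right$core_start)
    stop("islands are not in template order")
  if (left$core_end < right$core_start) {
    return(structure(list(offsets = integer(), ambiguity = 0L,
                          direct_repeat_len = NA_integer_, gap = TRUE,
                          truncated = FALSE),
                     class = "join_candidate"))
  }
  offs <- right$core_start:left$core_end
  k <- left$core_end - right$core_start
  truncated <- left$core_end >= left$ext_end ||
    right$core_start <= right$ext_start
  structure(list(offsets = as.integer(offs), ambiguity = length(offs),
                 direct_repeat_len = as.integer(k), gap = FALSE,
                 truncated = truncated),
            class = "join_candidate")
}

#' Score splice-site consensus at the candidate join positions
#'
#' For each offset and each strand, donor and acceptor windows are built from
#' the island consensus sequences (core plus tails; positions outside an
#' island are N-padded and score 0) and scored against the splice model. On
#' the plus strand the donor comes from the upstream (left) island's right
#' side and the acceptor from the downstream (right) island's left side;
#' mirrored and reverse-complemented on the minus strand. The best-scoring
#' offset per strand is returned (ties to the smallest offset).
#'
#' @param candidate a [find_join_offsets()] result.
#' @param left,right the islands the candidate joins.
#' @param pwm a [build_pwm()] splice model.
#' @return tibble with one row per strand: `strand`, `offset`, `donor_seq`,
#'   `acceptor_seq`, `score`, `high_confidence`, `ambiguity`,
#'   `direct_repeat_len`.
#' @export
call_splice <- function(candidate, left, right, pwm) {
  w <- pwm$windows
  if (candidate$gap || length(candidate$offsets) == 0L)
    return(tibble(strand = character(), offset = integer(),
                  donor_seq = character(), acceptor_seq = character(),
                  score = double(), high_confidence = logical(),
                  ambiguity = integer(), direct_repeat_len = integer()))
  rows <- list()
  for (o in candidate$offsets) {
    don_plus <- .island_substr(left, o - w$donor_exon, o + w$donor_intron)
    acc_plus <- .island_substr(right, o - w$acceptor_intron,
                               o + w$acceptor_exon)
    don_minus <- revcomp(.island_substr(right, o - w$donor_intron,
                                        o + w$donor_exon))
    acc_minus <- revcomp(.island_substr(left, o - w$acceptor_exon,
                                        o + w$acceptor_intron))
    rows[[length(rows) + 1L]] <- tibble(
      strand = c("+", "-"), offset = o,
      donor_seq = c(don_plus, don_minus),
      acceptor_seq = c(acc_plus, acc_minus),
      score = score_junction(c(don_plus, don_minus),
                             c(acc_plus, acc_minus), pwm),
      high_confidence = high_confidence(c(don_plus, don_minus),
                                        c(acc_plus, acc_minus), pwm))
  }
  all <- bind_rows(rows)
  best <- all %>%
    group_by(.data$strand) %>%
    arrange(desc(.data$high_confidence), desc(.data$score), .data$offset) %>%
    slice(1) %>%
    ungroup()
  best$ambiguity <- candidate$ambiguity
  best$direct_repeat_len <- candidate$direct_repeat_len
  arrange(best, .data$strand)
}

#' Assemble connected islands from per-junction splice calls
#'
#' A connected island is a maximal run of sequential islands whose
#' consecutive junctions all carry same-strand high-confidence splice calls.
#' A single run spanning the template certifies the object as producible by
#' splicing; multiple runs indicate a suspected track-crossing fusion; a
#' strand flip between runs indicates a fusion with strand switch; junctions
#' high-confidence on both strands are retained on both and flagged
#' ambiguous.
#'
#' @param islands an `island_set` (ordered by template position).
#' @param splice_calls list of [call_splice()] tibbles, one per adjacent
#'   junction (length `length(islands) - 1`).
#' @return list of class `connected_islands` with `runs` (list of island
#'   index vectors), `run_strands`, `junction_calls` (all calls with a
#'   `junction` column), and `diagnostics`.
#' @export
build_connected_islands <- function(islands, splice_calls) {
  n <- length(islands)
  stopifnot(length(splice_calls) == max(0L, n - 1L))
  jc <- if (n > 1L)
    bind_rows(lapply(seq_along(splice_calls), function(j) {
      x <- splice_calls[[j]]
      if (nrow(x) > 0L) x$junction <- j
      x
    })) else tibble()
  strand_sets <- lapply(seq_len(max(0L, n - 1L)), function(j) {
    x <- splice_calls[[j]]
    if (nrow(x) == 0L) character() else x$strand[x$high_confidence]
  })
  runs <- list(); run_strands <- character()
  if (n > 0L) {
    cur <- 1L
    allowed <- c("+", "-")
    cur_calls <- character()
    for (j in seq_len(max(0L, n - 1L))) {
      nxt <- intersect(allowed, strand_sets[[j]])
      if (length(nxt) > 0L) {
        allowed <- nxt
        cur <- c(cur, j + 1L)
        cur_calls <- c(cur_calls, nxt[1])
      } else {
        runs[[length(runs) + 1L]] <- cur
        run_strands <- c(run_strands, .run_strand(allowed, cur_calls))
        cur <- j + 1L
        allowed <- c("+", "-")
        cur_calls <- character()
      }
    }
    runs[[length(runs) + 1L]] <- cur
    run_strands <- c(run_strands, .run_strand(allowed, cur_calls))
  }
  ambiguous <- which(vapply(strand_sets, function(s)
    all(c("+", "-") %in% s), logical(1)))
  diagnostics <- list(
    n_islands = n, n_connected = length(runs),
    spans_whole_template = length(runs) == 1L,
    fusion_suspected = length(runs) > 1L,
    strand_flip = length(runs) > 1L &&
      any(run_strands[-1] != run_strands[-length(run_strands)] &
            run_strands[-1] != "." &
            run_strands[-length(run_strands)] != "."),
    ambiguous_junctions = ambiguous)
  structure(list(runs = runs, run_strands = run_strands,
                 junction_calls = jc, diagnostics = diagnostics),
            class = "connected_islands")
}

# The run's strand: the single allowed strand, else the majority strand of
# its member calls; "." for a singleton run with no calls.
.run_strand <- function(allowed, cur_calls) {
  if (length(cur_calls) == 0L) return(".")
  if (length(allowed) == 1L) return(allowed)
  names(sort(table(cur_calls), decreasing = TRUE))[1]
}

#' @export
print.connected_islands <- function(x, ...) {
  d <- x$diagnostics
  cat("<connected_islands> ", d$n_islands, " island(s) -> ", d$n_connected,
      " connected island(s)",
      if (d$fusion_suspected) " [suspected fusion]",
      if (d$strand_flip) " [strand flip]",
      if (length(d$ambiguous_junctions)) " [ambiguous junction]", "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.connected_islands <- function(x, ...) {
  if (length(x$runs) == 0L)
    return(tibble(run = integer(), strand = character(),
                  first_island = integer(), last_island = integer(),
                  n_islands = integer()))
  tibble(run = seq_along(x$runs), strand = x$run_strands,
         first_island = vapply(x$runs, min, integer(1)),
         last_island = vapply(x$runs, max, integer(1)),
         n_islands = lengths(x$runs))
}

#' @export
glance.connected_islands <- function(x, ...) {
  d <- x$diagnostics
  tibble(n_islands = d$n_islands, n_connected = d$n_connected,
         spans_whole_template = d$spans_whole_template,
         fusion_suspected = d$fusion_suspected,
         strand_flip = d$strand_flip,
         n_ambiguous_junctions = length(d$ambiguous_junctions))
}

#' Resolve a bridged junction into hidden-exon records
#'
#' Islands whose cores lie within the bridge's insert interval on the object
#' and that belong to the same connected island as the flanking
#' reference-matching islands become hidden-exon calls: for each, the exon
#' boundaries are the splice-selected join offsets of its two junctions, the
#' exon sequence is the island consensus between them (reported in mRNA
#' orientation), and the donor/acceptor windows and scores are attached.
#' Bridges whose insert has no overlapping island, or whose insert islands
#' fail the splicing test, are reported as unresolved rather than as exons.
#'
#' @param call one row of a [classify_junctions()] table with status
#'   `bridged`.
#' @param islands the object's `island_set`.
#' @param connected the object's [build_connected_islands()] result.
#' @param slack tolerance (nt) when matching island cores to the insert
#'   interval (direct repeats can shift core edges).
#' @return list of class `hidden_exon_call` with `status` one of
#'   `hidden_exons`, `splice_fail`, `unresolved_bridge`, and `exons` (a
#'   tibble, possibly empty).
#' @export
resolve_hidden_exons <- function(call, islands, connected, slack = 20L) {
  stopifnot(call$status == "bridged")
  a <- call$insert_q_start; b <- call$insert_q_end
  info <- tidy(islands)
  empty <- tibble(exon_index = integer(), tmpl_start = integer(),
                  tmpl_end = integer(), seq_mrna = character(),
                  donor_seq = character(), acceptor_seq = character(),
                  donor_score = double(), acceptor_score = double(),
                  left_tail = character(), right_tail = character())
  ins_idx <- which(info$core_start >= a - slack & info$core_end <= b + slack)
  if (length(ins_idx) == 0L)
    return(structure(list(status = "unresolved_bridge", exons = empty,
                          transcript_id = call$transcript_id,
                          junction_index = call$junction_index,
                          object_id = call$object_id),
                     class = "hidden_exon_call"))
  lo <- min(ins_idx) - 1L; hi <- max(ins_idx) + 1L
  run_ok <- any(vapply(connected$runs, function(r)
    all(seq(max(lo, 1L), min(hi, length(islands))) %in% r), logical(1)))
  flanks_ok <- lo >= 1L && hi <= length(islands)
  jc <- connected$junction_calls
  pick <- function(j, strand) {
    x <- jc[jc$junction == j & jc$strand == strand & jc$high_confidence, ]
    if (nrow(x) == 0L) NULL else x[1, ]
  }
  strand <- if (length(connected$runs) > 0L) {
    ri <- which(vapply(connected$runs, function(r) ins_idx[1] %in% r,
                       logical(1)))[1]
    connected$run_strands[ri]
  } else "."
  if (!flanks_ok || !run_ok || strand == ".")
    return(structure(list(status = "splice_fail", exons = empty,
                          transcript_id = call$transcript_id,
                          junction_index = call$junction_index,
                          object_id = call$object_id),
                     class = "hidden_exon_call"))
  rows <- list()
  ok <- TRUE
  for (i in ins_idx) {
    cl <- pick(i - 1L, strand)  # junction left of island i
    cr <- pick(i, strand)       # junction right of island i
    if (is.null(cl) || is.null(cr)) { ok <- FALSE; break }
    o1 <- cl$offset; o2 <- cr$offset
    isl <- islands[[i]]
    seq_t <- .island_substr(isl, o1, o2)
    # donor/acceptor of the exon's own boundaries, mRNA sense
    if (strand == "+") {
      acc <- cl; don <- cr
      seq_m <- seq_t
    } else {
      acc <- cr; don <- cl
      seq_m <- revcomp(seq_t)
    }
    rows[[length(rows) + 1L]] <- tibble(
      exon_index = NA_integer_, tmpl_start = o1, tmpl_end = o2,
      seq_mrna = seq_m,
      donor_seq = don$donor_seq, acceptor_seq = acc$acceptor_seq,
      donor_score = don$score, acceptor_score = acc$score,
      left_tail = isl$left_tail, right_tail = isl$right_tail)
  }
  if (!ok)
    return(structure(list(status = "splice_fail", exons = empty,
                          transcript_id = call$transcript_id,
                          junction_index = call$junction_index,
                          object_id = call$object_id),
                     class = "hidden_exon_call"))
  exons <- bind_rows(rows)
  # number left-to-right in mRNA order
  exons <- if (strand == "+") arrange(exons, .data$tmpl_start) else
    arrange(exons, desc(.data$tmpl_start))
  exons$exon_index <- seq_len(nrow(exons))
  structure(list(status = "hidden_exons", exons = exons, strand = strand,
                 transcript_id = call$transcript_id,
                 junction_index = call$junction_index,
                 object_id = call$object_id),
            class = "hidden_exon_call")
}

#' @export
print.hidden_exon_call <- function(x, ...) {
  cat("<hidden_exon_call> ", x$transcript_id, " junction ",
      x$junction_index, ": ", x$status,
      if (x$status == "hidden_exons")
        paste0(" (", nrow(x$exons), " exon(s))"), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.hidden_exon_call <- function(x, ...) {
  if (nrow(x$exons) == 0L) return(x$exons)
  mutate(x$exons, transcript_id = x$transcript_id,
         junction_index = x$junction_index, object_id = x$object_id,
         .before = 1)
}
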