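# End-to-end orchestration: bridge test -> island consensus -> splice model
# -> splicing test -> (optional) conservation test, plus N-island verdicts,
# flanking-island extension calls and report writing.

#' Pipeline parameter bundle
#'
#' Collects the stage parameters with the package defaults; every value is
#' echoed into the run report.
#'
#' @param align an [align_params()] object.
#' @param windows a [splice_windows()] object.
#' @param score_cutoff splice high-confidence cutoff in bits.
#' @param pwm_pseudocount pseudocount for [build_pwm()].
#' @param half_bridge_max_gap,half_bridge_min_tail_frac half-bridge criteria.
#' @param min_local_length,max_mismatch_frac,read_word_size read-alignment
#'   parameters.
#' @param seed_enrichment_threshold boundary-seed fold enrichment.
#' @param consensus_majority,min_agree_overlap,max_rounds island-growth
#'   parameters.
#' @param protein a [protein_align_params()] object.
#' @param n_scrambles,improvement_threshold conservation-test parameters.
#' @param flank_distance flanking-island distance in nt.
#' @param seed integer seed for the scramble RNG.
#' @return list of class `exonpatch_params`.
#' @export
exonpatch_params <- function(align = align_params(),
                             windows = splice_windows(),
                             score_cutoff = 11,
                             pwm_pseudocount = 0,
                             half_bridge_max_gap = 50L,
                             half_bridge_min_tail_frac = 0.6,
                             min_local_length = 20L,
                             max_mismatch_frac = 0.05,
                             read_word_size = 12L,
                             seed_enrichment_threshold = 10,
                             consensus_majority = 0.75,
                             min_agree_overlap = 20L,
                             max_rounds = 50L,
                             protein = protein_align_params(),
                             n_scrambles = 20L,
                             improvement_threshold = 10,
                             flank_distance = 100L,
                             seed = 1L) {
  structure(as.list(environment()), class = "exonpatch_params")
}

# island + splicing-test analysis of one transcript object
.analyse_object <- function(template, reads, pwm, p) {
  islands <- islands_for_template(
    reads, template,
    min_local_length = p$min_local_length,
    max_mismatch_frac = p$max_mismatch_frac,
    word_size = p$read_word_size,
    seed_enrichment_threshold = p$seed_enrichment_threshold,
    consensus_majority = p$consensus_majority,
    min_agree_overlap = p$min_agree_overlap,
    max_rounds = p$max_rounds)
  n <- length(islands)
  calls <- if (n > 1L) lapply(seq_len(n - 1L), function(j) {
    cand <- find_join_offsets(islands[[j]], islands[[j + 1L]], template)
    call_splice(cand, islands[[j]], islands[[j + 1L]], pwm)
  }) else list()
  connected <- build_connected_islands(islands, calls)
  list(islands = islands, splice_calls = calls, connected = connected)
}

#' Run the full hidden-exon discovery pipeline
#'
#' Classifies every junction of every model against the transcript objects
#' (separated-HSP test), trains the splice model on the annotation's
#' non-N-flagged junctions (unless `pwm` is supplied), runs the island
#' consensus and splicing test on every object with an HSP, resolves bridged
#' N-flagged junctions into hidden-exon records, applies the conservation
#' test when a proteome is given, and classifies flanking-island extensions.
#'
#' @param assembly the (N-containing) `genome_assembly` under scrutiny.
#' @param models named list of [transcript_model()] objects on `assembly`.
#' @param objects named character vector of transcript-object sequences.
#' @param genomic_reads tibble of genomic reads (`read_id`, `seq`).
#' @param proteome optional named character vector of homolog peptides.
#' @param params an [exonpatch_params()] bundle.
#' @param pwm optional pre-built [build_pwm()] model.
#' @return list of class `exonpatch_report`; see the report elements
#'   `n_islands`, `junctions`, `hidden_exons`, `island_verdicts`,
#'   `object_diagnostics`, `conservation`, `extensions`, `params`.
#' @export
run_exonpatch <- function(assembly, models, objects, genomic_reads,
                          proteome = NULL, params = exonpatch_params(),
                          pwm = NULL) {
  p <- params
  islands_tbl <- find_n_islands(assembly, models, p$flank_distance)
  if (is.null(pwm)) {
    train <- extract_training_junctions(models, assembly, p$windows,
                                        include_n_flagged = FALSE)
    pwm <- build_pwm(train$donor, train$acceptor, p$windows,
                     pseudocount = p$pwm_pseudocount,
                     score_cutoff = p$score_cutoff)
  }
  hsps <- align_objects(objects, models, p$align)
  calls <- bind_rows(lapply(models, function(m)
    classify_junctions(hsps, m, objects, p$half_bridge_max_gap,
                       p$half_bridge_min_tail_frac)))
  junctions <- aggregate_junction_table(calls, models)

  analysed_ids <- intersect(names(objects), unique(hsps$object_id))
  analyses <- lapply(analysed_ids, function(oid)
    .analyse_object(objects[[oid]], genomic_reads, pwm, p))
  names(analyses) <- analysed_ids
  object_diag <- bind_rows(lapply(analysed_ids, function(oid) {
    g <- glance(analyses[[oid]]$connected)
    g$object_id <- oid
    g
  }))

  # hidden-exon resolution for bridged N-flagged junctions
  hx_rows <- list(); hx_calls <- list()
  bridged <- junctions[junctions$status == "bridged" & junctions$n_flag, ,
                       drop = FALSE]
  for (i in seq_len(nrow(bridged))) {
    row <- bridged[i, ]
    an <- analyses[[row$object_id]]
    if (is.null(an)) next
    hx <- resolve_hidden_exons(row, an$islands, an$connected)
    hx_calls[[length(hx_calls) + 1L]] <- hx
    t <- tidy(hx)
    if (nrow(t) > 0L) hx_rows[[length(hx_rows) + 1L]] <- t
  }
  hidden_exons <- if (length(hx_rows)) bind_rows(hx_rows) else
    tibble(transcript_id = character(), junction_index = integer(),
           object_id = character(), exon_index = integer(),
           tmpl_start = integer(), tmpl_end = integer(),
           seq_mrna = character(), donor_seq = character(),
           acceptor_seq = character(), donor_score = double(),
           acceptor_score = double(), left_tail = character(),
           right_tail = character())
  resolution <- bind_rows(
    tibble(transcript_id = character(), junction_index = integer(),
           object_id = character(), resolution = character(),
           n_exons = integer()),
    lapply(hx_calls, function(h)
      tibble(transcript_id = h$transcript_id,
             junction_index = h$junction_index, object_id = h$object_id,
             resolution = h$status,
             n_exons = nrow(h$exons))))

  # conservation test per bridged N-flagged junction
  conservation <- .run_conservation(bridged, objects, proteome, p)

  # per-island verdicts
  island_verdicts <- .island_verdicts(islands_tbl, junctions, resolution)

  extensions <- classify_flanking_extensions(models, islands_tbl, objects,
                                             hsps, analyses, proteome, p)

  structure(list(n_islands = islands_tbl, junctions = junctions,
                 pwm = pwm, hidden_exons = hidden_exons,
                 resolution = resolution,
                 island_verdicts = island_verdicts,
                 object_diagnostics = object_diag,
                 conservation = conservation, extensions = extensions,
                 analyses = analyses, params = p),
            class = "exonpatch_report")
}

.run_conservation <- function(bridged, objects, proteome, p) {
  empty <- tibble(transcript_id = character(), junction_index = integer(),
                  object_id = character(), subject_id = character(),
                  s1 = double(), s2 = double(), max_s3 = double(),
                  delta = double(), verdict = character())
  if (nrow(bridged) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(bridged))) {
    row <- bridged[i, ]
    obj <- objects[[row$object_id]]
    a <- row$insert_q_start; b <- row$insert_q_end
    # flanks are the two HSP query segments in object order
    if (row$l_q_start <= row$r_q_start) {
      flank_left <- substr(obj, row$l_q_start + 1L, row$l_q_end)
      flank_right <- substr(obj, row$r_q_start + 1L, row$r_q_end)
    } else {
      flank_left <- substr(obj, row$r_q_start + 1L, row$r_q_end)
      flank_right <- substr(obj, row$l_q_start + 1L, row$l_q_end)
    }
    insert <- substr(obj, a + 1L, b)
    if (is.null(proteome)) {
      rows[[i]] <- tibble(transcript_id = row$transcript_id,
                          junction_index = row$junction_index,
                          object_id = row$object_id,
                          subject_id = NA_character_, s1 = NA_real_,
                          s2 = NA_real_, max_s3 = NA_real_, delta = NA_real_,
                          verdict = "not_tested")
      next
    }
    sel <- select_subject_peptide(paste0(flank_left, flank_right), proteome,
                                  p$protein)
    if (is.na(sel$subject_id)) {
      rows[[i]] <- tibble(transcript_id = row$transcript_id,
                          junction_index = row$junction_index,
                          object_id = row$object_id,
                          subject_id = NA_character_, s1 = NA_real_,
                          s2 = sel$score, max_s3 = NA_real_,
                          delta = NA_real_, verdict = "no_common_subject")
      next
    }
    res <- improvement_test(flank_left, flank_right, insert,
                            proteome[[sel$subject_id]], p$protein,
                            n_scrambles = p$n_scrambles,
                            improvement_threshold = p$improvement_threshold,
                            seed = p$seed + i)
    rows[[i]] <- tibble(transcript_id = row$transcript_id,
                        junction_index = row$junction_index,
                        object_id = row$object_id,
                        subject_id = sel$subject_id, s1 = res$s1,
                        s2 = res$s2, max_s3 = max(res$s3),
                        delta = res$delta, verdict = res$verdict)
  }
  bind_rows(rows)
}

.island_verdicts <- function(islands_tbl, junctions, resolution) {
  intr <- islands_tbl[islands_tbl$context == "intronic", , drop = FALSE]
  if (nrow(intr) == 0L)
    return(tibble(contig = character(), start = integer(), end = integer(),
                  host_transcript = character(), host_intron = integer(),
                  junction_status = character(), verdict = character()))
  out <- lapply(seq_len(nrow(intr)), function(i) {
    r <- intr[i, ]
    j <- junctions[junctions$transcript_id == r$host_transcript &
                     junctions$junction_index == r$host_intron, ,
                   drop = FALSE]
    status <- if (nrow(j) > 0L) j$status[1] else "no_information"
    res <- resolution[resolution$transcript_id == r$host_transcript &
                        resolution$junction_index == r$host_intron, ,
                      drop = FALSE]
    verdict <- if (status == "covered") "purely_intronic"
    else if (status == "bridged" && nrow(res) > 0L &&
             res$resolution[1] == "hidden_exons") "hidden_exons"
    else if (status %in% c("bridged", "half_bridged")) "unresolved"
    else "no_information"
    tibble(contig = r$contig, start = r$start, end = r$end,
           host_transcript = r$host_transcript, host_intron = r$host_intron,
           junction_status = status, verdict = verdict)
  })
  bind_rows(out)
}

#' Classify gene-model extensions into flanking N-islands
#'
#' A transcript object half-bridging a flanking island (one end aligned to
#' the model terminus facing the island, the other hanging with a long
#' unaligned tail) whose hanging tail is part of the object's connected
#' island and, when a proteome is supplied, passes the translated-improvement
#' test, is reported as a gene-model extension.
#'
#' @param models named list of transcript models.
#' @param islands_tbl [find_n_islands()] output.
#' @param objects named character vector of object sequences.
#' @param hsps [align_objects()] output.
#' @param analyses per-object island analyses (internal structure of
#'   [run_exonpatch()]).
#' @param proteome optional named peptide vector.
#' @param p an [exonpatch_params()] bundle.
#' @return tibble of extension calls.
#' @export
classify_flanking_extensions <- function(models, islands_tbl, objects, hsps,
                                         analyses, proteome, p) {
  empty <- tibble(contig = character(), island_start = integer(),
                  island_end = integer(), transcript_id = character(),
                  object_id = character(), model_end = character(),
                  tail_len = integer(), in_connected_island = logical(),
                  delta = double(), verdict = character())
  fl <- islands_tbl[islands_tbl$context == "flanking", , drop = FALSE]
  if (nrow(fl) == 0L || nrow(hsps) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(fl))) {
    r <- fl[i, ]
    for (m in models) {
      if (m$contig != r$contig) next
      span1 <- min(m$exons[, 1]); span2 <- max(m$exons[, 2])
      before <- r$end <= span1 && span1 - r$end <= p$flank_distance
      after <- r$start >= span2 && r$start - span2 <= p$flank_distance
      if (!before && !after) next
      L <- nchar(m$spliced)
      # spliced terminus facing the island
      p_end <- if ((before && m$strand == "+") || (after && m$strand == "-"))
        0L else L
      h <- hsps[hsps$transcript_id == m$transcript_id, , drop = FALSE]
      for (oid in unique(h$object_id)) {
        ho <- h[h$object_id == oid, , drop = FALSE]
        best <- ho[which.max(ho$score), ]
        olen <- nchar(objects[[oid]])
        near <- if (p_end == 0L) best$s_start <= p$half_bridge_max_gap else
          L - best$s_end <= p$half_bridge_max_gap
        # hanging tail on the island side, in object coordinates
        toward_low_q <- (p_end == 0L) == (best$strand == "+")
        tail_len <- if (toward_low_q) best$q_start else olen - best$q_end
        if (!near || tail_len <= p$half_bridge_min_tail_frac * olen) next
        an <- analyses[[oid]]
        in_ci <- FALSE
        if (!is.null(an) && length(an$islands) > 0L) {
          ti <- tidy(an$islands)
          tail_iv <- if (toward_low_q) c(0L, best$q_start) else
            c(best$q_end, olen)
          hit <- which(pmax(ti$core_start, tail_iv[1]) <
                         pmin(ti$core_end, tail_iv[2]))
          anchor <- which(pmax(ti$core_start, best$q_start) <
                            pmin(ti$core_end, best$q_end))
          in_ci <- length(hit) > 0L && length(anchor) > 0L &&
            any(vapply(an$connected$runs, function(rr)
              any(hit %in% rr) && any(anchor %in% rr), logical(1)))
        }
        delta <- NA_real_; verdict <- "not_tested"
        if (!is.null(proteome) && in_ci) {
          flank <- substr(objects[[oid]], best$q_start + 1L, best$q_end)
          tail_seq <- if (toward_low_q)
            substr(objects[[oid]], 1L, best$q_start) else
              substr(objects[[oid]], best$q_end + 1L, olen)
          sel <- select_subject_peptide(flank, proteome, p$protein)
          if (!is.na(sel$subject_id)) {
            res <- improvement_test(flank, "", tail_seq,
                                    proteome[[sel$subject_id]], p$protein,
                                    n_scrambles = p$n_scrambles,
                                    improvement_threshold =
                                      p$improvement_threshold,
                                    seed = p$seed + i)
            delta <- res$delta
            verdict <- res$verdict
          } else verdict <- "no_common_subject"
        }
        keep <- in_ci && (is.null(proteome) || verdict == "conserved")
        if (keep)
          rows[[length(rows) + 1L]] <- tibble(
            contig = r$contig, island_start = r$start, island_end = r$end,
            transcript_id = m$transcript_id, object_id = oid,
            model_end = if (p_end == 0L) "5prime" else "3prime",
            tail_len = as.integer(tail_len), in_connected_island = in_ci,
            delta = delta, verdict = verdict)
      }
    }
  }
  if (length(rows)) bind_rows(rows) else empty
}

#' @export
print.exonpatch_report <- function(x, ...) {
  s <- attr(x$junctions, "summary")
  cat("<exonpatch_report>\n")
  cat("  junctions:", nrow(x$junctions), "(",
      sum(x$junctions$n_flag), "N-flagged )\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %s n_flag=%s: %d\n", s$status[i], s$n_flag[i],
                s$n_junctions[i]))
  cat("  hidden exons called:", nrow(x$hidden_exons), "\n")
  cat("  island verdicts:",
      paste(sprintf("%s=%d", names(table(x$island_verdicts$verdict)),
                    table(x$island_verdicts$verdict)), collapse = " "), "\n")
  cat("  suspected fusions:",
      sum(x$object_diagnostics$fusion_suspected), "of",
      nrow(x$object_diagnostics), "objects\n")
  cat("  flanking extensions:", nrow(x$extensions), "\n")
  invisible(x)
}

#' @export
glance.exonpatch_report <- function(x, ...) {
  tibble(n_junctions = nrow(x$junctions),
         n_n_flagged = sum(x$junctions$n_flag),
         n_covered = sum(x$junctions$status == "covered"),
         n_bridged = sum(x$junctions$status == "bridged"),
         n_half_bridged = sum(x$junctions$status == "half_bridged"),
         n_no_information = sum(x$junctions$status == "no_information"),
         n_hidden_exons = nrow(x$hidden_exons),
         n_islands_hidden = sum(x$island_verdicts$verdict == "hidden_exons"),
         n_islands_intronic =
           sum(x$island_verdicts$verdict == "purely_intronic"),
         n_fusions_suspected = sum(x$object_diagnostics$fusion_suspected),
         n_extensions = nrow(x$extensions))
}

#' Write the run report to a directory
#'
#' Emits `report.json`, `junctions.tsv`, `conservation.tsv`,
#' `hidden_exons.fa` (exon plus recovered intronic tails) and
#' `hidden_exons.gff3` (exon features on the host transcript's spliced
#' coordinates, score = mean splice bits).
#'
#' @param report an `exonpatch_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$junctions, file.path(dir, "junctions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$conservation,
                     file.path(dir, "conservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hx <- report$hidden_exons
  if (nrow(hx) > 0L) {
    ids <- sprintf("%s.j%d.exon%d", hx$transcript_id, hx$junction_index,
                   hx$exon_index)
    fa <- setNames(paste0(hx$left_tail, hx$seq_mrna, hx$right_tail), ids)
    fa <- fa[nchar(fa) > 0]
    write_genome_fasta(as_genome_assembly(fa),
                       file.path(dir, "hidden_exons.fa"))
    gff <- c("##gff-version 3",
             paste(hx$object_id, "exonpatch", "exon", hx$tmpl_start + 1L,
                   hx$tmpl_end,
                   round((hx$donor_score + hx$acceptor_score) / 2, 2), "+",
                   ".", paste0("ID=", ids, ";Parent=", hx$transcript_id),
                   sep = "\t"))
    writeLines(gff, file.path(dir, "hidden_exons.gff3"))
  }
  js <- list(summary = as.list(glance(report)),
             island_verdicts = report$island_verdicts,
             hidden_exons = report$hidden_exons,
             object_diagnostics = report$object_diagnostics,
             extensions = report$extensions,
             params = lapply(report$params, function(v)
               if (is.list(v)) unclass(v) else v))
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
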