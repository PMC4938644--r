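# planted junction scene: template two segments; island tails carry the
# splice consensus (or not) at the segment boundary b
junction_scene <- function(b = 150L, total = 300L, planted = TRUE,
                           repeat_len = 0L, seed = 1L) {
  withr::with_seed(seed, {
    tmpl <- random_nt(total, 0.65)
    don_tail <- if (planted)
      paste0("GTAAGT", random_nt(74, 0.65)) else random_nt(80, 0.65)
    acc_tail <- if (planted)
      paste0(random_nt(74, 0.65), "TTTTAG") else random_nt(80, 0.65)
    left <- fake_island(tmpl, 0L, b + repeat_len, right_tail = don_tail)
    right <- fake_island(tmpl, b, total, left_tail = acc_tail)
    list(template = tmpl, left = left, right = right, b = b)
  })
}

test_that("join positions are unique without a repeat and k+1 under a k-nt repeat", {
  for (k in 0:4) {
    sc <- junction_scene(repeat_len = k, seed = 20L + k)
    cand <- find_join_offsets(sc$left, sc$right, sc$template)
    expect_equal(cand$ambiguity, k + 1L)
    expect_equal(cand$direct_repeat_len, k)
    expect_equal(cand$offsets, seq(sc$b, sc$b + k))
    expect_false(cand$gap)
  }
  # non-meeting cores are a gap, not a join
  sc <- junction_scene(seed = 30L)
  sc$right$core_start <- sc$b + 40L
  gap <- find_join_offsets(sc$left, sc$right, sc$template)
  expect_true(gap$gap)
  expect_equal(gap$ambiguity, 0L)
  # non-adjacent islands are a caller error
  expect_error(find_join_offsets(sc$right, sc$left), "template order")
})

test_that("planted splice consensus in the tails is called on the plus strand", {
  pwm <- pwm_from_consensus(800)
  sc <- junction_scene(planted = TRUE, seed = 41L)
  calls <- call_splice(find_join_offsets(sc$left, sc$right), sc$left,
                       sc$right, pwm)
  plus <- calls[calls$strand == "+", ]
  expect_true(plus$high_confidence)
  expect_equal(plus$offset, sc$b)
  expect_equal(substr(plus$donor_seq, 4, 5), "GT")
  expect_equal(substr(plus$acceptor_seq, 5, 6), "AG")
  expect_gte(plus$score, 11)
})

test_that("reverse-complement consensus is called on the minus strand", {
  pwm <- pwm_from_consensus(800)
  withr::local_seed(43)
  tmpl <- random_nt(300, 0.65)
  b <- 150L
  # on the minus strand the donor lives in the RIGHT island's left tail
  # (revcomp of GTAAGT... reads ...ACTTAC) and the acceptor in the LEFT
  # island's right tail
  don_m <- paste0("GTAAGT", random_nt(74, 0.65))     # minus-sense donor
  acc_m <- paste0(random_nt(74, 0.65), "TTTTAG")     # minus-sense acceptor
  left <- fake_island(tmpl, 0L, b, right_tail = oracle_revcomp(acc_m))
  right <- fake_island(tmpl, b, 300L, left_tail = oracle_revcomp(don_m))
  calls <- call_splice(find_join_offsets(left, right), left, right, pwm)
  minus <- calls[calls$strand == "-", ]
  expect_true(minus$high_confidence)
  plus <- calls[calls$strand == "+", ]
  expect_false(plus$high_confidence)
})

test_that("random GC-rich tails rarely fake a high-confidence splice", {
  pwm <- pwm_from_consensus(800)
  withr::local_seed(47)
  hits <- vapply(1:300, function(i) {
    tmpl <- random_nt(120, 0.65)
    left <- fake_island(tmpl, 0L, 60L, right_tail = random_nt(40, 0.65))
    right <- fake_island(tmpl, 60L, 120L, left_tail = random_nt(40, 0.65))
    calls <- call_splice(find_join_offsets(left, right), left, right, pwm)
    any(calls$high_confidence)
  }, logical(1))
  expect_lt(mean(hits), 0.1)
})

test_that("short tails are N-padded and degrade gracefully", {
  pwm <- pwm_from_consensus(800)
  withr::local_seed(48)
  tmpl <- random_nt(200, 0.65)
  left <- fake_island(tmpl, 0L, 100L, right_tail = "GTA")  # 3 of 6 intron nt
  right <- fake_island(tmpl, 100L, 200L, left_tail = "AG")
  calls <- call_splice(find_join_offsets(left, right), left, right, pwm)
  expect_equal(nrow(calls), 2L)
  expect_true(all(is.finite(calls$score)))
  expect_equal(substr(calls$donor_seq[calls$strand == "+"], 7, 9), "NNN")
})

test_that("no high-confidence call ever lacks literal GT/AG", {
  pwm <- pwm_from_consensus(400)
  pwm$score_cutoff <- 0         # even with no score requirement
  withr::local_seed(49)
  don <- draw_windows(300, "donor")
  acc <- draw_windows(300, "acceptor")
  # corrupt the dinucleotides in half of them
  idx <- 1:150
  substr(don[idx], 4, 5) <- "CC"
  hc <- high_confidence(don, acc, pwm)
  expect_true(all(!hc[idx]))
  expect_true(all(hc[-idx]))
})

fake_calls <- function(strands, hc = TRUE) {
  lapply(strands, function(s) {
    if (is.na(s))
      return(tibble::tibble(strand = c("+", "-"), offset = 0L,
                            donor_seq = "", acceptor_seq = "", score = 0,
                            high_confidence = FALSE, ambiguity = 1L,
                            direct_repeat_len = 0L))
    tibble::tibble(strand = c("+", "-"), offset = 0L, donor_seq = "",
                   acceptor_seq = "", score = c(14, 3),
                   high_confidence = if (s == "both") c(TRUE, TRUE) else
                     c(s == "+", s == "-"),
                   ambiguity = 1L, direct_repeat_len = 0L)
  })
}

test_that("same-strand high-confidence splices chain islands into connected islands", {
  isl <- lapply(1:4, function(i)
    fake_island(strrep("ACGT", 100), (i - 1L) * 100L, i * 100L))
  ci <- build_connected_islands(isl, fake_calls(c("+", "+", "+")))
  expect_equal(ci$diagnostics$n_connected, 1L)
  expect_true(ci$diagnostics$spans_whole_template)
  expect_false(ci$diagnostics$fusion_suspected)
  expect_equal(ci$run_strands, "+")

  # a failed middle junction splits the chain: suspected fusion
  ci2 <- build_connected_islands(isl, fake_calls(c("+", NA, "+")))
  expect_equal(ci2$diagnostics$n_connected, 2L)
  expect_true(ci2$diagnostics$fusion_suspected)

  # strand flip between runs
  ci3 <- build_connected_islands(isl, fake_calls(c("+", NA, "-")))
  expect_true(ci3$diagnostics$strand_flip)

  # a junction callable on both strands is retained and flagged
  ci4 <- build_connected_islands(isl, fake_calls(c("+", "both", "+")))
  expect_equal(ci4$diagnostics$n_connected, 1L)
  expect_equal(ci4$diagnostics$ambiguous_junctions, 2L)
})

test_that("bridged junctions resolve planted hidden exons with exact boundaries", {
  cfg <- simulation_config(n_genes = 4L, hidden_exon_genes = 1L,
                           intronic_island_genes = 1L, error_rate = 0,
                           fusion_rate = 0)
  ds <- simulate_dataset(cfg, seed = 57)
  rep <- run_exonpatch(ds$truth$assembly, ds$truth$models, ds$objects,
                       ds$reads$genomic)
  hx_true <- ds$truth$hidden_exons
  expect_gt(nrow(hx_true), 0L)
  expect_equal(sort(rep$hidden_exons$seq_mrna), sort(hx_true$seq_mrna))
  # a covered N-island is reported purely intronic, with zero exon calls
  iv <- rep$island_verdicts
  planted_intronic <- ds$truth$islands[ds$truth$islands$type == "intronic", ]
  for (i in seq_len(nrow(planted_intronic)))
    expect_true(all(iv$verdict[iv$host_transcript ==
                                 planted_intronic$transcript_id[i]] !=
                      "hidden_exons"))
})
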