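# a template spliced from discontiguous genomic segments, plus the genomic
# source the reads tile
segmented_scene <- function(seg_lens, intron_len = 300L, seed = 1L) {
  withr::with_seed(seed, {
    segs <- vapply(seg_lens, random_nt, character(1), gc = 0.65)
    introns <- replicate(length(seg_lens) + 1L, random_nt(intron_len, 0.65))
    genomic <- paste0(introns[1],
                      paste(vapply(seq_along(segs), function(i)
                        paste0(segs[i], introns[i + 1L]), character(1)),
                        collapse = ""))
    list(template = paste(segs, collapse = ""), segs = segs,
         genomic = genomic,
         bounds = cumsum(seg_lens))
  })
}

test_that("local read alignment has local semantics and a minimum length", {
  withr::local_seed(2)
  tmpl <- random_nt(300)
  reads <- tibble::tibble(
    read_id = c("full", "half", "short"),
    seq = c(substr(tmpl, 41, 140),
            paste0(substr(tmpl, 241, 300), random_nt(40)),
            paste0(substr(tmpl, 101, 115), random_nt(85))))
  al <- local_align_reads(reads, tmpl)
  expect_setequal(al$read_id, c("full", "half"))
  full <- al[al$read_id == "full", ]
  expect_equal(c(full$tmpl_start, full$tmpl_end), c(40L, 140L))
  half <- al[al$read_id == "half", ]
  expect_equal(half$tmpl_end, 300L)            # finish at template end
  expect_equal(half$read_end - half$read_start, 60L)
})

test_that("start/finish pileups mark the segment boundary; contiguous templates stay silent", {
  sc <- segmented_scene(c(300L, 300L), seed = 3L)
  withr::local_seed(4)
  reads <- tile_reads(sc$genomic, 100L, 60)
  al <- local_align_reads(reads, sc$template)
  sig <- detect_boundaries(al)
  internal <- sig[sig$position > 0 & sig$position < 600, ]
  expect_setequal(internal$position, 300L)
  expect_setequal(internal$side, c("start", "finish"))
  expect_true(all(internal$enrichment >= 10))

  # negative control: one contiguous segment
  withr::local_seed(5)
  tmpl <- random_nt(600)
  reads2 <- tile_reads(tmpl, 100L, 60)
  sig2 <- detect_boundaries(local_align_reads(reads2, tmpl))
  expect_equal(nrow(sig2[sig2$position > 10 & sig2$position < 590, ]), 0L)
})

test_that("grown islands recover the exact segment with ~80-nt intronic tails", {
  sc <- segmented_scene(c(300L, 300L), seed = 6L)
  withr::local_seed(7)
  reads <- tile_reads(sc$genomic, 100L, 60)
  isl <- islands_for_template(reads, sc$template)
  expect_equal(length(isl), 2L)
  ti <- tidy(isl)
  # cores tile the template exactly up to chance direct-repeat jitter
  expect_lte(abs(ti$core_start[1] - 0L), 0L)
  expect_lte(abs(ti$core_end[2] - 600L), 0L)
  expect_lte(abs(ti$core_end[1] - 300L), 5L)
  expect_lte(abs(ti$core_start[2] - 300L), 5L)
  tails <- c(ti$left_tail_len, ti$right_tail_len)
  expect_true(all(abs(tails - 80L) <= 6L))
  # tails are prefixes/suffixes of the true adjacent intronic sequence:
  # island 1 core consensus + right tail appears verbatim in the genome
  i1 <- isl[[1]]
  expect_true(grepl(i1$right_tail, sc$genomic, fixed = TRUE))
  expect_true(grepl(i1$left_tail, sc$genomic, fixed = TRUE))
  # and tails do not align to the template at or above the local minimum
  h <- ungapped_local_align(i1$right_tail, sc$template,
                            align_params(min_score = 20L))
  expect_equal(nrow(h), 0L)
})

test_that("reads sharing only a short internal repeat are discarded by consensus", {
  sc <- segmented_scene(c(400L), seed = 8L)
  withr::local_seed(9)
  reads <- tile_reads(sc$genomic, 100L, 50)
  # two foreign reads sharing a 25-nt repeat with the template interior
  rep25 <- substr(sc$template, 188, 212)
  foreign <- tibble::tibble(
    read_id = c("rep1", "rep2"),
    seq = c(paste0(random_nt(40), rep25, random_nt(35)),
            paste0(random_nt(30), rep25, random_nt(45))))
  al <- local_align_reads(dplyr::bind_rows(reads, foreign), sc$template)
  expect_true(all(c("rep1", "rep2") %in% al$read_id))  # they do align
  isl <- islands_for_template(NULL, sc$template, alignments = al)
  expect_equal(length(isl), 1L)
  expect_false(any(c("rep1", "rep2") %in% isl[[1]]$read_ids))
})

test_that("one island per discontiguous segment, in template order", {
  sc <- segmented_scene(c(250L, 200L, 250L), seed = 10L)
  withr::local_seed(11)
  reads <- tile_reads(sc$genomic, 100L, 60)
  isl <- islands_for_template(reads, sc$template)
  expect_equal(length(isl), 3L)
  ti <- tidy(isl)
  expect_true(all(diff(ti$core_start) > 0))
  expect_lte(abs(ti$core_end[1] - 250L), 5L)
  expect_lte(abs(ti$core_end[2] - 450L), 5L)
  # islands share no sequence outside the template frame: consecutive
  # islands' consensus differ over the tail overlap region
  for (j in 1:2) {
    a <- isl[[j]]; b <- isl[[j + 1L]]
    lo <- max(a$ext_start, b$ext_start)
    hi <- min(a$ext_end, b$ext_end)
    sa <- substr(a$consensus, lo - a$ext_start + 1L, hi - a$ext_start)
    sb <- substr(b$consensus, lo - b$ext_start + 1L, hi - b$ext_start)
    mism <- sum(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
    expect_gt(mism / nchar(sa), 0.3)
  }

  # single-segment template: exactly one island
  withr::local_seed(12)
  one <- segmented_scene(c(500L), seed = 13L)
  reads1 <- tile_reads(one$genomic, 100L, 50)
  isl1 <- islands_for_template(reads1, one$template)
  expect_equal(length(isl1), 1L)
  expect_equal(isl1[[1]]$core_start, 0L)
  expect_equal(isl1[[1]]$core_end, 500L)
})

test_that("boundary enrichment grows with read length", {
  sc <- segmented_scene(c(400L, 400L), seed = 14L)
  enr <- vapply(c(50L, 100L, 150L), function(rl) {
    withr::with_seed(rl, {
      reads <- tile_reads(sc$genomic, rl, 80)
      al <- local_align_reads(reads, sc$template)
      sig <- detect_boundaries(al, seed_enrichment_threshold = 5)
      s <- sig[sig$position == 400 & sig$side == "start", ]
      if (nrow(s) == 0L) 0 else s$enrichment
    })
  }, numeric(1))
  expect_true(all(diff(enr) > 0))
  # expectation is read_length - min_local_length + 1, up to sampling noise
  expect_equal(enr[2] / (100 - 20 + 1), 1, tolerance = 0.25)
})

test_that("a seed nobody touches yields an empty island", {
  withr::local_seed(15)
  tmpl <- random_nt(200)
  reads <- tibble::tibble(read_id = "r1", seq = substr(tmpl, 1, 100))
  al <- local_align_reads(reads, tmpl)
  out <- grow_island(list(position = 180L, side = "start"), al, tmpl)
  expect_null(out)
})
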