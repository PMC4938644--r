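small_cfg <- function(...) {
  simulation_config(n_genes = 4L, hidden_exon_genes = 1L,
                    intronic_island_genes = 1L, ...)
}

test_that("the same seed reproduces the dataset byte-identically", {
  a <- simulate_dataset(small_cfg(), seed = 3)
  b <- simulate_dataset(small_cfg(), seed = 3)
  expect_identical(a$truth$genome, b$truth$genome)
  expect_identical(a$truth$assembly, b$truth$assembly)
  expect_identical(a$objects, b$objects)
  expect_identical(a$reads$genomic$seq, b$reads$genomic$seq)
  c_ <- simulate_dataset(small_cfg(), seed = 4)
  expect_false(identical(a$truth$genome, c_$truth$genome))
})

test_that("masking hides the planted exons and flags the junction", {
  ds <- simulate_genome(small_cfg(), seed = 11)
  isl <- ds$islands
  expect_equal(nrow(isl), 2L)
  hid <- isl[isl$type == "hidden", ]
  # the masked model lost exactly n_hidden exons
  mt <- ds$models_true[[hid$transcript_id]]
  mm <- ds$models[[hid$transcript_id]]
  expect_equal(nrow(mt$exons) - nrow(mm$exons), hid$n_hidden)
  # the masked junction splices out the island and is N-flagged
  expect_true(mm$junctions$n_flag[hid$masked_junction])
  # hidden exon sequences are in the true mRNA but nowhere in the assembly
  for (s in ds$hidden_exons$seq_mrna) {
    expect_true(grepl(s, mt$spliced, fixed = TRUE))
    expect_false(grepl(s, ds$assembly[[1]], fixed = TRUE))
    expect_false(grepl(oracle_revcomp(s), ds$assembly[[1]], fixed = TRUE))
  }
  # the island interval in the masked assembly is all N, maximal
  a <- ds$assembly[[1]]
  run <- substr(a, hid$masked_start + 1L, hid$masked_end)
  expect_equal(run, strrep("N", hid$est_length))
  # N-run length is an estimate, not the true length
  found <- find_n_islands(ds$assembly, ds$models)
  expect_true(all(found$context[found$length >= 10] == "intronic"))
})

test_that("models on the masked assembly splice to the mRNA minus hidden exons", {
  ds <- simulate_genome(small_cfg(), seed = 13)
  for (id in names(ds$models)) {
    true_sp <- ds$models_true[[id]]$spliced
    hx <- ds$hidden_exons[ds$hidden_exons$transcript_id == id, ]
    expect_gt(nchar(ds$models[[id]]$spliced), 0L)
    want <- true_sp
    for (s in hx$seq_mrna) want <- sub(s, "", want, fixed = TRUE)
    expect_identical(ds$models[[id]]$spliced, want)
  }
})

test_that("read sets match the configured depth and error rate", {
  cfg <- small_cfg(error_rate = 0.01, genomic_depth = 50)
  ds <- simulate_dataset(cfg, seed = 17)
  glen <- nchar(ds$truth$genome[[1]])
  depth <- nrow(ds$reads$genomic) * 100 / glen
  expect_equal(depth, 50, tolerance = 0.1)
  # observed mismatch rate vs the truth via the provenance columns
  rd <- ds$reads$genomic
  truth_seq <- substring(ds$truth$genome[[1]], rd$src_start + 1L,
                         rd$src_start + 100L)
  placed <- ifelse(rd$src_strand == "-",
                   vapply(rd$seq, oracle_revcomp, character(1)), rd$seq)
  mism <- mapply(function(a, b)
    sum(utf8ToInt(a) != utf8ToInt(b)), placed, truth_seq)
  rate <- sum(mism) / (length(mism) * 100)
  expect_equal(rate, 0.01, tolerance = 0.2)
  # RNA reads are sampled from true mRNA: never contain N
  expect_false(any(grepl("N", ds$reads$rna$seq, fixed = TRUE)))
  expect_equal(attr(ds$reads$rna, "read_length"), 50L)
  expect_equal(attr(ds$reads$genomic, "read_length"), 100L)
})

test_that("object registry tracks fragments and fusions; rate 0 means none", {
  ds0 <- make_transcript_objects(simulate_genome(small_cfg(), seed = 19),
                                 small_cfg(fusion_rate = 0), seed = 19)
  expect_equal(sum(ds0$registry$type == "fusion"), 0L)

  cfg <- small_cfg(fusion_rate = 0.5, fragment_objects = 2L)
  tr <- simulate_genome(cfg, seed = 23)
  obj <- make_transcript_objects(tr, cfg, seed = 23)
  expect_equal(sum(obj$registry$type == "fusion"), 2L)
  expect_equal(sum(obj$registry$type == "fragment"), 2L)
  # a full object for a hidden-exon gene contains the hidden sequence
  hid <- tr$islands[tr$islands$type == "hidden", ]
  oid <- paste0("obj_", hid$transcript_id)
  o <- obj$objects[[oid]]
  ori <- obj$registry$orientation[obj$registry$object_id == oid]
  if (ori == "-") o <- oracle_revcomp(o)
  for (s in tr$hidden_exons$seq_mrna)
    expect_true(grepl(s, o, fixed = TRUE))
  # fusions concatenate two mRNAs (second possibly flipped)
  fus <- obj$registry[obj$registry$type == "fusion", ][1, ]
  gg <- strsplit(fus$genes, "+", fixed = TRUE)[[1]]
  m1 <- tr$models_true[[gg[1]]]$spliced
  expect_equal(substr(obj$objects[[fus$object_id]], 1, nchar(m1)), m1)
})

test_that("datasets write to disk and read back", {
  ds <- simulate_dataset(small_cfg(), seed = 29)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "assembly_masked.fa", "models.gff3", "objects.fa",
    "rna.fastq", "genomic.fastq", "truth.json")))))
  g <- load_genome(file.path(dir, "genome.fa"))
  expect_identical(unclass(g), unclass(ds$truth$genome))
  rd <- load_reads(file.path(dir, "genomic.fastq"))
  expect_identical(rd$seq, ds$reads$genomic$seq)
  models <- load_transcript_models(file.path(dir, "models.gff3"),
                                   load_genome(file.path(
                                     dir, "assembly_masked.fa")))
  expect_setequal(names(models), names(ds$truth$models))
})
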