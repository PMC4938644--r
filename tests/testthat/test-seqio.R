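test_that("FASTA genomes load with case folding and validation", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1 some description", "acgtNNN", "ACGT"), f)
  g <- load_genome(f)
  expect_s3_class(g, "genome_assembly")
  expect_named(g, "c1")
  expect_equal(unname(nchar(g)), 11L)
  expect_equal(unname(g[["c1"]]), "ACGTNNNACGT")

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(load_genome(empty), "malformed|no records")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), dup)
  expect_error(load_genome(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACRT"), bad)
  expect_error(load_genome(bad), "invalid residue in contig 'a' at offset 2")
})

test_that("genome FASTA round-trips byte-for-byte", {
  withr::local_seed(3)
  g <- as_genome_assembly(c(c1 = random_nt(333), c2 = paste0(
    random_nt(50), "NNNN", random_nt(20))))
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, f)
  expect_equal(unclass(load_genome(f)), unclass(g))
})

test_that("maximal N runs are located and classified", {
  g <- as_genome_assembly(c(c1 = "AANNNAA"))
  isl <- find_n_islands(g)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start, 2L)
  expect_equal(isl$end, 5L)
  expect_equal(isl$context, "intergenic")

  fx <- two_exon_fixture(with_n = TRUE)
  isl <- find_n_islands(fx$genome, list(fx$model))
  expect_equal(isl$context, "intronic")
  expect_equal(isl$host_transcript, "t1")
  expect_equal(isl$host_intron, 1L)
  # the island is a maximal run: neighbours are not N
  s <- fx$genome[["chr"]]
  expect_false(substr(s, isl$start, isl$start) == "N")
  expect_false(substr(s, isl$end + 1L, isl$end + 1L) == "N")
})

test_that("flanking label follows the 100-bp rule, exonic wins over it", {
  withr::local_seed(5)
  body <- random_nt(300)
  # island starting 80 nt downstream of the model's 3' end
  g <- as_genome_assembly(c(chr = paste0(body, random_nt(80),
                                         strrep("N", 30), random_nt(50))))
  m <- transcript_model("t1", "chr", "+",
                        data.frame(start = 0L, end = 300L), g)
  isl <- find_n_islands(g, list(m), flank_distance = 100L)
  expect_equal(isl$context, "flanking")
  isl2 <- find_n_islands(g, list(m), flank_distance = 50L)
  expect_equal(isl2$context, "intergenic")

  g2 <- as_genome_assembly(c(chr = paste0(random_nt(100), strrep("N", 10),
                                          random_nt(100))))
  m2 <- transcript_model("t2", "chr", "+",
                         data.frame(start = 95L, end = 150L), g2)
  expect_equal(find_n_islands(g2, list(m2))$context, "exonic")
})

test_that("spliced sequence and junctions follow strand conventions", {
  withr::local_seed(7)
  e1 <- random_nt(30); i1 <- random_nt(40); e2 <- random_nt(20)
  g <- as_genome_assembly(c(chr = paste0("AAAA", e1, i1, e2, "TTTT")))
  ex <- data.frame(start = c(4L, 4L + 30L + 40L), end = c(34L, 94L))
  mp <- transcript_model("p", "chr", "+", ex, g)
  expect_equal(mp$spliced, paste0(e1, e2))
  expect_equal(mp$junctions$spliced_pos, 30L)
  expect_equal(mp$junctions$intron_start, 34L)
  expect_equal(mp$junctions$intron_end, 74L)
  expect_false(mp$junctions$n_flag)

  mm <- transcript_model("m", "chr", "-", ex, g)
  expect_equal(mm$spliced, paste0(oracle_revcomp(e2), oracle_revcomp(e1)))
  expect_equal(mm$junctions$spliced_pos, 20L)

  # N strictly inside the intron flags the junction
  gn <- as_genome_assembly(c(chr = paste0("AAAA", e1, "ACGTNNNNACGT",
                                          substr(i1, 13, 40), e2, "TTTT")))
  mn <- transcript_model("n", "chr", "+", ex, gn)
  expect_true(mn$junctions$n_flag)
})

test_that("transcript model validation rejects degenerate input", {
  g <- as_genome_assembly(c(chr = strrep("ACGT", 30)))
  expect_error(transcript_model("x", "chr", "+",
                                data.frame(start = 0L, end = 200L), g),
               "outside contig")
  expect_error(transcript_model("x", "chr", "+",
                                data.frame(start = c(0L, 5L),
                                           end = c(10L, 15L)), g),
               "overlapping")
  expect_error(transcript_model("x", "nope", "+",
                                data.frame(start = 0L, end = 4L), g),
               "unknown contig")
})

test_that("GFF3 models round-trip exactly, including minus strand", {
  ds <- simulate_genome(simulation_config(n_genes = 4L,
                                          hidden_exon_genes = 1L,
                                          intronic_island_genes = 1L),
                        seed = 19)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_models_gff3(ds$models, f)
  back <- load_transcript_models(f, ds$assembly)
  expect_setequal(names(back), names(ds$models))
  for (id in names(ds$models)) {
    expect_equal(back[[id]]$exons, ds$models[[id]]$exons)
    expect_equal(back[[id]]$strand, ds$models[[id]]$strand)
    expect_equal(back[[id]]$spliced, ds$models[[id]]$spliced)
    expect_equal(back[[id]]$junctions, ds$models[[id]]$junctions)
  }
})

test_that("splicing exon intervals from the genome reproduces the spliced sequence", {
  ds <- simulate_genome(simulation_config(n_genes = 3L,
                                          hidden_exon_genes = 1L,
                                          intronic_island_genes = 0L),
                        seed = 23)
  for (m in ds$models_true) {
    pieces <- substring(ds$genome[[m$contig]], m$exons[, 1] + 1L,
                        m$exons[, 2])
    want <- if (m$strand == "+") paste(pieces, collapse = "") else
      paste(rev(vapply(pieces, oracle_revcomp, character(1))), collapse = "")
    expect_identical(m$spliced, want)
  }
})
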