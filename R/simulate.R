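# Fixture factory: GC-rich genomes with multi-exon genes whose splice sites
# follow a stated consensus, N-masked assemblies hiding zero or more exons,
# spliced transcript objects (with deliberate fusion artifacts), uniformly
# tiled reads, and the truth tables tests assert against.

.rand_seq <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.draw_from_profile <- function(profile) {
  # profile: 4 x L probability matrix (rows A C G T)
  paste(vapply(seq_len(ncol(profile)), function(i)
    sample(c("A", "C", "G", "T"), 1L, prob = profile[, i]), character(1)),
    collapse = "")
}

#' Default splice-site consensus used by the simulator
#'
#' Invariant GT/AG dinucleotides (8 bits) plus five strongly informative
#' positions at consensus probability 0.93 with A/T consensus bases (donor
#' +3 A, +4 A, +6 T after the GT; acceptor -4 T, -3 T before the AG),
#' echoing the A/T-rich donor (GTAAGT-like) and polypyrimidine acceptor of
#' GC-rich genomes. Total specified information is ~15.6 bits, so the
#' model's maximum score is ~15 and the 11-bit two-step test passes ~99.7%
#' of true junctions.
#'
#' @param windows a [splice_windows()] object (3+6 / 6+3 by default).
#' @param consensus_prob probability of the consensus base at informative
#'   positions.
#' @return list with `donor` and `acceptor` 4-by-L probability matrices
#'   (rows A, C, G, T).
#' @export
default_splice_consensus <- function(windows = splice_windows(),
                                     consensus_prob = 0.93) {
  uni <- rep(0.25, 4)
  inv <- function(b) { p <- rep(0, 4); p[match(b, .BASES)] <- 1; p }
  inf <- function(b) {
    p <- rep((1 - consensus_prob) / 3, 4)
    p[match(b, .BASES)] <- consensus_prob
    p
  }
  donor <- matrix(uni, nrow = 4,
                  ncol = windows$donor_exon + windows$donor_intron)
  i0 <- windows$donor_exon
  donor[, i0 + 1L] <- inv("G"); donor[, i0 + 2L] <- inv("T")
  donor[, i0 + 3L] <- inf("A"); donor[, i0 + 4L] <- inf("A")
  donor[, i0 + 6L] <- inf("T")
  acceptor <- matrix(uni, nrow = 4,
                     ncol = windows$acceptor_intron + windows$acceptor_exon)
  ai <- windows$acceptor_intron
  acceptor[, ai - 3L] <- inf("T"); acceptor[, ai - 2L] <- inf("T")
  acceptor[, ai - 1L] <- inv("A"); acceptor[, ai] <- inv("G")
  rownames(donor) <- rownames(acceptor) <- .BASES
  list(donor = donor, acceptor = acceptor, windows = windows)
}

#' Simulation configuration
#'
#' The defaults are the package's reference study conditions: a ~200 kb
#' 65%-GC single-contig genome with 20 multi-exon genes, 100-nt genomic and
#' 50-nt RNA reads at 30x depth with 0.5% substitution error, six genes with
#' an N-island hiding one to three exons, four genes with a purely intronic
#' island, and a 10% fusion-artifact rate among transcript objects.
#'
#' @param gc genome GC fraction.
#' @param n_genes number of genes.
#' @param exons_per_gene,exon_len,intron_len,intergenic_len integer ranges
#'   `c(min, max)` in exons / nt.
#' @param consensus splice consensus from [default_splice_consensus()].
#' @param hidden_exon_genes number of genes whose island hides exons.
#' @param hidden_exon_range range of hidden-exon counts per island.
#' @param intronic_island_genes number of genes with an exon-free island.
#' @param island_margin range of intron nt left unmasked next to the
#'   retained exons (keeps the masked junction's splice windows real).
#' @param island_length_factor range of the estimated/true island length
#'   ratio (the mask length only estimates the hidden length).
#' @param rna_read_length,genomic_read_length read lengths in nt.
#' @param rna_depth,genomic_depth mean coverage.
#' @param error_rate per-base substitution error rate.
#' @param fragment_objects number of extra subfragment objects.
#' @param fusion_rate fusion artifacts per gene (0.1 -> 2 fused objects for
#'   20 genes).
#' @param fusion_flip_prob probability a fusion flips the second gene's
#'   strand.
#' @param contig contig name.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(gc = 0.65, n_genes = 20L,
                              exons_per_gene = c(4L, 8L),
                              exon_len = c(90L, 240L),
                              intron_len = c(200L, 600L),
                              intergenic_len = c(4000L, 8000L),
                              consensus = default_splice_consensus(),
                              hidden_exon_genes = 6L,
                              hidden_exon_range = c(1L, 3L),
                              intronic_island_genes = 4L,
                              island_margin = c(20L, 60L),
                              island_length_factor = c(0.5, 2.0),
                              rna_read_length = 50L,
                              genomic_read_length = 100L,
                              rna_depth = 30, genomic_depth = 30,
                              error_rate = 0.005,
                              fragment_objects = 0L, fusion_rate = 0.1,
                              fusion_flip_prob = 0.5, contig = "chr1") {
  stopifnot(gc > 0, gc < 1, all(exon_len > 0), all(intron_len > 0),
            hidden_exon_genes + intronic_island_genes <= n_genes)
  structure(as.list(environment()), class = "sim_config")
}

.runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

# one gene in mRNA orientation: sequence plus exon intervals (gene-local)
.build_gene <- function(cfg, n_exons) {
  w <- cfg$consensus$windows
  ex_len <- .runif_int(n_exons, cfg$exon_len)
  in_len <- .runif_int(max(0L, n_exons - 1L), cfg$intron_len)
  parts <- character(0)
  ex_start <- integer(n_exons)
  pos <- 0L
  for (i in seq_len(n_exons)) {
    ex_start[i] <- pos
    parts <- c(parts, .rand_seq(ex_len[i], cfg$gc))
    pos <- pos + ex_len[i]
    if (i < n_exons) {
      don <- .draw_from_profile(
        cfg$consensus$donor[, (w$donor_exon + 1L):ncol(cfg$consensus$donor),
                            drop = FALSE])
      acc <- .draw_from_profile(
        cfg$consensus$acceptor[, seq_len(w$acceptor_intron), drop = FALSE])
      mid <- .rand_seq(in_len[i] - nchar(don) - nchar(acc), cfg$gc)
      parts <- c(parts, don, mid, acc)
      pos <- pos + in_len[i]
    }
  }
  list(seq = paste(parts, collapse = ""),
       exons = cbind(start = ex_start, end = ex_start + ex_len))
}

#' Simulate a genome, its gene models, and an N-masked assembly
#'
#' Generates the true genome and transcript models, selects islands per the
#' configuration (introns that are partially masked, optionally swallowing
#' one or more complete internal exons plus their introns), and produces the
#' masked assembly together with its annotation — transcript models whose
#' N-flagged junctions splice out the islands, exactly as a draft reference
#' would. The mask length is the true hidden length times a random factor,
#' mimicking the length-estimate semantics of assembly gaps.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; the whole truth set is a deterministic function
#'   of `(config, seed)`.
#' @return list of class `truth_set`: `genome` and `models_true` (the real
#'   sequence), `assembly` and `models` (the N-masked reference the pipeline
#'   sees), `islands` (planted-island registry with true and masked
#'   coordinates), `hidden_exons` (per-exon registry with mRNA-orientation
#'   sequences), and the `config`.
#' @export
simulate_genome <- function(config = simulation_config(), seed = 1L) {
  withr::with_seed(seed, .simulate_genome(config))
}

.simulate_genome <- function(cfg) {
  n_exons <- .runif_int(cfg$n_genes, cfg$exons_per_gene)
  # genes hiding exons need at least k + 2 exons; bump where needed
  k_hidden <- .runif_int(cfg$n_genes, cfg$hidden_exon_range)
  hidden_genes <- sample(cfg$n_genes, cfg$hidden_exon_genes)
  intronic_genes <- sample(setdiff(seq_len(cfg$n_genes), hidden_genes),
                           cfg$intronic_island_genes)
  n_exons[hidden_genes] <- pmax(n_exons[hidden_genes],
                                k_hidden[hidden_genes] + 2L)
  genes <- lapply(n_exons, function(m) .build_gene(cfg, m))
  strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)

  contig_parts <- character(0)
  pos <- 0L
  gene_rows <- list()
  for (g in seq_len(cfg$n_genes)) {
    gap <- .runif_int(1L, cfg$intergenic_len)
    contig_parts <- c(contig_parts, .rand_seq(gap, cfg$gc))
    pos <- pos + gap
    gs <- genes[[g]]
    glen <- nchar(gs$seq)
    if (strands[g] == "+") {
      seq_g <- gs$seq
      ex <- gs$exons + pos
    } else {
      seq_g <- revcomp(gs$seq)
      ex <- cbind(start = pos + glen - gs$exons[, "end"],
                  end = pos + glen - gs$exons[, "start"])
      ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    }
    contig_parts <- c(contig_parts, seq_g)
    gene_rows[[g]] <- list(strand = strands[g], exons = ex,
                           mrna_exons = n_exons[g])
    pos <- pos + glen
  }
  gap <- .runif_int(1L, cfg$intergenic_len)
  contig_parts <- c(contig_parts, .rand_seq(gap, cfg$gc))
  genome <- as_genome_assembly(setNames(paste(contig_parts, collapse = ""),
                                        cfg$contig))

  models_true <- list()
  for (g in seq_len(cfg$n_genes)) {
    id <- sprintf("g%02d.t1", g)
    models_true[[id]] <- transcript_model(id, cfg$contig,
                                          gene_rows[[g]]$strand,
                                          gene_rows[[g]]$exons, genome,
                                          gene_id = sprintf("g%02d", g))
  }

  # island plan: mask intervals in TRUE genomic coordinates
  island_rows <- list()
  hidden_rows <- list()
  for (g in sort(c(hidden_genes, intronic_genes))) {
    m <- models_true[[sprintf("g%02d.t1", g)]]
    nx <- nrow(m$exons)
    strand <- m$strand
    if (g %in% hidden_genes) {
      k <- min(k_hidden[g], nx - 2L)
      cand <- seq(2L, nx - k)                 # first hidden exon, mRNA index
      e0 <- cand[sample.int(length(cand), 1L)]
      # mRNA exon index -> genomic exon row
      gidx <- if (strand == "+") e0:(e0 + k - 1L) else
        (nx - e0 + 1L):(nx - e0 - k + 2L)
      gidx <- sort(gidx)
      left_exon <- min(gidx) - 1L
      right_exon <- max(gidx) + 1L
      marg <- .runif_int(2L, cfg$island_margin)
      mask_s <- m$exons[left_exon, 2] + marg[1]
      mask_e <- m$exons[right_exon, 1] - marg[2]
      type <- "hidden"
      n_hidden <- k
    } else {
      # mask the middle of one internal intron, hiding nothing
      j <- sample(nx - 1L, 1L)                # genomic intron index
      is_ <- m$exons[j, 2]; ie_ <- m$exons[j + 1L, 1]
      marg <- .runif_int(2L, cfg$island_margin)
      mask_s <- is_ + marg[1]
      mask_e <- ie_ - marg[2]
      if (mask_e - mask_s < 10L) { mask_s <- is_ + 20L; mask_e <- ie_ - 20L }
      type <- "intronic"
      n_hidden <- 0L
      gidx <- integer()
      e0 <- NA_integer_
    }
    est_len <- max(10L, as.integer(round(
      (mask_e - mask_s) * runif(1, cfg$island_length_factor[1],
                                cfg$island_length_factor[2]))))
    island_rows[[length(island_rows) + 1L]] <- tibble(
      gene = g, transcript_id = m$transcript_id, type = type,
      true_start = mask_s, true_end = mask_e, est_length = est_len,
      n_hidden = n_hidden,
      first_hidden_mrna_exon = e0)
    if (n_hidden > 0L) {
      for (ei in seq_len(n_hidden)) {
        mrna_i <- e0 + ei - 1L
        grow <- if (strand == "+") mrna_i else nx - mrna_i + 1L
        seq_g <- substr(genome[[m$contig]], m$exons[grow, 1] + 1L,
                        m$exons[grow, 2])
        hidden_rows[[length(hidden_rows) + 1L]] <- tibble(
          gene = g, transcript_id = m$transcript_id,
          hidden_exon = ei, mrna_exon = mrna_i,
          true_start = m$exons[grow, 1], true_end = m$exons[grow, 2],
          seq_mrna = if (strand == "+") seq_g else revcomp(seq_g))
      }
    }
  }
  islands <- if (length(island_rows)) bind_rows(island_rows) else
    tibble(gene = integer(), transcript_id = character(), type = character(),
           true_start = integer(), true_end = integer(),
           est_length = integer(), n_hidden = integer(),
           first_hidden_mrna_exon = integer())
  hidden <- if (length(hidden_rows)) bind_rows(hidden_rows) else
    tibble(gene = integer(), transcript_id = character(),
           hidden_exon = integer(), mrna_exon = integer(),
           true_start = integer(), true_end = integer(),
           seq_mrna = character())

  # build the masked assembly and remap coordinates
  islands <- arrange(islands, .data$true_start)
  src <- genome[[cfg$contig]]
  parts <- character(0)
  prev <- 0L
  offset <- 0L          # masked coord = true coord + offset (piecewise)
  islands$masked_start <- NA_integer_
  islands$masked_end <- NA_integer_
  shift_at <- integer(0); shift_by <- integer(0)
  for (i in seq_len(nrow(islands))) {
    s <- islands$true_start[i]; e <- islands$true_end[i]
    parts <- c(parts, substr(src, prev + 1L, s), strrep("N",
                                                        islands$est_length[i]))
    islands$masked_start[i] <- s + offset
    islands$masked_end[i] <- s + offset + islands$est_length[i]
    offset <- offset + islands$est_length[i] - (e - s)
    shift_at <- c(shift_at, e); shift_by <- c(shift_by, offset)
    prev <- e
  }
  parts <- c(parts, substr(src, prev + 1L, nchar(src)))
  assembly <- as_genome_assembly(setNames(paste(parts, collapse = ""),
                                          cfg$contig))
  remap <- function(x) {
    if (length(shift_at) == 0L) return(x)
    idx <- findInterval(x, shift_at)
    x + c(0L, shift_by)[idx + 1L]
  }

  models_masked <- list()
  for (g in seq_len(cfg$n_genes)) {
    m <- models_true[[sprintf("g%02d.t1", g)]]
    drop_rows <- integer()
    isl_g <- islands[islands$gene == g & islands$type == "hidden", ]
    if (nrow(isl_g) > 0L) {
      drop_rows <- which(m$exons[, 1] >= isl_g$true_start[1] &
                           m$exons[, 2] <= isl_g$true_end[1])
    }
    ex <- m$exons
    if (length(drop_rows)) ex <- ex[-drop_rows, , drop = FALSE]
    ex <- cbind(start = remap(ex[, 1]), end = remap(ex[, 2]))
    models_masked[[m$transcript_id]] <-
      transcript_model(m$transcript_id, cfg$contig, m$strand, ex, assembly,
                       gene_id = m$gene_id)
  }

  # the masked model's junction index that splices out each island
  islands$masked_junction <- NA_integer_
  for (i in seq_len(nrow(islands))) {
    mm <- models_masked[[islands$transcript_id[i]]]
    jx <- mm$junctions
    hit <- which(jx$intron_start <= islands$masked_start[i] &
                   jx$intron_end >= islands$masked_end[i])
    islands$masked_junction[i] <- if (length(hit)) hit[1] else NA_integer_
  }

  structure(list(genome = genome, models_true = models_true,
                 assembly = assembly, models = models_masked,
                 islands = islands, hidden_exons = hidden, config = cfg),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set> ", length(x$models_true), " genes on ",
      format(nchar(x$genome[[1]]), big.mark = ","), " nt; ",
      nrow(x$islands), " planted island(s) (",
      sum(x$islands$type == "hidden"), " hiding ",
      sum(x$islands$n_hidden), " exon(s))\n", sep = "")
  invisible(x)
}

#' Generate transcript objects from a truth set
#'
#' One object per gene — the true spliced mRNA, so objects for genes with
#' hidden exons contain the hidden sequence the masked reference lacks — in
#' random orientation (RNA libraries are non-strand-specific), plus optional
#' subfragments and fusion artifacts (two mRNAs concatenated, optionally
#' strand-flipped, emulating in silico track-crossing).
#'
#' @param truth a [simulate_genome()] result.
#' @param config the same [simulation_config()].
#' @param seed integer seed.
#' @return list with `objects` (named character vector) and `registry`
#'   (tibble: `object_id`, `type`, `genes`, `orientation`, `strand_flip`).
#' @export
make_transcript_objects <- function(truth, config = truth$config, seed = 1L) {
  withr::with_seed(seed, {
    mrnas <- vapply(truth$models_true, `[[`, character(1), "spliced")
    n <- length(mrnas)
    ori <- sample(c("+", "-"), n, replace = TRUE)
    objs <- ifelse(ori == "+", mrnas, revcomp(mrnas))
    names(objs) <- sprintf("obj_%s", names(truth$models_true))
    reg <- tibble(object_id = names(objs), type = "full",
                  genes = names(truth$models_true), orientation = ori,
                  strand_flip = FALSE)
    if (config$fragment_objects > 0L) {
      for (i in seq_len(config$fragment_objects)) {
        g <- sample(n, 1L)
        len <- nchar(mrnas[g])
        fl <- as.integer(round(runif(1, 0.3, 0.7) * len))
        st <- sample(len - fl, 1L)
        frag <- substr(mrnas[g], st, st + fl - 1L)
        o <- sample(c("+", "-"), 1L)
        id <- sprintf("frag_%02d", i)
        objs[id] <- if (o == "+") frag else revcomp(frag)
        reg <- bind_rows(reg, tibble(object_id = id, type = "fragment",
                                     genes = names(truth$models_true)[g],
                                     orientation = o, strand_flip = FALSE))
      }
    }
    n_fus <- round(config$fusion_rate * config$n_genes)
    if (n_fus > 0L) {
      for (i in seq_len(n_fus)) {
        gg <- sample(n, 2L)
        flip <- runif(1) < config$fusion_flip_prob
        second <- if (flip) revcomp(mrnas[gg[2]]) else mrnas[gg[2]]
        id <- sprintf("fus_%02d", i)
        objs[id] <- paste0(mrnas[gg[1]], second)
        reg <- bind_rows(reg, tibble(
          object_id = id, type = "fusion",
          genes = paste(names(truth$models_true)[gg], collapse = "+"),
          orientation = "+", strand_flip = flip))
      }
    }
    list(objects = objs, registry = reg)
  })
}

.add_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  k <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(k > 0L)
  for (i in hit) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample(length(chars), k[i])
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

.sample_reads <- function(sources, n_reads, read_len, error_rate, prefix) {
  lens <- nchar(sources)
  ok <- lens >= read_len
  sources <- sources[ok]; lens <- lens[ok]
  src <- sample(length(sources), n_reads, replace = TRUE,
                prob = lens - read_len + 1)
  start <- vapply(src, function(i)
    sample(lens[i] - read_len + 1L, 1L), integer(1))
  seqs <- substr(sources[src], start, start + read_len - 1L)
  flip <- runif(n_reads) < 0.5
  seqs[flip] <- revcomp(seqs[flip])
  seqs <- .add_errors(seqs, error_rate)
  # provenance columns (truth metadata; ignored by the pipeline)
  out <- tibble(read_id = sprintf("%s%06d", prefix, seq_len(n_reads)),
                seq = unname(seqs),
                src = names(sources)[src], src_start = start - 1L,
                src_strand = ifelse(flip, "-", "+"))
  attr(out, "read_length") <- as.integer(read_len)
  out
}

#' Simulate RNA and genomic read sets from a truth set
#'
#' RNA reads sample the true spliced mRNAs (both strands), genomic reads the
#' true genome, both with uniform start positions and the configured per-base
#' substitution error rate. Genomic reads therefore cover hidden exons and
#' their flanking introns even though the masked assembly does not.
#'
#' @param truth a [simulate_genome()] result.
#' @param config the same [simulation_config()].
#' @param seed integer seed.
#' @return list with tibbles `rna` and `genomic` (columns `read_id`, `seq`;
#'   attribute `read_length`).
#' @export
simulate_reads <- function(truth, config = truth$config, seed = 1L) {
  withr::with_seed(seed, {
    glen <- sum(nchar(truth$genome))
    n_gen <- ceiling(config$genomic_depth * glen /
                       config$genomic_read_length)
    genomic <- .sample_reads(unclass(truth$genome), n_gen,
                             config$genomic_read_length, config$error_rate,
                             "gr")
    mrnas <- vapply(truth$models_true, `[[`, character(1), "spliced")
    n_rna <- ceiling(config$rna_depth * sum(nchar(mrnas)) /
                       config$rna_read_length)
    rna <- .sample_reads(mrnas, n_rna, config$rna_read_length,
                         config$error_rate, "rr")
    list(rna = rna, genomic = genomic)
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_genome()],
#' [make_transcript_objects()] and [simulate_reads()] on independent
#' substreams derived from one seed, so each stage is reproducible in
#' isolation.
#'
#' @param config a [simulation_config()].
#' @param seed integer master seed.
#' @return list with `truth`, `objects`, `object_registry`, `reads`.
#' @export
simulate_dataset <- function(config = simulation_config(), seed = 1L) {
  truth <- simulate_genome(config, seed = seed)
  obj <- make_transcript_objects(truth, config, seed = seed + 1000L)
  reads <- simulate_reads(truth, config, seed = seed + 2000L)
  list(truth = truth, objects = obj$objects,
       object_registry = obj$registry, reads = reads)
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `assembly_masked.fa`, `models.gff3`, `objects.fa`,
#' `rna.fastq`, `genomic.fastq` and `truth.json` under `outdir`.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_genome_fasta(dataset$truth$genome, p("genome.fa"))
  write_genome_fasta(dataset$truth$assembly, p("assembly_masked.fa"))
  write_models_gff3(dataset$truth$models, p("models.gff3"))
  write_genome_fasta(as_genome_assembly(dataset$objects), p("objects.fa"))
  write_reads_fastq(dataset$reads$rna, p("rna.fastq"))
  write_reads_fastq(dataset$reads$genomic, p("genomic.fastq"))
  jsonlite::write_json(
    list(islands = dataset$truth$islands,
         hidden_exons = dataset$truth$hidden_exons,
         objects = dataset$object_registry),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
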