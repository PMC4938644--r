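# Readers/writers for external formats and the shared coordinate model.
# All internal coordinates are 0-based half-open; GFF3 I/O converts to and
# from the standard 1-based inclusive dialect.

#' Reverse-complement a nucleotide string
#'
#' Vectorised over `x`; ambiguity codes other than N are not expected anywhere
#' in this package and are mapped to N.
#' @param x character vector of nucleotide strings over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTacgt", "TGCATGCA", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Load a genome assembly from FASTA
#'
#' Sequences are case-folded to upper case (soft-masking is ignored) and the
#' alphabet is restricted to A/C/G/T/N. Contig ids are the first whitespace-
#' delimited token of each FASTA header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return a named character vector of class `genome_assembly`, one element
#'   per contig, in file order.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("malformed FASTA '", path, "': no records")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  as_genome_assembly(seqs)
}

#' Construct a genome assembly from in-memory sequences
#'
#' @param seqs named character vector of contig sequences (A/C/G/T/N, any
#'   case).
#' @return a `genome_assembly`.
#' @export
as_genome_assembly <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all contigs must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L))
    stop("empty contig: ", names(seqs)[nchar(seqs) == 0L][1])
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("invalid residue in contig '", names(seqs)[i], "' at offset ",
         bad[i] - 1L)
  }
  structure(seqs, class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", length(x), " contig(s), ",
      format(sum(nchar(x)), big.mark = ","), " nt total, ",
      format(sum(nchar(gsub("[^N]", "", x)))), " N\n", sep = "")
  invisible(x)
}

#' Write a genome assembly to FASTA
#'
#' @param genome a `genome_assembly`.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(genome)) {
    writeLines(paste0(">", id), con)
    s <- genome[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Load sequencing reads from FASTQ (or FASTA)
#'
#' Qualities are read but ignored by downstream analysis.
#'
#' @param path path to a FASTQ file (FASTA also accepted via `format`).
#' @param format `"fastq"` or `"fasta"`.
#' @return a tibble with columns `read_id`, `seq`, carrying the typical read
#'   length in attribute `read_length`.
#' @export
load_reads <- function(path, format = "fastq") {
  set <- Biostrings::readDNAStringSet(path, format = format)
  reads <- tibble(read_id = sub("\\s.*$", "", names(set)),
                  seq = unname(toupper(as.character(set))))
  attr(reads, "read_length") <- as.integer(round(median(nchar(reads$seq))))
  reads
}

#' Write reads to FASTQ
#'
#' Constant quality `I` is emitted; the analysis never consumes qualities.
#' @param reads tibble with `read_id` and `seq` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                             "+", qual)), path)
  invisible(path)
}

#' Construct a transcript model
#'
#' Builds the spliced sequence and the ordered junction list of a transcript
#' from its genomic exon intervals. Junctions are indexed in mRNA (strand)
#' order; the `spliced_pos` of junction *j* is the cumulative spliced length
#' through mRNA exon *j*, i.e. the 0-based spliced coordinate of the first
#' base of exon *j + 1*. A junction is N-flagged when at least one N run lies
#' strictly inside its intron.
#'
#' @param transcript_id,gene_id identifiers.
#' @param contig contig id in `genome`.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix or data frame with columns `start`, `end`
#'   (0-based half-open genomic intervals, any order; they are sorted).
#' @param genome a `genome_assembly`.
#' @return a list of class `transcript_model` with elements `transcript_id`,
#'   `gene_id`, `contig`, `strand`, `exons` (sorted matrix), `spliced`
#'   (mRNA-orientation sequence) and `junctions` (tibble with
#'   `junction_index`, `spliced_pos`, `intron_start`, `intron_end`, `n_flag`).
#' @export
transcript_model <- function(transcript_id, contig, strand, exons, genome,
                             gene_id = transcript_id) {
  exons <- as.matrix(as.data.frame(exons)[, c("start", "end")])
  storage.mode(exons) <- "integer"
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  dimnames(exons) <- list(NULL, c("start", "end"))
  if (nrow(exons) == 0L) stop("transcript '", transcript_id, "' has no exons")
  if (any(exons[, 2] - exons[, 1] < 1L))
    stop("transcript '", transcript_id, "' has an empty exon")
  if (nrow(exons) > 1L && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("transcript '", transcript_id, "' has overlapping exons")
  if (!contig %in% names(genome))
    stop("transcript '", transcript_id, "' on unknown contig '", contig, "'")
  clen <- nchar(genome[[contig]])
  if (any(exons[, 1] < 0L) || any(exons[, 2] > clen))
    stop("transcript '", transcript_id, "' extends outside contig '", contig,
         "' [0,", clen, ")")
  stopifnot(strand %in% c("+", "-"))

  exon_seqs <- substring(genome[[contig]], exons[, 1] + 1L, exons[, 2])
  if (strand == "+") {
    spliced <- paste(exon_seqs, collapse = "")
    mrna_order <- seq_len(nrow(exons))
  } else {
    spliced <- paste(rev(revcomp(exon_seqs)), collapse = "")
    mrna_order <- rev(seq_len(nrow(exons)))
  }
  m <- nrow(exons)
  if (m > 1L) {
    lens <- (exons[, 2] - exons[, 1])[mrna_order]
    # intron following mRNA exon j, in genomic coordinates
    gi <- if (strand == "+") seq_len(m - 1L) else rev(seq_len(m - 1L))
    intron_start <- unname(exons[gi, 2])
    intron_end <- unname(exons[gi + 1L, 1])
    intron_seq <- substring(genome[[contig]], intron_start + 1L, intron_end)
    junctions <- tibble(
      junction_index = seq_len(m - 1L),
      spliced_pos = unname(cumsum(lens)[-m]),
      intron_start = intron_start,
      intron_end = intron_end,
      n_flag = grepl("N", intron_seq, fixed = TRUE)
    )
  } else {
    junctions <- tibble(junction_index = integer(), spliced_pos = integer(),
                        intron_start = integer(), intron_end = integer(),
                        n_flag = logical())
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 contig = contig, strand = strand, exons = exons,
                 spliced = spliced, junctions = junctions),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$transcript_id, " (", x$strand, ") ", x$contig,
      ":", x$exons[1, 1], "-", x$exons[nrow(x$exons), 2], " ",
      nrow(x$exons), " exon(s), spliced ", nchar(x$spliced), " nt, ",
      sum(x$junctions$n_flag), " N-flagged junction(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.transcript_model <- function(x, ...) {
  tibble(transcript_id = x$transcript_id, gene_id = x$gene_id,
         contig = x$contig, strand = x$strand,
         exon = seq_len(nrow(x$exons)),
         start = x$exons[, 1], end = x$exons[, 2])
}

#' Load transcript models from GFF3
#'
#' Reads `gene`/`mRNA`/`exon` features (1-based inclusive coordinates) and
#' returns strand-aware [transcript_model()] objects with 0-based half-open
#' internal coordinates.
#'
#' @param path path to a GFF3 file.
#' @param genome a `genome_assembly` covering the models.
#' @return a named list of `transcript_model` objects.
#' @export
load_transcript_models <- function(path, genome) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  if (nrow(mrna) == 0L) stop("no mRNA features in '", path, "'")
  parent <- vapply(exons$Parent, function(p) as.character(p)[1], character(1))
  models <- lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$ID[i]
    ex <- exons[parent == tid, , drop = FALSE]
    if (nrow(ex) == 0L) stop("mRNA '", tid, "' has no exons")
    gid <- if (!is.null(mrna$Parent) && length(mrna$Parent[[i]]) > 0)
      as.character(mrna$Parent[[i]])[1] else tid
    transcript_model(tid, as.character(mrna$seqnames[i]),
                     as.character(mrna$strand[i]),
                     data.frame(start = ex$start - 1L, end = ex$end),
                     genome, gene_id = gid)
  })
  setNames(models, vapply(models, `[[`, character(1), "transcript_id"))
}

#' Write transcript models to GFF3
#'
#' Emits `gene`, `mRNA` and `exon` features in the standard 1-based inclusive
#' dialect; round-trips exactly through [load_transcript_models()].
#'
#' @param models list of `transcript_model` objects.
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_models_gff3 <- function(models, path, source = "exonpatch") {
  lines <- c("##gff-version 3")
  for (m in models) {
    g1 <- min(m$exons[, 1]) + 1L
    g2 <- max(m$exons[, 2])
    lines <- c(lines,
      paste(m$contig, source, "gene", g1, g2, ".", m$strand, ".",
            paste0("ID=", m$gene_id), sep = "\t"),
      paste(m$contig, source, "mRNA", g1, g2, ".", m$strand, ".",
            paste0("ID=", m$transcript_id, ";Parent=", m$gene_id), sep = "\t"),
      paste(m$contig, source, "exon", m$exons[, 1] + 1L, m$exons[, 2], ".",
            m$strand, ".",
            paste0("ID=", m$transcript_id, ".exon", seq_len(nrow(m$exons)),
                   ";Parent=", m$transcript_id), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Locate and classify N-islands
#'
#' An N-island is a maximal run of N in the assembly. Each island is labelled
#' `intronic` (fully inside an annotated intron; the label that wins all
#' others), `exonic` (overlapping an annotated exon), `flanking` (outside
#' every model but starting within `flank_distance` of a gene-model boundary)
#' or `intergenic`. Intronic islands carry their host transcript and intron
#' index; `n_hosts` counts models whose introns contain the island, so ties
#' remain visible.
#'
#' @param genome a `genome_assembly`.
#' @param models list of `transcript_model` objects (may be empty).
#' @param flank_distance distance in nt defining the flanking label.
#' @param min_length islands shorter than this are dropped.
#' @return tibble with columns `contig`, `start`, `end`, `length`, `context`,
#'   `host_transcript`, `host_intron`, `n_hosts`.
#' @export
find_n_islands <- function(genome, models = list(), flank_distance = 100L,
                           min_length = 1L) {
  rows <- list()
  for (contig in names(genome)) {
    m <- gregexpr("N+", genome[[contig]])[[1]]
    if (m[1] == -1L) next
    rows[[contig]] <- tibble(contig = contig,
                             start = as.integer(m) - 1L,
                             end = as.integer(m) - 1L +
                               attr(m, "match.length"))
  }
  islands <- if (length(rows)) bind_rows(rows) else
    tibble(contig = character(), start = integer(), end = integer())
  islands <- islands[islands$end - islands$start >= min_length, , drop = FALSE]
  n <- nrow(islands)
  context <- rep("intergenic", n)
  host_t <- rep(NA_character_, n)
  host_i <- rep(NA_integer_, n)
  n_hosts <- rep(0L, n)
  for (m in models) {
    span1 <- min(m$exons[, 1]); span2 <- max(m$exons[, 2])
    if (span2 > nchar(genome[[m$contig]]))
      stop("model '", m$transcript_id, "' out of contig bounds")
    on_contig <- islands$contig == m$contig
    for (i in which(on_contig)) {
      s <- islands$start[i]; e <- islands$end[i]
      jx <- m$junctions
      inside <- which(jx$intron_start <= s & e <= jx$intron_end)
      if (length(inside) > 0L) {
        n_hosts[i] <- n_hosts[i] + 1L
        if (context[i] != "intronic") {
          context[i] <- "intronic"
          host_t[i] <- m$transcript_id
          host_i[i] <- jx$junction_index[inside[1]]
        }
        next
      }
      if (context[i] == "intronic") next
      hits_exon <- any(pmax(s, m$exons[, 1]) < pmin(e, m$exons[, 2]))
      if (hits_exon) {
        context[i] <- "exonic"
      } else if (context[i] != "exonic" &&
                 !(s >= span1 && e <= span2) &&
                 (min(abs(c(s, e) - span1), abs(c(s, e) - span2)) <=
                    flank_distance) &&
                 pmax(s, span1) >= pmin(e, span2)) {
        context[i] <- "flanking"
      }
    }
  }
  islands$length <- islands$end - islands$start
  islands$context <- context
  islands$host_transcript <- host_t
  islands$host_intron <- host_i
  islands$n_hosts <- n_hosts
  islands[order(islands$contig, islands$start), ]
}
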