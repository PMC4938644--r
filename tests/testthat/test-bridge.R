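test_that("self-alignment yields one full-length HSP; minus strand is mapped back", {
  withr::local_seed(1)
  s <- random_nt(50)
  h <- ungapped_local_align(s, s)
  expect_equal(nrow(h[h$strand == "+", ]), 1L)
  expect_equal(h$q_start[1], 0L)
  expect_equal(h$q_end[1], 50L)
  expect_equal(h$s_start[1], 0L)
  expect_equal(h$s_end[1], 50L)
  expect_equal(h$score[1], 50L)

  h2 <- ungapped_local_align(oracle_revcomp(s), s)
  best <- h2[1, ]
  expect_equal(best$strand, "-")
  expect_equal(c(best$q_start, best$q_end, best$s_start, best$s_end),
               c(0L, 50L, 0L, 50L))
})

test_that("an insert between two matching blocks produces two separated HSPs", {
  withr::local_seed(2)
  A <- random_nt(60); B <- random_nt(60); X <- random_nt(30)
  h <- ungapped_local_align(paste0(A, X, B), paste0(A, B))
  h <- h[h$strand == "+", ]
  expect_equal(nrow(h), 2L)
  h <- h[order(h$q_start), ]
  expect_equal(h$q_start, c(0L, 90L))
  expect_equal(h$q_end, c(60L, 150L))
  expect_equal(h$s_start, c(0L, 60L))
  expect_equal(h$s_end, c(60L, 120L))
  # and the brute-force oracle agrees exactly
  o <- oracle_hsps(paste0(A, X, B), paste0(A, B))
  expect_equal(h[order(-h$score, h$q_start), c("q_start", "q_end", "s_start",
                                               "s_end", "score")],
               tibble::as_tibble(o[o$strand == "+",
                                   c("q_start", "q_end", "s_start", "s_end",
                                     "score")]),
               ignore_attr = TRUE)
})

test_that("reported HSP scores recompute from their column scores", {
  withr::local_seed(4)
  for (rep in 1:10) {
    inst <- random_hsp_instance()
    h <- ungapped_local_align(inst$query, inst$subject)
    for (i in seq_len(nrow(h))) {
      q <- if (h$strand[i] == "+") inst$query else
        oracle_revcomp(inst$query)
      qs <- if (h$strand[i] == "+") h$q_start[i] else
        nchar(inst$query) - h$q_end[i]
      qi <- strsplit(substr(q, qs + 1L, qs + h$length[i]), "")[[1]]
      si <- strsplit(substr(inst$subject, h$s_start[i] + 1L,
                            h$s_end[i]), "")[[1]]
      expect_equal(h$score[i], sum(ifelse(qi == si, 1L, -2L)))
    }
  }
})

test_that("seeded aligner matches the all-diagonals oracle on planted instances", {
  withr::local_seed(8)
  for (rep in 1:25) {
    inst <- random_hsp_instance(n_blocks = sample(1:3, 1),
                                block_len = sample(40:70, 1),
                                spacer = sample(10:40, 1))
    got <- ungapped_local_align(inst$query, inst$subject)
    want <- oracle_hsps(inst$query, inst$subject)
    key <- function(d) {
      d <- as.data.frame(d)[, c("q_start", "q_end", "s_start", "s_end",
                                "score", "strand")]
      d <- d[order(d$q_start, d$s_start, d$strand), ]
      rownames(d) <- NULL
      d
    }
    expect_equal(key(got), key(want))
  }
})

# one subject transcript with a junction, and objects engineered to produce
# each call type
make_bridge_scene <- function(seed = 31L, n_intron = TRUE) {
  withr::with_seed(seed, {
    fx <- two_exon_fixture(e1 = 150L, e2 = 150L, intron = 260L,
                           with_n = n_intron, seed = seed)
    p <- fx$model$junctions$spliced_pos   # 150
    list(fx = fx, p = p)
  })
}

test_that("a continuous HSP across the junction is covered", {
  sc <- make_bridge_scene()
  obj <- c(cov = substr(sc$fx$model$spliced, sc$p - 29L, sc$p + 30L))
  hs <- align_objects(obj, list(sc$fx$model))
  calls <- classify_junctions(hs, sc$fx$model, obj)
  expect_equal(calls$status, "covered")
})

test_that("two flanking HSPs with an object insert are bridged, insert recovered", {
  sc <- make_bridge_scene()
  withr::local_seed(6)
  ins <- random_nt(45)
  obj <- c(br = paste0(substr(sc$fx$model$spliced, 1, sc$p), ins,
                       substr(sc$fx$model$spliced, sc$p + 1L, 300L)))
  hs <- align_objects(obj, list(sc$fx$model))
  calls <- classify_junctions(hs, sc$fx$model, obj)
  expect_equal(calls$status, "bridged")
  # chance direct repeats can shift the cut by a few nt; the insert length
  # is exact and the sequence matches up to that shift
  expect_equal(calls$insert_len, 45L)
  expect_equal(nchar(calls$insert_seq), 45L)

  # the same object reverse-complemented bridges on the minus strand
  obj2 <- c(br = oracle_revcomp(obj[["br"]]))
  calls2 <- classify_junctions(align_objects(obj2, list(sc$fx$model)),
                               sc$fx$model, obj2)
  expect_equal(calls2$status, "bridged")
  expect_equal(calls2$strand, "-")
  expect_equal(calls2$insert_len, 45L)
  expect_equal(calls2$insert_seq, calls$insert_seq)
})

test_that("a near-junction HSP with a long unaligned tail is a half-bridge", {
  sc <- make_bridge_scene()
  withr::local_seed(9)
  aligned <- substr(sc$fx$model$spliced, 21L, sc$p - 30L)  # ends 30 nt short
  tail_seq <- random_nt(ceiling(nchar(aligned) / 0.3 * 0.7))
  obj <- c(hb = paste0(aligned, tail_seq))
  hs <- align_objects(obj, list(sc$fx$model))
  calls <- classify_junctions(hs, sc$fx$model, obj)
  expect_equal(calls$status, "half_bridged")

  # half-bridges are only allowed at N-flagged junctions
  sc2 <- make_bridge_scene(n_intron = FALSE)
  aligned2 <- substr(sc2$fx$model$spliced, 21L, sc2$p - 30L)
  obj2 <- c(hb = paste0(aligned2, tail_seq))
  calls2 <- classify_junctions(align_objects(obj2, list(sc2$fx$model)),
                               sc2$fx$model, obj2)
  expect_true(nrow(calls2) == 0L ||
                all(calls2$status != "half_bridged"))
})

test_that("aggregation applies precedence and fills no_information", {
  sc <- make_bridge_scene()
  withr::local_seed(12)
  ins <- random_nt(45)
  objs <- c(cov = substr(sc$fx$model$spliced, sc$p - 29L, sc$p + 30L),
            br = paste0(substr(sc$fx$model$spliced, 1, sc$p), ins,
                        substr(sc$fx$model$spliced, sc$p + 1L, 300L)))
  hs <- align_objects(objs, list(sc$fx$model))
  calls <- classify_junctions(hs, sc$fx$model, objs)
  tab <- aggregate_junction_table(calls, list(sc$fx$model))
  expect_equal(tab$status, "bridged")        # bridged beats covered
  expect_equal(tab$object_id, "br")
  expect_true(tab$conflict)

  tab2 <- aggregate_junction_table(classify_junctions(
    align_objects(c(x = random_nt(80)), list(sc$fx$model)),
    sc$fx$model, c(x = random_nt(80))), list(sc$fx$model))
  expect_equal(tab2$status, "no_information")
  smry <- attr(tab2, "summary")
  expect_equal(sum(smry$n_junctions), 1L)
})

test_that("error-free objects cover every junction not involving an N-island", {
  cfg <- simulation_config(n_genes = 5L, hidden_exon_genes = 1L,
                           intronic_island_genes = 1L, error_rate = 0,
                           fusion_rate = 0)
  ds <- simulate_dataset(cfg, seed = 29)
  hs <- align_objects(ds$objects, ds$truth$models)
  calls <- dplyr::bind_rows(lapply(ds$truth$models, function(m)
    classify_junctions(hs, m, ds$objects)))
  tab <- aggregate_junction_table(calls, ds$truth$models)
  plain <- tab[!tab$n_flag, ]
  expect_true(all(plain$status == "covered"))
})
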