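# helper: minimal alignment row(s) for constructed cascade tests
aln_row <- function(read_id, q_start, q_end, tx, t_start,
                    e_value = 1e-9) {
  tibble::tibble(read_id = read_id, q_start = as.integer(q_start),
                 q_end = as.integer(q_end), transcript_id = tx,
                 t_start = as.integer(t_start),
                 t_end = as.integer(t_start + (q_end - q_start)),
                 matches = as.integer(q_end - q_start), e_value = e_value)
}
read_of <- function(id, len) tibble::tibble(read_id = id,
                                            sequence = strrep("A", len))

test_that("the non-hybrid rule is boundary-inclusive and prioritised", {
  # 60-nt read, one alignment covering 45 nt -> 15 unaligned -> non-hybrid
  aln <- dplyr::bind_rows(aln_row("r", 0, 45, "TX1", 0),
                          aln_row("r", 0, 25, "TX1", 200),
                          aln_row("r", 26, 60, "TX1", 400))
  got <- call_hybrids(aln, read_of("r", 60))
  expect_equal(got$class, "non_hybrid") # despite a valid hybrid pair
  # 16 nt unaligned -> the hybrid pair wins
  aln2 <- dplyr::bind_rows(aln_row("r", 0, 44, "TX1", 0),
                           aln_row("r", 0, 25, "TX1", 200),
                           aln_row("r", 26, 60, "TX1", 400))
  got2 <- call_hybrids(aln2, read_of("r", 60))
  expect_equal(got2$class, "unique") # only the 25+34 pair passes the filters
  expect_equal(got2$prox_start, 200L)
})

test_that("arm pairs respect the q-gap/overlap window of 4 nt", {
  mk <- function(gap) {
    dplyr::bind_rows(aln_row("r", 0, 30, "TX1", 0),
                     aln_row("r", 30 + gap, 70, "TX1", 500))
  }
  for (gap in c(-4, 0, 4)) {
    expect_equal(call_hybrids(mk(gap), read_of("r", 80))$class, "unique")
  }
  for (gap in c(-5, 5)) {
    expect_equal(call_hybrids(mk(gap), read_of("r", 80))$class, "none")
  }
})

test_that("intra-transcript reference overlaps are removed, adjacency kept", {
  mk <- function(t2) {
    dplyr::bind_rows(aln_row("r", 0, 30, "TX1", 100),
                     aln_row("r", 30, 60, "TX1", t2))
  }
  expect_equal(call_hybrids(mk(129), read_of("r", 80))$class, "none")
  got <- call_hybrids(mk(130), read_of("r", 80)) # touching, not overlapping
  expect_equal(got$class, "unique")
  expect_equal(got$prox_start, 100L)
  expect_equal(got$dist_start, 130L)
})

test_that("the first arm must start within 5 nt of the read 5' end", {
  mk <- function(q0) {
    dplyr::bind_rows(aln_row("r", q0, q0 + 30, "TX1", 0),
                     aln_row("r", q0 + 30, q0 + 60, "TX1", 500))
  }
  expect_equal(call_hybrids(mk(5), read_of("r", 100))$class, "unique")
  expect_equal(call_hybrids(mk(6), read_of("r", 100))$class, "none")
})

test_that("proximal/distal labels follow reference orientation within a
transcript", {
  aln <- dplyr::bind_rows(aln_row("r", 0, 30, "TX1", 800),
                          aln_row("r", 30, 60, "TX1", 100))
  got <- call_hybrids(aln, read_of("r", 70))
  expect_equal(got$class, "unique")
  expect_equal(got$prox_start, 100L)
  expect_equal(got$dist_start, 800L)
  expect_false(got$inter_transcript)
})

test_that("multimap resolution uses the unique pool, then aligned length", {
  pool <- tibble::tibble(read_id = "u1", q1_start = 0L, q1_end = 30L,
                         q2_start = 30L, q2_end = 60L,
                         prox_tx = "TX1", prox_start = 95L, prox_end = 125L,
                         dist_tx = "TX1", dist_start = 495L, dist_end = 525L,
                         total_aligned = 60L, inter_transcript = FALSE)
  cand <- dplyr::bind_rows(
    dplyr::mutate(pool, read_id = "m", prox_start = 100L, prox_end = 130L,
                  dist_start = 500L, dist_end = 530L, total_aligned = 58L),
    dplyr::mutate(pool, read_id = "m", prox_tx = "TX2", dist_tx = "TX2",
                  total_aligned = 60L))
  got <- resolve_multimaps(cand, pool)
  expect_equal(nrow(got), 1)
  expect_equal(got$prox_tx, "TX1") # pool overlap beats higher aligned length
  # two pool-overlapping candidates: greatest total_aligned wins
  cand2 <- dplyr::bind_rows(
    dplyr::mutate(cand[1, ], total_aligned = 58L),
    dplyr::mutate(cand[1, ], prox_start = 90L, prox_end = 120L,
                  dist_start = 490L, dist_end = 520L, total_aligned = 52L))
  expect_equal(resolve_multimaps(cand2, pool)$total_aligned, 58L)
  # equal total_aligned -> unresolved
  cand3 <- dplyr::mutate(cand2, total_aligned = 58L)
  expect_equal(nrow(resolve_multimaps(cand3, pool)), 0)
})

test_that("directional UMI deduplication collapses within mapping keys only", {
  base <- tibble::tibble(read_id = NA_character_, umi = NA_character_,
                         prox_tx = "TX1", prox_start = 100L, prox_end = 130L,
                         dist_tx = "TX1", dist_start = 500L, dist_end = 530L)
  h <- dplyr::bind_rows(
    dplyr::mutate(base[rep(1, 2), ], read_id = c("a", "b"), umi = "AAAA"),
    dplyr::mutate(base[rep(1, 10), ], read_id = sprintf("c%d", 1:10),
                  umi = "CCCC"),
    dplyr::mutate(base, read_id = "d", umi = "CCCA"),
    dplyr::mutate(base, read_id = "e", umi = "AAAA", dist_start = 900L))
  got <- dedup_hybrids(h)
  # AAAA x2 -> 1; CCCC x10 + CCCA x1 -> 1 (directional merge);
  # AAAA at another distal start -> its own molecule
  expect_equal(nrow(got), 3)
  expect_equal(sum(got$dup_count), nrow(h))
  merged <- got[got$umi == "CCCC", ]
  expect_equal(merged$dup_count, 11L)
  # a distant UMI at equal counts is not merged
  h2 <- dplyr::bind_rows(
    dplyr::mutate(base[rep(1, 2), ], read_id = c("x1", "x2"), umi = "AAAA"),
    dplyr::mutate(base[rep(1, 2), ], read_id = c("y1", "y2"), umi = "AAAT"))
  expect_equal(nrow(dedup_hybrids(h2)), 2) # 2 >= 2*2-1 fails
  h3 <- dplyr::bind_rows(
    dplyr::mutate(base[rep(1, 3), ], read_id = c("x1", "x2", "x3"), umi = "AAAA"),
    dplyr::mutate(base[rep(1, 2), ], read_id = c("y1", "y2"), umi = "AAAT"))
  expect_equal(nrow(dedup_hybrids(h3)), 1) # 3 >= 2*2-1 holds
  expect_error(dedup_hybrids(dplyr::mutate(base, umi = NA_character_)),
               "UMI")
})

test_that("dedup never merges hybrids with different arm-start keys", {
  set.seed(51)
  base <- tibble::tibble(prox_tx = "TX1", prox_end = 130L,
                         dist_tx = "TX1", dist_end = 530L)
  h <- dplyr::bind_rows(lapply(1:80, function(i) {
    dplyr::mutate(base, read_id = sprintf("r%d", i),
                  umi = paste(sample(c("A", "C", "G", "T"), 4,
                                     replace = TRUE), collapse = ""),
                  prox_start = sample(c(100L, 101L), 1),
                  dist_start = sample(c(500L, 501L), 1))
  }))
  got <- dedup_hybrids(h)
  key_in <- unique(paste(h$prox_start, h$dist_start))
  key_out <- paste(got$prox_start, got$dist_start)
  expect_true(all(key_out %in% key_in))
  agg_in <- table(paste(h$prox_start, h$dist_start))
  agg_out <- tapply(got$dup_count, key_out, sum)
  expect_equal(as.integer(agg_out[names(agg_in)]), as.integer(agg_in))
})

test_that("linker-read arms place uniquely or not at all", {
  set.seed(52)
  ref <- random_reference(2, 1200)
  # plant a shared 20-mer so one arm multimaps
  shared <- hiclipr:::random_dna(20)
  s1 <- ref$sequence[1]; s2 <- ref$sequence[2]
  substr(s1, 601, 620) <- shared
  substr(s2, 301, 320) <- shared
  ref2 <- make_reference(tibble::tibble(
    transcript_id = ref$transcript_id, sequence = c(s1, s2)))
  lnk <- "CTGTAGGCACCATCAATAC"
  mk <- function(id, a1, a2) tibble::tibble(
    read_id = id, sequence = paste0(strrep("A", 6), a1, lnk, a2))
  reads <- dplyr::bind_rows(
    mk("ok", substr(s1, 101, 125), substr(s1, 401, 425)),
    mk("multi", substr(s1, 101, 125), shared),
    mk("ovl", substr(s1, 101, 125), substr(s1, 96, 120)))
  prep <- prepare_reads(reads, linker = lnk, umi_length = 6)
  got <- place_linker_hybrids(prep, ref2)
  expect_equal(got$read_id, "ok")
  expect_equal(got$prox_start, 100L)
  expect_equal(got$dist_start, 400L)
  expect_equal(got$source, "linker_full")
  expect_equal(attr(got, "n_unplaced"), 2L)
})
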