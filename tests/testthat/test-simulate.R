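test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_transcripts = 6, length_range = c(400, 600),
                    n_duplexes = 20, n_reads = 50)
  set.seed(111); a <- sim_transcriptome(cfg)
  set.seed(111); b <- sim_transcriptome(cfg)
  expect_identical(a$reference$sequence, b$reference$sequence)
  expect_identical(a$truth, b$truth)
  set.seed(7); ra <- sim_reads(a$reference, a$truth, cfg)
  set.seed(7); rb <- sim_reads(b$reference, b$truth, cfg)
  expect_identical(ra, rb)
})

test_that("planted arms really base-pair and every read has provenance", {
  set.seed(112)
  cfg <- sim_config(n_transcripts = 8, n_duplexes = 30, n_reads = 120)
  sim <- sim_transcriptome(cfg)
  seqs <- setNames(sim$reference$sequence, sim$reference$transcript_id)
  for (k in sample(nrow(sim$truth), 10)) {
    d <- sim$truth[k, ]
    a1 <- substr(seqs[[d$prox_tx]], d$prox_start + 1, d$prox_end)
    a2 <- substr(seqs[[d$dist_tx]], d$dist_start + 1, d$dist_end)
    expect_gte(duplex_mfe(a1, a2)$n_pairs, 8)
  }
  reads <- sim_reads(sim$reference, sim$truth, cfg)
  expect_true(all(reads$duplex_id %in% sim$truth$duplex_id))
  expect_true(all(nchar(reads$umi) == cfg$umi_length))
  # read sequences embed their UMI
  expect_equal(substr(reads$sequence, 1, cfg$umi_length), reads$umi)
})

test_that("an empty simulation yields empty outputs", {
  set.seed(113)
  sim <- sim_transcriptome(sim_config(n_transcripts = 0, n_duplexes = 0))
  expect_equal(nrow(sim$reference), 0)
  expect_equal(nrow(sim$truth), 0)
  expect_error(sim_transcriptome(sim_config(n_transcripts = 2,
                                            length_range = c(60, 70))),
               "unsatisfiable")
})

test_that("read-type fractions and linker truncations follow the config", {
  set.seed(114)
  cfg <- sim_config(n_transcripts = 8, n_duplexes = 30, n_reads = 600,
                    read_fractions = c(linker = 1, direct = 0, stemloop = 0),
                    pcr_rate = 0)
  sim <- sim_transcriptome(cfg)
  reads <- sim_reads(sim$reference, sim$truth, cfg)
  expect_true(all(reads$type == "linker"))
  lk <- find_linker(substring(reads$sequence, cfg$umi_length + 1),
                    cfg$linker)
  expect_true(all(lk$linker_status != "none"))
  # truncation proportions within exact binomial bounds
  obs <- table(factor(reads$linker_status,
                      c("full", "trunc1", "trunc2")))
  for (s in names(cfg$trunc_probs)) {
    ci <- stats::binom.test(obs[[s]], nrow(reads))$conf.int
    expect_true(cfg$trunc_probs[[s]] >= ci[1] - 0.02 &&
                  cfg$trunc_probs[[s]] <= ci[2] + 0.02)
  }
})

test_that("PCR duplication respects the configured rate and UMI errors", {
  set.seed(115)
  cfg0 <- sim_config(n_transcripts = 6, n_duplexes = 20, n_reads = 200,
                     pcr_rate = 0)
  sim <- sim_transcriptome(cfg0)
  r0 <- sim_reads(sim$reference, sim$truth, cfg0)
  expect_false(any(r0$is_duplicate))
  keys <- paste(r0$umi, r0$tx1, r0$a1_start, r0$a2_start)
  expect_equal(anyDuplicated(keys), 0L)
  cfg1 <- sim_config(n_transcripts = 6, n_duplexes = 20, n_reads = 200,
                     pcr_rate = 0.3)
  r1 <- sim_reads(sim$reference, sim$truth, cfg1)
  expect_gt(sum(r1$is_duplicate), 0)
  expect_lt(abs(sum(r1$is_duplicate) / 200 - 0.3), 0.12)
})

test_that("rate tables plant recoverable clusters deterministically", {
  set.seed(116); a <- sim_rates(30)
  set.seed(116); b <- sim_rates(30)
  expect_identical(a, b)
  expect_equal(sort(unique(a$true_cluster)), 1:3)
  one <- sim_rates(10, cluster_spec = tibble::tibble(
    synthesis = 0, processing = 0, degradation = 0, sd = 0.1))
  expect_equal(unique(one$true_cluster), 1)
})

test_that("planted hairpin peaks carry exact stem and loop geometry", {
  set.seed(117)
  sim <- sim_peak_hairpins(n_planted = 5, n_control = 3)
  expect_equal(nrow(sim$peaks), 8)
  expect_equal(nrow(sim$truth), 5)
  seqs <- setNames(sim$reference$sequence, sim$reference$transcript_id)
  for (k in seq_len(5)) {
    tr <- sim$truth[k, ]
    a1 <- substr(seqs[[tr$transcript_id]], tr$a1_start + 1, tr$a1_end)
    a2 <- substr(seqs[[tr$transcript_id]], tr$a2_start + 1, tr$a2_end)
    ds <- duplex_mfe(a1, a2, model = "simple")
    expect_equal(ds$n_pairs, tr$stem) # the full stem pairs, nothing more
    expect_equal(tr$a2_start - tr$a1_end, tr$loop)
  }
})

test_that("FASTQ round-trips reads with header-encoded UMIs", {
  set.seed(118)
  cfg <- sim_config(n_transcripts = 5, n_duplexes = 10, n_reads = 30)
  sim <- sim_transcriptome(cfg)
  reads <- sim_reads(sim$reference, sim$truth, cfg)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(nrow(back), nrow(reads))
  expect_equal(back$sequence, reads$sequence)
  umi <- extract_umi(back, "header")
  expect_equal(umi$umi, reads$umi)
})
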