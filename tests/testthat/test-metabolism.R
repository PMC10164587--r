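test_that("expression matching thresholds at the duplex-gene 5th percentile", {
  rates <- tibble::tibble(gene_id = sprintf("G%03d", 1:200),
                          synthesis = 1, processing = 1, degradation = 1,
                          copy_number = c(1:100, seq(3, 300, 3)))
  dup_genes <- sprintf("G%03d", 1:100) # copy numbers 1..100
  got <- match_expression(rates, dup_genes)
  expect_equal(attr(got, "threshold"), 5.95) # interpolated 5th percentile
  expect_true(all(got$copy_number > 5.95))
  expect_equal(sum(got$has_duplex), sum((1:100) > 5.95))
  # all above threshold stay; single duplex gene thresholds at its value
  all_in <- match_expression(dplyr::mutate(rates, copy_number = 100),
                             dup_genes)
  expect_equal(nrow(all_in), 0) # nothing strictly above
  one <- match_expression(rates, "G050")
  expect_equal(attr(one, "threshold"), 50)
  expect_true(all(one$copy_number > 50))
  expect_error(match_expression(rates, "NOPE"), "duplex")
})

test_that("k-medoid clustering recovers planted rate classes", {
  skip_if_not_installed("mclust")
  set.seed(91)
  rates <- sim_rates(n_genes = 60)
  fit <- cluster_metabolism(rates)
  expect_equal(fit$k, 3L)
  ari <- mclust::adjustedRandIndex(fit$assignments$cluster,
                                   rates$true_cluster)
  expect_gte(ari, 0.95)
  expect_equal(fit$silhouette$k[which.max(fit$silhouette$avg_width)], 3)
  # label semantics: A has the highest mean degradation
  m <- dplyr::inner_join(rates, fit$assignments, by = "gene_id") %>%
    dplyr::group_by(cluster) %>%
    dplyr::summarise(deg = mean(log10(degradation)))
  expect_equal(m$cluster[which.max(m$deg)], "A")
  expect_equal(m$cluster[which.min(m$deg)], "C")
})

test_that("metabolism clustering is scale- and order-invariant", {
  set.seed(92)
  rates <- sim_rates(n_genes = 40)
  a <- cluster_metabolism(rates)
  b <- cluster_metabolism(dplyr::mutate(rates, degradation = degradation * 10))
  expect_equal(a$assignments, b$assignments) # z-scoring absorbs the scale
  perm <- sample.int(nrow(rates))
  c2 <- cluster_metabolism(rates[perm, ])
  expect_equal(dplyr::arrange(c2$assignments, gene_id),
               dplyr::arrange(a$assignments, gene_id))
  # degenerate input collapses with a warning
  same <- tibble::tibble(gene_id = sprintf("G%d", 1:5), synthesis = 1,
                         processing = 1, degradation = 1)
  expect_warning(d <- cluster_metabolism(same), "degenerate")
  expect_equal(unique(d$assignments$cluster), "A")
  # non-positive rates are dropped with a message
  bad <- dplyr::bind_rows(rates,
                          tibble::tibble(gene_id = "BAD", synthesis = -1,
                                         processing = 1, degradation = 1,
                                         copy_number = 1, true_cluster = 1))
  expect_message(e <- cluster_metabolism(bad), "dropped")
  expect_false("BAD" %in% e$assignments$gene_id)
})

test_that("compaction scores apply the intron corrections", {
  utr <- tibble::tibble(transcript_id = "TX1", start = 100L, end = 600L)
  d <- function(ps, de) tibble::tibble(duplex_id = "D1", prox_tx = "TX1",
                                       prox_start = as.integer(ps),
                                       dist_end = as.integer(de))
  # duplex spanning the whole intron-less UTR -> 1
  expect_equal(compaction_score(d(100, 600), utr)$compaction, 1)
  # span 100 in a 500-nt UTR -> 0.2; in a 400-nt UTR -> 0.25
  utr400 <- tibble::tibble(transcript_id = "TX1", start = 100L, end = 500L)
  expect_equal(compaction_score(d(150, 250), utr400)$compaction, 0.25)
  # a 100-nt intron inside both span and UTR: (300-100)/(500-100) = 0.5
  utr500 <- tibble::tibble(transcript_id = "TX1", start = 0L, end = 500L)
  introns <- tibble::tibble(transcript_id = "TX1", start = 100L, end = 200L)
  got <- compaction_score(d(50, 350), utr500, introns)
  expect_equal(got$span_corrected, 200L)
  expect_equal(got$utr3_length_corrected, 400L)
  expect_equal(got$compaction, 0.5)
  # an intron outside both intervals changes nothing
  far <- tibble::tibble(transcript_id = "TX1", start = 8000L, end = 8100L)
  expect_equal(compaction_score(d(50, 350), utr500, far)$compaction,
               compaction_score(d(50, 350), utr500)$compaction)
  # errors: duplex outside the UTR; corrected length non-positive
  expect_error(compaction_score(d(700, 900), utr), "UTR")
  all_intron <- tibble::tibble(transcript_id = "TX1", start = 0L, end = 500L)
  expect_error(compaction_score(d(0, 500), utr500, all_intron),
               "non-positive")
})

test_that("thirds spanned counts distinct thirds intersected", {
  utr <- tibble::tibble(start = 0L, end = 300L)
  d <- function(ps, de) tibble::tibble(prox_start = as.integer(ps),
                                       dist_end = as.integer(de))
  expect_equal(thirds_spanned(d(10, 50), utr), 1)
  expect_equal(thirds_spanned(d(10, 290), utr), 3)
  expect_equal(thirds_spanned(d(90, 110), utr), 2)
  expect_equal(thirds_spanned(d(100, 150), utr), 1) # starts exactly at t1
  # remainder goes to the last third
  utr2 <- tibble::tibble(start = 0L, end = 304L)
  expect_equal(thirds_spanned(d(202, 303), utr2), 1)
})
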