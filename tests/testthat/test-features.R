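# hand-constructed structures: arms and explicit pair lists
perfect6 <- make_structure("GGGGGG", "CCCCCC",
                           lapply(1:6, function(i) c(i, 7L - i)))

test_that("loop annotation distinguishes bulges from internal loops", {
  expect_equal(nrow(annotate_loops(perfect6)), 0)
  # 1-nt gap on arm1 only after pair 3 -> bulge
  bulged <- make_structure("GGGAGGG", "CCCCCC",
                           list(c(1, 6), c(2, 5), c(3, 4),
                                c(5, 3), c(6, 2), c(7, 1)))
  loops <- annotate_loops(bulged)
  expect_equal(loops$kind, "bulge")
  expect_equal(loops$arm1_len, 1L)
  expect_equal(loops$arm2_len, 0L)
  expect_equal(loops$stem_position, 3L)
  # 2-nt gaps on both arms -> one (2,2) internal loop
  il <- make_structure("GGGAAGGG", "CCCAACCC",
                       list(c(1, 8), c(2, 7), c(3, 6),
                            c(6, 3), c(7, 2), c(8, 1)))
  got <- annotate_loops(il)
  expect_equal(got$kind, "internal_loop")
  expect_equal(c(got$arm1_len, got$arm2_len), c(2L, 2L))
  # 2-nt gap on one arm only is still an internal loop, not a bulge
  il2 <- make_structure("GGGAAGGG", "CCCCCC",
                        list(c(1, 6), c(2, 5), c(3, 4),
                             c(6, 3), c(7, 2), c(8, 1)))
  expect_equal(annotate_loops(il2)$kind, "internal_loop")
})

test_that("symmetry classes follow the strict all-mirrored rule", {
  expect_equal(classify_symmetry(perfect6), "perfect")
  sym <- make_structure("GGGAAGGG", "CCCAACCC",
                        list(c(1, 8), c(2, 7), c(3, 6),
                             c(6, 3), c(7, 2), c(8, 1)))
  expect_equal(classify_symmetry(sym), "symmetric")
  bulged <- make_structure("GGGAGGG", "CCCCCC",
                           list(c(1, 6), c(2, 5), c(3, 4),
                                c(5, 3), c(6, 2), c(7, 1)))
  expect_equal(classify_symmetry(bulged), "asymmetric_with_bulge")
  asym <- make_structure("GGGAAGGG", "CCCACCC",
                         list(c(1, 7), c(2, 6), c(3, 5),
                              c(6, 3), c(7, 2), c(8, 1)))
  expect_equal(classify_symmetry(asym), "asymmetric_no_bulge")
  expect_equal(symmetry_fraction(sym), 1)
  expect_equal(symmetry_fraction(bulged), 0)
})

test_that("mirrored loop insertions stay symmetric for any loop size", {
  set.seed(81)
  for (rep in 1:20) {
    stem1 <- sample(2:5, 1); stem2 <- sample(2:5, 1)
    gap <- sample(1:6, 1)
    n <- stem1 + gap + stem2
    arm1 <- paste0(strrep("G", stem1), strrep("A", gap), strrep("G", stem2))
    arm2 <- paste0(strrep("C", stem2), strrep("A", gap), strrep("C", stem1))
    pairs <- c(lapply(seq_len(stem1), function(i) c(i, n + 1L - i)),
               lapply(seq_len(stem2), function(i) {
                 c(stem1 + gap + i, stem2 + 1L - i)
               }))
    ds <- make_structure(arm1, arm2, pairs)
    expect_equal(classify_symmetry(ds),
                 if (gap == 0) "perfect" else "symmetric")
  }
})

test_that("composition reports pair content and contiguous stems", {
  got <- composition(perfect6)
  expect_equal(got$au_pair_pct, 0)
  expect_equal(got$gc_pct, 100)
  expect_equal(got$percent_paired, 100)
  expect_equal(got$longest_stem_segment, 6L)
  mixed <- make_structure("AUGC", "GCAU",
                          list(c(1, 4), c(2, 3), c(3, 2), c(4, 1)))
  expect_equal(composition(mixed)$au_pair_pct, 50)
  # 3 pairs, bulge, then 5 pairs -> longest segment 5
  arm1 <- "GGGAGGGGG"; arm2 <- "CCCCCCCC"
  pairs <- c(lapply(1:3, function(i) c(i, 9L - i)),
             lapply(1:5, function(i) c(4L + i, 6L - i)))
  expect_equal(composition(make_structure(arm1, arm2, pairs))$
                 longest_stem_segment, 5L)
  empty <- make_structure("AAAA", "AAAA", list(), energy = 0)
  expect_equal(composition(empty)$n_pairs, 0L)
})

test_that("span classes use the printed boundaries and partition all spans", {
  d <- tibble::tibble(duplex_id = sprintf("D%d", 1:4),
                      span = c(24L, 25L, 100L, 101L))
  got <- classify_spans(d)
  expect_equal(got$span_class, c("short", "medium", "medium", "long"))
  derived <- tibble::tibble(duplex_id = "D5", span = NA_integer_,
                            sources = "derived")
  expect_equal(classify_spans(derived)$span_class, "derived")
  expect_error(classify_spans(tibble::tibble(duplex_id = "D6",
                                             span = NA_integer_)),
               "span undefined")
  spans <- sample(0:500, 200, replace = TRUE)
  cls <- classify_spans(tibble::tibble(duplex_id = as.character(spans),
                                       span = spans))$span_class
  expect_true(all(cls %in% c("short", "medium", "long")))
  expect_equal(cls == "short", spans < 25)
  expect_equal(cls == "long", spans > 100)
})

test_that("span mixture EM recovers planted components with monotone
likelihood", {
  set.seed(82)
  x <- c(rnorm(1000, 250, 50), rnorm(1000, 20, 8))
  fit <- fit_span_mixture(x, k = 2)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_lt(abs(fit$mu[1] - 250), 3 * 50 / sqrt(1000))
  expect_lt(abs(fit$mu[2] - 20), 3 * 8 / sqrt(1000))
  expect_lt(abs(fit$lambda[1] - 0.5), 0.05)
  td <- tidy(fit)
  expect_equal(td$mu, fit$mu)
  expect_true(glance(fit)$converged)
  # one component reduces to the sample moments
  f1 <- fit_span_mixture(x, k = 1)
  expect_equal(f1$mu, mean(x), tolerance = 1e-6)
  expect_equal(f1$sigma, sd(x) * sqrt((length(x) - 1) / length(x)),
               tolerance = 1e-3)
  # degenerate data floors sigma
  fd <- fit_span_mixture(rep(5, 20), k = 2)
  expect_equal(fd$lambda[1], 1)
  expect_equal(fd$sigma[1], 1e-3)
})

test_that("span mixture agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(83)
  x <- c(rnorm(600, 250, 50), rnorm(600, 20, 8))
  fit <- fit_span_mixture(x, k = 2)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mus <- sort(mc$parameters$mean, decreasing = TRUE)
  expect_equal(fit$mu, unname(mus), tolerance = 0.02)
})

test_that("duplex feature tables combine structure, loops and energies", {
  set.seed(84)
  sim <- sim_transcriptome(sim_config(n_transcripts = 4,
                                      length_range = c(400, 500),
                                      n_duplexes = 8, inter_fraction = 0))
  dup <- sim$truth %>%
    dplyr::mutate(duplex_id = .data$duplex_id,
                  inter_transcript = FALSE)
  fx <- duplex_features(dup, sim$reference)
  expect_equal(nrow(fx), nrow(dup))
  expect_true(all(fx$n_pairs >= 8)) # planted complementary arms
  expect_true(all(fx$energy < 0))
  expect_true(all(fx$percent_paired > 0 & fx$percent_paired <= 100))
  expect_true(all(fx$normalised_energy < 0))
})
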