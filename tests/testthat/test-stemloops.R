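# constructed profile helpers
mk_profiles <- function(mat, rel = -100:100) {
  dplyr::bind_rows(lapply(seq_len(nrow(mat)), function(i) {
    tibble::tibble(peak_id = sprintf("p%03d", i), transcript_id = "TX1",
                   peak_start = 300L, rel_pos = rel, prob = mat[i, ],
                   control_prob = NA_real_)
  }))
}
m_curve <- function(shift = 0, rel = -100:100) {
  x <- rep(0.2, length(rel))
  b1 <- rel >= (5 + shift) & rel <= (25 + shift)
  b2 <- rel >= (30 + shift) & rel <= (46 + shift)
  x[b1] <- 0.9; x[b2] <- 0.85
  x
}

test_that("metaprofiles average with NaN-ignoring mean and SEM", {
  m <- rbind(rep(0.5, 201), rep(0.5, 201))
  got <- build_metaprofile(mk_profiles(m))
  expect_equal(unique(got$mean), 0.5)
  expect_equal(unique(got$sem), 0)
  m2 <- rbind(rep(0, 201), rep(1, 201))
  got2 <- build_metaprofile(mk_profiles(m2))
  expect_equal(unique(got2$mean), 0.5)
  expect_equal(unique(got2$sem), 0.5)
  m3 <- rbind(rep(0.2, 201), rep(0.4, 201), rep(NA_real_, 201))
  got3 <- build_metaprofile(mk_profiles(m3))
  expect_equal(unique(got3$mean), 0.3, tolerance = 1e-12)
  expect_equal(unique(got3$n), 2L)
  expect_error(build_metaprofile(mk_profiles(m3)[0, ]), "no profiles")
})

test_that("the M-shape detector needs two separated above-mean maxima", {
  pos <- 1:66
  two_bumps <- 0.3 + 0.5 * exp(-(pos - 18)^2 / 40) +
    0.5 * exp(-(pos - 48)^2 / 40)
  expect_true(detect_m_shape(two_bumps))
  expect_false(detect_m_shape(rep(0.5, 66)))
  one_bump <- 0.3 + 0.5 * exp(-(pos - 30)^2 / 80)
  expect_false(detect_m_shape(one_bump))
  # small-amplitude noise around a flat profile is not an M
  set.seed(101)
  noisy <- 0.5 + rnorm(66, 0, 0.01)
  expect_false(detect_m_shape(noisy))
})

test_that("arm delineation finds the local minima flanking the bumps", {
  reg <- delineate_arms(m_curve()[match(1:100, -100:100)])
  expect_false(is.null(reg))
  expect_lte(abs(reg$prox[2] - 26), 2) # first minimum near the 25/30 gap
  expect_equal(reg$prox[1], 1, tolerance = 2)
  expect_equal(reg$dist[1], reg$prox[2] + 1)
  expect_lte(abs(reg$dist[2] - 47), 3)
  expect_null(delineate_arms(rep(0.5, 100)))
  # a metaprofile tibble works too
  mp <- tibble::tibble(rel_pos = -100:100, mean = m_curve())
  reg2 <- delineate_arms(mp)
  expect_equal(reg2$prox, reg$prox)
})

test_that("profile clustering separates planted shapes and orders labels", {
  set.seed(102)
  flat <- t(vapply(1:30, function(i) {
    pmin(pmax(rep(0.25, 201) + rnorm(201, 0, 0.05), 0), 1)
  }, numeric(201)))
  emm <- t(vapply(1:30, function(i) {
    pmin(pmax(m_curve() + rnorm(201, 0, 0.05), 0), 1)
  }, numeric(201)))
  prof <- mk_profiles(rbind(emm, flat))
  cl <- cluster_peak_profiles(prof)
  expect_equal(cl$k, 2)
  asg <- cl$assignments
  planted <- as.integer(sub("p", "", asg$peak_id)) <= 30
  # cluster 1 = higher mean region probability = the M-shaped group
  expect_gte(mean(asg$cluster[planted] == 1), 0.98)
  expect_gte(mean(asg$cluster[!planted] == 2), 0.98)
  flags <- dplyr::distinct(asg, cluster, m_shape)
  expect_true(flags$m_shape[flags$cluster == 1])
  expect_false(flags$m_shape[flags$cluster == 2])
})

test_that("three shifted M groups give three shift-ordered clusters", {
  set.seed(103)
  mats <- lapply(c(0, 8, 16), function(sh) {
    t(vapply(1:25, function(i) {
      pmin(pmax(m_curve(sh) + rnorm(201, 0, 0.04), 0), 1)
    }, numeric(201)))
  })
  prof <- mk_profiles(do.call(rbind, mats))
  cl <- cluster_peak_profiles(prof, ks = 2:6)
  expect_equal(cl$k, 3)
  asg <- cl$assignments
  grp <- (as.integer(sub("p", "", asg$peak_id)) - 1) %/% 25
  tab <- table(asg$cluster, grp)
  # every planted shift maps to exactly one cluster
  expect_true(all(apply(tab, 2, function(x) max(x) / sum(x)) >= 0.95))
  # labels ordered by mean region probability: earliest shift has most
  # signal inside +10..+75 tail and the latest the most, so ordering is
  # deterministic even if not identity; just require a bijection
  expect_equal(length(unique(apply(tab, 2, which.max))), 3)
})

test_that("identical profiles collapse to a single cluster", {
  prof <- mk_profiles(matrix(0.4, nrow = 5, ncol = 201))
  cl <- cluster_peak_profiles(prof)
  expect_equal(cl$k, 1L)
  expect_equal(unique(cl$assignments$cluster), 1L)
})

test_that("duplex derivation recovers a planted hairpin and filters short
stems", {
  set.seed(104)
  # 12-bp stem, 6-nt loop planted 1 nt downstream of the peak start
  stem <- "GCAGGCGAUCGC"
  hp <- paste0(stem, "AACAAA", hiclipr:::revcomp(gsub("U", "T", stem)))
  bg <- hiclipr:::random_dna(400, 0.4)
  seqs <- paste0(substr(bg, 1, 200), gsub("U", "T", hp),
                 substr(bg, 231, 400))
  ref <- make_reference(tibble::tibble(transcript_id = "TX1",
                                       sequence = seqs))
  peak <- tibble::tibble(peak_id = "pk1", transcript_id = "TX1",
                         start = 199L)
  got <- derive_duplex(peak, c(1, 15), c(16, 42), ref)
  expect_false(is.null(got))
  expect_true(got$passes_filter)
  expect_equal(got$loop_length, 6L)
  expect_lte(abs(got$prox_start - 200L), 1)
  expect_lte(abs(got$dist_end - 230L), 1)
  # a 5-bp stem fails the >= 8 bp filter
  stem5 <- "GCAGG"
  hp5 <- paste0(stem5, "AACAAA", hiclipr:::revcomp(stem5))
  seqs5 <- paste0(strrep("A", 200), hp5, strrep("A", 150))
  ref5 <- make_reference(tibble::tibble(transcript_id = "TX1",
                                        sequence = seqs5))
  got5 <- derive_duplex(peak, c(1, 12), c(13, 25), ref5)
  expect_false(is.null(got5) && got5$passes_filter)
  # unstructured downstream sequence yields no duplex at all
  gotA <- derive_duplex(peak, c(1, 12), c(13, 25),
                        make_reference(tibble::tibble(
                          transcript_id = "TX1",
                          sequence = strrep("A", 400))))
  expect_null(gotA)
})

test_that("derivation handles empty input and off-reference peaks", {
  ref <- random_reference(1, 400)
  empty <- derive_stemloops(tibble::tibble(peak_id = character(),
                                           transcript_id = character(),
                                           start = integer()), ref)
  expect_equal(nrow(empty$duplexes), 0)
  off <- tibble::tibble(peak_id = c("a", "b"),
                        transcript_id = c("TX01", "MISSING"),
                        start = c(100L, 50L))
  expect_message(
    der <- derive_stemloops(off, ref, utr3_only = FALSE, ks = 2:3),
    "skipped")
  expect_equal(der$n_skipped, 1L)
})

test_that("derived duplex intervals lie downstream of their peaks", {
  set.seed(105)
  sim <- sim_peak_hairpins(n_planted = 6, n_control = 2, utr_length = 450)
  der <- derive_stemloops(sim$peaks, sim$reference, ks = 2:3,
                          control_iterations = 0)
  d <- der$duplexes
  if (nrow(d) > 0) {
    expect_true(all(d$prox_start >= d$peak_start))
    expect_true(all(d$dist_start >= d$prox_end))
    expect_true(all(d$loop_length >= 0))
  }
})
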