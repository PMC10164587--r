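#' Pairing-probability profiles around crosslink peak starts
#'
#' For every peak, computes the windowed per-base pairing probability of the
#' host transcript in the -`flank`..+`flank` region centred on the peak start
#' (positions outside the transcript are NA-padded). Probabilities are
#' computed on a clipped subsequence wide enough that every window covering a
#' profiled base is included, so values equal the full-transcript
#' computation. Optionally a control profile is computed from
#' dinucleotide-shuffled copies of the transcript.
#'
#' @param peaks Tibble with `peak_id`, `transcript_id`, `start` (0-based
#'   transcript coordinate of the peak start), or a BED path (chrom column
#'   holding transcript ids).
#' @param reference Reference tibble.
#' @param window Folding window length (default 100 nt).
#' @param flank Profile half-width (default 100 nt; profiles are
#'   2 * flank + 1 long).
#' @param control_iterations Shuffles averaged into the control profile per
#'   peak (0 disables).
#' @return Long tibble: `peak_id`, `transcript_id`, `peak_start`, `rel_pos`
#'   (-flank..+flank), `prob`, `control_prob`. Peaks on missing transcripts
#'   are skipped with a message.
#' @export
peak_profiles <- function(peaks, reference, window = 100, flank = 100,
                          control_iterations = 0) {
  peaks <- read_peaks(peaks)
  seqs <- setNames(reference$sequence, reference$transcript_id)
  missing <- !peaks$transcript_id %in% names(seqs)
  if (any(missing)) {
    inform(sprintf("peak_profiles: skipped %d peaks on missing transcripts",
                   sum(missing)))
    peaks <- peaks[!missing, , drop = FALSE]
  }
  off <- peaks$start >= nchar(seqs[peaks$transcript_id]) | peaks$start < 0
  if (any(off)) {
    inform(sprintf("peak_profiles: skipped %d peaks outside their transcript",
                   sum(off)))
    peaks <- peaks[!off, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(peaks)), function(k) {
    tx <- peaks$transcript_id[k]
    s <- seqs[[tx]]
    L <- nchar(s)
    p0 <- peaks$start[k]
    lo <- max(0L, p0 - flank - (window - 1L))
    hi <- min(L, p0 + flank + window)
    sub <- substr(s, lo + 1, hi)
    prob <- pairing_probabilities(sub, window = window)$prob
    ctrl_prob <- if (control_iterations > 0) {
      rowMeans(vapply(dinucleotide_shuffle(sub, control_iterations),
                      function(x) {
                        pairing_probabilities(x, window = window)$prob
                      }, numeric(nchar(sub))))
    } else rep(NA_real_, nchar(sub))
    rel <- (-flank):flank
    abs_pos <- p0 + rel
    inside <- abs_pos >= 0 & abs_pos < L
    pv <- cv <- rep(NA_real_, length(rel))
    pv[inside] <- prob[abs_pos[inside] - lo + 1]
    cv[inside] <- ctrl_prob[abs_pos[inside] - lo + 1]
    tibble(peak_id = peaks$peak_id[k], transcript_id = tx, peak_start = p0,
           rel_pos = rel, prob = pv, control_prob = cv)
  })
  bind_rows(rows)
}

read_peaks <- function(peaks) {
  if (is.character(peaks) && length(peaks) == 1) {
    bed <- rtracklayer::import.bed(peaks)
    df <- as_tibble(as.data.frame(bed))
    peaks <- tibble(
      peak_id = if ("name" %in% names(df) && !all(is.na(df$name))) df$name
                else sprintf("peak%05d", seq_len(nrow(df))),
      transcript_id = as.character(df$seqnames),
      start = df$start - 1L)
  }
  as_tibble(peaks)
}

#' Metaprofile (mean and standard error) across peak profiles
#'
#' @param profiles Long profile tibble from [peak_profiles()].
#' @param value Column to summarise (`"prob"` or `"control_prob"`).
#' @return Tibble `rel_pos`, `mean`, `sem`, `n` (NaN-ignoring).
#' @export
build_metaprofile <- function(profiles, value = "prob") {
  if (nrow(profiles) == 0) abort("no profiles")
  profiles %>%
    group_by(.data$rel_pos) %>%
    summarise(n = sum(!is.na(.data[[value]])),
              mean = mean(.data[[value]], na.rm = TRUE),
              sem = stats::sd(.data[[value]], na.rm = TRUE) /
                sqrt(pmax(1, sum(!is.na(.data[[value]])))),
              .groups = "drop") %>%
    mutate(sem = if_else(.data$n <= 1, 0, .data$sem)) %>%
    select("rel_pos", "mean", "sem", "n")
}

#' Detect the paired-unpaired-paired ('M'-shaped) profile signature
#'
#' TRUE when the smoothed profile (moving average, width 5) has at least two
#' local maxima above the region mean separated by a local minimum below it.
#' A small amplitude margin (default 0.05 probability units) is required on
#' both sides of the mean so that flat-but-noisy profiles (such as
#' shuffled-sequence controls) are not called M-shaped.
#'
#' @param x Numeric profile over the clustering region (e.g. +10..+75).
#' @param smooth Moving-average width (default 5).
#' @param margin Minimum excursion above/below the region mean (default
#'   0.05).
#' @return Logical.
#' @export
detect_m_shape <- function(x, smooth = 5, margin = 0.05) {
  x <- as.numeric(x)
  if (all(is.na(x))) return(FALSE)
  sm <- moving_average(x, smooth)
  m <- mean(sm, na.rm = TRUE)
  maxima <- local_extrema(sm, "max")
  maxima <- maxima[sm[maxima] > m + margin]
  if (length(maxima) < 2) return(FALSE)
  minima <- local_extrema(sm, "min")
  for (a in seq_len(length(maxima) - 1)) {
    between <- minima[minima > maxima[a] & minima < maxima[a + 1]]
    if (any(sm[between] < m - margin)) return(TRUE)
  }
  FALSE
}

#' Cluster peak pairing-probability profiles
#'
#' Extracts the profile region (default +10..+75 nt relative to peak starts),
#' drops peaks with more than `max_na` missing values there, imputes the rest
#' with position means, and runs k-means (over `ks`) choosing the k with the
#' best mean silhouette width. Clusters are labelled by decreasing mean
#' region probability (cluster 1 = most paired) and flagged `m_shape` when
#' their metaprofile shows the paired-unpaired-paired signature.
#'
#' @param profiles Long profile tibble from [peak_profiles()].
#' @param region Two-element vector of relative positions (default
#'   `c(10, 75)`).
#' @param ks Candidate numbers of clusters (default 2:8; shrunk when there
#'   are few profiles).
#' @param max_na Maximum fraction of missing region values per peak.
#' @param nstart k-means restarts (default 10).
#' @return Object of class `peak_clusters`: `assignments` (peak_id, cluster,
#'   m_shape), `k`, `silhouette` (k, avg_width), `metaprofiles` (cluster,
#'   rel_pos, mean, sem, n) over the full profile width, and `region`.
#' @export
cluster_peak_profiles <- function(profiles, region = c(10, 75), ks = 2:8,
                                  max_na = 0.2, nstart = 10) {
  reg <- profiles %>%
    filter(.data$rel_pos >= region[1], .data$rel_pos <= region[2]) %>%
    tidyr::pivot_wider(id_cols = "peak_id", names_from = "rel_pos",
                       values_from = "prob")
  mat <- as.matrix(reg[, -1])
  rownames(mat) <- reg$peak_id
  ok <- rowMeans(is.na(mat)) <= max_na
  mat <- mat[ok, , drop = FALSE]
  if (nrow(mat) == 0) abort("no usable profiles in the clustering region")
  cm <- colMeans(mat, na.rm = TRUE)
  for (j in seq_len(ncol(mat))) mat[is.na(mat[, j]), j] <- cm[j]
  ks <- ks[ks < nrow(mat)]
  sil <- tibble(k = integer(), avg_width = numeric())
  best <- NULL
  if (nrow(unique(mat)) == 1 || length(ks) == 0) {
    assignment <- rep(1L, nrow(mat))
    k_best <- 1L
  } else {
    d <- stats::dist(mat)
    fits <- list()
    for (k in ks) {
      fit <- kmeans(mat, centers = k, nstart = nstart, iter.max = 50)
      sw <- mean(cluster::silhouette(fit$cluster, d)[, 3])
      sil <- bind_rows(sil, tibble(k = k, avg_width = sw))
      fits[[as.character(k)]] <- fit
    }
    k_best <- sil$k[which.max(sil$avg_width)]
    best <- fits[[as.character(k_best)]]
    assignment <- best$cluster
  }
  # label clusters by decreasing mean region probability
  means <- tapply(rowMeans(mat), assignment, mean)
  relabel <- setNames(rank(-means, ties.method = "first"), names(means))
  assignment <- as.integer(relabel[as.character(assignment)])
  asg <- tibble(peak_id = rownames(mat), cluster = assignment)
  meta <- profiles %>%
    inner_join(asg, by = "peak_id") %>%
    group_by(.data$cluster) %>%
    dplyr::group_modify(~ build_metaprofile(.x)) %>%
    ungroup()
  m_flags <- meta %>%
    filter(.data$rel_pos >= region[1], .data$rel_pos <= region[2]) %>%
    group_by(.data$cluster) %>%
    summarise(m_shape = detect_m_shape(.data$mean), .groups = "drop")
  asg <- left_join(asg, m_flags, by = "cluster")
  structure(list(assignments = asg, k = k_best, silhouette = sil,
                 metaprofiles = meta, region = region),
            class = "peak_clusters")
}

#' @export
print.peak_clusters <- function(x, ...) {
  cat(sprintf("peak profile clustering: k = %d (%d peaks)\n", x$k,
              nrow(x$assignments)))
  print(count(x$assignments, .data$cluster, .data$m_shape))
  invisible(x)
}

#' @export
tidy.peak_clusters <- function(x, ...) x$assignments

#' Delineate proximal and distal arm regions from a cluster metaprofile
#'
#' Local minima of the smoothed metaprofile over the +1..+100 nt region
#' partition it: the proximal arm region runs from the rise start (the local
#' minimum, if any, preceding the first maximum) to the first minimum after
#' that maximum; the distal arm region continues to the next minimum. A
#' minimum falling on a region edge is assigned to the proximal region.
#' Profiles without the two required minima are rejected (NULL).
#'
#' @param metaprofile Tibble with `rel_pos`, `mean` (a cluster metaprofile)
#'   or numeric vector over +1..+100.
#' @param smooth Moving-average width (default 5).
#' @return List with `prox` and `dist`, each `c(from, to)` in nt downstream
#'   of the peak start (inclusive), or NULL when rejected.
#' @export
delineate_arms <- function(metaprofile, smooth = 5) {
  if (is.data.frame(metaprofile)) {
    mp <- filter(metaprofile, .data$rel_pos >= 1, .data$rel_pos <= 100)
    x <- mp$mean[order(mp$rel_pos)]
  } else {
    x <- as.numeric(metaprofile)
  }
  sm <- moving_average(x, smooth)
  maxima <- local_extrema(sm, "max")
  minima <- local_extrema(sm, "min")
  m <- mean(sm, na.rm = TRUE)
  maxima <- maxima[sm[maxima] > m]
  if (length(maxima) < 2) return(NULL)
  m1cand <- minima[minima > maxima[1] & minima < maxima[2]]
  if (length(m1cand) == 0) return(NULL)
  m1 <- m1cand[which.min(sm[m1cand])]
  m2cand <- minima[minima > maxima[2]]
  if (length(m2cand) == 0) {
    # fall back to where the profile decays below the region mean
    after <- which(seq_along(sm) > maxima[2] & sm < m)
    if (length(after) == 0) return(NULL)
    m2 <- after[1]
  } else {
    m2 <- m2cand[1]
  }
  rise <- minima[minima < maxima[1]]
  start <- if (length(rise) > 0) rise[length(rise)] else 1L
  list(prox = c(start, m1), dist = c(m1 + 1L, m2))
}

#' Derive a stem-loop duplex downstream of one crosslink peak
#'
#' Extracts the proximal and distal arm region sequences at the peak start
#' offsets (clipped to the transcript), predicts their minimum-free-energy
#' duplex, trims unpaired flanking nucleotides so the arm intervals start and
#' end at the outermost pair, and applies the minimum-stem filter. The
#' default `stem_rule = "contiguous"` requires the longest contiguous helix
#' to reach `min_stem` base pairs, reflecting the stem length a double-strand
#' RNA-binding domain engages; `"total"` counts all pairs in the duplex.
#'
#' @param peak One-row tibble (`peak_id`, `transcript_id`, `start`).
#' @param prox_region,dist_region Arm regions `c(from, to)` in nt downstream
#'   of the peak start (inclusive), from [delineate_arms()].
#' @param reference Reference tibble.
#' @param model Energy model.
#' @param min_stem Minimum number of base pairs (default 8).
#' @param stem_rule `"contiguous"` (default) applies `min_stem` to the
#'   longest contiguous stem segment; `"total"` to the total pair count.
#' @return One-row tibble (`peak_id`, arm intervals, `n_pairs`,
#'   `longest_stem`, `energy`, `loop_length`, `passes_filter`,
#'   `dot_bracket`) or NULL when no duplex forms or a region is empty after
#'   clipping.
#' @export
derive_duplex <- function(peak, prox_region, dist_region, reference,
                          model = "nearest_neighbour", min_stem = 8,
                          stem_rule = c("contiguous", "total")) {
  stem_rule <- match.arg(stem_rule)
  seqs <- setNames(reference$sequence, reference$transcript_id)
  s <- seqs[[peak$transcript_id]]
  if (is.null(s)) return(NULL)
  L <- nchar(s)
  p0 <- peak$start
  clip <- function(reg) {
    from <- max(0L, p0 + reg[1]); to <- min(L, p0 + reg[2] + 1L)
    if (from >= to) return(NULL)
    c(from, to) # 0-based half-open transcript interval
  }
  pr <- clip(prox_region); dr <- clip(dist_region)
  if (is.null(pr) || is.null(dr)) return(NULL)
  a1 <- substr(s, pr[1] + 1, pr[2])
  a2 <- substr(s, dr[1] + 1, dr[2])
  ds <- duplex_mfe(a1, a2, model = model)
  if (ds$n_pairs == 0) return(NULL)
  p <- ds$pairs
  prox_start <- pr[1] + min(p$i) - 1L
  prox_end <- pr[1] + max(p$i)
  dist_start <- dr[1] + min(p$j) - 1L
  dist_end <- dr[1] + max(p$j)
  comp <- composition(ds)
  passes <- if (stem_rule == "contiguous") {
    comp$longest_stem_segment >= min_stem
  } else {
    ds$n_pairs >= min_stem
  }
  tibble(peak_id = peak$peak_id, transcript_id = peak$transcript_id,
         peak_start = p0, prox_start = prox_start, prox_end = prox_end,
         dist_start = dist_start, dist_end = dist_end,
         n_pairs = ds$n_pairs, longest_stem = comp$longest_stem_segment,
         energy = ds$energy,
         loop_length = dist_start - prox_end,
         passes_filter = passes, dot_bracket = ds$dot_bracket)
}

#' Derive short-range stem-loop duplexes from crosslink peaks
#'
#' End-to-end derivation workflow: pairing-probability profiles around peak
#' starts (with shuffled controls), profile clustering, selection of clusters
#' with the paired-unpaired-paired signature, arm-region delineation per
#' cluster, per-peak duplex derivation and the minimum-stem filter. Peaks are
#' restricted to the 3' UTR of a representative transcript per gene when
#' `utr3_only` is set (representative table `gene_id` -> `transcript_id`, or
#' the longest annotated 3' UTR as fallback).
#'
#' @param peaks Peak tibble or BED path (see [peak_profiles()]).
#' @param reference Reference tibble.
#' @param window Folding window (default 100 nt).
#' @param region Clustering region relative to peak starts (default
#'   `c(10, 75)`).
#' @param ks Candidate cluster numbers (default 2:8).
#' @param min_stem Minimum base pairs for a bound stem-loop (default 8).
#' @param stem_rule Apply `min_stem` to the longest contiguous stem
#'   (`"contiguous"`, default) or to the total pair count (`"total"`); see
#'   [derive_duplex()].
#' @param control_iterations Per-peak shuffled-control iterations for the
#'   control metaprofile (default 1; the control metaprofile additionally
#'   averages across peaks).
#' @param utr3_only Restrict peaks to 3' UTR regions (default TRUE).
#' @param representative Optional tibble `gene_id`, `transcript_id` choosing
#'   the representative transcript per gene.
#' @param model Energy model.
#' @return Object of class `stemloop_derivation`: `profiles`, `clusters`
#'   (a `peak_clusters`), `arms` (per-cluster regions), `duplexes` (derived
#'   duplex tibble), `control_metaprofile`, `n_skipped`.
#' @export
derive_stemloops <- function(peaks, reference, window = 100,
                             region = c(10, 75), ks = 2:8, min_stem = 8,
                             stem_rule = c("contiguous", "total"),
                             control_iterations = 1, utr3_only = TRUE,
                             representative = NULL,
                             model = "nearest_neighbour") {
  stem_rule <- match.arg(stem_rule)
  peaks <- read_peaks(peaks)
  n_in <- nrow(peaks)
  if (n_in == 0) {
    return(structure(list(profiles = tibble(), clusters = NULL,
                          arms = list(), duplexes = tibble(),
                          control_metaprofile = tibble(), n_skipped = 0L),
                     class = "stemloop_derivation"))
  }
  if (utr3_only) {
    keep_tx <- utr3_transcripts(reference, representative)
    ann <- annotate_intervals(
      tibble(transcript_id = peaks$transcript_id, start = peaks$start,
             end = peaks$start + 1L)[peaks$transcript_id %in%
                                       reference$transcript_id, ],
      reference)
    ok_ids <- ann$transcript_id[ann$region == "UTR3"]
    peaks <- filter(peaks, .data$transcript_id %in% keep_tx,
                    .data$transcript_id %in% ok_ids |
                      !.data$transcript_id %in% reference$transcript_id)
  }
  profiles <- peak_profiles(peaks, reference, window = window,
                            control_iterations = control_iterations)
  n_skipped <- n_in - length(unique(profiles$peak_id))
  clusters <- cluster_peak_profiles(profiles, region = region, ks = ks)
  m_clusters <- unique(clusters$assignments$cluster[
    clusters$assignments$m_shape])
  arms <- list()
  dup_rows <- list()
  for (cl in sort(m_clusters)) {
    mp <- filter(clusters$metaprofiles, .data$cluster == cl)
    reg <- delineate_arms(mp)
    arms[[as.character(cl)]] <- reg
    if (is.null(reg)) next
    ids <- clusters$assignments$peak_id[clusters$assignments$cluster == cl]
    for (pid in ids) {
      pk <- peaks[peaks$peak_id == pid, ][1, ]
      d <- derive_duplex(pk, reg$prox, reg$dist, reference, model = model,
                         min_stem = min_stem, stem_rule = stem_rule)
      if (!is.null(d)) dup_rows[[length(dup_rows) + 1]] <- d
    }
  }
  duplexes <- bind_rows(dup_rows)
  if (nrow(duplexes) > 0) {
    duplexes <- mutate(duplexes, source = "derived")
  }
  ctrl_meta <- if (any(!is.na(profiles$control_prob))) {
    build_metaprofile(profiles, value = "control_prob")
  } else tibble()
  structure(list(profiles = profiles, clusters = clusters, arms = arms,
                 duplexes = duplexes, control_metaprofile = ctrl_meta,
                 n_skipped = n_skipped),
            class = "stemloop_derivation")
}

# representative transcript per gene for the 3' UTR restriction
utr3_transcripts <- function(reference, representative = NULL) {
  if (!is.null(representative)) {
    return(unique(as_tibble(representative)$transcript_id))
  }
  regs <- tx_regions(reference) %>%
    filter(.data$region_kind == "UTR3") %>%
    mutate(len = .data$end - .data$start) %>%
    inner_join(select(reference, "transcript_id", "gene_id"),
               by = "transcript_id") %>%
    group_by(.data$gene_id) %>%
    arrange(dplyr::desc(.data$len), .data$transcript_id,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  regs$transcript_id
}

#' @export
print.stemloop_derivation <- function(x, ...) {
  cat(sprintf(
    "stem-loop derivation: %d profiles, %d derived duplexes (%d pass)\n",
    length(unique(x$profiles$peak_id)), nrow(x$duplexes),
    if (nrow(x$duplexes)) sum(x$duplexes$passes_filter) else 0L))
  invisible(x)
}

#' @export
tidy.stemloop_derivation <- function(x, ...) x$duplexes

#' @export
glance.stemloop_derivation <- function(x, ...) {
  tibble(n_peaks = length(unique(x$profiles$peak_id)),
         k = if (is.null(x$clusters)) NA_integer_ else x$clusters$k,
         n_derived = nrow(x$duplexes),
         n_passing = if (nrow(x$duplexes)) sum(x$duplexes$passes_filter)
                     else 0L,
         median_loop = if (nrow(x$duplexes))
           stats::median(x$duplexes$loop_length[x$duplexes$passes_filter])
           else NA_real_,
         n_skipped = x$n_skipped)
}
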