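#' Expression-matched gene set for duplex/non-duplex comparisons
#'
#' Computes the 5th percentile (linear interpolation between order
#' statistics, the default quantile definition) of gene copy number among
#' duplex-bearing genes and keeps all genes, of either group, whose copy
#' number exceeds that threshold.
#'
#' @param rates Metabolism tibble with `gene_id` and `copy_number`.
#' @param duplex_genes Character vector of duplex-bearing gene ids.
#' @param probs Percentile used for the threshold (default 0.05).
#' @return Filtered tibble with a `has_duplex` column; the threshold is
#'   attached as the `threshold` attribute.
#' @export
match_expression <- function(rates, duplex_genes, probs = 0.05) {
  rates <- as_tibble(rates)
  with_dup <- rates$gene_id %in% duplex_genes
  if (!any(with_dup)) abort("no duplex-bearing genes in the rate table")
  thr <- unname(quantile(rates$copy_number[with_dup], probs, type = 7,
                         na.rm = TRUE))
  out <- rates %>%
    mutate(has_duplex = with_dup) %>%
    filter(.data$copy_number > thr)
  attr(out, "threshold") <- thr
  out
}

#' Cluster genes by RNA metabolism rates (k-medoids)
#'
#' Rates are log10-transformed, then scaled and centred per rate so
#' synthesis, processing and degradation carry equal weight. Partitioning
#' around medoids (PAM) is run for each candidate k with the average
#' silhouette width reported; the final clustering uses `k` (default 3).
#' Clusters are relabelled A, B, C, ... by decreasing mean degradation rate
#' so the labels are reproducible (A = highest degradation).
#'
#' @param rates Tibble with `gene_id`, `synthesis`, `processing`,
#'   `degradation` (positive rates; non-positive records are dropped with a
#'   message).
#' @param k Number of clusters for the final fit (default 3).
#' @param ks Candidate k values for the silhouette profile (default 2:8).
#' @return Object of class `metabolism_clusters`: `assignments` (gene_id,
#'   cluster), `silhouette` (k, avg_width), `k`, `medoids`, `scaled`
#'   (the transformed matrix). Supports [tidy()] and [glance()].
#' @export
cluster_metabolism <- function(rates, k = 3, ks = 2:8) {
  rates <- as_tibble(rates)
  ok <- rates$synthesis > 0 & rates$processing > 0 & rates$degradation > 0 &
    stats::complete.cases(rates[, c("synthesis", "processing",
                                    "degradation")])
  if (any(!ok)) {
    inform(sprintf("cluster_metabolism: dropped %d records with missing or
non-positive rates", sum(!ok)) )
    rates <- rates[ok, , drop = FALSE]
  }
  if (nrow(rates) < k) abort("fewer records than clusters")
  m <- scale(log10(as.matrix(rates[, c("synthesis", "processing",
                                       "degradation")])))
  rownames(m) <- rates$gene_id
  if (nrow(unique(m)) == 1) {
    warn("degenerate rate table: all records identical; single cluster")
    asg <- tibble(gene_id = rates$gene_id, cluster = "A")
    return(structure(list(assignments = asg,
                          silhouette = tibble(k = integer(),
                                              avg_width = numeric()),
                          k = 1L, medoids = m[1, , drop = FALSE],
                          scaled = m),
                     class = "metabolism_clusters"))
  }
  ks <- unique(pmin(ks, nrow(rates) - 1))
  sil <- bind_rows(lapply(ks, function(kk) {
    fit <- cluster::pam(m, kk, pamonce = 0)
    tibble(k = kk, avg_width = fit$silinfo$avg.width)
  }))
  fit <- cluster::pam(m, k, pamonce = 0)
  # relabel by decreasing mean degradation (A = highest degradation)
  deg <- tapply(rates$degradation, fit$clustering, function(x)
    mean(log10(x)))
  ord <- rank(-deg, ties.method = "first")
  labels <- LETTERS[ord[as.character(fit$clustering)]]
  asg <- tibble(gene_id = rates$gene_id, cluster = labels)
  structure(list(assignments = asg,
                 silhouette = sil, k = as.integer(k),
                 medoids = fit$medoids, scaled = m),
            class = "metabolism_clusters")
}

#' @export
print.metabolism_clusters <- function(x, ...) {
  cat(sprintf("metabolism k-medoid clustering: k = %d, %d genes\n", x$k,
              nrow(x$assignments)))
  print(count(x$assignments, .data$cluster))
  invisible(x)
}

#' @export
tidy.metabolism_clusters <- function(x, ...) x$assignments

#' @export
glance.metabolism_clusters <- function(x, ...) {
  best <- if (nrow(x$silhouette) > 0) {
    x$silhouette$k[which.max(x$silhouette$avg_width)]
  } else NA_integer_
  tibble(k = x$k, n = nrow(x$assignments), best_silhouette_k = best,
         avg_silhouette = if (nrow(x$silhouette) > 0) {
           x$silhouette$avg_width[match(x$k, x$silhouette$k)]
         } else NA_real_)
}

#' Intron-corrected 3' UTR compaction score of a duplex
#'
#' The duplex span (proximal arm start to distal arm end) and the 3' UTR
#' length are each corrected by subtracting the lengths of 3' UTR introns
#' they contain; the compaction score is the corrected span divided by the
#' corrected UTR length (1 = the duplex spans the whole 3' UTR).
#'
#' @param duplexes Duplex tibble (intra-transcript; `prox_tx`, `prox_start`,
#'   `dist_end`, `duplex_id`).
#' @param utr3 Tibble of representative 3' UTRs: `transcript_id`, `start`,
#'   `end` (0-based half-open; when a transcript has several rows the
#'   longest UTR overlapping the duplex is used).
#' @param introns Optional tibble `transcript_id`, `start`, `end` of 3' UTR
#'   introns.
#' @return Tibble: `duplex_id`, `transcript_id`, `span_corrected`,
#'   `utr3_length_corrected`, `compaction`, `thirds_spanned`.
#' @export
compaction_score <- function(duplexes, utr3, introns = NULL) {
  utr3 <- as_tibble(utr3)
  introns <- if (is.null(introns)) {
    tibble(transcript_id = character(), start = integer(), end = integer())
  } else as_tibble(introns)
  rows <- lapply(seq_len(nrow(duplexes)), function(i) {
    d <- duplexes[i, ]
    u <- filter(utr3, .data$transcript_id == d$prox_tx,
                .data$start < d$dist_end, .data$end > d$prox_start)
    if (nrow(u) == 0) {
      abort(sprintf("duplex %s does not overlap a 3' UTR", d$duplex_id))
    }
    u <- u[which.max(u$end - u$start), ]
    span_iv <- c(d$prox_start, d$dist_end)
    ii <- filter(introns, .data$transcript_id == d$prox_tx)
    in_span <- sum(pmax(0L, pmin(ii$end, span_iv[2]) -
                          pmax(ii$start, span_iv[1])))
    in_utr <- sum(pmax(0L, pmin(ii$end, u$end) - pmax(ii$start, u$start)))
    span_c <- (span_iv[2] - span_iv[1]) - in_span
    utr_c <- (u$end - u$start) - in_utr
    if (utr_c <= 0) abort("corrected 3' UTR length is non-positive")
    tibble(duplex_id = d$duplex_id, transcript_id = d$prox_tx,
           span_corrected = as.integer(span_c),
           utr3_length_corrected = as.integer(utr_c),
           compaction = span_c / utr_c,
           thirds_spanned = thirds_spanned(d, u))
  })
  bind_rows(rows)
}

#' Number of 3' UTR thirds spanned by a duplex
#'
#' Splits the 3' UTR into three equal thirds (the remainder goes to the last
#' third) and counts how many distinct thirds the interval from the proximal
#' arm start to the distal arm end intersects.
#'
#' @param duplex One-row duplex tibble (`prox_start`, `dist_end`).
#' @param utr3 One-row tibble (`start`, `end`) of the 3' UTR.
#' @return Integer in 1..3.
#' @export
thirds_spanned <- function(duplex, utr3) {
  len <- utr3$end - utr3$start
  t1 <- utr3$start + len %/% 3
  t2 <- utr3$start + 2 * (len %/% 3)
  bounds_lo <- c(utr3$start, t1, t2)
  bounds_hi <- c(t1, t2, utr3$end)
  s <- max(duplex$prox_start, utr3$start)
  e <- min(duplex$dist_end, utr3$end)
  sum(bounds_lo < e & bounds_hi > s)
}
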