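#' Call hybrid reads from filtered partial alignments
#'
#' Implements the hybrid-solution selection cascade for reads without a
#' linker. Per read: (1) if any single alignment leaves at most
#' `max_unaligned` nucleotides of the read unaligned, the read is deemed a
#' non-hybrid (non-hybrid solutions are prioritised over hybrid solutions);
#' (2) otherwise all alignment pairs, ordered by read position, are
#' cross-joined and filtered: pairs overlapping by more than `max_gap` nt or
#' separated by more than `max_gap` nt in the read are removed, pairs mapping
#' to overlapping regions of the same reference sequence are removed, and
#' solutions whose first arm starts more than `max_start_offset` nt into the
#' read (the crosslink position, taken as the read 5' end) are removed;
#' (3) a read with exactly one surviving solution is called a hybrid, several
#' solutions make it a multimapper (optionally resolved against the pool of
#' unique solutions, see [resolve_multimaps()]), none make it `none`.
#'
#' For intra-transcript solutions the arm with the smaller reference start is
#' labelled proximal (reference orientation); for inter-transcript solutions
#' read order is kept.
#'
#' @param alignments Filtered alignments ([filter_alignments()]).
#' @param reads Tibble with `read_id`, `sequence` (for read lengths).
#' @param max_gap Maximum read-coordinate gap or overlap between arms
#'   (default 4).
#' @param max_unaligned Maximum unaligned read length for the non-hybrid
#'   short-circuit (default 15).
#' @param max_start_offset Maximum read offset of the first arm (default 5).
#' @param resolve Resolve multimapping reads against the unique-solution
#'   pool (default TRUE).
#' @return Tibble with one row per read: `read_id`, `class` (`non_hybrid`,
#'   `unique`, `ambiguous`, `none`) and, for unique calls, the solution
#'   columns `q1_start`, `q1_end`, `q2_start`, `q2_end`, `prox_tx`,
#'   `prox_start`, `prox_end`, `dist_tx`, `dist_start`, `dist_end`,
#'   `total_aligned`, `inter_transcript`. A `class_counts` attribute
#'   tabulates the calls.
#' @export
call_hybrids <- function(alignments, reads, max_gap = 4, max_unaligned = 15,
                         max_start_offset = 5, resolve = TRUE) {
  reads <- as_tibble(reads)
  read_len <- tibble(read_id = reads$read_id,
                     read_length = nchar(reads$sequence))
  aln <- alignments %>%
    inner_join(read_len, by = "read_id") %>%
    group_by(.data$read_id) %>%
    mutate(.aid = row_number()) %>%
    ungroup()

  nonhyb <- aln %>%
    filter(.data$read_length - (.data$q_end - .data$q_start) <=
             max_unaligned) %>%
    distinct(.data$read_id) %>%
    pull(.data$read_id)

  cand <- filter(aln, !.data$read_id %in% nonhyb)
  sols <- hybrid_solutions(cand, max_gap = max_gap,
                           max_start_offset = max_start_offset)

  n_per_read <- count(sols, .data$read_id)
  uniq_ids <- n_per_read$read_id[n_per_read$n == 1]
  multi_ids <- n_per_read$read_id[n_per_read$n > 1]
  unique_sols <- filter(sols, .data$read_id %in% uniq_ids)

  resolved <- NULL
  if (resolve && length(multi_ids) > 0 && nrow(unique_sols) > 0) {
    resolved <- resolve_multimaps(filter(sols, .data$read_id %in% multi_ids),
                                  unique_sols)
    multi_ids <- setdiff(multi_ids, resolved$read_id)
  }

  sol_cols <- c("q1_start", "q1_end", "q2_start", "q2_end", "prox_tx",
                "prox_start", "prox_end", "dist_tx", "dist_start", "dist_end",
                "total_aligned", "inter_transcript")
  chosen <- bind_rows(unique_sols, resolved)
  out <- read_len %>%
    select("read_id") %>%
    mutate(class = dplyr::case_when(
      .data$read_id %in% nonhyb ~ "non_hybrid",
      .data$read_id %in% chosen$read_id ~ "unique",
      .data$read_id %in% multi_ids ~ "ambiguous",
      TRUE ~ "none")) %>%
    left_join(select(chosen, "read_id", dplyr::all_of(sol_cols)),
              by = "read_id")
  attr(out, "class_counts") <- count(out, .data$class)
  out
}

# enumerate candidate two-arm solutions per read and apply the pair filters
hybrid_solutions <- function(aln, max_gap = 4, max_start_offset = 5) {
  if (nrow(aln) == 0) {
    return(tibble(read_id = character(), q1_start = integer(),
                  q1_end = integer(), q2_start = integer(),
                  q2_end = integer(), prox_tx = character(),
                  prox_start = integer(), prox_end = integer(),
                  dist_tx = character(), dist_start = integer(),
                  dist_end = integer(), total_aligned = integer(),
                  inter_transcript = logical()))
  }
  p <- inner_join(aln, aln, by = "read_id", suffix = c("", ".y"),
                  relationship = "many-to-many") %>%
    filter(.data$.aid != .data$.aid.y,
           .data$q_start < .data$q_start.y |
             (.data$q_start == .data$q_start.y & .data$.aid < .data$.aid.y))
  gap <- p$q_start.y - p$q_end
  p <- p[gap >= -max_gap & gap <= max_gap, , drop = FALSE]
  same_tx <- p$transcript_id == p$transcript_id.y
  t_ovl <- same_tx & p$t_start < p$t_end.y & p$t_start.y < p$t_end
  p <- p[!t_ovl, , drop = FALSE]
  p <- p[p$q_start <= max_start_offset, , drop = FALSE]
  if (nrow(p) == 0) {
    return(hybrid_solutions(aln[0, , drop = FALSE]))
  }
  swap <- p$transcript_id == p$transcript_id.y &
    p$t_start.y < p$t_start
  tibble(read_id = p$read_id,
         q1_start = p$q_start, q1_end = p$q_end,
         q2_start = p$q_start.y, q2_end = p$q_end.y,
         prox_tx = if_else(swap, p$transcript_id.y, p$transcript_id),
         prox_start = if_else(swap, p$t_start.y, p$t_start),
         prox_end = if_else(swap, p$t_end.y, p$t_end),
         dist_tx = if_else(swap, p$transcript_id, p$transcript_id.y),
         dist_start = if_else(swap, p$t_start, p$t_start.y),
         dist_end = if_else(swap, p$t_end, p$t_end.y),
         total_aligned = (p$q_end - p$q_start) +
           (p$q_end.y - p$q_start.y),
         inter_transcript = p$transcript_id != p$transcript_id.y) %>%
    distinct(.data$read_id, .data$prox_tx, .data$prox_start, .data$prox_end,
             .data$dist_tx, .data$dist_start, .data$dist_end,
             .keep_all = TRUE)
}

#' Resolve multimapping reads against the unique-solution pool
#'
#' A multimapping read's solutions are kept when both arms overlap (by at
#' least one nucleotide, on matching transcripts) some solution in the pool
#' of unique solutions from the same run. If more than one candidate
#' survives, the one with the greatest total aligned read length wins; ties
#' (or no pool overlap) leave the read ambiguous.
#'
#' @param multi_solutions Candidate solutions of multimapping reads
#'   (shape of [call_hybrids()] solution columns plus `read_id`).
#' @param unique_pool Unique solutions from the same run.
#' @return Tibble of resolved solutions (subset of `multi_solutions`, one row
#'   per resolved read).
#' @export
resolve_multimaps <- function(multi_solutions, unique_pool) {
  if (nrow(multi_solutions) == 0 || nrow(unique_pool) == 0) {
    return(multi_solutions[0, , drop = FALSE])
  }
  pool <- select(unique_pool, "prox_tx", "dist_tx",
                 p_start = "prox_start", p_end = "prox_end",
                 d_start = "dist_start", d_end = "dist_end")
  cand <- multi_solutions %>%
    mutate(.cid = row_number()) %>%
    inner_join(pool, by = c("prox_tx", "dist_tx"),
               relationship = "many-to-many") %>%
    filter(.data$prox_start < .data$p_end, .data$p_start < .data$prox_end,
           .data$dist_start < .data$d_end, .data$d_start < .data$dist_end) %>%
    distinct(.data$.cid, .keep_all = TRUE) %>%
    select(-"p_start", -"p_end", -"d_start", -"d_end", -".cid")
  if (nrow(cand) == 0) return(multi_solutions[0, , drop = FALSE])
  cand %>%
    group_by(.data$read_id) %>%
    filter(.data$total_aligned == max(.data$total_aligned)) %>%
    filter(n() == 1) %>%
    ungroup()
}

#' Place the two arms of linker reads on the reference
#'
#' Each arm of a linker-containing read is aligned independently; a hybrid is
#' reported only when both arms have a unique best placement and, for
#' intra-transcript placements, the two reference intervals do not overlap.
#' The e-value filter of the direct path is not applied here: arms are as
#' short as the minimum flank and their placement is judged by unique best
#' score instead.
#'
#' @param prepared Output of [prepare_reads()] (linker reads with
#'   `arms_ok = TRUE` are used).
#' @param reference Reference tibble.
#' @param tile,step Aligner parameters (see [align_partial()]).
#' @param min_score Minimum matches for an arm segment; capped at the arm
#'   length so minimum-flank arms remain placeable (default 15).
#' @return Tibble of hybrid reads: `read_id`, `umi`, `source`
#'   (`linker_full` / `linker_trunc`), solution columns as in
#'   [call_hybrids()]; attribute `n_unplaced` counts linker reads without a
#'   unique two-arm placement.
#' @export
place_linker_hybrids <- function(prepared, reference, tile = 11, step = 5,
                                 min_score = 15) {
  x <- filter(prepared, .data$arms_ok)
  if (nrow(x) == 0) {
    return(tibble(read_id = character(), umi = character(),
                  source = character()))
  }
  place_arm <- function(seqs) {
    aln <- align_partial(tibble(read_id = x$read_id, sequence = seqs),
                         reference, tile = tile, step = step,
                         min_score = min(min_score, min(nchar(seqs))))
    aln %>%
      group_by(.data$read_id) %>%
      filter(.data$matches == max(.data$matches)) %>%
      filter(n() == 1) %>%
      ungroup()
  }
  a1 <- place_arm(x$arm1)
  a2 <- place_arm(x$arm2)
  placed <- inner_join(a1, a2, by = "read_id", suffix = c("_1", "_2")) %>%
    filter(!(.data$transcript_id_1 == .data$transcript_id_2 &
               .data$t_start_1 < .data$t_end_2 &
               .data$t_start_2 < .data$t_end_1))
  meta <- select(x, "read_id", "umi", "linker_status", "arm1")
  out <- placed %>%
    inner_join(meta, by = "read_id") %>%
    mutate(
      swap = .data$transcript_id_1 == .data$transcript_id_2 &
        .data$t_start_2 < .data$t_start_1,
      source = if_else(.data$linker_status == "full", "linker_full",
                       "linker_trunc"),
      q1_start = .data$q_start_1, q1_end = .data$q_end_1,
      q2_start = nchar(.data$arm1) + .data$q_start_2,
      q2_end = nchar(.data$arm1) + .data$q_end_2,
      prox_tx = if_else(.data$swap, .data$transcript_id_2,
                        .data$transcript_id_1),
      prox_start = if_else(.data$swap, .data$t_start_2, .data$t_start_1),
      prox_end = if_else(.data$swap, .data$t_end_2, .data$t_end_1),
      dist_tx = if_else(.data$swap, .data$transcript_id_1,
                        .data$transcript_id_2),
      dist_start = if_else(.data$swap, .data$t_start_1, .data$t_start_2),
      dist_end = if_else(.data$swap, .data$t_end_1, .data$t_end_2),
      total_aligned = .data$matches_1 + .data$matches_2,
      inter_transcript = .data$transcript_id_1 != .data$transcript_id_2) %>%
    select("read_id", "umi", "source", "q1_start", "q1_end", "q2_start",
           "q2_end", "prox_tx", "prox_start", "prox_end", "dist_tx",
           "dist_start", "dist_end", "total_aligned", "inter_transcript")
  attr(out, "n_unplaced") <- nrow(x) - nrow(out)
  out
}

#' Collapse PCR duplicates with a directional UMI network
#'
#' Hybrids are grouped by the mapping key (proximal transcript and start,
#' distal transcript and start). Within a group, UMIs at Hamming distance 1
#' are connected when the higher count A satisfies
#' \eqn{count(A) \ge 2 \cdot count(B) - 1}; each connected network collapses
#' to its highest-count UMI and one representative read is emitted per
#' network (the directional method, extended to use the transcript and start
#' coordinates of both arms).
#'
#' @param hybrids Tibble with `read_id`, `umi`, `prox_tx`, `prox_start`,
#'   `dist_tx`, `dist_start` (additional columns are carried through from the
#'   representative read).
#' @return Deduplicated tibble with a `dup_count` column (reads collapsed
#'   into each unique molecule).
#' @export
dedup_hybrids <- function(hybrids) {
  if (nrow(hybrids) == 0) return(mutate(hybrids, dup_count = integer(0)))
  if (!"umi" %in% names(hybrids) || anyNA(hybrids$umi)) {
    abort("missing UMI on input hybrids")
  }
  key <- paste(hybrids$prox_tx, hybrids$prox_start, hybrids$dist_tx,
               hybrids$dist_start, sep = "\r")
  parts <- split(seq_len(nrow(hybrids)), key)
  reps <- lapply(parts, function(idx) {
    umis <- hybrids$umi[idx]
    tab <- sort(table(umis), decreasing = TRUE)
    u <- names(tab)
    comp <- umi_components(u, as.integer(tab))
    vapply(split(seq_along(u), comp), function(members) {
      rep_umi <- u[members[which.max(tab[members])]]
      c(idx[match(rep_umi, umis)], sum(tab[members]))
    }, numeric(2))
  })
  take <- unlist(lapply(reps, function(m) m[1, ]))
  cnt <- unlist(lapply(reps, function(m) m[2, ]))
  out <- hybrids[take, , drop = FALSE]
  out$dup_count <- as.integer(cnt)
  out[order(take), , drop = FALSE]
}

# connected components of the directional UMI graph
umi_components <- function(umis, counts) {
  k <- length(umis)
  if (k == 1) return(1L)
  m <- do.call(rbind, strsplit(umis, ""))
  edges <- NULL
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (sum(m[i, ] != m[j, ]) == 1) {
        hi <- max(counts[i], counts[j]); lo <- min(counts[i], counts[j])
        if (hi >= 2 * lo - 1) edges <- rbind(edges, c(i, j))
      }
    }
  }
  if (is.null(edges)) return(seq_len(k))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, k - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(k)]
}
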