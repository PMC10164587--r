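# Independent brute-force oracles used to validate the implementation paths.
# These deliberately re-derive results from first principles (exhaustive
# scans / enumeration) and share no code with the package internals.

# --- exhaustive partial-alignment scan -------------------------------------
# All maximal exact diagonal runs of >= min_len nt between a read and every
# reference sequence, found by scoring every diagonal of the full match
# matrix (no seeding, no indexing).
bf_alignments <- function(read_seq, reference, min_len = 15) {
  r <- utf8ToInt(read_seq)
  L <- length(r)
  out <- list()
  for (t in seq_len(nrow(reference))) {
    s <- utf8ToInt(reference$sequence[t])
    N <- length(s)
    M <- outer(r, s, "==")
    R <- matrix(0L, L, N)
    R[1, ] <- M[1, ] + 0L
    if (L > 1) {
      for (i in 2:L) {
        R[i, 2:N] <- ifelse(M[i, 2:N], R[i - 1, 1:(N - 1)] + 1L, 0L)
        R[i, 1] <- M[i, 1] + 0L
      }
    }
    # run ends: R >= min_len and no continuation down-diagonal
    cont <- matrix(FALSE, L, N)
    if (L > 1) cont[1:(L - 1), 1:(N - 1)] <- M[2:L, 2:N]
    ends <- which(R >= min_len & !cont, arr.ind = TRUE)
    if (nrow(ends) > 0) {
      len <- R[ends]
      out[[length(out) + 1]] <- tibble::tibble(
        q_start = ends[, 1] - len, q_end = ends[, 1],
        transcript_id = reference$transcript_id[t],
        t_start = ends[, 2] - len, t_end = ends[, 2],
        matches = len)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(q_start = integer(), q_end = integer(),
                          transcript_id = character(), t_start = integer(),
                          t_end = integer(), matches = integer()))
  }
  dplyr::bind_rows(out)
}

# --- independent hybrid-call cascade ---------------------------------------
# Straight-line re-implementation of the per-read selection rules with
# explicit loops; returns list(class, solution-or-NULL).
oracle_call <- function(read_seq, aln, n_ref, max_evalue = 0.001,
                        max_hits = 100, max_gap = 4, max_unaligned = 15,
                        max_start_offset = 5) {
  L <- nchar(read_seq)
  ev <- 0.621 * L * n_ref * exp(-1.33 * aln$matches)
  aln <- aln[ev <= max_evalue, , drop = FALSE]
  if (nrow(aln) > max_hits) return(list(class = "dropped", sol = NULL))
  # best per q-span, ties kept
  keep <- rep(FALSE, nrow(aln))
  for (i in seq_len(nrow(aln))) {
    same <- aln$q_start == aln$q_start[i] & aln$q_end == aln$q_end[i]
    keep[i] <- aln$matches[i] == max(aln$matches[same])
  }
  aln <- aln[keep, , drop = FALSE]
  if (nrow(aln) == 0) return(list(class = "none", sol = NULL))
  if (any(L - (aln$q_end - aln$q_start) <= max_unaligned)) {
    return(list(class = "non_hybrid", sol = NULL))
  }
  sols <- list()
  n <- nrow(aln)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (aln$q_start[i] > aln$q_start[j]) next
    if (aln$q_start[i] == aln$q_start[j] && i > j) next
    gap <- aln$q_start[j] - aln$q_end[i]
    if (gap > max_gap || gap < -max_gap) next
    if (aln$transcript_id[i] == aln$transcript_id[j] &&
        aln$t_start[i] < aln$t_end[j] && aln$t_start[j] < aln$t_end[i]) next
    if (aln$q_start[i] > max_start_offset) next
    swap <- aln$transcript_id[i] == aln$transcript_id[j] &&
      aln$t_start[j] < aln$t_start[i]
    a <- if (swap) j else i; b <- if (swap) i else j
    sols[[length(sols) + 1]] <- c(
      aln$transcript_id[a], aln$t_start[a], aln$t_end[a],
      aln$transcript_id[b], aln$t_start[b], aln$t_end[b])
  }
  sols <- unique(sols)
  if (length(sols) == 0) return(list(class = "none", sol = NULL))
  if (length(sols) == 1) return(list(class = "unique", sol = sols[[1]]))
  list(class = "ambiguous", sol = NULL)
}

# --- brute-force intermolecular MFE under the simple model -----------------
# Enumerates every monotone matching between the arms (i ascending in arm1,
# j descending in arm2), rejecting pairings with a helix shorter than 2
# stacked pairs; energy = pair energies + 1 kcal/mol per internal unpaired nt.
brute_mfe_simple <- function(arm1, arm2) {
  a1 <- strsplit(gsub("T", "U", toupper(arm1)), "")[[1]]
  a2 <- strsplit(gsub("T", "U", toupper(arm2)), "")[[1]]
  n <- length(a1); m <- length(a2)
  pe <- function(x, y) {
    p <- paste0(x, y)
    if (p %in% c("GC", "CG")) -3
    else if (p %in% c("AU", "UA")) -2
    else if (p %in% c("GU", "UG")) -1
    else NA_real_
  }
  best <- 0
  evalp <- function(pairs) {
    if (length(pairs) == 0) return(NULL)
    e <- 0; runlen <- 1
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      e <- e + pe(a1[p[1]], a2[p[2]])
      if (k > 1) {
        q <- pairs[[k - 1]]
        g1 <- p[1] - q[1] - 1; g2 <- q[2] - p[2] - 1
        if (g1 == 0 && g2 == 0) runlen <- runlen + 1
        else { if (runlen < 2) return(NULL); e <- e + g1 + g2; runlen <- 1 }
      }
    }
    if (runlen < 2) return(NULL)
    e
  }
  rec <- function(i, jmax, pairs) {
    ev <- evalp(pairs)
    if (!is.null(ev) && ev < best) best <<- ev
    if (i > n || jmax < 1) return()
    rec(i + 1, jmax, pairs)
    for (j in seq_len(jmax)) {
      if (!is.na(pe(a1[i], a2[j]))) rec(i + 1, j - 1, c(pairs, list(c(i, j))))
    }
  }
  rec(1, m, list())
  best
}

# --- exhaustive Boltzmann ensemble for one sequence ------------------------
# Enumerates all non-crossing structures (WC + G:U, hairpin loops >= 3 nt,
# every pair stacked with an inner or outer neighbour) and returns per-base
# paired probabilities at 37 C under the simple pair-energy model plus a
# +4.1 kcal/mol nucleation penalty per maximal helix.
brute_pair_probs <- function(seq) {
  ch <- strsplit(gsub("T", "U", toupper(seq)), "")[[1]]
  n <- length(ch)
  pe <- function(x, y) {
    p <- paste0(x, y)
    if (p %in% c("GC", "CG")) -3
    else if (p %in% c("AU", "UA")) -2
    else if (p %in% c("GU", "UG")) -1 else NA_real_
  }
  enum_sub <- function(avail) {
    if (length(avail) == 0) return(list(list()))
    i <- avail[1]; rest <- avail[-1]
    out <- enum_sub(rest)
    for (j in rest) {
      if (j - i - 1 < 3) next
      if (is.na(pe(ch[i], ch[j]))) next
      inside <- rest[rest > i & rest < j]
      after <- rest[rest > j]
      for (ins in enum_sub(inside)) {
        for (aft in enum_sub(after)) {
          out[[length(out) + 1]] <- c(list(c(i, j)), ins, aft)
        }
      }
    }
    out
  }
  structs <- enum_sub(seq_len(n))
  ok <- vapply(structs, function(prs) {
    if (length(prs) == 0) return(TRUE)
    pset <- vapply(prs, function(p) paste(p[1], p[2]), "")
    all(vapply(prs, function(p) {
      paste(p[1] - 1, p[2] + 1) %in% pset ||
        paste(p[1] + 1, p[2] - 1) %in% pset
    }, TRUE))
  }, TRUE)
  structs <- structs[ok]
  RT <- 0.6163
  w <- vapply(structs, function(prs) {
    if (length(prs) == 0) return(1)
    pset <- vapply(prs, function(p) paste(p[1], p[2]), "")
    n_helix <- sum(vapply(prs, function(p) {
      !(paste(p[1] - 1, p[2] + 1) %in% pset) # pair opens a maximal helix
    }, TRUE))
    e <- sum(vapply(prs, function(p) pe(ch[p[1]], ch[p[2]]), 0)) +
      4.1 * n_helix
    exp(-e / RT)
  }, 0)
  Z <- sum(w)
  prob <- numeric(n)
  for (k in seq_along(structs)) {
    for (p in structs[[k]]) {
      prob[p[1]] <- prob[p[1]] + w[k] / Z
      prob[p[2]] <- prob[p[2]] + w[k] / Z
    }
  }
  prob
}

# dinucleotide count table of a sequence
dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

# build a duplex_structure by hand from arm sequences and a pair list
make_structure <- function(arm1, arm2, pairs, energy = -10) {
  p <- tibble::tibble(i = vapply(pairs, function(x) as.integer(x[1]), 1L),
                      j = vapply(pairs, function(x) as.integer(x[2]), 1L))
  hiclipr:::new_duplex_structure(gsub("T", "U", toupper(arm1)),
                                 gsub("T", "U", toupper(arm2)),
                                 p, energy, "simple")
}

# small helper: random reference tibble
random_reference <- function(n_tx, len, gc = 0.5) {
  make_reference(tibble::tibble(
    transcript_id = sprintf("TX%02d", seq_len(n_tx)),
    sequence = vapply(seq_len(n_tx), function(i) hiclipr:::random_dna(len, gc),
                      "")))
}
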