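#' Minimum-free-energy intermolecular duplex between two arm sequences
#'
#' Dynamic program over antiparallel, non-crossing pairings of the two arms
#' (no intramolecular pairs), allowing Watson-Crick (A:U, G:C) and G:U wobble
#' pairs and disallowing lonely pairs (every helix has at least two stacked
#' pairs). Two energy models are built in:
#' * `"nearest_neighbour"` (default): stacking energies from a documented
#'   Turner-style table, logarithmic bulge/internal-loop penalties with an
#'   asymmetry term, and a duplex initiation penalty of +4.1 kcal/mol.
#' * `"simple"`: additive per-pair energies (G:C -3, A:U -2, G:U -1
#'   kcal/mol) and +1 kcal/mol per unpaired loop nucleotide. Fully
#'   enumerable, used as the reference model for exhaustive oracles.
#'
#' If no pairing achieves negative energy the result is the empty structure
#' with energy 0.
#'
#' @param arm1,arm2 Arm sequences, 5'->3' (RNA or DNA alphabet; N never
#'   pairs).
#' @param model `"nearest_neighbour"` or `"simple"`.
#' @return A `duplex_structure`: list with `arm1`, `arm2` (RNA alphabet),
#'   `pairs` (tibble `i`, `j`; 1-based positions in arm1/arm2, `i`
#'   increasing, `j` decreasing), `n_pairs`, `energy` (kcal/mol),
#'   `dot_bracket` (`"((..((&))..))"` style) and `model`.
#' @export
duplex_mfe <- function(arm1, arm2, model = c("nearest_neighbour", "simple")) {
  model <- match.arg(model)
  a1 <- norm_seq(arm1); a2 <- norm_seq(arm2)
  if (nchar(a1) < 1 || nchar(a2) < 1) abort("empty arm sequence")
  if (nchar(a1) > 2000 || nchar(a2) > 2000) abort("arm longer than 2000 nt")
  res <- cpp_duplex_mfe(a1, a2, if (model == "simple") 0L else 1L)
  pairs <- tibble(i = res$i + 1L, j = res$j + 1L)
  new_duplex_structure(as_rna(a1), as_rna(a2), pairs, res$energy, model)
}

new_duplex_structure <- function(arm1, arm2, pairs, energy, model) {
  db1 <- rep(".", nchar(arm1)); db2 <- rep(".", nchar(arm2))
  db1[pairs$i] <- "("; db2[pairs$j] <- ")"
  structure(list(arm1 = arm1, arm2 = arm2, pairs = pairs,
                 n_pairs = nrow(pairs), energy = energy,
                 dot_bracket = paste0(paste(db1, collapse = ""), "&",
                                      paste(db2, collapse = "")),
                 model = model),
            class = "duplex_structure")
}

#' @export
print.duplex_structure <- function(x, ...) {
  cat(x$arm1, "&", x$arm2, "\n", sep = "")
  cat(x$dot_bracket, sprintf(" (%.2f kcal/mol, %d pairs, %s model)\n",
                             x$energy, x$n_pairs, x$model), sep = "")
  invisible(x)
}

#' Hybridisation energy normalised per paired residue
#'
#' Divides the duplex energy by the total number of paired residues
#' (both arms counted: 2 x number of pairs).
#'
#' @param structure A `duplex_structure`.
#' @return Energy per paired residue (kcal/mol), or NA for an empty pairing.
#' @export
normalised_energy <- function(structure) {
  if (structure$n_pairs == 0) return(NA_real_)
  structure$energy / (2 * structure$n_pairs)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson Euler-path shuffle: the returned sequences have exactly
#' the dinucleotide counts (and hence first and last nucleotide) of the
#' input. The Euler path is drawn uniformly by sampling a random arborescence
#' towards the terminal nucleotide with Wilson's loop-erased random walk and
#' randomising the remaining edge order.
#'
#' @param sequence A single sequence (length >= 2; shorter inputs are
#'   returned unchanged).
#' @param n Number of shuffles to return.
#' @return Character vector of `n` shuffled sequences.
#' @export
dinucleotide_shuffle <- function(sequence, n = 1) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L < 2) return(rep(sequence, n))
  vapply(seq_len(n), function(dummy) euler_shuffle(chars), "")
}

euler_shuffle <- function(chars) {
  L <- length(chars)
  verts <- unique(chars)
  if (length(verts) == 1) return(paste(chars, collapse = ""))
  from <- chars[-L]; to <- chars[-1]
  edges <- split(to, factor(from, levels = verts))
  last <- chars[L]; first <- chars[1]
  # out-degree-weighted random walk graph for Wilson's algorithm
  repeat {
    tree_edge <- wilson_arborescence(verts, edges, last)
    # order out-edges per vertex: random order, designated tree edge last
    ordered <- lapply(verts, function(v) {
      e <- edges[[v]]
      if (length(e) == 0) return(character(0))
      if (v == last || is.na(tree_edge[v])) return(sample2(e))
      k <- match(tree_edge[v], e)
      rest <- e[-k]
      c(sample2(rest), tree_edge[v])
    })
    names(ordered) <- verts
    # Euler walk
    ptr <- setNames(rep(1L, length(verts)), verts)
    out <- character(L); out[1] <- first
    v <- first
    ok <- TRUE
    for (i in 2:L) {
      e <- ordered[[v]]
      if (ptr[v] > length(e)) { ok <- FALSE; break }
      nxt <- e[ptr[v]]
      ptr[v] <- ptr[v] + 1L
      out[i] <- nxt
      v <- nxt
    }
    if (ok) return(paste(out, collapse = ""))
  }
}

sample2 <- function(x) if (length(x) <= 1) x else sample(x)

# random arborescence towards `root` on the dinucleotide multigraph
wilson_arborescence <- function(verts, edges, root) {
  tree <- setNames(rep(NA_character_, length(verts)), verts)
  in_tree <- setNames(verts == root, verts)
  for (v in verts) {
    if (in_tree[v]) next
    # loop-erased random walk from v to the current tree
    path_next <- setNames(rep(NA_character_, length(verts)), verts)
    u <- v
    while (!in_tree[u]) {
      e <- edges[[u]]
      if (length(e) == 0) break # dead end other than root: restart caller
      nxt <- e[sample.int(length(e), 1)]
      path_next[u] <- nxt
      u <- nxt
    }
    u <- v
    while (!is.na(path_next[u]) && !in_tree[u]) {
      tree[u] <- path_next[u]
      in_tree[u] <- TRUE
      u <- path_next[u]
    }
  }
  tree
}

#' Shuffled-control hybridisation energy
#'
#' Mean minimum free energy over `n_iter` iterations of independently
#' shuffling both arm sequences (preserving dinucleotide content).
#'
#' @param arm1,arm2 Arm sequences.
#' @param n_iter Number of shuffle iterations (default 100).
#' @param model Energy model (see [duplex_mfe()]).
#' @return Mean control energy (kcal/mol).
#' @export
control_energy <- function(arm1, arm2,
                           n_iter = 100,
                           model = c("nearest_neighbour", "simple")) {
  model <- match.arg(model)
  s1 <- dinucleotide_shuffle(arm1, n_iter)
  s2 <- dinucleotide_shuffle(arm2, n_iter)
  mean(vapply(seq_len(n_iter), function(i) {
    duplex_mfe(s1[i], s2[i], model = model)$energy
  }, numeric(1)))
}

#' Windowed per-nucleotide base-pairing probability
#'
#' Slides windows of length `window` one nucleotide at a time over the
#' sequence; within each window the equilibrium probability that each base is
#' paired is computed from the McCaskill-style partition function over
#' non-crossing structures (Watson-Crick + G:U pairs, hairpin loops of at
#' least `minloop` nt, no lonely pairs) at 37 degrees C. Boltzmann weights
#' come from the simple per-pair energy model plus a helix nucleation
#' penalty of +4.1 kcal/mol charged once per maximal helix, which keeps
#' spurious short helices in random sequence from saturating the ensemble.
#' Each base's probability is the mean over all windows covering it.
#'
#' @param sequence Input sequence (RNA or DNA alphabet).
#' @param window Window length in nt (default 100).
#' @param minloop Minimum hairpin loop length (default 3).
#' @return Tibble with `pos` (1-based) and `prob` in \[0, 1\].
#' @export
pairing_probabilities <- function(sequence, window = 100, minloop = 3) {
  s <- norm_seq(sequence)
  if (nchar(s) < 1) abort("empty sequence")
  p <- cpp_pairing_probabilities(s, as.integer(window), as.integer(minloop))
  tibble(pos = seq_len(nchar(s)), prob = p)
}

#' Pairing profile with dinucleotide-shuffled control
#'
#' @param sequence Input sequence.
#' @param window Window length (default 100).
#' @param shuffles Number of dinucleotide-preserving shuffles averaged into
#'   the control track (0 disables the control).
#' @return Tibble `pos`, `prob`, `control_prob` (NA when `shuffles = 0`).
#' @export
pairing_profile <- function(sequence, window = 100, shuffles = 0) {
  out <- pairing_probabilities(sequence, window = window)
  if (shuffles > 0) {
    sh <- dinucleotide_shuffle(sequence, shuffles)
    ctrl <- rowMeans(vapply(sh, function(x) {
      pairing_probabilities(x, window = window)$prob
    }, numeric(nrow(out))))
    out$control_prob <- ctrl
  } else {
    out$control_prob <- NA_real_
  }
  out
}
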