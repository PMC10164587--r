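# Karlin-Altschul constants for ungapped +1/-2 nucleotide scoring,
# used to attach e-values to the built-in aligner's segments
KA_LAMBDA <- 1.33
KA_K <- 0.621

#' Partial alignment of reads against a transcriptome
#'
#' Built-in seed-and-extend partial aligner: exact 11-mer seeds looked up in a
#' reference index sampled every 5 positions (tile size 11, step 5), each seed
#' extended to its maximal exact segment. Segments with fewer than `min_score`
#' matching nucleotides are discarded. An e-value is attached to each segment
#' using the Karlin-Altschul formula \eqn{e = K m n e^{-\lambda S}} with the
#' ungapped +1/-2 nucleotide constants (\eqn{\lambda} = 1.33, K = 0.621),
#' where m is the read length, n the total reference length and S the number
#' of matches. Coordinates are 0-based half-open. Mismatch- or gap-tolerant
#' partial alignments can be supplied instead via [read_psl()] or
#' [read_blast8()].
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param reference A reference tibble (see [read_transcriptome()]).
#' @param tile Seed k-mer size (default 11).
#' @param step Reference index sampling step (default 5).
#' @param min_score Minimum matches per segment (default 15).
#' @return Tibble: `read_id`, `q_start`, `q_end`, `transcript_id`, `t_start`,
#'   `t_end`, `matches`, `e_value`.
#' @export
align_partial <- function(reads, reference, tile = 11, step = 5,
                          min_score = 15) {
  if (nrow(reference) == 0) abort("empty reference index")
  hits <- cpp_seed_extend(norm_seq(reads$sequence),
                          reference$sequence, as.integer(tile),
                          as.integer(step), as.integer(min_score))
  n_ref <- sum(nchar(reference$sequence))
  out <- as_tibble(hits) %>%
    mutate(read_id = reads$read_id[.data$read],
           transcript_id = reference$transcript_id[.data$t],
           m = nchar(reads$sequence)[.data$read],
           e_value = KA_K * .data$m * n_ref *
             exp(-KA_LAMBDA * .data$matches)) %>%
    select("read_id", "q_start", "q_end", "transcript_id", "t_start",
           "t_end", "matches", "e_value")
  out
}

#' Import partial alignments from a PSL file
#'
#' Maps a (p)blat PSL file onto the package's partial-alignment records.
#' Multi-block (gapped) and minus-strand rows are dropped with a message,
#' preserving the ungapped plus-strand alignment contract; e-values are
#' computed with the same Karlin-Altschul formula as the built-in aligner
#' since PSL carries none.
#'
#' @param path PSL path (no header; 21 standard columns).
#' @param n_ref Total reference length (for the e-value); default the sum of
#'   target sizes seen in the file.
#' @return Tibble in the same shape as [align_partial()].
#' @export
read_psl <- function(path, n_ref = NULL) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       comment = "psLayout")
  x <- x[!is.na(suppressWarnings(as.integer(x[[1]]))), ]
  keep <- x[[9]] == "+" & as.integer(x[[18]]) == 1L
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("read_psl: dropped %d gapped/minus-strand rows", n_drop))
  }
  x <- x[keep, ]
  if (is.null(n_ref)) n_ref <- sum(as.numeric(unique(x[[15]])))
  tibble(read_id = as.character(x[[10]]),
         q_start = as.integer(x[[12]]), q_end = as.integer(x[[13]]),
         transcript_id = as.character(x[[14]]),
         t_start = as.integer(x[[16]]), t_end = as.integer(x[[17]]),
         matches = as.integer(x[[1]]),
         e_value = KA_K * as.integer(x[[11]]) * n_ref *
           exp(-KA_LAMBDA * as.integer(x[[1]])))
}

#' Import partial alignments from BLAST-8 (tabular) output
#'
#' Reads the 12-column blast tabular format, converting coordinates to
#' 0-based half-open and using the file's own e-values. Gapped and
#' minus-strand rows are dropped with a message.
#'
#' @param path BLAST-8 / outfmt 6 path.
#' @return Tibble in the same shape as [align_partial()].
#' @export
read_blast8 <- function(path) {
  x <- readr::read_tsv(path, col_names = c(
    "read_id", "transcript_id", "pident", "length", "mismatch", "gapopen",
    "q_start1", "q_end1", "t_start1", "t_end1", "e_value", "bitscore"),
    col_types = "ccdiiiiiiidd", comment = "#")
  keep <- x$gapopen == 0 & x$t_start1 <= x$t_end1
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("read_blast8: dropped %d gapped/minus-strand rows",
                   n_drop))
  }
  x <- x[keep, ]
  tibble(read_id = x$read_id,
         q_start = x$q_start1 - 1L, q_end = x$q_end1,
         transcript_id = x$transcript_id,
         t_start = x$t_start1 - 1L, t_end = x$t_end1,
         matches = as.integer(round(x$length * x$pident / 100)),
         e_value = x$e_value)
}

#' Filter partial alignments before hybrid calling
#'
#' Applies the alignment filter cascade: keep alignments with e-value at most
#' `max_evalue`; drop entire reads retaining more than `max_hits` alignments;
#' then keep only the best-scoring alignment for each distinct read
#' (q_start, q_end) span, retaining ties.
#'
#' @param alignments Tibble from [align_partial()] (or the importers).
#' @param max_evalue E-value threshold (default 0.001).
#' @param max_hits Maximum surviving alignments per read (default 100).
#' @return Filtered tibble; attribute `dropped_reads` lists reads removed by
#'   the `max_hits` rule.
#' @export
filter_alignments <- function(alignments, max_evalue = 0.001,
                              max_hits = 100) {
  x <- filter(alignments, .data$e_value <= max_evalue)
  hits <- count(x, .data$read_id)
  drop <- hits$read_id[hits$n > max_hits]
  if (length(drop) > 0) {
    inform(sprintf("filter_alignments: dropped %d reads with > %d alignments",
                   length(drop), max_hits))
    x <- filter(x, !.data$read_id %in% drop)
  }
  if (nrow(x) > 0) {
    x <- x %>%
      group_by(.data$read_id, .data$q_start, .data$q_end) %>%
      filter(.data$matches == max(.data$matches)) %>%
      ungroup()
  }
  attr(x, "dropped_reads") <- drop
  x
}
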