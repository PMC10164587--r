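#' Per-arm overlap fractions between two hybrids
#'
#' Returns NULL unless both arm pairs overlap by at least one nucleotide and
#' the hybrids share the same (ordered) transcript pairing; otherwise the
#' per-arm fraction overlap-length / union-span for the proximal and distal
#' arms.
#'
#' @param h1,h2 One-row tibbles (or lists) with `prox_tx`, `prox_start`,
#'   `prox_end`, `dist_tx`, `dist_start`, `dist_end`.
#' @return `c(f_prox, f_dist)` or NULL.
#' @export
hybrid_overlap_fraction <- function(h1, h2) {
  if (h1$prox_tx != h2$prox_tx || h1$dist_tx != h2$dist_tx) return(NULL)
  ov_p <- interval_overlap(h1$prox_start, h1$prox_end,
                           h2$prox_start, h2$prox_end)
  ov_d <- interval_overlap(h1$dist_start, h1$dist_end,
                           h2$dist_start, h2$dist_end)
  if (ov_p < 1 || ov_d < 1) return(NULL)
  un_p <- max(h1$prox_end, h2$prox_end) - min(h1$prox_start, h2$prox_start)
  un_d <- max(h1$dist_end, h2$dist_end) - min(h1$dist_start, h2$dist_start)
  c(f_prox = ov_p / un_p, f_dist = ov_d / un_d)
}

#' Cluster hybrids into duplexes by graph connected components
#'
#' Builds an undirected graph with hybrids as nodes and edges between hybrids
#' whose two arms both overlap with a fraction of at least `min_fraction`
#' (overlap length over the union span of the two arms). Connected components
#' become duplexes; duplex arm ends are the per-arm medians of the member
#' starts and ends (even counts resolve to the lower middle value, keeping
#' integer coordinates) and the support is the number of member hybrids.
#' Transitive chaining through components is inherent to the method; an
#' optional `max_component_span` guard can split runaway chains.
#'
#' @param hybrids Deduplicated hybrid tibble (columns `prox_tx`,
#'   `prox_start`, `prox_end`, `dist_tx`, `dist_start`, `dist_end`;
#'   optional `source`, `support`).
#' @param min_fraction Minimum per-arm overlap fraction (default 0.5).
#' @param max_component_span Optional cap on a component's arm union span;
#'   NULL (default) disables the guard.
#' @return Duplex tibble: `duplex_id`, arm intervals, `support`, `sources`,
#'   `span` (distal start minus proximal end; NA for inter-transcript) and
#'   `inter_transcript`.
#' @export
cluster_duplexes <- function(hybrids, min_fraction = 0.5,
                             max_component_span = NULL) {
  h <- as_tibble(hybrids)
  if (nrow(h) == 0) {
    return(tibble(duplex_id = character(), prox_tx = character(),
                  prox_start = integer(), prox_end = integer(),
                  dist_tx = character(), dist_start = integer(),
                  dist_end = integer(), support = integer(),
                  sources = character(), span = integer(),
                  inter_transcript = logical()))
  }
  if (!"source" %in% names(h)) h$source <- "direct"
  if (!"support" %in% names(h)) h$support <- 1L
  h <- mutate(h, .hid = row_number(),
              .grp = paste(.data$prox_tx, .data$dist_tx, sep = "\r"))
  edges <- h %>%
    group_by(.data$.grp) %>%
    dplyr::group_map(~ group_edges(.x, min_fraction)) %>%
    bind_rows()
  g <- igraph::make_empty_graph(n = nrow(h), directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
    igraph::E(g)$weight <- pmin(edges$f_prox, edges$f_dist)
  }
  comp <- igraph::components(g)$membership
  h$.comp <- comp
  dup <- h %>%
    group_by(.data$.comp) %>%
    summarise(prox_tx = first(.data$prox_tx),
              prox_start = med_lo(.data$prox_start),
              prox_end = med_lo(.data$prox_end),
              dist_tx = first(.data$dist_tx),
              dist_start = med_lo(.data$dist_start),
              dist_end = med_lo(.data$dist_end),
              support = sum(.data$support),
              sources = paste(sort(unique(unlist(
                strsplit(.data$source, ",")))), collapse = ","),
              .groups = "drop") %>%
    mutate(inter_transcript = .data$prox_tx != .data$dist_tx,
           span = if_else(.data$inter_transcript, NA_integer_,
                          as.integer(.data$dist_start - .data$prox_end))) %>%
    arrange(.data$prox_tx, .data$prox_start, .data$prox_end, .data$dist_tx,
            .data$dist_start, .data$dist_end, .data$support) %>%
    mutate(duplex_id = sprintf("D%05d", row_number())) %>%
    select("duplex_id", "prox_tx", "prox_start", "prox_end", "dist_tx",
           "dist_start", "dist_end", "support", "sources", "span",
           "inter_transcript")
  if (!is.null(max_component_span)) {
    too_wide <- (dup$prox_end - dup$prox_start > max_component_span) |
      (dup$dist_end - dup$dist_start > max_component_span)
    if (any(too_wide)) {
      warn(sprintf("%d duplexes exceed max_component_span", sum(too_wide)))
    }
  }
  dup
}

# candidate edges for one ordered transcript pair, via interval overlap joins
group_edges <- function(h, min_fraction) {
  n <- nrow(h)
  if (n < 2) {
    return(tibble(from = integer(), to = integer(),
                  f_prox = numeric(), f_dist = numeric()))
  }
  pr <- IRanges::IRanges(h$prox_start + 1L, h$prox_end)
  di <- IRanges::IRanges(h$dist_start + 1L, h$dist_end)
  op <- IRanges::findOverlaps(pr, pr, minoverlap = 1L)
  od <- IRanges::findOverlaps(di, di, minoverlap = 1L)
  key_p <- paste(S4Vectors::queryHits(op), S4Vectors::subjectHits(op))
  key_d <- paste(S4Vectors::queryHits(od), S4Vectors::subjectHits(od))
  both <- intersect(key_p, key_d)
  if (length(both) == 0) {
    return(tibble(from = integer(), to = integer(),
                  f_prox = numeric(), f_dist = numeric()))
  }
  ij <- do.call(rbind, strsplit(both, " "))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  keep <- i < j
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0) {
    return(tibble(from = integer(), to = integer(),
                  f_prox = numeric(), f_dist = numeric()))
  }
  ovp <- interval_overlap(h$prox_start[i], h$prox_end[i],
                          h$prox_start[j], h$prox_end[j])
  ovd <- interval_overlap(h$dist_start[i], h$dist_end[i],
                          h$dist_start[j], h$dist_end[j])
  unp <- pmax(h$prox_end[i], h$prox_end[j]) -
    pmin(h$prox_start[i], h$prox_start[j])
  und <- pmax(h$dist_end[i], h$dist_end[j]) -
    pmin(h$dist_start[i], h$dist_start[j])
  fp <- ovp / unp; fd <- ovd / und
  keep <- fp >= min_fraction & fd >= min_fraction
  tibble(from = h$.hid[i[keep]], to = h$.hid[j[keep]],
         f_prox = fp[keep], f_dist = fd[keep])
}

#' Merge duplex atlases from several sources
#'
#' Pools experimentally detected hybrids/duplexes (linker and direct) and
#' derived stem-loop duplexes, re-applies the same graph-based clustering and
#' reports per-source support. Inputs keep their `source` tags; merged
#' duplexes carry the union of member sources.
#'
#' @param ... Duplex or hybrid tibbles (each with arm interval columns and a
#'   `source` column; `support` defaults to 1 per row).
#' @param min_fraction Minimum per-arm overlap fraction (default 0.5).
#' @return Duplex tibble as from [cluster_duplexes()], plus `n_sources`.
#' @export
merge_atlases <- function(..., min_fraction = 0.5) {
  inputs <- list(...)
  inputs <- inputs[vapply(inputs, function(x) !is.null(x) && nrow(x) > 0,
                          TRUE)]
  if (length(inputs) == 0) {
    out <- cluster_duplexes(tibble(prox_tx = character(),
                                   prox_start = integer(),
                                   prox_end = integer(),
                                   dist_tx = character(),
                                   dist_start = integer(),
                                   dist_end = integer()))
    return(mutate(out, n_sources = integer(0)))
  }
  cols <- c("prox_tx", "prox_start", "prox_end", "dist_tx", "dist_start",
            "dist_end", "source", "support")
  pooled <- bind_rows(lapply(inputs, function(x) {
    x <- as_tibble(x)
    if (!"source" %in% names(x)) {
      x$source <- if ("sources" %in% names(x)) x$sources else "direct"
    }
    if (!"support" %in% names(x)) x$support <- 1L
    select(x, dplyr::all_of(cols))
  }))
  out <- cluster_duplexes(pooled, min_fraction = min_fraction)
  mutate(out, n_sources = lengths(strsplit(.data$sources, ",")))
}

#' Write a duplex atlas as a BEDPE-like TSV
#' @param duplexes Duplex tibble.
#' @param path Output path.
#' @export
write_duplex_table <- function(duplexes, path) {
  readr::write_tsv(select(duplexes, "prox_tx", "prox_start", "prox_end",
                          "dist_tx", "dist_start", "dist_end", "duplex_id",
                          "support", "sources", "span"), path)
  invisible(path)
}

#' Write duplex arms as a 12-column BED with two blocks per intra-transcript
#' duplex (inter-transcript duplexes are written as two 6-column rows).
#' @param duplexes Duplex tibble.
#' @param path Output path.
#' @export
write_duplex_bed <- function(duplexes, path) {
  intra <- filter(duplexes, !.data$inter_transcript)
  lines <- character(0)
  if (nrow(intra) > 0) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t+\t%d\t%d\t0,0,0\t2\t%d,%d\t%d,%d",
                     intra$prox_tx, intra$prox_start, intra$dist_end,
                     intra$duplex_id, pmin(1000L, intra$support * 100L),
                     intra$prox_start, intra$dist_end,
                     intra$prox_end - intra$prox_start,
                     intra$dist_end - intra$dist_start,
                     0L, intra$dist_start - intra$prox_start)
  }
  inter <- filter(duplexes, .data$inter_transcript)
  if (nrow(inter) > 0) {
    lines <- c(lines,
               sprintf("%s\t%d\t%d\t%s_prox\t%d\t+", inter$prox_tx,
                       inter$prox_start, inter$prox_end, inter$duplex_id,
                       pmin(1000L, inter$support * 100L)),
               sprintf("%s\t%d\t%d\t%s_dist\t%d\t+", inter$dist_tx,
                       inter$dist_start, inter$dist_end, inter$duplex_id,
                       pmin(1000L, inter$support * 100L)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Contact matrix of hybrid/duplex arm positions on one transcript
#'
#' @param hybrids Hybrid or duplex tibble.
#' @param transcript Transcript id.
#' @param bin Bin width in nt (default 10).
#' @return Tibble `bin_prox`, `bin_dist` (bin start coordinates), `n`.
#' @export
contact_matrix <- function(hybrids, transcript, bin = 10) {
  x <- filter(hybrids, .data$prox_tx == transcript,
              .data$dist_tx == transcript)
  w <- if ("support" %in% names(x)) x$support else rep(1L, nrow(x))
  tibble(bin_prox = (x$prox_start %/% bin) * bin,
         bin_dist = (x$dist_start %/% bin) * bin, w = w) %>%
    group_by(.data$bin_prox, .data$bin_dist) %>%
    summarise(n = sum(.data$w), .groups = "drop")
}

#' Arc-plot table for duplexes on one transcript
#' @param duplexes Duplex tibble.
#' @param transcript Transcript id.
#' @return Tibble `start` (proximal arm midpoint), `end` (distal arm
#'   midpoint), `count` (support).
#' @export
arc_table <- function(duplexes, transcript) {
  x <- filter(duplexes, .data$prox_tx == transcript,
              .data$dist_tx == transcript)
  tibble(start = (x$prox_start + x$prox_end) %/% 2,
         end = (x$dist_start + x$dist_end) %/% 2,
         count = if ("support" %in% names(x)) x$support else rep(1L, nrow(x)))
}
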