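#' Load a transcriptome reference with region annotation
#'
#' Reads transcript sequences from a FASTA file together with an optional
#' region annotation, and returns a tibble of transcript records used
#' throughout the package. Sequences are stored uppercase with U normalised to
#' T; coordinates are 0-based half-open everywhere. Transcripts without any
#' annotation receive a single full-length `noncoding` region.
#'
#' The annotation can be
#' * a GTF/GFF file with `exon`, `CDS`, `five_prime_utr`/`three_prime_utr`
#'   (or `UTR5`/`UTR3`) features, which is lifted from genomic to transcript
#'   coordinates via the exon chain (GTF is 1-based inclusive and converted on
#'   read), or
#' * a tab-separated table (or data frame) with columns
#'   `transcript_id`, `region_kind`, `start`, `end` already in 0-based
#'   half-open transcript coordinates.
#'
#' @param fasta Path to a FASTA file. Headers are split on whitespace; the
#'   first token is the transcript id and the second, when present, the gene
#'   id (else gene id = transcript id).
#' @param annotation Optional path to a GTF/GFF or region TSV, or a data frame
#'   of regions.
#' @return A tibble with columns `transcript_id`, `gene_id`, `biotype`,
#'   `sequence`, `length` and a `regions` list-column of per-transcript region
#'   tibbles (`region_kind`, `start`, `end`).
#' @export
read_transcriptome <- function(fasta, annotation = NULL) {
  seqs <- Biostrings::readBStringSet(fasta)
  headers <- strsplit(names(seqs), "\\s+")
  tx_id <- vapply(headers, `[`, "", 1)
  gene_id <- vapply(headers, function(h) if (length(h) >= 2) h[2] else h[1], "")
  if (anyDuplicated(tx_id)) {
    abort(sprintf("duplicate transcript_id in FASTA: %s",
                  tx_id[duplicated(tx_id)][1]))
  }
  regions <- if (is.null(annotation)) NULL else read_regions(annotation)
  make_reference(tibble(
    transcript_id = tx_id, gene_id = gene_id, biotype = "mRNA",
    sequence = unname(as.character(seqs))
  ), regions = regions)
}

read_regions <- function(annotation) {
  if (is.data.frame(annotation)) return(as_tibble(annotation))
  if (grepl("\\.(gtf|gff3?)(\\.gz)?$", annotation, ignore.case = TRUE)) {
    return(gtf_to_tx_regions(annotation))
  }
  readr::read_tsv(annotation,
                  col_names = c("transcript_id", "region_kind", "start", "end"),
                  col_types = "ccii", comment = "#")
}

# lift genomic GTF features onto transcript coordinates using the exon chain
gtf_to_tx_regions <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as_tibble(as.data.frame(gr))
  if (!"transcript_id" %in% names(df)) {
    abort("GTF annotation lacks a transcript_id attribute")
  }
  kind_map <- c(five_prime_utr = "UTR5", UTR5 = "UTR5", CDS = "CDS",
                three_prime_utr = "UTR3", UTR3 = "UTR3")
  out <- lapply(split(df, df$transcript_id), function(d) {
    ex <- d[d$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0) return(NULL)
    minus <- ex$strand[1] == "-"
    ex <- ex[order(ex$start, decreasing = minus), , drop = FALSE]
    offs <- cumsum(c(0, head(ex$end - ex$start + 1, -1)))
    feats <- d[as.character(d$type) %in% names(kind_map), , drop = FALSE]
    if (nrow(feats) == 0) return(NULL)
    pieces <- lapply(seq_len(nrow(feats)), function(i) {
      fs <- feats$start[i]; fe <- feats$end[i]
      hit <- which(ex$start <= fe & ex$end >= fs)
      do.call(rbind, lapply(hit, function(k) {
        s <- max(fs, ex$start[k]); e <- min(fe, ex$end[k])
        if (minus) {
          ts <- offs[k] + (ex$end[k] - e)
        } else {
          ts <- offs[k] + (s - ex$start[k])
        }
        data.frame(transcript_id = d$transcript_id[1],
                   region_kind = unname(kind_map[as.character(feats$type[i])]),
                   start = ts, end = ts + (e - s + 1))
      }))
    })
    do.call(rbind, pieces)
  })
  # merge touching pieces of the same kind (features split across exons)
  merge_adjacent_regions(bind_rows(out))
}

merge_adjacent_regions <- function(regions) {
  regions <- regions %>% arrange(.data$transcript_id, .data$start)
  res <- regions %>%
    group_by(.data$transcript_id) %>%
    mutate(new_block = cumsum(c(TRUE, !(.data$region_kind[-1] ==
                                          head(.data$region_kind, -1) &
                                          .data$start[-1] ==
                                          head(.data$end, -1))))) %>%
    group_by(.data$transcript_id, .data$new_block) %>%
    summarise(region_kind = first(.data$region_kind),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    select("transcript_id", "region_kind", "start", "end")
  res
}

#' Build a validated transcriptome reference from tibbles
#'
#' @param transcripts Tibble with `transcript_id`, `sequence` and optionally
#'   `gene_id`, `biotype`.
#' @param regions Optional region tibble (`transcript_id`, `region_kind`,
#'   `start`, `end`), 0-based half-open.
#' @return A reference tibble (see [read_transcriptome()]).
#' @export
make_reference <- function(transcripts, regions = NULL) {
  tx <- as_tibble(transcripts)
  if (anyDuplicated(tx$transcript_id)) {
    abort(sprintf("duplicate transcript_id: %s",
                  tx$transcript_id[duplicated(tx$transcript_id)][1]))
  }
  if (!"gene_id" %in% names(tx)) tx$gene_id <- tx$transcript_id
  if (!"biotype" %in% names(tx)) tx$biotype <- "mRNA"
  tx$sequence <- norm_seq(tx$sequence)
  tx$length <- nchar(tx$sequence)
  if (any(tx$length < 1)) abort("empty sequence in reference")
  reg_list <- vector("list", nrow(tx))
  names(reg_list) <- tx$transcript_id
  if (!is.null(regions)) {
    regions <- as_tibble(regions)
    regions$start <- as.integer(regions$start)
    regions$end <- as.integer(regions$end)
    unknown <- setdiff(unique(regions$transcript_id), tx$transcript_id)
    if (length(unknown) > 0) {
      abort(sprintf("regions reference unknown transcript: %s", unknown[1]))
    }
    by_tx <- split(regions, regions$transcript_id)
    for (id in names(by_tx)) {
      r <- by_tx[[id]] %>% arrange(.data$start)
      len <- tx$length[match(id, tx$transcript_id)]
      if (any(r$start < 0) || any(r$end > len) || any(r$start >= r$end)) {
        abort(sprintf("region outside sequence bounds for transcript %s", id))
      }
      if (nrow(r) > 1 && any(r$start[-1] < head(r$end, -1))) {
        abort(sprintf("overlapping regions for transcript %s", id))
      }
      reg_list[[id]] <- tibble(region_kind = r$region_kind,
                               start = r$start, end = r$end)
    }
  }
  for (i in seq_along(reg_list)) {
    if (is.null(reg_list[[i]])) {
      reg_list[[i]] <- tibble(region_kind = "noncoding", start = 0L,
                              end = tx$length[i])
    }
  }
  tx$regions <- unname(reg_list)
  tx %>% select("transcript_id", "gene_id", "biotype", "sequence", "length",
                "regions")
}

#' Flatten the per-transcript regions of a reference into one tibble
#' @param reference A reference tibble.
#' @return Tibble with `transcript_id`, `region_kind`, `start`, `end`.
#' @export
tx_regions <- function(reference) {
  tidyr::unnest(select(reference, "transcript_id", "regions"),
                "regions")
}

# region ranking used to break overlap ties (3' UTR outranks CDS)
REGION_RANK <- c(UTR3 = 3, CDS = 2, UTR5 = 1, noncoding = 0)

#' Annotate transcript intervals with their region kind
#'
#' Assigns each interval the region kind with the largest overlap; ties are
#' broken by the ranking UTR3 > CDS > UTR5 > noncoding, reflecting the 3' UTR
#' priority used when annotating crosslink and duplex intervals.
#'
#' @param intervals Tibble with `transcript_id`, `start`, `end`
#'   (0-based half-open).
#' @param reference A reference tibble.
#' @return `intervals` with a `region` column appended.
#' @export
annotate_intervals <- function(intervals, reference) {
  intervals <- as_tibble(intervals)
  unknown <- setdiff(unique(intervals$transcript_id), reference$transcript_id)
  if (length(unknown) > 0) {
    abort(sprintf("unknown transcript: %s", unknown[1]))
  }
  regs <- tx_regions(reference)
  joined <- intervals %>%
    mutate(.row = row_number()) %>%
    inner_join(regs, by = "transcript_id", suffix = c("", ".r"),
               relationship = "many-to-many") %>%
    mutate(ov = interval_overlap(.data$start, .data$end,
                                 .data$start.r, .data$end.r)) %>%
    filter(.data$ov > 0) %>%
    group_by(.data$.row) %>%
    arrange(dplyr::desc(.data$ov),
            dplyr::desc(REGION_RANK[.data$region_kind]), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select(".row", region = "region_kind")
  out <- intervals %>%
    mutate(.row = row_number()) %>%
    left_join(joined, by = ".row") %>%
    select(-".row")
  out$region[is.na(out$region)] <- "noncoding"
  out
}

#' Write a reference back to FASTA plus a region TSV
#' @param reference A reference tibble.
#' @param fasta,regions_tsv Output paths (either may be NULL to skip).
#' @export
write_transcriptome <- function(reference, fasta = NULL, regions_tsv = NULL) {
  if (!is.null(fasta)) {
    x <- Biostrings::DNAStringSet(reference$sequence)
    names(x) <- paste(reference$transcript_id, reference$gene_id)
    Biostrings::writeXStringSet(x, fasta, width = 80L)
  }
  if (!is.null(regions_tsv)) {
    readr::write_tsv(tx_regions(reference), regions_tsv, col_names = FALSE)
  }
  invisible(reference)
}
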