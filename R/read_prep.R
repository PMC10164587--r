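#' Locate the linker adapter (full-length or 3'-truncated) in read sequences
#'
#' Searches each sequence for an exact occurrence of the linker, then of the
#' linker missing its last nucleotide, then missing its last two (up to
#' `max_trunc`). The longest matching variant wins and its first (leftmost)
#' occurrence is reported, so a truncated status is never reported when the
#' full linker is present.
#'
#' @param sequences Character vector of read sequences.
#' @param linker Linker adapter sequence (no default: the linker is
#'   library-specific and must be supplied).
#' @param max_trunc Maximum number of trailing linker nucleotides that may be
#'   missing (default 2).
#' @return Tibble with `linker_status` (`none`, `full`, `trunc1`, `trunc2`),
#'   `position` (0-based start of the match, -1 if none) and `linker_length`
#'   (length of the matched variant, 0 if none).
#' @export
find_linker <- function(sequences, linker, max_trunc = 2) {
  linker <- norm_seq(linker)
  if (nchar(linker) <= max_trunc) abort("linker shorter than max_trunc")
  sequences <- norm_seq(sequences)
  status <- rep("none", length(sequences))
  pos <- rep(-1L, length(sequences))
  len <- rep(0L, length(sequences))
  for (k in 0:max_trunc) {
    variant <- substr(linker, 1, nchar(linker) - k)
    todo <- status == "none" & nchar(sequences) > 0
    if (!any(todo)) break
    hit <- regexpr(variant, sequences[todo], fixed = TRUE)
    found <- hit != -1
    idx <- which(todo)[found]
    status[idx] <- c("full", "trunc1", "trunc2")[k + 1]
    pos[idx] <- as.integer(hit[found]) - 1L
    len[idx] <- nchar(variant)
  }
  tibble(linker_status = status, position = pos, linker_length = len)
}

#' Extract unique molecular identifiers from reads
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param scheme `"5prime"` (UMI is the first `umi_length` nt of the read) or
#'   `"header"` (UMI encoded in the read id as `..._rbc:UMI`).
#' @param umi_length UMI length for the `5prime` scheme.
#' @return `reads` with `umi` added and (for `5prime`) the UMI removed from
#'   `sequence`; reads shorter than the UMI are dropped and the count is
#'   reported via the `n_dropped` attribute and a message.
#' @export
extract_umi <- function(reads, scheme = c("5prime", "header"),
                        umi_length = 6) {
  scheme <- match.arg(scheme)
  reads <- as_tibble(reads)
  if (scheme == "header") {
    m <- regmatches(reads$read_id,
                    regexpr("rbc:[ACGTUN]+", reads$read_id))
    umi <- rep(NA_character_, nrow(reads))
    has <- grepl("rbc:[ACGTUN]+", reads$read_id)
    umi[has] <- sub("^rbc:", "", m)
    out <- mutate(reads, umi = umi)
    n_drop <- sum(!has)
    out <- filter(out, !is.na(.data$umi))
  } else {
    keep <- nchar(reads$sequence) > umi_length
    n_drop <- sum(!keep)
    out <- reads[keep, , drop = FALSE]
    out <- mutate(out,
                  umi = substr(.data$sequence, 1, umi_length),
                  sequence = substr(.data$sequence, umi_length + 1,
                                    nchar(.data$sequence)))
  }
  if (n_drop > 0) inform(sprintf("extract_umi: dropped %d reads", n_drop))
  attr(out, "n_dropped") <- n_drop
  out
}

#' Prepare reads: UMI extraction, linker detection and arm splitting
#'
#' Runs the linker-path read preparation: extracts UMIs, locates full or
#' truncated linker adapters, and splits linker-containing reads into the two
#' hybrid arms. Reads whose linker is flanked by fewer than `min_flank`
#' nucleotides on either side are flagged (`arms_ok = FALSE`) and excluded
#' from the linker alignment path, mirroring the requirement of at least 12 nt
#' flanking the linker.
#'
#' @param reads Tibble with `read_id`, `sequence`, or a FASTQ path.
#' @param linker Linker sequence, or NULL to skip linker detection (all reads
#'   are then `linker_status = "none"`).
#' @param umi_scheme,umi_length See [extract_umi()].
#' @param min_flank Minimum arm length flanking the linker (default 12 nt).
#' @param max_trunc Maximum linker 3' truncation searched (default 2 nt).
#' @return Tibble with `read_id`, `umi`, `sequence` (UMI removed),
#'   `linker_status`, `linker_pos`, `arm1`, `arm2`, `arms_ok`. A
#'   `linker_counts` attribute tabulates reads per linker status.
#' @export
prepare_reads <- function(reads, linker = NULL,
                          umi_scheme = "5prime", umi_length = 6,
                          min_flank = 12, max_trunc = 2) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  reads <- extract_umi(reads, scheme = umi_scheme, umi_length = umi_length)
  reads$sequence <- norm_seq(reads$sequence)
  if (is.null(linker)) {
    out <- mutate(reads, linker_status = "none", linker_pos = -1L,
                  arm1 = NA_character_, arm2 = NA_character_,
                  arms_ok = FALSE)
  } else {
    lk <- find_linker(reads$sequence, linker, max_trunc = max_trunc)
    out <- reads %>%
      mutate(linker_status = lk$linker_status, linker_pos = lk$position,
             arm1 = if_else(lk$linker_status == "none", NA_character_,
                            substr(.data$sequence, 1, lk$position)),
             arm2 = if_else(lk$linker_status == "none", NA_character_,
                            substr(.data$sequence,
                                   lk$position + lk$linker_length + 1,
                                   nchar(.data$sequence))),
             arms_ok = .data$linker_status != "none" &
               nchar(.data$arm1) >= min_flank &
               nchar(.data$arm2) >= min_flank)
    out$arms_ok[is.na(out$arms_ok)] <- FALSE
  }
  attr(out, "linker_counts") <- count(out, .data$linker_status)
  out
}

#' Stitch the two arms of linker reads back together
#'
#' Concatenates the proximal and distal arm after removal of the intervening
#' linker, recording the junction so the arms can be recovered.
#'
#' @param prepared Output of [prepare_reads()].
#' @return Tibble with `read_id`, `umi`, `stitched`, `junction` (length of
#'   arm1; the stitched read re-splits into the arms at this offset).
#' @export
stitch_arms <- function(prepared) {
  x <- filter(prepared, .data$arms_ok)
  if (any(is.na(x$arm1) | is.na(x$arm2))) abort("arms absent")
  tibble(read_id = x$read_id, umi = x$umi,
         stitched = paste0(x$arm1, x$arm2),
         junction = nchar(x$arm1))
}
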