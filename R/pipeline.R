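#' Detect hybrid reads end to end (linker and direct paths)
#'
#' Convenience wrapper chaining read preparation, linker-arm placement,
#' direct-path partial alignment with the filter cascade, and directional
#' UMI deduplication into one deduplicated hybrid table.
#'
#' @param reads Read tibble (`read_id`, `sequence`) or FASTQ path.
#' @param reference Reference tibble.
#' @param linker Linker sequence, or NULL when the library has none.
#' @param umi_scheme,umi_length See [extract_umi()].
#' @param max_evalue,max_hits See [filter_alignments()].
#' @param max_gap,max_unaligned,max_start_offset See [call_hybrids()].
#' @param min_flank Minimum linker flank (default 12).
#' @return Deduplicated hybrid tibble with `source` tags; attributes
#'   `class_counts` (direct-path call classes) and `linker_counts`.
#' @export
detect_hybrids <- function(reads, reference, linker = NULL,
                           umi_scheme = "5prime", umi_length = 6,
                           max_evalue = 0.001, max_hits = 100, max_gap = 4,
                           max_unaligned = 15, max_start_offset = 5,
                           min_flank = 12) {
  prepared <- prepare_reads(reads, linker = linker, umi_scheme = umi_scheme,
                            umi_length = umi_length, min_flank = min_flank)
  linker_hybrids <- place_linker_hybrids(prepared, reference)
  direct_reads <- filter(prepared, .data$linker_status == "none")
  aln <- align_partial(direct_reads, reference)
  aln <- filter_alignments(aln, max_evalue = max_evalue,
                           max_hits = max_hits)
  calls <- call_hybrids(aln, direct_reads, max_gap = max_gap,
                        max_unaligned = max_unaligned,
                        max_start_offset = max_start_offset)
  direct_hybrids <- calls %>%
    filter(.data$class == "unique") %>%
    inner_join(select(direct_reads, "read_id", "umi"), by = "read_id") %>%
    mutate(source = "direct")
  hybrids <- bind_rows(
    select(linker_hybrids, dplyr::any_of(c(
      "read_id", "umi", "source", "prox_tx", "prox_start", "prox_end",
      "dist_tx", "dist_start", "dist_end", "total_aligned",
      "inter_transcript"))),
    select(direct_hybrids, dplyr::any_of(c(
      "read_id", "umi", "source", "prox_tx", "prox_start", "prox_end",
      "dist_tx", "dist_start", "dist_end", "total_aligned",
      "inter_transcript"))))
  out <- dedup_hybrids(hybrids)
  attr(out, "class_counts") <- attr(calls, "class_counts")
  attr(out, "linker_counts") <- attr(prepared, "linker_counts")
  out
}

#' Run the full synthetic-to-atlas pipeline, writing artefacts to disk
#'
#' Chains simulation, hybrid detection, duplex clustering and structure
#' characterisation, writing each stage as a TSV/FASTA/FASTQ artefact plus a
#' JSON manifest with row counts. Stages operate on the on-disk artefacts of
#' the previous stage, so each is independently re-runnable.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [sim_config()].
#' @param seed Random seed for the simulation.
#' @param model Energy model for duplex structures.
#' @return The manifest as a named list (invisibly written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(out_dir, config = sim_config(), seed = 1,
                         model = "nearest_neighbour") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  set.seed(seed)
  sim <- sim_transcriptome(config)
  write_transcriptome(sim$reference, pth("reference.fa"),
                      pth("regions.tsv"))
  readr::write_tsv(sim$truth, pth("truth_duplexes.tsv"))
  reads <- sim_reads(sim$reference, sim$truth, config)
  write_fastq(reads, pth("reads.fastq"))
  readr::write_tsv(select(reads, -"sequence"), pth("truth_reads.tsv"))

  reference <- read_transcriptome(pth("reference.fa"), pth("regions.tsv"))
  hybrids <- detect_hybrids(read_fastq(pth("reads.fastq")), reference,
                            linker = config$linker,
                            umi_scheme = "header",
                            umi_length = config$umi_length)
  readr::write_tsv(hybrids, pth("hybrids.tsv"))

  duplexes <- cluster_duplexes(readr::read_tsv(pth("hybrids.tsv"),
                                               show_col_types = FALSE))
  write_duplex_table(duplexes, pth("duplexes.tsv"))
  write_duplex_bed(duplexes, pth("duplexes.bed"))

  atlas <- readr::read_tsv(pth("duplexes.tsv"), show_col_types = FALSE)
  atlas$inter_transcript <- atlas$prox_tx != atlas$dist_tx
  feats <- duplex_features(atlas, reference, model = model)
  readr::write_tsv(feats, pth("duplex_features.tsv"))

  manifest <- list(
    seed = seed,
    files = lapply(list(
      reference = "reference.fa", regions = "regions.tsv",
      reads = "reads.fastq", hybrids = "hybrids.tsv",
      duplexes = "duplexes.tsv", duplex_bed = "duplexes.bed",
      features = "duplex_features.tsv"), function(f) {
        list(path = f, rows = artefact_rows(pth(f)))
      }))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

artefact_rows <- function(path) {
  n <- length(readLines(path, warn = FALSE))
  if (grepl("\\.fastq$", path)) return(n %/% 4L)
  if (grepl("\\.tsv$", path)) return(max(0L, n - 1L))
  n
}
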