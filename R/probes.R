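#' Read probe alignments from a BED6 file
#'
#' One record per probe: the single best genomic alignment of the probe
#' sequence. The BED name field is the probe id.
#'
#' @param path BED6 file.
#' @param platform platform label stored in the `platform` column.
#' @return tibble with columns `probe_id`, `platform`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open).
#' @export
read_probes <- function(path, platform) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    probe_id = gr$name %||% sprintf("probe%06d", seq_along(gr)),
    platform = platform,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Assign microarray probes to lncRNA candidates and coding genes
#'
#' Each probe interval is intersected with the \emph{exons} of lncRNA
#' candidates and of coding transcripts. A probe that hits exons of exactly
#' one lncRNA gene yields a lncRNA assignment; exactly one coding gene, a
#' coding assignment. Probes hitting two or more distinct genes of the same
#' kind are dropped entirely for that kind, because their hybridization
#' signal cannot be attributed to a single gene. Ambiguity is judged at the
#' gene level (`gene_symbol`), so a probe covering two isoforms of one gene
#' is kept; among a gene's isoforms the reported `target_id` is the
#' transcript with the largest probe overlap (ties to the lexicographically
#' first id).
#'
#' A probe on a chromosome absent from the annotation is simply unassigned.
#'
#' @param probes probe tibble from [read_probes()].
#' @param annots annotation tibble; split internally with
#'   [lncrna_candidates()] and [coding_transcripts()].
#' @param require_same_strand require probe and transcript on the same
#'   strand (default `TRUE`: expression microarray probes are strand
#'   specific).
#' @param min_overlap_bp minimum probe/exon overlap in bp (default 1: any
#'   overlap).
#' @param min_lnc_length passed to [lncrna_candidates()].
#' @return tibble with columns `probe_id`, `platform`, `target_id`,
#'   `target_kind` (`"lncRNA"` or `"coding"`), `gene_symbol`.
#' @export
assign_probes <- function(probes, annots, require_same_strand = TRUE,
                          min_overlap_bp = 1L, min_lnc_length = 200L) {
  check_cols(probes, c("probe_id", "platform", "chrom", "start", "end", "strand"))
  lnc <- lncrna_candidates(annots, min_length = min_lnc_length)
  cod <- coding_transcripts(annots)
  dplyr::bind_rows(
    assign_probes_one_kind(probes, lnc, "lncRNA", require_same_strand, min_overlap_bp),
    assign_probes_one_kind(probes, cod, "coding", require_same_strand, min_overlap_bp)
  )
}

# exon-level intersection against one kind of target
assign_probes_one_kind <- function(probes, targets, kind,
                                   require_same_strand, min_overlap_bp) {
  empty <- tibble::tibble(
    probe_id = character(), platform = character(),
    target_id = character(), target_kind = character(),
    gene_symbol = character()
  )
  if (nrow(targets) == 0L || nrow(probes) == 0L) return(empty)
  exons <- targets |>
    dplyr::select("transcript_id", "gene_symbol", "chrom", "strand",
                  "exon_starts", "exon_ends") |>
    tidyr::unnest(c("exon_starts", "exon_ends")) |>
    dplyr::rename(start = "exon_starts", end = "exon_ends")
  hits <- overlap_pairs(probes, exons, min_overlap = min_overlap_bp,
                        ignore_strand = !require_same_strand)
  if (nrow(hits) == 0L) return(empty)
  hits |>
    dplyr::mutate(
      probe_id = probes$probe_id[.data$query],
      platform = probes$platform[.data$query],
      target_id = exons$transcript_id[.data$subject],
      gene_symbol = exons$gene_symbol[.data$subject],
      overlap = interval_overlap_bp(
        probes$start[.data$query], probes$end[.data$query],
        exons$start[.data$subject], exons$end[.data$subject]
      )
    ) |>
    # total probe/transcript overlap across that transcript's exons
    dplyr::group_by(.data$probe_id, .data$platform, .data$target_id,
                    .data$gene_symbol) |>
    dplyr::summarise(overlap = sum(.data$overlap), .groups = "drop") |>
    dplyr::group_by(.data$probe_id, .data$platform) |>
    dplyr::filter(dplyr::n_distinct(.data$gene_symbol) == 1L) |>
    dplyr::arrange(dplyr::desc(.data$overlap), .data$target_id,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(target_kind = kind) |>
    dplyr::select("probe_id", "platform", "target_id", "target_kind",
                  "gene_symbol")
}

#' Summarize a probe reannotation
#'
#' @param assignments output of [assign_probes()].
#' @return tibble with one row per platform: counts of lncRNA probes, coding
#'   probes and unique lncRNA genes, plus a final `all` row where unique
#'   lncRNAs are counted once across platforms.
#' @export
summarize_reannotation <- function(assignments) {
  check_cols(assignments, c("probe_id", "platform", "target_id", "target_kind"))
  per_platform <- assignments |>
    dplyr::group_by(.data$platform) |>
    dplyr::summarise(
      n_lncrna_probes = sum(.data$target_kind == "lncRNA"),
      n_coding_probes = sum(.data$target_kind == "coding"),
      n_unique_lncrnas = dplyr::n_distinct(
        .data$target_id[.data$target_kind == "lncRNA"]
      ),
      .groups = "drop"
    )
  total <- tibble::tibble(
    platform = "all",
    n_lncrna_probes = sum(assignments$target_kind == "lncRNA"),
    n_coding_probes = sum(assignments$target_kind == "coding"),
    n_unique_lncrnas = dplyr::n_distinct(
      assignments$target_id[assignments$target_kind == "lncRNA"]
    )
  )
  dplyr::bind_rows(per_platform, total)
}
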