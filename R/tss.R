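#' Extract TSS tags from aligned TSS-seq reads
#'
#' The 5' end of each aligned read marks one observed transcription start:
#' for `+` strand reads that is the leftmost aligned base (`start`), for `-`
#' strand reads the rightmost (`end - 1` in 0-based half-open coordinates).
#' Duplicate tags at one position are all kept: tag counts are read counts.
#'
#' @param reads tibble with columns `chrom`, `start`, `end`, `strand`
#'   (BED6-style, 0-based half-open); use [read_tss_reads()] for files.
#' @return tibble with columns `chrom`, `pos`, `strand`, one row per read.
#'   Reads without a `+`/`-` strand are rejected and counted in a warning.
#' @export
extract_tags <- function(reads) {
  check_cols(reads, c("chrom", "start", "end", "strand"))
  bad <- !(reads$strand %in% c("+", "-"))
  if (any(bad)) {
    rlang::warn(sprintf("%d read(s) without usable strand rejected", sum(bad)))
    reads <- reads[!bad, , drop = FALSE]
  }
  tibble::tibble(
    chrom = reads$chrom,
    pos = ifelse(reads$strand == "+", reads$start, reads$end - 1L),
    strand = reads$strand
  )
}

#' Read TSS-seq read alignments from a BED file
#' @param path BED6 file of aligned reads (one record per read).
#' @return tibble with `chrom`, `start`, `end`, `strand`.
#' @export
read_tss_reads <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Cluster TSS tags by single-linkage chaining
#'
#' Tags on the same chromosome and strand are sorted by position and chained
#' into a cluster while the gap between adjacent tags is at most
#' `cluster_gap` bp ("closer than 20 bp" implemented as an inclusive
#' boundary, configurable). Clusters never mix strands or chromosomes.
#'
#' @param tags tibble from [extract_tags()].
#' @param cluster_gap maximum distance in bp between adjacent member tags
#'   (default 20).
#' @return tibble with columns `chrom`, `strand`, `start`, `end` (half-open
#'   span of member positions, i.e. `end = max(pos) + 1`), `tag_count` and a
#'   list-column `positions` of the sorted member tag positions (with
#'   duplicates).
#' @export
cluster_tags <- function(tags, cluster_gap = 20L) {
  check_cols(tags, c("chrom", "pos", "strand"))
  if (nrow(tags) == 0L) {
    return(tibble::tibble(
      chrom = character(), strand = character(), start = integer(),
      end = integer(), tag_count = integer(), positions = list()
    ))
  }
  tags |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::arrange(.data$pos, .by_group = TRUE) |>
    dplyr::mutate(
      .cluster = cumsum(c(TRUE, diff(.data$pos) > cluster_gap))
    ) |>
    dplyr::group_by(.data$chrom, .data$strand, .data$.cluster) |>
    dplyr::summarise(
      start = min(.data$pos),
      end = max(.data$pos) + 1L,
      tag_count = dplyr::n(),
      positions = list(.data$pos),
      .groups = "drop"
    ) |>
    dplyr::select(-".cluster") |>
    dplyr::arrange(.data$chrom, .data$strand, .data$start)
}

#' Group TSS clusters into TSS regions and filter by tag support
#'
#' Same-strand clusters are chained into one region while the gap between
#' nearest cluster edges is at most `group_gap` bp (conventional BED merge
#' semantics: edge distance, not center distance). A region's `tag_count` is
#' the sum over member clusters; regions supported by fewer than `min_tags`
#' tags are discarded.
#'
#' @param clusters tibble from [cluster_tags()].
#' @param group_gap maximum edge-to-edge gap in bp between member clusters
#'   (default 400).
#' @param min_tags minimum supporting tag count (default 20; regions with
#'   fewer are dropped).
#' @return tibble with columns `region_id`, `chrom`, `strand`, `start`,
#'   `end`, `tag_count`, `n_clusters`.
#' @export
group_clusters <- function(clusters, group_gap = 400L, min_tags = 20L) {
  check_cols(clusters, c("chrom", "strand", "start", "end", "tag_count"))
  empty <- tibble::tibble(
    region_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), tag_count = integer(),
    n_clusters = integer()
  )
  if (nrow(clusters) == 0L) return(empty)
  out <- clusters |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      .gap = as.numeric(.data$start) -
        dplyr::lag(cummax(as.numeric(.data$end)), default = -Inf),
      .region = cumsum(.data$.gap > group_gap)
    ) |>
    dplyr::group_by(.data$chrom, .data$strand, .data$.region) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      tag_count = sum(.data$tag_count),
      n_clusters = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$tag_count >= min_tags) |>
    dplyr::arrange(.data$chrom, .data$strand, .data$start) |>
    dplyr::mutate(region_id = sprintf("tssr%05d", dplyr::row_number())) |>
    dplyr::select("region_id", "chrom", "strand", "start", "end",
                  "tag_count", "n_clusters")
  out
}

#' Build TSS regions from aligned reads in one call
#'
#' Convenience wrapper: [extract_tags()] then [cluster_tags()] then
#' [group_clusters()].
#'
#' @inheritParams extract_tags
#' @inheritParams cluster_tags
#' @inheritParams group_clusters
#' @return see [group_clusters()].
#' @export
build_tss_regions <- function(reads, cluster_gap = 20L, group_gap = 400L,
                              min_tags = 20L) {
  reads |>
    extract_tags() |>
    cluster_tags(cluster_gap = cluster_gap) |>
    group_clusters(group_gap = group_gap, min_tags = min_tags)
}

#' Write TSS regions as BED6 (tag count in the score column)
#' @param regions tibble from [group_clusters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tss_regions <- function(regions, path) {
  gr <- as_granges0(regions)
  gr$name <- regions$region_id
  gr$score <- regions$tag_count
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
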