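#' Read transcript models from a BED12 or GTF file
#'
#' Returns one row per transcript model in the package's standard annotation
#' tibble. Coordinates are 0-based half-open (BED convention); GTF input
#' (1-based closed) is converted at this boundary and nowhere else.
#'
#' The BED12 `name` field may carry up to three `|`-separated tokens:
#' `transcript_id`, `gene_symbol` and an explicit biotype (`coding` /
#' `noncoding`). When the biotype token is absent it is resolved from the
#' transcript id prefix in RefSeq style: ids starting `NR` are non-coding,
#' ids starting `NM` are coding. For GTF, the `transcript_biotype` (or
#' `gene_biotype`) attribute is used: `protein_coding` is coding, anything
#' else non-coding. Records whose biotype cannot be resolved are skipped and
#' counted in a single warning.
#'
#' @param path file path.
#' @param source source label recorded in the `source` column (e.g.
#'   `"refseq"`, `"ucsc"`, `"fantom"`, `"ensembl"`, `"synthetic"`).
#' @param format `"bed12"` or `"gtf"`; `"auto"` guesses from the extension.
#' @return A tibble with columns `transcript_id`, `source`, `chrom`, `start`,
#'   `end`, `strand`, `exon_starts`, `exon_ends` (list-columns of integer
#'   vectors), `biotype`, `gene_symbol` and `spliced_length`.
#' @seealso [load_annotations()], [write_bed12()]
#' @export
read_transcripts <- function(path, source = "synthetic",
                             format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) "gtf" else "bed12"
  }
  out <- switch(format,
    bed12 = read_transcripts_bed12(path, source),
    gtf = read_transcripts_gtf(path, source)
  )
  n_skip <- attr(out, "n_biotype_skipped")
  if (!is.null(n_skip) && n_skip > 0L) {
    rlang::warn(sprintf(
      "%d record(s) in %s skipped: biotype could not be resolved", n_skip, path
    ))
  }
  attr(out, "n_biotype_skipped") <- NULL
  out
}

read_transcripts_bed12 <- function(path, source) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) rlang::abort(sprintf(
      "malformed BED record in %s: %s", path, conditionMessage(e)
    ))
  )
  if (length(gr) == 0L) return(empty_annotation(source))
  name <- gr$name %||% sprintf("tx%06d", seq_along(gr))
  parts <- stringr::str_split(name, stringr::fixed("|"))
  tx_id <- purrr::map_chr(parts, 1)
  gene <- purrr::map_chr(parts, ~ if (length(.x) >= 2) .x[[2]] else .x[[1]])
  bio_tok <- purrr::map_chr(parts, ~ if (length(.x) >= 3) .x[[3]] else NA_character_)
  biotype <- resolve_biotype(bio_tok, tx_id)

  blocks <- gr$blocks
  if (is.null(blocks)) {
    ex_start <- as.list(GenomicRanges::start(gr) - 1L)
    ex_end <- as.list(GenomicRanges::end(gr))
  } else {
    offs <- GenomicRanges::start(gr) - 1L # 0-based transcript start
    ex_start <- purrr::map2(as.list(IRanges::start(blocks)), offs, ~ .y + .x - 1L)
    ex_end <- purrr::map2(as.list(IRanges::end(blocks)), offs, ~ .y + .x)
  }
  out <- tibble::tibble(
    transcript_id = tx_id,
    source = source,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    exon_starts = ex_start,
    exon_ends = ex_end,
    biotype = biotype,
    gene_symbol = gene
  )
  finalize_annotation(out, sum(is.na(biotype)))
}

read_transcripts_gtf <- function(path, source) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) rlang::abort(sprintf(
      "malformed GTF record in %s: %s", path, conditionMessage(e)
    ))
  )
  ex <- gr[tolower(gr$type) == "exon"]
  if (length(ex) == 0L) return(empty_annotation(source))
  bio_attr <- ex$transcript_biotype %||% ex$gene_biotype %||%
    rep(NA_character_, length(ex))
  df <- tibble::tibble(
    transcript_id = ex$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    ex_start = GenomicRanges::start(ex) - 1L,
    ex_end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_symbol = ex$gene_name %||% ex$gene_id %||% ex$transcript_id,
    bio_attr = as.character(bio_attr)
  )
  out <- df |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(.data$ex_start, .by_group = TRUE) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$ex_start),
      end = max(.data$ex_end),
      strand = dplyr::first(.data$strand),
      exon_starts = list(.data$ex_start),
      exon_ends = list(.data$ex_end),
      gene_symbol = dplyr::first(.data$gene_symbol),
      bio_attr = dplyr::first(.data$bio_attr),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      source = source,
      biotype = dplyr::case_when(
        .data$bio_attr == "protein_coding" ~ "coding",
        !is.na(.data$bio_attr) ~ "noncoding",
        TRUE ~ resolve_biotype(NA_character_, .data$transcript_id)
      )
    ) |>
    dplyr::select(
      "transcript_id", "source", "chrom", "start", "end", "strand",
      "exon_starts", "exon_ends", "biotype", "gene_symbol"
    )
  finalize_annotation(out, sum(is.na(out$biotype)))
}

resolve_biotype <- function(token, transcript_id) {
  dplyr::case_when(
    token %in% c("coding", "noncoding") ~ token,
    stringr::str_starts(transcript_id, "NR") ~ "noncoding",
    stringr::str_starts(transcript_id, "NM") ~ "coding",
    TRUE ~ NA_character_
  )
}

finalize_annotation <- function(out, n_skipped) {
  out <- out |>
    dplyr::filter(!is.na(.data$biotype)) |>
    dplyr::mutate(
      spliced_length = purrr::map2_int(
        .data$exon_starts, .data$exon_ends, ~ sum(.y - .x)
      )
    )
  attr(out, "n_biotype_skipped") <- n_skipped
  out
}

empty_annotation <- function(source) {
  tibble::tibble(
    transcript_id = character(), source = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    exon_starts = list(), exon_ends = list(), biotype = character(),
    gene_symbol = character(), spliced_length = integer()
  )
}

#' Load and merge transcript annotations from several sources
#'
#' Reads each file with [read_transcripts()] and merges the results.
#' Transcripts identical in `(chrom, start, end, strand, exon structure)`
#' across sources are collapsed into a single record whose `source` column
#' lists all contributing sources (comma-separated); differing isoforms are
#' kept as separate records because the deduplication key includes the exon
#' structure.
#'
#' @param paths character vector of annotation files.
#' @param sources source label per file (recycled if length 1).
#' @param format passed to [read_transcripts()].
#' @return An annotation tibble (see [read_transcripts()] for columns).
#' @examples
#' \dontrun{
#' annots <- load_annotations(c("refgene.bed", "ensembl.gtf"),
#'                            sources = c("refseq", "ensembl"))
#' }
#' @export
load_annotations <- function(paths, sources = "synthetic",
                             format = "auto") {
  sources <- rep_len(sources, length(paths))
  purrr::map2(paths, sources, read_transcripts, format = format) |>
    dplyr::bind_rows() |>
    merge_annotations()
}

#' Merge in-memory annotation tibbles, deduplicating identical models
#'
#' @param annots annotation tibble (possibly a bind of several sources).
#' @return deduplicated annotation tibble; the `source` column of a collapsed
#'   record is the comma-joined, sorted unique set of source labels.
#' @export
merge_annotations <- function(annots) {
  check_cols(annots, c("chrom", "start", "end", "strand", "exon_starts",
                       "exon_ends", "biotype"))
  annots |>
    dplyr::mutate(
      .exon_key = purrr::map2_chr(
        .data$exon_starts, .data$exon_ends,
        ~ paste(.x, .y, sep = "-", collapse = ";")
      )
    ) |>
    dplyr::group_by(
      .data$chrom, .data$start, .data$end, .data$strand, .data$.exon_key,
      .data$biotype
    ) |>
    dplyr::summarise(
      transcript_id = dplyr::first(.data$transcript_id),
      source = paste(sort(unique(unlist(
        stringr::str_split(.data$source, stringr::fixed(","))
      ))), collapse = ","),
      exon_starts = .data$exon_starts[1],
      exon_ends = .data$exon_ends[1],
      gene_symbol = dplyr::first(.data$gene_symbol),
      spliced_length = dplyr::first(.data$spliced_length),
      .groups = "drop"
    ) |>
    dplyr::select(
      "transcript_id", "source", "chrom", "start", "end", "strand",
      "exon_starts", "exon_ends", "biotype", "gene_symbol", "spliced_length"
    ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
}

#' Extract lncRNA candidates from an annotation set
#'
#' A lncRNA candidate is a non-coding transcript whose spliced (exonic)
#' length is at least `min_length` nucleotides; shorter non-coding RNAs
#' (snoRNAs, miRNA precursors, ...) are excluded. The length rule applies to
#' the spliced length, not the genomic span, and the boundary (exactly
#' `min_length`) is included.
#'
#' @param annots annotation tibble.
#' @param min_length minimum spliced length in nt (default 200, the
#'   conventional lncRNA definition).
#' @return the subset of `annots` that are lncRNA candidates.
#' @export
lncrna_candidates <- function(annots, min_length = 200L) {
  check_cols(annots, c("biotype", "spliced_length"))
  dplyr::filter(
    annots, .data$biotype == "noncoding",
    .data$spliced_length >= min_length
  )
}

#' Coding transcripts of an annotation set
#' @param annots annotation tibble.
#' @return the coding subset.
#' @export
coding_transcripts <- function(annots) {
  check_cols(annots, "biotype")
  dplyr::filter(annots, .data$biotype == "coding")
}

#' Write an annotation tibble as BED12
#'
#' The `name` field is written as `transcript_id|gene_symbol|biotype` so a
#' round trip through [read_transcripts()] reproduces all three.
#'
#' @param annots annotation tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(annots, path) {
  check_cols(annots, c("transcript_id", "chrom", "start", "end", "strand",
                       "exon_starts", "exon_ends", "biotype", "gene_symbol"))
  grl <- GenomicRanges::GRangesList(purrr::pmap(
    list(annots$chrom, annots$exon_starts, annots$exon_ends, annots$strand),
    function(chrom, es, ee, st) {
      GenomicRanges::GRanges(chrom, IRanges::IRanges(es + 1L, ee), strand = st)
    }
  ))
  names(grl) <- paste(annots$transcript_id, annots$gene_symbol,
                      annots$biotype, sep = "|")
  bed <- rtracklayer::asBED(grl)
  rtracklayer::export(bed, path, format = "bed")
  invisible(path)
}
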