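#' Associate TSS regions with lncRNA candidates
#'
#' Scans the lncRNA span plus `flank` bp on each side for TSS regions.
#' Association is same-strand by default: the TSS of an antisense transcript
#' should not validate the sense lncRNA.
#'
#' @param lnc lncRNA candidate tibble (annotation columns).
#' @param tss_regions tibble from [group_clusters()].
#' @param flank bp added upstream and downstream of the lncRNA span
#'   (default 30000).
#' @param same_strand require lncRNA and TSS region on the same strand
#'   (default `TRUE`).
#' @return tibble with one row per (lncRNA, TSS region) association:
#'   `transcript_id`, `region_id` plus the region's coordinates and
#'   `tag_count`.
#' @export
associate_tss <- function(lnc, tss_regions, flank = 30000L,
                          same_strand = TRUE) {
  check_cols(lnc, c("transcript_id", "chrom", "start", "end", "strand"))
  check_cols(tss_regions, c("region_id", "chrom", "strand", "start", "end",
                            "tag_count"))
  expanded <- lnc |>
    dplyr::mutate(start = pmax(0L, .data$start - flank),
                  end = .data$end + flank)
  hits <- overlap_pairs(expanded, tss_regions, ignore_strand = !same_strand)
  tibble::tibble(
    transcript_id = lnc$transcript_id[hits$query],
    region_id = tss_regions$region_id[hits$subject],
    chrom = tss_regions$chrom[hits$subject],
    strand = tss_regions$strand[hits$subject],
    start = tss_regions$start[hits$subject],
    end = tss_regions$end[hits$subject],
    tag_count = tss_regions$tag_count[hits$subject]
  ) |>
    dplyr::arrange(.data$transcript_id, .data$start)
}

#' Keep only TSS regions supported by active chromatin
#'
#' A candidate TSS region is retained if it is overlapped (within `window`
#' bp) by at least one peak of any mark in `marks`, in either condition.
#' H3K27Ac is deliberately not in the default filter set: the filter asks
#' for promoter/initiation evidence (H3K4me3, H3K4me1, PolII), not generic
#' activity.
#'
#' @param tss_assoc association tibble from [associate_tss()] (or any tibble
#'   of TSS regions with `chrom`, `start`, `end`).
#' @param peaks peak tibble with columns `mark`, `condition`, `chrom`,
#'   `start`, `end`.
#' @param marks marks accepted as evidence.
#' @param window bp by which a peak may miss the region and still count
#'   (default 0: direct overlap).
#' @param missing_mark what to do when a mark in `marks` has no peaks at
#'   all: `"skip"` drops it from the filter with a warning, `"abort"` errors.
#' @return the subset of `tss_assoc` with chromatin support.
#' @export
filter_by_chromatin <- function(tss_assoc, peaks,
                                marks = c("H3K4me3", "H3K4me1", "PolII"),
                                window = 0L,
                                missing_mark = c("skip", "abort")) {
  missing_mark <- match.arg(missing_mark)
  check_cols(peaks, c("mark", "chrom", "start", "end"))
  absent <- setdiff(marks, unique(peaks$mark))
  if (length(absent) > 0L) {
    msg <- sprintf("no peaks for mark(s): %s", paste(absent, collapse = ", "))
    if (missing_mark == "abort") rlang::abort(msg)
    rlang::warn(paste(msg, "- mark(s) skipped in the chromatin filter"))
  }
  use <- dplyr::filter(peaks, .data$mark %in% marks)
  if (nrow(tss_assoc) == 0L) return(tss_assoc)
  if (nrow(use) == 0L) return(tss_assoc[0, , drop = FALSE])
  hits <- overlap_pairs(tss_assoc, use, ignore_strand = TRUE,
                        maxgap = if (window > 0) as.integer(window) else -1L)
  keep <- sort(unique(hits$query))
  tss_assoc[keep, , drop = FALSE]
}

#' Remove lncRNA TSS regions that clash with coding-gene TSSs
#'
#' A lncRNA TSS region overlapping the promoter-window of any coding gene's
#' own TSS cannot be attributed to the lncRNA with confidence and is
#' excluded. Coding TSS windows are the coding transcripts' 5' ends extended
#' by `ambiguity_window` bp on each side; the clash test is strand-agnostic
#' (a close coding TSS on either strand makes the signal ambiguous).
#'
#' @param tss_assoc association tibble (see [associate_tss()]).
#' @param coding coding transcript tibble.
#' @param ambiguity_window half-width in bp of the coding TSS window
#'   (default 500).
#' @return the subset of `tss_assoc` without coding-TSS clashes.
#' @export
exclude_ambiguous_tss <- function(tss_assoc, coding, ambiguity_window = 500L) {
  if (nrow(tss_assoc) == 0L || nrow(coding) == 0L) return(tss_assoc)
  check_cols(coding, c("chrom", "start", "end", "strand"))
  tss_pos <- tss_position(coding)
  coding_windows <- tibble::tibble(
    chrom = coding$chrom,
    start = pmax(0L, tss_pos - ambiguity_window),
    end = tss_pos + ambiguity_window + 1L
  )
  hits <- overlap_pairs(tss_assoc, coding_windows, ignore_strand = TRUE)
  if (nrow(hits) == 0L) return(tss_assoc)
  tss_assoc[-sort(unique(hits$query)), , drop = FALSE]
}

# 0-based TSS position of a transcript: start on +, end-1 on -.
tss_position <- function(df) {
  ifelse(df$strand == "+", df$start, df$end - 1L)
}

#' Collapse coding transcripts to gene loci
#'
#' One row per coding gene: the union span of its transcripts plus the union
#' of their exons (list-columns), used by positional classification and
#' neighbor analysis.
#'
#' @param coding coding transcript tibble.
#' @return tibble with `gene_symbol`, `chrom`, `start`, `end`, `strand`,
#'   `exon_starts`, `exon_ends`.
#' @export
coding_gene_loci <- function(coding) {
  check_cols(coding, c("gene_symbol", "chrom", "start", "end", "strand",
                       "exon_starts", "exon_ends"))
  coding |>
    dplyr::group_by(.data$gene_symbol, .data$chrom, .data$strand) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      exon_starts = list(unlist(.data$exon_starts)),
      exon_ends = list(unlist(.data$exon_ends)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
}

# For each row of `query`, pick the neighbor gene: the overlapping gene with
# the longest overlap, otherwise the gene with the smallest gap; ties broken
# by smaller gene start. Returns a tibble aligned with `query` rows:
# neighbor_gene, neighbor_distance (0 if overlapping, Inf if no gene on the
# chromosome), overlap_bp, plus the neighbor row index into `genes`.
neighbor_lookup <- function(query, genes) {
  n <- nrow(query)
  out <- tibble::tibble(
    neighbor_gene = rep(NA_character_, n),
    neighbor_distance = rep(Inf, n),
    overlap_bp = rep(0L, n),
    neighbor_idx = rep(NA_integer_, n)
  )
  if (nrow(genes) == 0L || n == 0L) return(out)
  for (i in seq_len(n)) {
    same_chr <- which(genes$chrom == query$chrom[i])
    if (length(same_chr) == 0L) next
    ov <- interval_overlap_bp(query$start[i], query$end[i],
                              genes$start[same_chr], genes$end[same_chr])
    if (any(ov > 0L)) {
      cand <- same_chr[ov == max(ov)]
      best <- cand[which.min(genes$start[cand])]
      out$neighbor_gene[i] <- genes$gene_symbol[best]
      out$neighbor_distance[i] <- 0
      out$overlap_bp[i] <- max(ov)
      out$neighbor_idx[i] <- best
    } else {
      gap <- interval_gap_bp(query$start[i], query$end[i],
                             genes$start[same_chr], genes$end[same_chr])
      cand <- same_chr[gap == min(gap)]
      best <- cand[which.min(genes$start[cand])]
      out$neighbor_gene[i] <- genes$gene_symbol[best]
      out$neighbor_distance[i] <- min(gap)
      out$neighbor_idx[i] <- best
    }
  }
  out
}

#' Classify lncRNAs by position relative to coding genes
#'
#' Each lncRNA is assigned to exactly one of five classes by its relation to
#' its neighbor coding gene (the gene with the longest overlap, or, if none
#' overlaps, the nearest gene):
#' \describe{
#'   \item{exonic_sense}{lncRNA exons overlap coding exons on the same strand}
#'   \item{intronic_sense}{overlaps the coding locus on the same strand but
#'     only in introns}
#'   \item{antisense}{overlaps the coding locus on the opposite strand}
#'   \item{bidirectional}{no overlap, opposite strand, and closer than
#'     `bidirectional_max` bp}
#'   \item{intergenic}{everything else (including lncRNAs on a chromosome
#'     with no coding gene, whose `neighbor_distance` is `Inf`)}
#' }
#'
#' @param lnc lncRNA tibble (annotation columns).
#' @param coding coding transcript tibble; collapsed internally with
#'   [coding_gene_loci()].
#' @param bidirectional_max distance bound in bp for the bidirectional class
#'   (default 1000, strict `<`).
#' @param bidirectional_metric `"gene"` measures the gap between the lncRNA
#'   and the gene locus; `"tss"` measures the distance between the lncRNA
#'   TSS and the gene TSS.
#' @return tibble with `transcript_id`, `position_class`, `neighbor_gene`,
#'   `neighbor_distance` (bp; 0 when overlapping, `Inf` when no coding gene
#'   shares the chromosome).
#' @export
classify_position <- function(lnc, coding, bidirectional_max = 1000L,
                              bidirectional_metric = c("gene", "tss")) {
  bidirectional_metric <- match.arg(bidirectional_metric)
  check_cols(lnc, c("transcript_id", "chrom", "start", "end", "strand",
                    "exon_starts", "exon_ends"))
  genes <- coding_gene_loci(coding)
  nb <- neighbor_lookup(lnc, genes)
  cls <- character(nrow(lnc))
  for (i in seq_len(nrow(lnc))) {
    if (is.na(nb$neighbor_idx[i])) {
      cls[i] <- "intergenic"
      next
    }
    g <- nb$neighbor_idx[i]
    same <- lnc$strand[i] == genes$strand[g]
    if (nb$neighbor_distance[i] == 0) {
      if (!same) {
        cls[i] <- "antisense"
      } else {
        ex_ov <- any(outer_overlap(lnc$exon_starts[[i]], lnc$exon_ends[[i]],
                                   genes$exon_starts[[g]], genes$exon_ends[[g]]))
        cls[i] <- if (ex_ov) "exonic_sense" else "intronic_sense"
      }
    } else {
      d <- if (bidirectional_metric == "tss") {
        abs(tss_position(lnc[i, ]) - tss_position(genes[g, ]))
      } else {
        nb$neighbor_distance[i]
      }
      cls[i] <- if (!same && d < bidirectional_max) "bidirectional" else "intergenic"
    }
  }
  tibble::tibble(
    transcript_id = lnc$transcript_id,
    position_class = cls,
    neighbor_gene = nb$neighbor_gene,
    neighbor_distance = nb$neighbor_distance
  )
}

# any pairwise overlap between two interval sets
outer_overlap <- function(s1, e1, s2, e2) {
  if (length(s1) == 0L || length(s2) == 0L) return(FALSE)
  m <- outer(s1, e2, `<`) & outer(e1, s2, `>`)
  m
}

#' Name lncRNAs after their neighboring coding genes
#'
#' Regulated lncRNAs are conventionally named `lncRNA-<GeneSymbol>` after
#' their neighbor coding gene; when several lncRNAs share a neighbor the
#' second and later get numeric suffixes (`lncRNA-Rel`, `lncRNA-Rel-2`, ...).
#' lncRNAs without a neighbor keep their internal id.
#'
#' @param catalog tibble with `transcript_id` and `neighbor_gene`.
#' @return `catalog` with a `display_name` column added.
#' @export
name_lncrnas <- function(catalog) {
  check_cols(catalog, c("transcript_id", "neighbor_gene"))
  catalog |>
    dplyr::group_by(.data$neighbor_gene) |>
    dplyr::mutate(
      display_name = dplyr::if_else(
        is.na(.data$neighbor_gene),
        .data$transcript_id,
        paste0("lncRNA-", .data$neighbor_gene,
               dplyr::if_else(dplyr::row_number() == 1L, "",
                              paste0("-", dplyr::row_number())))
      )
    ) |>
    dplyr::ungroup()
}

#' Build the validated lncRNA catalog
#'
#' Runs the full validation chain on lncRNA candidates: TSS association
#' within `flank` bp, chromatin-peak filtering, coding-TSS ambiguity
#' exclusion, positional classification and naming. Only lncRNAs with at
#' least one surviving TSS region enter the catalog. The primary TSS of each
#' lncRNA (the anchor for windowed chromatin analyses) is the midpoint of
#' its surviving TSS region with the highest tag count.
#'
#' @param lnc lncRNA candidate tibble ([lncrna_candidates()]).
#' @param coding coding transcript tibble.
#' @param tss_regions tibble from [group_clusters()].
#' @param peaks chromatin peak tibble (see [filter_by_chromatin()]).
#' @param flank,same_strand passed to [associate_tss()].
#' @param marks,peak_window passed to [filter_by_chromatin()].
#' @param ambiguity_window passed to [exclude_ambiguous_tss()].
#' @param bidirectional_max,bidirectional_metric passed to
#'   [classify_position()].
#' @return A catalog tibble of class `lnc_catalog`: one row per validated
#'   lncRNA with span columns, `n_tss_regions`, `primary_tss`, `tag_count`
#'   (of the primary region), `position_class`, `neighbor_gene`,
#'   `neighbor_distance`, `display_name`. Attributes: `tss_map` (the
#'   surviving lncRNA-to-TSS-region associations) and `funnel` (stage
#'   counts).
#' @export
build_catalog <- function(lnc, coding, tss_regions, peaks,
                          flank = 30000L, same_strand = TRUE,
                          marks = c("H3K4me3", "H3K4me1", "PolII"),
                          peak_window = 0L, ambiguity_window = 500L,
                          bidirectional_max = 1000L,
                          bidirectional_metric = "gene") {
  assoc <- associate_tss(lnc, tss_regions, flank = flank,
                         same_strand = same_strand)
  n_with_tss <- dplyr::n_distinct(assoc$transcript_id)
  assoc <- filter_by_chromatin(assoc, peaks, marks = marks,
                               window = peak_window)
  n_after_chromatin <- dplyr::n_distinct(assoc$transcript_id)
  assoc <- exclude_ambiguous_tss(assoc, coding,
                                 ambiguity_window = ambiguity_window)
  n_after_ambiguity <- dplyr::n_distinct(assoc$transcript_id)

  primary <- assoc |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(dplyr::desc(.data$tag_count), .data$start,
                   .by_group = TRUE) |>
    dplyr::summarise(
      n_tss_regions = dplyr::n(),
      primary_tss = as.integer(floor((.data$start[1] + .data$end[1]) / 2)),
      tag_count = .data$tag_count[1],
      .groups = "drop"
    )
  kept <- dplyr::semi_join(lnc, primary, by = "transcript_id")
  cls <- classify_position(kept, coding,
                           bidirectional_max = bidirectional_max,
                           bidirectional_metric = bidirectional_metric)
  catalog <- kept |>
    dplyr::inner_join(primary, by = "transcript_id") |>
    dplyr::inner_join(cls, by = "transcript_id") |>
    name_lncrnas() |>
    dplyr::rename(lnc_id = "transcript_id")
  attr(catalog, "tss_map") <- assoc
  attr(catalog, "funnel") <- tibble::tibble(
    stage = c("lncRNA candidates", "with TSS evidence",
              "after chromatin filter", "after ambiguity filter"),
    n = c(nrow(lnc), n_with_tss, n_after_chromatin, n_after_ambiguity)
  )
  class(catalog) <- c("lnc_catalog", class(catalog))
  catalog
}
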