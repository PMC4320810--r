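# Chromatin signal around lncRNA TSSs. Coverage tracks travel as bedGraph
# tibbles (chrom, start, end, value; 0-based half-open) with a library size
# per track; densities are normalized to 10 million reads and averaged per
# base over the window.

#' Read a bedGraph coverage track
#' @param path bedGraph file.
#' @return tibble `chrom`, `start`, `end`, `value` (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = gr$score
  )
}

#' Read a peak file (BED3/BED6/narrowPeak)
#' @param path peak file.
#' @param mark,condition labels stored alongside the intervals.
#' @return tibble `mark`, `condition`, `chrom`, `start`, `end`.
#' @export
read_peaks <- function(path, mark, condition = "unstim") {
  fmt <- if (grepl("narrowPeak$", path)) "narrowPeak" else "bed"
  gr <- rtracklayer::import(path, format = fmt)
  tibble::tibble(
    mark = mark, condition = condition,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Normalized signal density in windows around TSS positions
#'
#' For each anchor position, sums the per-base coverage over
#' `[tss - window, tss + window)`, scales to a 10-million-read library and
#' divides by the window width: the result is mean normalized signal per
#' base. Windows truncated at a chromosome edge (position 0, or
#' `chrom_lengths` if given) are divided by the truncated width. Anchors on
#' chromosomes absent from the track get density 0 with one warning.
#'
#' @param coverage bedGraph tibble ([read_bedgraph()]).
#' @param anchors tibble with columns `lnc_id` and `chrom`, plus `primary_tss`
#'   (or `pos`) giving the anchor position.
#' @param window half-width in bp (default 2000, i.e. a 4 kb window).
#' @param library_size total aligned reads behind the track; densities are
#'   scaled by `1e7 / library_size`.
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   right-edge truncation.
#' @return tibble `lnc_id`, `density`.
#' @export
quantify_window <- function(coverage, anchors, window = 2000L,
                            library_size = 1e7, chrom_lengths = NULL) {
  check_cols(coverage, c("chrom", "start", "end", "value"))
  check_cols(anchors, c("lnc_id", "chrom"))
  pos <- anchors$primary_tss %||% anchors$pos
  if (is.null(pos)) rlang::abort("anchors need a `primary_tss` or `pos` column")
  win <- tibble::tibble(
    chrom = anchors$chrom,
    start = pmax(0L, pos - window),
    end = pos + window
  )
  if (!is.null(chrom_lengths)) {
    lens <- chrom_lengths[win$chrom]
    win$end <- pmin(win$end, ifelse(is.na(lens), win$end, lens))
  }
  absent <- !(win$chrom %in% unique(coverage$chrom))
  if (any(absent)) {
    rlang::warn(sprintf(
      "%d anchor(s) on chromosomes absent from the coverage track; density 0",
      sum(absent)
    ))
  }
  # absent chromosomes are handled above; silence the seqlevel notice
  hits <- suppressWarnings(overlap_pairs(win, coverage, ignore_strand = TRUE))
  signal <- rep(0, nrow(win))
  if (nrow(hits) > 0L) {
    contrib <- interval_overlap_bp(
      win$start[hits$query], win$end[hits$query],
      coverage$start[hits$subject], coverage$end[hits$subject]
    ) * coverage$value[hits$subject]
    agg <- tapply(contrib, hits$query, sum)
    signal[as.integer(names(agg))] <- agg
  }
  width <- pmax(1L, win$end - win$start)
  tibble::tibble(
    lnc_id = anchors$lnc_id,
    density = signal * (1e7 / library_size) / width
  )
}

#' Quantify all marks and conditions around catalog TSSs
#'
#' @param catalog `lnc_catalog` tibble (needs `lnc_id`, `chrom`,
#'   `primary_tss`).
#' @param tracks tibble with one row per track: columns `mark`, `condition`,
#'   `coverage` (list-column of bedGraph tibbles) and `library_size`.
#' @inheritParams quantify_window
#' @return tibble `lnc_id`, `mark`, `condition`, `density`.
#' @export
quantify_marks <- function(catalog, tracks, window = 2000L,
                           chrom_lengths = NULL) {
  check_cols(tracks, c("mark", "condition", "coverage", "library_size"))
  purrr::pmap(
    list(tracks$mark, tracks$condition, tracks$coverage, tracks$library_size),
    function(mark, condition, cov, lib) {
      quantify_window(cov, catalog, window = window, library_size = lib,
                      chrom_lengths = chrom_lengths) |>
        dplyr::mutate(mark = mark, condition = condition)
    }
  ) |>
    dplyr::bind_rows() |>
    dplyr::select("lnc_id", "mark", "condition", "density")
}

#' Classify lncRNAs as enhancer-like or promoter-associated
#'
#' The ratio of H3K4me1 to H3K4me3 density in the 4 kb window centered on
#' the TSS separates enhancer-like lncRNAs (elncRNA, ratio high) from
#' promoter-associated ones (plncRNA, ratio low). A pseudo-density
#' `epsilon` regularizes the ratio; by default it is 0.1 times the median
#' nonzero density over both marks, which makes the classification invariant
#' to rescaling both tracks by a common factor. Classification uses the
#' unstimulated condition by default (stimulation barely moves the ratio);
#' `pool_conditions` averages the two conditions instead.
#'
#' @param signals density tibble from [quantify_marks()].
#' @param ratio_threshold elncRNA iff ratio strictly greater (default 1;
#'   ties go to plncRNA).
#' @param epsilon pseudo-density; `NULL` (default) uses 0.1 x median nonzero
#'   density of the two marks used.
#' @param condition condition used (default `"unstim"`).
#' @param pool_conditions average densities over all conditions instead.
#' @return tibble `lnc_id`, `me1_density`, `me3_density`, `ratio`,
#'   `chromatin_class` (`"elncRNA"`, `"plncRNA"`, or `"unclassified"` when
#'   both densities are 0).
#' @export
classify_chromatin <- function(signals, ratio_threshold = 1,
                               epsilon = NULL, condition = "unstim",
                               pool_conditions = FALSE) {
  check_cols(signals, c("lnc_id", "mark", "condition", "density"))
  use <- dplyr::filter(signals, .data$mark %in% c("H3K4me1", "H3K4me3"))
  if (!pool_conditions) {
    use <- dplyr::filter(use, .data$condition == !!condition)
  }
  wide <- use |>
    dplyr::group_by(.data$lnc_id, .data$mark) |>
    dplyr::summarise(density = mean(.data$density), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "mark", values_from = "density",
                       values_fill = 0)
  check_cols(wide, c("H3K4me1", "H3K4me3"), "chromatin signals")
  if (is.null(epsilon)) {
    nz <- c(wide$H3K4me1, wide$H3K4me3)
    nz <- nz[nz > 0]
    epsilon <- if (length(nz) > 0) 0.1 * stats::median(nz) else 0.1
  }
  wide |>
    dplyr::mutate(
      ratio = (.data$H3K4me1 + epsilon) / (.data$H3K4me3 + epsilon),
      chromatin_class = dplyr::case_when(
        .data$H3K4me1 == 0 & .data$H3K4me3 == 0 ~ "unclassified",
        .data$ratio > ratio_threshold ~ "elncRNA",
        TRUE ~ "plncRNA"
      )
    ) |>
    dplyr::rename(me1_density = "H3K4me1", me3_density = "H3K4me3") |>
    dplyr::select("lnc_id", "me1_density", "me3_density", "ratio",
                  "chromatin_class")
}

#' Relate chromatin-mark changes to expression changes
#'
#' For each mark and chromatin class, lncRNAs are split into an "increased"
#' and a "decreased" group by the log2 ratio of stimulated to unstimulated
#' density (beyond `change_threshold` either way; a pseudo-density of 0.1 x
#' the median nonzero density stabilizes the ratio). Each group's integrated
#' expression log2 fold changes are compared against all lncRNAs of that
#' class by a one-sided two-sample Kolmogorov-Smirnov test: the increased
#' group is tested for a right shift, the decreased group for a left shift,
#' reflecting that all four marks are activity marks.
#'
#' @param signals density tibble from [quantify_marks()] (both conditions).
#' @param expression tibble `lnc_id`, `log2fc` of integrated expression
#'   changes.
#' @param change_threshold log2 ratio beyond which a mark counts as changed
#'   (default `log2(1.5)`).
#' @param min_group groups smaller than this get a low-n warning (default 5).
#' @return tibble `mark`, `chromatin_class` (if present in `expression`),
#'   `group` (`increased`/`decreased`), `n`, `ks_D`, `ks_p`.
#' @export
mark_change_vs_expression <- function(signals, expression,
                                      change_threshold = log2(1.5),
                                      min_group = 5L) {
  check_cols(signals, c("lnc_id", "mark", "condition", "density"))
  check_cols(expression, c("lnc_id", "log2fc"))
  wide <- signals |>
    tidyr::pivot_wider(names_from = "condition", values_from = "density")
  check_cols(wide, c("unstim", "LPS"), "mark signals")
  nz <- c(wide$unstim, wide$LPS)
  nz <- nz[nz > 0]
  eps <- if (length(nz) > 0) 0.1 * stats::median(nz) else 0.1
  wide <- wide |>
    dplyr::mutate(delta = log2((.data$LPS + eps) / (.data$unstim + eps))) |>
    dplyr::inner_join(expression, by = "lnc_id")
  group_col <- if ("chromatin_class" %in% names(wide)) "chromatin_class" else NULL
  wide |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("mark", group_col)))) |>
    dplyr::group_modify(function(df, key) {
      all_fc <- df$log2fc
      run_one <- function(sel, side, label) {
        fc <- df$log2fc[sel]
        if (length(fc) == 0L) {
          return(tibble::tibble(group = label, n = 0L, ks_D = NA_real_,
                                ks_p = NA_real_))
        }
        if (length(fc) < min_group) {
          rlang::warn(sprintf("group '%s' has n = %d < %d", label,
                              length(fc), min_group))
        }
        kt <- ks_shift_test(fc, all_fc, side = side)
        tibble::tibble(group = label, n = length(fc),
                       ks_D = kt$statistic, ks_p = kt$p.value)
      }
      dplyr::bind_rows(
        run_one(df$delta > change_threshold, "right", "increased"),
        run_one(df$delta < -change_threshold, "left", "decreased")
      )
    }) |>
    dplyr::ungroup()
}

#' One-sided two-sample KS shift test
#'
#' Tests whether `x` is shifted to the right (`side = "right"`: `x`
#' stochastically larger, its ECDF below the reference's) or to the left of
#' `reference`. Thin wrapper over [stats::ks.test()] mapping the shift
#' direction onto its `alternative` argument (a right shift is
#' `alternative = "less"` in ECDF terms).
#'
#' @param x sample of interest.
#' @param reference comparison sample. When `x` is a subset of the
#'   reference (as in [mark_change_vs_expression()], which follows the
#'   group-versus-all-lncRNAs convention), the shared members make the test
#'   conservative.
#' @param side `"right"` or `"left"`: the shift direction tested.
#' @return list with `statistic` (D) and `p.value`.
#' @export
ks_shift_test <- function(x, reference, side = c("right", "left")) {
  side <- match.arg(side)
  kt <- suppressWarnings(stats::ks.test(
    x, reference, alternative = if (side == "right") "less" else "greater"
  ))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Chi-square test of regulation direction by chromatin class
#'
#' Tests whether up/down regulation is distributed differently between
#' elncRNAs and plncRNAs (2x2 table, no continuity correction by default).
#'
#' @param calls tibble with columns `chromatin_class` and `direction` for
#'   the regulated lncRNAs.
#' @param correct continuity correction (default `FALSE`).
#' @return `htest` object from [stats::chisq.test()].
#' @export
regulation_class_test <- function(calls, correct = FALSE) {
  check_cols(calls, c("chromatin_class", "direction"))
  tab <- table(calls$chromatin_class, calls$direction)
  suppressWarnings(stats::chisq.test(tab, correct = correct))
}
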