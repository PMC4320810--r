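#' Nearest coding-gene neighbor for each lncRNA
#'
#' The neighbor of a lncRNA is the coding gene with the longest overlapping
#' region, or, if no gene overlaps, the gene at the smallest gap (ties to
#' the smaller gene start). Distance is 0 exactly when the loci overlap.
#'
#' @param catalog catalog or annotation tibble (`lnc_id` or `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`).
#' @param coding coding transcript tibble; collapsed to gene loci
#'   internally.
#' @return tibble `lnc_id`, `gene_symbol`, `distance`, `overlap_bp`.
#' @export
nearest_neighbor <- function(catalog, coding) {
  id <- catalog[["lnc_id"]] %||% catalog[["transcript_id"]]
  if (is.null(id)) rlang::abort("catalog needs an `lnc_id` or `transcript_id` column")
  check_cols(catalog, c("chrom", "start", "end"))
  genes <- coding_gene_loci(coding)
  nb <- neighbor_lookup(catalog, genes)
  tibble::tibble(
    lnc_id = id,
    gene_symbol = nb$neighbor_gene,
    distance = nb$neighbor_distance,
    overlap_bp = nb$overlap_bp
  )
}

#' Neighbor co-expression and distance comparisons
#'
#' Two complementary analyses on lncRNA/neighbor-gene pairs:
#' \itemize{
#'   \item per grouping level (position class or chromatin class), the
#'     neighbor-gene log2 fold changes of LPS-changed lncRNAs are compared
#'     against the fold changes of \emph{all} genes by a two-sample KS test
#'     (co-regulated neighbors shift the distribution);
#'   \item elncRNA vs plncRNA neighbor distances are compared by a
#'     two-sample t-test, restricted to intergenic and bidirectional
#'     lncRNAs (classes where a distance is meaningful).
#' }
#'
#' @param pairs tibble with one row per lncRNA: `lnc_id`, `gene_symbol`,
#'   `distance`, `gene_log2fc`, `lnc_changed` (logical: lncRNA called
#'   LPS-regulated), plus the grouping column and (for the distance test)
#'   `chromatin_class` and `position_class`.
#' @param all_gene_log2fc numeric vector: integrated fold changes of all
#'   coding genes (the KS reference).
#' @param grouping column name to group the KS analysis by (default
#'   `"position_class"`).
#' @param min_group groups with fewer changed lncRNAs than this are skipped
#'   with a warning (default 3).
#' @return list with `ks` (tibble `group`, `n`, `ks_D`, `ks_p`) and
#'   `distance_test` (`htest` or `NULL` when a class is missing).
#' @export
neighbor_coexpression <- function(pairs, all_gene_log2fc,
                                  grouping = "position_class",
                                  min_group = 3L) {
  check_cols(pairs, c("lnc_id", "gene_log2fc", "lnc_changed", grouping))
  ks <- pairs |>
    dplyr::filter(.data$lnc_changed, !is.na(.data$gene_log2fc)) |>
    dplyr::group_by(group = .data[[grouping]]) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < min_group) {
        rlang::warn(sprintf("group '%s' has n = %d < %d; skipped",
                            as.character(key$group[1]), nrow(df), min_group))
        return(tibble::tibble(n = nrow(df), ks_D = NA_real_, ks_p = NA_real_))
      }
      kt <- suppressWarnings(stats::ks.test(df$gene_log2fc, all_gene_log2fc))
      tibble::tibble(n = nrow(df), ks_D = unname(kt$statistic),
                     ks_p = kt$p.value)
    }) |>
    dplyr::ungroup()
  dist_test <- NULL
  if (all(c("chromatin_class", "position_class", "distance") %in% names(pairs))) {
    sub <- dplyr::filter(
      pairs,
      .data$position_class %in% c("intergenic", "bidirectional"),
      .data$chromatin_class %in% c("elncRNA", "plncRNA"),
      is.finite(.data$distance)
    )
    if (dplyr::n_distinct(sub$chromatin_class) == 2L &&
        min(table(sub$chromatin_class)) >= 2L) {
      dist_test <- stats::t.test(distance ~ chromatin_class, data = sub)
    }
  }
  list(ks = ks, distance_test = dist_test)
}

#' Sign concordance of lncRNA and neighbor-gene fold changes
#' @param pairs tibble with `lnc_log2fc` and `gene_log2fc`.
#' @return fraction of pairs with equal fold-change sign (pairs with a
#'   missing value excluded).
#' @export
sign_concordance <- function(pairs) {
  check_cols(pairs, c("lnc_log2fc", "gene_log2fc"))
  ok <- !is.na(pairs$lnc_log2fc) & !is.na(pairs$gene_log2fc)
  mean(sign(pairs$lnc_log2fc[ok]) == sign(pairs$gene_log2fc[ok]))
}

#' Associate transcription-factor peaks with lncRNA promoters
#'
#' A lncRNA is bound by a TF when at least one peak of that TF lies within
#' the promoter-proximal window `[primary_tss - window, primary_tss +
#' window)` (strand-agnostic: peaks carry no strand). Besides the per-lncRNA
#' bound flags the summary reports Venn-style counts over the four classic
#' LPS transcription factors (p65, IRF3, JunB, cJun), the mean pairwise
#' distance between different TFs' nearest peak summits on co-bound
#' lncRNAs, and the fraction of Bcl6-bound lncRNAs also bound by at least
#' one of the four after stimulation.
#'
#' @param catalog catalog tibble (`lnc_id`, `chrom`, `primary_tss`).
#' @param tf_peaks tibble `tf`, `condition`, `chrom`, `start`, `end`.
#' @param window half-width of the promoter-proximal window in bp
#'   (default 10000).
#' @param condition condition whose peaks define binding (default `"LPS"`).
#' @param core_tfs the TF set used for Venn counts and the Bcl6
#'   co-localization fraction.
#' @return list with:
#'   \describe{
#'     \item{binding}{tibble `lnc_id` x `tf` with `bound` and
#'       `nearest_summit` (bp position of the nearest peak summit, NA when
#'       unbound)}
#'     \item{venn}{tibble `tf_set` (comma-joined subset of `core_tfs`),
#'       `n` for each non-empty combination}
#'     \item{n_bound_any}{number of lncRNAs bound by >= 1 core TF}
#'     \item{per_tf}{tibble `tf`, `n_bound`}
#'     \item{mean_pairwise_summit_distance}{mean over co-bound lncRNAs of
#'       pairwise distances between different TFs' nearest summits}
#'     \item{bcl6_colocalization}{fraction of Bcl6-bound lncRNAs also bound
#'       by >= 1 core TF (NA when Bcl6 absent)}
#'   }
#' @export
associate_tf_peaks <- function(catalog, tf_peaks, window = 10000L,
                               condition = "LPS",
                               core_tfs = c("p65", "IRF3", "JunB", "cJun")) {
  check_cols(catalog, c("lnc_id", "chrom", "primary_tss"))
  check_cols(tf_peaks, c("tf", "condition", "chrom", "start", "end"))
  peaks <- dplyr::filter(tf_peaks, .data$condition == !!condition)
  tfs <- unique(peaks$tf)
  win <- tibble::tibble(
    chrom = catalog$chrom,
    start = pmax(0L, catalog$primary_tss - window),
    end = catalog$primary_tss + window
  )
  binding <- purrr::map(tfs, function(tf_i) {
    pk <- dplyr::filter(peaks, .data$tf == tf_i)
    hits <- overlap_pairs(win, pk, ignore_strand = TRUE)
    summit <- rep(NA_real_, nrow(catalog))
    if (nrow(hits) > 0L) {
      hits <- hits |>
        dplyr::mutate(
          s = (pk$start[.data$subject] + pk$end[.data$subject]) / 2,
          d = abs(.data$s - catalog$primary_tss[.data$query])
        ) |>
        dplyr::group_by(.data$query) |>
        dplyr::slice_min(.data$d, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
      summit[hits$query] <- hits$s
    }
    tibble::tibble(
      lnc_id = catalog$lnc_id, tf = tf_i,
      bound = !is.na(summit), nearest_summit = summit
    )
  }) |>
    dplyr::bind_rows()
  core_present <- intersect(core_tfs, tfs)
  core_bind <- dplyr::filter(binding, .data$tf %in% core_present, .data$bound)
  venn <- core_bind |>
    dplyr::group_by(.data$lnc_id) |>
    dplyr::summarise(
      tf_set = paste(sort(unique(.data$tf)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::count(.data$tf_set, name = "n")
  per_tf <- binding |>
    dplyr::group_by(.data$tf) |>
    dplyr::summarise(n_bound = sum(.data$bound), .groups = "drop")
  # mean pairwise distance between different core TFs' nearest summits
  co <- core_bind |>
    dplyr::group_by(.data$lnc_id) |>
    dplyr::filter(dplyr::n() >= 2L) |>
    dplyr::summarise(
      mean_pair = mean(stats::dist(.data$nearest_summit)),
      .groups = "drop"
    )
  mean_pair_dist <- if (nrow(co) > 0L) mean(co$mean_pair) else NA_real_
  bcl6_frac <- NA_real_
  if ("Bcl6" %in% tfs) {
    bcl6_lnc <- binding$lnc_id[binding$tf == "Bcl6" & binding$bound]
    if (length(bcl6_lnc) > 0L) {
      bcl6_frac <- mean(bcl6_lnc %in% core_bind$lnc_id)
    }
  }
  missing_tf <- setdiff(core_tfs, tfs)
  if (length(missing_tf) > 0L) {
    rlang::warn(sprintf("no peaks for TF(s): %s; omitted from summaries",
                        paste(missing_tf, collapse = ", ")))
  }
  list(
    binding = binding,
    venn = venn,
    n_bound_any = dplyr::n_distinct(core_bind$lnc_id),
    per_tf = per_tf,
    mean_pairwise_summit_distance = mean_pair_dist,
    bcl6_colocalization = bcl6_frac
  )
}

#' Two-sided KS enrichment of TF-target lncRNAs' expression changes
#'
#' Compares the integrated fold changes of the lncRNAs bound by a TF
#' against all lncRNAs with a two-sided two-sample KS test, per TF (and per
#' chromatin class when present in `expression`).
#'
#' @param binding binding tibble from [associate_tf_peaks()]`$binding`.
#' @param expression tibble `lnc_id`, `log2fc`, optionally
#'   `chromatin_class`.
#' @return tibble `tf` (x class), `n_targets`, `ks_D`, `ks_p`.
#' @export
tf_target_expression_shift <- function(binding, expression) {
  check_cols(binding, c("lnc_id", "tf", "bound"))
  check_cols(expression, c("lnc_id", "log2fc"))
  group_col <- if ("chromatin_class" %in% names(expression)) "chromatin_class" else NULL
  df <- dplyr::inner_join(binding, expression, by = "lnc_id")
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("tf", group_col)))) |>
    dplyr::group_modify(function(d, key) {
      targets <- d$log2fc[d$bound]
      if (length(targets) < 3L) {
        return(tibble::tibble(n_targets = length(targets), ks_D = NA_real_,
                              ks_p = NA_real_))
      }
      kt <- suppressWarnings(stats::ks.test(targets, d$log2fc))
      tibble::tibble(n_targets = length(targets),
                     ks_D = unname(kt$statistic), ks_p = kt$p.value)
    }) |>
    dplyr::ungroup()
}
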