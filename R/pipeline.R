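#' Run the full lncRNA discovery and profiling pipeline
#'
#' Orchestrates every stage on an in-memory universe (real data loaded with
#' the package readers into the same shapes, or [simulate_universe()]
#' output): probe assignment, TSS region building, catalog validation and
#' classification, per-dataset preprocessing and fold changes, robust rank
#' aggregation in both directions, chromatin classification and
#' mark-vs-expression analysis, neighbor analysis and TF association. The
#' pipeline itself draws no random numbers, so a rerun on the same universe
#' is identical.
#'
#' Exonic-sense lncRNAs are excluded from the expression analyses by
#' default: most are fragments of coding-gene UTRs or decay isoforms and
#' their probes cannot distinguish the lncRNA from its host mRNA.
#'
#' @param universe a list with elements `annotation`, `probes`,
#'   `tss_reads`, `chromatin_peaks`, `chromatin_tracks`, `tf_peaks`,
#'   `datasets` (see [simulate_universe()]).
#' @param alpha Bonferroni-adjusted significance cutoff (default 0.05).
#' @param knn_k neighbours for imputation.
#' @param flank,marks,ambiguity_window,bidirectional_max passed to
#'   [build_catalog()].
#' @param cluster_gap,group_gap,min_tags passed to [build_tss_regions()].
#' @param tf_window promoter-proximal half-width for TF association.
#' @param exclude_exonic drop exonic-sense lncRNAs from expression
#'   integration (default `TRUE`).
#' @return an `lnc_pipeline` list: `catalog`, `assignments`,
#'   `tss_regions`, `fc_tables`, `rra_up`, `rra_down`, `regulated`,
#'   `chromatin` (densities + calls), `mark_ks`, `neighbors`, `tf`,
#'   `funnel` (stage-count tibble) and `params`.
#' @export
run_all <- function(universe, alpha = 0.05, knn_k = 10L,
                    flank = 30000L, marks = c("H3K4me3", "H3K4me1", "PolII"),
                    ambiguity_window = 500L, bidirectional_max = 1000L,
                    cluster_gap = 20L, group_gap = 400L, min_tags = 20L,
                    tf_window = 10000L, exclude_exonic = TRUE) {
  needed <- c("annotation", "probes", "tss_reads", "chromatin_peaks",
              "chromatin_tracks", "tf_peaks", "datasets")
  missing <- setdiff(needed, names(universe))
  if (length(missing) > 0L) {
    rlang::abort(paste("universe is missing:", paste(missing, collapse = ", ")))
  }
  annots <- universe$annotation
  lnc_cand <- lncrna_candidates(annots)
  coding <- coding_transcripts(annots)

  ## probes -> assignments
  assignments <- assign_probes(universe$probes, annots)
  lnc_detected_ids <- unique(
    assignments$target_id[assignments$target_kind == "lncRNA"]
  )
  lnc_detected <- dplyr::filter(lnc_cand,
                                .data$transcript_id %in% lnc_detected_ids)

  ## TSS regions
  tss_regions <- build_tss_regions(universe$tss_reads,
                                   cluster_gap = cluster_gap,
                                   group_gap = group_gap, min_tags = min_tags)

  ## validated catalog
  catalog <- build_catalog(lnc_detected, coding, tss_regions,
                           universe$chromatin_peaks, flank = flank,
                           marks = marks,
                           ambiguity_window = ambiguity_window,
                           bidirectional_max = bidirectional_max)

  ## per-dataset fold changes
  fc_tables <- purrr::pmap(
    list(universe$datasets$matrix, universe$datasets$samples,
         universe$datasets$dataset_id, universe$datasets$platform),
    function(mat, samples, dataset_id, platform) {
      dataset_fold_changes(
        mat,
        dplyr::filter(assignments, .data$platform == !!platform),
        samples, dataset_id = dataset_id, k = knn_k
      )
    }
  ) |>
    dplyr::bind_rows()

  ## integrate lncRNA expression
  tested_ids <- catalog$lnc_id
  if (exclude_exonic) {
    tested_ids <- catalog$lnc_id[catalog$position_class != "exonic_sense"]
  }
  lnc_fc <- dplyr::filter(fc_tables, .data$transcript_id %in% tested_ids)
  rra_up <- rra_aggregate(lnc_fc, "up")
  rra_down <- rra_aggregate(lnc_fc, "down")
  regulated <- call_regulated(rra_up, rra_down, alpha = alpha)

  ## integrated (mean) log2 fold changes for downstream distribution tests
  mean_fc <- fc_tables |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(log2fc = mean(.data$log2fc), .groups = "drop")

  ## chromatin signatures at catalog TSSs
  signals <- quantify_marks(catalog, universe$chromatin_tracks)
  chromatin <- classify_chromatin(signals)
  lnc_expr <- mean_fc |>
    dplyr::rename(lnc_id = "transcript_id") |>
    dplyr::inner_join(
      dplyr::select(chromatin, "lnc_id", "chromatin_class"), by = "lnc_id"
    ) |>
    dplyr::semi_join(tibble::tibble(lnc_id = tested_ids), by = "lnc_id")
  mark_ks <- mark_change_vs_expression(signals, lnc_expr)

  ## regulation direction by chromatin class
  reg_tbl <- dplyr::bind_rows(
    dplyr::mutate(regulated$up, direction = "up"),
    dplyr::mutate(regulated$down, direction = "down")
  ) |>
    dplyr::left_join(
      dplyr::select(chromatin, "lnc_id", "chromatin_class"),
      by = c(transcript_id = "lnc_id")
    )
  class_test <- if (nrow(reg_tbl) > 0L &&
                    dplyr::n_distinct(reg_tbl$chromatin_class) == 2L &&
                    dplyr::n_distinct(reg_tbl$direction) == 2L) {
    regulation_class_test(reg_tbl)
  } else {
    NULL
  }

  ## neighbors
  nb <- nearest_neighbor(catalog, coding)
  gene_fc <- fc_tables |>
    dplyr::filter(.data$target_kind == "coding") |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(log2fc = mean(.data$log2fc), .groups = "drop")
  gene_symbol_fc <- coding |>
    dplyr::select("transcript_id", "gene_symbol") |>
    dplyr::inner_join(gene_fc, by = "transcript_id") |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(gene_log2fc = mean(.data$log2fc), .groups = "drop")
  pairs <- catalog |>
    tibble::as_tibble() |>
    dplyr::select("lnc_id", "position_class", "neighbor_gene",
                  "neighbor_distance") |>
    dplyr::left_join(nb, by = "lnc_id") |>
    dplyr::left_join(gene_symbol_fc, by = "gene_symbol") |>
    dplyr::left_join(
      dplyr::rename(mean_fc, lnc_id = "transcript_id",
                    lnc_log2fc = "log2fc"),
      by = "lnc_id"
    ) |>
    dplyr::left_join(
      dplyr::select(chromatin, "lnc_id", "chromatin_class"), by = "lnc_id"
    ) |>
    dplyr::mutate(
      lnc_changed = .data$lnc_id %in% c(regulated$up$transcript_id,
                                        regulated$down$transcript_id)
    )
  coexpr <- neighbor_coexpression(pairs, gene_symbol_fc$gene_log2fc)

  ## transcription factors
  tf <- associate_tf_peaks(catalog, universe$tf_peaks, window = tf_window)
  tf_shift <- tf_target_expression_shift(tf$binding, lnc_expr)

  funnel <- build_funnel(universe, assignments, lnc_detected, catalog,
                         chromatin, regulated, tf)
  structure(
    list(
      catalog = catalog, assignments = assignments,
      tss_regions = tss_regions, fc_tables = fc_tables,
      rra_up = rra_up, rra_down = rra_down, regulated = regulated,
      chromatin = list(signals = signals, calls = chromatin,
                       class_test = class_test),
      mark_ks = mark_ks,
      neighbors = list(pairs = pairs, coexpression = coexpr),
      tf = c(tf, list(expression_shift = tf_shift)),
      funnel = funnel,
      params = list(alpha = alpha, knn_k = knn_k, flank = flank,
                    marks = marks, ambiguity_window = ambiguity_window,
                    bidirectional_max = bidirectional_max,
                    cluster_gap = cluster_gap, group_gap = group_gap,
                    min_tags = min_tags, tf_window = tf_window,
                    exclude_exonic = exclude_exonic)
    ),
    class = "lnc_pipeline"
  )
}

build_funnel <- function(universe, assignments, lnc_detected, catalog,
                         chromatin, regulated, tf) {
  class_counts <- table(catalog$position_class)
  chrom_counts <- table(chromatin$chromatin_class)
  tibble::tibble(
    stage = c(
      "probes in", "probes assigned", "lncRNAs from probes",
      "with TSS evidence", "after chromatin filter",
      "after ambiguity filter (catalog)",
      paste0("class: ", names(class_counts)),
      paste0("chromatin: ", names(chrom_counts)),
      "regulated up", "regulated down", "TF-bound (>=1 core TF)"
    ),
    n = c(
      nrow(universe$probes), nrow(assignments), nrow(lnc_detected),
      attr(catalog, "funnel")$n[2:4],
      as.integer(class_counts), as.integer(chrom_counts),
      nrow(regulated$up), nrow(regulated$down), tf$n_bound_any
    )
  )
}

#' @export
print.lnc_pipeline <- function(x, ...) {
  cat("lncRNA pipeline run\n")
  cat(sprintf("  catalog: %d lncRNAs\n", nrow(x$catalog)))
  cat(sprintf("  regulated: %d up, %d down (alpha = %g)\n",
              nrow(x$regulated$up), nrow(x$regulated$down), x$params$alpha))
  cat("  funnel:\n")
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("    %-34s %6d\n", x$funnel$stage[i], x$funnel$n[i]))
  }
  invisible(x)
}
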