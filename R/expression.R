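# Expression matrices travel as "long-friendly" tibbles: a `probe_id` column
# followed by one numeric column per sample. Sample-to-condition maps travel
# separately as a tibble (sample, condition) so the matrix stays tidy.

#' Impute missing expression values by row-wise k nearest neighbours
#'
#' Missing cells of a probe-level matrix are replaced by the unweighted mean
#' of the values, in that column, of the `k` nearest probes. Distance
#' between two probes is the Euclidean distance over the columns observed in
#' both, rescaled by the number of shared columns so rows with different
#' missingness are comparable; probes sharing no observed column are at
#' infinite distance. Observed cells are never altered.
#'
#' @param mat tibble with a `probe_id` column and numeric sample columns.
#' @param k number of neighbours (default 10). If fewer complete candidate
#'   rows are usable, `k` is truncated with a warning.
#' @return `mat` with missing cells imputed.
#' @export
knn_impute <- function(mat, k = 10L) {
  check_cols(mat, "probe_id")
  x <- as.matrix(mat[setdiff(names(mat), "probe_id")])
  storage.mode(x) <- "double"
  if (!any(is.na(x))) return(mat)
  if (any(colSums(!is.na(x)) == 0L)) {
    rlang::abort("column(s) with all values missing cannot be imputed")
  }
  if (any(rowSums(!is.na(x)) == 0L)) {
    rlang::abort("row(s) with all values missing cannot be imputed")
  }
  n <- nrow(x)
  if (k > n - 1L) {
    rlang::warn(sprintf("k = %d exceeds usable rows; truncated to %d", k, n - 1L))
    k <- n - 1L
  }
  miss_rows <- which(rowSums(is.na(x)) > 0L)
  filled <- x
  for (i in miss_rows) {
    shared <- !is.na(x) & rep(!is.na(x[i, ]), each = n)
    diff2 <- (x - rep(x[i, ], each = n))^2
    diff2[!shared] <- 0
    n_shared <- rowSums(shared)
    d <- sqrt(rowSums(diff2) / n_shared) # normalized Euclidean
    d[n_shared == 0L] <- Inf
    d[i] <- Inf
    ord <- order(d)
    for (j in which(is.na(x[i, ]))) {
      donors <- ord[!is.na(x[ord, j]) & is.finite(d[ord])]
      donors <- utils::head(donors, k)
      if (length(donors) == 0L) {
        rlang::abort(sprintf(
          "cell (%s, %s) has no usable neighbour", mat$probe_id[i],
          colnames(x)[j]
        ))
      }
      filled[i, j] <- mean(x[donors, j])
    }
  }
  out <- mat
  out[setdiff(names(mat), "probe_id")] <- as.data.frame(filled)
  out
}

#' Collapse a probe-level matrix to transcript level
#'
#' Each transcript's value per sample is the arithmetic mean of the values
#' of the probes assigned to it; probes without an assignment are dropped.
#'
#' @param mat probe-level tibble (`probe_id` + sample columns).
#' @param assignments assignment tibble from [assign_probes()] (filtered to
#'   this platform by the caller or carrying a single platform).
#' @return tibble with a `transcript_id` column, a `target_kind` column and
#'   the per-sample means.
#' @export
collapse_to_transcripts <- function(mat, assignments) {
  check_cols(mat, "probe_id")
  check_cols(assignments, c("probe_id", "target_id", "target_kind"))
  sample_cols <- setdiff(names(mat), "probe_id")
  mat |>
    dplyr::inner_join(
      dplyr::select(assignments, "probe_id", "target_id", "target_kind"),
      by = "probe_id", relationship = "many-to-many"
    ) |>
    dplyr::group_by(transcript_id = .data$target_id, .data$target_kind) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(sample_cols), mean),
      .groups = "drop"
    )
}

#' Per-transcript log2 fold change between conditions
#'
#' Values are log2 intensities, so the log2 fold change is the difference of
#' the per-condition means: `mean(stimulated) - mean(unstimulated)`.
#'
#' @param transcript_mat tibble from [collapse_to_transcripts()].
#' @param samples tibble with columns `sample` and `condition`
#'   (`"unstim"` / `"LPS"`).
#' @param dataset_id label recorded in the output.
#' @return a fold-change tibble: `dataset_id`, `transcript_id`,
#'   `target_kind`, `log2fc`, plus attribute `n_listed` (rows per kind are
#'   ranked against the full table length downstream).
#' @export
log2_fold_change <- function(transcript_mat, samples, dataset_id = "dataset") {
  check_cols(transcript_mat, c("transcript_id"))
  check_cols(samples, c("sample", "condition"))
  stim <- samples$sample[samples$condition == "LPS"]
  base <- samples$sample[samples$condition == "unstim"]
  if (length(stim) == 0L || length(base) == 0L) {
    rlang::abort("both conditions need at least one sample")
  }
  kind <- if ("target_kind" %in% names(transcript_mat)) {
    transcript_mat$target_kind
  } else {
    NA_character_
  }
  tibble::tibble(
    dataset_id = dataset_id,
    transcript_id = transcript_mat$transcript_id,
    target_kind = kind,
    log2fc = rowMeans(as.matrix(transcript_mat[stim])) -
      rowMeans(as.matrix(transcript_mat[base]))
  )
}

#' Per-dataset preprocessing in one call
#'
#' [knn_impute()] then [collapse_to_transcripts()] then
#' [log2_fold_change()], the standard route from a raw probe matrix to a
#' fold-change table.
#'
#' @inheritParams knn_impute
#' @inheritParams collapse_to_transcripts
#' @inheritParams log2_fold_change
#' @return see [log2_fold_change()].
#' @export
dataset_fold_changes <- function(mat, assignments, samples,
                                 dataset_id = "dataset", k = 10L) {
  mat |>
    knn_impute(k = k) |>
    collapse_to_transcripts(assignments) |>
    log2_fold_change(samples, dataset_id = dataset_id)
}

#' Pearson consistency between datasets' fold changes
#'
#' Fold-change agreement between every pair of datasets, computed on the
#' transcripts shared by the pair; pairs sharing fewer than `min_shared`
#' transcripts are reported as `NA`.
#'
#' @param fc_tables fold-change tibble covering several datasets
#'   (`dataset_id`, `transcript_id`, `log2fc`).
#' @param min_shared minimum shared transcripts (default 10).
#' @return tibble `dataset_a`, `dataset_b`, `n_shared`, `pearson_r`.
#' @export
fold_change_correlation <- function(fc_tables, min_shared = 10L) {
  check_cols(fc_tables, c("dataset_id", "transcript_id", "log2fc"))
  ids <- unique(fc_tables$dataset_id)
  pairs <- t(utils::combn(ids, 2L))
  purrr::map2(pairs[, 1], pairs[, 2], function(a, b) {
    fa <- dplyr::filter(fc_tables, .data$dataset_id == a)
    fb <- dplyr::filter(fc_tables, .data$dataset_id == b)
    shared <- dplyr::inner_join(fa, fb, by = "transcript_id",
                                suffix = c("_a", "_b"))
    tibble::tibble(
      dataset_a = a, dataset_b = b, n_shared = nrow(shared),
      pearson_r = if (nrow(shared) >= min_shared) {
        stats::cor(shared$log2fc_a, shared$log2fc_b)
      } else {
        NA_real_
      }
    )
  }) |>
    dplyr::bind_rows()
}
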