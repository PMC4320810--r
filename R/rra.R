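# Robust rank aggregation (RRA) of per-dataset fold-change rankings.
#
# Per dataset each transcript gets a normalized rank r = rank/N (rank 1 =
# strongest change in the requested direction). Under the null hypothesis
# that a transcript is unremarkable, its normalized ranks across datasets
# behave like i.i.d. Uniform(0,1) draws. For the sorted ranks r(1) <= ... <=
# r(n), beta_k = P(Binomial(n, r(k)) >= k) asks how surprising it is that at
# least k of n uniform draws fall at or below r(k). The score rho is the
# minimum beta_k over k, and the p-value applies a Bonferroni factor n for
# having minimized over n order statistics.

#' Aggregate fold-change rankings across datasets (robust rank aggregation)
#'
#' @param fc_tables fold-change tibble covering all datasets: columns
#'   `dataset_id`, `transcript_id`, `log2fc` (see [log2_fold_change()]).
#'   Transcripts absent from a dataset are simply missing rows; each
#'   dataset's ranks are normalized by that dataset's own list length.
#' @param direction `"up"` ranks the most LPS-induced transcript first
#'   (descending log2fc), `"down"` the most repressed (ascending).
#' @param bonferroni_both_directions if `TRUE` the Bonferroni factor `m` is
#'   doubled to account for testing both directions (default `FALSE`: `m` =
#'   transcripts tested in this direction).
#' @return An `rra_result` tibble, sorted by adjusted p-value (this ordering
#'   is the aggregated-rank, "AR score", ranking): columns `transcript_id`,
#'   `direction`, `n_datasets`, `rho`, `p`, `p_adj`, and a list-column
#'   `normalized_ranks` (sorted ascending). Ties in `log2fc` get average
#'   ranks.
#' @examples
#' fc <- tibble::tibble(
#'   dataset_id = rep(c("d1", "d2"), each = 2),
#'   transcript_id = rep(c("a", "b"), 2),
#'   log2fc = c(2, 0.5, 1.5, 0.1)
#' )
#' rra_aggregate(fc, "up")
#' @export
rra_aggregate <- function(fc_tables, direction = c("up", "down"),
                          bonferroni_both_directions = FALSE) {
  direction <- match.arg(direction)
  check_cols(fc_tables, c("dataset_id", "transcript_id", "log2fc"))
  ranked <- fc_tables |>
    dplyr::group_by(.data$dataset_id) |>
    dplyr::mutate(
      r = if (direction == "up") {
        rank(-.data$log2fc, ties.method = "average") / dplyr::n()
      } else {
        rank(.data$log2fc, ties.method = "average") / dplyr::n()
      }
    ) |>
    dplyr::ungroup()
  res <- ranked |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      n_datasets = dplyr::n(),
      normalized_ranks = list(sort(.data$r)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rho = purrr::map_dbl(.data$normalized_ranks, rho_score),
      p = pmin(1, .data$rho * .data$n_datasets),
      direction = direction
    )
  m <- nrow(res) * (1L + bonferroni_both_directions)
  res <- res |>
    dplyr::mutate(p_adj = pmin(1, .data$p * m)) |>
    dplyr::arrange(.data$p_adj, .data$p, .data$rho) |>
    dplyr::select("transcript_id", "direction", "n_datasets", "rho", "p",
                  "p_adj", "normalized_ranks")
  attr(res, "m") <- m
  attr(res, "n_datasets_total") <- dplyr::n_distinct(fc_tables$dataset_id)
  class(res) <- c("rra_result", class(res))
  res
}

# rho for one sorted vector of normalized ranks: min over k of
# P(Binomial(n, r_k) >= k), via the stable binomial survival function.
rho_score <- function(r) {
  n <- length(r)
  k <- seq_len(n)
  min(stats::pbinom(k - 1, n, r, lower.tail = FALSE))
}

#' Call significantly regulated transcripts from both RRA directions
#'
#' Transcripts with Bonferroni-adjusted p-value strictly below `alpha` in a
#' direction are called regulated in that direction. A transcript
#' significant in both directions (pathological under any sane input) is
#' assigned to the direction with the smaller adjusted p-value, with a
#' warning.
#'
#' @param up,down `rra_result` tibbles from [rra_aggregate()] run with
#'   `direction = "up"` and `"down"`.
#' @param alpha significance cutoff on the adjusted p-value (default 0.05,
#'   strict `<`).
#' @return list with elements `up` and `down`, each the subset of the
#'   corresponding input.
#' @export
call_regulated <- function(up, down, alpha = 0.05) {
  stopifnot(inherits(up, "rra_result"), inherits(down, "rra_result"))
  sig_up <- dplyr::filter(tibble::as_tibble(up), .data$p_adj < alpha)
  sig_down <- dplyr::filter(tibble::as_tibble(down), .data$p_adj < alpha)
  both <- intersect(sig_up$transcript_id, sig_down$transcript_id)
  if (length(both) > 0L) {
    rlang::warn(sprintf(
      "%d transcript(s) significant in both directions; assigned to the smaller p_adj",
      length(both)
    ))
    for (id in both) {
      pu <- sig_up$p_adj[sig_up$transcript_id == id]
      pd <- sig_down$p_adj[sig_down$transcript_id == id]
      if (pu <= pd) {
        sig_down <- dplyr::filter(sig_down, .data$transcript_id != id)
      } else {
        sig_up <- dplyr::filter(sig_up, .data$transcript_id != id)
      }
    }
  }
  list(up = sig_up, down = sig_down)
}

#' @export
tidy.rra_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("transcript_id", "direction", "n_datasets", "rho", "p",
                  "p_adj") |>
    dplyr::mutate(ar_score = .data$p)
}

#' @export
glance.rra_result <- function(x, ...) {
  tibble::tibble(
    n_transcripts = nrow(x),
    n_datasets = attr(x, "n_datasets_total") %||% max(x$n_datasets),
    direction = x$direction[1] %||% NA_character_,
    bonferroni_m = attr(x, "m"),
    n_significant_0.05 = sum(x$p_adj < 0.05)
  )
}

#' Waterfall plot of aggregated rank scores
#'
#' Plots the signed log10 AR score (`-log10(p)` for the up direction,
#' `+log10(p)` for down) for the top transcripts, the usual convention for
#' annotating aggregated-rank heatmaps.
#'
#' @param object an `rra_result`.
#' @param n_top number of transcripts shown (default 30).
#' @param alpha cutoff drawn as a reference line (Bonferroni-adjusted).
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.rra_result <- function(object, n_top = 30, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::slice(seq_len(min(n_top, nrow(object)))) |>
    dplyr::mutate(
      signed_score = ifelse(.data$direction == "up", -1, 1) * log10(.data$p),
      transcript_id = factor(.data$transcript_id,
                             levels = rev(.data$transcript_id)),
      significant = .data$p_adj < alpha
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$transcript_id, y = .data$signed_score,
    fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL,
      y = if (df$direction[1] == "up") "-log10(AR score)" else "log10(AR score)",
      fill = sprintf("p_adj < %.2g", alpha)
    ) +
    ggplot2::theme_minimal()
}
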