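#' A hand-checkable micro-universe
#'
#' A fixture small enough to verify every pipeline stage by hand: a 20 kb
#' single-chromosome genome with one coding gene and two lncRNAs, a
#' three-tag TSS example, a two-dataset fold-change table, and a pair of
#' chromatin density examples. The `expected` element records the
#' hand-computed answers:
#'
#' \itemize{
#'   \item tags at 100, 115, 140 (+ strand) cluster into \{100, 115\} and
#'     \{140\}: the 15 bp gap chains, the 25 bp gap does not;
#'   \item `lncT.bid` sits 800 bp upstream of `GeneT` on the opposite
#'     strand (gap < 1 kb, no overlap): bidirectional; `lncT.int` lies
#'     inside the intron on the same strand: intronic_sense;
#'   \item transcript `a` ranks 1 of 2 in both datasets, so its sorted
#'     normalized ranks are (0.5, 0.5), beta = (0.75, 0.25), rho = 0.25 and
#'     p = min(1, 0.25 x 2) = 0.5; transcript `b` has ranks (1, 1) and
#'     p = 1;
#'   \item me1 = 10 vs me3 = 2 gives ratio > 1: elncRNA; me1 = 2 vs
#'     me3 = 10: plncRNA.
#' }
#'
#' @return list with `annotation`, `tags`, `fc_tables`, `signals` and
#'   `expected`.
#' @export
worked_toy <- function() {
  annotation <- tibble::tibble(
    transcript_id = c("NM_T1", "lncT.bid", "lncT.int"),
    source = "synthetic",
    chrom = "chrT",
    start = c(10000L, 8000L, 11200L),
    end = c(14000L, 9200L, 11800L),
    strand = c("+", "-", "+"),
    exon_starts = list(c(10000L, 13000L), 8000L, 11200L),
    exon_ends = list(c(11000L, 14000L), 9200L, 11800L),
    biotype = c("coding", "noncoding", "noncoding"),
    gene_symbol = c("GeneT", "lncT.bid", "lncT.int"),
    spliced_length = c(2000L, 1200L, 600L)
  )
  tags <- tibble::tibble(
    chrom = "chrT", pos = c(100L, 115L, 140L), strand = "+"
  )
  fc_tables <- tibble::tibble(
    dataset_id = rep(c("d1", "d2"), each = 2),
    transcript_id = rep(c("a", "b"), 2),
    log2fc = c(2.0, 0.5, 1.5, 0.1)
  )
  signals <- tibble::tibble(
    lnc_id = rep(c("lncT.bid", "lncT.int"), each = 2),
    mark = rep(c("H3K4me1", "H3K4me3"), 2),
    condition = "unstim",
    density = c(10, 2, 2, 10)
  )
  expected <- list(
    clusters = list(c(100L, 115L), 140L),
    position_class = c(lncT.bid = "bidirectional", lncT.int = "intronic_sense"),
    bidirectional_gap = 800L,
    rra = tibble::tibble(
      transcript_id = c("a", "b"),
      rho = c(0.25, 1),
      p = c(0.5, 1)
    ),
    chromatin_class = c(lncT.bid = "elncRNA", lncT.int = "plncRNA")
  )
  list(annotation = annotation, tags = tags, fc_tables = fc_tables,
       signals = signals, expected = expected)
}
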