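mk_region <- function(id, chrom, strand, start, end, count = 50L) {
  tibble::tibble(region_id = id, chrom = chrom, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 tag_count = as.integer(count), n_clusters = 1L)
}

test_that("TSS association is windowed, strand-aware and flank-monotone", {
  lnc <- annot_row("NR_l", "chr1", 100000, 102000, "+", "noncoding")
  regions <- dplyr::bind_rows(
    mk_region("near_up", "chr1", "+", 90000, 90020),    # 10 kb upstream
    mk_region("far_up", "chr1", "+", 64900, 64920),     # 35 kb upstream
    mk_region("anti", "chr1", "-", 100000, 100020),     # opposite strand
    mk_region("inside", "chr1", "+", 100500, 100520)
  )
  got <- associate_tss(lnc, regions, flank = 30000L)
  expect_setequal(got$region_id, c("near_up", "inside"))
  loose <- associate_tss(lnc, regions, flank = 30000L, same_strand = FALSE)
  expect_true("anti" %in% loose$region_id)
  # enlarging the flank never loses associations
  for (fl in c(0L, 5000L, 40000L)) {
    sub <- associate_tss(lnc, regions, flank = fl)
    sup <- associate_tss(lnc, regions, flank = fl + 10000L)
    expect_true(all(sub$region_id %in% sup$region_id))
  }
})

test_that("chromatin filter needs a peak of H3K4me3, H3K4me1 or PolII", {
  assoc <- dplyr::bind_rows(
    mk_region("r_me3", "chr1", "+", 1000, 1020),
    mk_region("r_naked", "chr1", "+", 5000, 5020),
    mk_region("r_k27", "chr1", "+", 9000, 9020)
  ) |>
    dplyr::mutate(transcript_id = "NR_x")
  peaks <- tibble::tibble(
    mark = c("H3K4me3", "H3K27Ac"), condition = "unstim", chrom = "chr1",
    start = c(900L, 8900L), end = c(1100L, 9100L)
  )
  expect_warning(kept <- filter_by_chromatin(assoc, peaks), "PolII")
  expect_equal(kept$region_id, "r_me3")
  # a window rescues a peak that narrowly misses
  peaks2 <- tibble::tibble(mark = "PolII", condition = "LPS", chrom = "chr1",
                           start = 5050L, end = 5200L)
  expect_equal(
    suppressWarnings(filter_by_chromatin(assoc, peaks2, window = 50L))$region_id,
    "r_naked"
  )
  expect_error(
    filter_by_chromatin(assoc, peaks, missing_mark = "abort"), "PolII"
  )
})

test_that("ambiguous TSS regions near coding TSSs are excluded", {
  coding <- annot_row("NM_g", "chr1", 50000, 60000, "+", "coding")
  assoc <- dplyr::bind_rows(
    mk_region("clash", "chr1", "+", 49800, 49820),   # inside TSS +- 500
    mk_region("edge", "chr1", "+", 50520, 50540),    # just outside
    mk_region("clean", "chr1", "+", 80000, 80020)
  ) |>
    dplyr::mutate(transcript_id = c("NR_a", "NR_a", "NR_b"))
  kept <- exclude_ambiguous_tss(assoc, coding, ambiguity_window = 500L)
  expect_setequal(kept$region_id, c("edge", "clean"))
  # the minus-strand coding TSS is at end - 1
  coding_m <- annot_row("NM_m", "chr1", 50000, 60000, "-", "coding")
  kept_m <- exclude_ambiguous_tss(
    mk_region("at3prime", "chr1", "+", 59900, 59920) |>
      dplyr::mutate(transcript_id = "NR_c"),
    coding_m
  )
  expect_equal(nrow(kept_m), 0L)
})

test_that("positional classification follows the five-class rule table", {
  gene <- annot_row("NM_g", "chr1", 100000, 120000, "+", "coding",
                    gene = "GeneG",
                    exon_starts = c(100000, 110000),
                    exon_ends = c(101000, 120000))
  mk_lnc <- function(id, start, end, strand) {
    annot_row(id, "chr1", start, end, strand, "noncoding")
  }
  cases <- dplyr::bind_rows(
    mk_lnc("in_intron", 103000, 105000, "+"),
    mk_lnc("on_exon", 100500, 102000, "+"),
    mk_lnc("anti", 103000, 105000, "-"),
    mk_lnc("bid", 98500, 99200, "-"),      # gap 800, opposite strand
    mk_lnc("same_near", 98500, 99200, "+"),  # gap 800 but same strand
    mk_lnc("far", 90000, 95000, "-")       # gap 5 kb
  )
  got <- classify_position(cases, gene)
  expect_equal(
    got$position_class,
    c("intronic_sense", "exonic_sense", "antisense", "bidirectional",
      "intergenic", "intergenic")
  )
  expect_equal(got$neighbor_gene, rep("GeneG", 6))
  expect_equal(got$neighbor_distance[got$transcript_id == "bid"], 800)
  # no coding gene on the chromosome
  lost <- classify_position(mk_lnc("alone", 0, 2000, "+"),
                            gene |> dplyr::mutate(chrom = "chr9"))
  expect_equal(lost$position_class, "intergenic")
  expect_equal(lost$neighbor_distance, Inf)
})

test_that("classification agrees with the brute-force rule table on random layouts", {
  set.seed(21)
  for (rep in 1:300) {
    n_genes <- sample(1:4, 1)
    genes <- purrr::map(seq_len(n_genes), function(i) {
      s <- sample(0:80000, 1)
      w <- sample(2000:15000, 1)
      n_ex <- sample(1:3, 1)
      bounds <- sort(sample(seq(s, s + w, by = 50), 2 * n_ex))
      annot_row(sprintf("NM_%d", i), "chr1", s, s + w,
                sample(c("+", "-"), 1), "coding", gene = sprintf("G%d", i),
                exon_starts = bounds[seq(1, 2 * n_ex, 2)],
                exon_ends = bounds[seq(2, 2 * n_ex, 2)])
    }) |> dplyr::bind_rows()
    s <- sample(0:80000, 1)
    lnc <- annot_row("NR_x", "chr1", s, s + sample(300:4000, 1),
                     sample(c("+", "-"), 1), "noncoding")
    got <- classify_position(lnc, genes)$position_class
    gl <- coding_gene_loci(genes)
    want <- oracle_classify(lnc$start, lnc$end, lnc$strand,
                            lnc$exon_starts[[1]], lnc$exon_ends[[1]], gl)
    expect_equal(got, want)
  }
})

test_that("naming uses the neighbor symbol with numeric collision suffixes", {
  catalog <- tibble::tibble(
    transcript_id = c("l1", "l2", "l3", "l4"),
    neighbor_gene = c("Nfkb2", "Rel", "Rel", NA)
  )
  named <- name_lncrnas(catalog)
  expect_equal(named$display_name,
               c("lncRNA-Nfkb2", "lncRNA-Rel", "lncRNA-Rel-2", "l4"))
})

test_that("build_catalog keeps only TSS-validated lncRNAs and reports the funnel", {
  coding <- annot_row("NM_g", "chr1", 200000, 220000, "+", "coding",
                      gene = "GeneG")
  lnc <- dplyr::bind_rows(
    annot_row("NR_good", "chr1", 100000, 102000, "+", "noncoding"),
    annot_row("NR_no_tss", "chr1", 500000, 502000, "+", "noncoding"),
    annot_row("NR_ambig", "chr1", 199000, 199700, "+", "noncoding")
  )
  regions <- dplyr::bind_rows(
    mk_region("r1", "chr1", "+", 99990, 100011, count = 40L),
    mk_region("r2", "chr1", "+", 199790, 199811, count = 30L) # at coding TSS
  )
  peaks <- tibble::tibble(
    mark = "H3K4me3", condition = "unstim", chrom = "chr1",
    start = c(99500L, 199500L), end = c(100500L, 200500L)
  )
  expect_warning(cat <- build_catalog(lnc, coding, regions, peaks),
                 "skipped in the chromatin filter")
  expect_equal(cat$lnc_id, "NR_good")
  expect_equal(cat$primary_tss, 100000L)
  funnel <- attr(cat, "funnel")
  expect_equal(funnel$n, c(3L, 2L, 2L, 1L))
  expect_true(all(diff(funnel$n) <= 0))
})
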