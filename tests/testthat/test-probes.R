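probe_row <- function(id, chrom, start, end, strand, platform = "p1") {
  tibble::tibble(probe_id = id, platform = platform, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand)
}

test_that("probes assign to unique genes and ambiguous probes are dropped", {
  annots <- dplyr::bind_rows(
    annot_row("NR_a", "chr1", 1000, 2000, "+", "noncoding", gene = "lncA"),
    annot_row("NR_b", "chr1", 1900, 3000, "+", "noncoding", gene = "lncB"),
    annot_row("NM_c", "chr1", 10000, 20000, "-", "coding", gene = "GeneC",
              exon_starts = c(10000, 19000), exon_ends = c(11000, 20000))
  )
  probes <- dplyr::bind_rows(
    probe_row("inside_one", "chr1", 1200, 1250, "+"),
    probe_row("two_lnc", "chr1", 1950, 1990, "+"),   # exons of lncA and lncB
    probe_row("coding_intron", "chr1", 15000, 15050, "-"), # intron only
    probe_row("coding_exon", "chr1", 10100, 10150, "-"),
    probe_row("wrong_strand", "chr1", 1200, 1250, "-"),
    probe_row("other_chrom", "chr9", 100, 150, "+")
  )
  out <- assign_probes(probes, annots)
  expect_equal(out$target_id[out$probe_id == "inside_one"], "NR_a")
  expect_false("two_lnc" %in% out$probe_id)
  expect_false("coding_intron" %in% out$probe_id)
  expect_equal(out$target_kind[out$probe_id == "coding_exon"], "coding")
  expect_false("wrong_strand" %in% out$probe_id)
  expect_false("other_chrom" %in% out$probe_id)
  # strand-agnostic mode is a superset of strand-aware
  loose <- assign_probes(probes, annots, require_same_strand = FALSE)
  expect_true(all(
    paste(out$probe_id, out$target_kind) %in%
      paste(loose$probe_id, loose$target_kind)
  ))
  expect_true("wrong_strand" %in% loose$probe_id)
})

test_that("two isoforms of one gene do not make a probe ambiguous", {
  annots <- dplyr::bind_rows(
    annot_row("NR_iso1", "chr1", 1000, 3000, "+", "noncoding", gene = "lncA"),
    annot_row("NR_iso2", "chr1", 1000, 3000, "+", "noncoding", gene = "lncA",
              exon_starts = c(1000, 2500), exon_ends = c(2000, 3000))
  )
  out <- assign_probes(probe_row("p", "chr1", 1100, 1160, "+"), annots)
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene_symbol, "lncA")
})

test_that("assignment matches a brute-force all-pairs scan on random instances", {
  set.seed(11)
  for (rep in 1:5) {
    n_tx <- 40L
    annots <- purrr::map(seq_len(n_tx), function(i) {
      s <- sample(0:50000, 1)
      annot_row(sprintf("NR_%03d", i), sample(c("chr1", "chr2"), 1),
                s, s + sample(200:2000, 1),
                sample(c("+", "-"), 1), "noncoding",
                gene = sprintf("g%03d", i))
    }) |> dplyr::bind_rows()
    probes <- purrr::map(1:120, function(i) {
      s <- sample(0:51000, 1)
      probe_row(sprintf("pr%03d", i), sample(c("chr1", "chr2"), 1),
                s, s + 50, sample(c("+", "-"), 1))
    }) |> dplyr::bind_rows()
    got <- assign_probes(probes, annots, min_lnc_length = 200L)
    # naive oracle: count distinct genes each probe's interval hits
    expected <- purrr::map(seq_len(nrow(probes)), function(i) {
      hit <- purrr::map_lgl(seq_len(n_tx), function(j) {
        annots$chrom[j] == probes$chrom[i] &&
          annots$strand[j] == probes$strand[i] &&
          annots$start[j] < probes$end[i] && annots$end[j] > probes$start[i]
      })
      genes <- unique(annots$gene_symbol[hit])
      if (length(genes) == 1L) {
        tibble::tibble(probe_id = probes$probe_id[i], gene_symbol = genes)
      }
    }) |> dplyr::bind_rows()
    expect_setequal(paste(got$probe_id, got$gene_symbol),
                    paste(expected$probe_id, expected$gene_symbol))
  }
})

test_that("reannotation summary counts are consistent with the assignments", {
  assignments <- tibble::tibble(
    probe_id = c("a", "b", "c", "d"),
    platform = c("p1", "p1", "p2", "p1"),
    target_id = c("NR_1", "NR_2", "NR_1", "NM_9"),
    target_kind = c("lncRNA", "lncRNA", "lncRNA", "coding"),
    gene_symbol = c("l1", "l2", "l1", "G9")
  )
  s <- summarize_reannotation(assignments)
  expect_equal(s$n_lncrna_probes[s$platform == "p1"], 2L)
  expect_equal(s$n_coding_probes[s$platform == "p1"], 1L)
  # NR_1 seen on both platforms counts once in the union row
  expect_equal(s$n_unique_lncrnas[s$platform == "all"], 2L)
  expect_equal(sum(s$n_lncrna_probes[s$platform != "all"]),
               s$n_lncrna_probes[s$platform == "all"])
})
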