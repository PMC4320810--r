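test_that("nearest neighbor prefers longest overlap, then smallest gap", {
  genes <- dplyr::bind_rows(
    annot_row("NM_a", "chr1", 1000, 5000, "+", "coding", gene = "A"),
    annot_row("NM_b", "chr1", 4500, 9000, "+", "coding", gene = "B"),
    annot_row("NM_c", "chr1", 20000, 25000, "-", "coding", gene = "C")
  )
  lnc <- dplyr::bind_rows(
    annot_row("inside", "chr1", 2000, 2500, "+", "noncoding"),
    # overlaps A by 400 and B by 800
    annot_row("two_ov", "chr1", 4600, 5400, "+", "noncoding"),
    # gaps: 1000 to B's end, 10000 to C
    annot_row("gapped", "chr1", 10000, 10500, "+", "noncoding"),
    annot_row("far_side", "chr1", 26200, 27000, "+", "noncoding")
  )
  nb <- nearest_neighbor(lnc, genes)
  expect_equal(nb$gene_symbol,
               c("A", "B", "B", "C"))
  expect_equal(nb$distance, c(0, 0, 1000, 1200))
  expect_equal(nb$overlap_bp[2], 800L)
})

test_that("nearest neighbor agrees with an exhaustive scan on random layouts", {
  set.seed(51)
  for (rep in 1:20) {
    genes <- purrr::map(1:30, function(i) {
      s <- sample(0:2e5, 1)
      annot_row(sprintf("NM_%d", i), "chr1", s, s + sample(1000:9000, 1),
                sample(c("+", "-"), 1), "coding", gene = sprintf("G%d", i))
    }) |> dplyr::bind_rows()
    s <- sample(0:2e5, 1)
    lnc <- annot_row("NR_q", "chr1", s, s + 1500, "+", "noncoding")
    nb <- nearest_neighbor(lnc, genes)
    gl <- coding_gene_loci(genes)
    ov <- pmax(0, pmin(lnc$end, gl$end) - pmax(lnc$start, gl$start))
    if (any(ov > 0)) {
      cand <- which(ov == max(ov))
      expect_equal(nb$gene_symbol,
                   gl$gene_symbol[cand[which.min(gl$start[cand])]])
      expect_equal(nb$distance, 0)
    } else {
      gap <- pmax(0, pmax(lnc$start, gl$start) - pmin(lnc$end, gl$end))
      expect_equal(nb$distance, min(gap))
    }
  }
})

test_that("co-expressed neighbors shift the KS distribution; permuted ones do not", {
  set.seed(53)
  n <- 50
  all_gene_fc <- rnorm(2000)
  lnc_fc <- rnorm(n, 2, 1)
  pairs <- tibble::tibble(
    lnc_id = paste0("l", 1:n),
    gene_symbol = paste0("G", 1:n),
    distance = sample(0:50000, n),
    position_class = "intergenic",
    chromatin_class = rep(c("elncRNA", "plncRNA"), n / 2),
    gene_log2fc = lnc_fc + rnorm(n, 0, 0.3),
    lnc_log2fc = lnc_fc,
    lnc_changed = TRUE
  )
  out <- neighbor_coexpression(pairs, all_gene_fc)
  expect_lt(out$ks$ks_p, 0.05)
  # permuted neighbor fold changes from the null distribution: no shift
  null_pairs <- dplyr::mutate(pairs, gene_log2fc = sample(all_gene_fc, n))
  p_null <- replicate(20, {
    np <- dplyr::mutate(pairs, gene_log2fc = sample(all_gene_fc, n))
    neighbor_coexpression(np, all_gene_fc)$ks$ks_p
  })
  expect_gt(mean(p_null > 0.05), 0.8)
  # identical distance distributions across classes: t statistic is 0
  dvec <- sample(100:5000, n / 2)
  out2 <- neighbor_coexpression(
    dplyr::mutate(pairs,
                  chromatin_class = rep(c("elncRNA", "plncRNA"), each = n / 2),
                  distance = rep(dvec, 2)),
    all_gene_fc
  )
  expect_gt(out2$distance_test$p.value, 0.99)
  # sign concordance under strong planted co-regulation
  expect_gte(sign_concordance(pairs), 0.75)
})

test_that("TF association respects the promoter window and summarizes Venn cells", {
  catalog <- tibble::tibble(
    lnc_id = paste0("l", 1:4), chrom = "chr1",
    primary_tss = c(100000L, 200000L, 300000L, 400000L)
  )
  tf_peaks <- dplyr::bind_rows(
    tibble::tibble(tf = "p65", condition = "LPS", chrom = "chr1",
                   start = 104900L, end = 105100L),   # +5 kb: bound
    tibble::tibble(tf = "p65", condition = "LPS", chrom = "chr1",
                   start = 211900L, end = 212100L),   # +12 kb: not bound
    tibble::tibble(tf = "IRF3", condition = "LPS", chrom = "chr1",
                   start = 99000L, end = 99300L),
    tibble::tibble(tf = "IRF3", condition = "unstim", chrom = "chr1",
                   start = 304000L, end = 304200L)    # wrong condition
  )
  expect_warning(
    out <- associate_tf_peaks(catalog, tf_peaks,
                              core_tfs = c("p65", "IRF3", "JunB", "cJun")),
    "omitted"
  )
  b <- out$binding
  expect_true(b$bound[b$lnc_id == "l1" & b$tf == "p65"])
  expect_false(b$bound[b$lnc_id == "l2" & b$tf == "p65"])
  expect_false(any(b$bound[b$lnc_id == "l3"]))
  expect_equal(out$venn$tf_set, "IRF3,p65")
  expect_equal(out$venn$n, 1L)
  expect_equal(out$n_bound_any, 1L)
  # l1 co-bound by p65 (summit 105000) and IRF3 (summit 99150)
  expect_equal(out$mean_pairwise_summit_distance, 5850)
})

test_that("Venn cells sum to the bound count and windows are monotone", {
  set.seed(57)
  for (rep in 1:20) {
    catalog <- tibble::tibble(
      lnc_id = paste0("l", 1:30), chrom = "chr1",
      primary_tss = sort(sample(seq(5e4, 5e6, by = 100), 30))
    )
    tf_peaks <- purrr::map(c("p65", "IRF3", "JunB", "cJun"), function(tf) {
      n <- sample(10:40, 1)
      s <- sample(seq(0, 5.1e6, by = 50), n)
      tibble::tibble(tf = tf, condition = "LPS", chrom = "chr1",
                     start = s, end = s + 200L)
    }) |> dplyr::bind_rows()
    small <- associate_tf_peaks(catalog, tf_peaks, window = 5000L)
    expect_equal(sum(small$venn$n), small$n_bound_any)
    big <- associate_tf_peaks(catalog, tf_peaks, window = 20000L)
    expect_gte(big$n_bound_any, small$n_bound_any)
    pt <- dplyr::inner_join(small$per_tf, big$per_tf, by = "tf",
                            suffix = c("_s", "_b"))
    expect_true(all(pt$n_bound_b >= pt$n_bound_s))
  }
})

test_that("TF-target expression shift reports per-TF KS results", {
  set.seed(59)
  binding <- tibble::tibble(
    lnc_id = rep(paste0("l", 1:60), 2),
    tf = rep(c("p65", "IRF3"), each = 60),
    bound = c(rep(c(TRUE, FALSE), times = c(20, 40)), rep(FALSE, 60))
  )
  expression <- tibble::tibble(
    lnc_id = paste0("l", 1:60),
    log2fc = c(rnorm(20, 3), rnorm(40))
  )
  out <- tf_target_expression_shift(binding, expression)
  expect_lt(out$ks_p[out$tf == "p65"], 0.05)
  expect_true(is.na(out$ks_p[out$tf == "IRF3"])) # no targets
})
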