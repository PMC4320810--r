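test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_config(seed = 7)
  u1 <- simulate_universe(cfg)
  u2 <- simulate_universe(cfg)
  expect_identical(u1$annotation, u2$annotation)
  expect_identical(u1$tss_reads, u2$tss_reads)
  expect_identical(u1$datasets$matrix, u2$datasets$matrix)
  expect_identical(u1$truth, u2$truth)
  u3 <- simulate_universe(small_config(seed = 8))
  expect_false(identical(u1$tss_reads, u3$tss_reads))
})

test_that("inconsistent configurations are rejected", {
  expect_error(small_config(n_up = 30L, n_down = 30L), "eligible")
  expect_error(simulation_config(n_tf_all_four = 20L, n_tf_unbound = 10L),
               "TF")
  expect_error(small_config(n_datasets = 7L), "multiple")
  expect_error(
    simulation_config(n_lnc = c(exonic_sense = 1L, intronic_sense = 1L)),
    "five"
  )
})

test_that("generated files are format-valid and re-readable by the package readers", {
  u <- simulate_universe(small_config())
  dir <- withr::local_tempdir()
  write_universe(u, dir)
  back <- read_transcripts(file.path(dir, "annotation.bed"))
  expect_equal(nrow(back), nrow(u$annotation))
  expect_setequal(back$transcript_id, u$annotation$transcript_id)
  reads <- read_tss_reads(file.path(dir, "tss_reads.bed"))
  expect_equal(nrow(reads), nrow(u$tss_reads))
  expect_true(all(reads$strand %in% c("+", "-")))
  pr <- read_probes(file.path(dir, "probes_platform1.bed"), "platform1")
  expect_equal(nrow(pr), sum(u$probes$platform == "platform1"))
  cov <- read_bedgraph(file.path(dir, "coverage_H3K4me3_unstim.bedGraph"))
  expect_equal(nrow(cov), nrow(u$chromatin_tracks$coverage[[1]]))
  pk_files <- list.files(dir, "^peaks_", full.names = TRUE)
  expect_gt(length(pk_files), 0)
  pk <- read_peaks(pk_files[1], mark = "m")
  expect_true(all(pk$end > pk$start))
  mat <- readr::read_tsv(file.path(dir, "expression_dataset01.tsv"),
                         show_col_types = FALSE)
  expect_equal(dim(mat), dim(u$datasets$matrix[[1]]))
})

test_that("TSS tags concentrate at the planted start sites", {
  u <- simulate_universe(small_config())
  tags <- extract_tags(u$tss_reads)
  truth <- u$truth$lnc
  validated <- truth[truth$validated, ]
  for (i in seq_len(nrow(validated))) {
    n_near <- sum(tags$chrom == validated$chrom[i] &
                    tags$strand == validated$strand[i] &
                    abs(tags$pos - validated$true_tss[i]) <= 10)
    expect_gte(n_near, 20)
  }
  # decoys have no tag pile-up
  decoys <- truth[!truth$validated, ]
  for (i in seq_len(nrow(decoys))) {
    n_near <- sum(tags$chrom == decoys$chrom[i] &
                    abs(tags$pos - decoys$true_tss[i]) <= 10)
    expect_lte(n_near, 2)
  }
})

test_that("the noiseless limit plants exact per-dataset fold changes", {
  u <- simulate_universe(small_config(noise_sd = 0, missing_cell_rate = 0))
  annots <- u$annotation
  asg <- assign_probes(u$probes, annots)
  d <- u$datasets[1, ]
  fc <- dataset_fold_changes(
    d$matrix[[1]],
    dplyr::filter(asg, platform == d$platform[[1]]),
    d$samples[[1]], dataset_id = d$dataset_id[[1]]
  )
  truth <- u$truth$lnc
  up_ids <- truth$lnc_id[truth$regulation == "up"]
  measured <- fc$log2fc[fc$transcript_id %in% up_ids]
  expect_gt(length(measured), 0)
  expect_equal(measured, rep(2, length(measured)), tolerance = 1e-10)
  null_ids <- truth$lnc_id[truth$regulation == "null"]
  expect_equal(max(abs(fc$log2fc[fc$transcript_id %in% null_ids])), 0,
               tolerance = 1e-10)
})

test_that("every lncRNA stays measurable on at least one platform", {
  u <- simulate_universe(small_config())
  lnc_probe_platforms <- u$probes |>
    dplyr::filter(grepl("^lncR", gsub("^pf[0-9]+_", "", probe_id))) |>
    dplyr::mutate(lnc_id = sub("_\\d+$", "", sub("^pf[0-9]+_", "", probe_id)))
  expect_setequal(unique(lnc_probe_platforms$lnc_id), u$truth$lnc$lnc_id)
})

test_that("the worked toy reproduces its hand-computed answers", {
  toy <- worked_toy()
  cl <- cluster_tags(toy$tags, cluster_gap = 20L)
  expect_equal(cl$positions, toy$expected$clusters)
  cls <- classify_position(
    dplyr::filter(toy$annotation, biotype == "noncoding"),
    coding_transcripts(toy$annotation)
  )
  expect_equal(
    stats::setNames(cls$position_class, cls$transcript_id),
    toy$expected$position_class
  )
  expect_equal(
    cls$neighbor_distance[cls$transcript_id == "lncT.bid"],
    toy$expected$bidirectional_gap
  )
  res <- rra_aggregate(toy$fc_tables, "up") |> tibble::as_tibble()
  got <- dplyr::arrange(res, transcript_id)
  expect_equal(got$rho, toy$expected$rra$rho)
  expect_equal(got$p, toy$expected$rra$p)
  calls <- classify_chromatin(toy$signals)
  expect_equal(
    stats::setNames(calls$chromatin_class, calls$lnc_id)[
      names(toy$expected$chromatin_class)],
    toy$expected$chromatin_class
  )
})
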