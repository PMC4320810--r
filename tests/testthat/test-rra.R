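test_that("rho and p follow the binomial order-statistic definition", {
  # n = 1, r = 0.2: rho = P(Bin(1, .2) >= 1) = 0.2, p = 0.2
  fc1 <- tibble::tibble(dataset_id = "d1",
                        transcript_id = paste0("t", 1:5),
                        log2fc = c(5, 4, 3, 2, 1))
  res1 <- rra_aggregate(fc1, "up")
  top <- res1[res1$transcript_id == "t1", ]
  expect_equal(top$rho, 0.2)
  expect_equal(top$p, 0.2)
  # n = 2, ranks (0.5, 0.5): beta = (0.75, 0.25), rho = 0.25, p = 0.5
  fc2 <- tibble::tibble(
    dataset_id = rep(c("d1", "d2"), each = 2),
    transcript_id = rep(c("a", "b"), 2),
    log2fc = c(2, 0.5, 1.5, 0.1)
  )
  res2 <- rra_aggregate(fc2, "up")
  expect_equal(res2$rho[res2$transcript_id == "a"], 0.25)
  expect_equal(res2$p[res2$transcript_id == "a"], 0.5)
  expect_equal(res2$normalized_ranks[res2$transcript_id == "a"][[1]],
               c(0.5, 0.5))
  # "down" flips the ranking: b is now the consistent top transcript
  res2d <- rra_aggregate(fc2, "down")
  expect_equal(res2d$rho[res2d$transcript_id == "b"], 0.25)
})

test_that("rho matches exact binomial-tail summation to 1e-12", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(1:12, 1)
    r <- sort(runif(n))
    expect_equal(rho_score(r), oracle_rho(r), tolerance = 1e-12)
  }
})

test_that("rho is invariant to dataset order and monotone in single ranks", {
  set.seed(23)
  base_fc <- purrr::map(1:6, function(d) {
    tibble::tibble(dataset_id = paste0("d", d),
                   transcript_id = paste0("t", 1:30),
                   log2fc = rnorm(30))
  })
  res_a <- rra_aggregate(dplyr::bind_rows(base_fc), "up")
  res_b <- rra_aggregate(dplyr::bind_rows(rev(base_fc)), "up")
  expect_equal(
    dplyr::arrange(tibble::as_tibble(res_a), transcript_id)$rho,
    dplyr::arrange(tibble::as_tibble(res_b), transcript_id)$rho
  )
  # improving any one rank never increases rho
  for (i in 1:50) {
    n <- sample(2:12, 1)
    r <- sort(runif(n))
    j <- sample(n, 1)
    r2 <- sort(replace(r, j, r[j] * runif(1)))
    expect_lte(rho_score(r2), rho_score(r) + 1e-12)
  }
})

test_that("the aggregated p-value is conservative under a uniform null", {
  set.seed(29)
  n_tx <- 2000L
  n_ds <- 12L
  p <- vapply(seq_len(n_tx), function(i) {
    r <- sort(runif(n_ds))
    min(1, rho_score(r) * n_ds)
  }, 0)
  expect_lte(mean(p < 0.05), 0.0625)
  expect_gt(mean(p < 0.05), 0) # not degenerate
})

test_that("regulated calls use a strict cutoff and resolve double calls", {
  mk_res <- function(ids, p_adj, direction) {
    structure(
      tibble::tibble(transcript_id = ids, direction = direction,
                     n_datasets = 2L, rho = p_adj / 4, p = p_adj / 2,
                     p_adj = p_adj,
                     normalized_ranks = rep(list(c(0.1, 0.2)), length(ids))),
      class = c("rra_result", class(tibble::tibble())), m = 2
    )
  }
  up <- mk_res(c("a", "b", "c"), c(0.04, 0.05, 0.2), "up")
  down <- mk_res(c("c", "d"), c(0.01, 0.049), "down")
  called <- call_regulated(up, down)
  expect_equal(called$up$transcript_id, "a")     # 0.05 exactly is out
  expect_setequal(called$down$transcript_id, c("c", "d"))
  # a transcript significant both ways goes to the smaller p_adj
  up2 <- mk_res("x", 0.001, "up")
  down2 <- mk_res("x", 0.01, "down")
  expect_warning(both <- call_regulated(up2, down2), "both directions")
  expect_equal(both$up$transcript_id, "x")
  expect_equal(nrow(both$down), 0L)
})

test_that("a consistently top-ranked transcript dominates the AR ordering", {
  set.seed(31)
  fc <- purrr::map(1:8, function(d) {
    tibble::tibble(dataset_id = paste0("d", d),
                   transcript_id = paste0("t", 1:50),
                   log2fc = c(10, rnorm(49)))
  }) |> dplyr::bind_rows()
  res <- rra_aggregate(fc, "up")
  expect_equal(res$transcript_id[1], "t1")
  expect_lt(res$p_adj[1], 1e-6)
})

test_that("tidy, glance and autoplot expose the fit", {
  fc <- tibble::tibble(
    dataset_id = rep(c("d1", "d2"), each = 3),
    transcript_id = rep(c("a", "b", "c"), 2),
    log2fc = c(3, 2, 1, 3, 2, 1)
  )
  res <- rra_aggregate(fc, "up")
  td <- generics::tidy(res)
  expect_named(td, c("transcript_id", "direction", "n_datasets", "rho", "p",
                     "p_adj", "ar_score"))
  gl <- generics::glance(res)
  expect_equal(gl$n_transcripts, 3L)
  expect_equal(gl$bonferroni_m, 3)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
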