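# Shared fixtures and independent oracles. Oracles are deliberately naive
# (quadratic scans, explicit summations) and share no code with the package
# implementation they check.

annot_row <- function(id, chrom, start, end, strand, biotype,
                      gene = id, exon_starts = NULL, exon_ends = NULL,
                      source = "synthetic") {
  if (is.null(exon_starts)) {
    exon_starts <- start
    exon_ends <- end
  }
  spliced <- as.integer(sum(exon_ends - exon_starts))
  tibble::tibble(
    transcript_id = id, source = source, chrom = chrom,
    start = as.integer(start), end = as.integer(end), strand = strand,
    exon_starts = list(as.integer(exon_starts)),
    exon_ends = list(as.integer(exon_ends)),
    biotype = biotype, gene_symbol = gene,
    spliced_length = spliced
  )
}

# O(n^2) pairwise single-linkage clustering of integer positions: two
# positions are linked when within `gap`; clusters are connected components.
oracle_cluster <- function(pos, gap) {
  pos <- sort(pos)
  n <- length(pos)
  if (n == 0L) return(list())
  comp <- seq_len(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) <= gap && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  unname(split(pos, comp))[order(vapply(split(pos, comp), min, 0))]
}

# Exact binomial tail by explicit summation (no pbinom).
oracle_binom_tail <- function(k, n, p) {
  j <- k:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

oracle_rho <- function(r) {
  r <- sort(r)
  n <- length(r)
  min(vapply(seq_len(n), function(k) oracle_binom_tail(k, n, r[k]), 0))
}

# Rule-table positional classification, brute force over all genes.
oracle_classify <- function(lnc_start, lnc_end, lnc_strand,
                            lnc_ex_start, lnc_ex_end, genes, bid_max = 1000) {
  ov <- pmax(0, pmin(lnc_end, genes$end) - pmax(lnc_start, genes$start))
  same_chr <- rep(TRUE, nrow(genes)) # caller pre-filters chromosome
  if (!any(same_chr)) return("intergenic")
  if (any(ov > 0)) {
    cand <- which(ov == max(ov))
    g <- cand[which.min(genes$start[cand])]
    if (lnc_strand != genes$strand[g]) return("antisense")
    ex_ov <- FALSE
    for (a in seq_along(lnc_ex_start)) {
      for (b in seq_along(genes$exon_starts[[g]])) {
        if (lnc_ex_start[a] < genes$exon_ends[[g]][b] &&
            lnc_ex_end[a] > genes$exon_starts[[g]][b]) ex_ov <- TRUE
      }
    }
    return(if (ex_ov) "exonic_sense" else "intronic_sense")
  }
  gap <- pmax(0, pmax(lnc_start, genes$start) - pmin(lnc_end, genes$end))
  cand <- which(gap == min(gap))
  g <- cand[which.min(genes$start[cand])]
  if (lnc_strand != genes$strand[g] && gap[g] < bid_max) "bidirectional" else "intergenic"
}

# The default synthetic universe and its pipeline run are expensive enough
# to share across test files; computed at most once per session.
.fixture_cache <- new.env(parent = emptyenv())

default_universe <- function() {
  if (is.null(.fixture_cache$universe)) {
    .fixture_cache$universe <- simulate_universe(simulation_config(seed = 1))
  }
  .fixture_cache$universe
}

default_run <- function() {
  if (is.null(.fixture_cache$run)) {
    .fixture_cache$run <- suppressWarnings(run_all(default_universe()))
  }
  .fixture_cache$run
}

# a small universe for structural tests where the defaults would be slow
small_config <- function(seed = 42, ...) {
  args <- list(
    seed = seed,
    n_coding_genes = 60L,
    n_lnc = c(exonic_sense = 4L, intronic_sense = 6L, antisense = 10L,
              bidirectional = 8L, intergenic = 20L),
    n_no_tss = 2L, n_overlap_gene_pairs = 2L,
    n_datasets = 6L, n_platforms = 3L,
    n_up = 4L, n_down = 3L,
    n_tf_all_four = 2L, n_tf_unbound = 1L
  )
  do.call(simulation_config, utils::modifyList(args, list(...)))
}
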