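# Synthetic universe with planted truth.
#
# The generator lays out a toy genome in which every downstream claim of the
# pipeline has a known answer: coding genes on a regular grid, one lncRNA of
# a known positional class per host gene, TSS-seq tags concentrated at true
# TSSs over a Poisson background, enhancer-like vs promoter-like histone
# coverage at lncRNA TSSs, twelve expression datasets over three
# pseudo-platforms with planted up/down regulation, and TF peaks planted
# near regulated loci.

#' Simulation configuration
#'
#' Defaults define the standard study conditions: 12 datasets over 3
#' pseudo-platforms, 15 planted up- and 12 down-regulated lncRNAs at log2
#' effect +/-2 with noise sd 0.5, enhancer/promoter H3K4me1:H3K4me3 density
#' ratios of 4:1 and 1:4, TSS tags at rate 3/bp within 10 bp of each true
#' TSS over a 1e-5/bp background, and a 20% per-platform lncRNA dropout to
#' exercise rank aggregation with missing lists.
#'
#' @param seed integer seed; a fixed seed makes the universe byte-identical.
#' @param n_chromosomes,chrom_length genome shape (default 3 x 20 Mb).
#' @param n_coding_genes regular coding genes, split evenly over
#'   chromosomes (default 360).
#' @param n_lnc named integer vector: lncRNAs per positional class.
#' @param n_no_tss extra intergenic decoy candidates with no TSS tags (they
#'   must fall out of the validated catalog).
#' @param n_overlap_gene_pairs same-strand overlapping coding-gene pairs
#'   whose shared exon window hosts the planted ambiguous probes.
#' @param n_platforms,n_datasets,samples_per_condition expression design.
#' @param n_up,n_down,effect_up,effect_down,noise_sd planted regulation.
#' @param probe_length,probes_per_transcript probe design.
#' @param frac_ambiguous fraction of probes per platform planted as
#'   ambiguous (hitting two coding genes).
#' @param platform_dropout fraction of lncRNAs omitted per platform.
#' @param missing_cell_rate fraction of matrix cells set missing.
#' @param tss_tag_rate,background_tag_rate Poisson tag rates per bp.
#' @param frac_elncRNA fraction of lncRNAs planted enhancer-like.
#' @param enhancer_ratio,promoter_ratio,base_density histone coverage:
#'   elncRNA windows get H3K4me1 = `base_density * enhancer_ratio` vs
#'   H3K4me3 = `base_density`; plncRNA the reverse with `promoter_ratio`.
#' @param mark_change_fold LPS fold change of H3K4me3/H3K27Ac/PolII
#'   coverage at regulated lncRNA TSSs (up: x fold, down: / fold).
#' @param library_size nominal reads behind each coverage track.
#' @param n_tf_all_four regulated lncRNAs bound by all four core TFs.
#' @param n_tf_unbound regulated lncRNAs bound by no TF.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    n_chromosomes = 3L, chrom_length = 2e7,
    n_coding_genes = 360L,
    n_lnc = c(exonic_sense = 30L, intronic_sense = 60L, antisense = 150L,
              bidirectional = 100L, intergenic = 220L),
    n_no_tss = 10L,
    n_overlap_gene_pairs = 8L,
    n_platforms = 3L, n_datasets = 12L, samples_per_condition = 3L,
    n_up = 15L, n_down = 12L, effect_up = 2, effect_down = -2,
    noise_sd = 0.5,
    probe_length = 50L, probes_per_transcript = 2L,
    frac_ambiguous = 0.02,
    platform_dropout = 0.2,
    missing_cell_rate = 0.01,
    tss_tag_rate = 3, background_tag_rate = 1e-5,
    frac_elncRNA = 0.37,
    enhancer_ratio = 4, promoter_ratio = 4, base_density = 1,
    mark_change_fold = 3,
    library_size = 1e7,
    n_tf_all_four = 5L, n_tf_unbound = 4L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  required_classes <- c("exonic_sense", "intronic_sense", "antisense",
                        "bidirectional", "intergenic")
  if (!setequal(names(cfg$n_lnc), required_classes)) {
    rlang::abort("n_lnc must name exactly the five positional classes")
  }
  if (any(unlist(cfg[c("n_coding_genes", "n_datasets", "n_platforms",
                       "samples_per_condition")]) <= 0) ||
      any(cfg$n_lnc < 0)) {
    rlang::abort("counts must be positive")
  }
  n_hosted <- sum(cfg$n_lnc[c("exonic_sense", "intronic_sense", "antisense",
                              "bidirectional")])
  if (n_hosted > cfg$n_coding_genes) {
    rlang::abort("need at least one coding gene per hosted (non-intergenic) lncRNA")
  }
  n_eligible <- sum(cfg$n_lnc) - cfg$n_lnc[["exonic_sense"]]
  if (cfg$n_up + cfg$n_down > n_eligible) {
    rlang::abort("more regulated lncRNAs requested than eligible (non-exonic) lncRNAs")
  }
  if (cfg$n_tf_all_four + cfg$n_tf_unbound > cfg$n_up + cfg$n_down) {
    rlang::abort("TF binding plan exceeds the number of regulated lncRNAs")
  }
  genes_per_chrom <- ceiling(cfg$n_coding_genes / cfg$n_chromosomes)
  spacing <- floor((cfg$chrom_length - 1e6) / genes_per_chrom)
  if (spacing < 120000) {
    rlang::abort("gene slots closer than 120 kb; enlarge chrom_length or reduce n_coding_genes")
  }
  if (cfg$n_datasets %% cfg$n_platforms != 0L) {
    rlang::abort("n_datasets must be a multiple of n_platforms")
  }
  invisible(cfg)
}

#' Generate the synthetic universe
#'
#' @param cfg a `sim_config` from [simulation_config()].
#' @return a `lnc_universe` list with elements `annotation` (annotation
#'   tibble of coding genes and lncRNA candidates), `tss_reads` (BED6-style
#'   read tibble), `chromatin_peaks`, `chromatin_tracks` (one row per
#'   mark/condition with a bedGraph list-column and `library_size`),
#'   `tf_peaks`, `probes` (all platforms), `datasets` (one row per dataset:
#'   `dataset_id`, `platform`, list-columns `matrix` and `samples`),
#'   `truth` (list of `lnc`, `genes`, `tf` truth tibbles) and `config`.
#' @export
simulate_universe <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_config(cfg)
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))

  ## ---- coding gene grid ----
  genes_per_chrom <- ceiling(cfg$n_coding_genes / cfg$n_chromosomes)
  spacing <- floor((cfg$chrom_length - 1e6) / genes_per_chrom)
  g_idx <- seq_len(cfg$n_coding_genes)
  genes <- tibble::tibble(
    gene_i = g_idx,
    chrom = chroms[((g_idx - 1L) %/% genes_per_chrom) + 1L],
    slot = ((g_idx - 1L) %% genes_per_chrom),
    start = as.integer(1e5 + ((g_idx - 1L) %% genes_per_chrom) * spacing),
    strand = ifelse(g_idx %% 2L == 1L, "+", "-")
  ) |>
    dplyr::mutate(
      end = .data$start + 20000L,
      transcript_id = sprintf("NM_%04d", .data$gene_i),
      gene_symbol = sprintf("Gene%04d", .data$gene_i)
    )
  coding <- genes |>
    dplyr::mutate(
      source = "synthetic",
      exon_starts = purrr::map(.data$start, ~ .x + c(0L, 6000L, 12000L, 19000L)),
      exon_ends = purrr::map(.data$start, ~ .x + c(1000L, 7000L, 13000L, 20000L)),
      biotype = "coding",
      spliced_length = 4000L
    )

  ## ---- overlapping coding-gene pairs (ambiguity substrate) ----
  pair_rows <- list()
  if (cfg$n_overlap_gene_pairs > 0L) {
    per_chrom <- ceiling(cfg$n_overlap_gene_pairs / cfg$n_chromosomes)
    pair_i <- seq_len(cfg$n_overlap_gene_pairs)
    base_start <- as.integer(1e5 + genes_per_chrom * spacing + 10000)
    pchrom <- chroms[((pair_i - 1L) %/% per_chrom) + 1L]
    pstart <- base_start + ((pair_i - 1L) %% per_chrom) * 50000L
    if (any(pstart + 20000L > cfg$chrom_length)) {
      rlang::abort("no room for overlap gene pairs; enlarge chrom_length")
    }
    mk <- function(id, sym, chrom, s, e) {
      tibble::tibble(
        transcript_id = id, source = "synthetic", chrom = chrom,
        start = s, end = e, strand = "+",
        exon_starts = list(s), exon_ends = list(e),
        biotype = "coding", gene_symbol = sym, spliced_length = e - s
      )
    }
    pair_rows <- purrr::map(pair_i, function(i) {
      s <- pstart[i]
      dplyr::bind_rows(
        mk(sprintf("NM_A%03d", i), sprintf("GeneOvlA%03d", i), pchrom[i],
           s, s + 10000L),
        mk(sprintf("NM_B%03d", i), sprintf("GeneOvlB%03d", i), pchrom[i],
           s + 9500L, s + 19500L)
      )
    })
  }
  coding_annot <- dplyr::bind_rows(
    coding |>
      dplyr::select("transcript_id", "source", "chrom", "start", "end",
                    "strand", "exon_starts", "exon_ends", "biotype",
                    "gene_symbol", "spliced_length"),
    dplyr::bind_rows(pair_rows)
  )

  ## ---- lncRNA placement ----
  n_hosted <- sum(cfg$n_lnc[c("exonic_sense", "intronic_sense", "antisense",
                              "bidirectional")])
  host_genes <- sample(g_idx, n_hosted) # which gene hosts which lncRNA
  hosted_class <- rep(
    c("exonic_sense", "intronic_sense", "antisense", "bidirectional"),
    times = cfg$n_lnc[c("exonic_sense", "intronic_sense", "antisense",
                        "bidirectional")]
  )
  place_hosted <- function(class, g) {
    G <- genes$start[g]
    st <- genes$strand[g]
    anti <- flip_strand(st)
    switch(class,
      exonic_sense = list(start = G + 6200L, end = G + 6800L, strand = st),
      intronic_sense = list(start = G + 2000L, end = G + 4500L, strand = st),
      antisense = list(start = G + 8000L, end = G + 11000L, strand = anti),
      bidirectional = {
        gap <- sample(600:900, 1L)
        L <- 1500L
        if (st == "+") {
          list(start = G - gap - L, end = G - gap, strand = anti)
        } else {
          list(start = G + 20000L + gap, end = G + 20000L + gap + L,
               strand = anti)
        }
      }
    )
  }
  hosted <- purrr::map2(hosted_class, host_genes, function(cl, g) {
    p <- place_hosted(cl, g)
    tibble::tibble(
      position_class = cl, host_gene = g, chrom = genes$chrom[g],
      start = as.integer(p$start), end = as.integer(p$end), strand = p$strand
    )
  }) |>
    dplyr::bind_rows()
  n_inter <- cfg$n_lnc[["intergenic"]] + cfg$n_no_tss
  if (n_inter > cfg$n_coding_genes) {
    rlang::abort("too many intergenic lncRNAs for the gene grid")
  }
  inter_slots <- sample(g_idx, n_inter)
  # the slot gene is the intergenic lncRNA's nearest gene (gap ~ spacing/2)
  intergenic <- tibble::tibble(
    position_class = "intergenic",
    host_gene = inter_slots,
    chrom = genes$chrom[inter_slots],
    start = as.integer(genes$start[inter_slots] + spacing %/% 2),
    strand = sample(c("+", "-"), n_inter, replace = TRUE)
  ) |>
    dplyr::mutate(end = .data$start + 2000L)
  lnc <- dplyr::bind_rows(hosted, intergenic) |>
    dplyr::mutate(
      lnc_id = sprintf("lncR.%04d", dplyr::row_number()),
      validated = dplyr::row_number() <= (dplyr::n() - cfg$n_no_tss),
      true_tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L)
    )

  ## ---- planted truth: chromatin class and regulation ----
  n_lnc_total <- nrow(lnc)
  n_elnc <- round(cfg$frac_elncRNA * n_lnc_total)
  lnc$chromatin_class <- sample(c(
    rep("elncRNA", n_elnc), rep("plncRNA", n_lnc_total - n_elnc)
  ))
  eligible <- which(lnc$validated & lnc$position_class != "exonic_sense")
  reg_idx <- sample(eligible, cfg$n_up + cfg$n_down)
  lnc$regulation <- "null"
  lnc$regulation[reg_idx[seq_len(cfg$n_up)]] <- "up"
  lnc$regulation[reg_idx[cfg$n_up + seq_len(cfg$n_down)]] <- "down"
  lnc$effect <- dplyr::case_when(
    lnc$regulation == "up" ~ cfg$effect_up,
    lnc$regulation == "down" ~ cfg$effect_down,
    TRUE ~ 0
  )

  lnc_annot <- lnc |>
    dplyr::mutate(
      transcript_id = .data$lnc_id, source = "synthetic",
      exon_starts = purrr::map(.data$start, identity),
      exon_ends = purrr::map(.data$end, identity),
      biotype = "noncoding",
      gene_symbol = .data$lnc_id,
      spliced_length = .data$end - .data$start
    ) |>
    dplyr::select("transcript_id", "source", "chrom", "start", "end",
                  "strand", "exon_starts", "exon_ends", "biotype",
                  "gene_symbol", "spliced_length")
  annotation <- dplyr::bind_rows(coding_annot, lnc_annot) |>
    dplyr::arrange(.data$chrom, .data$start)

  ## ---- TSS-seq reads ----
  true_tss <- dplyr::bind_rows(
    lnc |>
      dplyr::filter(.data$validated) |>
      dplyr::select("chrom", pos = "true_tss", "strand"),
    coding |>
      dplyr::mutate(pos = ifelse(.data$strand == "+", .data$start,
                                 .data$end - 1L)) |>
      dplyr::select("chrom", "pos", "strand")
  )
  tag_pos <- purrr::pmap(true_tss, function(chrom, pos, strand) {
    offs <- -10:10
    counts <- stats::rpois(length(offs), cfg$tss_tag_rate)
    tibble::tibble(chrom = chrom, pos = pos + rep(offs, counts),
                   strand = strand)
  }) |>
    dplyr::bind_rows()
  bg <- purrr::map(chroms, function(ch) {
    purrr::map(c("+", "-"), function(st) {
      n_bg <- stats::rpois(1L, cfg$background_tag_rate * cfg$chrom_length)
      tibble::tibble(
        chrom = ch,
        pos = as.integer(floor(stats::runif(n_bg, 30, cfg$chrom_length - 31))),
        strand = st
      )
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
  tags <- dplyr::bind_rows(tag_pos, bg)
  read_len <- 30L
  tss_reads <- tibble::tibble(
    chrom = tags$chrom,
    start = ifelse(tags$strand == "+", tags$pos, tags$pos - read_len + 1L),
    end = ifelse(tags$strand == "+", tags$pos + read_len, tags$pos + 1L),
    strand = tags$strand
  ) |>
    dplyr::mutate(start = pmax(0L, as.integer(.data$start)),
                  end = as.integer(.data$end)) |>
    dplyr::arrange(.data$chrom, .data$start)

  ## ---- chromatin peaks and coverage ----
  lnc_v <- dplyr::filter(lnc, .data$validated)
  coding_tss <- ifelse(coding$strand == "+", coding$start, coding$end - 1L)
  peak_at <- function(pos, chrom, mark, condition, half = 500L) {
    tibble::tibble(mark = mark, condition = condition, chrom = chrom,
                   start = as.integer(pos - half), end = as.integer(pos + half))
  }
  chromatin_peaks <- purrr::map(c("unstim", "LPS"), function(cond) {
    dplyr::bind_rows(
      # enhancer-like loci carry H3K4me1 peaks, promoter-like H3K4me3;
      # PolII marks every active TSS; coding promoters get H3K4me3 + PolII
      peak_at(lnc_v$true_tss[lnc_v$chromatin_class == "elncRNA"],
              lnc_v$chrom[lnc_v$chromatin_class == "elncRNA"],
              "H3K4me1", cond),
      peak_at(lnc_v$true_tss[lnc_v$chromatin_class == "plncRNA"],
              lnc_v$chrom[lnc_v$chromatin_class == "plncRNA"],
              "H3K4me3", cond),
      peak_at(lnc_v$true_tss, lnc_v$chrom, "PolII", cond),
      peak_at(lnc_v$true_tss, lnc_v$chrom, "H3K27Ac", cond),
      peak_at(coding_tss, coding$chrom, "H3K4me3", cond),
      peak_at(coding_tss, coding$chrom, "PolII", cond)
    )
  }) |>
    dplyr::bind_rows()

  W <- 2000L
  track_value <- function(mark, cond) {
    me1 <- ifelse(lnc_v$chromatin_class == "elncRNA",
                  cfg$base_density * cfg$enhancer_ratio, cfg$base_density)
    me3 <- ifelse(lnc_v$chromatin_class == "plncRNA",
                  cfg$base_density * cfg$promoter_ratio, cfg$base_density)
    v <- switch(mark,
      H3K4me1 = me1, H3K4me3 = me3,
      H3K27Ac = rep(cfg$base_density, nrow(lnc_v)),
      PolII = rep(cfg$base_density, nrow(lnc_v))
    )
    # activity marks move with expression after stimulation; H3K4me1 does not
    if (cond == "LPS" && mark != "H3K4me1") {
      v <- v * ifelse(lnc_v$regulation == "up", cfg$mark_change_fold,
                      ifelse(lnc_v$regulation == "down",
                             1 / cfg$mark_change_fold, 1))
    }
    v
  }
  chromatin_tracks <- tidyr::expand_grid(
    mark = c("H3K4me3", "H3K4me1", "H3K27Ac", "PolII"),
    condition = c("unstim", "LPS")
  ) |>
    dplyr::mutate(
      coverage = purrr::map2(.data$mark, .data$condition, function(mk, cond) {
        tibble::tibble(
          chrom = lnc_v$chrom,
          start = pmax(0L, lnc_v$true_tss - W),
          end = lnc_v$true_tss + W,
          value = track_value(mk, cond)
        ) |>
          dplyr::arrange(.data$chrom, .data$start)
      }),
      library_size = cfg$library_size
    )

  ## ---- transcription factor peaks ----
  core_tfs <- c("p65", "IRF3", "JunB", "cJun")
  reg <- lnc_v |>
    dplyr::filter(.data$regulation != "null") |>
    dplyr::arrange(dplyr::desc(.data$regulation == "up"), .data$lnc_id)
  tf_plan <- matrix(FALSE, nrow(reg), length(core_tfs),
                    dimnames = list(reg$lnc_id, core_tfs))
  all_four <- seq_len(cfg$n_tf_all_four)
  unbound <- nrow(reg) - seq_len(cfg$n_tf_unbound) + 1L
  tf_plan[all_four, ] <- TRUE
  for (i in setdiff(seq_len(nrow(reg)), c(all_four, unbound))) {
    # a random non-empty, non-full subset, so the all-four cell stays planted
    sel <- stats::runif(length(core_tfs)) < 0.5
    if (!any(sel)) sel[sample(length(core_tfs), 1L)] <- TRUE
    if (all(sel)) sel[sample(length(core_tfs), 1L)] <- FALSE
    tf_plan[i, ] <- sel
  }
  null_bound <- sample(lnc_v$lnc_id[lnc_v$regulation == "null"],
                       min(20L, sum(lnc_v$regulation == "null")))
  tf_offsets <- c(p65 = 200L, IRF3 = -400L, JunB = 900L, cJun = -900L,
                  Bcl6 = 500L)
  tf_peak_rows <- function(ids, tf, condition) {
    pos <- lnc_v$true_tss[match(ids, lnc_v$lnc_id)] + tf_offsets[[tf]]
    tibble::tibble(tf = tf, condition = condition,
                   chrom = lnc_v$chrom[match(ids, lnc_v$lnc_id)],
                   start = as.integer(pos - 150L), end = as.integer(pos + 150L))
  }
  tf_peaks <- purrr::map(core_tfs, function(tf) {
    ids <- c(rownames(tf_plan)[tf_plan[, tf]],
             null_bound[seq_along(null_bound) %% length(core_tfs) + 1L ==
                          match(tf, core_tfs)])
    tf_peak_rows(ids, tf, "LPS")
  }) |>
    dplyr::bind_rows()
  # Bcl6: five loci at rest (four of them core-bound), one after stimulation
  bcl6_unstim <- c(reg$lnc_id[seq_len(min(4L, nrow(reg)))],
                   reg$lnc_id[unbound[1]])
  bcl6_lps <- reg$lnc_id[1]
  tf_peaks <- dplyr::bind_rows(
    tf_peaks,
    tf_peak_rows(bcl6_unstim, "Bcl6", "unstim") |>
      dplyr::mutate(tf = "Bcl6"),
    tf_peak_rows(bcl6_lps, "Bcl6", "LPS") |>
      dplyr::mutate(tf = "Bcl6")
  )

  ## ---- probes and expression ----
  expr_tx <- dplyr::bind_rows(
    lnc |>
      dplyr::select(transcript_id = "lnc_id", "chrom", "start", "end",
                    "strand", "effect") |>
      dplyr::mutate(kind = "lncRNA"),
    coding_annot |>
      dplyr::select("transcript_id", "chrom", "start", "end", "strand") |>
      dplyr::mutate(effect = 0, kind = "coding")
  )
  # neighbor genes of regulated lncRNAs co-regulate with them
  nb_gene <- genes$transcript_id[lnc$host_gene]
  for (i in which(lnc$regulation != "null" & !is.na(lnc$host_gene))) {
    j <- match(nb_gene[i], expr_tx$transcript_id)
    expr_tx$effect[j] <- lnc$effect[i] + stats::rnorm(1L, 0, 0.3)
  }
  baseline <- stats::setNames(stats::runif(nrow(expr_tx), 4, 12),
                              expr_tx$transcript_id)
  platform_offset <- stats::rnorm(cfg$n_platforms, 0, 0.3)

  lnc_ids <- lnc$lnc_id
  dropout <- purrr::map(seq_len(cfg$n_platforms), function(p) {
    sample(lnc_ids, round(cfg$platform_dropout * length(lnc_ids)))
  })
  dropped_all <- Reduce(intersect, dropout)
  for (id in dropped_all) { # every lncRNA stays measurable somewhere
    p <- sample(cfg$n_platforms, 1L)
    dropout[[p]] <- setdiff(dropout[[p]], id)
  }

  probes <- purrr::map(seq_len(cfg$n_platforms), function(p) {
    keep <- expr_tx |>
      dplyr::filter(!(.data$transcript_id %in% dropout[[p]]))
    shift <- (p - 1L) * 7L
    reg_probes <- purrr::map(seq_len(cfg$probes_per_transcript), function(i) {
      off <- 10L + shift + (i - 1L) * (cfg$probe_length + 25L)
      tibble::tibble(
        probe_id = sprintf("pf%d_%s_%d", p, keep$transcript_id, i),
        platform = sprintf("platform%d", p),
        chrom = keep$chrom,
        start = as.integer(keep$start + off),
        end = as.integer(keep$start + off + cfg$probe_length),
        strand = keep$strand,
        transcript_id = keep$transcript_id
      )
    }) |>
      dplyr::bind_rows()
    n_amb <- ceiling(cfg$frac_ambiguous * nrow(reg_probes))
    amb <- tibble::tibble()
    if (n_amb > 0L && cfg$n_overlap_gene_pairs > 0L) {
      pairA <- dplyr::filter(coding_annot,
                             grepl("^NM_A", .data$transcript_id))
      slots_per_pair <- max(1L, ceiling(n_amb / nrow(pairA)))
      grid <- tidyr::expand_grid(pair = seq_len(nrow(pairA)),
                                 slot = seq_len(slots_per_pair))[seq_len(n_amb), ]
      ov_start <- pairA$end[grid$pair] - 500L # shared window of the pair
      amb <- tibble::tibble(
        probe_id = sprintf("pf%d_amb_%03d", p, seq_len(n_amb)),
        platform = sprintf("platform%d", p),
        chrom = pairA$chrom[grid$pair],
        start = as.integer(ov_start + (grid$slot - 1L) * 55L),
        end = as.integer(ov_start + (grid$slot - 1L) * 55L + cfg$probe_length),
        strand = "+",
        transcript_id = NA_character_
      )
    }
    dplyr::bind_rows(reg_probes, amb)
  }) |>
    dplyr::bind_rows()

  k <- cfg$samples_per_condition
  sample_tbl <- tibble::tibble(
    sample = c(sprintf("unstim_%d", seq_len(k)), sprintf("LPS_%d", seq_len(k))),
    condition = rep(c("unstim", "LPS"), each = k)
  )
  datasets_per_platform <- cfg$n_datasets %/% cfg$n_platforms
  datasets <- purrr::map(seq_len(cfg$n_datasets), function(d) {
    p <- ((d - 1L) %/% datasets_per_platform) + 1L
    pr <- dplyr::filter(probes, .data$platform == sprintf("platform%d", p))
    base <- ifelse(is.na(pr$transcript_id), stats::runif(nrow(pr), 4, 12),
                   baseline[pr$transcript_id]) + platform_offset[p]
    eff <- ifelse(is.na(pr$transcript_id), 0,
                  expr_tx$effect[match(pr$transcript_id, expr_tx$transcript_id)])
    vals <- vapply(seq_len(nrow(sample_tbl)), function(s) {
      mu <- base + eff * (sample_tbl$condition[s] == "LPS")
      mu + stats::rnorm(nrow(pr), 0, cfg$noise_sd)
    }, numeric(nrow(pr)))
    colnames(vals) <- sample_tbl$sample
    if (cfg$missing_cell_rate > 0) {
      na_mask <- matrix(
        stats::runif(length(vals)) < cfg$missing_cell_rate, nrow(pr)
      )
      # keep at least one observation per probe
      na_mask[rowSums(!na_mask) == 0L, 1L] <- FALSE
      vals[na_mask] <- NA_real_
    }
    tibble::tibble(
      dataset_id = sprintf("dataset%02d", d),
      platform = sprintf("platform%d", p),
      matrix = list(dplyr::bind_cols(
        tibble::tibble(probe_id = pr$probe_id), tibble::as_tibble(vals)
      )),
      samples = list(sample_tbl)
    )
  }) |>
    dplyr::bind_rows()

  truth_lnc <- lnc |>
    dplyr::select("lnc_id", "chrom", "start", "end", "strand", "true_tss",
                  "position_class", "chromatin_class", "regulation",
                  "effect", "validated", "host_gene") |>
    dplyr::mutate(
      neighbor_gene = ifelse(is.na(.data$host_gene), NA_character_,
                             genes$gene_symbol[.data$host_gene])
    ) |>
    dplyr::select(-"host_gene")
  truth_tf <- dplyr::bind_rows(
    tibble::tibble(
      lnc_id = rep(rownames(tf_plan), length(core_tfs)),
      tf = rep(core_tfs, each = nrow(tf_plan)),
      bound = as.vector(tf_plan)
    ),
    tibble::tibble( # background binding at unregulated loci, one TF each
      lnc_id = null_bound,
      tf = core_tfs[seq_along(null_bound) %% length(core_tfs) + 1L],
      bound = TRUE
    )
  )
  truth_genes <- expr_tx |>
    dplyr::filter(.data$kind == "coding") |>
    dplyr::select("transcript_id", "effect")

  structure(
    list(
      annotation = annotation,
      tss_reads = tss_reads,
      chromatin_peaks = chromatin_peaks,
      chromatin_tracks = chromatin_tracks,
      tf_peaks = tf_peaks,
      probes = dplyr::select(probes, -"transcript_id"),
      datasets = datasets,
      truth = list(lnc = truth_lnc, genes = truth_genes, tf = truth_tf),
      config = cfg
    ),
    class = "lnc_universe"
  )
}

#' Write a simulated universe to disk in standard formats
#'
#' Emits the annotation as BED12, probes as BED6 per platform, TSS reads as
#' BED6, chromatin peaks as BED per mark/condition, coverage as bedGraph,
#' TF peaks as BED per TF/condition, expression matrices as TSV with a
#' manifest, and the truth tables as TSV. Everything is re-readable with
#' the package's own readers.
#'
#' @param universe a `lnc_universe`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir) {
  stopifnot(inherits(universe, "lnc_universe"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed12(universe$annotation, file.path(dir, "annotation.bed"))
  for (p in unique(universe$probes$platform)) {
    pr <- dplyr::filter(universe$probes, .data$platform == p)
    gr <- as_granges0(pr)
    gr$name <- pr$probe_id
    rtracklayer::export(gr, file.path(dir, paste0("probes_", p, ".bed")),
                        format = "bed")
  }
  gr <- as_granges0(universe$tss_reads)
  rtracklayer::export(gr, file.path(dir, "tss_reads.bed"), format = "bed")
  pk <- universe$chromatin_peaks
  for (key in unique(paste(pk$mark, pk$condition, sep = "_"))) {
    sub <- pk[paste(pk$mark, pk$condition, sep = "_") == key, ]
    rtracklayer::export(as_granges0(sub, use_strand = FALSE),
                        file.path(dir, paste0("peaks_", key, ".bed")),
                        format = "bed")
  }
  tr <- universe$chromatin_tracks
  for (i in seq_len(nrow(tr))) {
    cov <- tr$coverage[[i]]
    gr <- as_granges0(cov, use_strand = FALSE)
    gr$score <- cov$value
    rtracklayer::export(
      gr, file.path(dir, sprintf("coverage_%s_%s.bedGraph", tr$mark[i],
                                 tr$condition[i])),
      format = "bedGraph"
    )
  }
  tp <- universe$tf_peaks
  for (key in unique(paste(tp$tf, tp$condition, sep = "_"))) {
    sub <- tp[paste(tp$tf, tp$condition, sep = "_") == key, ]
    rtracklayer::export(as_granges0(sub, use_strand = FALSE),
                        file.path(dir, paste0("tf_", key, ".bed")),
                        format = "bed")
  }
  manifest <- universe$datasets |>
    dplyr::mutate(file = sprintf("expression_%s.tsv", .data$dataset_id)) |>
    dplyr::select("dataset_id", "platform", "file")
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  for (i in seq_len(nrow(universe$datasets))) {
    readr::write_tsv(
      universe$datasets$matrix[[i]],
      file.path(dir, sprintf("expression_%s.tsv",
                             universe$datasets$dataset_id[i]))
    )
  }
  readr::write_tsv(universe$datasets$samples[[1]],
                   file.path(dir, "samples.tsv"))
  readr::write_tsv(universe$truth$lnc, file.path(dir, "truth_lnc.tsv"))
  readr::write_tsv(universe$truth$genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(universe$truth$tf, file.path(dir, "truth_tf.tsv"))
  invisible(dir)
}
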