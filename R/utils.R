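# Internal coordinate plumbing.
#
# Every user-facing tibble in probelnc carries 0-based half-open coordinates
# (BED convention: `start` is the first base, `end` one past the last).
# GenomicRanges is 1-based closed, so conversion happens exactly here and in
# the file readers, nowhere else.

# tibble (chrom,start,end[,strand]) -> GRanges
as_granges0 <- function(df, use_strand = TRUE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  strand <- if (use_strand && "strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

# Overlap pairs between two 0-based tibbles; returns tibble of row indices.
overlap_pairs <- function(query, subject, min_overlap = 1L,
                          ignore_strand = TRUE, maxgap = -1L) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(tibble::tibble(query = integer(), subject = integer()))
  }
  if (maxgap > -1L) min_overlap <- 0L # findOverlaps allows only one of the two
  hits <- GenomicRanges::findOverlaps(
    as_granges0(query, use_strand = !ignore_strand),
    as_granges0(subject, use_strand = !ignore_strand),
    minoverlap = min_overlap, maxgap = maxgap,
    ignore.strand = ignore_strand
  )
  tibble::tibble(
    query = S4Vectors::queryHits(hits),
    subject = S4Vectors::subjectHits(hits)
  )
}

# Width of the intersection of [s1,e1) and [s2,e2); 0 when disjoint.
interval_overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Gap in bp between two non-overlapping half-open intervals (0 if they touch
# or overlap).
interval_gap_bp <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

check_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    rlang::abort(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Opposite of a strand vector.
flip_strand <- function(strand) ifelse(strand == "+", "-", "+")
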