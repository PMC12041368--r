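# Interval engine. All intervals in memory are 0-based half-open data.frames
# with columns chrom/start/end (+ optional name, score); GenomicRanges is the
# workhorse behind the surface, with the +1 shift applied in as_gr()/from_gr()
# and nowhere else.

#' Construct a genomic-interval table
#'
#' The unit of all overlap logic: 0-based half-open intervals. `start < end`
#' is enforced (zero-width intervals are rejected).
#'
#' @param chrom chromosome labels.
#' @param start 0-based inclusive start positions.
#' @param end exclusive end positions.
#' @param name optional per-interval labels.
#' @param score optional numeric scores.
#' @return a data.frame with class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(chrom)
  if (length(start) != n || length(end) != n)
    stopf("chrom/start/end lengths differ")
  if (any(!nzchar(chrom))) stopf("empty chromosome label")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stopf("invalid interval at row %d: need 0 <= start < end (got [%s, %s))",
          bad[1], format(start[bad[1]]), format(end[bad[1]]))
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(name)) out$name <- as.character(name)
  if (!is.null(score)) out$score <- as.numeric(score)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = norm_chrom(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
}

from_gr <- function(gr, chrom_map = NULL) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (!is.null(chrom_map)) {
    hit <- match(chrom, norm_chrom(chrom_map))
    chrom <- ifelse(is.na(hit), chrom, chrom_map[hit])
  }
  genomic_intervals(chrom = chrom,
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr))
}

gi_sort <- function(x) {
  x[order(norm_chrom(x$chrom), x$start, x$end), , drop = FALSE]
}

#' Intersect two interval tracks
#'
#' Returns every overlapping fragment with the row indices of its parents.
#' Half-open semantics: abutting intervals do not overlap.
#'
#' @param a,b interval data.frames (chrom/start/end).
#' @return sorted data.frame of fragments with columns `chrom`, `start`,
#'   `end`, `a_index`, `b_index` (and `a_name`/`b_name` when present).
#' @export
gi_intersect <- function(a, b) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), a_index = integer(),
                      b_index = integer(), stringsAsFactors = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  gra <- as_gr(a)
  grb <- as_gr(b)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gra, grb))
  if (length(ov) == 0) return(empty)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  frag <- IRanges::pintersect(IRanges::ranges(gra)[qi],
                              IRanges::ranges(grb)[si])
  out <- data.frame(chrom = a$chrom[qi],
                    start = IRanges::start(frag) - 1,
                    end = IRanges::end(frag),
                    a_index = qi, b_index = si,
                    stringsAsFactors = FALSE)
  if (!is.null(a$name)) out$a_name <- a$name[qi]
  if (!is.null(b$name)) out$b_name <- b$name[si]
  rownames(out) <- NULL
  out <- out[order(norm_chrom(out$chrom), out$start, out$end,
                   out$a_index, out$b_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge overlapping or abutting intervals
#'
#' @param x interval data.frame.
#' @return sorted data.frame of disjoint merged intervals.
#' @export
gi_merge <- function(x) {
  if (nrow(x) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  red <- GenomicRanges::reduce(as_gr(x))
  out <- from_gr(red, chrom_map = unique(x$chrom))
  out <- gi_sort(out)
  rownames(out) <- NULL
  as.data.frame(out)
}

gi_width <- function(x) sum(x$end - x$start)

#' Fraction of each target interval covered by a track
#'
#' Covering intervals are merged first, so stacked coverage never counts a
#' base twice and abutting pieces cover seamlessly.
#'
#' @param targets interval data.frame whose rows are scored.
#' @param by covering interval data.frame.
#' @return numeric vector in \[0,1\], one value per row of `targets`.
#' @export
gi_coverage_fraction <- function(targets, by) {
  if (nrow(targets) == 0) return(numeric())
  covered <- numeric(nrow(targets))
  if (nrow(by) > 0) {
    frag <- gi_intersect(targets, gi_merge(by))
    if (nrow(frag) > 0) {
      bp <- tapply(frag$end - frag$start, frag$a_index, sum)
      covered[as.integer(names(bp))] <- as.numeric(bp)
    }
  }
  covered / (targets$end - targets$start)
}

#' Percentage of significant elements among annotated elements
#'
#' Reported to two decimals, matching the field's reporting convention
#' (e.g. 1 of 6 coding elements -> 16.67). An empty denominator yields
#' `NA` (undefined), never 0.
#'
#' @param n_significant,n_total non-negative counts, `n_significant <= n_total`.
#' @return numeric percentage(s) rounded to 2 decimals; `NA` where
#'   `n_total == 0`.
#' @export
enrichment_percent <- function(n_significant, n_total) {
  if (any(n_significant < 0) || any(n_total < 0))
    stopf("counts must be non-negative")
  if (any(n_significant > n_total))
    stopf("n_significant exceeds n_total")
  out <- round(100 * n_significant / n_total, 2)
  out[n_total == 0] <- NA_real_
  out
}

#' Build risk-locus intervals around GWAS index SNPs
#'
#' Each locus extends 500 kb upstream and downstream of the lead SNP,
#' giving a 1 Mb region (clipped at chromosome edges). Positions are
#' 1-based on input; regions are 0-based half-open.
#'
#' @param index data.frame with columns `locus_id`, `chrom`, `pos`
#'   (1-based index-SNP position) and optionally `histotype`.
#' @param genome a [gen_genome()] model (chromosome names and sizes).
#' @param flank_bp flank on each side of the lead SNP (default 500,000).
#' @return data.frame with `locus_id`, `chrom`, `start`, `end`,
#'   `index_pos`, `histotype`.
#' @export
build_risk_loci <- function(index, genome, flank_bp = 500000) {
  need <- c("locus_id", "chrom", "pos")
  if (!all(need %in% names(index)))
    stopf("index table needs columns: %s", paste(need, collapse = ", "))
  sizes <- genome$chrom_sizes
  hit <- match(norm_chrom(index$chrom), norm_chrom(names(sizes)))
  if (anyNA(hit))
    stopf("unknown chromosome '%s' in risk-locus table",
          index$chrom[which(is.na(hit))[1]])
  size <- as.numeric(sizes[hit])
  pos <- as.numeric(index$pos)
  if (any(pos < 1 | pos > size))
    stopf("index SNP position outside its chromosome")
  p0 <- pos - 1                       # 0-based base of the index SNP
  start <- pmax(0, p0 - flank_bp)
  end <- pmin(size, p0 + flank_bp)
  data.frame(locus_id = as.character(index$locus_id),
             chrom = as.character(index$chrom),
             start = start, end = end,
             index_pos = pos,
             histotype = if (!is.null(index$histotype))
               as.character(index$histotype) else NA_character_,
             stringsAsFactors = FALSE)
}
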