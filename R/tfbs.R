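# PWM scanning and motif-disruption scoring: a transparent stand-in for
# information-content-weighted motif-disruption tools. Scores are
# min-max-normalized log2-likelihoods, so the per-column consensus scores
# exactly 1 and the per-column worst sequence exactly 0; a variant is
# called disrupting when either allele sits in a strong site and the two
# alleles' best scores differ by at least the delta threshold.

seq_to_idx <- function(seq) {
  idx <- match(strsplit(seq, "")[[1]], DNA_BASES)
  if (anyNA(idx)) stopf("sequence contains a non-ACGT base")
  idx
}

#' Score one sequence window against a PWM
#'
#' Raw score = sum over columns of log2 p(base); normalized to \[0,1\]
#' with the per-column best/worst probabilities as the bounds, so the
#' consensus sequence scores 1 and the anti-consensus 0.
#'
#' @param seq character string of the motif length (A/C/G/T).
#' @param pwm a `pwm` object.
#' @return normalized score in \[0,1\].
#' @export
score_site <- function(seq, pwm) {
  logp <- log2(pwm$prob)
  L <- ncol(logp)
  idx <- seq_to_idx(seq)
  if (length(idx) != L) stopf("sequence length != motif length")
  raw_max <- sum(apply(logp, 2, max))
  raw_min <- sum(apply(logp, 2, min))
  if (raw_max - raw_min < 1e-12)
    stopf("zero-information motif '%s'", pwm$tf)
  raw <- sum(logp[cbind(idx, seq_len(L))])
  (raw - raw_min) / (raw_max - raw_min)
}

# normalized scores of every window of `seq` (forward strand);
# vectorized over windows
scan_scores_fwd <- function(seq, pwm) {
  logp <- log2(pwm$prob)
  L <- ncol(logp)
  idx <- seq_to_idx(seq)
  n <- length(idx)
  if (n < L) return(numeric())
  raw_max <- sum(apply(logp, 2, max))
  raw_min <- sum(apply(logp, 2, min))
  if (raw_max - raw_min < 1e-12)
    stopf("zero-information motif '%s'", pwm$tf)
  nw <- n - L + 1
  raw <- numeric(nw)
  for (j in seq_len(L))
    raw <- raw + logp[cbind(idx[j:(nw + j - 1)], j)]
  (raw - raw_min) / (raw_max - raw_min)
}

#' Scan a sequence for PWM matches on both strands
#'
#' @param seq character string.
#' @param pwm a `pwm` object.
#' @return data.frame with `start` (0-based window start within `seq`),
#'   `strand` ("+"/"-"), `score`.
#' @export
scan_sites <- function(seq, pwm) {
  fwd <- scan_scores_fwd(seq, pwm)
  if (length(fwd) == 0)
    return(data.frame(start = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  rev <- rev(scan_scores_fwd(revcomp(seq), pwm))
  data.frame(start = rep(seq_along(fwd) - 1L, 2),
             strand = rep(c("+", "-"), each = length(fwd)),
             score = c(fwd, rev), stringsAsFactors = FALSE)
}

#' Score a variant's motif-disruption potential against one PWM
#'
#' Both alleles are scored over ALL windows overlapping the variant
#' position, on both strands; the best window may differ between alleles.
#' `disrupting` requires the stronger allele to reach
#' `strong_site_threshold` and the allele scores to differ by at least
#' `delta_threshold`.
#'
#' @param variant one-row variant data.frame (`chrom`, `pos` 1-based,
#'   `ref`, `alt`).
#' @param sequences named character vector of chromosome sequences.
#' @param pwm a `pwm` object.
#' @param strong_site_threshold minimum best-allele score (default 0.85).
#' @param delta_threshold minimum |ref - alt| score change (default 0.10).
#' @return one-row data.frame: variant fields, `tf_name`, `ref_score`,
#'   `alt_score`, `delta`, `disrupting`.
#' @export
score_variant <- function(variant, sequences, pwm,
                          strong_site_threshold = 0.85,
                          delta_threshold = 0.10) {
  cn <- variant$chrom
  hit <- match(norm_chrom(cn), norm_chrom(names(sequences)))
  if (is.na(hit)) stopf("no sequence for chromosome '%s'", cn)
  seq <- sequences[[hit]]
  L <- ncol(pwm$prob)
  pos <- as.integer(variant$pos)
  n <- nchar(seq)
  if (pos < 1 || pos > n) stopf("variant position outside sequence")
  here <- substr(seq, pos, pos)
  if (here != variant$ref)
    stopf("ref allele '%s' disagrees with sequence base '%s' at %s:%d",
          variant$ref, here, cn, pos)
  a <- max(1, pos - L + 1)
  b <- min(n, pos + L - 1)
  ctx_ref <- substr(seq, a, b)
  at <- pos - a + 1
  ctx_alt <- ctx_ref
  substr(ctx_alt, at, at) <- variant$alt
  best <- function(ctx) {
    sc <- scan_sites(ctx, pwm)
    # keep only windows that truly cover the variant base
    sc <- sc[sc$start <= at - 1 & at - 1 < sc$start + L, , drop = FALSE]
    if (nrow(sc) == 0) 0 else max(sc$score)
  }
  ref_score <- best(ctx_ref)
  alt_score <- best(ctx_alt)
  delta <- ref_score - alt_score
  data.frame(chrom = cn, pos = pos, ref = variant$ref, alt = variant$alt,
             tf_name = pwm$tf, ref_score = ref_score,
             alt_score = alt_score, delta = delta,
             disrupting = max(ref_score, alt_score) >= strong_site_threshold &
               abs(delta) >= delta_threshold,
             stringsAsFactors = FALSE)
}

#' Per-TF counts of motif-disrupting germline variants within elements
#'
#' Variants are first restricted to those overlapping the supplied
#' elements (>= 1 bp); every (variant, PWM) pair is then scored and
#' disrupting calls are counted per TF.
#'
#' @param variants variant data.frame (germline: `sample` may be NA).
#' @param pwms named list of `pwm` objects.
#' @param sequences named character vector of chromosome sequences.
#' @param elements interval data.frame restricting the search.
#' @param strong_site_threshold,delta_threshold see [score_variant()].
#' @return list with `calls` (all scored pairs) and `counts` (per-TF
#'   disrupting-variant counts, sorted descending).
#' @export
germline_disrupted_tfs <- function(variants, pwms, sequences, elements,
                                   strong_site_threshold = 0.85,
                                   delta_threshold = 0.10) {
  empty_counts <- data.frame(tf_name = character(),
                             n_disrupting = integer(),
                             stringsAsFactors = FALSE)
  if (nrow(variants) > 0 && nrow(elements) > 0) {
    vi <- data.frame(chrom = variants$chrom, start = variants$pos - 1,
                     end = variants$pos, stringsAsFactors = FALSE)
    keep <- unique(gi_intersect(vi, elements)$a_index)
    variants <- variants[keep, , drop = FALSE]
  } else {
    variants <- variants[0, , drop = FALSE]
  }
  if (nrow(variants) == 0)
    return(list(calls = data.frame(), counts = empty_counts))
  calls <- list()
  for (i in seq_len(nrow(variants)))
    for (p in pwms)
      calls[[length(calls) + 1]] <-
        score_variant(variants[i, , drop = FALSE], sequences, p,
                      strong_site_threshold, delta_threshold)
  calls <- do.call(rbind, calls)
  agg <- tapply(calls$disrupting, calls$tf_name, sum)
  counts <- data.frame(tf_name = names(agg),
                       n_disrupting = as.integer(agg),
                       stringsAsFactors = FALSE)
  counts <- counts[counts$n_disrupting > 0, , drop = FALSE]
  counts <- counts[order(-counts$n_disrupting, counts$tf_name), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  list(calls = calls, counts = counts)
}

#' Somatic mutation burden on predicted TF binding sites per element
#'
#' Binding sites are predicted by scanning each element's sequence for
#' windows (either strand) with normalized score >= `site_threshold`;
#' somatic SNVs falling inside a TF's predicted sites within the element
#' are counted. A (TF, element) row passes the filter when it collects at
#' least `min_mutations` mutations.
#'
#' @param elements interval data.frame (regulatory elements; `name`
#'   optional).
#' @param snvs somatic variant data.frame.
#' @param pwms named list of `pwm` objects.
#' @param sequences named character vector of chromosome sequences.
#' @param site_threshold minimum normalized site score (default 0.85).
#' @param min_mutations filter threshold (default 3).
#' @return data.frame, one row per (TF, element) with > 0 mutations:
#'   `tf_name`, `chrom`, `start`, `end`, `element`, `n_mutations`,
#'   `passes_filter`.
#' @export
somatic_tf_burden <- function(elements, snvs, pwms, sequences,
                              site_threshold = 0.85, min_mutations = 3) {
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, , drop = FALSE]
    hit <- match(norm_chrom(el$chrom), norm_chrom(names(sequences)))
    if (is.na(hit))
      stopf("no sequence available for element on '%s'", el$chrom)
    seq <- substr(sequences[[hit]], el$start + 1, el$end)
    in_el <- norm_chrom(snvs$chrom) == norm_chrom(el$chrom) &
      (snvs$pos - 1) >= el$start & (snvs$pos - 1) < el$end
    pos0_rel <- snvs$pos[in_el] - 1 - el$start
    for (p in pwms) {
      L <- ncol(p$prob)
      sc <- scan_sites(seq, p)
      sc <- sc[sc$score >= site_threshold, , drop = FALSE]
      if (nrow(sc) == 0 || length(pos0_rel) == 0) next
      covered <- vapply(pos0_rel, function(x)
        any(x >= sc$start & x < sc$start + L), logical(1))
      n_mut <- sum(covered)
      if (n_mut == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        tf_name = p$tf, chrom = el$chrom, start = el$start, end = el$end,
        element = el$name %||% sprintf("%s:%d-%d", el$chrom, el$start,
                                       el$end),
        n_mutations = n_mut, passes_filter = n_mut >= min_mutations,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tf_name = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      element = character(), n_mutations = integer(),
                      passes_filter = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Intersection of germline- and somatic-disrupted TF lists
#'
#' Whole-string name matching (dimer names like "PPARA::RXRA" are atomic);
#' output order follows the first list.
#'
#' @param germline_tfs,somatic_tfs character vectors of TF names.
#' @return character vector of common TFs.
#' @export
intersect_tf_lists <- function(germline_tfs, somatic_tfs) {
  unique(germline_tfs[germline_tfs %in% somatic_tfs])
}
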