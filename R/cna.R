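# Recurrent copy-number region calling from segmentation data (a
# simplified, permutation-based stand-in for a full G-score model),
# chromatin-state coverage of the called regions, and risk-locus
# intersection. Users with externally produced recurrent-region calls can
# skip the caller and feed their regions straight into annotate_cna() /
# cna_in_loci().

# per-sample altered intervals (merged) in one direction
altered_intervals <- function(segments, threshold, direction) {
  keep <- if (direction == "amp") segments$seg_mean >= threshold
          else segments$seg_mean <= threshold
  seg <- segments[keep, , drop = FALSE]
  split(seg[, c("chrom", "start", "end")], seg$sample)
}

# bin indices (1-based) hit by intervals on one chromosome of length L
bins_hit <- function(starts, ends, bin_bp, n_bins) {
  if (length(starts) == 0) return(integer())
  lo <- pmax(0L, as.integer(starts %/% bin_bp))
  hi <- pmin(n_bins - 1L, as.integer((ends - 1) %/% bin_bp))
  unique(unlist(mapply(function(a, b) seq.int(a, b), lo, hi,
                       SIMPLIFY = FALSE))) + 1L
}

# circularly shift intervals on [0, L) by offset, splitting the wrap
shift_circular <- function(starts, ends, offset, L) {
  s <- (starts + offset) %% L
  e <- s + (ends - starts)
  wrap <- e > L
  data.frame(start = c(s[!wrap], s[wrap], rep(0, sum(wrap))),
             end = c(e[!wrap], rep(L, sum(wrap)), e[wrap] - L))
}

#' Call recurrent CNA regions from segmentation data
#'
#' The genome is binned; per bin and direction, the observed frequency is
#' the fraction of samples whose altered segments (|seg.mean| past the
#' threshold) overlap the bin. The null circularly permutes each sample's
#' altered-segment layout along the chromosome (preserving each sample's
#' total altered bp exactly); the per-bin p-value is
#' `(1 + #permutations with frequency >= observed) / (1 + n_perm)`.
#' BH-significant adjacent bins of one direction are merged into regions.
#'
#' @param segments segment data.frame ([read_seg()] layout); each sample's
#'   segments must not overlap within a chromosome.
#' @param t_amp,t_del seg.mean thresholds (defaults +0.3 / -0.3 log2).
#' @param bin_bp bin width (default 10 kb).
#' @param n_perm circular permutations (default 1000).
#' @param fdr BH q threshold (default 0.25, the customary q-value
#'   convention for recurrent-CNA calling).
#' @param seed RNG seed.
#' @param genome optional [gen_genome()] model; inferred from segment
#'   extents when absent.
#' @return data.frame of regions: `chrom`, `start`, `end`, `direction`,
#'   `frequency` (max bin frequency), `p_value`, `q_value` (minima over
#'   merged bins).
#' @export
call_recurrent_cna <- function(segments, t_amp = 0.3, t_del = -0.3,
                               bin_bp = 10000, n_perm = 1000, fdr = 0.25,
                               seed = 1, genome = NULL) {
  if (t_amp <= 0 || t_del >= 0) stopf("need t_amp > 0 > t_del")
  # overlapping segments within one sample are malformed input
  for (s in unique(segments$sample)) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    seg <- seg[order(norm_chrom(seg$chrom), seg$start), , drop = FALSE]
    same <- norm_chrom(seg$chrom[-1]) == norm_chrom(seg$chrom[-nrow(seg)])
    if (any(same & seg$start[-1] < seg$end[-nrow(seg)]))
      stopf("overlapping segments within sample %s", s)
  }
  sizes <- if (!is.null(genome)) genome$chrom_sizes else {
    agg <- tapply(segments$end, norm_chrom(segments$chrom), max)
    setNames(as.numeric(agg), names(agg))
  }
  samples <- unique(segments$sample)
  n_samples <- length(samples)
  set.seed(as.integer(seed))
  out <- list()
  for (direction in c("amp", "del")) {
    thr <- if (direction == "amp") t_amp else t_del
    alt <- altered_intervals(segments, thr, direction)
    for (cn in names(sizes)) {
      L <- sizes[[cn]]
      n_bins <- as.integer(ceiling(L / bin_bp))
      per_sample <- lapply(samples, function(s) {
        iv <- alt[[s]]
        if (is.null(iv)) return(NULL)
        iv <- iv[norm_chrom(iv$chrom) == norm_chrom(cn), , drop = FALSE]
        if (nrow(iv) == 0) NULL else iv
      })
      obs <- integer(n_bins)
      for (iv in per_sample) {
        if (is.null(iv)) next
        h <- bins_hit(iv$start, iv$end, bin_bp, n_bins)
        obs[h] <- obs[h] + 1L
      }
      if (all(obs == 0)) next
      exceed <- integer(n_bins)
      for (p in seq_len(n_perm)) {
        cnt <- integer(n_bins)
        for (iv in per_sample) {
          if (is.null(iv)) next
          sh <- shift_circular(iv$start, iv$end, sample.int(L, 1), L)
          h <- bins_hit(sh$start, sh$end, bin_bp, n_bins)
          cnt[h] <- cnt[h] + 1L
        }
        exceed <- exceed + as.integer(cnt >= obs)
      }
      pval <- (1 + exceed) / (1 + n_perm)
      out[[paste(direction, cn)]] <- data.frame(
        chrom = cn, bin = seq_len(n_bins),
        start = (seq_len(n_bins) - 1) * bin_bp,
        end = pmin(seq_len(n_bins) * bin_bp, L),
        direction = direction, frequency = obs / n_samples,
        p_value = pval, stringsAsFactors = FALSE)
    }
  }
  bins <- do.call(rbind, out)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      frequency = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE)
  if (is.null(bins)) return(empty)
  rownames(bins) <- NULL
  regions <- list()
  for (direction in c("amp", "del")) {
    db <- bins[bins$direction == direction, , drop = FALSE]
    if (nrow(db) == 0) next
    db$q_value <- stats::p.adjust(db$p_value, method = "BH")
    sig <- db[db$q_value < fdr, , drop = FALSE]
    if (nrow(sig) == 0) next
    sig <- sig[order(norm_chrom(sig$chrom), sig$bin), , drop = FALSE]
    grp <- cumsum(c(1, (norm_chrom(sig$chrom[-1]) !=
                          norm_chrom(sig$chrom[-nrow(sig)])) |
                       (sig$bin[-1] != sig$bin[-nrow(sig)] + 1)))
    for (g in unique(grp)) {
      r <- sig[grp == g, , drop = FALSE]
      regions[[length(regions) + 1]] <- data.frame(
        chrom = r$chrom[1], start = min(r$start), end = max(r$end),
        direction = direction, frequency = max(r$frequency),
        p_value = min(r$p_value), q_value = min(r$q_value),
        stringsAsFactors = FALSE)
    }
  }
  if (length(regions) == 0) return(empty)
  res <- do.call(rbind, regions)
  res <- res[order(norm_chrom(res$chrom), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

CHROMATIN_STATES <- c("active_region", "active_promoter", "weak_promoter",
                      "active_enhancer", "weak_enhancer", "transcribed",
                      "insulator")

#' Chromatin-state coverage of recurrent CNA regions
#'
#' For every (cell type, state, direction) combination present in the
#' inputs, computes the bp of called CNA regions covered by the state and
#' the fraction of the direction's total CNA bp. State tracks must use
#' the seven-state vocabulary (low-signal regions are excluded upstream,
#' before this step).
#'
#' @param regions recurrent-region data.frame (from
#'   [call_recurrent_cna()] or an external caller) with `direction`.
#' @param state_tracks named list (cell type -> interval data.frame whose
#'   `name` column holds the chromatin state).
#' @return data.frame: `cell_type`, `state`, `direction`, `covered_bp`,
#'   `fraction_of_cna_bp`.
#' @export
annotate_cna <- function(regions, state_tracks) {
  for (ct in names(state_tracks)) {
    bad <- setdiff(unique(state_tracks[[ct]]$name), CHROMATIN_STATES)
    if (length(bad))
      stopf("unknown chromatin state '%s' in track '%s'; allowed: %s",
            bad[1], ct, paste(CHROMATIN_STATES, collapse = ", "))
  }
  rows <- list()
  for (direction in intersect(c("amp", "del"), unique(regions$direction))) {
    reg <- gi_merge(regions[regions$direction == direction, , drop = FALSE])
    total <- gi_width(reg)
    for (ct in names(state_tracks)) {
      track <- state_tracks[[ct]]
      for (st in unique(track$name)) {
        states <- gi_merge(track[track$name == st, , drop = FALSE])
        frag <- gi_intersect(reg, states)
        covered <- if (nrow(frag)) sum(frag$end - frag$start) else 0
        rows[[length(rows) + 1]] <- data.frame(
          cell_type = ct, state = st, direction = direction,
          covered_bp = covered,
          fraction_of_cna_bp = if (total > 0) covered / total else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_type = character(), state = character(),
                      direction = character(), covered_bp = numeric(),
                      fraction_of_cna_bp = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Intersect recurrent CNA regions with risk loci
#'
#' @param regions recurrent-region data.frame with `direction`.
#' @param loci risk-locus data.frame from [build_risk_loci()].
#' @return list with `per_locus` (one row per locus x overlapping region,
#'   with a `multi_locus` flag for regions spanning several loci) and
#'   `summary` (counts of loci with any CNA / any amplification / any
#'   deletion).
#' @export
cna_in_loci <- function(regions, loci) {
  if (nrow(regions) == 0) {
    per_locus <- data.frame(locus_id = character(), chrom = character(),
                            region_start = numeric(), region_end = numeric(),
                            direction = character(), multi_locus = logical(),
                            stringsAsFactors = FALSE)
  } else {
    ov <- gi_intersect(regions, loci)
    n_loci_per_region <- table(ov$a_index)
    per_locus <- data.frame(
      locus_id = loci$locus_id[ov$b_index],
      chrom = regions$chrom[ov$a_index],
      region_start = regions$start[ov$a_index],
      region_end = regions$end[ov$a_index],
      direction = regions$direction[ov$a_index],
      multi_locus = as.integer(n_loci_per_region[as.character(ov$a_index)]) > 1,
      stringsAsFactors = FALSE)
    rownames(per_locus) <- NULL
  }
  amp_loci <- unique(per_locus$locus_id[per_locus$direction == "amp"])
  del_loci <- unique(per_locus$locus_id[per_locus$direction == "del"])
  summary <- data.frame(
    n_loci = length(unique(loci$locus_id)),
    loci_with_cna = length(unique(per_locus$locus_id)),
    loci_with_amp = length(amp_loci),
    loci_with_del = length(del_loci))
  list(per_locus = per_locus, summary = summary)
}
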