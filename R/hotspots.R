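# SNV recurrence tally and the frequently-mutated-element burden test,
# plus annotation enrichment genome-wide and within risk loci. The burden
# model is deliberately simple -- a uniform Poisson background per track,
# no trinucleotide or replication-timing covariates -- and is a stand-in
# for a full driver-discovery model: the layer of interest here is the
# enrichment computation on top of it.

#' Tally SNV recurrence across samples
#'
#' For every mutated (chrom, pos), k = the number of DISTINCT samples with
#' an SNV there (duplicate records from one sample count once). The
#' histogram maps k to the number of positions; the totals obey
#' `total_snvs = sum(k * count)` and `unique_positions = sum(count)`.
#'
#' @param snvs variant data.frame with `chrom`, `pos`, `sample`.
#' @return object of class `recurrence_tally`: list with `histogram`
#'   (data.frame `k`, `n_positions`), `total_snvs` (distinct
#'   sample-position events), `unique_positions`, `n_records` (raw rows).
#' @export
tally_recurrence <- function(snvs) {
  if (nrow(snvs) == 0) {
    return(structure(list(histogram = data.frame(k = integer(),
                                                 n_positions = integer()),
                          total_snvs = 0, unique_positions = 0,
                          n_records = 0L), class = "recurrence_tally"))
  }
  ev <- unique(data.frame(chrom = norm_chrom(snvs$chrom), pos = snvs$pos,
                          sample = snvs$sample, stringsAsFactors = FALSE))
  key <- paste(ev$chrom, ev$pos)
  k_per_pos <- table(key)
  hist <- table(as.integer(k_per_pos))
  histogram <- data.frame(k = as.integer(names(hist)),
                          n_positions = as.integer(hist))
  histogram <- histogram[order(-histogram$k), , drop = FALSE]
  rownames(histogram) <- NULL
  structure(list(histogram = histogram,
                 total_snvs = sum(histogram$k * histogram$n_positions),
                 unique_positions = sum(histogram$n_positions),
                 n_records = nrow(snvs)),
            class = "recurrence_tally")
}

#' Rebuild recurrence totals from a printed histogram
#'
#' Applies the tally invariants to a recurrence distribution given as
#' (k, number of positions) pairs -- e.g. a distribution printed in a
#' report -- returning the implied total SNV calls and unique positions.
#'
#' @param k integer vector: samples sharing a mutated position.
#' @param n_positions number of positions with each k.
#' @return a `recurrence_tally`.
#' @export
tally_from_histogram <- function(k, n_positions) {
  if (length(k) != length(n_positions)) stopf("k / n_positions mismatch")
  if (any(k < 1) || any(n_positions < 0)) stopf("invalid histogram")
  histogram <- data.frame(k = as.integer(k),
                          n_positions = as.numeric(n_positions))
  histogram <- histogram[order(-histogram$k), , drop = FALSE]
  rownames(histogram) <- NULL
  structure(list(histogram = histogram,
                 total_snvs = sum(histogram$k * histogram$n_positions),
                 unique_positions = sum(histogram$n_positions),
                 n_records = NA_integer_),
            class = "recurrence_tally")
}

#' @export
print.recurrence_tally <- function(x, ...) {
  cat(sprintf("Recurrence tally: %s SNVs across %s unique positions\n",
              format(x$total_snvs, big.mark = ","),
              format(x$unique_positions, big.mark = ",")))
  print(x$histogram)
  invisible(x)
}

#' Poisson burden test for one annotated element
#'
#' Pooled across samples: observed = SNV records inside the element,
#' expected = `background_rate * width`; the p-value is the inclusive
#' upper Poisson tail P(X >= observed).
#'
#' @param element one-row interval data.frame (chrom, start, end).
#' @param snvs variant data.frame.
#' @param background_rate pooled mutations per bp (across all samples).
#' @return one-row data.frame: `chrom`, `start`, `end`, `observed`,
#'   `expected`, `p_value`.
#' @export
test_element <- function(element, snvs, background_rate) {
  if (background_rate <= 0) stopf("background_rate must be > 0")
  w <- element$end - element$start
  if (any(w <= 0)) stopf("element width must be > 0")
  inside <- norm_chrom(snvs$chrom) == norm_chrom(element$chrom) &
    (snvs$pos - 1) >= element$start & (snvs$pos - 1) < element$end
  observed <- sum(inside)
  lambda <- background_rate * w
  p <- stats::ppois(observed - 1, lambda, lower.tail = FALSE)
  data.frame(chrom = element$chrom, start = element$start,
             end = element$end, observed = observed, expected = lambda,
             p_value = p, stringsAsFactors = FALSE)
}

#' Burden-test every element of a track
#'
#' The pooled background rate defaults to (SNVs overlapping the track's
#' merged footprint) / (merged track width). BH adjustment is applied
#' within the track; `significant = q < fdr`.
#'
#' @param track interval data.frame (name column = annotation class).
#' @param snvs variant data.frame.
#' @param fdr BH q-value threshold (default 0.05).
#' @param background_rate optional rate override (pooled mutations/bp).
#' @return data.frame, one row per element: coordinates, `annotation`,
#'   `observed`, `expected`, `p_value`, `q_value`, `significant`.
#' @export
scan_track <- function(track, snvs, fdr = 0.05, background_rate = NULL) {
  if (nrow(track) == 0) stopf("track is empty")
  merged <- gi_merge(track)
  width <- gi_width(merged)
  snv_iv <- if (nrow(snvs) > 0)
    data.frame(chrom = snvs$chrom, start = snvs$pos - 1, end = snvs$pos,
               stringsAsFactors = FALSE)
  else data.frame(chrom = character(), start = numeric(), end = numeric())
  if (is.null(background_rate)) {
    n_in <- nrow(gi_intersect(snv_iv, merged))
    background_rate <- n_in / width
    if (background_rate <= 0)
      stopf("no SNVs overlap the track; supply background_rate")
  }
  hits <- gi_intersect(snv_iv, track)
  observed <- integer(nrow(track))
  if (nrow(hits) > 0) {
    cnt <- table(hits$b_index)
    observed[as.integer(names(cnt))] <- as.integer(cnt)
  }
  w <- track$end - track$start
  lambda <- background_rate * w
  p <- stats::ppois(observed - 1, lambda, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(chrom = track$chrom, start = track$start, end = track$end,
             annotation = track$name %||% rep(NA_character_, nrow(track)),
             observed = observed, expected = lambda,
             p_value = p, q_value = q, significant = q < fdr,
             stringsAsFactors = FALSE)
}

#' Enrichment of significant elements by annotation and stratum
#'
#' The reported quantity is the percentage of frequently mutated elements
#' among all elements carrying the annotation, genome-wide, per
#' chromosome, or within risk loci (>= 1 bp overlap; an element inside
#' several loci counts once per locus and is flagged).
#'
#' @param results element table from [scan_track()] (possibly several
#'   tracks row-bound), with `annotation` and `significant` columns.
#' @param stratify_by `"genome"`, `"chromosome"`, or a risk-locus
#'   data.frame from [build_risk_loci()].
#' @return data.frame: `annotation`, `stratum`, `n_total`,
#'   `n_significant`, `percent`; attribute `n_multi_locus` counts
#'   elements assigned to more than one locus.
#' @export
enrich_elements <- function(results, stratify_by = "genome") {
  if (is.character(stratify_by) && stratify_by[1] == "genome") {
    strata <- rep("genome", nrow(results))
    idx <- seq_len(nrow(results))
  } else if (is.character(stratify_by) && stratify_by[1] == "chromosome") {
    strata <- results$chrom
    idx <- seq_len(nrow(results))
  } else {
    loci <- stratify_by
    ov <- gi_intersect(results, loci)
    idx <- ov$a_index
    strata <- loci$locus_id[ov$b_index]
    multi <- sum(table(ov$a_index) > 1)
    out <- enrich_count(results[idx, , drop = FALSE], strata,
                        all_strata = loci$locus_id,
                        all_annotations = unique(results$annotation))
    attr(out, "n_multi_locus") <- multi
    return(out)
  }
  out <- enrich_count(results[idx, , drop = FALSE], strata,
                      all_strata = unique(strata),
                      all_annotations = unique(results$annotation))
  attr(out, "n_multi_locus") <- 0L
  out
}

enrich_count <- function(rows, strata, all_strata, all_annotations) {
  grid <- expand.grid(annotation = all_annotations, stratum = all_strata,
                      stringsAsFactors = FALSE)
  grid$n_total <- mapply(function(a, s)
    sum(rows$annotation == a & strata == s), grid$annotation, grid$stratum)
  grid$n_significant <- mapply(function(a, s)
    sum(rows$annotation == a & strata == s & rows$significant),
    grid$annotation, grid$stratum)
  grid$percent <- enrichment_percent(grid$n_significant, grid$n_total)
  grid
}
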