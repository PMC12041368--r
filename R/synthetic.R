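# Synthetic-data generators. These emulate the statistical structure the
# downstream analyses assume -- non-negative signature activities coupled to
# planted gene expression, background + hotspot SNVs, recurrent CNA
# segments, annotation tracks tiling a toy genome, and PWMs with planted
# disruptable binding sites -- so that every stage runs and is testable
# with no external download. They make no attempt at realistic
# trinucleotide spectra or indel calls.

#' Build a toy genome model
#'
#' @param n_chroms number of chromosomes (>= 1).
#' @param size_bp chromosome length in bp (scalar, recycled, or one per
#'   chromosome); must be >= 10,000.
#' @param seed optional RNG seed (construction is deterministic; the seed
#'   is recorded for provenance).
#' @return list with `chrom_names` and named `chrom_sizes`.
#' @export
gen_genome <- function(n_chroms, size_bp, seed = NULL) {
  if (n_chroms < 1) stopf("n_chroms must be >= 1")
  sizes <- rep_len(as.numeric(size_bp), n_chroms)
  if (any(sizes < 10000)) stopf("chromosome sizes must be >= 10,000 bp")
  names <- paste0("chr", seq_len(n_chroms))
  list(chrom_names = names,
       chrom_sizes = setNames(sizes, names),
       seed = seed)
}

# Place n non-overlapping intervals of the given lengths uniformly on
# [0, size) via the gap-splitting trick; returns sorted starts.
place_nonoverlapping <- function(n, lens, size) {
  slack <- size - sum(lens)
  if (slack < 0) stopf("requested interval mass exceeds chromosome size")
  cuts <- sort(runif(n, 0, slack))
  gaps <- floor(c(cuts, slack) - c(0, cuts))
  starts <- cumsum(gaps[seq_len(n)] + c(0, lens[-n][seq_len(max(0, n - 1))]))
  starts
}

#' Generate named annotation tracks on a toy genome
#'
#' Emulates functional-annotation and chromatin-state tracks: for each
#' class, `n_per_class` non-overlapping elements with approximately
#' exponential lengths around `mean_len`, placed uniformly; classes are
#' placed independently of each other.
#'
#' @param genome a [gen_genome()] model.
#' @param classes character vector of annotation class names.
#' @param n_per_class elements per class (scalar or per class).
#' @param mean_len mean element length in bp.
#' @param seed RNG seed.
#' @return named list of [genomic_intervals()] tables (name column =
#'   class), each sorted by (chrom, start).
#' @export
gen_annotation_tracks <- function(genome, classes, n_per_class,
                                  mean_len = 500, seed = 1) {
  set.seed(as.integer(seed))
  n_per_class <- rep_len(as.integer(n_per_class), length(classes))
  sizes <- genome$chrom_sizes
  tracks <- list()
  for (k in seq_along(classes)) {
    n <- n_per_class[k]
    chrom <- sample(names(sizes), n, replace = TRUE,
                    prob = sizes / sum(sizes))
    lens <- pmax(1, round(stats::rexp(n, 1 / mean_len)))
    rows <- list()
    for (cn in unique(chrom)) {
      idx <- which(chrom == cn)
      starts <- place_nonoverlapping(length(idx), lens[idx], sizes[[cn]])
      rows[[cn]] <- data.frame(chrom = cn, start = starts,
                               end = starts + lens[idx],
                               stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    gi <- genomic_intervals(tab$chrom, tab$start, tab$end,
                            name = rep(classes[k], nrow(tab)))
    gi <- gi_sort(gi)
    rownames(gi) <- NULL
    tracks[[classes[k]]] <- gi
  }
  tracks
}

#' Simulate somatic SNVs with optional planted hotspots
#'
#' Per sample, background SNV counts are Poisson with mean
#' `background_rate * genome size`; positions are uniform. Inside each
#' hotspot the per-bp rate is `background_rate * rate_multiplier`.
#' `background_rate = 0` with no hotspots yields an empty table (all
#' downstream stages tolerate empty tables).
#'
#' @param genome a [gen_genome()] model.
#' @param n_samples number of tumour samples.
#' @param background_rate mutations per bp per sample.
#' @param hotspots optional data.frame with `chrom`, `start`, `end`,
#'   `rate_multiplier` (> 1).
#' @param seed RNG seed.
#' @return variant data.frame (`chrom`, `pos` 1-based, `ref`, `alt`,
#'   `sample`), sorted by (chrom, pos, sample).
#' @export
gen_snvs <- function(genome, n_samples, background_rate,
                     hotspots = NULL, seed = 1) {
  if (length(genome$chrom_sizes) == 0) stopf("empty genome")
  if (background_rate < 0) stopf("background_rate must be >= 0")
  if (!is.null(hotspots) && nrow(hotspots) > 0 &&
      any(hotspots$rate_multiplier <= 1))
    stopf("hotspot rate_multiplier must be > 1")
  set.seed(as.integer(seed))
  sizes <- genome$chrom_sizes
  samples <- sprintf("S%03d", seq_len(n_samples))
  rows <- list()
  for (s in samples) {
    for (cn in names(sizes)) {
      n_bg <- rpois(1, background_rate * sizes[[cn]])
      pos0 <- if (n_bg > 0) sample.int(sizes[[cn]], n_bg, replace = TRUE) - 1
              else integer()
      if (!is.null(hotspots) && nrow(hotspots) > 0) {
        hs <- hotspots[norm_chrom(hotspots$chrom) == norm_chrom(cn), ,
                       drop = FALSE]
        for (i in seq_len(nrow(hs))) {
          w <- hs$end[i] - hs$start[i]
          extra <- rpois(1, background_rate * (hs$rate_multiplier[i] - 1) * w)
          if (extra > 0)
            pos0 <- c(pos0, hs$start[i] + sample.int(w, extra,
                                                     replace = TRUE) - 1)
        }
      }
      if (length(pos0) == 0) next
      ref <- sample(DNA_BASES, length(pos0), replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1),
                    character(1), USE.NAMES = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = cn, pos = pos0 + 1, ref = ref, alt = alt, sample = s,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = numeric(), ref = character(),
               alt = character(), sample = character(),
               stringsAsFactors = FALSE)
  out <- out[order(norm_chrom(out$chrom), out$pos, out$sample), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate expression and coupled mutational-signature activities
#'
#' Expression is lognormal (`meanlog = 1`, `sdlog = 0.5` by default).
#' Signature activities are non-negative continuous scores: for a planted
#' (gene, signature) pair, `activity = max(0, slope * expr + intercept +
#' N(0, noise_sd))`; unplanted signatures are independent of every gene
#' (`max(0, intercept + N(0, base_sd))`).
#'
#' @param n_samples number of samples.
#' @param genes character vector of gene ids (unique).
#' @param signatures character vector of signature ids.
#' @param planted optional data.frame with `gene`, `signature`, `slope`,
#'   `noise_sd` (one planted association per row; several genes may drive
#'   the same signature, in which case their contributions add and the
#'   first row's `noise_sd` is used for that signature).
#' @param intercept baseline activity level (default 5).
#' @param base_sd residual sd for unplanted signatures (default 1).
#' @param meanlog,sdlog expression lognormal parameters.
#' @param seed RNG seed.
#' @return list with `expression` (samples x genes) and `activity`
#'   (samples x signatures) matrices sharing rownames.
#' @export
gen_signature_expression <- function(n_samples, genes, signatures,
                                     planted = NULL, intercept = 5,
                                     base_sd = 1, meanlog = 1, sdlog = 0.5,
                                     seed = 1) {
  if (anyDuplicated(genes)) stopf("duplicate gene ids")
  if (anyDuplicated(signatures)) stopf("duplicate signature ids")
  if (!is.null(planted) && nrow(planted) > 0) {
    if (!all(planted$gene %in% genes))
      stopf("planted gene not in gene set")
    if (!all(planted$signature %in% signatures))
      stopf("planted signature not in signature set")
    if (any(planted$noise_sd < 0)) stopf("noise_sd must be >= 0")
  }
  set.seed(as.integer(seed))
  samples <- sprintf("S%03d", seq_len(n_samples))
  expr <- matrix(rlnorm(n_samples * length(genes), meanlog, sdlog),
                 n_samples, length(genes),
                 dimnames = list(samples, genes))
  act <- matrix(pmax(0, intercept +
                       rnorm(n_samples * length(signatures), 0, base_sd)),
                n_samples, length(signatures),
                dimnames = list(samples, signatures))
  if (!is.null(planted) && nrow(planted) > 0) {
    # several planted genes may drive one signature; contributions add
    for (s in unique(planted$signature)) {
      rows <- planted[planted$signature == s, , drop = FALSE]
      mu <- intercept + as.vector(expr[, rows$gene, drop = FALSE] %*%
                                    rows$slope)
      act[, s] <- pmax(0, mu + rnorm(n_samples, 0, rows$noise_sd[1]))
    }
  }
  list(expression = expr, activity = act)
}

#' Simulate CNA segmentation with planted recurrent regions
#'
#' Each sample tiles every chromosome with background segments whose
#' seg.mean is N(0, 0.05); each planted recurrent region is altered in a
#' sample with probability `penetrance`, receiving a seg.mean of the
#' planted sign with magnitude uniform in \[0.5, 1.5\].
#'
#' @param genome a [gen_genome()] model.
#' @param n_samples number of samples.
#' @param recurrent_regions optional data.frame with `chrom`, `start`,
#'   `end`, `direction` ("amp" or "del"), `penetrance` in (0, 1\].
#' @param segs_per_chrom background segments per chromosome (default 6).
#' @param noise_sd background seg.mean sd (default 0.05).
#' @param seed RNG seed.
#' @return segment data.frame (`sample`, `chrom`, `start`, `end`,
#'   `n_markers`, `seg_mean`); per sample the segments tile each
#'   chromosome exactly once.
#' @export
gen_cna_segments <- function(genome, n_samples, recurrent_regions = NULL,
                             segs_per_chrom = 6, noise_sd = 0.05, seed = 1) {
  rr <- recurrent_regions
  if (!is.null(rr) && nrow(rr) > 0) {
    if (any(rr$penetrance <= 0 | rr$penetrance > 1))
      stopf("penetrance must be in (0, 1]")
    if (!all(rr$direction %in% c("amp", "del")))
      stopf("direction must be 'amp' or 'del'")
    # overlapping recurrent regions of opposite sign are contradictory
    if (nrow(rr) > 1) {
      ov <- gi_intersect(rr, rr)
      ov <- ov[ov$a_index != ov$b_index, , drop = FALSE]
      if (any(rr$direction[ov$a_index] != rr$direction[ov$b_index]))
        stopf("overlapping recurrent regions of opposite sign")
    }
  }
  set.seed(as.integer(seed))
  sizes <- genome$chrom_sizes
  samples <- sprintf("S%03d", seq_len(n_samples))
  rows <- list()
  for (s in samples) {
    for (cn in names(sizes)) {
      L <- sizes[[cn]]
      bp <- sort(sample.int(L - 1, max(0, segs_per_chrom - 1)))
      cuts <- c(0, bp)
      here <- if (!is.null(rr) && nrow(rr) > 0)
        rr[norm_chrom(rr$chrom) == norm_chrom(cn), , drop = FALSE]
      else rr
      if (!is.null(here) && nrow(here) > 0)
        cuts <- c(cuts, here$start, here$end)
      cuts <- sort(unique(pmin(pmax(cuts, 0), L)))
      cuts <- cuts[cuts < L]
      starts <- cuts
      ends <- c(cuts[-1], L)
      mean <- rnorm(length(starts), 0, noise_sd)
      if (!is.null(here) && nrow(here) > 0) {
        for (i in seq_len(nrow(here))) {
          if (runif(1) <= here$penetrance[i]) {
            sign <- if (here$direction[i] == "amp") 1 else -1
            inside <- starts >= here$start[i] & ends <= here$end[i]
            mean[inside] <- sign * runif(sum(inside), 0.5, 1.5)
          }
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, chrom = cn, start = starts, end = ends,
        n_markers = pmax(1, round((ends - starts) / 1000)),
        seg_mean = mean, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate PWMs, a genome sequence, and planted (non-)disruptive variants
#'
#' Each TF receives a high-information PWM (one dominant base per column)
#' and `n_sites` perfect-consensus binding sites planted at non-overlapping
#' positions in a random background sequence. Half the planted variants
#' change the most informative column of a planted site from its consensus
#' base to the worst base (disruptive truth); the other half fall at least
#' one motif length away from every planted site (neutral truth).
#'
#' @param n_tfs number of transcription factors.
#' @param motif_len motif length (>= 4).
#' @param genome a [gen_genome()] model (sequence is generated per
#'   chromosome).
#' @param n_sites planted sites per TF.
#' @param n_disruptors_per_tf disruptive variants planted per TF
#'   (matched by an equal number of neutral variants).
#' @param dominant_count,minor_count PFM counts for the dominant and the
#'   three minor bases per column (defaults 90 and 3).
#' @param seed RNG seed.
#' @return list with `pwms` (named list of `pwm`), `sequences` (named
#'   character vector per chromosome), `variants` (variant data.frame with
#'   `tf` and logical `truth_disruptive`), and `sites` (interval
#'   data.frame of planted sites, name = TF).
#' @export
gen_pwms_and_variants <- function(n_tfs, motif_len, genome, n_sites = 3,
                                  n_disruptors_per_tf = 1,
                                  dominant_count = 90, minor_count = 3,
                                  seed = 1) {
  if (motif_len < 4) stopf("motif_len must be >= 4")
  sizes <- genome$chrom_sizes
  total <- sum(sizes)
  if (n_tfs * n_sites * motif_len > total)
    stopf("planted site mass exceeds sequence length")
  set.seed(as.integer(seed))
  seqs <- lapply(sizes, function(L)
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""))
  seqs <- unlist(seqs)

  tf_names <- sprintf("TF%02d", seq_len(n_tfs))
  pwms <- list()
  for (tf in tf_names) {
    counts <- matrix(minor_count, 4, motif_len,
                     dimnames = list(DNA_BASES, NULL))
    dom <- sample.int(4, motif_len, replace = TRUE)
    counts[cbind(dom, seq_len(motif_len))] <- dominant_count
    pwms[[tf]] <- new_pwm(tf, counts = counts, pseudocount = 0.8)
  }

  # plant consensus sites, non-overlapping with a motif-length buffer
  n_total_sites <- n_tfs * n_sites
  site_rows <- list()
  occupied <- list()  # per chrom: matrix of taken [start, end) with buffer
  chrom_of <- sample(names(sizes), n_total_sites, replace = TRUE,
                     prob = sizes / sum(sizes))
  k <- 0
  for (tf in tf_names) {
    cons <- DNA_BASES[apply(pwms[[tf]]$prob, 2, which.max)]
    cons_str <- paste(cons, collapse = "")
    for (j in seq_len(n_sites)) {
      k <- k + 1
      cn <- chrom_of[k]
      L <- sizes[[cn]]
      for (try in 1:1000) {
        st <- sample.int(L - motif_len, 1) - 1    # 0-based start
        taken <- occupied[[cn]]
        clash <- !is.null(taken) &&
          any(st < taken[, 2] + motif_len & st + motif_len >
                taken[, 1] - motif_len)
        if (!clash) break
        if (try == 1000) stopf("could not place planted sites; genome too full")
      }
      occupied[[cn]] <- rbind(taken, c(st, st + motif_len))
      substr(seqs[[cn]], st + 1, st + motif_len) <- cons_str
      site_rows[[k]] <- data.frame(chrom = cn, start = st,
                                   end = st + motif_len, name = tf,
                                   stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL

  # disruptive variants: hit the most informative column of a planted site
  var_rows <- list()
  for (tf in tf_names) {
    p <- pwms[[tf]]$prob
    info <- log2(apply(p, 2, max) / apply(p, 2, min))
    col <- which.max(info)
    worst <- DNA_BASES[apply(p, 2, which.min)]
    mysites <- sites[sites$name == tf, , drop = FALSE]
    use <- mysites[rep_len(seq_len(nrow(mysites)), n_disruptors_per_tf), ,
                   drop = FALSE]
    for (i in seq_len(nrow(use))) {
      pos0 <- use$start[i] + col - 1
      ref <- substr(seqs[[use$chrom[i]]], pos0 + 1, pos0 + 1)
      var_rows[[length(var_rows) + 1]] <- data.frame(
        chrom = use$chrom[i], pos = pos0 + 1, ref = ref, alt = worst[col],
        sample = NA_character_, tf = tf, truth_disruptive = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  # neutral variants: uniform positions at least motif_len away from every
  # planted site of every TF
  n_neutral <- n_tfs * n_disruptors_per_tf
  placed <- 0
  while (placed < n_neutral) {
    cn <- sample(names(sizes), 1, prob = sizes / sum(sizes))
    pos0 <- sample.int(sizes[[cn]], 1) - 1
    near <- sites[norm_chrom(sites$chrom) == norm_chrom(cn), , drop = FALSE]
    if (nrow(near) > 0 &&
        any(pos0 >= near$start - motif_len & pos0 < near$end + motif_len))
      next
    ref <- substr(seqs[[cn]], pos0 + 1, pos0 + 1)
    alt <- sample(setdiff(DNA_BASES, ref), 1)
    placed <- placed + 1
    tf_for <- tf_names[((placed - 1) %% n_tfs) + 1]
    var_rows[[length(var_rows) + 1]] <- data.frame(
      chrom = cn, pos = pos0 + 1, ref = ref, alt = alt,
      sample = NA_character_, tf = tf_for, truth_disruptive = FALSE,
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, var_rows)
  rownames(variants) <- NULL
  list(pwms = pwms, sequences = seqs, variants = variants, sites = sites)
}

#' Write a provenance block for a simulated scenario
#'
#' One YAML block per scenario, stored alongside the outputs.
#'
#' @param params named list of generator parameters (including seeds).
#' @param path output path.
#' @export
write_scenario_yaml <- function(params, path) {
  yaml::write_yaml(params, path)
  invisible(path)
}
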