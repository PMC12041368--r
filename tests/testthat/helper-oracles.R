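# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately naive (per-base loops, term-by-term sums) so it
# shares no code path with the implementation it checks.

rand_intervals <- function(n, size, chrom = "chr1", max_len = 50) {
  start <- sample.int(size - max_len, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start,
             end = pmin(start + len, size), stringsAsFactors = FALSE)
}

# per-base membership masks over a [0, size) toy chromosome
base_mask <- function(iv, size) {
  m <- logical(size)
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i])
      m[(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  m
}

# per-base oracle: total overlapping bp between two tracks
oracle_overlap_bp <- function(a, b, size) {
  sum(base_mask(a, size) & base_mask(b, size))
}

# per-base oracle: covered fraction for each target row
oracle_coverage <- function(targets, by, size) {
  mb <- base_mask(by, size)
  vapply(seq_len(nrow(targets)), function(i) {
    idx <- (targets$start[i] + 1):targets$end[i]
    mean(mb[idx])
  }, numeric(1))
}

# per-base oracle: merged track as runs of covered bases
oracle_merge <- function(x, size) {
  m <- base_mask(x, size)
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# term-by-term Poisson upper tail P(X >= k): sums e^-l l^i / i! upward
# from i = k until the terms vanish
oracle_poisson_tail <- function(k, lambda) {
  if (k <= 0) return(1)
  t <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
  total <- 0
  i <- k
  while (t > total * 1e-18 || i < k + 10) {
    total <- total + t
    i <- i + 1
    t <- t * lambda / i
    if (i > k + 10000) break
  }
  total
}

# lm-based OLS slope-test oracle
oracle_ols <- function(x, y) {
  fit <- summary(stats::lm(y ~ x))
  co <- stats::coef(fit)
  list(slope = co["x", "Estimate"], p = co["x", "Pr(>|t|)"])
}

# brute-force normalized PWM window score
oracle_pwm_score <- function(seq, prob) {
  bases <- strsplit(seq, "")[[1]]
  raw <- 0
  for (j in seq_along(bases)) raw <- raw + unname(log2(prob[bases[j], j]))
  rmax <- 0; rmin <- 0
  for (j in seq_len(ncol(prob))) {
    rmax <- rmax + max(log2(prob[, j]))
    rmin <- rmin + min(log2(prob[, j]))
  }
  (raw - rmin) / (rmax - rmin)
}

toy_genome <- function(size = 10000, n_chroms = 1) {
  gen_genome(n_chroms, size)
}
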