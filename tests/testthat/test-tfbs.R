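make_pwm <- function(probs, tf = "T1") {
  m <- matrix(probs, 4, length(probs) / 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  germsoma:::new_pwm(tf, prob = m, pseudocount = 0.8)
}

test_that("consensus scores 1, anti-consensus 0, oracle agreement", {
  g <- gen_genome(1, 10000)
  tf <- gen_pwms_and_variants(4, 8, g, n_sites = 2, seed = 1)
  for (p in tf$pwms) {
    cons <- paste(rownames(p$prob)[apply(p$prob, 2, which.max)],
                  collapse = "")
    anti <- paste(rownames(p$prob)[apply(p$prob, 2, which.min)],
                  collapse = "")
    expect_equal(score_site(cons, p), 1)
    expect_equal(score_site(anti, p), 0)
  }
  # random PWM / sequence pairs against the brute-force log-sum oracle
  set.seed(14)
  for (i in 1:25) {
    L <- sample(4:10, 1)
    counts <- matrix(rpois(4 * L, 20) + 1, 4,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    p <- germsoma:::new_pwm("rand", counts = counts)
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    expect_equal(score_site(seq, p), oracle_pwm_score(seq, p$prob),
                 tolerance = 1e-12)
  }
  expect_error(score_site("ACGT", make_pwm(rep(0.25, 16))),
               "zero-information")
})

test_that("strand symmetry holds for scanning and palindromes", {
  set.seed(3)
  counts <- matrix(rpois(4 * 6, 15) + 1, 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- germsoma:::new_pwm("x", counts = counts)
  seq <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
  sites <- scan_sites(seq, p)
  # a window's reverse-strand score equals the forward score of its
  # reverse complement
  for (i in sample(which(sites$strand == "-"), 5)) {
    st <- sites$start[i]
    win <- substr(seq, st + 1, st + 6)
    expect_equal(sites$score[i], score_site(revcomp(win), p),
                 tolerance = 1e-12)
  }
  # palindromic motif: best scores identical across strands
  pal <- make_pwm(c(.85, .05, .05, .05,  .05, .85, .05, .05,
                    .05, .05, .85, .05,  .05, .05, .05, .85), "pal")
  # columns: A C G T -> reverse complement is itself
  s2 <- scan_sites(seq, pal)
  expect_equal(max(s2$score[s2$strand == "+"]),
               max(s2$score[s2$strand == "-"]), tolerance = 1e-12)
})

test_that("planted disruptive variants are flagged, neutral ones are not", {
  g <- gen_genome(1, 10000)
  tf <- gen_pwms_and_variants(4, 8, g, n_sites = 2, seed = 8)
  for (i in seq_len(nrow(tf$variants))) {
    v <- tf$variants[i, ]
    call <- score_variant(v, tf$sequences, tf$pwms[[v$tf]])
    if (v$truth_disruptive) {
      expect_equal(call$ref_score, 1)
      expect_true(call$disrupting)
      expect_gte(abs(call$delta), 0.10)
    } else {
      expect_false(call$disrupting)
    }
  }
  # a ref allele inconsistent with the sequence is an input error
  v <- tf$variants[1, ]
  v$ref <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  expect_error(score_variant(v, tf$sequences, tf$pwms[[v$tf]]),
               "disagrees")
})

test_that("germline disruption counts are per TF within elements", {
  g <- gen_genome(1, 10000)
  tf <- gen_pwms_and_variants(2, 8, g, n_sites = 2,
                              n_disruptors_per_tf = 2, seed = 12)
  elements <- genomic_intervals(tf$sites$chrom,
                                pmax(0, tf$sites$start - 10),
                                tf$sites$end + 10)
  res <- germline_disrupted_tfs(tf$variants, tf$pwms, tf$sequences,
                                elements)
  # two planted disruptors per TF, all inside elements
  for (nm in names(tf$pwms))
    expect_equal(res$counts$n_disrupting[res$counts$tf_name == nm], 2L)
  # counts sorted descending
  expect_true(all(diff(res$counts$n_disrupting) <= 0))
  # no variants inside elements -> empty table
  far <- genomic_intervals("chr1", 0, 1)
  res2 <- germline_disrupted_tfs(tf$variants, tf$pwms, tf$sequences, far)
  expect_equal(nrow(res2$counts), 0)
  # one variant disrupting two TFs contributes to each: duplicate the PWM
  pwms2 <- tf$pwms
  pwms2[["COPY"]] <- germsoma:::new_pwm("COPY", prob = tf$pwms[[1]]$prob,
                                        pseudocount = 0.8)
  v1 <- tf$variants[tf$variants$truth_disruptive &
                      tf$variants$tf == names(tf$pwms)[1], ][1, ]
  res3 <- germline_disrupted_tfs(v1, pwms2[c(1, 3)], tf$sequences,
                                 elements)
  expect_equal(res3$counts$n_disrupting, c(1L, 1L))
})

test_that("somatic binding-site burden applies the three-mutation filter", {
  g <- gen_genome(1, 10000)
  tf <- gen_pwms_and_variants(1, 8, g, n_sites = 1, seed = 21)
  site <- tf$sites[1, ]
  el <- genomic_intervals(site$chrom, pmax(0, site$start - 20),
                          site$end + 20, name = "elem1")
  mk_snvs <- function(n) {
    pos <- site$start + seq_len(n)          # inside the motif, 1-based
    data.frame(chrom = site$chrom, pos = pos,
               ref = substring(tf$sequences[[site$chrom]], pos, pos),
               alt = "A", sample = sprintf("S%d", seq_len(n)))
  }
  b3 <- somatic_tf_burden(el, mk_snvs(3), tf$pwms, tf$sequences)
  expect_equal(b3$n_mutations, 3)
  expect_true(b3$passes_filter)        # exactly at the >= 3 boundary
  b2 <- somatic_tf_burden(el, mk_snvs(2), tf$pwms, tf$sequences)
  expect_false(b2$passes_filter)
  # an SNV in the element but outside all predicted sites counts nowhere
  outside <- data.frame(chrom = site$chrom, pos = site$end + 15,
                        ref = "A", alt = "C", sample = "S1")
  b0 <- somatic_tf_burden(el, outside, tf$pwms, tf$sequences)
  expect_equal(nrow(b0), 0)
  # element without sequence
  el_bad <- genomic_intervals("chrZ", 0, 100)
  expect_error(somatic_tf_burden(el_bad, mk_snvs(1), tf$pwms,
                                 tf$sequences), "no sequence")
})

test_that("TF list intersection is exact on whole names", {
  expect_equal(intersect_tf_lists(c("A", "B", "C"), c("B", "C", "D")),
               c("B", "C"))
  expect_equal(intersect_tf_lists(c("A"), c("B")), character())
  # dimer names are atomic
  expect_equal(intersect_tf_lists(c("PPARA::RXRA", "RXRA"),
                                  c("PPARA::RXRA", "KLF9")),
               "PPARA::RXRA")
  expect_equal(intersect_tf_lists(c("RXRA"), c("PPARA::RXRA")),
               character())
})
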