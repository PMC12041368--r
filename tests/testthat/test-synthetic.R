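test_that("genome construction is deterministic and validated", {
  g <- gen_genome(2, 1e6, seed = 1)
  expect_equal(g$chrom_names, c("chr1", "chr2"))
  expect_equal(unname(g$chrom_sizes), c(1e6, 1e6))
  expect_identical(gen_genome(1, 10000, seed = 7), gen_genome(1, 10000, seed = 7))
  expect_error(gen_genome(1, 500), ">= 10,000")
  expect_error(gen_genome(0, 1e6), ">= 1")
})

test_that("annotation tracks are disjoint within class, sorted, in bounds", {
  g <- gen_genome(2, 20000)
  tracks <- gen_annotation_tracks(g, c("enhancer", "promoter"),
                                  n_per_class = 15, mean_len = 200, seed = 3)
  expect_named(tracks, c("enhancer", "promoter"))
  for (tr in tracks) {
    expect_true(all(tr$end > tr$start))
    for (cn in unique(tr$chrom)) {
      sub <- tr[tr$chrom == cn, ]
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))  # disjoint
      expect_true(all(sub$end <= g$chrom_sizes[[cn]]))
    }
    # sorted by (chrom, start)
    expect_identical(tr, germsoma:::gi_sort(tr))
  }
  expect_error(gen_annotation_tracks(gen_genome(1, 10000), "x",
                                     n_per_class = 500, mean_len = 5000),
               "exceeds chromosome size")
})

test_that("SNV generation: empty-rate contract, determinism, alleles", {
  g <- gen_genome(1, 50000)
  expect_equal(nrow(gen_snvs(g, 5, 0, seed = 1)), 0)
  a <- gen_snvs(g, 5, 1e-3, seed = 5)
  b <- gen_snvs(g, 5, 1e-3, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$ref != a$alt))
  expect_true(all(c(a$ref, a$alt) %in% c("A", "C", "G", "T")))
  expect_true(all(a$pos >= 1 & a$pos <= 50000))
  expect_error(gen_snvs(list(chrom_sizes = numeric()), 5, 1e-3), "empty")
  expect_error(gen_snvs(g, 5, 1e-3,
                        hotspots = data.frame(chrom = "chr1", start = 0,
                                              end = 100,
                                              rate_multiplier = 0.5)),
               "> 1")
})

test_that("hotspot mutation density approaches its rate multiplier", {
  g <- gen_genome(1, 50000)
  hs <- data.frame(chrom = "chr1", start = 10000, end = 11000,
                   rate_multiplier = 50)
  in_hot <- 0; in_bg <- 0
  for (seed in 1:25) {
    snv <- gen_snvs(g, 20, 1e-4, hotspots = hs, seed = seed)
    hot <- snv$pos - 1 >= 10000 & snv$pos - 1 < 11000
    in_hot <- in_hot + sum(hot)
    in_bg <- in_bg + sum(!hot)
  }
  dens_hot <- in_hot / 1000
  dens_bg <- in_bg / 49000
  expect_gt(dens_hot / dens_bg, 50 * 0.8)
  expect_lt(dens_hot / dens_bg, 50 * 1.2)
})

test_that("planted expression-activity associations are recoverable", {
  genes <- sprintf("G%02d", 1:20)
  sigs <- sprintf("SBS%d", 1:5)
  planted <- data.frame(gene = "G01", signature = "SBS1",
                        slope = 2, noise_sd = 0.01)
  sx <- gen_signature_expression(89, genes, sigs, planted, seed = 2)
  expect_true(all(sx$activity >= 0))
  fit <- fit_pair(sx$expression[, "G01"], sx$activity[, "SBS1"])
  expect_lt(abs(fit$slope - 2), 0.1)
  expect_identical(sx, gen_signature_expression(89, genes, sigs, planted,
                                                seed = 2))
  expect_error(gen_signature_expression(10, c("a", "a"), sigs),
               "duplicate gene ids")
  expect_error(gen_signature_expression(
    10, genes, sigs, data.frame(gene = "nope", signature = "SBS1",
                                slope = 1, noise_sd = 0)),
    "not in gene set")
})

test_that("with nothing planted, pairwise regressions are calibrated", {
  sx <- gen_signature_expression(89, sprintf("G%03d", 1:100),
                                 sprintf("S%02d", 1:10), seed = 9)
  scan <- assoc_scan(sx$expression, sx$activity, colnames(sx$expression))
  frac <- mean(scan$results$p_value < 0.05)
  mc <- sqrt(0.05 * 0.95 / nrow(scan$results))
  expect_lt(abs(frac - 0.05), 3 * mc + 1e-12)
})

test_that("CNA segments tile each chromosome once per sample", {
  g <- gen_genome(2, 100000)
  rr <- data.frame(chrom = "chr1", start = 20000, end = 30000,
                   direction = "amp", penetrance = 1.0)
  seg <- gen_cna_segments(g, 10, rr, seed = 4)
  for (s in unique(seg$sample)) {
    for (cn in c("chr1", "chr2")) {
      sub <- seg[seg$sample == s & seg$chrom == cn, ]
      sub <- sub[order(sub$start), ]
      expect_equal(sub$start[1], 0)
      expect_equal(sub$end[nrow(sub)], 1e5)
      expect_equal(sub$start[-1], sub$end[-nrow(sub)])  # no gap, no overlap
    }
  }
  # penetrance 1: every sample amplified across the region
  for (s in unique(seg$sample)) {
    inside <- seg$sample == s & seg$chrom == "chr1" &
      seg$start >= 20000 & seg$end <= 30000
    expect_true(all(seg$seg_mean[inside] >= 0.5))
  }
})

test_that("CNA penetrance behaves binomially and bad regions error", {
  g <- gen_genome(1, 100000)
  rr <- data.frame(chrom = "chr1", start = 40000, end = 50000,
                   direction = "amp", penetrance = 0.6)
  seg <- gen_cna_segments(g, 100, rr, seed = 8)
  amp <- vapply(unique(seg$sample), function(s) {
    any(seg$sample == s & seg$start >= 40000 & seg$end <= 50000 &
          seg$seg_mean >= 0.5)
  }, logical(1))
  expect_gte(sum(amp), qbinom(0.0005, 100, 0.6))
  expect_lte(sum(amp), qbinom(0.9995, 100, 0.6))
  bad <- data.frame(chrom = "chr1", start = c(0, 5000), end = c(10000, 15000),
                    direction = c("amp", "del"), penetrance = 1)
  expect_error(gen_cna_segments(g, 2, bad), "opposite sign")
})

test_that("generated PWMs are column-stochastic with planted consensus sites", {
  g <- gen_genome(1, 10000)
  tf <- gen_pwms_and_variants(3, 8, g, n_sites = 2, seed = 6)
  for (p in tf$pwms)
    expect_equal(colSums(p$prob), rep(1, 8), ignore_attr = TRUE,
                 tolerance = 1e-12)
  # every planted site carries the consensus sequence -> score 1
  for (i in seq_len(nrow(tf$sites))) {
    s <- tf$sites[i, ]
    win <- substr(tf$sequences[[s$chrom]], s$start + 1, s$end)
    expect_equal(score_site(win, tf$pwms[[s$name]]), 1)
  }
  # half disruptive, half neutral
  expect_equal(sum(tf$variants$truth_disruptive),
               sum(!tf$variants$truth_disruptive))
  expect_identical(tf, gen_pwms_and_variants(3, 8, g, n_sites = 2, seed = 6))
  expect_error(gen_pwms_and_variants(10, 200, g, n_sites = 100), "exceeds")
})
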