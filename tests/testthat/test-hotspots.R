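test_that("recurrence tally counts distinct samples per position", {
  snvs <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(100, 100, 100, 50, 60),
    ref = "A", alt = "G",
    sample = c("S1", "S1", "S2", "S1", "S1"))  # S1 duplicated at chr1:100
  t <- tally_recurrence(snvs)
  expect_equal(t$histogram,
               data.frame(k = c(2L, 1L), n_positions = c(1L, 2L)))
  expect_equal(t$total_snvs, 4)       # distinct (sample, position) events
  expect_equal(t$unique_positions, 3)
  expect_equal(t$n_records, 5L)
  empty <- tally_recurrence(snvs[0, ])
  expect_equal(empty$total_snvs, 0)
  expect_equal(empty$unique_positions, 0)
})

test_that("tally invariants reproduce totals from a printed histogram", {
  hist <- read.delim(system.file("extdata", "pcawg_ovary_snv_recurrence.tsv",
                                 package = "germsoma"))
  t <- tally_from_histogram(hist$k, hist$n_positions)
  expect_identical(t$total_snvs, 981675)
  expect_identical(t$unique_positions, 981172)
})

test_that("tally conservation holds on synthetic runs", {
  snv <- gen_snvs(gen_genome(1, 50000), 10, 5e-4, seed = 3)
  t <- tally_recurrence(snv)
  events <- nrow(unique(snv[, c("chrom", "pos", "sample")]))
  expect_equal(sum(t$histogram$k * t$histogram$n_positions), events)
  expect_equal(t$total_snvs, events)
  expect_equal(t$unique_positions,
               nrow(unique(snv[, c("chrom", "pos")])))
})

test_that("element burden test equals the closed-form Poisson tail", {
  el <- data.frame(chrom = "chr1", start = 0, end = 1000)
  none <- data.frame(chrom = character(), pos = numeric(),
                     sample = character())
  expect_equal(test_element(el, none, 0.001)$p_value, 1)  # P(X >= 0)
  # lambda = 1, observed = 3: 1 - e^-1 (1 + 1 + 1/2)
  snv3 <- data.frame(chrom = "chr1", pos = c(10, 20, 30), sample = "S1")
  p <- test_element(el, snv3, 0.001)$p_value
  expect_equal(p, 1 - exp(-1) * 2.5, tolerance = 1e-12)
  expect_error(test_element(el, snv3, 0), "> 0")
  expect_error(test_element(data.frame(chrom = "chr1", start = 5, end = 5),
                            snv3, 0.001), "width")
})

test_that("Poisson upper tail matches brute-force summation", {
  for (lambda in c(0.5, 1, 5, 20)) {
    for (k in c(0:10, 25, 50)) {
      got <- ppois(k - 1, lambda, lower.tail = FALSE)
      expect_equal(got, oracle_poisson_tail(k, lambda), tolerance = 1e-12)
    }
  }
})

test_that("scan_track recovers a planted hotspot as the top call", {
  g <- gen_genome(1, 200000)
  track <- gen_annotation_tracks(g, "enhancer", 100, 600, seed = 2)$enhancer
  widths <- track$end - track$start
  hot_idx <- which.max(widths)
  hs <- data.frame(chrom = track$chrom[hot_idx],
                   start = track$start[hot_idx],
                   end = track$end[hot_idx], rate_multiplier = 50)
  snv <- gen_snvs(g, 30, 2e-4, hotspots = hs, seed = 2)
  res <- scan_track(track, snv, fdr = 0.05)
  expect_equal(which.min(res$q_value), hot_idx)
  expect_true(res$significant[hot_idx])
})

test_that("under uniform mutations the track-wide false calls stay rare", {
  g <- gen_genome(1, 200000)
  track <- gen_annotation_tracks(g, "enhancer", 100, 600, seed = 4)$enhancer
  n_sig <- vapply(1:20, function(seed) {
    snv <- gen_snvs(g, 20, 2e-4, seed = seed)
    sum(scan_track(track, snv, fdr = 0.05)$significant)
  }, numeric(1))
  expect_lte(mean(n_sig), 0.05 * 100)
})

test_that("enrichment strata aggregate consistently", {
  res <- data.frame(
    chrom = rep(c("chr1", "chr2"), c(6, 4)),
    start = c(seq(0, 500, 100), seq(0, 300, 100)),
    end = c(seq(50, 550, 100), seq(50, 350, 100)),
    annotation = "coding",
    significant = c(TRUE, rep(FALSE, 5), TRUE, TRUE, FALSE, FALSE))
  gw <- enrich_elements(res, "genome")
  expect_equal(gw$n_total, 10)
  expect_equal(gw$n_significant, 3)
  expect_equal(gw$percent, 30)
  by_chrom <- enrich_elements(res, "chromosome")
  expect_equal(sum(by_chrom$n_total), gw$n_total)
  expect_equal(sum(by_chrom$n_significant), gw$n_significant)
  # genome-wide percent is the count-weighted combination of chromosomes
  expect_equal(100 * sum(by_chrom$n_significant) / sum(by_chrom$n_total),
               gw$percent, tolerance = 0.01)
})

test_that("locus-level enrichment mirrors the percentage convention", {
  # 6 coding elements inside the locus, exactly 1 significant -> 16.67
  res <- data.frame(chrom = "chr1",
                    start = seq(1000, 6000, 1000),
                    end = seq(1400, 6400, 1000),
                    annotation = "coding",
                    significant = c(TRUE, rep(FALSE, 5)))
  loci <- data.frame(locus_id = c("LA", "LB"), chrom = "chr1",
                     start = c(0, 50000), end = c(10000, 60000))
  enr <- enrich_elements(res, loci)
  la <- enr[enr$stratum == "LA", ]
  expect_equal(la$n_total, 6)
  expect_equal(la$percent, 16.67)
  lb <- enr[enr$stratum == "LB", ]
  expect_equal(lb$n_total, 0)
  expect_true(is.na(lb$percent))
})
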