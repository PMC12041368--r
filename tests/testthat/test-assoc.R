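test_that("fit_pair handles exact, noisy and degenerate inputs", {
  # perfect linearity: exact slope, p at numerical zero
  fit <- fit_pair(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(fit$slope, 2)
  expect_lt(fit$p_value, 1e-12)
  # noisy line: frozen against the lm oracle
  fit <- fit_pair(c(1, 2, 3, 4), c(2.1, 3.9, 6.2, 7.8))
  expect_equal(fit$slope, 1.94, tolerance = 1e-12)
  expect_equal(fit$p_value, 0.002171670245, tolerance = 1e-9)
  # constant activity
  fit <- fit_pair(c(1, 2, 3, 4), c(5, 5, 5, 5))
  expect_equal(fit$slope, 0)
  expect_equal(fit$p_value, 1)
  # zero expression variance is flagged degenerate
  fit <- fit_pair(c(2, 2, 2, 2), c(1, 3, 2, 4))
  expect_true(fit$degenerate)
  expect_equal(fit$p_value, 1)
  # pairwise NA dropping
  fit <- fit_pair(c(1, 2, 3, 4, NA), c(2, 4, 6, 8, 1))
  expect_equal(fit$n_samples, 4)
  expect_error(fit_pair(c(1, NA), c(2, 3)), ">= 3")
})

test_that("slope p-values match the closed-form t-test oracle", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.3 * x + rnorm(n)
    fit <- fit_pair(x, y)
    o <- oracle_ols(x, y)
    expect_equal(fit$slope, o$slope, tolerance = 1e-10)
    expect_equal(fit$p_value, o$p, tolerance = 1e-10)
  }
})

test_that("the vectorized scan equals per-pair fits", {
  set.seed(5)
  X <- matrix(rlnorm(30 * 6), 30, 6,
              dimnames = list(sprintf("S%02d", 1:30), sprintf("g%d", 1:6)))
  Y <- matrix(rnorm(30 * 4, 5), 30, 4,
              dimnames = list(sprintf("S%02d", 1:30), sprintf("s%d", 1:4)))
  scan <- assoc_scan(X, Y, colnames(X))
  for (i in sample(nrow(scan$results), 10)) {
    r <- scan$results[i, ]
    fit <- fit_pair(log2(X[, r$gene] + 1), Y[, r$signature])
    expect_equal(r$p_value, fit$p_value, tolerance = 1e-12)
    expect_equal(r$slope, fit$slope, tolerance = 1e-12)
  }
})

test_that("scan recovers a planted association and respects alpha", {
  genes <- sprintf("G%02d", 1:30)
  sigs <- sprintf("SBS%d", 1:3)
  planted <- data.frame(gene = "G01", signature = "SBS2",
                        slope = 2, noise_sd = 0.05)
  sx <- gen_signature_expression(89, genes, sigs, planted, seed = 3)
  gene_list <- genes[1:5]
  scan <- assoc_scan(sx$expression, sx$activity, gene_list)
  hit <- scan$results[scan$results$gene == "G01" &
                        scan$results$signature == "SBS2", ]
  expect_true(hit$significant)
  # at most a few false positives among the other 14 tests
  expect_lte(sum(scan$results$significant), 1 + 4)
  # alpha = 0 silences everything
  scan0 <- assoc_scan(sx$expression, sx$activity, gene_list, alpha = 0)
  expect_equal(sum(scan0$results$significant), 0)
  # absent list genes are skipped without corrupting counts
  expect_message(
    scan2 <- assoc_scan(sx$expression, sx$activity,
                        c(gene_list, "NOT_A_GENE")),
    "absent")
  expect_equal(scan2$counts$n_significant, scan$counts$n_significant)
  expect_equal(scan2$missing_genes, "NOT_A_GENE")
  expect_error(assoc_scan(sx$expression[1:3, ],
                          sx$activity[4:6, ], gene_list), "shared")
})

test_that("permutation p-value is the strict-exceedance fraction", {
  genes <- sprintf("G%03d", 1:120)
  sigs <- sprintf("SBS%d", 1:4)
  planted <- data.frame(gene = genes[1:10], signature = rep(sigs, 3)[1:10],
                        slope = 3, noise_sd = 0.05)
  # overwriting collisions: keep one planted pair per signature
  planted <- planted[!duplicated(planted$signature), ]
  sx <- gen_signature_expression(60, genes, sigs, planted, seed = 10)
  perm <- assoc_permutation_test(sx$expression, sx$activity,
                                 planted$gene, n_iter = 500, seed = 1)
  # strongly planted list beats every random list: strict-exceed edge
  expect_equal(perm$n_exceed, 0)
  expect_equal(perm$p_value, 0)
  expect_gt(perm$observed, max(perm$null_counts))
  expect_length(perm$null_counts, 500)
  expect_error(assoc_permutation_test(sx$expression, sx$activity,
                                      planted$gene, n_iter = 0), ">= 1")
  expect_error(assoc_permutation_test(sx$expression[, 1:4], sx$activity,
                                      colnames(sx$expression)[1:4]),
               "more genes")
})

test_that("planting a strong association never increases the permutation p", {
  genes <- sprintf("G%03d", 1:80)
  sigs <- sprintf("SBS%d", 1:4)
  for (seed in 1:3) {
    base <- gen_signature_expression(50, genes, sigs, seed = seed)
    lst <- genes[1:10]
    p0 <- assoc_permutation_test(base$expression, base$activity, lst,
                                 n_iter = 300, seed = 99)$p_value
    planted <- data.frame(gene = lst[1:3], signature = sigs[1:3],
                          slope = 4, noise_sd = 0.05)
    strong <- gen_signature_expression(50, genes, sigs, planted, seed = seed)
    p1 <- assoc_permutation_test(strong$expression, strong$activity, lst,
                                 n_iter = 300, seed = 99)$p_value
    expect_lte(p1, p0)
  }
})

test_that("signatures map to their proposed etiology groups", {
  expect_equal(map_etiology("SBS26"), "mismatch repair deficiency")
  expect_equal(map_etiology("DBS7"), "mismatch repair deficiency")
  expect_equal(map_etiology("ID1"), "homologous recombination deficiency")
  expect_equal(map_etiology("SBS40"), "age-related mutagenesis")
  expect_equal(map_etiology("SBS35"), "platinum chemotherapy treatment")
  expect_equal(map_etiology("SBS18"), "environmental factors")
  expect_equal(map_etiology("SBS13"), "APOBEC mutagenesis")
  expect_equal(map_etiology("SBS99"), "unassigned")
  expect_equal(map_etiology(c("SBS2", "XYZ")),
               c("APOBEC mutagenesis", "unassigned"))
})
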