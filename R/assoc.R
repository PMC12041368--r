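# Gene x signature association scan and the permutation gene-set null.
# The scan regresses signature activity on (log2-transformed) gene
# expression by ordinary least squares; significance is the nominal
# two-sided slope t-test at p < alpha with no multiplicity correction
# (BH is available behind a flag). The permutation test draws random gene
# lists of equal size from the whole expression matrix and asks how often
# a random list yields strictly more significant pairs than the real one.

#' Regress one signature's activity on one gene's expression
#'
#' Ordinary least squares with a two-sided t-test on the slope. Samples
#' with a missing value in either vector are dropped pairwise. Zero
#' expression variance yields a degenerate result (slope 0, p 1); a
#' constant activity vector likewise gives slope 0, p 1.
#'
#' @param expr per-sample expression values.
#' @param activity per-sample signature activities (same sample order).
#' @param gene,signature optional labels carried into the result.
#' @return one-row data.frame: `gene`, `signature`, `slope`, `intercept`,
#'   `p_value`, `n_samples`, `degenerate`.
#' @export
fit_pair <- function(expr, activity, gene = NA_character_,
                     signature = NA_character_) {
  if (length(expr) != length(activity))
    stopf("expr and activity lengths differ")
  keep <- stats::complete.cases(expr, activity)
  x <- as.numeric(expr[keep]); y <- as.numeric(activity[keep])
  n <- length(x)
  if (n < 3) stopf("need >= 3 complete observations")
  res <- ols_slope_test(x, y)
  data.frame(gene = gene, signature = signature,
             slope = res$slope, intercept = res$intercept,
             p_value = res$p, n_samples = n,
             degenerate = res$degenerate, stringsAsFactors = FALSE)
}

# closed-form simple OLS slope + two-sided t-test
ols_slope_test <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0)
    return(list(slope = 0, intercept = mean(y), p = 1, degenerate = TRUE))
  syy <- sum((y - mean(y))^2)
  if (syy == 0)
    return(list(slope = 0, intercept = mean(y), p = 1, degenerate = FALSE))
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- max(0, syy - slope^2 * sxx)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- if (se == 0) sign(slope) * Inf else slope / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(slope = slope, intercept = intercept, p = p, degenerate = FALSE)
}

# Vectorized p-value/slope matrices for all (gene, signature) pairs.
# Requires complete matrices; identical to fit_pair applied cell-wise.
pair_stats_matrix <- function(X, Y) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  sxx <- colSums(Xc^2)
  syy <- colSums(Yc^2)
  sxy <- crossprod(Xc, Yc)               # genes x signatures
  slope <- sxy / sxx
  # rss_{g,s} = syy_s - sxy_{g,s}^2 / sxx_g
  rss <- pmax(sweep(-(sxy^2) / sxx, 2, syy, "+"), 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- ifelse(se == 0, ifelse(slope == 0, 0, Inf), abs(slope) / se)
  p <- matrix(2 * stats::pt(-as.vector(tval), df = n - 2),
              nrow(tval), ncol(tval), dimnames = dimnames(tval))
  p[sxx == 0, ] <- 1
  slope[sxx == 0, ] <- 0
  p[, syy == 0] <- 1
  slope[, syy == 0] <- 0
  list(slope = slope, p = p)
}

prep_matrices <- function(expr_matrix, activity_matrix, log2_expr = TRUE) {
  common <- intersect(rownames(expr_matrix), rownames(activity_matrix))
  if (length(common) == 0) stopf("no samples shared between matrices")
  if (length(common) < 3) stopf("need >= 3 shared samples")
  X <- expr_matrix[common, , drop = FALSE]
  Y <- activity_matrix[common, , drop = FALSE]
  if (log2_expr) X <- log2(X + 1)
  list(X = X, Y = Y)
}

#' Scan a gene list against all signatures
#'
#' One OLS fit per (gene in list) x (signature); genes absent from the
#' expression matrix are skipped (and reported). Per-signature counts use
#' the nominal p < alpha with no multiple-testing correction; BH-adjusted
#' significance is additionally reported when `bh = TRUE`.
#'
#' @param expr_matrix samples x genes expression matrix.
#' @param activity_matrix samples x signatures activity matrix (samples
#'   intersected with the expression matrix by rowname).
#' @param gene_list character vector of susceptibility genes.
#' @param alpha nominal significance threshold (default 0.05).
#' @param log2_expr log2(x+1)-transform expression before fitting
#'   (default TRUE).
#' @param bh also compute BH-adjusted q-values across all pairs.
#' @return list with `results` (one row per pair), `counts` (per-signature
#'   significant-gene counts) and `missing_genes`.
#' @export
assoc_scan <- function(expr_matrix, activity_matrix, gene_list,
                       alpha = 0.05, log2_expr = TRUE, bh = FALSE) {
  m <- prep_matrices(expr_matrix, activity_matrix, log2_expr)
  missing <- setdiff(gene_list, colnames(m$X))
  if (length(missing))
    message(sprintf("assoc_scan: %d gene(s) absent from expression matrix",
                    length(missing)))
  genes <- intersect(gene_list, colnames(m$X))
  if (length(genes) == 0) stopf("no gene_list genes present in matrix")
  X <- m$X[, genes, drop = FALSE]
  if (anyNA(X) || anyNA(m$Y)) {
    rows <- list()
    for (g in genes) for (s in colnames(m$Y))
      rows[[length(rows) + 1]] <- fit_pair(X[, g], m$Y[, s], g, s)
    results <- do.call(rbind, rows)
  } else {
    st <- pair_stats_matrix(X, m$Y)
    results <- data.frame(
      gene = rep(genes, times = ncol(m$Y)),
      signature = rep(colnames(m$Y), each = length(genes)),
      slope = as.vector(st$slope),
      p_value = as.vector(st$p),
      n_samples = nrow(X), stringsAsFactors = FALSE)
  }
  results$significant <- results$p_value < alpha
  if (bh) {
    results$q_value <- stats::p.adjust(results$p_value, method = "BH")
    results$significant_bh <- results$q_value < alpha
  }
  counts <- data.frame(
    signature = colnames(m$Y),
    n_significant = vapply(colnames(m$Y), function(s)
      sum(results$significant[results$signature == s]), integer(1)),
    n_genes = length(genes), row.names = NULL, stringsAsFactors = FALSE)
  list(results = results, counts = counts, missing_genes = missing)
}

#' Permutation gene-set test for signature associations
#'
#' The observed statistic is the total number of significant
#' (gene, signature) pairs for the supplied list. Each iteration samples
#' an equally sized gene list uniformly without replacement from all
#' expression genes and recounts; the p-value is the fraction of
#' iterations whose count strictly exceeds the observed count
#' (`N / n_iter`). An optional (n+1)/(N+1)-style small-sample correction
#' is off by default.
#'
#' @param expr_matrix samples x genes expression matrix (must contain more
#'   genes than the list).
#' @param activity_matrix samples x signatures activity matrix.
#' @param gene_list character vector of susceptibility genes.
#' @param n_iter permutation iterations (default 10,000).
#' @param alpha per-pair significance threshold.
#' @param seed RNG seed.
#' @param log2_expr log2(x+1)-transform expression before fitting.
#' @param plus_one apply the +1/(n+1) small-sample correction.
#' @return list: `gene_list_size`, `n_iter`, `observed`, `n_exceed`,
#'   `p_value`, `null_counts` (length `n_iter`, retained for plotting).
#' @export
assoc_permutation_test <- function(expr_matrix, activity_matrix, gene_list,
                                   n_iter = 10000, alpha = 0.05, seed = 1,
                                   log2_expr = TRUE, plus_one = FALSE) {
  if (n_iter < 1) stopf("n_iter must be >= 1")
  m <- prep_matrices(expr_matrix, activity_matrix, log2_expr)
  genes <- intersect(gene_list, colnames(m$X))
  if (length(genes) == 0) stopf("no gene_list genes present in matrix")
  G <- ncol(m$X)
  if (G <= length(genes))
    stopf("expression matrix must contain more genes than the list")
  # The gene x signature p-matrix is fixed across iterations, so each
  # iteration reduces to summing precomputed per-gene significant-pair
  # counts over a random gene subset.
  st <- pair_stats_matrix(m$X, m$Y)
  per_gene <- rowSums(st$p < alpha)
  names(per_gene) <- colnames(m$X)
  observed <- sum(per_gene[genes])
  set.seed(as.integer(seed))
  null_counts <- vapply(seq_len(n_iter), function(i)
    sum(per_gene[sample.int(G, length(genes))]), numeric(1))
  n_exceed <- sum(null_counts > observed)
  p <- if (plus_one) (n_exceed + 1) / (n_iter + 1) else n_exceed / n_iter
  list(gene_list_size = length(genes), n_iter = n_iter,
       observed = observed, n_exceed = n_exceed, p_value = p,
       null_counts = null_counts)
}

#' Default signature etiology grouping
#'
#' COSMIC-proposed etiologies for the signatures recurrently associated
#' with ovarian cancer risk genes: mismatch repair deficiency, homologous
#' recombination deficiency, age-related mutagenesis, platinum
#' chemotherapy treatment, environmental factors, and APOBEC mutagenesis.
#'
#' @return named character vector mapping signature id to group.
#' @export
default_etiology_map <- function() {
  c(SBS26 = "mismatch repair deficiency",
    DBS7 = "mismatch repair deficiency",
    SBS3 = "homologous recombination deficiency",
    ID1 = "homologous recombination deficiency",
    ID2 = "homologous recombination deficiency",
    ID6 = "homologous recombination deficiency",
    ID8 = "homologous recombination deficiency",
    SBS40 = "age-related mutagenesis",
    SBS5 = "age-related mutagenesis",
    SBS1 = "age-related mutagenesis",
    ID4 = "age-related mutagenesis",
    ID5 = "age-related mutagenesis",
    DBS4 = "age-related mutagenesis",
    SBS35 = "platinum chemotherapy treatment",
    DBS5 = "platinum chemotherapy treatment",
    SBS18 = "environmental factors",
    DBS2 = "environmental factors",
    SBS2 = "APOBEC mutagenesis",
    SBS13 = "APOBEC mutagenesis",
    DBS11 = "APOBEC mutagenesis")
}

#' Map signature ids to etiology groups
#'
#' @param signature_id character vector of signature ids.
#' @param etiology_map named vector (default [default_etiology_map()]).
#' @return group labels; unknown signatures map to "unassigned".
#' @export
map_etiology <- function(signature_id, etiology_map = default_etiology_map()) {
  out <- unname(etiology_map[signature_id])
  out[is.na(out)] <- "unassigned"
  out
}
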