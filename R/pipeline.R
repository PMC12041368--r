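# End-to-end orchestration from a single config (YAML file or list):
# simulate -> assoc -> loci -> hotspots -> cna -> tfbs -> report. One
# global seed fans out to deterministic per-stage sub-seeds, so any stage
# is reproducible in isolation; a manifest records parameters, seeds and
# output checksums. Stages write plain TSV/BED so the report can be
# regenerated from saved outputs alone.

default_config <- function() {
  list(
    seed = 1,
    out_dir = "germsoma_run",
    stages = list(simulate = TRUE, assoc = TRUE, loci = TRUE,
                  hotspots = TRUE, cna = TRUE, tfbs = TRUE, report = TRUE),
    simulate = list(n_chroms = 2, chrom_size = 3e6, n_samples_expr = 89,
                    n_genes = 300, n_signatures = 12, n_planted_assoc = 3,
                    planted_slope = 2, planted_noise_sd = 0.5,
                    n_samples_snv = 40, background_rate = 2e-5,
                    n_hotspots = 3, hotspot_multiplier = 30,
                    hotspot_width = 1000,
                    annotation_classes = c("enhancer", "promoter",
                                           "coding", "utr3"),
                    n_per_class = 120, mean_element_len = 600,
                    n_samples_cna = 40, n_cna_regions = 2,
                    cna_penetrance = 0.7,
                    n_tfs = 4, motif_len = 8, n_sites = 3,
                    tf_site_multiplier = 800,
                    n_loci = 4),
    assoc = list(alpha = 0.05, n_permutations = 1000, log2_expr = TRUE),
    hotspots = list(fdr = 0.05),
    cna = list(t_amp = 0.3, t_del = -0.3, bin_bp = 10000, n_perm = 200,
               fdr = 0.25),
    tfbs = list(strong_site_threshold = 0.85, delta_threshold = 0.10,
                site_threshold = 0.85, min_mutations = 3))
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Load and validate a run configuration
#'
#' @param config path to a YAML file or a named list; missing entries
#'   fall back to package defaults.
#' @return validated config list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  if (!isTRUE(cfg$stages$simulate)) {
    needed <- c("expression", "activity", "gene_list", "snvs", "seg",
                "loci_index")
    for (f in needed) {
      if (is.null(cfg$inputs[[f]]))
        stopf("stage inputs missing: '%s' (simulate stage disabled)", f)
      if (!file.exists(cfg$inputs[[f]]))
        stopf("input file not found: %s", cfg$inputs[[f]])
    }
  }
  cfg
}

tsv_out <- function(x, dir, name) {
  path <- file.path(dir, name)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline end-to-end
#'
#' @param config see [load_config()].
#' @return invisibly, the manifest list (also written as
#'   `manifest.yaml` in the output directory).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  say <- function(fmt, ...) message(sprintf(paste0("[germsoma] ", fmt), ...))

  sim <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    say("simulate: generating inputs (seed %d)",
        stage_seed(cfg$seed, "simulate"))
    sim <- simulate_inputs(cfg)
    d <- file.path(out, "inputs"); dir.create(d, showWarnings = FALSE)
    written <- c(written,
                 tsv_out(sim$snvs, d, "snvs.tsv"),
                 write_seg(sim$segments, file.path(d, "segments.seg")),
                 write_matrix(sim$expression, file.path(d, "expression.tsv"),
                              "sample"),
                 write_matrix(sim$activity, file.path(d, "activities.tsv"),
                              "sample"),
                 tsv_out(sim$loci_index, d, "loci_index.tsv"),
                 write_jaspar(sim$pwms, file.path(d, "pwms.jaspar")),
                 tsv_out(sim$tf_variants, d, "credible_variants.tsv"))
    for (cls in names(sim$tracks))
      written <- c(written, write_bed(sim$tracks[[cls]],
                                      file.path(d, paste0(cls, ".bed"))))
    writeLines(unlist(lapply(names(sim$sequences), function(cn)
      c(paste0(">", cn), sim$sequences[[cn]]))),
      file.path(d, "genome.fa"))
    written <- c(written, file.path(d, "genome.fa"))
    write_scenario_yaml(c(cfg$simulate, list(seed = stage_seed(cfg$seed,
                                                               "simulate"))),
                        file.path(d, "scenario.yaml"))
  } else {
    sim <- load_inputs(cfg)
  }

  loci <- NULL
  if (isTRUE(cfg$stages$loci)) {
    say("loci: building 1 Mb risk regions")
    loci <- build_risk_loci(sim$loci_index, sim$genome)
    d <- file.path(out, "loci"); dir.create(d, showWarnings = FALSE)
    written <- c(written, tsv_out(loci, d, "risk_loci.tsv"),
                 write_bed(genomic_intervals(loci$chrom, loci$start,
                                             loci$end, name = loci$locus_id),
                           file.path(d, "risk_loci.bed")))
  }

  if (isTRUE(cfg$stages$assoc)) {
    say("assoc: gene x signature scan + permutation null")
    d <- file.path(out, "assoc"); dir.create(d, showWarnings = FALSE)
    scan <- assoc_scan(sim$expression, sim$activity, sim$gene_list,
                       alpha = cfg$assoc$alpha,
                       log2_expr = cfg$assoc$log2_expr)
    perm <- assoc_permutation_test(sim$expression, sim$activity,
                                   sim$gene_list,
                                   n_iter = cfg$assoc$n_permutations,
                                   alpha = cfg$assoc$alpha,
                                   seed = stage_seed(cfg$seed, "assoc"),
                                   log2_expr = cfg$assoc$log2_expr)
    counts <- scan$counts
    counts$etiology <- map_etiology(counts$signature)
    written <- c(written,
                 tsv_out(scan$results, d, "associations.tsv"),
                 tsv_out(counts, d, "signature_counts.tsv"),
                 tsv_out(data.frame(gene_list_size = perm$gene_list_size,
                                    n_iter = perm$n_iter,
                                    observed = perm$observed,
                                    n_exceed = perm$n_exceed,
                                    p_value = perm$p_value),
                         d, "permutation_summary.tsv"),
                 tsv_out(data.frame(iteration = seq_along(perm$null_counts),
                                    n_significant = perm$null_counts),
                         d, "permutation_null_counts.tsv"))
  }

  if (isTRUE(cfg$stages$hotspots)) {
    say("hotspots: burden test per annotation track + enrichment")
    d <- file.path(out, "hotspots"); dir.create(d, showWarnings = FALSE)
    tally <- tally_recurrence(sim$snvs)
    written <- c(written, tsv_out(tally$histogram, d, "recurrence.tsv"))
    all_res <- list()
    for (cls in names(sim$tracks)) {
      res <- scan_track(sim$tracks[[cls]], sim$snvs,
                        fdr = cfg$hotspots$fdr)
      all_res[[cls]] <- res
    }
    results <- do.call(rbind, all_res)
    rownames(results) <- NULL
    written <- c(written, tsv_out(results, d, "elements.tsv"))
    enr <- rbind(enrich_elements(results, "genome"),
                 enrich_elements(results, "chromosome"))
    written <- c(written, tsv_out(enr, d, "enrichment.tsv"))
    if (!is.null(loci)) {
      enr_loci <- enrich_elements(results, loci)
      written <- c(written, tsv_out(enr_loci, d, "enrichment_loci.tsv"))
    }
    sim$element_results <- results
  }

  if (isTRUE(cfg$stages$cna)) {
    say("cna: recurrent region calling (n_perm = %d)", cfg$cna$n_perm)
    d <- file.path(out, "cna"); dir.create(d, showWarnings = FALSE)
    regions <- cfg$cna$regions %||%
      call_recurrent_cna(sim$segments, t_amp = cfg$cna$t_amp,
                         t_del = cfg$cna$t_del, bin_bp = cfg$cna$bin_bp,
                         n_perm = cfg$cna$n_perm, fdr = cfg$cna$fdr,
                         seed = stage_seed(cfg$seed, "cna"),
                         genome = sim$genome)
    written <- c(written, tsv_out(regions, d, "recurrent_regions.tsv"))
    if (nrow(regions) > 0)
      written <- c(written,
                   write_bed(genomic_intervals(regions$chrom, regions$start,
                                               regions$end,
                                               name = regions$direction,
                                               score = regions$frequency),
                             file.path(d, "recurrent_regions.bed")))
    if (!is.null(sim$state_tracks)) {
      cov <- annotate_cna(regions, sim$state_tracks)
      written <- c(written, tsv_out(cov, d, "state_coverage.tsv"))
    }
    if (!is.null(loci)) {
      xl <- cna_in_loci(regions, loci)
      written <- c(written, tsv_out(xl$per_locus, d, "cna_in_loci.tsv"),
                   tsv_out(xl$summary, d, "cna_loci_summary.tsv"))
    }
  }

  if (isTRUE(cfg$stages$tfbs)) {
    say("tfbs: germline disruption calls + somatic binding-site burden")
    d <- file.path(out, "tfbs"); dir.create(d, showWarnings = FALSE)
    elements <- genomic_intervals(sim$sites$chrom,
                                  pmax(0, sim$sites$start - 20),
                                  sim$sites$end + 20,
                                  name = paste0("elem_",
                                                seq_len(nrow(sim$sites))))
    germ <- germline_disrupted_tfs(
      sim$tf_variants, sim$pwms, sim$sequences, elements,
      strong_site_threshold = cfg$tfbs$strong_site_threshold,
      delta_threshold = cfg$tfbs$delta_threshold)
    burden <- somatic_tf_burden(elements, sim$snvs, sim$pwms,
                                sim$sequences,
                                site_threshold = cfg$tfbs$site_threshold,
                                min_mutations = cfg$tfbs$min_mutations)
    common <- intersect_tf_lists(
      germ$counts$tf_name,
      unique(burden$tf_name[burden$passes_filter]))
    written <- c(written,
                 tsv_out(germ$calls, d, "germline_disruption_calls.tsv"),
                 tsv_out(germ$counts, d, "germline_tf_counts.tsv"),
                 tsv_out(burden, d, "somatic_tf_burden.tsv"))
    writeLines(common, file.path(d, "common_tfs.txt"))
    written <- c(written, file.path(d, "common_tfs.txt"))
  }

  if (isTRUE(cfg$stages$report)) {
    say("report: assembling summary tables")
    written <- c(written, write_report(out))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("germsoma")),
    seed = cfg$seed,
    stage_seeds = lapply(setNames(nm = names(cfg$stages)),
                         function(s) stage_seed(cfg$seed, s)),
    stages = cfg$stages,
    outputs = local({
      paths <- sort(written)
      rel <- substring(paths, nchar(out) + 2)
      as.list(setNames(unname(tools::md5sum(paths)), rel))
    }))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}

simulate_inputs <- function(cfg) {
  p <- cfg$simulate
  seed <- stage_seed(cfg$seed, "simulate")
  genome <- gen_genome(p$n_chroms, p$chrom_size)
  set.seed(seed)
  sizes <- genome$chrom_sizes

  genes <- sprintf("GENE%03d", seq_len(p$n_genes))
  sig_base <- paste0("SBS", seq_len(p$n_signatures))
  planted <- if (p$n_planted_assoc > 0)
    data.frame(gene = genes[seq_len(p$n_planted_assoc)],
               signature = sig_base[seq_len(p$n_planted_assoc)],
               slope = p$planted_slope, noise_sd = p$planted_noise_sd)
  else NULL
  sx <- gen_signature_expression(p$n_samples_expr, genes, sig_base,
                                 planted = planted, seed = seed + 1)
  gene_list <- unique(c(if (!is.null(planted)) planted$gene,
                        sample(genes, 20)))

  tracks <- gen_annotation_tracks(genome, p$annotation_classes,
                                  p$n_per_class, p$mean_element_len,
                                  seed = seed + 2)
  # plant hotspots inside elements of the first class
  first <- tracks[[1]]
  pick <- head(order(-(first$end - first$start)), p$n_hotspots)
  hotspots <- data.frame(chrom = first$chrom[pick],
                         start = first$start[pick],
                         end = pmin(first$end[pick],
                                    first$start[pick] + p$hotspot_width),
                         rate_multiplier = p$hotspot_multiplier)
  tf <- gen_pwms_and_variants(p$n_tfs, p$motif_len, genome,
                              n_sites = p$n_sites, seed = seed + 7)
  # somatic mutation pressure on a couple of planted binding sites, so the
  # somatic TFBS burden stage has sites that clear the >= 3-mutation filter
  tf_hot <- do.call(rbind, lapply(unique(tf$sites$name)[1:2], function(nm) {
    s <- tf$sites[tf$sites$name == nm, , drop = FALSE][1, ]
    data.frame(chrom = s$chrom, start = s$start, end = s$end,
               rate_multiplier = p$tf_site_multiplier)
  }))
  snvs <- gen_snvs(genome, p$n_samples_snv, p$background_rate,
                   hotspots = rbind(hotspots, tf_hot), seed = seed + 3)

  cna_regions <- data.frame(
    chrom = rep_len(names(sizes), p$n_cna_regions),
    start = round(as.numeric(sizes[rep_len(seq_along(sizes),
                                           p$n_cna_regions)]) * 0.3),
    end = round(as.numeric(sizes[rep_len(seq_along(sizes),
                                         p$n_cna_regions)]) * 0.3) + 100000,
    direction = rep_len(c("amp", "del"), p$n_cna_regions),
    penetrance = p$cna_penetrance)
  segments <- gen_cna_segments(genome, p$n_samples_cna, cna_regions,
                               seed = seed + 4)
  state_tracks <- list(
    HGSOC = do.call(rbind, unname(gen_annotation_tracks(
      genome, CHROMATIN_STATES, 40, 2000, seed = seed + 5))),
    FT = do.call(rbind, unname(gen_annotation_tracks(
      genome, CHROMATIN_STATES, 40, 2000, seed = seed + 6))))

  loci_index <- data.frame(
    locus_id = sprintf("L%02d", seq_len(p$n_loci)),
    chrom = rep_len(names(sizes), p$n_loci),
    pos = round(seq(0.35, 0.65, length.out = p$n_loci) *
                  as.numeric(sizes[rep_len(seq_along(sizes), p$n_loci)])),
    histotype = rep_len(c("HGSOC", "MOC"), p$n_loci))

  list(genome = genome, expression = sx$expression,
       activity = sx$activity, gene_list = gene_list, tracks = tracks,
       hotspot_truth = hotspots, snvs = snvs, segments = segments,
       cna_truth = cna_regions, state_tracks = state_tracks,
       pwms = tf$pwms, sequences = tf$sequences,
       tf_variants = tf$variants, sites = tf$sites,
       loci_index = loci_index)
}

load_inputs <- function(cfg) {
  inp <- cfg$inputs
  expr <- read_matrix(inp$expression)
  act <- read_matrix(inp$activity)
  snvs <- read_variants(inp$snvs, format = inp$snv_format %||% "tsv")
  segments <- read_seg(inp$seg)
  loci_index <- read.delim(inp$loci_index, stringsAsFactors = FALSE)
  gene_list <- readLines(inp$gene_list)
  tracks <- list()
  for (b in inp$tracks %||% character()) {
    gi <- read_bed(b)
    tracks[[sub("\\.bed$", "", basename(b))]] <- gi
  }
  genome <- if (!is.null(inp$genome_sizes)) {
    gs <- read.delim(inp$genome_sizes, header = FALSE)
    list(chrom_names = as.character(gs[[1]]),
         chrom_sizes = setNames(as.numeric(gs[[2]]),
                                as.character(gs[[1]])))
  } else {
    agg <- tapply(c(segments$end, snvs$pos),
                  c(segments$chrom, snvs$chrom), max)
    list(chrom_names = names(agg),
         chrom_sizes = setNames(as.numeric(agg), names(agg)))
  }
  pwms <- if (!is.null(inp$pwms)) read_jaspar(inp$pwms) else NULL
  sequences <- if (!is.null(inp$fasta)) read_fasta(inp$fasta) else NULL
  tf_variants <- if (!is.null(inp$credible_variants))
    read_variants(inp$credible_variants, format = "tsv") else NULL
  list(genome = genome, expression = expr, activity = act,
       gene_list = gene_list, tracks = tracks, snvs = snvs,
       segments = segments, state_tracks = NULL, pwms = pwms,
       sequences = sequences, tf_variants = tf_variants, sites = NULL,
       loci_index = loci_index)
}

#' Read a plain (uncompressed) FASTA file
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (length(heads) == 0) stopf("%s: no FASTA headers", path)
  out <- character(length(heads))
  names(out) <- sub("^>\\s*(\\S+).*", "\\1", lines[heads])
  bounds <- c(heads, length(lines) + 1)
  for (i in seq_along(heads))
    out[i] <- toupper(paste(lines[(heads[i] + 1):(bounds[i + 1] - 1)],
                            collapse = ""))
  out
}

#' Assemble human-readable summary tables from saved stage outputs
#'
#' Idempotent: regenerating the report from the same outputs rewrites
#' identical files. Sections for stages that did not run are omitted.
#'
#' @param out_dir pipeline output directory.
#' @return character vector of written report files, invisibly used by
#'   [run_pipeline()].
#' @export
write_report <- function(out_dir) {
  d <- file.path(out_dir, "report")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  lines <- c("germsoma run summary", "====================", "")
  written <- character()
  f <- file.path(out_dir, "assoc", "signature_counts.tsv")
  if (file.exists(f)) {
    counts <- read.delim(f, stringsAsFactors = FALSE)
    lines <- c(lines, "Signature association counts (genes significant per",
               "signature, with proposed etiology):",
               utils::capture.output(print(counts, row.names = FALSE)), "")
    ps <- file.path(out_dir, "assoc", "permutation_summary.tsv")
    if (file.exists(ps)) {
      perm <- read.delim(ps)
      lines <- c(lines, sprintf(
        "Permutation gene-set test: observed = %d significant pairs, p = %.4g (%d iterations).",
        perm$observed, perm$p_value, perm$n_iter), "")
    }
  }
  f <- file.path(out_dir, "hotspots", "enrichment.tsv")
  if (file.exists(f)) {
    enr <- read.delim(f, stringsAsFactors = FALSE)
    gw <- enr[enr$stratum == "genome", , drop = FALSE]
    lines <- c(lines, "Frequently mutated elements, genome-wide enrichment",
               "(percent of annotated elements significantly mutated):",
               utils::capture.output(print(gw, row.names = FALSE)), "")
    fl <- file.path(out_dir, "hotspots", "enrichment_loci.tsv")
    if (file.exists(fl)) {
      lc <- read.delim(fl, stringsAsFactors = FALSE)
      lc <- lc[!is.na(lc$percent) & lc$n_total > 0, , drop = FALSE]
      lines <- c(lines, "Within risk loci:",
                 utils::capture.output(print(lc, row.names = FALSE)), "")
    }
  }
  f <- file.path(out_dir, "cna", "cna_loci_summary.tsv")
  if (file.exists(f)) {
    s <- read.delim(f)
    lines <- c(lines, sprintf(
      "CNAs in risk loci: %d of %d loci carry a recurrent CNA (amp in %d, del in %d).",
      s$loci_with_cna, s$n_loci, s$loci_with_amp, s$loci_with_del), "")
    cv <- file.path(out_dir, "cna", "state_coverage.tsv")
    if (file.exists(cv)) {
      cov <- read.delim(cv, stringsAsFactors = FALSE)
      lines <- c(lines, "Chromatin-state coverage of recurrent CNAs:",
                 utils::capture.output(print(cov, row.names = FALSE)), "")
    }
  }
  f <- file.path(out_dir, "tfbs", "common_tfs.txt")
  if (file.exists(f)) {
    common <- readLines(f)
    lines <- c(lines, sprintf(
      "TFs disrupted by both germline variants and somatic mutations (n = %d): %s",
      length(common), paste(common, collapse = ", ")), "")
  }
  path <- file.path(d, "summary.txt")
  writeLines(lines, path)
  path
}
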