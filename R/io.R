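# Readers/writers for the external formats the pipeline touches. The one
# rule that matters: intervals are 0-based half-open in memory, BED is the
# native dialect; 1-based formats (VCF positions, SEG starts) are converted
# exactly once, here.

#' Read a BED track
#'
#' BED3+ with an optional name (column 4) and score (column 5). Lines
#' starting with `#`, `track` or `browser` are skipped.
#'
#' @param path file path.
#' @return a [genomic_intervals()] data.frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(genomic_intervals(character(), numeric(), numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(parts, length, integer(1))
  if (any(ncol < 3))
    stopf("%s line %d: BED needs >= 3 tab-separated columns",
          path, lineno[which(ncol < 3)[1]])
  chrom <- vapply(parts, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end))
    stopf("%s line %d: non-numeric coordinates",
          path, lineno[which(is.na(start) | is.na(end))[1]])
  bad <- which(start >= end)
  if (length(bad))
    stopf("%s line %d: start >= end (zero-width or inverted interval)",
          path, lineno[bad[1]])
  name <- ifelse(ncol >= 4, vapply(parts, function(p) p[min(4, length(p))],
                                   character(1)), NA_character_)
  score <- suppressWarnings(as.numeric(
    ifelse(ncol >= 5, vapply(parts, function(p) p[min(5, length(p))],
                             character(1)), NA_character_)))
  gi <- genomic_intervals(chrom, start, end)
  if (any(!is.na(name))) gi$name <- name
  if (any(!is.na(score))) gi$score <- score
  gi
}

#' Write intervals as BED
#'
#' @param intervals interval data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- list(intervals$chrom,
               format(intervals$start, scientific = FALSE, trim = TRUE),
               format(intervals$end, scientific = FALSE, trim = TRUE))
  if (!is.null(intervals$name)) {
    cols <- c(cols, list(intervals$name))
    if (!is.null(intervals$score)) cols <- c(cols, list(intervals$score))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

validate_snv_alleles <- function(ref, alt, where = "variant table") {
  ok_base <- function(x) x %in% DNA_BASES
  bad <- which(!ok_base(ref) | !ok_base(alt))
  if (length(bad))
    stopf("%s: malformed base at record %d (ref=%s alt=%s)",
          where, bad[1], ref[bad[1]], alt[bad[1]])
  same <- which(ref == alt)
  if (length(same))
    stopf("%s: ref equals alt at record %d", where, same[1])
  invisible(TRUE)
}

#' Read variants from a minimal VCF or a 5-column TSV
#'
#' Only SNVs are modelled. VCF rows with multi-base REF or ALT (indels,
#' MNVs) are skipped and counted in the `n_skipped` attribute;
#' multi-allelic rows are split into one record per alternate allele.
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"`. TSV columns: chrom, pos, ref, alt
#'   and optionally sample (germline credible variants carry no sample).
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `sample`; attribute `n_skipped` counts dropped non-SNV rows.
#' @export
read_variants <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(tab)))
      stopf("%s: TSV variants need columns %s", path,
            paste(need, collapse = ", "))
    out <- data.frame(chrom = as.character(tab$chrom),
                      pos = as.numeric(tab$pos),
                      ref = toupper(as.character(tab$ref)),
                      alt = toupper(as.character(tab$alt)),
                      sample = if (!is.null(tab$sample))
                        as.character(tab$sample) else NA_character_,
                      stringsAsFactors = FALSE)
    validate_snv_alleles(out$ref, out$alt, path)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  skipped <- 0L
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) stopf("%s: VCF row with < 5 fields", path)
    ref <- toupper(f[4])
    alts <- toupper(strsplit(f[5], ",", fixed = TRUE)[[1]])
    snv <- nchar(ref) == 1 & nchar(alts) == 1 & alts != "." & ref != "."
    skipped <- skipped + sum(!snv)
    if (!any(snv)) next
    recs[[i]] <- data.frame(chrom = f[1], pos = as.numeric(f[2]),
                            ref = ref, alt = alts[snv],
                            sample = NA_character_,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      sample = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  validate_snv_alleles(out$ref, out$alt, path)
  attr(out, "n_skipped") <- skipped
  out
}

#' Write a variant table as TSV
#'
#' @param variants variant data.frame (chrom, pos, ref, alt, sample).
#' @param path output path.
#' @export
write_variants <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CNA segments (SEG / GISTIC input dialect)
#'
#' Six tab-separated columns with a header: sample, chromosome, start,
#' end, number of markers, segment mean (log2 copy ratio). Starts are
#' 1-based inclusive on disk and converted to 0-based half-open.
#'
#' @param path file path.
#' @return data.frame with `sample`, `chrom`, `start` (0-based), `end`,
#'   `n_markers`, `seg_mean`.
#' @export
read_seg <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stopf("%s: SEG needs 6 columns", path)
  out <- data.frame(sample = as.character(tab[[1]]),
                    chrom = as.character(tab[[2]]),
                    start = as.numeric(tab[[3]]) - 1,
                    end = as.numeric(tab[[4]]),
                    n_markers = as.numeric(tab[[5]]),
                    seg_mean = as.numeric(tab[[6]]),
                    stringsAsFactors = FALSE)
  bad <- which(!(out$start < out$end))
  if (length(bad)) stopf("%s row %d: start >= end", path, bad[1])
  out
}

#' Write CNA segments as SEG
#'
#' @param segments segment data.frame as returned by [read_seg()].
#' @param path output path.
#' @export
write_seg <- function(segments, path) {
  disk <- data.frame(Sample = segments$sample,
                     Chromosome = segments$chrom,
                     Start = segments$start + 1,
                     End = segments$end,
                     Num_Markers = segments$n_markers,
                     Seg_Mean = segments$seg_mean)
  write.table(disk, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled samples-by-columns matrix from TSV
#'
#' First column holds row labels; header holds column labels. Duplicate
#' labels are an error.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- as.character(tab[[1]])
  if (anyDuplicated(rn)) stopf("%s: duplicate row labels", path)
  cn <- colnames(tab)[-1]
  if (anyDuplicated(cn)) stopf("%s: duplicate column labels", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(rn, cn)
  m
}

#' Write a labelled matrix as TSV
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param index_name header label for the row-label column.
#' @export
write_matrix <- function(m, path, index_name = "id") {
  tab <- data.frame(rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab)[1] <- index_name
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_pwm <- function(tf, counts = NULL, prob = NULL, pseudocount = 0.8) {
  if (is.null(prob)) {
    if (any(counts < 0)) stopf("PWM '%s': negative counts", tf)
    prob <- sweep(counts + pseudocount, 2,
                  colSums(counts + pseudocount), "/")
  }
  rownames(prob) <- DNA_BASES
  if (any(abs(colSums(prob) - 1) > 1e-9))
    stopf("PWM '%s': columns do not sum to 1", tf)
  structure(list(tf = tf, prob = prob, counts = counts,
                 pseudocount = pseudocount), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%d columns, pseudocount %g)\n",
              x$tf, ncol(x$prob), x$pseudocount))
  print(round(x$prob, 3))
  invisible(x)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR 2020 PFM text layout (`>ID NAME` header, then four
#' lines `A [ 4 19 0 ... ]`). Counts are converted to column-stochastic
#' probabilities after adding `pseudocount` to every cell.
#'
#' @param path file path.
#' @param pseudocount value added to every count before normalization
#'   (default 0.8).
#' @return named list of `pwm` objects (name = TF name).
#' @export
read_jaspar <- function(path, pseudocount = 0.8) {
  if (pseudocount <= 0) stopf("pseudocount must be positive")
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stopf("%s: no JASPAR '>' headers found", path)
  pwms <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    j <- if (h < length(heads)) heads[h + 1] - 1 else length(lines)
    toks <- strsplit(sub("^>", "", lines[i]), "[ \t]+")[[1]]
    tf <- if (length(toks) >= 2) toks[2] else toks[1]
    body <- lines[(i + 1):j]
    if (length(body) < 4) stopf("%s: PFM '%s' needs 4 base rows", path, tf)
    counts <- matrix(NA_real_, 4, 0)
    rowvals <- list()
    for (b in body[1:4]) {
      base <- toupper(substr(b, 1, 1))
      nums <- regmatches(b, gregexpr("[0-9.]+", b))[[1]]
      rowvals[[base]] <- as.numeric(nums)
    }
    if (!all(DNA_BASES %in% names(rowvals)))
      stopf("%s: PFM '%s' missing a base row", path, tf)
    L <- unique(lengths(rowvals))
    if (length(L) != 1) stopf("%s: PFM '%s' rows differ in length", path, tf)
    counts <- do.call(rbind, rowvals[DNA_BASES])
    if (any(counts < 0)) stopf("%s: PFM '%s' has negative counts", path, tf)
    pwms[[tf]] <- new_pwm(tf, counts = counts, pseudocount = pseudocount)
  }
  pwms
}

#' Write PWMs in JASPAR PFM text format
#'
#' Writes the stored count matrices (probability-only PWMs are scaled to
#' counts of 100 per column).
#'
#' @param pwms named list of `pwm` objects.
#' @param path output path.
#' @export
write_jaspar <- function(pwms, path) {
  out <- character()
  for (k in seq_along(pwms)) {
    p <- pwms[[k]]
    m <- p$counts %||% round(p$prob * 100, 4)
    out <- c(out, sprintf(">M%04d %s", k, p$tf),
             vapply(1:4, function(i) {
               sprintf("%s [ %s ]", DNA_BASES[i],
                       paste(format(m[i, ], trim = TRUE), collapse = " "))
             }, character(1)))
  }
  writeLines(out, path)
  invisible(path)
}
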