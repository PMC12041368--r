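DNA_BASES <- c("A", "C", "G", "T")

#' Normalize chromosome names for matching
#'
#' Strips a leading "chr" so that PCAWG-style ("1") and UCSC-style ("chr1")
#' names compare equal. Original spellings are preserved on output objects;
#' normalization happens only where tracks are matched against each other.
#'
#' @param x character vector of chromosome names.
#' @return character vector without the "chr" prefix.
#' @export
norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T strings.
#' @return reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic per-stage sub-seed derivation: keeps every stage individually
# reproducible from one pipeline seed. Always < 2^31.
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("simulate", "assoc", "loci", "hotspots",
                        "cna", "tfbs", "report"))
  if (is.na(idx)) idx <- 0L
  as.integer((as.numeric(seed) * 131 + idx * 10007) %% 2147483629)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
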