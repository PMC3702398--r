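#' @keywords internal
"_PACKAGE"

#' @importFrom stats dbinom dnorm integrate optim optimHess pnorm qlogis qnorm
#'   plogis rbinom rmultinom rnbinom rnorm runif setNames rbeta median sd
#'   pchisq quantile
#' @importFrom utils read.delim write.table head
NULL

# Site identity: (patient, chrom, pos, alt). The ref allele is deliberately
# excluded -- calls are matched across callers by position within a patient.
site_key <- function(x) {
  paste(x$patient_id, x$chrom, x$pos, x$alt, sep = "|")
}

#' Construct a table of candidate variant sites
#'
#' A variant site is a single-nucleotide candidate mutation position for one
#' patient. Site identity is the tuple (patient, chromosome, position, alt
#' allele); two callers reporting the same tuple are treated as calling the
#' same mutation.
#'
#' @param patient_id character vector of patient identifiers.
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-nucleotide reference and alternate alleles.
#' @return A `data.frame` with one row per site.
#' @export
variant_sites <- function(patient_id, chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("positions must be 1-based (>= 1)")
  bad <- nchar(ref) != 1L | nchar(alt) != 1L
  if (any(bad)) stop("variant sites are SNV-only: single-base ref and alt required")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  data.frame(
    patient_id = as.character(patient_id), chrom = as.character(chrom),
    pos = pos, ref = as.character(ref), alt = as.character(alt),
    stringsAsFactors = FALSE
  )
}

# All 2^K detection patterns as bitstrings, character k = caller k,
# lexicographic order ("00...0" first).
all_patterns <- function(K) {
  stopifnot(K >= 1)
  grid <- expand.grid(rep(list(c("0", "1")), K))[, K:1, drop = FALSE]
  apply(as.matrix(grid), 1, paste, collapse = "")
}

# bitstrings -> 0/1 matrix (rows = patterns, cols = callers)
pattern_bits <- function(patterns) {
  m <- do.call(rbind, lapply(strsplit(patterns, ""), as.integer))
  rownames(m) <- patterns
  m
}
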