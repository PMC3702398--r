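# Descriptive comparisons of multi-caller call sets: Venn/agreement
# summaries, caller-unique and caller-missed sets, depth-VAF
# stratification, raw-VCF presence, and the normal-VAF screen.

#' Venn counts over nonzero detection patterns
#'
#' @param patterns a [detection_patterns()] table.
#' @return Named integer vector over all `2^K - 1` nonzero-bit patterns.
#' @export
venn_counts <- function(patterns) {
  K <- nchar(patterns$pattern[1])
  if (nrow(patterns) == 0L) K <- length(attr(patterns, "callers"))
  cells <- all_patterns(K)
  cells <- cells[cells != strrep("0", K)]
  tab <- table(factor(patterns$pattern, levels = cells))
  setNames(as.integer(tab), cells)
}

#' Agreement summary: sites by number of detecting callers
#'
#' For the union and for each caller's call set, counts sites detected by
#' exactly 1, 2, ..., K callers.
#'
#' @param patterns a [detection_patterns()] table.
#' @param K number of callers (default from the table).
#' @return List with `union` (named count vector over 1..K) and
#'   `per_caller` (K x K matrix, rows = callers).
#' @export
agreement_summary <- function(patterns, K = NULL) {
  callers <- attr(patterns, "callers")
  if (is.null(K)) K <- length(callers)
  if (K < 2) stop("K must be >= 2")
  bits <- pattern_bits(patterns$pattern)
  ndet <- rowSums(bits)
  lev <- seq_len(K)
  union_hist <- table(factor(ndet, levels = lev))
  per <- t(vapply(seq_len(K), function(k)
    as.integer(table(factor(ndet[bits[, k] == 1], levels = lev))),
    integer(K)))
  rownames(per) <- callers
  colnames(per) <- lev
  list(union = setNames(as.integer(union_hist), lev), per_caller = per)
}

#' Caller-unique and caller-missed site sets
#'
#' For each caller, the sites detected by that caller alone ("only") and
#' the sites detected by every caller except it ("all-but").
#'
#' @param patterns a [detection_patterns()] table.
#' @param K number of callers (default from the table).
#' @return List with per-caller `only` and `all_but` site tables.
#' @export
unique_and_missed <- function(patterns, K = NULL) {
  callers <- attr(patterns, "callers")
  if (is.null(K)) K <- length(callers)
  if (K < 2) stop("K must be >= 2")
  bits <- pattern_bits(patterns$pattern)
  ndet <- rowSums(bits)
  only <- lapply(seq_len(K), function(k)
    patterns[ndet == 1 & bits[, k] == 1, , drop = FALSE])
  all_but <- lapply(seq_len(K), function(k)
    patterns[ndet == K - 1 & bits[, k] == 0, , drop = FALSE])
  names(only) <- names(all_but) <- callers
  list(only = only, all_but = all_but)
}

#' Stratify sites by tumor exome depth and VAF
#'
#' Bins each evaluable site into one cell of a depth x VAF grid; sites
#' lacking tumor exome depth are counted in a not-evaluable margin.
#' Default bins echo the visually salient thresholds of coverage/VAF
#' scatter summaries (40x, 100x, 200x; 10%, 20%, 50%).
#'
#' @param sites a site table (e.g. one of the [unique_and_missed()] sets).
#' @param evidence evidence table covering the sites.
#' @param depth_bins,vaf_bins monotone bin boundaries.
#' @return List with the count `grid` and `n_not_evaluable`.
#' @export
depth_vaf_strata <- function(sites, evidence,
                             depth_bins = c(0, 20, 40, 100, 200, Inf),
                             vaf_bins = c(0, 0.1, 0.2, 0.5, 1)) {
  i <- match(site_key(sites), site_key(evidence))
  depth <- evidence$exome_tumor_depth[i]
  v <- vaf(evidence$exome_tumor_alt[i], depth)
  ok <- !is.na(depth) & !is.na(v)
  grid <- table(
    depth = cut(depth[ok], depth_bins, right = FALSE, include.lowest = TRUE),
    vaf = cut(v[ok], vaf_bins, right = TRUE, include.lowest = TRUE)
  )
  list(grid = grid, n_not_evaluable = sum(!ok))
}

#' Fraction of target sites present in a caller's raw (pre-filter) VCF
#'
#' For mutations a caller uniquely missed, checks whether the caller at
#' least scanned them: the complement of the returned fraction is mass the
#' caller never reported at all.
#'
#' @param target_sites site table (e.g. the caller's all-but set).
#' @param raw_records the caller's full record table from
#'   [parse_caller_vcf()] (all statuses, PASS or not).
#' @return Fraction in `[0,1]` (NA when there are no target sites).
#' @export
raw_vcf_presence <- function(target_sites, raw_records) {
  if (nrow(target_sites) == 0L) return(NA_real_)
  mean(site_key(target_sites) %in% site_key(raw_records))
}

#' Fraction of sites with a normal-sample variant signal
#'
#' Share of evaluable sites whose normal exome VAF exceeds `cutoff`
#' (default 2%) -- a minimal requirement for a germline variant to have
#' been detectable in the normal sample.
#'
#' @param sites site table.
#' @param evidence evidence table covering the sites.
#' @param cutoff normal VAF cutoff (default 0.02).
#' @return Fraction over evaluable sites.
#' @export
normal_vaf_screen <- function(sites, evidence, cutoff = 0.02) {
  i <- match(site_key(sites), site_key(evidence))
  v <- vaf(evidence$exome_normal_alt[i], evidence$exome_normal_depth[i])
  mean(v > cutoff, na.rm = TRUE)
}
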