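# Reading per-caller somatic call sets and building detection-pattern tables.
#
# The input dialect is VCF v4.x with the somatic status in an INFO key
# (default SS, values SOMATIC/GERMLINE/WILDTYPE), the filter status in the
# FILTER column (PASS vs anything else), and TUMOR/NORMAL sample columns
# carrying DP and AD (ref,alt) fields.

#' Parse one caller's VCF output into a record table
#'
#' Reads a per-caller, per-patient VCF and returns one row per (position,
#' alt allele). Multi-allelic records are split into one record per alt;
#' non-SNV alts are skipped and counted in the skip report attached as
#' attribute `"skip_report"`. Records with an unrecognized somatic-status
#' code are kept with status `"unknown"` (with a warning).
#'
#' @param path path to a VCF file.
#' @param caller_id caller label attached to every record.
#' @param patient_id patient label attached to every record.
#' @param ss_key INFO key holding the somatic status (default `"SS"`).
#' @return A `data.frame` of caller records with columns `caller_id`,
#'   `patient_id`, `chrom`, `pos`, `ref`, `alt`, `somatic_status`,
#'   `filter_pass`, `tumor_depth`, `tumor_alt`, `normal_depth`,
#'   `normal_alt`, `caller_quality`.
#' @export
parse_caller_vcf <- function(path, caller_id, patient_id, ss_key = "SS") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  check_vcf_header(path)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcf@fix
  empty <- data.frame(
    caller_id = character(), patient_id = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    somatic_status = character(), filter_pass = logical(),
    tumor_depth = integer(), tumor_alt = integer(),
    normal_depth = integer(), normal_alt = integer(),
    caller_quality = numeric(), stringsAsFactors = FALSE
  )
  if (is.null(fix) || nrow(fix) == 0L) {
    attr(empty, "skip_report") <- list(n_non_snv = 0L, n_unknown_status = 0L)
    return(empty)
  }

  gt <- vcf@gt
  fmt <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
  ss <- vcfR::extract.info(vcf, element = ss_key)

  rows <- vector("list", nrow(fix))
  n_non_snv <- 0L
  n_unknown <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ref <- fix[i, "REF"]
    tum <- sample_fields(gt[i, "TUMOR"], fmt[[i]])
    nor <- sample_fields(gt[i, "NORMAL"], fmt[[i]])
    status <- map_somatic_status(ss[i])
    if (is.na(status)) {
      n_unknown <- n_unknown + 1L
      warning("unknown somatic-status code '", ss[i], "' at ",
              fix[i, "CHROM"], ":", fix[i, "POS"], "; mapped to 'unknown'",
              call. = FALSE)
      status <- "unknown"
    }
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    for (a in seq_along(alts)) {
      alt <- alts[a]
      if (nchar(ref) != 1L || nchar(alt) != 1L ||
          !alt %in% c("A", "C", "G", "T")) {
        n_non_snv <- n_non_snv + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        caller_id = caller_id, patient_id = patient_id,
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alt,
        somatic_status = status,
        filter_pass = unname(fix[i, "FILTER"]) == "PASS",
        tumor_depth = tum$dp, tumor_alt = tum$ad[a],
        normal_depth = nor$dp, normal_alt = nor$ad[a],
        caller_quality = qual, stringsAsFactors = FALSE
      )
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "skip_report") <- list(n_non_snv = n_non_snv,
                                   n_unknown_status = n_unknown)
  out
}

check_vcf_header <- function(path) {
  lines <- readLines(path, n = 500L)
  if (length(lines) == 0L || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("malformed VCF header at line 1 of ", path,
         ": expected '##fileformat=VCF...'")
  }
  chrom_line <- which(startsWith(lines, "#CHROM"))
  if (length(chrom_line) == 0L) {
    stop("malformed VCF header in ", path, ": no '#CHROM' column line found")
  }
  cols <- strsplit(lines[chrom_line[1]], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 8L) {
    stop("malformed VCF header at line ", chrom_line[1], " of ", path,
         ": fewer than 8 columns")
  }
  invisible(TRUE)
}

map_somatic_status <- function(x) {
  if (is.na(x)) return(NA_character_)
  switch(toupper(x),
    SOMATIC = "somatic", GERMLINE = "germline", WILDTYPE = "wildtype",
    NA_character_)
}

# Split "GT:DP:AD"-style sample strings; AD is "ref,alt1[,alt2...]".
sample_fields <- function(x, fmt) {
  if (is.na(x)) return(list(dp = NA_integer_, ad = NA_integer_))
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  dp <- NA_integer_
  ad <- NA_integer_
  i_dp <- match("DP", fmt)
  i_ad <- match("AD", fmt)
  if (!is.na(i_dp) && i_dp <= length(parts)) dp <- as.integer(parts[i_dp])
  if (!is.na(i_ad) && i_ad <= length(parts)) {
    counts <- as.integer(strsplit(parts[i_ad], ",", fixed = TRUE)[[1]])
    ad <- counts[-1]  # drop the ref count; one entry per alt
  }
  list(dp = dp, ad = ad)
}

#' Extract a caller's final set of somatic mutations
#'
#' The final call set of a caller is the set of sites with somatic status
#' that pass all of the caller's filters (FILTER == PASS). Duplicate
#' reports of the same site are collapsed; a site reported as somatic with
#' conflicting filter status is an ambiguous caller output and raises an
#' error.
#'
#' @param records caller record table from [parse_caller_vcf()] (one caller).
#' @return A site `data.frame` (see [variant_sites()]).
#' @export
final_somatic_set <- function(records) {
  som <- records[records$somatic_status == "somatic", , drop = FALSE]
  if (nrow(som)) {
    keys <- site_key(som)
    conflict <- tapply(som$filter_pass, keys, function(v) length(unique(v)) > 1)
    if (any(conflict)) {
      stop("ambiguous caller output: site(s) reported somatic with ",
           "conflicting filter status: ",
           paste(names(conflict)[conflict], collapse = ", "))
    }
  }
  keep <- som[som$filter_pass, c("patient_id", "chrom", "pos", "ref", "alt"),
              drop = FALSE]
  keep <- keep[!duplicated(site_key(keep)), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Build the per-site detection-pattern map across callers
#'
#' Forms the union of all callers' final somatic sets and records, for each
#' site, the K-bit detection pattern: bit k is 1 iff caller k called the
#' site. Sites absent from a caller's call set count as "not called" (bit
#' 0). By construction no all-zero pattern appears.
#'
#' @param callsets named list of site `data.frame`s, one per caller.
#' @param caller_order character vector fixing the bit order; must cover
#'   every name in `callsets`.
#' @return A `data.frame` of union sites with a `pattern` bitstring column;
#'   attribute `"callers"` records the bit order.
#' @export
detection_patterns <- function(callsets, caller_order) {
  missing <- setdiff(names(callsets), caller_order)
  if (length(missing)) {
    stop("configuration error: caller(s) in callsets missing from caller_order: ",
         paste(missing, collapse = ", "))
  }
  sets <- lapply(caller_order, function(k) {
    s <- callsets[[k]]
    if (is.null(s)) character(0) else site_key(s)
  })
  union_df <- do.call(rbind, lapply(caller_order, function(k) callsets[[k]]))
  if (is.null(union_df) || nrow(union_df) == 0L) {
    out <- variant_sites(character(), character(), integer(), character(), character())
    out$pattern <- character(0)
  } else {
    union_df <- union_df[!duplicated(site_key(union_df)), , drop = FALSE]
    keys <- site_key(union_df)
    bits <- vapply(sets, function(s) as.integer(keys %in% s),
                   integer(nrow(union_df)))
    bits <- matrix(bits, nrow = nrow(union_df))
    out <- union_df[, c("patient_id", "chrom", "pos", "ref", "alt"), drop = FALSE]
    out$pattern <- apply(bits, 1, paste, collapse = "")
    rownames(out) <- NULL
  }
  attr(out, "callers") <- caller_order
  class(out) <- c("detection_patterns", "data.frame")
  out
}

#' Tabulate detection patterns into the 2^K latent-class input
#'
#' Counts sites by detection pattern over all `2^K` cells (zeros included).
#' The all-zero cell -- positions screened but called by no caller -- cannot
#' be derived from the call sets and is supplied explicitly.
#'
#' @param patterns a [detection_patterns()] table, or a character vector of
#'   bitstrings.
#' @param K number of callers; taken from `patterns` when available.
#' @param zero_cell_count count for the all-zero pattern (default 0).
#' @param callers optional caller labels.
#' @return A `pattern_counts` object: named integer vector over all `2^K`
#'   bitstrings with attributes `K`, `callers` and `N`.
#' @export
pattern_count_table <- function(patterns, K = NULL, zero_cell_count = 0L,
                                callers = NULL) {
  if (zero_cell_count < 0) stop("zero_cell_count must be >= 0")
  if (is.data.frame(patterns)) {
    if (is.null(callers)) callers <- attr(patterns, "callers")
    patterns <- patterns$pattern
  }
  if (is.null(K)) {
    K <- if (length(patterns)) nchar(patterns[1]) else length(callers)
  }
  if (is.null(K) || K < 1) stop("K could not be determined")
  cells <- all_patterns(K)
  counts <- setNames(integer(length(cells)), cells)
  if (length(patterns)) {
    tab <- table(factor(patterns, levels = cells))
    counts[] <- as.integer(tab)
  }
  zero <- strrep("0", K)
  if (counts[zero] > 0)
    stop("input patterns contain an all-zero pattern; the zero cell is supplied externally")
  counts[zero] <- as.integer(zero_cell_count)
  pattern_counts(counts, callers = callers)
}

#' @rdname pattern_count_table
#' @param counts named non-negative integer vector over all `2^K` bitstrings.
#' @export
pattern_counts <- function(counts, callers = NULL) {
  K <- nchar(names(counts)[1])
  cells <- all_patterns(K)
  if (!setequal(names(counts), cells)) {
    stop("counts must cover exactly all 2^K patterns")
  }
  counts <- counts[cells]
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(callers)) callers <- paste0("caller", seq_len(K))
  structure(counts, K = K, callers = callers, N = sum(counts),
            class = "pattern_counts")
}

#' @method print pattern_counts
#' @export
print.pattern_counts <- function(x, ...) {
  cat("Detection-pattern counts: K =", attr(x, "K"),
      "callers (", paste(attr(x, "callers"), collapse = ", "), "), N =",
      attr(x, "N"), "\n")
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}

#' The 76-gene deep-sequencing validation table as a pattern-count fixture
#'
#' The published validation table for four callers (A, B, C, D) on the
#' targeted 76-gene regions, with each detection pattern's non-somatic and
#' somatic validation counts summed into a single cell count. The pattern
#' for callers A and B only does not occur and is 0. Totals: N = 4439,
#' detected by at least one caller = 138, detected by all four = 57.
#'
#' @return A [pattern_counts()] object with caller order A, B, C, D.
#' @export
table1_fixture <- function() {
  counts <- c(
    "0000" = 4301L,  # screened, called by none (4292 non-somatic + 9 somatic)
    "1000" = 7L, "0100" = 3L, "0010" = 2L, "0001" = 11L,
    "1100" = 0L, "1010" = 6L, "1001" = 5L,
    "0110" = 2L, "0101" = 2L, "0011" = 5L,
    "1110" = 3L,   # all but D
    "1101" = 4L,   # all but C
    "1011" = 18L,  # all but B
    "0111" = 13L,  # all but A
    "1111" = 57L
  )
  pattern_counts(counts, callers = c("A", "B", "C", "D"))
}

#' Read/write pattern-count tables as TSV
#'
#' The TSV has two columns, `pattern` (bitstring) and `count`.
#'
#' @param x a `pattern_counts` object.
#' @param path file path.
#' @export
write_pattern_tsv <- function(x, path) {
  df <- data.frame(pattern = names(x), count = as.integer(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_tsv
#' @param callers optional caller labels for the read table.
#' @export
read_pattern_tsv <- function(path, callers = NULL) {
  df <- read.delim(path, colClasses = c("character", "integer"))
  pattern_counts(setNames(df$count, df$pattern), callers = callers)
}
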