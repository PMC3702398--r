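# Shared fixture builders; everything is generated in code at test time.

small_config <- function(seed = 101, ...) {
  simulation_config(n_patients = 3, sites_per_patient = 300, seed = seed, ...)
}

# A cohort written to a temp directory; memoised per (seed, ...) within a
# single test file via the calling test's environment.
write_small_cohort <- function(dir = tempfile("cohort"), seed = 101, ...) {
  cohort <- simulate_cohort(small_config(seed = seed, ...))
  write_cohort(cohort, dir)
  list(dir = dir, cohort = cohort)
}

# Truth-derived final call set for one caller (the simulator's own record
# of emitted positive calls).
truth_callset <- function(truth, caller) {
  idx <- truth[[paste0("Y_", caller)]]
  truth[idx, c("patient_id", "chrom", "pos", "ref", "alt"), drop = FALSE]
}

# The 76-gene fixture expanded into a site-per-row pattern table.
fixture_patterns <- function() {
  fx <- table1_fixture()
  pats <- rep(names(fx)[names(fx) != "0000"],
              as.integer(fx[names(fx) != "0000"]))
  out <- variant_sites(paste0("P", seq_along(pats)), "1",
                       seq_along(pats), "A", "T")
  out$pattern <- pats
  attr(out, "callers") <- attr(fx, "callers")
  class(out) <- c("detection_patterns", "data.frame")
  out
}

# Handwritten VCF text for parser tests.
mini_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                     header = TRUE) {
  lines <- character(0)
  if (header) {
    lines <- c("##fileformat=VCFv4.2",
               "##INFO=<ID=SS,Number=1,Type=String,Description=\"status\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "TUMOR", "NORMAL", sep = "\t"))
  }
  writeLines(c(lines, records), path)
  path
}

vcf_record <- function(chrom = "1", pos = 100, ref = "A", alt = "T",
                       qual = 50, filter = "PASS", ss = "SOMATIC",
                       tumor = "./.:30:20,10", normal = "./.:25:25,0") {
  paste(chrom, pos, ".", ref, alt, qual, filter, paste0("SS=", ss),
        "GT:DP:AD", tumor, normal, sep = "\t")
}
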