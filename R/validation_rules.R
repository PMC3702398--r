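# Per-site validation schemes: gold-standard deep-seq rules, signed-quality
# pseudo-validation, RNA-seq validation, and strand-bias artifact filters.
# All threshold comparisons are strict (>, <) exactly as stated; ties fall
# to the negative side. A VAF at zero depth is undefined, never zero.

#' Default validation thresholds
#'
#' Gold-standard rule: deep-seq tumor VAF > 10% and normal VAF < 2%
#' (wildtype sub-rule: both < 2%); alternative signed-quality rule: tumor
#' score > 200, normal score < -100. Pseudo-validation headline thresholds:
#' tumor > 200, normal < -50. RNA validation: RNA VAF > 10%, normal exome
#' VAF < 2%, RNA depth >= 10x.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(gs_tumor_vaf = 0.10, gs_normal_vaf = 0.02,
       gs_q_tumor = 200, gs_q_normal = -100,
       q_t = 200, q_n = -50,
       f_t = 0.10, f_n = 0.02, rna_min_depth = 10L,
       strand_hi = 0.95, strand_lo = 0.05,
       ref_strand_lo = 0.30, ref_strand_hi = 0.70)
}

#' Signed variant-call quality
#'
#' Attaches a sign to a non-negative variant-call quality: positive when a
#' variant allele was found, negative (flipped) when none was, so that a
#' large negative value is strong support for the absence of a variant
#' allele. A zero score is uninformative either way.
#'
#' @param raw_quality non-negative quality score(s).
#' @param variant_found logical: was any variant allele observed?
#' @return Signed quality, same length as the inputs.
#' @export
signed_quality <- function(raw_quality, variant_found) {
  if (any(raw_quality < 0, na.rm = TRUE))
    stop("raw_quality must be non-negative")
  ifelse(variant_found, raw_quality, -raw_quality)
}

#' Gold-standard validation from deep-sequencing VAFs
#'
#' A site is `somatic` iff the deep-seq tumor VAF is > 10% and the deep-seq
#' normal VAF is < 2%; among the remainder it is `wildtype` iff both VAFs
#' are < 2%, else `non_somatic`. An undefined VAF (zero depth) yields
#' `not_evaluable`.
#'
#' @param tumor_deep_vaf,normal_deep_vaf deep-seq VAFs (NA when undefined).
#' @param tumor_cut,normal_cut thresholds (defaults 0.10 and 0.02).
#' @return Character vector of statuses.
#' @export
gs_validate <- function(tumor_deep_vaf, normal_deep_vaf,
                        tumor_cut = 0.10, normal_cut = 0.02) {
  out <- ifelse(tumor_deep_vaf > tumor_cut & normal_deep_vaf < normal_cut,
                "somatic",
         ifelse(tumor_deep_vaf < normal_cut & normal_deep_vaf < normal_cut,
                "wildtype", "non_somatic"))
  out[is.na(tumor_deep_vaf) | is.na(normal_deep_vaf)] <- "not_evaluable"
  out
}

#' Alternative gold-standard rule from signed quality scores
#'
#' `somatic` iff the signed tumor score is > 200 and the signed normal
#' score is < -100; else `non_somatic`.
#'
#' @param signed_q_tumor,signed_q_normal signed quality scores.
#' @param tumor_cut,normal_cut thresholds (defaults 200 and -100).
#' @return Character vector of statuses.
#' @export
gs_validate_alt <- function(signed_q_tumor, signed_q_normal,
                            tumor_cut = 200, normal_cut = -100) {
  ifelse(signed_q_tumor > tumor_cut & signed_q_normal < normal_cut,
         "somatic", "non_somatic")
}

#' Reconcile the two gold-standard criteria
#'
#' When the VAF rule and the signed-quality rule disagree on somatic vs
#' non-somatic the site is `ambiguous` and excluded from evaluation sets
#' rather than adjudicated. When they agree, the VAF rule's status (which
#' refines non-somatic into wildtype) is kept.
#'
#' @param status_vaf statuses from [gs_validate()].
#' @param status_q statuses from [gs_validate_alt()].
#' @return Character vector of reconciled statuses.
#' @export
reconcile_gs <- function(status_vaf, status_q) {
  som_vaf <- status_vaf == "somatic"
  som_q <- status_q == "somatic"
  out <- status_vaf
  out[som_vaf != som_q] <- "ambiguous"
  out[status_vaf == "not_evaluable"] <- "not_evaluable"
  out
}

#' Pseudo-validation by signed quality thresholds
#'
#' A site is pseudo-positive iff the signed tumor quality is `> q_t` and
#' the signed normal quality is `< q_n` (both strict).
#'
#' @param signed_q_tumor,signed_q_normal signed quality scores.
#' @param q_t,q_n thresholds (headline defaults 200 and -50).
#' @return Logical vector.
#' @export
pseudo_validate <- function(signed_q_tumor, signed_q_normal,
                            q_t = 200, q_n = -50) {
  signed_q_tumor > q_t & signed_q_normal < q_n
}

#' RNA-seq validation
#'
#' Sites with RNA depth below `min_depth` are `not_evaluable`. Otherwise
#' a site is `positive` iff the tumor RNA VAF is `> f_t` and the normal
#' exome VAF is `< f_n`, else `negative`.
#'
#' @param rna_depth tumor RNA-seq depth.
#' @param rna_vaf tumor RNA-seq VAF.
#' @param normal_exome_vaf matched-normal exome VAF.
#' @param f_t,f_n thresholds (defaults 0.10 and 0.02).
#' @param min_depth minimum RNA depth (default 10).
#' @return Character vector in `positive` / `negative` / `not_evaluable`.
#' @export
rna_validate <- function(rna_depth, rna_vaf, normal_exome_vaf,
                         f_t = 0.10, f_n = 0.02, min_depth = 10L) {
  if (min_depth < 1) stop("min_depth must be >= 1")
  out <- ifelse(rna_vaf > f_t & normal_exome_vaf < f_n, "positive", "negative")
  out[is.na(rna_vaf) | is.na(normal_exome_vaf)] <- "not_evaluable"
  out[is.na(rna_depth) | rna_depth < min_depth] <- "not_evaluable"
  out
}

#' Exome strand-bias filter (variant vs reference allele)
#'
#' Filters a site when the variant allele is strand-extreme (> 95% or < 5%
#' of variant reads on the forward strand) while the reference allele is
#' not itself extreme (forward fraction strictly inside (0.30, 0.70)).
#' Undefined fractions (no variant or no reference reads) are not filtered
#' and are returned as NA so callers can flag them.
#'
#' @param alt_fwd_frac forward-strand fraction of variant-allele reads.
#' @param ref_fwd_frac forward-strand fraction of reference-allele reads.
#' @param hi,lo variant-allele extremity cuts (defaults 0.95, 0.05).
#' @param ref_lo,ref_hi reference-allele non-extreme interval (0.30, 0.70).
#' @return Logical vector (NA where a fraction is undefined).
#' @export
exome_strand_filter <- function(alt_fwd_frac, ref_fwd_frac,
                                hi = 0.95, lo = 0.05,
                                ref_lo = 0.30, ref_hi = 0.70) {
  (alt_fwd_frac > hi | alt_fwd_frac < lo) &
    (ref_fwd_frac > ref_lo & ref_fwd_frac < ref_hi)
}

#' RNA strand-bias filter (both assays extreme)
#'
#' Filters a site when the variant allele shows strong strand bias (> 95%
#' or < 5% forward) in **both** the tumor exome-seq and the tumor RNA-seq.
#'
#' @param alt_fwd_frac_exome,alt_fwd_frac_rna forward-strand fractions of
#'   variant reads in the two assays.
#' @param hi,lo extremity cuts (defaults 0.95, 0.05).
#' @return Logical vector (NA where a fraction is undefined).
#' @export
rna_strand_filter <- function(alt_fwd_frac_exome, alt_fwd_frac_rna,
                              hi = 0.95, lo = 0.05) {
  (alt_fwd_frac_exome > hi | alt_fwd_frac_exome < lo) &
    (alt_fwd_frac_rna > hi | alt_fwd_frac_rna < lo)
}

#' Mark strand-extreme sites
#'
#' TRUE iff more than 95% or less than 5% of the reads carrying the
#' variant allele are on the forward strand (strict comparisons).
#'
#' @param alt_fwd_frac forward-strand fraction of variant reads.
#' @param hi,lo cuts (defaults 0.95, 0.05).
#' @return Logical vector.
#' @export
strand_bias_flag <- function(alt_fwd_frac, hi = 0.95, lo = 0.05) {
  alt_fwd_frac > hi | alt_fwd_frac < lo
}

#' Build the gold-standard evaluation set
#'
#' Applies the evaluation-set construction filters in order: deep-seq
#' tumor depth >= `deep_min`, exome tumor AND normal depth >= `exome_min`,
#' and removal of sites where the two gold-standard criteria disagree
#' (ambiguous). Each surviving site is labeled by [gs_validate()].
#'
#' @param evidence a site-evidence table (see [simulate_evidence()] for the
#'   column schema).
#' @param deep_min minimum deep-seq tumor depth (default 100).
#' @param exome_min minimum exome tumor and normal depth (default 10).
#' @param thresholds threshold list, see [default_thresholds()].
#' @return The surviving rows of `evidence` with added columns
#'   `deep_tumor_vaf`, `deep_normal_vaf`, `gs_status`.
#' @export
build_evaluation_set <- function(evidence, deep_min = 100, exome_min = 10,
                                 thresholds = default_thresholds()) {
  keep <- !is.na(evidence$deep_tumor_depth) & evidence$deep_tumor_depth >= deep_min
  ev <- evidence[keep, , drop = FALSE]
  keep2 <- !is.na(ev$exome_tumor_depth) & ev$exome_tumor_depth >= exome_min &
    !is.na(ev$exome_normal_depth) & ev$exome_normal_depth >= exome_min
  ev <- ev[keep2, , drop = FALSE]
  ev$deep_tumor_vaf <- vaf(ev$deep_tumor_alt, ev$deep_tumor_depth)
  ev$deep_normal_vaf <- vaf(ev$deep_normal_alt, ev$deep_normal_depth)
  s_vaf <- gs_validate(ev$deep_tumor_vaf, ev$deep_normal_vaf,
                       thresholds$gs_tumor_vaf, thresholds$gs_normal_vaf)
  s_q <- gs_validate_alt(ev$signed_q_tumor, ev$signed_q_normal,
                         thresholds$gs_q_tumor, thresholds$gs_q_normal)
  status <- reconcile_gs(s_vaf, s_q)
  ev <- ev[status != "ambiguous", , drop = FALSE]
  ev$gs_status <- status[status != "ambiguous"]
  rownames(ev) <- NULL
  ev
}

#' Variant allele fraction
#'
#' `alt / depth`, undefined (NA) when depth is zero or missing.
#'
#' @param alt variant-allele read count.
#' @param depth total read depth.
#' @return Numeric vector of fractions with NA where undefined.
#' @export
vaf <- function(alt, depth) {
  out <- rep(NA_real_, length(alt))
  ok <- !is.na(depth) & depth > 0
  out[ok] <- alt[ok] / depth[ok]
  out
}
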