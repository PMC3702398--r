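# End-to-end orchestration: simulate a cohort to disk, run the full
# comparison on a cohort directory, and recompute the in-text worked
# examples from their embedded inputs.

#' Simulate a cohort and write it to disk
#'
#' @param config a [simulation_config()].
#' @param outdir output directory.
#' @return Path to the cohort manifest, invisibly.
#' @export
run_simulate <- function(config = simulation_config(), outdir) {
  cohort <- simulate_cohort(config)
  write_cohort(cohort, outdir)
}

read_cohort_config <- function(dir) {
  cfg_path <- file.path(dir, "config.yaml")
  if (!file.exists(cfg_path)) return(NULL)
  yaml::read_yaml(cfg_path)
}

#' Run the full multi-caller comparison on a cohort directory
#'
#' Stages run in order: parse per-caller VCFs, build detection patterns,
#' descriptive discrepancy summaries, validation schemes (gold standard,
#' pseudo, RNA -- each only where its evidence exists), the latent class
#' fit, and the performance report. Per-stage site counts go to `message()`.
#'
#' @param dir cohort directory (as written by [run_simulate()]).
#' @param thresholds threshold list, see [default_thresholds()].
#' @param fit_random_effects also fit the RE model (needs K >= 4)?
#' @return A list report with elements `patterns`, `pattern_counts`,
#'   `discrepancy`, `labels`, `lcm`, `performance`.
#' @export
run_compare <- function(dir, thresholds = default_thresholds(),
                        fit_random_effects = FALSE) {
  cfg <- read_cohort_config(dir)
  if (is.null(cfg)) stop("data error [stage parse]: no config.yaml in ", dir)
  callers <- cfg$caller_names
  vcfs <- list.files(dir, pattern = "^caller.*\\.vcf$", full.names = TRUE)

  raw <- list()
  callsets <- list()
  for (ck in callers) {
    files <- grep(paste0("caller", ck, "_"), vcfs, value = TRUE, fixed = TRUE)
    recs <- do.call(rbind, lapply(files, function(f) {
      p <- sub(paste0("^caller", ck, "_(.*)\\.vcf$"), "\\1", basename(f))
      parse_caller_vcf(f, caller_id = ck, patient_id = p)
    }))
    raw[[ck]] <- recs
    callsets[[ck]] <- final_somatic_set(recs)
    message("stage parse: caller ", ck, ": ", nrow(recs), " records, ",
            nrow(callsets[[ck]]), " final somatic calls")
  }

  patterns <- detection_patterns(callsets, callers)
  message("stage patterns: ", nrow(patterns), " union sites")

  evidence <- NULL
  ev_path <- file.path(dir, "evidence.tsv")
  if (file.exists(ev_path)) {
    evidence <- read.delim(ev_path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  }
  zero_cell <- if (!is.null(evidence))
    sum(!site_key(evidence) %in% site_key(patterns)) else 0L
  counts <- pattern_count_table(patterns, zero_cell_count = zero_cell,
                                callers = callers)

  um <- unique_and_missed(patterns)
  disc <- list(
    venn = venn_counts(patterns),
    agreement = agreement_summary(patterns),
    unique_and_missed = um,
    raw_presence = vapply(callers, function(ck)
      raw_vcf_presence(um$all_but[[ck]], raw[[ck]]), numeric(1))
  )
  if (!is.null(evidence)) {
    disc$normal_vaf_screen <- normal_vaf_screen(patterns, evidence)
    disc$depth_vaf <- depth_vaf_strata(patterns, evidence)
  }
  message("stage discrepancy: done")

  labels <- list()
  if (!is.null(evidence)) {
    i <- match(site_key(patterns), site_key(evidence))
    ev <- evidence[i, , drop = FALSE]
    if (all(c("deep_tumor_depth", "deep_normal_depth") %in% names(ev))) {
      s_vaf <- gs_validate(vaf(ev$deep_tumor_alt, ev$deep_tumor_depth),
                           vaf(ev$deep_normal_alt, ev$deep_normal_depth),
                           thresholds$gs_tumor_vaf, thresholds$gs_normal_vaf)
      s_q <- gs_validate_alt(ev$signed_q_tumor, ev$signed_q_normal,
                             thresholds$gs_q_tumor, thresholds$gs_q_normal)
      labels$byGS <- reconcile_gs(s_vaf, s_q)
    }
    labels$byPseudo <- ifelse(
      pseudo_validate(ev$signed_q_tumor, ev$signed_q_normal,
                      thresholds$q_t, thresholds$q_n),
      "positive", "negative")
    if ("rna_depth" %in% names(ev)) {
      labels$byRNA <- rna_validate(ev$rna_depth,
                                   vaf(ev$rna_alt, ev$rna_depth),
                                   vaf(ev$exome_normal_alt, ev$exome_normal_depth),
                                   thresholds$f_t, thresholds$f_n,
                                   thresholds$rna_min_depth)
    } else {
      message("stage validation: RNA evidence absent; RNA scheme unavailable")
    }
    message("stage validation: ", length(labels), " scheme(s) labeled")
  }

  lcm <- list(ci = fit_ci(counts))
  if (fit_random_effects && attr(counts, "K") >= 4) {
    lcm$re <- fit_re(counts)
  }
  message("stage lcm: CI chi-square ",
          format(lcm$ci$pearson$chi2_unpooled, digits = 4), " on ",
          lcm$ci$pearson$df_unpooled, " df")

  perf <- if (length(labels))
    method_comparison_report(patterns, labels, lcm_fit = lcm$ci) else NULL
  message("stage performance: done")

  list(patterns = patterns, pattern_counts = counts, discrepancy = disc,
       labels = labels, lcm = lcm, performance = perf)
}

#' Recompute the in-text worked examples
#'
#' All inputs are embedded: the 76-gene validation pattern table (via
#' [table1_fixture()]), and the printed counts of the pseudo- and RNA-seq
#' validation examples, pushed through the ROC machinery.
#'
#' * Pseudo: of 6,692 evaluation sites (334 somatic), 287 exceed a tumor
#'   signed-quality of 300, 265 of them true; the exome strand filter
#'   removes 18 of the 22 false positives.
#' * RNA: of 1,945 sites with RNA depth >= 10x (95 somatic), 98 exceed 10%
#'   RNA VAF, 84 of them true; the RNA strand filter removes 9 of 14 false
#'   positives.
#'
#' @return List with the fixture totals, the Table-1 latent class fit, and
#'   the pre-/post-filter ROC points of the two examples.
#' @export
run_paper_examples <- function() {
  fx <- table1_fixture()
  detected_ge1 <- sum(fx[names(fx) != "0000"])
  fit <- fit_ci(fx)

  pseudo <- worked_example_curve(n_universe = 6692, n_true = 334,
                                 tp_at_cut = 265, fp_at_cut = 22,
                                 fp_filtered = 18, cutoff = 300)
  rna <- worked_example_curve(n_universe = 1945, n_true = 95,
                              tp_at_cut = 84, fp_at_cut = 14,
                              fp_filtered = 9, cutoff = 0.10)

  list(detected_by_at_least_one = detected_ge1,
       table1_fit = fit,
       pseudo = pseudo, rna = rna)
}

# Reconstruct a score/truth/filter configuration consistent with a printed
# worked example and sweep it through roc_like_curve.
worked_example_curve <- function(n_universe, n_true, tp_at_cut, fp_at_cut,
                                 fp_filtered, cutoff) {
  truth <- c(rep(TRUE, n_true), rep(FALSE, n_universe - n_true))
  score <- numeric(n_universe)
  score[seq_len(tp_at_cut)] <- cutoff * 1.01
  fp_idx <- n_true + seq_len(fp_at_cut)
  score[fp_idx] <- cutoff * 1.01
  flags <- rep(FALSE, n_universe)
  flags[fp_idx[seq_len(fp_filtered)]] <- TRUE
  list(
    before = roc_like_curve(score, truth, cutoff),
    after = roc_like_curve(score, truth, cutoff, filter_flags = flags)
  )
}
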