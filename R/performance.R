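# Turning validation labels and detection patterns into per-caller error
# rates, ROC-like curves, rescaled FP rates and ascertainment diagnostics.

positive_statuses <- c("somatic", "positive")
negative_statuses <- c("non_somatic", "wildtype", "germline", "negative")

#' Per-caller confusion counts against a validation scheme
#'
#' Sites whose label is `not_attempted` / `unknown` / `nonMAF` /
#' `not_evaluable`, or which fall outside `ascertainment_mask`, are
#' excluded from every rate denominator and reported as `n_not_attempted`.
#' FP rate = FP/(FP+TN); FN rate = FN/(FN+TP); empty denominators give NA,
#' never 0.
#'
#' @param patterns a [detection_patterns()] table.
#' @param labels per-site statuses aligned with `patterns` (or a named
#'   vector keyed by site).
#' @param ascertainment_mask optional logical vector: was validation
#'   attempted for the site?
#' @return `data.frame` with one row per caller: TP, FP, FN, TN,
#'   n_not_attempted, fp_rate, fn_rate.
#' @export
confusion_per_caller <- function(patterns, labels, ascertainment_mask = NULL) {
  callers <- attr(patterns, "callers")
  bits <- pattern_bits(patterns$pattern)
  if (!is.null(names(labels))) labels <- labels[site_key(patterns)]
  stopifnot(length(labels) == nrow(patterns))
  attempted <- labels %in% c(positive_statuses, negative_statuses)
  if (!is.null(ascertainment_mask)) attempted <- attempted & ascertainment_mask
  truth <- labels %in% positive_statuses
  out <- do.call(rbind, lapply(seq_along(callers), function(k) {
    called <- bits[, k] == 1
    tp <- sum(attempted & called & truth)
    fp <- sum(attempted & called & !truth)
    fn <- sum(attempted & !called & truth)
    tn <- sum(attempted & !called & !truth)
    data.frame(caller = callers[k], TP = tp, FP = fp, FN = fn, TN = tn,
               n_not_attempted = sum(!attempted),
               fp_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
               fn_rate = if (fn + tp > 0) fn / (fn + tp) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' ROC-like curve: true positive rate against false discovery rate
#'
#' For each threshold, the positives are the sites whose score exceeds it
#' (strictly); when `filter_flags` is supplied, flagged sites are removed
#' from the positive set first. TPR = TP / total true; FDR = FP/(TP+FP),
#' NA when there are no positives.
#'
#' @param score per-site real score (higher = more confident call).
#' @param truth per-site logical: is the site a true somatic mutation?
#' @param thresholds thresholds to sweep.
#' @param filter_flags optional logical: site removed by a strand filter.
#' @return `data.frame` of threshold, TP, FP, n_positive, tpr, fdr.
#' @export
roc_like_curve <- function(score, truth, thresholds, filter_flags = NULL) {
  stopifnot(length(score) == length(truth))
  if (is.null(filter_flags)) filter_flags <- rep(FALSE, length(score))
  filter_flags[is.na(filter_flags)] <- FALSE
  n_true <- sum(truth)
  out <- do.call(rbind, lapply(sort(thresholds, decreasing = TRUE), function(t) {
    pos <- !is.na(score) & score > t & !filter_flags
    tp <- sum(pos & truth)
    fp <- sum(pos & !truth)
    data.frame(threshold = t, TP = tp, FP = fp, n_positive = tp + fp,
               tpr = if (n_true > 0) tp / n_true else NA_real_,
               fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Rescale a false-positive count to a reference prevalence
#'
#' Expresses false positives per expected negative site under a universe
#' in which `ref_prevalence` of sites are truly somatic: with
#' `n_true_pos_eval` validated positives, the expected negative count is
#' `n_true_pos_eval * (1 - p) / p`, and the rescaled rate is the FP count
#' divided by it. This makes FP rates comparable across validation schemes
#' whose evaluable universes differ.
#'
#' @param fp_count false-positive count.
#' @param n_true_pos_eval number of validated true positives in the
#'   scheme's evaluable universe (> 0).
#' @param ref_prevalence reference somatic prevalence (default 0.03).
#' @return Rescaled FP rate.
#' @export
rescale_fp <- function(fp_count, n_true_pos_eval, ref_prevalence = 0.03) {
  if (n_true_pos_eval <= 0) stop("n_true_pos_eval must be > 0")
  fp_count / (n_true_pos_eval * (1 - ref_prevalence) / ref_prevalence)
}

#' Cross-tabulate detection patterns against validation groups
#'
#' Detects caller-driven ascertainment: if at least `flag_share` of the
#' attempted-validation sites carry caller k's bit, validation was in
#' effect restricted to that caller's calls, and rates for other callers
#' computed from these labels would be biased.
#'
#' @param labels per-site validation-group statuses (may include
#'   `not_attempted`, `unknown`, `nonMAF`).
#' @param patterns a [detection_patterns()] table aligned with `labels`.
#' @param flag_share share triggering the flag (default 0.99).
#' @return List with the `crosstab` (pattern x group) and `flagged`
#'   caller names (possibly empty).
#' @export
ascertainment_crosstab <- function(labels, patterns, flag_share = 0.99) {
  callers <- attr(patterns, "callers")
  if (!is.null(names(labels))) labels <- labels[site_key(patterns)]
  crosstab <- table(pattern = patterns$pattern, group = labels)
  attempted <- labels %in% c(positive_statuses, negative_statuses)
  flagged <- character(0)
  if (any(attempted)) {
    bits <- pattern_bits(patterns$pattern)
    share <- colMeans(bits[attempted, , drop = FALSE] == 1)
    flagged <- callers[share >= flag_share]
  }
  list(crosstab = crosstab, flagged = flagged)
}

#' Per-caller, per-scheme method comparison report
#'
#' Assembles FN rates and rescaled FP rates for every caller under every
#' supplied validation scheme (plus, optionally, the marginal rates of a
#' latent class fit), and the pairwise agreement of schemes on their
#' shared evaluable sites.
#'
#' @param patterns a [detection_patterns()] table.
#' @param labels_list named list of per-site status vectors, one per
#'   scheme, each aligned with `patterns`.
#' @param lcm_fit optional `lcm_fit`; its FP rates are rescaled with the
#'   same reference prevalence.
#' @param ref_prevalence reference prevalence for FP rescaling.
#' @return List with `rates` (caller x scheme table of fn_rate and
#'   rescaled fp) and `agreement` (pairwise scheme agreement fractions).
#' @export
method_comparison_report <- function(patterns, labels_list, lcm_fit = NULL,
                                     ref_prevalence = 0.03) {
  stopifnot(length(labels_list) >= 1)
  rates <- do.call(rbind, lapply(names(labels_list), function(sch) {
    cc <- confusion_per_caller(patterns, labels_list[[sch]])
    n_true <- cc$TP[1] + cc$FN[1]
    cc$fp_rescaled <- if (n_true > 0)
      rescale_fp(cc$FP, n_true, ref_prevalence) else NA_real_
    cc$scheme <- sch
    cc[, c("scheme", "caller", "TP", "FP", "FN", "TN", "fp_rate",
           "fp_rescaled", "fn_rate")]
  }))
  if (!is.null(lcm_fit)) {
    pr <- if (lcm_fit$model == "ci") {
      list(fp = lcm_fit$params$fp, fn = lcm_fit$params$fn)
    } else marginal_rates(lcm_fit$params)
    # under the latent model the negative:positive ratio is (1-eta):eta;
    # rescale to the common reference prevalence
    eta <- lcm_fit$params$eta
    scale <- ((1 - eta) / eta) / ((1 - ref_prevalence) / ref_prevalence)
    rates <- rbind(rates, data.frame(
      scheme = "byLatent", caller = attr(patterns, "callers"),
      TP = NA, FP = NA, FN = NA, TN = NA,
      fp_rate = pr$fp, fp_rescaled = pr$fp * scale, fn_rate = pr$fn,
      stringsAsFactors = FALSE))
  }
  rownames(rates) <- NULL

  schemes <- names(labels_list)
  agreement <- NULL
  if (length(schemes) >= 2) {
    pairs <- utils::combn(schemes, 2)
    agreement <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- labels_list[[pairs[1, j]]]
      b <- labels_list[[pairs[2, j]]]
      eval_a <- a %in% c(positive_statuses, negative_statuses)
      eval_b <- b %in% c(positive_statuses, negative_statuses)
      both <- eval_a & eval_b
      pos_a <- a[both] %in% positive_statuses
      pos_b <- b[both] %in% positive_statuses
      data.frame(scheme_a = pairs[1, j], scheme_b = pairs[2, j],
                 n_shared = sum(both),
                 agreement = if (sum(both)) mean(pos_a == pos_b) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  list(rates = rates, agreement = agreement)
}
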