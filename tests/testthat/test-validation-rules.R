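test_that("signed_quality applies the sign-flip contract", {
  expect_equal(signed_quality(300, TRUE), 300)
  expect_equal(signed_quality(150, FALSE), -150)
  expect_equal(signed_quality(0, FALSE), 0)
  expect_error(signed_quality(-1, TRUE), "non-negative")
  expect_equal(signed_quality(c(10, 20), c(TRUE, FALSE)), c(10, -20))
})

test_that("gold-standard VAF rule partitions sites as printed", {
  expect_equal(gs_validate(0.12, 0.01), "somatic")
  expect_equal(gs_validate(0.01, 0.01), "wildtype")
  expect_equal(gs_validate(0.45, 0.44), "non_somatic")
  # strict boundaries fall negative
  expect_equal(gs_validate(0.10, 0.01), "non_somatic")
  expect_equal(gs_validate(0.12, 0.02), "non_somatic")
  expect_equal(gs_validate(NA, 0.01), "not_evaluable")
})

test_that("the signed-quality gold-standard rule uses strict 200/-100 cuts", {
  expect_equal(gs_validate_alt(250, -150), "somatic")
  expect_equal(gs_validate_alt(250, -50), "non_somatic")
  expect_equal(gs_validate_alt(199.9, -150), "non_somatic")
  expect_equal(gs_validate_alt(200, -150), "non_somatic")
})

test_that("disagreeing gold-standard criteria yield ambiguous, never adjudicated", {
  expect_equal(reconcile_gs("somatic", "somatic"), "somatic")
  expect_equal(reconcile_gs("somatic", "non_somatic"), "ambiguous")
  expect_equal(reconcile_gs("non_somatic", "somatic"), "ambiguous")
  expect_equal(reconcile_gs("wildtype", "non_somatic"), "wildtype")
})

test_that("pseudo-validation uses strict threshold comparisons", {
  expect_true(pseudo_validate(310, -60, q_t = 300, q_n = -50))
  expect_false(pseudo_validate(200, -60, q_t = 200, q_n = -50))
  expect_false(pseudo_validate(310, -50, q_t = 300, q_n = -50))
  # defaults are the headline 200 / -50 pair
  expect_true(pseudo_validate(201, -51))
  expect_false(pseudo_validate(201, -49))
})

test_that("RNA validation enforces the depth restriction", {
  expect_equal(rna_validate(50, 0.30, 0.00), "positive")
  expect_equal(rna_validate(5, 0.50, 0.00), "not_evaluable")
  expect_equal(rna_validate(50, 0.05, 0.00), "negative")
  expect_equal(rna_validate(50, 0.30, 0.05), "negative")
  expect_equal(rna_validate(10, 0.30, 0.00), "positive")  # >= min_depth
  expect_error(rna_validate(50, 0.3, 0, min_depth = 0), "min_depth")
})

test_that("strand filters implement the variant-vs-reference asymmetry", {
  expect_true(exome_strand_filter(0.97, 0.50))
  expect_false(exome_strand_filter(0.50, 0.50))
  expect_false(exome_strand_filter(0.97, 0.98))  # reference equally extreme
  expect_false(exome_strand_filter(0.97, 0.30))  # boundary excluded
  expect_true(is.na(exome_strand_filter(NA, 0.5)))

  expect_true(rna_strand_filter(0.98, 0.97))
  expect_false(rna_strand_filter(0.98, 0.50))
  expect_true(rna_strand_filter(0.04, 0.03))

  expect_true(strand_bias_flag(0.96))
  expect_false(strand_bias_flag(0.95))
  expect_false(strand_bias_flag(0.50))
  expect_true(strand_bias_flag(0.04))
})

test_that("raising thresholds never adds positives (nested positive sets)", {
  set.seed(11)
  qt <- runif(500, -400, 400)
  qn <- runif(500, -400, 400)
  cuts <- sort(runif(8, -100, 300))
  prev <- NULL
  for (q in cuts) {
    pos <- which(pseudo_validate(qt, qn, q_t = q, q_n = -50))
    if (!is.null(prev)) expect_true(all(pos %in% prev))
    prev <- pos
  }
  rv <- runif(500)
  nv <- runif(500, 0, 0.1)
  prev <- NULL
  for (f in seq(0.05, 0.5, by = 0.05)) {
    pos <- which(rna_validate(rep(50, 500), rv, nv, f_t = f) == "positive")
    if (!is.null(prev)) expect_true(all(pos %in% prev))
    prev <- pos
  }
})

test_that("gs_validate partitions evaluable sites exclusively", {
  set.seed(12)
  tv <- runif(2000)
  nv <- runif(2000, 0, 0.3)
  st <- gs_validate(tv, nv)
  expect_true(all(st %in% c("somatic", "wildtype", "non_somatic")))
  som <- tv > 0.10 & nv < 0.02
  wt <- !som & tv < 0.02 & nv < 0.02
  expect_equal(st == "somatic", som)
  expect_equal(st == "wildtype", wt)
})

test_that("strand filters only remove positives, never add them", {
  set.seed(13)
  score <- runif(400, 0, 400)
  truth <- runif(400) < 0.1
  flags <- runif(400) < 0.2
  before <- roc_like_curve(score, truth, thresholds = c(100, 200))
  after <- roc_like_curve(score, truth, thresholds = c(100, 200),
                          filter_flags = flags)
  expect_true(all(after$TP <= before$TP))
  expect_true(all(after$FP <= before$FP))
})

test_that("evaluation-set construction applies depth filters in order", {
  set.seed(14)
  cohort <- simulate_cohort(small_config(seed = 21))
  ev <- cohort$evidence
  built <- build_evaluation_set(ev)
  # independent brute-force recount
  k1 <- ev$deep_tumor_depth >= 100
  k2 <- k1 & ev$exome_tumor_depth >= 10 & ev$exome_normal_depth >= 10
  sv <- gs_validate(ifelse(ev$deep_tumor_depth > 0,
                           ev$deep_tumor_alt / ev$deep_tumor_depth, NA),
                    ifelse(ev$deep_normal_depth > 0,
                           ev$deep_normal_alt / ev$deep_normal_depth, NA))
  sq <- gs_validate_alt(ev$signed_q_tumor, ev$signed_q_normal)
  amb <- (sv == "somatic") != (sq == "somatic") & sv != "not_evaluable"
  expect_equal(nrow(built), sum(k2 & !amb))
  expect_true(all(built$deep_tumor_depth >= 100))
  expect_true(all(built$exome_normal_depth >= 10))
  # boundary: depth 99 deep / depth 9 exome excluded
  ev2 <- ev[1:2, ]
  ev2$deep_tumor_depth <- c(99L, 150L)
  ev2$exome_normal_depth <- c(50L, 9L)
  expect_equal(nrow(build_evaluation_set(ev2)), 0L)
})

test_that("the exome strand filter removes artifact false positives at the configured rate", {
  set.seed(15)
  cfg <- simulation_config(n_patients = 10, sites_per_patient = 2000, eta = 0,
                           germline_fraction = 0,
                           wildtype_artifact_fraction = 1,
                           strand_artifact_prob = 0.5)
  tr <- simulate_truth(cfg)
  ev <- simulate_evidence(tr, cfg)
  ok <- ev$exome_tumor_alt >= 5 & (ev$exome_tumor_depth - ev$exome_tumor_alt) >= 5
  filt <- exome_strand_filter(ev$exome_tumor_alt_fwd / ev$exome_tumor_alt,
                              ev$exome_tumor_ref_fwd /
                                (ev$exome_tumor_depth - ev$exome_tumor_alt))
  expect_lt(abs(mean(filt[ok]) - cfg$strand_artifact_prob), 0.05)
})
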