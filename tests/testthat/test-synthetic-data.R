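test_that("truth simulation respects degenerate prevalence settings", {
  set.seed(1)
  cfg0 <- simulation_config(n_patients = 2, sites_per_patient = 100, eta = 0,
                            germline_fraction = 0, wildtype_artifact_fraction = 0)
  tr0 <- simulate_truth(cfg0)
  expect_true(all(tr0$D == "clean_wildtype"))
  expect_true(all(tr0$true_tumor_vaf == 0 & tr0$true_normal_vaf == 0))

  # eta = 1: all somatic; mean tumor VAF = purity * E[c] / 2 (c ~ U[0.2, 1])
  cfg1 <- simulation_config(n_patients = 10, sites_per_patient = 2000, eta = 1)
  tr1 <- simulate_truth(cfg1)
  expect_true(all(tr1$D == "somatic"))
  expect_true(all(tr1$true_normal_vaf == 0))
  mu <- cfg1$purity * 0.6 / 2
  sd_c <- cfg1$purity / 2 * sqrt((1 - 0.2)^2 / 12)
  expect_lt(abs(mean(tr1$true_tumor_vaf) - mu), 3 * sd_c / sqrt(nrow(tr1)))
})

test_that("somatic fraction matches the configured prevalence", {
  set.seed(2)
  cfg <- simulation_config(n_patients = 50, sites_per_patient = 2000, eta = 0.03)
  tr <- simulate_truth(cfg)
  n <- nrow(tr)
  expect_lt(abs(mean(tr$D == "somatic") - 0.03),
            3 * sqrt(0.03 * 0.97 / n))
  # non-somatic mass split per configuration
  nonsom <- tr$D != "somatic"
  expect_lt(abs(mean(tr$D[nonsom] == "germline") - cfg$germline_fraction), 0.02)
  expect_lt(abs(mean(tr$D[nonsom] == "wildtype_artifact") -
                  cfg$wildtype_artifact_fraction), 0.02)
})

test_that("caller calls collapse to exact Bernoulli rates when sigma = 0", {
  set.seed(3)
  cfg <- simulation_config(n_patients = 1, sites_per_patient = 500, eta = 0.5,
                           caller_fp = rep(0, 4), caller_fn = rep(0, 4))
  tr <- simulate_caller_calls(simulate_truth(cfg), cfg)
  for (ck in cfg$caller_names) {
    expect_equal(tr[[paste0("Y_", ck)]], tr$D == "somatic")
  }
})

test_that("sigma = 0 pattern frequencies match the conditional-independence model", {
  set.seed(4)
  cfg <- simulation_config(n_patients = 100, sites_per_patient = 1000,
                           eta = 0.05,
                           caller_fp = c(0.01, 0.02, 0.05, 0.03),
                           caller_fn = c(0.2, 0.3, 0.1, 0.15))
  tr <- simulate_caller_calls(simulate_truth(cfg), cfg)
  ymat <- sapply(cfg$caller_names, function(ck) tr[[paste0("Y_", ck)]]) * 1L
  pat <- apply(ymat, 1, paste, collapse = "")
  n <- nrow(tr)
  p <- ci_pattern_prob(lcm_ci_params(cfg$eta, cfg$caller_fp, cfg$caller_fn))
  obs <- table(factor(pat, levels = names(p)))
  for (cell in names(p)) {
    sd_cell <- sqrt(n * p[cell] * (1 - p[cell]))
    expect_lt(abs(obs[cell] - n * p[cell]), 3 * sd_cell + 3)
  }
})

test_that("with a random effect the marginal rates stay calibrated", {
  set.seed(5)
  cfg <- simulation_config(n_patients = 50, sites_per_patient = 1000,
                           eta = 0.5, sigma = 1.5)
  tr <- simulate_caller_calls(simulate_truth(cfg), cfg)
  som <- tr$D == "somatic"
  for (k in seq_len(cfg$K)) {
    y <- tr[[paste0("Y_", cfg$caller_names[k])]]
    sens <- 1 - cfg$caller_fn[k]
    expect_lt(abs(mean(y[som]) - sens),
              3 * sqrt(sens * (1 - sens) / sum(som)))
    fp <- cfg$caller_fp[k]
    expect_lt(abs(mean(y[!som]) - fp),
              3 * sqrt(fp * (1 - fp) / sum(!som)) + 5 / sum(!som))
  }
})

test_that("evidence generation honours the error model and strand signature", {
  set.seed(6)
  cfg <- simulation_config(n_patients = 5, sites_per_patient = 2000,
                           eta = 0, germline_fraction = 0,
                           wildtype_artifact_fraction = 0, seq_error = 0)
  tr <- simulate_truth(cfg)
  ev <- simulate_evidence(tr, cfg)
  expect_true(all(ev$exome_tumor_alt == 0 & ev$deep_tumor_alt == 0 &
                    ev$rna_alt == 0))
  expect_true(all(ev$signed_q_tumor[ev$exome_tumor_depth > 0] < 0))

  # artifact sites carry the extreme one-strand signature at the configured rate
  set.seed(7)
  cfg2 <- simulation_config(n_patients = 5, sites_per_patient = 2000, eta = 0,
                            germline_fraction = 0,
                            wildtype_artifact_fraction = 1,
                            strand_artifact_prob = 0.5)
  tr2 <- simulate_truth(cfg2)
  ev2 <- simulate_evidence(tr2, cfg2)
  frac <- ev2$exome_tumor_alt_fwd / ev2$exome_tumor_alt
  ok <- !is.na(frac) & ev2$exome_tumor_alt >= 5
  extreme <- frac[ok] > 0.95 | frac[ok] < 0.05
  expect_lt(abs(mean(extreme) - 0.5), 3 * sqrt(0.25 / sum(ok)) + 0.02)

  # somatic sites: RNA alt reads only where RNA depth > 0; RNA VAF unbiased
  set.seed(8)
  cfg3 <- simulation_config(n_patients = 10, sites_per_patient = 1000, eta = 1,
                            seq_error = 0)
  tr3 <- simulate_truth(cfg3)
  ev3 <- simulate_evidence(tr3, cfg3)
  expect_true(all(ev3$rna_alt[ev3$rna_depth == 0] == 0))
  deep <- ev3$rna_depth >= 20
  expect_lt(abs(mean(ev3$rna_alt[deep] / ev3$rna_depth[deep] -
                       tr3$true_tumor_vaf[deep])), 0.01)
})

test_that("cohorts are reproducible and the manifest tracks the config", {
  d1 <- tempfile("c1"); d2 <- tempfile("c2"); d3 <- tempfile("c3")
  write_cohort(simulate_cohort(small_config(seed = 42)), d1)
  write_cohort(simulate_cohort(small_config(seed = 42)), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_equal(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_equal(unname(h1), unname(h2))

  # 2 patients x 3 callers -> 6 VCFs plus evidence/truth/config in manifest
  cfg <- simulation_config(n_patients = 2, sites_per_patient = 50, K = 3,
                           caller_fp = c(0.01, 0.01, 0.01),
                           caller_fn = c(0.2, 0.2, 0.2), seed = 9)
  man <- yaml::read_yaml(run_simulate(cfg, d3))
  expect_equal(sum(grepl("\\.vcf$", man$files)), 6L)
  expect_equal(sum(grepl("\\.tsv$", man$files)), 2L)

  # config hash changes when any field changes
  d4 <- tempfile("c4")
  cfg2 <- simulation_config(n_patients = 2, sites_per_patient = 50, K = 3,
                            caller_fp = c(0.01, 0.01, 0.01),
                            caller_fn = c(0.2, 0.2, 0.2), seed = 9,
                            purity = 0.8)
  man2 <- yaml::read_yaml(run_simulate(cfg2, d4))
  expect_false(identical(man$config_md5, man2$config_md5))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(germline_fraction = 0.7,
                                 wildtype_artifact_fraction = 0.4), "<= 1")
  expect_error(simulation_config(caller_fp = c(0.5, 0.01, 0.01, 0.01),
                                 caller_fn = c(0.6, 0.2, 0.2, 0.2)),
               "identifiability")
  expect_error(simulation_config(K = 3), "length K")
})
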