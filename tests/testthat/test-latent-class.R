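test_that("ci_pattern_prob matches brute-force enumeration and normalizes", {
  # perfect single caller splits mass by prevalence
  p1 <- ci_pattern_prob(lcm_ci_params(0.5, 0, 0), "1")
  expect_equal(unname(p1), 0.5)

  pars <- lcm_ci_params(0.1, c(.01, .02, .05), c(.2, .3, .1))
  got <- ci_pattern_prob(pars, "101")
  expect_equal(unname(got),
               oracle_ci_prob(0.1, c(.01, .02, .05), c(.2, .3, .1), c(1, 0, 1)),
               tolerance = 1e-12)

  set.seed(21)
  for (i in 1:10) {
    K <- sample(2:5, 1)
    pars <- lcm_ci_params(runif(1, .01, .9), runif(K, .001, .3),
                          runif(K, .05, .4))
    p <- ci_pattern_prob(pars)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    y <- sample(0:1, K, replace = TRUE)
    expect_equal(unname(ci_pattern_prob(pars, y)),
                 oracle_ci_prob(pars$eta, pars$fp, pars$fn, y),
                 tolerance = 1e-12)
  }
})

test_that("ci_loglik sums count-weighted log cell probabilities", {
  pars <- lcm_ci_params(0.2, c(.01, .02, .03), c(.1, .2, .3))
  cells <- ci_pattern_prob(pars)
  counts <- setNames(integer(8), names(cells))
  counts["111"] <- 50L
  pc <- pattern_counts(counts)
  expect_equal(ci_loglik(pars, pc), 50 * log(cells["111"]),
               ignore_attr = TRUE)

  set.seed(22)
  counts2 <- setNames(as.integer(rmultinom(1, 200, rep(1 / 8, 8))),
                      names(cells))
  pc2 <- pattern_counts(counts2)
  expect_equal(ci_loglik(pars, pc2),
               sum(counts2 * log(cells[names(counts2)])), ignore_attr = TRUE)
})

test_that("model degrees of freedom follow the cells-minus-parameters rule", {
  expect_equal(lcm_df(4, "ci"), 6L)
  expect_equal(lcm_df(3, "ci"), 0L)
  expect_equal(lcm_df(4, "re"), 5L)
  expect_error(lcm_df(2, "re"), "not identifiable")
})

test_that("pearson_gof computes and pools correctly", {
  expect_equal(pearson_gof(c(50, 50), c(50, 50))$chi2, 0)
  expect_equal(pearson_gof(c(60, 40), c(50, 50))$chi2, 4)
  set.seed(23)
  o <- rmultinom(1, 500, runif(8))[, 1]
  e <- as.numeric(o + rnorm(8)); e <- e * sum(o) / sum(e)
  if (all(e >= 0.5)) expect_equal(pearson_gof(o, e)$chi2, sum((o - e)^2 / e))
  pooled <- pearson_gof(c(10, 1, 0), c(10.6, 0.2, 0.2))
  expect_equal(pooled$n_pooled, 2L)
  expect_equal(pooled$chi2,
               (10 - 10.6)^2 / 10.6 + (1 - 0.4)^2 / 0.4)
  expect_error(pearson_gof(c(0.2, 0.2), c(0.3, 0.1)), "floor")
})

test_that("EM recovers known conditional-independence parameters", {
  set.seed(24)
  eta <- 0.05
  fp <- c(0.01, 0.003, 0.02, 0.005)
  fn <- c(0.2, 0.35, 0.1, 0.15)
  pc <- draw_ci_counts(eta, fp, fn, 1e5)
  fit <- fit_ci(pc)
  se <- lcm_se(fit)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$eta - eta), 3 * se["eta"])
  for (k in 1:4) {
    expect_lt(abs(fit$params$fp[k] - fp[k]), 3 * se[paste0("fp", k)] + 1e-4)
    expect_lt(abs(fit$params$fn[k] - fn[k]), 3 * se[paste0("fn", k)] + 1e-3)
  }
  # fitted counts conserve the total
  expect_equal(sum(fit$fitted_counts), attr(pc, "N"), tolerance = 1e-8)
})

test_that("EM handles the degenerate two-cell table", {
  counts <- setNames(integer(16), names(table1_fixture()))
  counts["0000"] <- 900L
  counts["1111"] <- 100L
  set.seed(25)
  fit <- fit_ci(pattern_counts(counts))
  expect_lt(abs(fit$params$eta - 0.1), 0.01)
  expect_true(all(fit$params$fp < 0.01))
  expect_true(all(fit$params$fn < 0.01))
})

test_that("EM log-likelihood trace is monotone and label orientation holds", {
  set.seed(26)
  for (i in 1:5) {
    pc <- draw_ci_counts(runif(1, .02, .3), runif(4, .001, .1),
                         runif(4, .05, .4), 2e4)
    fit <- fit_ci(pc, n_restarts = 5)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_true(mean(1 - fit$params$fn) > mean(fit$params$fp))
  }
  expect_error(fit_ci(pattern_counts(setNames(c(5L, 3L, 2L, 1L),
                                              c("00", "10", "01", "11")))),
               "K < 3")
})

test_that("EM attains at least the dense-grid likelihood on K=3 tables", {
  set.seed(27)
  pc <- draw_ci_counts(0.1, c(0.04, 0.08, 0.06), c(0.22, 0.3, 0.26), 3000,
                       callers = c("H", "I", "J"))
  fit <- suppressWarnings(fit_ci(pc))
  expect_gte(fit$loglik, oracle_grid_loglik(pc) - 1e-6)
})

test_that("random-effects pattern probabilities match numerical integration", {
  # sigma = 0 collapses to conditional independence at Phi(a)
  pars0 <- lcm_re_params(0.2, qnorm(c(.01, .05, .1)), qnorm(c(.8, .9, .7)), 0)
  ci0 <- lcm_ci_params(0.2, c(.01, .05, .1), 1 - c(.8, .9, .7))
  expect_equal(re_pattern_prob(pars0), ci_pattern_prob(ci0), tolerance = 1e-12)

  set.seed(28)
  pars <- lcm_re_params(0.15, c(-2.5, -1.8, -2.0), c(1.0, 0.6, 1.4), 1.2)
  p <- re_pattern_prob(pars)
  expect_equal(sum(p), 1, tolerance = 1e-8)
  for (pat in c("000", "101", "111", "010")) {
    y <- as.integer(strsplit(pat, "")[[1]])
    expect_equal(unname(re_pattern_prob(pars, pat)),
                 oracle_re_prob(0.15, pars$a0, pars$a1, 1.2, y),
                 tolerance = 1e-6)
  }
  expect_error(re_pattern_prob(pars, n_quad = 5), "n_quad")
})

test_that("marginal rates use the probit-normal closed form", {
  pars0 <- lcm_re_params(0.2, c(-1, -2), c(1, 2), 0)
  expect_equal(marginal_rates(pars0)$fp, pnorm(c(-1, -2)))
  pars_sym <- lcm_re_params(0.2, c(0, 0), c(1, 1), 3)
  expect_equal(marginal_rates(pars_sym)$fp, c(0.5, 0.5))
  pars <- lcm_re_params(0.2, c(-1.5, -0.5), c(1, 0.3), 2)
  mr <- marginal_rates(pars)
  expect_equal(mr$fp[1], oracle_re_marginal(-1.5, 2), tolerance = 1e-8)
  expect_equal(1 - mr$fn[2], oracle_re_marginal(0.3, 2), tolerance = 1e-8)
})

test_that("the RE fit nests the CI fit and recovers sigma at the boundary", {
  set.seed(29)
  pc <- draw_ci_counts(0.05, c(0.01, 0.003, 0.02, 0.005),
                       c(0.2, 0.35, 0.1, 0.15), 5e4)
  ci <- fit_ci(pc)
  re <- fit_re(pc, n_restarts = 3)
  expect_gte(re$loglik, ci$loglik - 1e-6)
  expect_lt(re$params$sigma, 0.2)
  mr <- marginal_rates(re$params)
  expect_equal(mr$fp, ci$params$fp, tolerance = 0.02)
  expect_equal(mr$fn, ci$params$fn, tolerance = 0.05)

  fx <- table1_fixture()
  set.seed(30)
  fit_fx_ci <- fit_ci(fx)
  fit_fx_re <- fit_re(fx, n_restarts = 3)
  expect_gte(fit_fx_re$loglik, fit_fx_ci$loglik - 1e-6)
})

test_that("fit reports round-trip through JSON", {
  set.seed(31)
  fit <- fit_ci(table1_fixture())
  path <- tempfile(fileext = ".json")
  write_lcm_json(fit, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$model, "ci")
  expect_equal(back$pearson$chi2_unpooled, fit$pearson$chi2_unpooled)
  expect_equal(back$params$eta, fit$params$eta)
  expect_equal(sum(unlist(back$observed_counts)), 4439)
})
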