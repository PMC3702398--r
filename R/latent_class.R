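# Latent class models for per-caller error rates without a gold standard.
#
# K callers evaluate N positions; the true somatic status D of a position is
# latent with prevalence eta. Under conditional independence (CI), callers
# err independently given D, giving 1+2K free parameters (eta plus each
# caller's false-positive and false-negative rate). The random-effects (RE)
# extension induces per-site dependence through a shared standard-normal
# random effect b entering a probit link: P(Y_k=1 | D=d, b) =
# Phi(a_{d,k} + sigma*b), with one variance loading sigma shared between the
# somatic and non-somatic classes (one extra parameter).

#' Conditional-independence latent class parameters
#'
#' @param eta mutation prevalence, in (0,1).
#' @param fp per-caller false-positive rates P(Y=1 | D=0), each in (0,1).
#' @param fn per-caller false-negative rates P(Y=0 | D=1), each in (0,1).
#' @return An object of class `lcm_ci_params`.
#' @export
lcm_ci_params <- function(eta, fp, fn) {
  if (length(fp) != length(fn)) stop("fp and fn must have the same length")
  if (eta <= 0 || eta >= 1) stop("eta must be in (0,1)")
  if (any(fp < 0 | fp >= 1 | fn < 0 | fn >= 1))
    stop("all rates must be in [0,1)")
  if (any(1 - fn <= fp))
    stop("identifiability requires sensitivity 1-fn[k] > fp[k] for every caller")
  structure(list(eta = eta, fp = fp, fn = fn, K = length(fp)),
            class = "lcm_ci_params")
}

#' Random-effects probit latent class parameters
#'
#' @param eta mutation prevalence, in (0,1).
#' @param a0,a1 per-caller probit intercepts for the non-somatic and somatic
#'   classes.
#' @param sigma shared random-effect loading, `>= 0`.
#' @return An object of class `lcm_re_params`.
#' @export
lcm_re_params <- function(eta, a0, a1, sigma) {
  if (length(a0) != length(a1)) stop("a0 and a1 must have the same length")
  if (eta <= 0 || eta >= 1) stop("eta must be in (0,1)")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(eta = eta, a0 = a0, a1 = a1, sigma = sigma, K = length(a0)),
            class = "lcm_re_params")
}

ci_cell_probs <- function(eta, fp, sens, bits) {
  # clamp away from 0/1 so 0 * log(0) cannot produce NaN in the products
  cl <- function(x) pmin(pmax(x, 1e-300), 1 - 1e-16)
  p0 <- exp(bits %*% log(cl(fp)) + (1 - bits) %*% log(cl(1 - fp)))
  p1 <- exp(bits %*% log(cl(sens)) + (1 - bits) %*% log(cl(1 - sens)))
  as.numeric((1 - eta) * p0 + eta * p1)
}

#' Pattern probability under the conditional-independence model
#'
#' `P(Y = y) = (1-eta) prod_k fp_k^{y_k} (1-fp_k)^{1-y_k} +
#'  eta prod_k (1-fn_k)^{y_k} fn_k^{1-y_k}`.
#'
#' @param params an [lcm_ci_params()] object.
#' @param pattern a bitstring (or vector of bitstrings), a 0/1 vector of
#'   length K, or `NULL` for all `2^K` patterns.
#' @return Probability vector (named by bitstring when `pattern` is NULL
#'   or a bitstring).
#' @export
ci_pattern_prob <- function(params, pattern = NULL) {
  bits <- resolve_patterns(pattern, params$K)
  p <- ci_cell_probs(params$eta, params$fp, 1 - params$fn, bits)
  setNames(p, rownames(bits))
}

resolve_patterns <- function(pattern, K) {
  if (is.null(pattern)) return(pattern_bits(all_patterns(K)))
  if (is.character(pattern)) {
    if (any(nchar(pattern) != K)) stop("pattern length must equal K")
    return(pattern_bits(pattern))
  }
  if (length(pattern) != K) stop("pattern length must equal K")
  m <- matrix(as.integer(pattern), nrow = 1)
  rownames(m) <- paste(m[1, ], collapse = "")
  m
}

#' Multinomial log-likelihood of a pattern-count table under the CI model
#'
#' @param params an [lcm_ci_params()] object.
#' @param counts a [pattern_counts()] table with matching K.
#' @param floor probability floor inside logarithms.
#' @return The log-likelihood `sum_y n_y log P(Y=y)` (kernel; no
#'   multinomial coefficient).
#' @export
ci_loglik <- function(params, counts, floor = 1e-12) {
  stopifnot(attr(counts, "K") == params$K)
  p <- ci_pattern_prob(params)[names(counts)]
  sum(as.numeric(counts) * log(pmax(p, floor)))
}

#' Degrees of freedom of the latent class models
#'
#' Cells minus one minus free parameters: `2^K - 1 - (2K+1)` for the CI
#' model and `2^K - 1 - (2K+2)` for the shared-variance RE model.
#'
#' @param K number of callers (`>= 2`).
#' @param model `"ci"` or `"re"`.
#' @return Integer degrees of freedom.
#' @export
lcm_df <- function(K, model = c("ci", "re")) {
  model <- match.arg(model)
  if (K < 2) stop("K must be >= 2")
  df <- 2^K - 1L - (2L * K + 1L) - (model == "re")
  if (df < 0) stop("model not identifiable: negative degrees of freedom for K = ", K)
  as.integer(df)
}

#' Pearson goodness-of-fit statistic with small-cell pooling
#'
#' Computes `sum (O-E)^2 / E`. Cells with expected count below `floor` are
#' pooled into a single remainder cell (the pooled statistic and the number
#' of pooled cells are reported alongside the unpooled statistic, since
#' standard practice varies).
#'
#' @param observed observed counts (a [pattern_counts()] or numeric vector).
#' @param fitted expected counts, same cells and total.
#' @param floor minimum expected count for a cell to stand alone.
#' @return List with `chi2` (pooled), `chi2_unpooled`, `n_pooled`, and
#'   `df_loss` (cells lost to pooling, for df adjustment).
#' @export
pearson_gof <- function(observed, fitted, floor = 0.5) {
  o <- as.numeric(observed)
  e <- as.numeric(fitted)
  if (length(o) != length(e)) stop("observed and fitted must align")
  if (abs(sum(o) - sum(e)) > 1e-6 * max(1, sum(o)))
    stop("fitted total must equal observed total")
  if (all(e < floor)) stop("all cells below the pooling floor; statistic undefined")
  chi2_unpooled <- sum((o - e)^2 / e)
  small <- e < floor
  if (any(small)) {
    chi2 <- sum((o[!small] - e[!small])^2 / e[!small]) +
      (sum(o[small]) - sum(e[small]))^2 / sum(e[small])
    df_loss <- sum(small) - 1L
  } else {
    chi2 <- chi2_unpooled
    df_loss <- 0L
  }
  list(chi2 = chi2, chi2_unpooled = chi2_unpooled,
       n_pooled = sum(small), df_loss = as.integer(df_loss))
}

#' Fit the conditional-independence latent class model by EM
#'
#' Maximum likelihood on a `2^K` pattern-count table via EM with
#' posterior-responsibility E-step and closed-form M-step, restarted from
#' multiple stratified random starts (draws from the session RNG; seed it
#' for reproducibility). The returned solution is oriented so that mean
#' sensitivity exceeds mean false-positive rate (class 1 = somatic).
#'
#' @param counts a [pattern_counts()] table, K >= 3.
#' @param n_restarts number of random starts (default 20).
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations per start.
#' @return An object of class `lcm_fit` with elements `model`, `params`,
#'   `loglik`, `fitted_counts`, `pearson` (chi2 pooled/unpooled, df both
#'   ways), `df`, `converged`, `n_restarts_used`, `loglik_trace`.
#' @export
fit_ci <- function(counts, n_restarts = 20, tol = 1e-8, max_iter = 5000) {
  K <- attr(counts, "K")
  if (K < 3) stop("model not identifiable for K < 3 (no positive degrees of freedom)")
  if (K == 3) warning("K = 3: model is saturated (df = 0); goodness of fit is uninformative")
  bits <- pattern_bits(names(counts))
  n <- as.numeric(counts)
  N <- sum(n)
  if (N <= 0) stop("empty count table")

  best <- NULL
  # stratified starts: eta spread over (0, 1/2), error rates modest
  eta0 <- (seq_len(n_restarts) - runif(n_restarts)) / (2 * n_restarts)
  for (r in seq_len(n_restarts)) {
    fit <- em_ci(n, bits, eta = max(eta0[r], 1e-4),
                 fp = runif(K, 0.001, 0.2), sens = runif(K, 0.5, 0.99),
                 tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  # class orientation: class 1 is the class with higher mean detection rate
  if (mean(best$sens) < mean(best$fp)) {
    best <- list(eta = 1 - best$eta, fp = 1 - best$sens, sens = 1 - best$fp,
                 loglik = best$loglik, trace = best$trace,
                 converged = best$converged)
  }
  params <- structure(list(eta = best$eta, fp = best$fp, fn = 1 - best$sens,
                           K = K), class = "lcm_ci_params")
  finish_fit(params, counts, best$loglik, "ci", best$converged, n_restarts,
             best$trace)
}

em_ci <- function(n, bits, eta, fp, sens, tol, max_iter) {
  N <- sum(n)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  eps <- 1e-10
  for (it in seq_len(max_iter)) {
    w1 <- eta * exp(bits %*% log(pmax(sens, eps)) +
                    (1 - bits) %*% log(pmax(1 - sens, eps)))
    w0 <- (1 - eta) * exp(bits %*% log(pmax(fp, eps)) +
                          (1 - bits) %*% log(pmax(1 - fp, eps)))
    r <- as.numeric(w1 / (w0 + w1))
    eta <- min(max(sum(n * r) / N, eps), 1 - eps)
    m1 <- sum(n * r)
    m0 <- N - m1
    sens <- pmin(pmax(colSums(n * r * bits) / m1, eps), 1 - eps)
    fp <- pmin(pmax(colSums(n * (1 - r) * bits) / m0, eps), 1 - eps)
    ll <- sum(n * log(pmax(ci_cell_probs(eta, fp, sens, bits), 1e-12)))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(eta = eta, fp = fp, sens = sens, loglik = ll, trace = trace,
       converged = converged)
}

finish_fit <- function(params, counts, loglik, model, converged,
                       n_restarts_used, trace) {
  probs <- if (model == "ci") ci_pattern_prob(params)
           else re_pattern_prob(params)
  fitted <- attr(counts, "N") * probs[names(counts)]
  gof <- pearson_gof(counts, fitted)
  df0 <- lcm_df(attr(counts, "K"), model)
  structure(list(
    model = model, params = params, loglik = loglik,
    fitted_counts = fitted,
    pearson = list(chi2 = gof$chi2, chi2_unpooled = gof$chi2_unpooled,
                   df = df0 - gof$df_loss, df_unpooled = df0,
                   n_pooled = gof$n_pooled),
    df = df0, converged = converged, n_restarts_used = n_restarts_used,
    loglik_trace = trace, counts = counts
  ), class = "lcm_fit")
}

#' @method print lcm_fit
#' @export
print.lcm_fit <- function(x, ...) {
  cat("Latent class fit (", toupper(x$model), " model), K = ",
      x$params$K, ", N = ", attr(x$counts, "N"), "\n", sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      if (!x$converged) " (NOT converged)", "\n")
  cat("  prevalence eta:", format(x$params$eta, digits = 4), "\n")
  rates <- if (x$model == "ci") {
    data.frame(fp = x$params$fp, fn = x$params$fn)
  } else {
    as.data.frame(marginal_rates(x$params))
  }
  rownames(rates) <- attr(x$counts, "callers")
  print(round(rates, 5))
  cat("  Pearson chi-square:", format(x$pearson$chi2_unpooled, digits = 4),
      "on", x$pearson$df_unpooled, "df")
  if (x$pearson$n_pooled > 0) {
    cat(" (pooled:", format(x$pearson$chi2, digits = 4), "on",
        x$pearson$df, "df)")
  }
  cat("\n")
  invisible(x)
}

#' Pattern probability under the random-effects probit model
#'
#' Integrates the class-conditional product of probit detection
#' probabilities over the standard-normal random effect by Gauss-Hermite
#' quadrature, then mixes the classes with weights (1-eta, eta).
#'
#' @param params an [lcm_re_params()] object.
#' @param pattern as in [ci_pattern_prob()].
#' @param n_quad number of quadrature nodes (`>= 10`).
#' @return Probability vector.
#' @export
re_pattern_prob <- function(params, pattern = NULL, n_quad = 40) {
  if (n_quad < 10) stop("n_quad must be >= 10")
  bits <- resolve_patterns(pattern, params$K)
  gh <- pracma::gaussHermite(n_quad)
  p <- re_cell_probs(params$eta, params$a0, params$a1, params$sigma, bits, gh)
  setNames(p, rownames(bits))
}

# cell probabilities given GH nodes; b = sqrt(2)*x, weight w/sqrt(pi)
re_cell_probs <- function(eta, a0, a1, sigma, bits, gh) {
  b <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  class_prob <- function(a) {
    # phi[j,k] = Phi(a_k + sigma*b_j)
    phi <- pnorm(outer(b * sigma, a, `+`))
    phi <- pmin(pmax(phi, 1e-14), 1 - 1e-14)
    # for each pattern y: sum_j w_j prod_k phi^y (1-phi)^(1-y)
    lp <- log(phi)
    lq <- log(1 - phi)
    exp_terms <- exp(lp %*% t(bits) + lq %*% t(1 - bits))
    as.numeric(crossprod(w, exp_terms))
  }
  (1 - eta) * class_prob(a0) + eta * class_prob(a1)
}

#' Marginal error rates implied by the random-effects model
#'
#' Integrating the probit over the random effect gives closed-form marginal
#' rates: `fp_k = Phi(a0_k / sqrt(1+sigma^2))`,
#' `fn_k = 1 - Phi(a1_k / sqrt(1+sigma^2))`.
#'
#' @param params an [lcm_re_params()] object.
#' @return List with per-caller `fp` and `fn`.
#' @export
marginal_rates <- function(params) {
  s <- sqrt(1 + params$sigma^2)
  list(fp = pnorm(params$a0 / s), fn = 1 - pnorm(params$a1 / s))
}

#' Fit the random-effects probit latent class model
#'
#' Maximum likelihood by quasi-Newton optimization (BFGS) of the
#' quadrature-marginalized multinomial log-likelihood, on transformed
#' parameters (logit prevalence, probit intercepts, log sigma). One start
#' is always taken at the conditional-independence solution with sigma
#' near zero, so the RE log-likelihood is never below the CI one (the CI
#' model is nested at sigma = 0); the remaining starts are random.
#'
#' @param counts a [pattern_counts()] table, K >= 4 for df >= 1.
#' @param n_restarts total number of starts (default 10).
#' @param tol relative convergence tolerance passed to the optimizer.
#' @param max_iter maximum optimizer iterations per start.
#' @param n_quad Gauss-Hermite nodes (default 40).
#' @return An `lcm_fit` object (see [fit_ci()]); `params` is an
#'   [lcm_re_params()].
#' @export
fit_re <- function(counts, n_restarts = 10, tol = 1e-10, max_iter = 500,
                   n_quad = 40) {
  K <- attr(counts, "K")
  if (K < 4) stop("random-effects model needs K >= 4 for positive degrees of freedom")
  bits <- pattern_bits(names(counts))
  n <- as.numeric(counts)
  gh <- pracma::gaussHermite(n_quad)

  negll <- function(theta) {
    eta <- plogis(theta[1])
    a0 <- theta[2:(K + 1)]
    a1 <- theta[(K + 2):(2 * K + 1)]
    sigma <- exp(theta[2 * K + 2])
    p <- re_cell_probs(eta, a0, a1, sigma, bits, gh)
    -sum(n * log(pmax(p, 1e-12)))
  }

  ci <- fit_ci(counts, n_restarts = max(5, n_restarts))
  starts <- list(c(qlogis(ci$params$eta),
                   qnorm(pmin(pmax(ci$params$fp, 1e-6), 1 - 1e-6)),
                   qnorm(pmin(pmax(1 - ci$params$fn, 1e-6), 1 - 1e-6)),
                   log(1e-4)))
  for (r in seq_len(max(0, n_restarts - 1))) {
    starts[[r + 1]] <- c(qlogis(runif(1, 0.005, 0.4)),
                         qnorm(runif(K, 0.001, 0.2)),
                         qnorm(runif(K, 0.5, 0.99)),
                         log(runif(1, 0.2, 2)))
  }

  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      optim(s, negll, method = "BFGS",
            control = list(maxit = max_iter, reltol = tol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("random-effects fit failed from every start")

  theta <- best$par
  eta <- plogis(theta[1])
  a0 <- theta[2:(K + 1)]
  a1 <- theta[(K + 2):(2 * K + 1)]
  sigma <- exp(theta[2 * K + 2])
  # orient classes: class 1 = higher mean marginal detection probability
  if (mean(pnorm(a1)) < mean(pnorm(a0))) {
    tmp <- a0; a0 <- a1; a1 <- tmp
    eta <- 1 - eta
  }
  params <- structure(list(eta = eta, a0 = a0, a1 = a1, sigma = sigma, K = K),
                      class = "lcm_re_params")
  finish_fit(params, counts, -best$value, "re",
             best$convergence == 0, length(starts), numeric(0))
}

#' Standard errors for latent class fits
#'
#' Inverts the observed information (numerical Hessian of the multinomial
#' log-likelihood at the MLE). When the Hessian is not invertible -- as at
#' boundary estimates -- falls back to a parametric bootstrap.
#'
#' @param fit an `lcm_fit` object.
#' @param n_boot bootstrap replicates for the fallback (default 50).
#' @return Named vector of standard errors (`eta`, `fp1..fpK`/`a0..`,
#'   `fn1..fnK`/`a1..`, and `sigma` for the RE model).
#' @export
lcm_se <- function(fit, n_boot = 50) {
  counts <- fit$counts
  K <- fit$params$K
  bits <- pattern_bits(names(counts))
  n <- as.numeric(counts)
  if (fit$model == "ci") {
    par <- c(fit$params$eta, fit$params$fp, 1 - fit$params$fn)
    ll <- function(th) {
      sum(n * log(pmax(ci_cell_probs(th[1], th[2:(K + 1)],
                                     th[(K + 2):(2 * K + 1)], bits), 1e-12)))
    }
    names_out <- c("eta", paste0("fp", 1:K), paste0("fn", 1:K))
  } else {
    gh <- pracma::gaussHermite(40)
    par <- c(fit$params$eta, fit$params$a0, fit$params$a1, fit$params$sigma)
    ll <- function(th) {
      sum(n * log(pmax(re_cell_probs(th[1], th[2:(K + 1)],
                                     th[(K + 2):(2 * K + 1)],
                                     th[2 * K + 2], bits, gh), 1e-12)))
    }
    names_out <- c("eta", paste0("a0_", 1:K), paste0("a1_", 1:K), "sigma")
  }
  H <- tryCatch(optimHess(par, ll), error = function(e) NULL)
  se <- NULL
  if (!is.null(H)) {
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) se <- sqrt(diag(V))
  }
  if (is.null(se)) se <- lcm_boot_se(fit, n_boot)
  if (fit$model == "ci") {
    # sensitivity SE equals fn SE (fn = 1 - sens)
    setNames(se, names_out)
  } else {
    setNames(se, names_out)
  }
}

lcm_boot_se <- function(fit, n_boot) {
  counts <- fit$counts
  N <- attr(counts, "N")
  probs <- fit$fitted_counts / N
  draws <- rmultinom(n_boot, N, probs)
  ests <- apply(draws, 2, function(d) {
    bc <- pattern_counts(setNames(as.integer(d), names(counts)),
                         callers = attr(counts, "callers"))
    f <- tryCatch({
      if (fit$model == "ci") fit_ci(bc, n_restarts = 3)
      else suppressWarnings(fit_re(bc, n_restarts = 2))
    }, error = function(e) NULL)
    if (is.null(f)) return(rep(NA_real_, if (fit$model == "ci") 2 * fit$params$K + 1
                               else 2 * fit$params$K + 2))
    if (fit$model == "ci") c(f$params$eta, f$params$fp, 1 - f$params$fn)
    else c(f$params$eta, f$params$a0, f$params$a1, f$params$sigma)
  })
  apply(ests, 1, sd, na.rm = TRUE)
}

#' Write a latent class fit report as JSON
#'
#' Emits parameters, log-likelihood, Pearson statistics (pooled and
#' unpooled), degrees of freedom, fitted counts and convergence
#' diagnostics in a machine-readable form.
#'
#' @param fit an `lcm_fit` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lcm_json <- function(fit, path) {
  params <- unclass(fit$params)
  report <- list(
    model = fit$model,
    params = params,
    marginal_rates = if (fit$model == "re") marginal_rates(fit$params),
    loglik = fit$loglik,
    pearson = fit$pearson,
    fitted_counts = as.list(fit$fitted_counts),
    observed_counts = as.list(setNames(as.integer(fit$counts),
                                       names(fit$counts))),
    callers = attr(fit$counts, "callers"),
    converged = fit$converged,
    n_restarts_used = fit$n_restarts_used
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
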