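# Synthetic multi-caller cohorts with known latent truth.
#
# The generator mirrors the generative structure the downstream analysis
# assumes: latent somatic status D at prevalence eta; per-caller detection
# through a random-effects probit (the shared-variance 2LCR1-style model),
# so that sigma = 0 collapses to conditional independence at exactly the
# configured marginal FP/FN rates; VAF mixtures for somatic, germline and
# "germline-like" artifact sites; negative-binomial exome/deep/RNA depths;
# strand-bias artifact signatures; and monotone signed quality scores.

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: 16 patients, four
#' callers at prevalence 3%, per-caller error rates near the 76-gene
#' latent-class estimates, ~80x exome and 3x-higher deep coverage, and an
#' overdispersed RNA depth under which about a third of sites reach 10x.
#'
#' @param n_patients number of patients (default 16).
#' @param sites_per_patient candidate sites per patient (default 400).
#' @param eta somatic prevalence among sites, in `[0,1]`.
#' @param K number of callers.
#' @param caller_fp,caller_fn per-caller marginal false-positive and
#'   false-negative rates.
#' @param sigma random-effect loading (0 = conditional independence).
#' @param germline_fraction,wildtype_artifact_fraction fractions of the
#'   non-somatic mass that are germline and strand-artifact
#'   ("germline-like") sites; the remainder is clean wildtype.
#' @param purity tumor purity in (0,1]; somatic tumor VAF is
#'   `purity * c / 2` with clonal fraction `c ~ Uniform(clonal_range)`.
#' @param clonal_range range of the clonal fraction (default `c(0.2, 1)`).
#' @param depth_mean_exome,depth_mean_deep mean exome and deep-seq depths.
#' @param depth_dispersion negative-binomial size for DNA depths.
#' @param rna_depth_mean,rna_depth_dispersion negative-binomial mean and
#'   size for tumor RNA depth (defaults 12 and 0.35, giving ~33% of sites
#'   at >= 10x).
#' @param strand_artifact_prob probability an artifact site carries an
#'   extreme one-strand variant-allele signature.
#' @param seq_error per-base sequencing error rate.
#' @param raw_report_prob probability that a site not called by a caller
#'   still appears (filtered or non-somatic) in that caller's raw VCF.
#' @param caller_names caller labels (default `LETTERS[1:K]`).
#' @param seed integer seed; one global seed drives the whole cohort.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 16L, sites_per_patient = 400L,
                              eta = 0.03, K = 4L,
                              caller_fp = c(0.0016, 0.0007, 0.0003, 0.0024),
                              caller_fn = c(0.20, 0.31, 0.10, 0.10),
                              sigma = 0,
                              germline_fraction = 0.43,
                              wildtype_artifact_fraction = 0.12,
                              purity = 0.7, clonal_range = c(0.2, 1),
                              depth_mean_exome = 80, depth_mean_deep = 240,
                              depth_dispersion = 8,
                              rna_depth_mean = 12, rna_depth_dispersion = 0.35,
                              strand_artifact_prob = 0.5,
                              seq_error = 0.001,
                              raw_report_prob = 0.4,
                              caller_names = NULL, seed = 1L) {
  if (length(caller_fp) != K || length(caller_fn) != K)
    stop("caller_fp and caller_fn must have length K")
  if (eta < 0 || eta > 1) stop("eta must be in [0,1]")
  if (any(caller_fp < 0 | caller_fp >= 1 | caller_fn < 0 | caller_fn >= 1))
    stop("configuration error: caller rates must be in [0,1)")
  if (any(1 - caller_fn <= caller_fp))
    stop("configuration error: identifiability requires 1 - fn[k] > fp[k]")
  if (germline_fraction < 0 || wildtype_artifact_fraction < 0 ||
      germline_fraction + wildtype_artifact_fraction > 1)
    stop("configuration error: germline_fraction + wildtype_artifact_fraction must be <= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  if (purity <= 0 || purity > 1) stop("purity must be in (0,1]")
  if (is.null(caller_names)) caller_names <- LETTERS[seq_len(K)]
  cfg <- list(n_patients = as.integer(n_patients),
              sites_per_patient = as.integer(sites_per_patient),
              eta = eta, K = as.integer(K),
              caller_fp = caller_fp, caller_fn = caller_fn, sigma = sigma,
              germline_fraction = germline_fraction,
              wildtype_artifact_fraction = wildtype_artifact_fraction,
              purity = purity, clonal_range = clonal_range,
              depth_mean_exome = depth_mean_exome,
              depth_mean_deep = depth_mean_deep,
              depth_dispersion = depth_dispersion,
              rna_depth_mean = rna_depth_mean,
              rna_depth_dispersion = rna_depth_dispersion,
              strand_artifact_prob = strand_artifact_prob,
              seq_error = seq_error, raw_report_prob = raw_report_prob,
              caller_names = caller_names, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Draw latent truth for a synthetic cohort
#'
#' Each site gets a true status (somatic / germline / wildtype_artifact /
#' clean_wildtype), a standard-normal random effect `b`, true tumor and
#' normal VAFs, and a forward-strand rate for its variant allele (0.5 for
#' real variants; near 0 or 1 for strand-artifact sites).
#'
#' @param config a [simulation_config()]. Call inside `set.seed()` or via
#'   [simulate_cohort()] for reproducibility.
#' @return A `data.frame` with one row per site (class `truth_table`).
#' @export
simulate_truth <- function(config) {
  n_per <- config$sites_per_patient
  n <- config$n_patients * n_per
  patient_id <- rep(sprintf("P%02d", seq_len(config$n_patients)), each = n_per)
  chrom <- as.character(sample.int(22L, n, replace = TRUE))
  pos <- as.integer(unlist(lapply(seq_len(config$n_patients), function(i)
    sort(sample.int(5e7L, n_per)))))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  u <- runif(n)
  g <- config$germline_fraction
  a <- config$wildtype_artifact_fraction
  D <- ifelse(u < config$eta, "somatic",
       ifelse(u < config$eta + (1 - config$eta) * g, "germline",
       ifelse(u < config$eta + (1 - config$eta) * (g + a),
              "wildtype_artifact", "clean_wildtype")))

  b <- rnorm(n)
  tvaf <- numeric(n)
  nvaf <- numeric(n)
  som <- D == "somatic"
  cc <- runif(sum(som), config$clonal_range[1], config$clonal_range[2])
  tvaf[som] <- config$purity * cc / 2
  germ <- D == "germline"
  # heterozygous germline, center shifted to ~45% by reference-alignment bias
  tvaf[germ] <- pmin(pmax(rnorm(sum(germ), 0.45, 0.03), 0.30), 0.60)
  nvaf[germ] <- pmin(pmax(rnorm(sum(germ), 0.45, 0.03), 0.30), 0.60)
  art <- D == "wildtype_artifact"
  # matched low-but-nonzero VAFs in tumor and normal ("germline-like")
  v <- runif(sum(art), 0.05, 0.35)
  nvaf[art] <- v
  tvaf[art] <- pmin(pmax(v + rnorm(sum(art), 0, 0.03), 0.02), 0.5)

  strand_rate <- rep(0.5, n)
  extreme <- art & (runif(n) < config$strand_artifact_prob)
  # the artifact signature: every variant read on one strand
  strand_rate[extreme] <- ifelse(runif(sum(extreme)) < 0.5, 0, 1)

  out <- data.frame(patient_id = patient_id, chrom = chrom, pos = pos,
                    ref = ref, alt = alt, D = D, b = b,
                    true_tumor_vaf = tvaf, true_normal_vaf = nvaf,
                    strand_rate = strand_rate,
                    strand_extreme = extreme,
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_table", "data.frame")
  attr(out, "config") <- config
  out
}

# Probit intercept giving a target marginal rate under loading sigma:
# Phi(a / sqrt(1 + sigma^2)) = rate  =>  a = qnorm(rate) * sqrt(1 + sigma^2)
probit_intercept <- function(rate, sigma) qnorm(rate) * sqrt(1 + sigma^2)

#' Draw per-caller calls from the random-effects probit model
#'
#' `Y_k ~ Bernoulli(Phi(a_{d,k} + sigma * b))` with intercepts solved so
#' the marginal rates equal the configured `caller_fp` (non-somatic class)
#' and `1 - caller_fn` (somatic class). With `sigma = 0` this reduces to
#' independent Bernoulli draws at exactly the configured rates. Also draws
#' raw-VCF reporting indicators for sites a caller did not call.
#'
#' @param truth a [simulate_truth()] table.
#' @param config the matching [simulation_config()].
#' @return `truth` with added logical columns `Y_<caller>` and `R_<caller>`
#'   (reported in that caller's raw VCF).
#' @export
simulate_caller_calls <- function(truth, config) {
  n <- nrow(truth)
  d <- as.integer(truth$D == "somatic")
  for (k in seq_len(config$K)) {
    a0 <- probit_intercept(config$caller_fp[k], config$sigma)
    a1 <- probit_intercept(1 - config$caller_fn[k], config$sigma)
    p <- pnorm(ifelse(d == 1, a1, a0) + config$sigma * truth$b)
    y <- runif(n) < p
    truth[[paste0("Y_", config$caller_names[k])]] <- y
    truth[[paste0("R_", config$caller_names[k])]] <-
      y | (runif(n) < config$raw_report_prob)
  }
  truth
}

nb_depth <- function(n, mu, size) rnbinom(n, mu = mu, size = size)

draw_assay <- function(n, depth_mu, size, true_vaf, strand_rate, err) {
  depth <- nb_depth(n, depth_mu, size)
  alt <- rbinom(n, depth, pmin(true_vaf + err, 1))
  alt_fwd <- rbinom(n, alt, strand_rate)
  ref_fwd <- rbinom(n, depth - alt, 0.5)
  list(depth = depth, alt = alt, alt_fwd = alt_fwd, ref_fwd = ref_fwd)
}

# Phred-scaled binomial log-likelihood ratio of the observed alt count
# against an error-only model; monotone in alt at fixed depth. When no alt
# read was seen the homozygous-reference confidence (vs a heterozygous
# alternative) is computed and the sign flipped by signed_quality().
raw_quality_score <- function(alt, depth, err) {
  err <- max(err, 1e-6)
  found <- !is.na(alt) & alt > 0
  q <- numeric(length(alt))
  f <- which(found)
  if (length(f)) {
    vhat <- pmax(alt[f] / depth[f], err)
    q[f] <- (dbinom(alt[f], depth[f], vhat, log = TRUE) -
             dbinom(alt[f], depth[f], err, log = TRUE)) * 10 / log(10)
  }
  nf <- which(!found & !is.na(depth) & depth > 0)
  if (length(nf)) {
    q[nf] <- (dbinom(0L, depth[nf], err, log = TRUE) -
              dbinom(0L, depth[nf], 0.45, log = TRUE)) * 10 / log(10)
  }
  list(raw = q, found = found)
}

#' Draw sequencing evidence for every site and assay
#'
#' Generates depth, variant-allele and strand counts for the exome
#' tumor/normal pair, the deep-seq tumor/normal pair (~3x the exome
#' depth), and the tumor RNA-seq (overdispersed depth with a mass at
#' zero), plus signed tumor/normal quality scores computed from the exome
#' counts.
#'
#' @param truth a [simulate_truth()] table (calls not required).
#' @param config the matching [simulation_config()].
#' @return A site-evidence `data.frame` keyed like `truth`.
#' @export
simulate_evidence <- function(truth, config) {
  n <- nrow(truth)
  err <- config$seq_error
  sr <- truth$strand_rate
  ex_t <- draw_assay(n, config$depth_mean_exome, config$depth_dispersion,
                     truth$true_tumor_vaf, sr, err)
  ex_n <- draw_assay(n, config$depth_mean_exome, config$depth_dispersion,
                     truth$true_normal_vaf, sr, err)
  dp_t <- draw_assay(n, config$depth_mean_deep, config$depth_dispersion,
                     truth$true_tumor_vaf, sr, err)
  dp_n <- draw_assay(n, config$depth_mean_deep, config$depth_dispersion,
                     truth$true_normal_vaf, sr, err)
  rna <- draw_assay(n, config$rna_depth_mean, config$rna_depth_dispersion,
                    truth$true_tumor_vaf, sr, err)

  qt <- raw_quality_score(ex_t$alt, ex_t$depth, err)
  qn <- raw_quality_score(ex_n$alt, ex_n$depth, err)

  out <- data.frame(
    patient_id = truth$patient_id, chrom = truth$chrom, pos = truth$pos,
    ref = truth$ref, alt = truth$alt,
    exome_tumor_depth = ex_t$depth, exome_tumor_alt = ex_t$alt,
    exome_tumor_alt_fwd = ex_t$alt_fwd, exome_tumor_ref_fwd = ex_t$ref_fwd,
    exome_normal_depth = ex_n$depth, exome_normal_alt = ex_n$alt,
    exome_normal_alt_fwd = ex_n$alt_fwd, exome_normal_ref_fwd = ex_n$ref_fwd,
    deep_tumor_depth = dp_t$depth, deep_tumor_alt = dp_t$alt,
    deep_tumor_alt_fwd = dp_t$alt_fwd, deep_tumor_ref_fwd = dp_t$ref_fwd,
    deep_normal_depth = dp_n$depth, deep_normal_alt = dp_n$alt,
    deep_normal_alt_fwd = dp_n$alt_fwd, deep_normal_ref_fwd = dp_n$ref_fwd,
    rna_depth = rna$depth, rna_alt = rna$alt,
    rna_alt_fwd = rna$alt_fwd, rna_ref_fwd = rna$ref_fwd,
    signed_q_tumor = signed_quality(qt$raw, qt$found),
    signed_q_normal = signed_quality(qn$raw, qn$found),
    stringsAsFactors = FALSE
  )
  out
}

#' Simulate a complete cohort
#'
#' Seeds the RNG from `config$seed` and runs [simulate_truth()],
#' [simulate_caller_calls()] and [simulate_evidence()].
#'
#' @param config a [simulation_config()].
#' @return List with `truth`, `evidence` and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  set.seed(config$seed)
  truth <- simulate_truth(config)
  truth <- simulate_caller_calls(truth, config)
  evidence <- simulate_evidence(truth, config)
  list(truth = truth, evidence = evidence, config = config)
}

vcf_header <- function() {
  paste(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SS,Number=1,Type=String,Description=\"Somatic status (SOMATIC/GERMLINE/WILDTYPE)\">",
    "##FILTER=<ID=low_qual,Description=\"Filtered by the caller\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", "NORMAL", sep = "\t"),
    sep = "\n")
}

#' Write per-caller per-patient VCFs for a simulated cohort
#'
#' Each caller's VCF for a patient contains its somatic PASS calls
#' (`Y = 1`) plus any raw-reported sites (`R = 1`): germline-truth sites
#' as GERMLINE/PASS, other uncalled sites as SOMATIC with a `low_qual`
#' filter. Depth/alt fields come from the exome evidence.
#'
#' @param truth truth table with `Y_`/`R_` columns.
#' @param evidence matching evidence table.
#' @param outdir output directory (created if needed).
#' @param config the cohort's [simulation_config()].
#' @return Character vector of files written, invisibly.
#' @export
write_caller_vcfs <- function(truth, evidence, outdir, config) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(identical(site_key(truth), site_key(evidence)))
  files <- character(0)
  qual <- round(abs(evidence$signed_q_tumor), 1)
  for (ck in config$caller_names) {
    y <- truth[[paste0("Y_", ck)]]
    r <- truth[[paste0("R_", ck)]]
    for (p in unique(truth$patient_id)) {
      idx <- which(truth$patient_id == p & r)
      idx <- idx[order(truth$chrom[idx], truth$pos[idx])]
      path <- file.path(outdir, paste0("caller", ck, "_", p, ".vcf"))
      lines <- vcf_header()
      if (length(idx)) {
        called <- y[idx]
        is_germ <- truth$D[idx] == "germline"
        ss <- ifelse(called, "SOMATIC", ifelse(is_germ, "GERMLINE", "SOMATIC"))
        filt <- ifelse(called | is_germ, "PASS", "low_qual")
        rec <- paste(
          truth$chrom[idx], truth$pos[idx], ".", truth$ref[idx],
          truth$alt[idx], qual[idx], filt, paste0("SS=", ss), "GT:DP:AD",
          paste0("./.:", evidence$exome_tumor_depth[idx], ":",
                 evidence$exome_tumor_depth[idx] - evidence$exome_tumor_alt[idx],
                 ",", evidence$exome_tumor_alt[idx]),
          paste0("./.:", evidence$exome_normal_depth[idx], ":",
                 evidence$exome_normal_depth[idx] - evidence$exome_normal_alt[idx],
                 ",", evidence$exome_normal_alt[idx]),
          sep = "\t")
        lines <- c(lines, rec)
      }
      writeLines(lines, path)
      files <- c(files, path)
    }
  }
  invisible(files)
}

#' Write a simulated cohort to disk
#'
#' Emits per-caller per-patient VCFs, `evidence.tsv`, `truth.tsv`, a YAML
#' echo of the configuration and a manifest recording the seed, the MD5
#' hash of the configuration and every file written. Outputs are
#' deterministic given the seed.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param outdir output directory.
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  vcfs <- write_caller_vcfs(cohort$truth, cohort$evidence, outdir,
                            cohort$config)
  ev_path <- file.path(outdir, "evidence.tsv")
  tr_path <- file.path(outdir, "truth.tsv")
  write.table(cohort$evidence, ev_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$truth, tr_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  cfg <- cohort$config
  class(cfg) <- NULL
  writeLines(yaml::as.yaml(cfg), cfg_path)
  manifest <- list(
    seed = cohort$config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_sites = nrow(cohort$truth),
    files = basename(c(vcfs, ev_path, tr_path, cfg_path))
  )
  man_path <- file.path(outdir, "manifest.yaml")
  writeLines(yaml::as.yaml(manifest), man_path)
  invisible(man_path)
}
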