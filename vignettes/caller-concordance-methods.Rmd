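---
title: "Methods: multi-caller somatic mutation comparison and latent class error-rate estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-caller somatic mutation comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callerConcord)
```

# Scope and data model

`callerConcord` compares somatic SNV call sets produced by K mutation
callers on the same tumor–normal pairs. A *site* is the tuple (patient,
chromosome, 1-based position, alt allele); the reference allele is
deliberately excluded from site identity, because calls are matched
across callers by position within a patient. Multi-allelic VCF records
are split into one record per alt allele, and non-SNV alts are dropped
with a counted warning — the comparison is SNV-only.

A caller's *final call set* is the set of sites it reported with somatic
status and a passing filter. Sites absent from a caller's VCF are treated
as "not called" (a 0 bit), not as missing data; whether an uncalled site
was at least *reported* pre-filter is a separate descriptive statistic
(`raw_vcf_presence()`). The K-bit detection patterns of all union sites,
tabulated over all 2^K cells, are the input to the latent class models.
The all-zero cell — positions screened but called by nobody — cannot be
derived from the call sets and must be supplied externally; for the
bundled 76-gene validation table it is 4301.

# The latent class models

Let D_i be the unobserved true somatic status of site i, with prevalence
η = P(D_i = 1), and Y_ik caller k's call. Under **conditional
independence (CI)**, callers err independently given D_i, so the
probability of a detection pattern y is

$$P(Y = y) = (1-\eta)\prod_k \alpha_k^{y_k}(1-\alpha_k)^{1-y_k}
           + \eta\prod_k (1-\beta_k)^{y_k}\beta_k^{1-y_k},$$

with α_k the false-positive and β_k the false-negative rate of caller k:
1 + 2K parameters against 2^K − 1 free cells, leaving 2^K − 1 − (2K+1)
degrees of freedom (6 for K = 4; 0 for K = 3, where the model is
saturated and goodness of fit is uninformative).

The **random-effects (RE) extension** drops the independence assumption:
conditionally on a standard-normal site effect b_i shared by all callers,

$$P(Y_{ik} = 1 \mid D_i = d, b_i) = \Phi(a_{dk} + \sigma b_i),$$

with a single loading σ shared between the somatic and non-somatic
classes — one extra parameter. Sites that are "hard" (low VAF, low depth,
artifact-prone) get a small b_i and all callers tend to miss them
together. Marginally, integrating over b gives the closed form
fp_k = Φ(a_{0k}/√(1+σ²)) and 1 − fn_k = Φ(a_{1k}/√(1+σ²))
(`marginal_rates()`); σ = 0 collapses the RE model to CI exactly.

## Fitting and numerical choices

* **CI model**: EM with posterior-responsibility E-step and closed-form
  M-step. Defaults: 20 restarts, tolerance 1e-8 on the log-likelihood,
  5000 max iterations. Restarts are stratified — starting prevalences
  spread over (0, 0.5), error rates drawn modestly — because the
  likelihood is bimodal under class-label switching. The log-likelihood
  trace of the winning run is stored so monotonicity is testable.
* **RE model**: the marginal likelihood is computed by 40-node
  Gauss–Hermite quadrature and maximized by BFGS on transformed
  parameters (logit η, raw intercepts, log σ). One start is always the CI
  solution with σ ≈ 0; since CI is nested in RE at σ = 0, the RE
  log-likelihood can never fall below the CI one (asserted in tests).
* **Label switching** is resolved deterministically after fitting: class
  1 ("somatic") is the class with the higher mean detection probability,
  matching the biological orientation that sensitivity exceeds the
  false-positive rate. The `lcm_ci_params()` constructor enforces
  1 − fn_k > fp_k.
* **Floors and pooling**: probabilities are floored at 1e-12 inside
  logarithms. For the Pearson χ², cells with expected count < 0.5 are
  pooled into a remainder cell with the df reduced accordingly; both
  pooled and unpooled statistics are reported, since pooling conventions
  vary (on the bundled 76-gene table no cell falls below the floor, so
  the two coincide).
* **Standard errors** come from the inverse observed information
  (numerical Hessian at the MLE), with a parametric bootstrap fallback
  when the Hessian is not invertible, as at boundary estimates.
* **Degenerate inputs**: K < 3 is refused (no identifiable df); K = 3 is
  fitted with a saturation warning; empty tables are an error.

# Validation schemes and filters

All threshold comparisons are strict (`>`, `<`) exactly as stated in the
rules; ties fall to the negative side. A VAF at zero depth is undefined
(`not_evaluable`), never silently zero.

* **Gold standard** (independent deep sequencing, ~3x the exome depth):
  somatic iff deep tumor VAF > 10% and deep normal VAF < 2%; among the
  rest, wildtype iff both < 2%. An alternative criterion uses signed
  quality scores (tumor > 200, normal < −100). When the two criteria
  disagree on somatic vs non-somatic, the site is `ambiguous` and
  excluded from evaluation sets rather than adjudicated.
  `build_evaluation_set()` applies the construction filters in order:
  deep tumor depth ≥ 100x, exome tumor and normal depth ≥ 10x, ambiguity
  removal.
* **Pseudo-validation**: signed quality scores give a common confidence
  scale across callers. The sign contract: a non-negative variant-call
  quality is flipped negative when no variant allele was found, so a
  large negative value is strong support for homozygous reference.
  Pseudo-positive iff tumor score > q_t (default 200) and normal score
  < q_n (default −50).
* **RNA validation**: only sites with tumor RNA depth ≥ 10x are
  evaluable (a 5x display variant exists as an option); positive iff RNA
  VAF > 10% and normal exome VAF < 2%. Expression variation means some
  true DNA variants never appear in RNA, which caps the attainable TPR.
* **Strand-bias filters**: the exome filter removes a site when the
  variant allele is strand-extreme (> 95% or < 5% forward) while the
  reference allele is not (forward fraction strictly inside
  (0.30, 0.70)). The published wording of the reference clause ("less
  than 70% or larger than 30%") is logically vacuous as printed; we
  implement the reading consistent with the filter's purpose — reference
  allele *not itself extreme* — and keep the interval configurable. The
  RNA filter requires the variant allele to be extreme in *both* the
  tumor exome and the RNA data, because the variant/reference strand
  correspondence is weaker in RNA even for true variants.

# Performance summaries

ROC-like curves report the true positive rate against the false
*discovery* rate, not the false positive rate: validation universes are
ascertained, so absolute negatives are not meaningful, while FDR has an
intuitive scale. Strand filters inside the sweep only remove positives,
so positive sets stay nested across thresholds.

FP counts are rescaled to a common reference prevalence (default 3%)
before cross-scheme comparison: with T validated true positives, the
expected negative count in a 97:3 universe is T(1−p)/p, and the rescaled
rate is FP divided by it. This formula is this package's concrete
rendering of the rescaling idea (the original description is one
sentence); it is monotone in FP, so caller rankings are preserved, and
the reference prevalence is configurable.

`ascertainment_crosstab()` guards against caller-driven validation: if ≥
99% (configurable) of attempted-validation sites carry one caller's bit,
that caller is flagged, and rates for the *other* callers computed from
these labels should not be trusted.

# The synthetic cohort generator

The generator exists so that every downstream stage has a testable truth.
Its defaults encode the emulated study conditions, chosen once:

* 16 patients, 4 callers, prevalence η = 0.03 — the reference somatic
  share used for FP rescaling.
* Per-caller FP/FN defaults (fp ≈ 0.0016, 0.0007, 0.0003, 0.0024;
  fn ≈ 0.20, 0.31, 0.10, 0.10) sit near the 76-gene latent-class
  estimates, so simulated cohorts resemble the fitted table.
* Caller calls are drawn from the shared-variance probit RE model with
  intercepts solved from the target marginal rates via the
  Φ(a/√(1+σ²)) identity, so the *marginal* FP/FN rates equal the
  configured values for any σ, and σ = 0 reduces to exact conditional
  independence.
* Non-somatic mass splits 0.43 germline / 0.12 "germline-like"
  strand-artifact / remainder clean wildtype, following the composition
  of the 6,692-site evaluation set (2,716 heterozygous-range and 787
  germline-like of 6,692). Germline VAFs center at 0.45, not 0.50,
  modeling the alignment bias toward the reference allele. Artifact
  sites get matched low-but-nonzero VAFs (normal VAF uniform on
  0.05–0.35) in both samples.
* Somatic tumor VAF is purity × c/2 with clonal fraction c uniform on
  [0.2, 1] and purity 0.7; the normal VAF is 0.
* Depths are negative-binomial: exome mean 80x, deep-seq 3x higher
  (240x), dispersion 8. RNA depth uses mean 12 and dispersion 0.35,
  which puts ~33% of sites at ≥ 10x — inside the stated 30–40% band for
  RNA-evaluable sites — and includes a point mass at zero coverage.
* With probability 0.5 an artifact site carries the extreme strand
  signature — *every* variant read on one strand — mirroring the
  observed ~50% extreme-strand share among germline-like variants; real
  variants use a balanced rate of 0.5. The artifact rate is calibrated
  to targeted-region data and is illustrative for whole-exome scale.
* Signed quality scores are a phred-scaled binomial log-likelihood ratio
  of the observed alt count against an error-only model (error rate
  0.001), sign-flipped when no alt read was seen. This is our own stated
  monotone score satisfying the sign contract; it is *not* a genotype
  likelihood model, only a monotone summary of (alt, depth).
* One global seed drives the whole cohort; identical seeds give
  byte-identical outputs, and the manifest records the configuration
  hash.

What the generator does **not** emulate: read-level error processes
(FASTQ/BAM), mapping artifacts, indels, patient-level heterogeneity in
purity or error rates, and caller-specific filter idiosyncrasies (a
caller's non-calls are exchangeable given D and b). Consequently,
passing tests show that the *statistical machinery* behaves as designed
under the assumed generative model — they do not certify performance on
real sequencing data, where conditional dependence can take forms the
shared random effect does not capture.

# Problem sizes used in the test suite

Unit tests use cohorts of a few hundred to a few thousand sites. The
parameter-recovery checks use 2^4 pattern tables of N = 100,000 sites
across 20 seeds for the CI model and one N = 100,000 cohort at σ = 1.5
for the RE model — sizes at which the multinomial information makes
3-standard-error recovery a sharp test while the whole suite stays
within a desktop minute. The brute-force likelihood grid for the K = 3
oracle-equivalence check varies prevalence and a common fp/fn in steps
of 0.02 (a subset of the full parameter space, hence a valid lower bound
on the maximized likelihood).

# Known limitations

* Whole-exome figures from the original benchmark (5,380 union calls,
  the 31/28/16/25% agreement split, the 233 → 121 χ² drop of the RE
  model, the ~75% single-caller FP share) depend on controlled-access
  data and are documented expectations only; nothing in this package
  recomputes them.
* The latent class models assume one prevalence across sites and
  patients; strong patient effects would call for stratified fits.
* The RE model uses a single shared variance component. Class-specific
  variances or pairwise dependence terms are out of scope — more general
  dependence structures reportedly did not improve the fit much on the
  motivating data.
* Validation labels from external tables (e.g. `nonMAF`, `unknown`) are
  accepted as-is; the package does not parse MAF files.
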