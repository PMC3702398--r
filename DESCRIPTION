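Package: callerConcord
Title: Comparing Somatic Mutation Callers Beyond Venn Diagrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing somatic single-nucleotide-variant call sets
    produced by multiple mutation callers on the same tumor-normal pairs.
    Reads per-caller VCF outputs, builds K-caller detection-pattern tables,
    and characterizes discrepancies (Venn and agreement summaries,
    caller-unique and caller-missed sets, depth/VAF stratification, raw-VCF
    presence checks). Implements four validation approaches: gold-standard
    labeling from independent deep sequencing, signed-quality
    pseudo-validation, RNA-seq validation with strand-bias artifact filters,
    and latent class models (conditional independence and a shared-variance
    random-effects probit extension) that estimate per-caller false-positive
    and false-negative rates without any gold standard. A synthetic cohort
    generator with known latent truth makes the whole pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
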