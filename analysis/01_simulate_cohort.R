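#!/usr/bin/env Rscript
# Generate the default desk-scale synthetic cohort (300 wheat samples x 2,000
# peptide clusters, 60 planted trait-associated peptides, QC injections every
# 48 samples, injected technical-factor offsets and injection-order drift)
# and write the raw matrix, sample metadata and ground truth under results/.

suppressPackageStartupMessages(library(wheatlma))

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- generate_cohort(cohort_config(), seed = 42)
write_lcms_csv(sim$matrix, file.path(out, "matrix_raw.csv"),
               file.path(out, "sample_meta.csv"))
write_truth_json(sim$truth, file.path(out, "truth.json"))

smp <- sim$matrix$samples
cat("cohort:", nrow(sim$matrix$features), "features x", nrow(smp),
    "samples (", sum(smp$is_qc), "QCs )\n")
cat("planted biomarkers:", length(sim$truth$biomarker_ids),
    "( up:", sum(sim$truth$expected_direction == "up"),
    "/ down:", sum(sim$truth$expected_direction == "down"), ")\n")
tr <- smp$trait_u_per_g[!smp$is_qc]
cat(sprintf("trait: %d measured, %.1f%% < 0.2 U/g, range %.2f-%.2f U/g\n",
            sum(!is.na(tr)), 100 * mean(tr < 0.2, na.rm = TRUE),
            min(tr, na.rm = TRUE), max(tr, na.rm = TRUE)))
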