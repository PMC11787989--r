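#!/usr/bin/env Rscript
# Validate the reduced-order model the way continuum FE spine models are
# validated: geometric similarity of the gravity-loaded spine to the clinical
# measurements (< 5 deg), segmental range of motion under 4 N m pure
# moments, and the upright concave/convex balance of the paravertebral
# muscle axial forces.

suppressPackageStartupMessages(library(spinebrace))
dir.create("results", showWarnings = FALSE)

val <- run_validation(curve_params())
print(val)

utils::write.table(cbind(segment = rownames(val$rom), as.data.frame(val$rom)),
                   "results/rom_validation.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
utils::write.table(val$muscle$table, "results/muscle_ratios_upright.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("\nOverall validation: %s\n", if (val$pass) "PASS" else "FAIL"))
cat("Wrote results/rom_validation.tsv, muscle_ratios_upright.tsv\n")
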