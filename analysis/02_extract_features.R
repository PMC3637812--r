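#!/usr/bin/env Rscript
# Stage 2: reduce claims to binary predictors.
#
# Applies the code dictionary's per-category lookback windows (4 y for
# procedures, 1 y for symptoms, 5 y for conditions/hospitalizations/
# surgeries; half-open, index day excluded) to the claims table from
# stage 1 and writes one row per patient: age, sex and 14 flags.

suppressPackageStartupMessages(library(screenlca))

truth <- read.csv("results/cohort/truth.csv", stringsAsFactors = FALSE)
claims <- read.csv("results/cohort/claims.csv", stringsAsFactors = FALSE)
features <- extract_features(claims, truth)
write.csv(features, "results/features.csv", row.names = FALSE, quote = FALSE)

flags <- setdiff(names(features), c("patient_id", "age", "sex"))
freq <- sort(100 * colMeans(features[flags]), decreasing = TRUE)
cat(sprintf("Extracted %d features for %d patients.\n", length(flags), nrow(features)))
cat("Flag frequencies (%):\n")
print(round(freq, 1))
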