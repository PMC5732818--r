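#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates the default 49-case synthetic CT cohort (33 responders labeled
# CR/PR, 16 nonresponders labeled SD) with anisotropic 0.97 x 0.97 x 2.5 mm
# voxels, per-case tumor geometry and texture heterogeneity, and a perturbed
# second-observer contour per case. Writes NIfTI volumes + masks and the
# label table under results/cohort/.

suppressPackageStartupMessages(library(crtradiomics))

seed <- 1L
spec <- cohort_spec(n_responders = 33, n_nonresponders = 16, seed = seed)
cases <- generate_cohort(spec)
split <- make_split(vapply(cases, `[[`, TRUE, "responder"), n_test = 12L,
                    seed = seed + 31L)
split_lab <- ifelse(seq_along(cases) %in% split$test, "test", "train")
write_cohort(cases, "results/cohort", split = split_lab, spec = spec)

labels <- vapply(cases, `[[`, "", "label")
message(sprintf("wrote %d cases to results/cohort (%s)", length(cases),
                paste(sprintf("%s=%d", names(table(labels)), table(labels)),
                      collapse = ", ")))
message(sprintf("train/test split: %d / %d (stratified)",
                length(split$train), length(split$test)))
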