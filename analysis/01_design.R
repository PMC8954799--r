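#!/usr/bin/env Rscript
# Stage 1: build the replicated full-factorial design.
#
# Three metals (Cd, Pb, Cr) varied over three nutrient-solution levels
# (countryside / urban / heavily polluted) give 3^3 = 27 growth conditions;
# three pot replicates each give 81 plant samples.

library(phytodoe)

dir.create("results", showWarnings = FALSE)

factors <- aviculare_factors()
cat("Factors (uM):\n")
print(as.data.frame(factors))

design <- replicate_design(full_factorial(factors), k = 3)
cat(sprintf("\nDesign: %d unique runs, %d rows with replicates\n",
            length(unique(design$run_id)), nrow(design)))

centres <- vapply(seq_len(nrow(factors)), function(i) {
  code_level(factors$central[i], factors[i, ])
}, numeric(1))
cat("Coded central levels (the urban level is not the coded origin):\n")
print(round(stats::setNames(centres, factors$name), 2))

write_factors(factors, "results/factors.csv")
write_design(design, "results/design.csv")
cat("\nWrote results/factors.csv and results/design.csv\n")
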