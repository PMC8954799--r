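#!/usr/bin/env Rscript
# Stage 4: fit the ten-term quadratic model for every response metal.
#
# One ordinary-least-squares fit per shoot metal on all 81 replicate
# observations (71 residual df): intercept, three linear effects, three
# binary interactions, three squared effects, in coded units. Stars follow
# the conventional bands (* p<0.05, ** p<0.01, *** p<0.001).

library(phytodoe)

design <- read_design("results/design.csv")
uptake <- tibble::as_tibble(utils::read.csv("results/uptake.csv"))

fits <- fit_uptake_models(design, uptake, alpha = 0.05)

for (m in names(fits)) {
  cat("\n")
  print(fits[[m]])
  utils::write.csv(as.data.frame(coef_table(fits[[m]])),
                   sprintf("results/fit_%s.csv", m), row.names = FALSE)
}
cat("\nWrote results/fit_<metal>.csv for", length(fits), "responses\n")
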