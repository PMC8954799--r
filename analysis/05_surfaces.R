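#!/usr/bin/env Rscript
# Stage 5: response and confidence-semiamplitude surfaces.
#
# For each response metal, the fitted quadratic is evaluated on a 41 x 41
# grid over one factor pair (the remaining factor fixed at coded 0, the
# display convention for the urban level). The semiamplitude grid is the
# half-width of the 95% confidence interval of the mean response; nodes
# where |response| exceeds it are significantly different from zero.

library(phytodoe)

design <- read_design("results/design.csv")
uptake <- tibble::as_tibble(utils::read.csv("results/uptake.csv"))
fits <- fit_uptake_models(design, uptake)

pairs <- list(Cd = c("Cd", "Cr"), Cr = c("Cr", "Pb"), Pb = c("Cd", "Cr"),
              Cu = c("Cd", "Cr"), Zn = c("Pb", "Cd"))
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

for (m in names(pairs)) {
  tab <- surface_table(fits[[m]], pairs[[m]], resolution = 41)
  utils::write.csv(as.data.frame(tab),
                   sprintf("results/surface_%s.csv", m), row.names = FALSE)
  render_surface(tab, value = "response",
                 path = sprintf("results/figures/%s_response.png", m))
  render_surface(tab, value = "semiamplitude",
                 path = sprintf("results/figures/%s_semiamplitude.png", m))
  cat(sprintf(
    "%-2s over (%s, %s): response %5.2f-%6.2f mg/kg, %3.0f%% of nodes significant\n",
    m, pairs[[m]][1], pairs[[m]][2], min(tab$response), max(tab$response),
    100 * mean(tab$significant)))
}
cat("\nWrote results/surface_<metal>.csv and results/figures/*.png\n")
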