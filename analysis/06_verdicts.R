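#!/usr/bin/env Rscript
# Stage 6: bioindication verdicts.
#
# A metal is a usable bioindicator when its shoot concentration tracks its
# own medium concentration (significant, positive linear term) without being
# dominated by the other metals. Cd, Pb and Cr are judged against their own
# design factor; Cu and Zn, held constant in the medium, can only pass if no
# varied metal influences their uptake at all.

library(phytodoe)

design <- read_design("results/design.csv")
uptake <- tibble::as_tibble(utils::read.csv("results/uptake.csv"))
fits <- fit_uptake_models(design, uptake)

own <- c(Cd = "Cd", Cr = "Cr", Pb = "Pb", Cu = NA, Zn = NA)
verdicts <- lapply(names(fits), function(m) {
  classify(fits[[m]], own_factor = if (is.na(own[[m]])) NULL else own[[m]])
})
names(verdicts) <- names(fits)

for (v in verdicts) { cat("\n"); print(v) }

smry <- summarize_verdicts(verdicts)
utils::write.csv(as.data.frame(smry), "results/verdicts.csv",
                 row.names = FALSE)
if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(as.data.frame(smry), "results/verdicts.json",
                       auto_unbox = TRUE, digits = NA)
}

md <- c("# Bioindication verdicts (simulated study)", "",
        "| Metal | Status | Positive |", "|---|---|---|",
        sprintf("| %s | %s | %s |", smry$metal, smry$status,
                ifelse(smry$positive, "yes", "no")))
writeLines(md, "results/verdicts.md")

cat(sprintf("\nPositive verdicts: %s\n",
            paste(smry$metal[smry$positive], collapse = ", ")))
cat("Wrote results/verdicts.{csv,json,md}\n")
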