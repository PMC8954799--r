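#!/usr/bin/env Rscript
# Stage 3: exercise the AAS quantification chain on forward-simulated
# signals.
#
# Each simulated tissue concentration is pushed through the measurement
# model — 100 mg of powder ashed and dissolved in 4 mL of digest, dilution
# into the calibration range, peak area from the metal's calibration line —
# and then quantified back with the same chain a lab would use (blank
# subtraction, calibration line, dilution factor, LoD flagging). The
# round-trip error measures the chain's numerical fidelity; spike-recovery
# and control checks demonstrate the QC rules.

library(phytodoe)

seed <- 1L
uptake <- tibble::as_tibble(utils::read.csv("results/uptake.csv"))

# calibration lines fitted from synthetic standard signals on each metal's
# published standard series (slopes are plausible instrument sensitivities)
standards <- aviculare_standards()
slopes <- c(Cd = 1.8, Cr = 0.9, Cu = 1.1, Pb = 0.6, Zn = 14)
set.seed(seed)
cals <- lapply(seq_len(nrow(standards)), function(i) {
  s <- standards[i, ]
  conc <- c(s$c1, s$c2, s$c3)
  blanks <- stats::rnorm(3, 0.05, 0.002)
  signal <- mean(blanks) + slopes[[s$metal]] * conc +
    stats::rnorm(3, 0, 0.01 * slopes[[s$metal]] * s$c3)
  fit_calibration(data.frame(concentration = conc, signal = signal),
                  blanks, metal = s$metal, unit_scale = s$unit_scale)
})
names(cals) <- standards$metal
for (cal in cals) print(cal)

records <- simulate_aas_records(uptake, cals, seed = seed, signal_sd = 0)
quantified <- quantify_aas(records, cals)

cat(sprintf("\nQuantified %d AAS records; %d below LoD\n",
            nrow(quantified), sum(quantified$below_lod)))
for (m in names(cals)) {
  truth <- uptake[[m]]
  got <- quantified$tissue_mg_per_kg[quantified$metal == m]
  cat(sprintf("  %-2s max |recovered - true| = %.2g mg/kg\n",
              m, max(abs(got - truth))))
}

# QC demonstrations on the Cd chain
rec <- spike_recovery(measured_spiked = 1085, measured_base = 100,
                      spike_added = 1000)
print(rec)
print(control_check(measured = 4.1, nominal = 4))

utils::write.csv(as.data.frame(quantified), "results/quantified.csv",
                 row.names = FALSE)
cat("\nWrote results/quantified.csv\n")
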