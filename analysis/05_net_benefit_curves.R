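#!/usr/bin/env Rscript
# Stage 5 — net benefit of the four treatment strategies across the NWT grid.
#
# Strategies compared against the treat-no-one reference (net benefit 0):
# treat everybody with one regimen (NB = ATE - T), treat by the severity
# rule (SAPS II ITE > T), and treat by the optimal individual model
# (regimen with the maximal predicted effect, given its effect exceeds T).
# Percentile bootstrap bands from trial-stratified patient resampling.

suppressPackageStartupMessages(library(steroidite))

cohort <- read_cohort("results/cohort.csv")
ite_opt <- read.csv("results/ite_optimal.csv")
ite_sev <- read.csv("results/ite_saps2.csv")

strategies <- list(
  treat_none = list(type = "treat_none"),
  treat_all_hydrocortisone = list(type = "treat_all",
                                  d = ite_opt$hydrocortisone),
  treat_all_combination = list(type = "treat_all", d = ite_opt$combination),
  rule_saps2 = list(type = "rule", d = ite_sev$d),
  rule_optimal = list(type = "rule", d = ite_opt$d))

curves <- net_benefit_curves(strategies, nwt_grid = 2:100,
                             bootstrap_B = 500, seed = 505,
                             strata = cohort$trial)
write.csv(curves, "results/net_benefit.csv", row.names = FALSE)

at25 <- curves[curves$nwt == 25, ]
cat("Net benefit at NWT 25 (T = 0.04):\n")
for (i in seq_len(nrow(at25)))
  cat(sprintf("  %-26s NB %6.3f (%6.3f, %6.3f)  treating %5.1f%%\n",
              at25$strategy[i], at25$net_benefit[i], at25$ci_lo[i],
              at25$ci_hi[i], 100 * at25$treated_fraction[i]))

cross <- subset(curves, strategy == "treat_all_hydrocortisone" &
                          net_benefit > 0)
cat(sprintf("\nTreat-all (hydrocortisone) becomes positive at NWT > %s\n",
            if (nrow(cross)) min(cross$nwt) else "none in grid"))
rule_vs_all <- merge(
  curves[curves$strategy == "rule_optimal", c("nwt", "net_benefit")],
  curves[curves$strategy == "treat_all_hydrocortisone",
         c("nwt", "net_benefit")], by = "nwt")
cat(sprintf("Optimal-model rule >= treat-all at %d of %d grid points\n",
            sum(rule_vs_all$net_benefit.x >= rule_vs_all$net_benefit.y),
            nrow(rule_vs_all)))

png("results/net_benefit.png", width = 900, height = 600)
plot(curves, main = "Net benefit by number willing to treat")
dev.off()
cat("Written: results/net_benefit.csv, results/net_benefit.png\n")
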