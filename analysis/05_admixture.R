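#!/usr/bin/env Rscript
# Supervised admixture: three-cluster (African/Asian/European) ancestry
# fractions for the admixed cohorts, compared with the generator's true
# Dirichlet fractions, plus the two-cluster African/European model for the
# ASW-like cohort.

library(polyTE)

sim <- simulate_polyte(serial_founder_preset(seed = 42))
m <- sim$matrix; panel <- sim$panel
dir.create("results", showWarnings = FALSE)

targets <- panel$sample[panel$group == "American"]
fit <- supervised_admixture(m, panel, c("African", "European", "Asian"),
                            targets)
write_q_matrix(fit$q, "results/admixed_q.txt")

qt <- sim$truth$q_true[targets, c("African", "European", "Asian")]
cat(sprintf("Mean |q_hat - q_true| over %d admixed individuals: %.3f\n",
            length(targets), mean(abs(fit$q - qt))))
for (pop in c("ASW_SIM", "LAT_SIM")) {
  i <- panel$population[match(targets, panel$sample)] == pop
  cat(sprintf("%s mean ancestry (est | truth): %s | %s\n", pop,
              paste(sprintf("%.2f", colMeans(fit$q[i, ])), collapse = "/"),
              paste(sprintf("%.2f", colMeans(qt[i, ])), collapse = "/")))
}
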