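#!/usr/bin/env Rscript
# Two-group survival comparison around the 25% early-lethality question.
#
# The published comparison contrasts egg survival of crosses that should
# segregate lethal NN zygotes (both parents Nn carriers) with crosses that
# cannot, reporting means of 89.16 +/- 3.76% vs 88.20 +/- 2.77% (P = 0.63,
# Student's t-test) for the Hungarian brooders — i.e. no trace of the
# expected quarter loss. Per-cross raw rates are not deposited, so this
# script exercises the comparison on simulated data under the two competing
# transmission models.

suppressPackageStartupMessages(library(carpscales))
dir.create("results", showWarnings = FALSE)
seed <- 20260926

carrier_pairs <- list(c("ssNn", "ssNn"), c("SsNn", "ssNn"), c("SsNn", "SsNn"),
                      c("ssNn", "ssNn"), c("SsNn", "ssNn"))
control_pairs <- list(c("ssNn", "ssnn"), c("ssnn", "ssnn"), c("SsNn", "ssnn"),
                      c("SSnn", "ssNn"), c("Ssnn", "ssnn"))

run <- function(model, label, seed) {
  a <- simulate_survival_rates(carrier_pairs, model = model, seed = seed)
  b <- simulate_survival_rates(control_pairs, model = model, seed = seed + 1L)
  res <- compare_survival(a, b)
  data.frame(
    scenario = label,
    carrier_mean = res$means[["a"]], carrier_sd = res$sds[["a"]],
    control_mean = res$means[["b"]], control_sd = res$sds[["b"]],
    t = res$statistic, p_value = res$p_value, stringsAsFactors = FALSE
  )
}

tab <- rbind(
  run(standard_model(), "standard (NN lethal, Asian-type)", seed),
  run(weak_n_model(), "weak-N (NN viable, Hungarian-type)", seed + 100L)
)
write.csv(tab, "results/survival_comparison.csv", row.names = FALSE)

cat("Simulated survival comparison -> results/survival_comparison.csv\n\n")
print(tab, row.names = FALSE, digits = 4)
cat("\nUnder the standard model the carrier x carrier group loses ~25% of",
    "zygotes and the t-test separates the groups decisively; under the",
    "weak-N model both groups hatch at the baseline rate and the test finds",
    "no difference — the direction of the published Hungarian result.\n")
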