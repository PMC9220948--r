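#!/usr/bin/env Rscript
# Line-tension sweep: how the equilibrium raft radius responds to the
# tension of the ordered/disordered boundary.
#
# Sweeps sigma over 0.1-3 pN (20 points) at the default membrane
# parameters and compares an exponential growth law (ln R* linear in
# sigma) against a plain linear one on the interior rows. High-affinity
# surface binding is hypothesised to raise line tension, so this curve is
# the model's bridge from binding to macrodomain formation.
#
# Writes: results/sweep.csv, results/sweep_fit.json, results/sweep_config.yaml

library(raftsizer)

cfg <- read_run_config(
  system.file("extdata", "default_run_config.yaml", package = "raftsizer")
)
cfg$output_dir <- "results"
out <- run_sweep(cfg)

print(out$result)
tab <- out$result$table
cat(sprintf(
  "\nR* spans %.3g nm at sigma = %.2g pN to %.4g nm at sigma = %.2g pN;\n",
  tab$R_star_nm[1], tab$sigma_pN[1],
  tab$R_star_nm[nrow(tab)], tab$sigma_pN[nrow(tab)]
))
cat(sprintf(
  "all %d rows have interior minima and R* increases strictly: %s\n",
  nrow(tab), all(diff(tab$R_star_nm) > 0)
))
cat(sprintf(
  "exponential law preferred (R^2 %.4f vs %.4f linear)\n",
  out$result$growth_fit$r_squared, out$result$comparison_fit$r_squared
))
cat("\nWrote", out$csv, "and", out$fit_json, "\n")
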