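#!/usr/bin/env Rscript
# Loop-design differential expression on the staged cohort: four hybridized
# samples per stage with dye-swap mates, background correction, within-array
# loess and between-array quantile normalization, the moderated loop model,
# DEG selection (FC > 1.5, p < 0.05, A >= 7) and the cross-contrast
# partition. Reads results/staged_cohort.tsv (run 02_stage.R first).

library(follistage)

SEED <- 2026L
staged <- utils::read.delim("results/staged_cohort.tsv")

# four hybridized samples per stage: the most stage-characteristic x scores
pick <- function(stage, scorer) {
  d <- staged[staged$stage == stage, ]
  d$sample_id[order(scorer(d$x_score))][1:4]
}
hyb <- c(pick("growing", function(x) -x),
         pick("plateau", function(x) abs(x - median(x))),
         pick("atretic", identity))
assignment <- setNames(staged$stage[match(hyb, staged$sample_id)], hyb)

# injected truth: 100 probes regulated per transition (half up, half down)
eff <- rep(c(1, -1), each = 50)
de_config <- list(G_vs_P = setNames(eff, sprintf("P%05d", 1:100)),
                  P_vs_A = setNames(eff, sprintf("P%05d", 101:200)))
arrays <- simulate_loop_arrays(assignment, n_probes = 2000,
                               de_config = de_config, dye_bias = 0.3,
                               seed = SEED + 1000L)
norm <- normalize_between_quantile(
  normalize_within_loess(background_correct(arrays)))
fit <- fit_loop_model(norm)
cat(sprintf("Moderated model: d0 = %.1f, s0^2 = %.4f, dye coef mean %.3f\n",
            fit$d0, fit$s0_2, mean(fit$dye_coef)))

degs <- lapply(fit$contrasts, select_degs, crit = deg_criteria())
for (cn in names(fit$contrasts)) {
  write_tsv(fit$contrasts[[cn]], sprintf("results/contrast_%s.tsv", cn))
  write_tsv(degs[[cn]], sprintf("results/degs_%s.tsv", cn))
  cat(sprintf("%s: %d DEGs (%d up, %d down)\n", cn, nrow(degs[[cn]]),
              sum(degs[[cn]]$direction == "up"),
              sum(degs[[cn]]$direction == "down")))
}

part <- partition_contrasts(degs$G_vs_P, degs$P_vs_A, degs$G_vs_A)
write_tsv(part$table, "results/deg_partition.tsv")
cat("Partition:", paste(names(part$counts), unlist(part$counts),
                        collapse = ", "), "\n")

truth <- data.frame(probe = arrays$probes,
                    true_G_vs_P = unname(arrays$truth$effects$G_vs_P),
                    true_P_vs_A = unname(arrays$truth$effects$P_vs_A),
                    true_G_vs_A = unname(arrays$truth$effects$G_vs_A))
write_tsv(truth, "results/true_effects.tsv")
tp <- mean(sprintf("P%05d", 101:200) %in% degs$P_vs_A$probe)
cat(sprintf("Sensitivity for the injected P-vs-A effects: %.0f%%\n", 100 * tp))
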