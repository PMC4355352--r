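#!/usr/bin/env Rscript
# Between-group analysis of the normalized single-channel data sets: with
# four biological replicates per stage and dye-swap mates, the green channel
# carries eight data sets per growth stage. Projects them onto the two
# between-group axes and scores the segregation. Reads
# results/staged_cohort.tsv (run 02_stage.R first).

library(follistage)

SEED <- 2026L
staged <- utils::read.delim("results/staged_cohort.tsv")
pick <- function(stage, scorer) {
  d <- staged[staged$stage == stage, ]
  d$sample_id[order(scorer(d$x_score))][1:4]
}
hyb <- c(pick("growing", function(x) -x),
         pick("plateau", function(x) abs(x - median(x))),
         pick("atretic", identity))
assignment <- setNames(staged$stage[match(hyb, staged$sample_id)], hyb)

eff <- rep(c(1, -1), each = 50)
de_config <- list(G_vs_P = setNames(eff, sprintf("P%05d", 1:100)),
                  P_vs_A = setNames(eff, sprintf("P%05d", 101:200)))
arrays <- simulate_loop_arrays(assignment, n_probes = 2000,
                               de_config = de_config, dye_bias = 0.3,
                               seed = SEED + 1000L)
norm <- normalize_between_quantile(
  normalize_within_loess(background_correct(arrays)))

green <- extract_channel_data(norm, "green")
stages <- attr(green, "stages")
cat("Data sets per stage:", paste(names(table(stages)), table(stages),
                                  collapse = ", "), "\n")

bga <- between_group_analysis(green, stages)
scores <- data.frame(dataset = rownames(bga$sample_scores), stage = stages,
                     bga$sample_scores)
write_tsv(scores, "results/bga_scores.tsv")
cat(sprintf("Axes: %d; inertia explained %.1f%% / %.1f%%\n",
            ncol(bga$sample_scores), 100 * bga$inertia_explained[1],
            100 * bga$inertia_explained[2]))
cat(sprintf("Mean silhouette of the stage groups: %.3f\n",
            separation_score(bga)))

pdf("results/bga_scatter.pdf", width = 5, height = 5)
plot(bga$sample_scores, col = factor(stages), pch = 19,
     main = "Between-group analysis of single-channel data sets")
legend("topright", legend = levels(factor(stages)), col = 1:3, pch = 19)
dev.off()
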