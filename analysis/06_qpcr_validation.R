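#!/usr/bin/env Rscript
# qPCR validation branch on the staged cohort (seven samples per stage):
# five-point standard curves, quantification, geNORM normalization with
# EIF2B2/SF3A1, theca-contamination QC on CYP17A1 (one atretic sample is
# simulated as contaminated), and the per-gene stage statistics.

library(follistage)

SEED <- 2026L
staged <- utils::read.delim("results/staged_cohort.tsv")
ids <- staged$sample_id[staged$stage %in% c("growing", "plateau", "atretic")]
assignment <- setNames(staged$stage[match(ids, staged$sample_id)], ids)
contaminated <- ids[assignment == "atretic"][2]

sim <- simulate_qpcr(assignment, contaminated_sample = contaminated,
                     seed = SEED + 2000L)
curves <- lapply(split(sim$standards, sim$standards$gene), fit_standard_curve)
curve_tab <- do.call(rbind, lapply(curves, function(cv)
  data.frame(gene = cv$gene, slope = cv$slope, intercept = cv$intercept,
             efficiency = cv$efficiency, r2 = cv$r2)))
write_tsv(curve_tab, "results/qpcr_curves.tsv")
cat(sprintf("Standard curves: efficiencies %.0f%%-%.0f%%, r2 >= %.4f\n",
            100 * min(curve_tab$efficiency), 100 * max(curve_tab$efficiency),
            min(curve_tab$r2)))

panel <- quantify(sim$panel, curves)
normed <- genorm_normalize(panel)
cat(sprintf("geNORM reference stability M = %.2f (EIF2B2), %.2f (SF3A1)\n",
            normed$stability_M["EIF2B2"], normed$stability_M["SF3A1"]))

qc <- contamination_qc(normed$panel, "CYP17A1")
cat(sprintf("Contamination QC: Bartlett p = %.3g; flagged: %s (simulated: %s)\n",
            qc$bartlett_p,
            if (nrow(qc$flagged)) paste(qc$flagged$sample, collapse = ", ")
            else "none", contaminated))

clean <- normed$panel[!normed$panel$sample %in% qc$flagged$sample &
                        !normed$panel$gene %in% c("EIF2B2", "SF3A1", "CYP17A1"), ]
stats_tab <- stage_stats(clean)
write_tsv(stats_tab, "results/qpcr_stats.tsv")
cat(sprintf("Stage statistics for %d genes; %d with a significant linear trend\n",
            nrow(stats_tab), sum(stats_tab$trend_p < 0.05, na.rm = TRUE)))
print(stats_tab[, c("gene", "anova_p", "trend_p", "letters")])
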