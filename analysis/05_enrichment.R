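#!/usr/bin/env Rscript
# Gene-set and signed-regulon scoring of the P-vs-A DEG list: Fisher
# over-representation of the truly regulated probe set, and the activation
# z-score of the truth-derived "atresia program" regulon (expected directions
# from the injected effect signs). Reads results/ from 03.

library(follistage)

contrast <- utils::read.delim("results/contrast_P_vs_A.tsv")
degs <- utils::read.delim("results/degs_P_vs_A.tsv")
truth <- utils::read.delim("results/true_effects.tsv")

universe <- truth$probe
true_set <- truth$probe[truth$true_P_vs_A != 0]
p_fisher <- fisher_enrichment(degs$probe, true_set, universe)
cat(sprintf("Fisher over-representation of the truly regulated set: p = %.3g\n",
            p_fisher))

reg <- regulon("atresia_program",
               setNames(sign(truth$true_P_vs_A[truth$true_P_vs_A != 0]),
                        true_set))
res <- activation_zscore(degs, reg)
cat(sprintf("Activation z-score: z = %.2f over %d overlapping genes -> %s\n",
            res$z, res$n_overlap, res$call))

# a direction-inverted control regulon must flip the call
reg_inv <- regulon("atresia_program_inverted", -reg$members)
res_inv <- activation_zscore(degs, reg_inv)
cat(sprintf("Inverted control: z = %.2f -> %s\n", res_inv$z, res_inv$call))

write_tsv(data.frame(regulator = c(res$regulator_id, res_inv$regulator_id),
                     z = c(res$z, res_inv$z),
                     n_overlap = c(res$n_overlap, res_inv$n_overlap),
                     call = c(res$call, res_inv$call),
                     fisher_p = p_fisher),
          "results/enrichment.tsv")
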