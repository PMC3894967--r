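#!/usr/bin/env Rscript
# Stage 1: generate the default two-region, two-arm synthetic study and
# write it to disk as the TSV bundle every later stage consumes.
#
# The cohort mirrors a chronic-corticosterone antidepressant experiment:
# 11 fluoxetine-treated and 8 control animals, dorsal and ventral dentate
# gyrus profiled per animal, ~45,000 probes, behaviors coupled to the
# per-animal latent state.

suppressMessages(library(exprstate))

out_dir <- "results/study"
seed <- 1L

params <- generator_params(seed = seed)
study <- generate_study(params)
print(study)

paths <- write_study(study, out_dir)
cat("wrote", length(paths), "files to", out_dir, "\n")

info <- unique(study$info[, c("animal_id", "treatment",
                              "fst_immobility_s", "nsf_latency_s")])
cat(sprintf("\ntreated group mean FST immobility: %.0f s, control: %.0f s\n",
            mean(info$fst_immobility_s[info$treatment == "CORT_FLX"]),
            mean(info$fst_immobility_s[info$treatment == "CORT"])))
tt <- group_compare(info$fst_immobility_s[info$treatment == "CORT_FLX"],
                    info$fst_immobility_s[info$treatment == "CORT"])
cat(sprintf("FST group difference: t = %.2f, p = %.4g\n", tt$t, tt$p_value))

pres <- mean(study$annotation$present_fraction > 0.5)
cat(sprintf("probes present in >50%% of samples: %.1f%%\n", 100 * pres))
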