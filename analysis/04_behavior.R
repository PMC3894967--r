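#!/usr/bin/env Rscript
# Stage 4: relate the state score to antidepressant-sensitive behaviors.
# Flags treated animals whose response is ambiguous (responder on exactly
# one of the two tests), then correlates each region's PCA1 with forced
# swim immobility and novelty-suppressed-feeding latency, with and
# without the exclusion.

suppressMessages(library(exprstate))

study_dir <- "results/study"
out_dir <- "results/behavior"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

zprep <- function(m) zscore_rows(suppressWarnings(drop_constant_rows(m)))

regions <- c("dorsal", "ventral")
expr <- lapply(regions, function(r)
  load_expression(file.path(study_dir, paste0("expression_", r, ".tsv")),
                  file.path(study_dir, "sample_info.tsv"))$expression)
names(expr) <- regions
info <- read.delim(file.path(study_dir, "sample_info.tsv"))

scores <- lapply(regions, function(r) compute_pca1(zprep(expr[[r]])))
names(scores) <- regions
treat <- info$treatment[match(scores$dorsal$sample_ids, info$sample_id)]
scores <- lapply(scores, orient_scores,
                 anchor = as.numeric(treat == "CORT_FLX"))

flags <- flag_ambiguous_responders(info[info$treatment == "CORT_FLX", ],
                                   info[info$treatment == "CORT", ])
cat(sprintf("%d of %d treated animals ambiguous (responder on one test only)\n",
            sum(flags$ambiguous), nrow(flags)))
write.table(flags, file.path(out_dir, "responder_flags.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (excl in c(TRUE, FALSE)) {
  rep_ <- behavior_state_report(scores, info, exclude_ambiguous = excl)
  cat(sprintf("\nstate-behavior associations (%s ambiguous animals):\n",
              if (excl) "excluding" else "including"))
  print(rep_[, c("region", "behavior", "method", "r", "p_value", "n")],
        digits = 3)
  write.table(rep_, file.path(out_dir, sprintf("associations_%s.tsv",
                                               if (excl) "excluded" else "all")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
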