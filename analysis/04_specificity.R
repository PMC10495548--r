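#!/usr/bin/env Rscript
# Host specificity of the barcoded individuals: binomial GLMs for the
# probability that an individual was trapped at a usual host of its
# (assigned) species, with tree-type and host-species effects,
# likelihood-ratio tests, and the receptive-vs-vegetative interval.
#
# Usage: Rscript analysis/04_specificity.R [--out results]

suppressPackageStartupMessages(library(figwasp))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
res_dir <- get_arg("--out", "results")

bar <- read.csv(file.path(res_dir, "data", "barcodes.csv"),
                stringsAsFactors = FALSE)
asg <- read.delim(file.path(res_dir, "assignments.tsv"),
                  stringsAsFactors = FALSE)
bar <- merge(bar, asg[, c("individual_id", "assigned_species")],
             by = "individual_id")
registry <- synthetic_registry(length(unique(bar$host_fig_species)))

s3 <- run_stage3_specificity(bar, registry)
write.table(s3$aic, file.path(res_dir, "stage3_aic.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(s3$ci, file.path(res_dir, "stage3_treetype_ci.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Stage 3 on", nrow(s3$data), "individuals\n")
cat(sprintf("Observed usual-host fractions: receptive %.3f, vegetative %.3f\n",
            s3$p_usual[["receptive"]], s3$p_usual[["vegetative"]]))
cat(sprintf("Tree-type LRT: chi-square(%d) = %.2f, p = %.3g\n",
            s3$lrt_tree_type$df, s3$lrt_tree_type$chisq, s3$lrt_tree_type$p))
if (!is.null(s3$lrt_host)) {
  cat(sprintf("Host-species LRT: chi-square(%d) = %.2f, p = %.3g\n",
              s3$lrt_host$df, s3$lrt_host$chisq, s3$lrt_host$p))
}
cat("Receptive - vegetative (logit scale):\n")
print(s3$ci, row.names = FALSE)
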