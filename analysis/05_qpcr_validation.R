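#!/usr/bin/env Rscript
# Stage 5: qRT-PCR validation by relative quantification.
#
# Applies the 2^-ddCt rule to the triplicate Ct plate: per condition,
# delta-Ct = mean over replicates of (Ct_gene - Ct_reference) pairing by
# replicate; delta-delta-Ct = hypoxia minus normoxia; fold change =
# 2^(-ddCt). Welch t-tests on the per-replicate delta-Ct values call
# significant up-regulation at alpha = 0.05.

suppressMessages(library(nbhypoxia))

data_dir <- "results/data"
out_dir <- "results/qpcr"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ct <- read.csv(file.path(data_dir, "qpcr_ct.csv"), stringsAsFactors = FALSE)
res <- quantify_qpcr(ct, reference_gene = "ACTB")
write.table(res, file.path(out_dir, "qpcr_quantification.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("relative expression (hypoxia vs normoxia, reference ACTB):")
for (i in seq_len(nrow(res)))
  message(sprintf("  %-9s log2 fold %+.2f  fold %5.2f  p = %.3g%s",
                  res$gene[i], res$log2_fold[i], res$fold_change[i],
                  res$p[i], if (res$significant_up[i]) "  *" else ""))
message(sum(res$significant_up), " of ", nrow(res),
        " genes significantly up-regulated in hypoxia")
message("stage 5 complete: ", file.path(out_dir, "qpcr_quantification.tsv"))
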