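#!/usr/bin/env Rscript
# Stage 5: selection analysis — per-gene and genome pN/pS, the Fisher+BH
# positive-selection scan, and nitrification-gene class comparisons
# (Kruskal-Wallis + Dunn with Holm correction and a compact letter display).

suppressMessages(library(strainpop))

ann <- read_reference("results/simulated/reference.fa",
                      "results/simulated/reference.gff")
snps <- read_result_table("results/snps.tsv", "snps")
pooled <- read_site_counts("results/pooled_counts.tsv")

sel <- gene_selection_stats(snps, ann)
sel <- positive_selection_scan(sel)
data.table::fwrite(sel, "results/gene_selection.tsv", sep = "\t")

gp <- genome_pnps(sel)
cat(sprintf("genome pN/pS = %.3f (nN=%d over %.0f sites; nS=%d over %.0f)\n",
            gp$pnps, gp$n_nonsyn, gp$nonsyn_sites, gp$n_syn, gp$syn_sites))
cat(sprintf("%d genes flagged under positive selection\n", sum(sel$outlier)))
n_inf <- sum(is.infinite(sel$pnps))
cat(sprintf("%d genes with nonsynonymous-only polymorphism (pN/pS undefined,\n",
            n_inf))
cat("excluded from gene-level means)\n")

# per-gene pi for the class comparison
dt <- data.table::as.data.table(pooled)[sample == "ALL"]
cnt <- as.matrix(dt[, c("nA", "nC", "nG", "nT")])
dt$site_pi <- pi_site(cnt)
gene_pi <- vapply(seq_len(nrow(ann$genes)), function(i) {
  g <- ann$genes[i, ]
  sub <- dt[contig == g$contig_id & pos >= g$start & pos <= g$end]
  sum(sub$site_pi, na.rm = TRUE) / nrow(sub)
}, numeric(1))

cls <- ifelse(ann$genes$gene_class == "other", "other", "nitrification")
res <- compare_gene_classes(gene_pi, cls)
cat(sprintf("\ngene-class pi comparison (nitrification vs other): KW p = %.3f\n",
            res$kruskal$p.value))
print(res$letters)
data.table::fwrite(res$dunn, "results/gene_class_dunn.tsv", sep = "\t")
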