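#!/usr/bin/env Rscript
# Stage 3 - diversity and differentiation.
#
# Per-site diversity (A_O, rarefied AR, unbiased H_E, F_IS), global and
# pairwise Nei-Chesser G_ST and Hedrick G''_ST, exact G tests of pairwise
# differentiation with FDR control, and a bottleneck scan (TPM, variance 12,
# 95% single-step, one-tail Wilcoxon heterozygosity-excess test per site).

library(poolscape)

seed <- as.integer(Sys.getenv("POOLSCAPE_SEED", "1"))
out <- "results/run"
d <- read_genepop(file.path(out, "genotypes_qc.gen"))

g <- min(vapply(dataset_sites(d), function(s)
  min(vapply(d$loci, function(l) sum(allele_counts(d, l, s)), numeric(1))),
  numeric(1)))
div <- site_diversity(d, rarefaction_genes = g)
write.table(div, file.path(out, "site_diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("diversity across %d sites: mean AR %.2f, mean He %.2f, mean Fis %.3f\n",
            nrow(div), mean(div$ar), mean(div$he), mean(div$fis, na.rm = TRUE)))

glob <- gst_nei_chesser(d)
k <- length(dataset_sites(d))
cat(sprintf("global Gst %.4f, G''st %.4f\n", glob$gst,
            g_double_prime_st(glob$mean_hs, glob$mean_ht, k)))

pw <- pairwise_differentiation(d)
write_pairwise(pw$gst, file.path(out, "pairwise_gst.tsv"))
write_pairwise(pw$gst_hedrick, file.path(out, "pairwise_gst_hedrick.tsv"))
cat(sprintf("pairwise Gst range: %.4f to %.4f; cor(Gst, G''st) = %.3f\n",
            min(lower_vec(pw$gst)), max(lower_vec(pw$gst)),
            cor(lower_vec(pw$gst), lower_vec(pw$gst_hedrick))))

sites <- dataset_sites(d)
cmb <- combn(sites, 2, simplify = FALSE)
gt <- do.call(rbind, lapply(cmb, function(pp) {
  data.frame(site1 = pp[1], site2 = pp[2],
             p = exact_g_test_pairwise(d, pp, n_mc = 500, seed = seed)$p)
}))
adj <- fdr_adjust(gt$p)
gt$p_adjusted <- adj$p_adjusted
gt$significant <- adj$significant
write.table(gt, file.path(out, "exact_g_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sum(gt$significant), "of", nrow(gt),
    "pairwise exact G tests significant after FDR\n")

bt <- do.call(rbind, lapply(sites, function(s) {
  p <- tryCatch(bottleneck_tpm_test(d, s, n_sims = 200, seed = seed)$p,
                error = function(e) NA_real_)
  data.frame(site = s, p = p)
}))
bt$p_adjusted <- fdr_adjust(bt$p[!is.na(bt$p)])$p_adjusted[
  match(seq_len(nrow(bt)), which(!is.na(bt$p)))]
write.table(bt, file.path(out, "bottleneck.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("bottleneck heterozygosity-excess p-values:",
    paste(sprintf("%.2f", bt$p), collapse = " "), "\n")
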