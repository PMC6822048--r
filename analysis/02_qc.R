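#!/usr/bin/env Rscript
# Stage 2 - quality control.
#
# Reads the simulated genotypes and applies the filter cascade: individuals
# with fewer than five called loci are dropped, then sites with fewer than
# ten genotyped individuals. Null-allele frequencies are estimated per locus
# (Chakraborty and Brookfield-1), and Monte Carlo exact tests of
# Hardy-Weinberg proportions (per locus x site) and linkage disequilibrium
# (per locus pair x site) are run with Benjamini-Hochberg FDR control at
# alpha = 0.05.

library(poolscape)

seed <- as.integer(Sys.getenv("POOLSCAPE_SEED", "1"))
out <- "results/run"
d <- read_genepop(file.path(out, "genotypes.gen"))

f1 <- filter_by_completeness(d, min_loci = 5)
f2 <- filter_sites_by_n(f1$data, min_n = 10)
d2 <- f2$data
cat("completeness filter removed", f1$report$removed, "individuals;",
    "site-size filter removed", f2$report$removed, "\n")

nulls <- null_allele_estimates(d2)
write.table(nulls, file.path(out, "null_alleles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("null-allele estimates (Chakraborty): ",
    paste(sprintf("%.3f", nulls$chakraborty), collapse = " "), "\n")

hwe <- do.call(rbind, lapply(dataset_sites(d2), function(s) {
  do.call(rbind, lapply(d2$loci, function(l) {
    p <- tryCatch(hwe_exact_test(d2, l, s, n_mc = 2000, seed = seed)$p,
                  error = function(e) NA_real_)
    data.frame(site = s, locus = l, p = p)
  }))
}))
hwe <- hwe[!is.na(hwe$p), ]
adj <- fdr_adjust(hwe$p)
hwe$p_adjusted <- adj$p_adjusted
hwe$significant <- adj$significant
write.table(hwe, file.path(out, "hwe_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sum(hwe$significant), "of", nrow(hwe),
    "HWE tests significant after FDR\n")

pairs <- combn(d2$loci, 2, simplify = FALSE)
ld <- do.call(rbind, lapply(dataset_sites(d2), function(s) {
  do.call(rbind, lapply(pairs, function(pp) {
    p <- tryCatch(ld_exact_test(d2, pp, s, n_mc = 1000, seed = seed)$p,
                  error = function(e) NA_real_)
    data.frame(site = s, locus1 = pp[1], locus2 = pp[2], p = p)
  }))
}))
ld <- ld[!is.na(ld$p), ]
adj <- fdr_adjust(ld$p)
ld$p_adjusted <- adj$p_adjusted
ld$significant <- adj$significant
write.table(ld, file.path(out, "ld_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sum(ld$significant), "of", nrow(ld),
    "LD tests significant after FDR\n")

write_genepop(d2, file.path(out, "genotypes_qc.gen"))
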