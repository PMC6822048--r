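#!/usr/bin/env Rscript
# Stage 4 - isolation by distance and its spatial scaling.
#
# Great-circle distances, Mantel tests of linearized G_ST against distance
# (9,999 permutations), linear / quadratic / log-distance IBD regressions
# with 5th/95th quantile envelopes, a 20-km Mantel correlogram, the IBD
# scaling profile (expanding distance-sorted windows with bootstrap
# intervals), and the per-site isolation index from the IBD residuals.

library(poolscape)

seed <- as.integer(Sys.getenv("POOLSCAPE_SEED", "1"))
out <- "results/run"
d <- read_genepop(file.path(out, "genotypes_qc.gen"))
sites <- read_site_table(file.path(out, "sites.tsv"))
sites <- sites[sites$site %in% dataset_sites(d), ]

D <- geo_distance_matrix(sites)
pw <- read_pairwise(file.path(out, "pairwise_gst.tsv"), kind = "gst")
Gl <- pairwise_matrix(linearize(unclass(pw)), rownames(pw), "linearized_gst")

mt <- mantel_test(Gl, D, n_perm = 9999, seed = seed)
cat(sprintf("Mantel test, linearized Gst vs km: r = %.3f, p = %.4f (9,999 perms)\n",
            mt$r, mt$p))
mt_log <- mantel_test(Gl, pairwise_matrix(log1p(unclass(D)), rownames(D)),
                      n_perm = 9999, seed = seed)
cat(sprintf("  log-distance: r = %.3f, p = %.4f\n", mt_log$r, mt_log$p))

fit <- ibd_regression(Gl, D, form = "linear", quantiles = c(0.05, 0.95))
cat(sprintf("OLS IBD: intercept %.3e, beta %.3e, R2 = %.3f\n",
            fit$coefficients[1], fit$coefficients[2], fit$r_squared))
fitq <- ibd_regression(Gl, D, form = "quadratic")
cat(sprintf("quadratic IBD R2 = %.3f\n", fitq$r_squared))

cg <- mantel_correlogram(Gl, D, class_width_km = 20, n_perm = 2000,
                         seed = seed)
write.table(cg, file.path(out, "correlogram.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("correlogram classes retained:", nrow(cg),
    "; significant:", sum(cg$significant), "\n")

prof <- ibd_scaling_profile(Gl, D, start_pairs = 20, n_boot = 1000,
                            seed = seed)
write.table(prof, file.path(out, "scaling_profile.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("scaling profile: beta from %.2e (first window) to %.2e (all pairs)\n",
            prof$beta[1], prof$beta[nrow(prof)]))

iso <- site_isolation_index(fit)
write.table(iso, file.path(out, "isolation_index.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("most isolated site:", iso$site[which.max(iso$isolation)],
    sprintf("(index %.4f)\n", max(iso$isolation, na.rm = TRUE)))
write_pairwise(D, file.path(out, "geo_distance_km.tsv"))
write_pairwise(fit$residual_matrix, file.path(out, "ibd_residuals.tsv"))
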