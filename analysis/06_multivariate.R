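#!/usr/bin/env Rscript
# Stage 6 - urbanization, isolation, and diversity.
#
# Builds site-level landscape covariates (developed cover and road/river
# densities around each deme), prunes collinear covariates at |r| > 0.7,
# regresses diversity and the isolation index on the retained covariates,
# and runs the two matrix-level analyses: dbRDA of pairwise G_ST with a
# lat/lon conditioning matrix and backward elimination, and MMRR with the
# pseudo-t permutation test.

library(poolscape)

seed <- as.integer(Sys.getenv("POOLSCAPE_SEED", "1"))
out <- "results/run"

cfg <- pipeline_config(out_dir = file.path(out, "rebuild"), seed = seed,
                       stages = "simulate")
sim <- run_pipeline(cfg)$results$sim

d <- read_genepop(file.path(out, "genotypes_qc.gen"))
ids <- dataset_sites(d)
demes <- sim$demes[match(ids, sim$demes$site), ]
sites <- sim$sites[match(ids, sim$sites$site), ]
div <- read.table(file.path(out, "site_diversity.tsv"), header = TRUE,
                  sep = "\t")
iso <- read.table(file.path(out, "isolation_index.tsv"), header = TRUE,
                  sep = "\t")
pw <- read_pairwise(file.path(out, "pairwise_gst.tsv"), kind = "gst")
G <- pairwise_matrix(unclass(pw)[ids, ids], ids, "gst")
D <- pairwise_matrix(
  unclass(read_pairwise(file.path(out, "geo_distance_km.tsv")))[ids, ids],
  ids, "geographic_km")

cov <- local_covariates(sim$land, demes)
cov <- cov[, c(TRUE, vapply(cov[-1], sd, numeric(1)) > 0), drop = FALSE]
pr <- collinearity_prune(cov[, -1, drop = FALSE], threshold = 0.7,
                         seed = seed)
cat("covariates retained after |r| > 0.7 pruning:",
    paste(pr$retained, collapse = ", "), "\n")
X <- cov[, pr$retained, drop = FALSE]

for (resp in c("ar", "he")) {
  fit <- multiple_regression(div[[resp]][match(ids, div$site)], X)
  cat(sprintf("%s ~ covariates: adj R2 %.3f, model p %.3f\n", toupper(resp),
              fit$adj_r_squared, fit$model_p))
}
fit_iso <- multiple_regression(iso$isolation[match(ids, iso$site)], X)
cat(sprintf("isolation ~ covariates: adj R2 %.3f, model p %.3f\n",
            fit_iso$adj_r_squared, fit_iso$model_p))
write.table(fit_iso$coefficients, file.path(out, "isolation_regression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

flag <- outlier_rule_max_covariate(cov, names(cov)[2], factor = 2)
if (length(flag)) cat("outlier rule flags:", paste(flag, collapse = ", "), "\n")

Xm <- stats::setNames(lapply(pr$retained, function(cn)
  pairwise_matrix(abs(outer(cov[[cn]], cov[[cn]], "-")), ids, cn)),
  pr$retained)
mm <- mmrr(pairwise_matrix(linearize(unclass(G)), ids, "lin"),
           c(Xm, list(distance = D)), n_perm = 10000, seed = seed)
cat("\nMMRR (10,000 permutations):\n")
print(mm$coefficients, digits = 3)
write.table(mm$coefficients, file.path(out, "mmrr.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

db <- dbrda(G, stats::setNames(as.data.frame(X), pr$retained),
            condition = sites[, c("lat", "lon")], n_perm = 10000,
            alpha = 0.05, seed = seed)
cat("\ndbRDA retained terms:\n")
print(db$retained, digits = 3)
cat(sprintf("variance explained (adj R2): terms %.3f, geography %.3f, combined %.3f\n",
            db$varpart$explanatory, db$varpart$condition,
            db$varpart$combined))
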