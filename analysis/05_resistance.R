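#!/usr/bin/env Rscript
# Stage 5 - landscape resistance modeling.
#
# Two-step procedure: (1) per-feature cost optimization - candidate cost
# grids (always including 1, the pure isolation-by-distance surface) are
# screened by circuit-theory effective resistance and partial Mantel tests
# of resistance vs linearized G_ST controlling for geographic distance;
# (2) all-subsets additive linear models over the features that beat IBD,
# ranked by AICc with Akaike weights.
#
# Needs the simulation stage's landscape in memory, so this driver re-runs
# the deterministic simulate stage (same seed) to rebuild it.

library(poolscape)

seed <- as.integer(Sys.getenv("POOLSCAPE_SEED", "1"))
out <- "results/run"

cfg <- pipeline_config(out_dir = file.path(out, "rebuild"), seed = seed,
                       stages = "simulate")
sim <- run_pipeline(cfg)$results$sim
land <- sim$land

d <- read_genepop(file.path(out, "genotypes_qc.gen"))
demes <- sim$demes[sim$demes$site %in% dataset_sites(d), ]
pw <- read_pairwise(file.path(out, "pairwise_gst.tsv"), kind = "gst")
ids <- demes$site
Gl <- pairwise_matrix(linearize(unclass(pw)[ids, ids]), ids, "linearized_gst")
D <- read_pairwise(file.path(out, "geo_distance_km.tsv"))[ids, ids]
D <- pairwise_matrix(D, ids, "geographic_km")

candidates <- list(interstates = c(1, 5, 25, 100, 500, 1000),
                   landcover_C = c(1, 5, 15, 50),
                   light_roads = c(1, 5, 10, 25, 100),
                   medium_rivers = c(1, 25, 100, 500),
                   tri = c(1, 100, 500, 1000))
opts <- list(); best <- list()
for (f in names(candidates)) {
  if (f != "tri" && !grepl("^landcover", f) && sum(land[[f]]) == 0) next
  o <- optimize_feature_cost(land, f, candidates[[f]], Gl, D, demes,
                             n_perm = 2000, seed = seed)
  opts[[f]] <- o
  cat(sprintf("%-14s best cost %-6s r2 %.3f %s\n", f, as.character(o$best_cost),
              max(o$table$r_squared, na.rm = TRUE),
              if (o$beats_ibd) "(beats IBD)" else ""))
  if (isTRUE(o$beats_ibd))
    best[[f]] <- pairwise_matrix(o$resistance, rownames(o$resistance),
                                 "resistance")
}
jsonlite::write_json(lapply(opts, function(o)
  list(best_cost = o$best_cost, beats_ibd = o$beats_ibd, table = o$table)),
  file.path(out, "cost_optimization.json"), auto_unbox = TRUE, digits = NA)

if (length(best)) {
  mt <- aicc_model_selection(Gl, best, D)
  write.table(as.data.frame(mt), file.path(out, "model_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("\ntop models (delta AICc < 2):\n")
  print(as.data.frame(mt)[mt$delta_aicc < 2,
                          c("model", "AICc", "delta_aicc", "weight")])
} else {
  cat("no feature beat the IBD baseline; no model table written\n")
}
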