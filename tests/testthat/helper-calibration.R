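# Type-I error calibrations for the permutation tests: each helper returns
# the fraction of null replicates rejected at alpha = 0.05. Reduced
# permutation counts (199) keep the runs fast; the add-one rule makes the
# rejection rule h <= 9 of 199, which is exact for continuous statistics.

calibrate_hwe <- function(n_rep = 1000, n = 25, p = c(0.5, 0.3, 0.2),
                          n_mc = 199, seed = 1) {
  set.seed(seed)
  mean(vapply(seq_len(n_rep), function(b) {
    d <- sim_hwe_site(n, p)
    hwe_exact_test(d, "L1", "S", n_mc = n_mc, seed = seed + b)$p <= 0.05
  }, logical(1)))
}

calibrate_ld <- function(n_rep = 1000, n = 25, n_mc = 199, seed = 2) {
  set.seed(seed)
  mean(vapply(seq_len(n_rep), function(b) {
    d <- sim_hwe_site(n, c(0.5, 0.3, 0.2), loci = c("L1", "L2"))
    ld_exact_test(d, c("L1", "L2"), "S", n_mc = n_mc,
                  seed = seed + b)$p <= 0.05
  }, logical(1)))
}

calibrate_exact_g <- function(n_rep = 600, n = 15, n_mc = 199, seed = 3) {
  set.seed(seed)
  mean(vapply(seq_len(n_rep), function(b) {
    a <- sim_hwe_site(n, c(0.4, 0.3, 0.3), site = "A", loci = c("L1", "L2"))
    bb <- sim_hwe_site(n, c(0.4, 0.3, 0.3), site = "B", loci = c("L1", "L2"))
    d <- genotype_dataset(c(a$site, bb$site), c(a$id, bb$id), a$loci,
                          rbind(a$a1, bb$a1), rbind(a$a2, bb$a2))
    exact_g_test_pairwise(d, c("A", "B"), n_mc = n_mc,
                          seed = seed + b)$p <= 0.05
  }, logical(1)))
}

calibrate_mantel <- function(n_rep = 1000, n = 10, n_perm = 199, seed = 4) {
  set.seed(seed)
  mean(vapply(seq_len(n_rep), function(b) {
    A <- rand_pairwise(n); B <- rand_pairwise(n)
    mantel_test(A, B, n_perm = n_perm, seed = seed + b)$p <= 0.05
  }, logical(1)))
}

calibrate_partial_mantel <- function(n_rep = 1000, n = 10, n_perm = 199,
                                     seed = 5) {
  set.seed(seed)
  mean(vapply(seq_len(n_rep), function(b) {
    A <- rand_pairwise(n); B <- rand_pairwise(n); C <- rand_pairwise(n)
    partial_mantel(A, B, C, n_perm = n_perm, seed = seed + b)$p <= 0.05
  }, logical(1)))
}

calibrate_mmrr <- function(n_rep = 600, n = 10, n_perm = 199, seed = 6) {
  set.seed(seed)
  mean(vapply(seq_len(n_rep), function(b) {
    Y <- rand_pairwise(n); X1 <- rand_pairwise(n)
    out <- mmrr(Y, list(x1 = X1), n_perm = n_perm, seed = seed + b)
    out$coefficients$p[out$coefficients$term == "x1"] <= 0.05
  }, logical(1)))
}

# one replicate of the barrier parameter-recovery experiment: simulate
# 15 demes on a 60 x 60 raster with a river of cost 500, optimize the river
# cost and run AICc selection against an unrelated candidate feature
recovery_replicate <- function(s, n_perm = 99) {
  land <- generate_landscape(60, 60, list(medium_rivers = 1, interstates = 1),
                             seed = s)
  demes <- place_demes(15, 60, 60, seed = s + 1000, stack = land)
  cfg <- simulation_config(n_demes = 15, deme_size = 50, n_loci = 8,
                           generations = 100, sample_sizes = 20,
                           seed = s + 2000)
  sim <- simulate_genotypes(land, demes, cfg,
                            true_costs = c(medium_rivers = 500))
  pw <- pairwise_differentiation(sim$data)
  D <- geo_distance_matrix(sim$sites)
  Gl <- pairwise_matrix(linearize(pw$gst), rownames(pw$gst), "linearized_gst")
  cand <- c(1, 25, 100, 500)
  o_riv <- optimize_feature_cost(land, "medium_rivers", cand, Gl, D, demes,
                                 n_perm = n_perm, seed = s)
  o_dec <- optimize_feature_cost(land, "interstates", cand, Gl, D, demes,
                                 n_perm = n_perm, seed = s + 1)
  preds <- list()
  if (isTRUE(o_riv$beats_ibd))
    preds$medium_rivers <- pairwise_matrix(o_riv$resistance,
                                           rownames(o_riv$resistance),
                                           "resistance")
  if (isTRUE(o_dec$beats_ibd))
    preds$interstates <- pairwise_matrix(o_dec$resistance,
                                         rownames(o_dec$resistance),
                                         "resistance")
  in_top <- FALSE
  if (length(preds)) {
    mt <- aicc_model_selection(Gl, preds, D)
    in_top <- any(grepl("medium_rivers", mt$model[mt$delta_aicc < 2]))
  }
  list(best_cost = o_riv$best_cost, in_top = in_top)
}
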