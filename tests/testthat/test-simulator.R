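test_that("simulation config validates its rates and sizes", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(mutation_rate = 1.5), "rates")
  expect_error(simulation_config(deme_size = 1), "deme_size")
  expect_error(simulation_config(generations = 0), "generations")
  expect_error(simulation_config(sample_sizes = 100, deme_size = 50),
               "sample_sizes")
})

test_that("TPM step distribution hits the target variance", {
  q <- poolscape:::tpm_geom_q(0.95, 12)
  set.seed(51)
  steps <- poolscape:::tpm_steps(2e5, 0.95, q)
  expect_equal(mean(steps), 0, tolerance = 0.05)
  expect_equal(var(as.numeric(steps)), 12, tolerance = 0.6)
  expect_equal(mean(abs(steps) == 1), 0.95, tolerance = 0.01)
})

test_that("same seed gives bit-identical datasets", {
  land <- generate_landscape(20, 20, list(), seed = 1)
  demes <- place_demes(6, 20, 20, seed = 2)
  cfg <- simulation_config(n_demes = 6, deme_size = 30, n_loci = 4,
                           generations = 30, sample_sizes = 10, seed = 9)
  s1 <- simulate_genotypes(land, demes, cfg)
  s2 <- simulate_genotypes(land, demes, cfg)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth$migration_matrix, s2$truth$migration_matrix)
})

test_that("migration matrix rows sum to one with dominant diagonal", {
  land <- generate_landscape(20, 20, list(), seed = 1)
  demes <- place_demes(6, 20, 20, seed = 2)
  cfg <- simulation_config(n_demes = 6, deme_size = 30, n_loci = 2,
                           generations = 5, sample_sizes = 10, seed = 3)
  M <- simulate_genotypes(land, demes, cfg)$truth$migration_matrix
  expect_equal(rowSums(M), rep(1, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  # the best-connected deme retains exactly the configured fraction; more
  # isolated demes retain more
  expect_equal(min(diag(M)), 0.9, tolerance = 1e-12)
  expect_true(all(diag(M) >= 0.9 - 1e-12))
  expect_true(all(diag(M) > apply(M - diag(diag(M)), 1, max)))
})

test_that("sampling the whole deme returns the full gene pool", {
  land <- generate_landscape(20, 20, list(), seed = 1)
  demes <- place_demes(4, 20, 20, seed = 2)
  cfg <- simulation_config(n_demes = 4, deme_size = 15, n_loci = 3,
                           generations = 10, sample_sizes = 15, seed = 4)
  sim <- simulate_genotypes(land, demes, cfg)
  # 2 N_e genes per deme per locus, all non-missing
  for (s in dataset_sites(sim$data))
    expect_equal(unname(sum(allele_counts(sim$data, "L01", s))), 30)
})

test_that("pure drift with no mutation fixes isolated demes (Gst -> 1)", {
  land <- generate_landscape(12, 12, list(), seed = 1)
  demes <- data.frame(site = c("A", "B"), row = c(3, 9), col = c(3, 9))
  reps <- sapply(1:5, function(s) {
    cfg <- simulation_config(n_demes = 2, deme_size = 10, n_loci = 10,
                             n_alleles_init = 4, mutation_rate = 0,
                             self_retention = 1, generations = 200,
                             sample_sizes = 10, seed = s)
    sim <- simulate_genotypes(land, demes, cfg)
    k_per_locus <- sapply(seq_len(10), function(j)
      length(unique(c(sim$data$a1[, j], sim$data$a2[, j]))))
    gst <- tryCatch(gst_nei_chesser(sim$data)$gst, error = function(e) NA)
    c(max_k = max(k_per_locus), gst = gst)
  })
  # after 20 N_e generations every deme is fixed at every locus
  expect_true(all(reps["max_k", ] <= 2))
  # multilocus Gst is exactly 1 whenever any locus fixed differently
  expect_true(all(is.na(reps["gst", ]) | reps["gst", ] == 1))
  expect_gte(sum(reps["gst", ] == 1, na.rm = TRUE), 3)
})

test_that("island-model migration (lambda = 0) shows no IBD trend", {
  land <- generate_landscape(24, 24, list(), seed = 1)
  demes <- place_demes(8, 24, 24, seed = 2)
  rs <- sapply(1:10, function(s) {
    cfg <- simulation_config(n_demes = 8, deme_size = 30, n_loci = 6,
                             migration_scale = 0, generations = 60,
                             sample_sizes = 12, seed = 100 + s)
    sim <- simulate_genotypes(land, demes, cfg)
    pw <- pairwise_differentiation(sim$data)
    D <- geo_distance_matrix(sim$sites)
    Gl <- pairwise_matrix(linearize(pw$gst), rownames(pw$gst), "lin")
    mantel_test(Gl, D, n_perm = 49, seed = s)$r
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("higher barrier cost raises differentiation across the barrier", {
  # expectation over replicates: Spearman correlation between true
  # effective resistance and linearized Gst is positive
  land <- generate_landscape(30, 30, list(medium_rivers = 1), seed = 21)
  demes <- place_demes(8, 30, 30, seed = 22, stack = land)
  rhos <- sapply(1:8, function(s) {
    cfg <- simulation_config(n_demes = 8, deme_size = 40, n_loci = 6,
                             generations = 80, sample_sizes = 15,
                             seed = 200 + s)
    sim <- simulate_genotypes(land, demes, cfg,
                              true_costs = c(medium_rivers = 500))
    pw <- pairwise_differentiation(sim$data)
    cor(lower_vec(pw$gst), lower_vec(sim$truth$resistance),
        method = "spearman")
  })
  expect_gt(mean(rhos), 0)
})

test_that("disconnected deme graphs are reported with the offending pair", {
  land <- generate_landscape(9, 9, list(), seed = 1)
  # nodata wall down the middle
  r <- matrix(1, 9, 9); r[, 5] <- NA
  land_cut <- land
  # emulate by a custom surface through effective_resistance contract:
  # simulate_genotypes builds its own surface, so test via a landscape with
  # an impassable NA column is not expressible; instead test the error path
  # directly on effective_resistance + migration construction
  er <- effective_resistance(r, data.frame(site = c("A", "B"), row = 5,
                                           col = c(2, 8)))
  expect_true(is.infinite(er["A", "B"]))
})

test_that("artifact injection: identity at zero rates, masks at the set rate", {
  land <- generate_landscape(20, 20, list(), seed = 1)
  demes <- place_demes(4, 20, 20, seed = 2)
  cfg0 <- simulation_config(n_demes = 4, deme_size = 40, n_loci = 6,
                            generations = 20, sample_sizes = 25, seed = 5)
  sim <- simulate_genotypes(land, demes, cfg0)
  out0 <- inject_artifacts(sim$data, cfg0)
  expect_identical(out0$data$a1, sim$data$a1)
  expect_identical(out0$data$id, sim$data$id)
  rates <- sapply(1:5, function(s) {
    cfg_m <- simulation_config(n_demes = 4, deme_size = 40, n_loci = 6,
                               generations = 20, sample_sizes = 25,
                               missing_rate = 0.15, seed = s)
    mean(is.na(inject_artifacts(sim$data, cfg_m)$data$a1))
  })
  expect_lt(abs(mean(rates) - 0.15), 0.02)
})

test_that("injected null alleles are recovered by the estimators", {
  land <- generate_landscape(20, 20, list(), seed = 1)
  demes <- place_demes(3, 20, 20, seed = 2)
  cfg <- simulation_config(n_demes = 3, deme_size = 60, n_loci = 50,
                           n_alleles_init = 8, generations = 15,
                           sample_sizes = 40, null_allele_freq = 0.28,
                           seed = 6)
  sim <- simulate_genotypes(land, demes, cfg)
  out <- inject_artifacts(sim$data, cfg)
  est <- null_allele_estimates(out$data)
  expect_equal(mean(est$chakraborty), 0.28, tolerance = 0.08)
  expect_equal(mean(out$truth$null_gene_fraction), 0.28, tolerance = 0.03)
})

test_that("injected sib families are removed back to one member by the filter", {
  land <- generate_landscape(20, 20, list(), seed = 1)
  demes <- place_demes(3, 20, 20, seed = 2)
  cfg <- simulation_config(n_demes = 3, deme_size = 40, n_loci = 6,
                           generations = 20, sample_sizes = 15,
                           sib_family_config = list(2, 5), seed = 7)
  sim <- simulate_genotypes(land, demes, cfg)
  out <- inject_artifacts(sim$data, cfg)
  fams <- out$truth$sib_families
  expect_equal(nrow(fams), 3 * 2 * 5)
  filt <- remove_siblings(out$data, fams, seed = 1)
  # one member retained per family
  kept <- table(fams$family[fams$individual %in% filt$data$id])
  expect_true(all(kept == 1))
  expect_equal(length(kept), 6)
  # non-sib individuals untouched
  expect_true(all(sim$data$id %in% filt$data$id))
})
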