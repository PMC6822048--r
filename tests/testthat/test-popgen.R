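test_that("rarefied allelic richness matches subsample enumeration", {
  # counts {A:3, B:1}, N = 4, g = 2: enumerate all C(4,2) gene subsamples
  d <- make_geno(list(S = list(L1 = cbind(c(104L, 104L), c(104L, 106L)))))
  div <- site_diversity(d, rarefaction_genes = 2)
  genes <- c(104, 104, 104, 106)
  subs <- combn(4, 2)
  k_mean <- mean(apply(subs, 2, function(ii) length(unique(genes[ii]))))
  expect_equal(div$ar, k_mean)  # = 1.5
  expect_equal(div$ar, 1.5)
  # random-case enumeration oracle
  set.seed(7)
  for (rep in 1:5) {
    g6 <- sample(c(104L, 106L, 108L), 6, replace = TRUE)
    dd <- make_geno(list(S = list(
      L1 = cbind(g6[c(1, 3, 5)], g6[c(2, 4, 6)]))))
    div2 <- site_diversity(dd, rarefaction_genes = 3)
    subs3 <- combn(6, 3)
    oracle <- mean(apply(subs3, 2, function(ii) length(unique(g6[ii]))))
    expect_equal(div2$ar, oracle, tolerance = 1e-12)
  }
})

test_that("site diversity handles monomorphic loci and reports unbiased He", {
  d <- make_geno(list(S = list(
    L1 = cbind(rep(104L, 5), rep(104L, 5)),            # monomorphic
    L2 = cbind(rep(104L, 5), rep(106L, 5)))))          # all het
  div <- site_diversity(d, rarefaction_genes = 2)
  # per locus: AR 1 and 2; He 0 and (10/9)(1 - 0.5) = 0.5556
  expect_equal(div$ao, 1.5)
  expect_equal(div$he, mean(c(0, 10 / 9 * 0.5)), tolerance = 1e-12)
  # raw gene diversity option
  div_raw <- site_diversity(d, rarefaction_genes = 2, he_unbiased = FALSE)
  expect_equal(div_raw$he, mean(c(0, 0.5)), tolerance = 1e-12)
  # all-monomorphic site: He = 0, F_IS undefined
  m <- make_geno(list(S = list(L1 = cbind(rep(104L, 5), rep(104L, 5)))))
  dm <- site_diversity(m, rarefaction_genes = 2)
  expect_equal(dm$he, 0)
  expect_true(is.na(dm$fis))
})

test_that("Gst is 1 for fixed different alleles and ~0 for identical pools", {
  fixed <- make_geno(list(A = list(L1 = cbind(rep(104L, 10), rep(104L, 10))),
                          B = list(L1 = cbind(rep(110L, 10), rep(110L, 10)))))
  expect_equal(gst_nei_chesser(fixed)$gst, 1)
  set.seed(8)
  big <- sim_hwe_site(500, c(0.5, 0.3, 0.2), site = "A")
  bigb <- sim_hwe_site(500, c(0.5, 0.3, 0.2), site = "B")
  both <- genotype_dataset(c(big$site, bigb$site), c(big$id, bigb$id), "L1",
                           rbind(big$a1, bigb$a1), rbind(big$a2, bigb$a2))
  expect_lt(abs(gst_nei_chesser(both)$gst), 0.01)
  mono <- make_geno(list(A = list(L1 = cbind(rep(104L, 5), rep(104L, 5))),
                         B = list(L1 = cbind(rep(104L, 5), rep(104L, 5)))))
  expect_error(gst_nei_chesser(mono), "monomorphic")
})

test_that("Gst equals the textbook oracle on multi-pop multi-locus fixtures", {
  set.seed(10)
  for (rep in 1:5) {
    pops <- lapply(1:3, function(i) {
      p <- as.vector(stats::rgamma(3, 1)); p <- p / sum(p)
      list(L1 = matrix(sample(c(104L, 106L, 108L), 2 * (5 + i), TRUE, p),
                       ncol = 2),
           L2 = matrix(sample(c(120L, 122L), 2 * (5 + i), TRUE), ncol = 2))
    })
    names(pops) <- c("A", "B", "C")
    d <- make_geno(pops, loci = c("L1", "L2"))
    expect_equal(gst_nei_chesser(d)$gst, oracle_gst(d), tolerance = 1e-12)
  }
})

test_that("Hedrick G''st follows the closed form and its limits", {
  expect_equal(g_double_prime_st(0.8, 0.85, 2), 0.5555556, tolerance = 1e-6)
  expect_equal(g_double_prime_st(0, 0.5, 2), 1)
  expect_equal(g_double_prime_st(0.6, 0.6, 4), 0)
  expect_error(g_double_prime_st(1, 1, 2), "undefined")
})

test_that("pairwise G''st dominates pairwise Gst and the two correlate on IBD data", {
  set.seed(12)
  land <- generate_landscape(30, 30, list(), seed = 31)
  demes <- place_demes(8, 30, 30, seed = 32)
  cfg <- simulation_config(n_demes = 8, deme_size = 40, n_loci = 6,
                           generations = 80, sample_sizes = 15, seed = 33)
  sim <- simulate_genotypes(land, demes, cfg)
  pw <- pairwise_differentiation(sim$data)
  g <- lower_vec(pw$gst); h <- lower_vec(pw$gst_hedrick)
  # the dominance identity needs Ht >= Hs; negative pairwise estimates are
  # retained by design and scale the other way
  nonneg <- g >= 0
  expect_true(all(h[nonneg] >= g[nonneg] - 1e-12))
  expect_gt(cor(g, h), 0.9)
})

test_that("linearization is d/(1-d)", {
  expect_equal(linearize(0), 0)
  expect_equal(linearize(0.5), 1)
  expect_equal(linearize(0.024), 0.0245902, tolerance = 1e-5)
  m <- pairwise_matrix(matrix(c(0, .2, .2, 0), 2), c("a", "b"))
  expect_equal(linearize(m)["a", "b"], 0.25)
})

test_that("bottleneck test has directional power and Monte Carlo stability", {
  set.seed(14)
  # equilibrium-ish site: mutation-drift balance from the forward simulator
  land <- generate_landscape(10, 10, list(), seed = 41)
  cfg <- simulation_config(n_demes = 2, deme_size = 60, n_loci = 6,
                           generations = 300, mutation_rate = 5e-3,
                           sample_sizes = 25, migration_scale = 0, seed = 42)
  sim <- simulate_genotypes(land, data.frame(row = c(3, 8), col = c(3, 8)), cfg)
  eq <- bottleneck_tpm_test(sim$data, "D01", n_sims = 120, seed = 1)
  expect_true(eq$p > 0 && eq$p <= 1)
  expect_true(all(eq$per_locus$heq_sd > 0))
  # Monte Carlo stability: doubling n_sims moves per-locus means < 2 SE
  eq2 <- bottleneck_tpm_test(sim$data, "D01", n_sims = 240, seed = 2)
  se <- eq$per_locus$heq_sd / sqrt(eq$per_locus$n_retained)
  expect_true(all(abs(eq$per_locus$heq_mean - eq2$per_locus$heq_mean)
                  < 4 * se + 0.05))
  # monomorphic loci are skipped: dataset with < 4 polymorphic loci errors
  mono <- make_geno(list(S = list(L1 = cbind(rep(104L, 10), rep(104L, 10)),
                                  L2 = cbind(rep(104L, 10), rep(106L, 10)))))
  expect_error(bottleneck_tpm_test(mono, "S", n_sims = 10), ">= 4")
})

test_that("a simulated crash yields smaller bottleneck p than equilibrium", {
  set.seed(15)
  land <- generate_landscape(10, 10, list(), seed = 51)
  # pass the gene pool through a few generations of tiny-N drift: allele
  # count falls faster than heterozygosity, the excess signature
  crash_genes <- function(genes, n_crash = 10, gens = 3) {
    pool <- genes
    for (g in seq_len(gens)) pool <- sample(pool, n_crash, replace = TRUE)
    sample(pool, length(genes), replace = TRUE)
  }
  ps <- sapply(1:5, function(s) {
    cfg <- simulation_config(n_demes = 1, deme_size = 80, n_loci = 6,
                             generations = 400, mutation_rate = 5e-3,
                             sample_sizes = 30, seed = 50 + s)
    sim <- simulate_genotypes(land, data.frame(row = 5, col = 5), cfg)
    d <- sim$data
    p_eq <- bottleneck_tpm_test(d, "D01", n_sims = 60, seed = s)$p
    a1 <- d$a1; a2 <- d$a2
    n <- nrow(a1)
    for (j in seq_along(d$loci)) {
      g <- crash_genes(c(a1[, j], a2[, j]))
      a1[, j] <- g[seq_len(n)]; a2[, j] <- g[n + seq_len(n)]
    }
    crashed <- genotype_dataset(d$site, d$id, d$loci, a1, a2)
    p_cr <- tryCatch(bottleneck_tpm_test(crashed, "D01", n_sims = 60,
                                         seed = s)$p,
                     error = function(e) NA_real_)
    c(eq = p_eq, crash = p_cr)
  })
  ok <- !is.na(ps["crash", ])
  expect_gte(sum(ok), 3)
  expect_lt(median(ps["crash", ok]), median(ps["eq", ]))
})
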