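test_that("geodesic distances match an independent haversine oracle", {
  ss <- vernal_pool_sites("spotted_salamander")
  two <- ss[ss$site %in% c("ALF-1", "SHA-1"), ]
  D <- geo_distance_matrix(two)
  o <- oracle_haversine(two$lat[1], two$lon[1], two$lat[2], two$lon[2])
  expect_equal(D["ALF-1", "SHA-1"], o, tolerance = 1e-3)
  # identical coordinates give zero (flagged)
  dup <- data.frame(site = c("a", "b"), lat = c(44, 44), lon = c(-69, -69))
  expect_warning(D0 <- geo_distance_matrix(dup), "duplicate")
  expect_equal(D0["a", "b"], 0)
})

test_that("Mantel test: identity gives r = 1, p matches exhaustive enumeration", {
  set.seed(21)
  A <- rand_pairwise(6)
  expect_equal(mantel_test(A, A, n_perm = 99)$r, 1)
  # exact p over all 120 permutations of 5 sites
  A5 <- rand_pairwise(5); B5 <- rand_pairwise(5)
  ex <- oracle_mantel_exhaustive(unclass(A5), unclass(B5))
  mt <- mantel_test(A5, B5, n_perm = 20000, seed = 2)
  expect_equal(mt$r, ex$r, tolerance = 1e-12)
  expect_lt(abs(mt$p - ex$p), 0.02)
  # constant matrix is an error
  ids4 <- rownames(A5)[1:4]
  C <- pairwise_matrix(matrix(1, 4, 4) - diag(4), ids4)
  A4 <- pairwise_matrix(unclass(A5)[ids4, ids4], ids4)
  expect_error(mantel_test(C, A4), "constant")
  # seed determinism
  expect_identical(mantel_test(A5, B5, n_perm = 99, seed = 7)$p,
                   mantel_test(A5, B5, n_perm = 99, seed = 7)$p)
})

test_that("Mantel p is invariant to simultaneous relabeling of both matrices", {
  set.seed(22)
  A <- rand_pairwise(7); B <- rand_pairwise(7)
  perm <- sample(7)
  ids <- rownames(A)[perm]
  A2 <- pairwise_matrix(unclass(A)[perm, perm], ids)
  B2 <- pairwise_matrix(unclass(B)[perm, perm], ids)
  m1 <- mantel_test(A, B, n_perm = 499, seed = 3)
  m2 <- mantel_test(A2, B2, n_perm = 499, seed = 3)
  expect_equal(m1$r, m2$r, tolerance = 1e-12)
  expect_lt(abs(m1$p - m2$p), 0.05)
})

test_that("partial Mantel limits: self-conditioning gives 0, A = B gives 1", {
  set.seed(23)
  A <- rand_pairwise(10); B <- rand_pairwise(10); C <- rand_pairwise(10)
  expect_lt(abs(partial_mantel(A, B, B, n_perm = 49)$r), 1e-7)
  expect_equal(partial_mantel(A, A, C, n_perm = 49)$r, 1, tolerance = 1e-10)
  # with C uncorrelated, partial r is close to plain r at moderate n
  A50 <- rand_pairwise(50); B50 <- rand_pairwise(50)
  # make A and B correlated
  Bc <- pairwise_matrix(0.7 * unclass(A50) + 0.3 * unclass(B50),
                        rownames(A50))
  C50 <- rand_pairwise(50)
  r_plain <- mantel_test(A50, Bc, n_perm = 9)$r
  r_part <- partial_mantel(A50, Bc, C50, n_perm = 9)$r
  expect_lt(abs(r_plain - r_part), 0.05)
})

test_that("partial Mantel agrees with vegan on the statistic", {
  set.seed(24)
  A <- rand_pairwise(12); B <- rand_pairwise(12); C <- rand_pairwise(12)
  mine <- partial_mantel(A, B, C, n_perm = 9)$r
  veg <- vegan::mantel.partial(stats::as.dist(A), stats::as.dist(B),
                               stats::as.dist(C), permutations = 0)
  expect_equal(mine, unname(veg$statistic), tolerance = 1e-10)
  m2 <- mantel_test(A, B, n_perm = 9)$r
  v2 <- vegan::mantel(stats::as.dist(A), stats::as.dist(B), permutations = 0)
  expect_equal(m2, unname(v2$statistic), tolerance = 1e-10)
})

test_that("Mantel correlogram finds short-range structure in linear IBD data", {
  set.seed(25)
  n <- 25
  sites <- data.frame(site = sprintf("s%02d", 1:n),
                      lat = 44 + runif(n, 0, 1), lon = -69 + runif(n, 0, 1))
  D <- geo_distance_matrix(sites)
  G <- pairwise_matrix(unclass(D) * 1e-3 +
                         unfold_noise(n, 0.004, rownames(D)), rownames(D))
  cg <- mantel_correlogram(G, D, class_width_km = 30, n_perm = 199, seed = 1)
  expect_gt(cg$r[1], 0)          # nearest class: positive autocorrelation
  expect_true(cg$r[1] > cg$r[nrow(cg)])  # declining with distance
  expect_true(all(diff(cg$class_hi) > 0))
  # degenerate single class
  cg1 <- mantel_correlogram(G, D, class_width_km = 1e4, n_perm = 49, seed = 1)
  expect_equal(nrow(cg1), 1)
})

test_that("IBD regression recovers exact lines, nests, and matches normal equations", {
  set.seed(26)
  n <- 10
  ids <- sprintf("s%d", 1:n)
  D <- rand_pairwise(n, ids) * 100
  x <- lower_vec(D)
  # exact linear data
  G <- pairwise_matrix(unfold_to_sym(0.002 + 3e-4 * x, ids), ids)
  fit <- ibd_regression(G, D, form = "linear")
  expect_equal(unname(fit$coefficients), c(0.002, 3e-4), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_true(all(abs(lower_vec(fit$residual_matrix)) < 1e-12))
  # quadratic truth: quadratic fit beats linear
  Gq <- pairwise_matrix(unfold_to_sym(0.01 - 1e-4 * x + 5e-6 * x^2, ids), ids)
  fl <- ibd_regression(Gq, D, form = "linear")
  fq <- ibd_regression(Gq, D, form = "quadratic")
  expect_gt(fq$r_squared, fl$r_squared)
  expect_equal(fq$r_squared, 1, tolerance = 1e-10)
  # random fixture vs closed-form OLS
  y <- lower_vec(G) + rnorm(length(x), 0, 0.01)
  Gr <- pairwise_matrix(unfold_to_sym(y, ids), ids)
  fr <- ibd_regression(Gr, D, form = "linear")
  o <- oracle_ols(x, y)
  expect_equal(unname(fr$coefficients), unname(o), tolerance = 1e-10)
  # log-x drops zero distances with a warning
  D0 <- unclass(D); D0[1, 2] <- D0[2, 1] <- 0
  expect_warning(ibd_regression(Gr, pairwise_matrix(D0, ids), form = "log-x"),
                 "zero-distance")
})

test_that("quantile regression lines match the pair-enumeration oracle", {
  set.seed(27)
  for (tau in c(0.05, 0.5, 0.95)) {
    x <- runif(40, 0, 10)
    y <- 1 + 0.5 * x + rnorm(40)
    fit <- quantile_line_fit(x, y, tau)
    orc <- oracle_quantile_enum(x, y, tau)
    loss <- function(cf) { u <- y - cf[1] - cf[2] * x; sum(u * (tau - (u < 0))) }
    expect_equal(loss(fit), orc$loss, tolerance = 1e-9)
  }
})

test_that("scaling profile: exact slope on noiseless data, last window = global fit", {
  set.seed(28)
  n <- 12
  ids <- sprintf("s%d", 1:n)
  D <- rand_pairwise(n, ids) * 50
  x <- lower_vec(D)
  G <- pairwise_matrix(unfold_to_sym(0.01 + 2e-4 * x, ids), ids)
  prof <- ibd_scaling_profile(G, D, start_pairs = 10, n_boot = 30, seed = 1)
  expect_true(all(abs(prof$beta - 2e-4) < 1e-12))
  expect_true(all(prof$ci_hi - prof$ci_lo < 1e-12))
  expect_true(!is.unsorted(prof$max_distance_km))
  # last window equals the global regression slope exactly
  noisy <- pairwise_matrix(unfold_to_sym(0.01 + 2e-4 * x +
                                           rnorm(length(x), 0, 0.005), ids), ids)
  pr2 <- ibd_scaling_profile(noisy, D, start_pairs = 10, n_boot = 10, seed = 2)
  glob <- ibd_regression(noisy, D, form = "linear")
  expect_equal(pr2$beta[nrow(pr2)], unname(glob$coefficients[2]),
               tolerance = 1e-12)
  # n_boot = 1 runs and collapses the interval
  pr3 <- ibd_scaling_profile(G, D, start_pairs = 10, n_boot = 1, seed = 3)
  expect_true(all(pr3$ci_lo == pr3$ci_hi))
})

test_that("isolation index: zero under perfect IBD, perturbation ranks first, sums to zero", {
  set.seed(29)
  n <- 15
  ids <- sprintf("s%02d", 1:n)
  D <- rand_pairwise(n, ids) * 80
  x <- lower_vec(D)
  G <- pairwise_matrix(unfold_to_sym(0.01 + 2e-4 * x, ids), ids)
  fit <- ibd_regression(G, D, form = "linear")
  iso <- site_isolation_index(fit)
  expect_true(all(abs(iso$isolation) < 1e-12))
  expect_true(all(iso$n_pairs == n - 1))
  # inflate one site's differentiation to all partners by delta
  delta <- 0.05
  Gp <- unclass(G)
  Gp["s03", ] <- Gp["s03", ] + delta
  Gp[, "s03"] <- Gp[, "s03"] + delta
  diag(Gp) <- 0
  fit2 <- ibd_regression(pairwise_matrix(Gp, ids), D, form = "linear")
  iso2 <- site_isolation_index(fit2)
  expect_equal(iso2$site[which.max(iso2$isolation)], "s03")
  expect_equal(max(iso2$isolation), delta * (n - 2) / n, tolerance = 0.01)
  # indices sum to ~0 on a complete design
  expect_lt(abs(sum(iso2$isolation)), 1e-10 * n)
  # invariance to adding a constant to all distances
  D2 <- pairwise_matrix(unclass(D) + 30 - diag(30, n), ids)
  fit3 <- ibd_regression(pairwise_matrix(Gp, ids), D2, form = "linear")
  expect_equal(site_isolation_index(fit3)$isolation, iso2$isolation,
               tolerance = 1e-10)
})

test_that("transformed and untransformed IBD residuals correlate and are reported", {
  set.seed(30)
  n <- 20
  sites <- data.frame(site = sprintf("s%02d", 1:n),
                      lat = 44 + runif(n, 0, 1.5), lon = -69 + runif(n, 0, 1.5))
  D <- geo_distance_matrix(sites)
  x <- lower_vec(D)
  G <- pairwise_matrix(unfold_to_sym(0.01 + 5e-5 * x +
                                       rnorm(length(x), 0, 0.004),
                                     sites$site), sites$site)
  f_lin <- ibd_regression(G, D, form = "linear")
  f_log <- ibd_regression(G, D, form = "log-x")
  r <- cor(lower_vec(f_lin$residual_matrix), lower_vec(f_log$residual_matrix))
  expect_gt(r, 0.8)
})
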