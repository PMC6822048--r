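test_that("collinearity pruning keeps orthogonal columns and collapses groups", {
  set.seed(61)
  X <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  out <- collinearity_prune(X, threshold = 0.7, seed = 1)
  expect_setequal(out$retained, c("a", "b", "c"))
  # duplicated column: exactly one of the pair survives
  X2 <- data.frame(a = X$a, a_dup = X$a + rnorm(40, 0, 1e-6), b = X$b)
  out2 <- collinearity_prune(X2, threshold = 0.7, seed = 1)
  expect_equal(sum(c("a", "a_dup") %in% out2$retained), 1)
  expect_true("b" %in% out2$retained)
  expect_equal(nrow(out2$decision_log), 3)
})

test_that("covariates built on a common urbanization axis collapse to the roads", {
  # canopy, impervious and distance-to-road all proportional to light roads
  # plus noise; the three road classes stay mutually uncorrelated
  set.seed(62)
  n <- 60
  light <- runif(n, 0, 5000)
  secondary <- runif(n, 0, 3000)
  primary <- runif(n, 0, 2000)
  X <- data.frame(
    light_roads = light, secondary_roads = secondary, primary_roads = primary,
    pct_canopy = 100 - 0.015 * light + rnorm(n, 0, 5),
    pct_impervious = 0.012 * light + rnorm(n, 0, 4),
    dist_to_road = 3000 - 0.5 * light + rnorm(n, 0, 150))
  out <- collinearity_prune(X, threshold = 0.7, seed = 3)
  # light roads, canopy, impervious and distance collapse into one group;
  # one representative survives alongside the other two road classes
  expect_true(all(c("secondary_roads", "primary_roads") %in% out$retained))
  expect_equal(length(out$retained), 3)
  proxy_group <- c("light_roads", "pct_canopy", "pct_impervious", "dist_to_road")
  expect_equal(sum(proxy_group %in% out$retained), 1)
  # across seeds the light-roads representative is drawn 1/4 of the time
  reps <- sapply(1:20, function(sd)
    sum(c("light_roads") %in% collinearity_prune(X, 0.7, seed = sd)$retained))
  expect_gt(sum(reps), 0)
})

test_that("multiple regression matches closed-form OLS and flags rank deficiency", {
  set.seed(63)
  n <- 30
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- 1 + 2 * X$x1 - 0.5 * X$x2
  fit <- suppressWarnings(multiple_regression(y, X))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  yn <- y + rnorm(n, 0, 0.3)
  fit2 <- multiple_regression(yn, X)
  o <- oracle_ols(as.matrix(X), yn)
  expect_equal(fit2$coefficients$beta, unname(o), tolerance = 1e-10)
  Xbad <- data.frame(x1 = X$x1, x1b = X$x1)
  expect_error(multiple_regression(yn, Xbad), "aliased")
})

test_that("outlier rule flags only values above factor x second-largest", {
  cov <- data.frame(site = c("a", "b", "c"), v = c(10, 21, 5))
  expect_equal(outlier_rule_max_covariate(cov, "v", factor = 2), "b")
  cov2 <- data.frame(site = c("a", "b", "c"), v = c(10, 19, 5))
  expect_equal(outlier_rule_max_covariate(cov2, "v", factor = 2), character(0))
  cov3 <- data.frame(site = c("a", "b", "c"), v = c(7, 7, 7))
  expect_equal(outlier_rule_max_covariate(cov3, "v"), character(0))
})

test_that("MMRR recovers exact coefficients and is relabeling-invariant", {
  set.seed(64)
  n <- 12
  ids <- sprintf("s%d", 1:n)
  X1 <- rand_pairwise(n, ids)
  Y <- pairwise_matrix(0.3 + 2 * unclass(X1) - diag(0.3, n), ids)
  out <- mmrr(Y, list(x1 = X1), n_perm = 49, seed = 1)
  expect_equal(out$coefficients$beta, c(0.3, 2), tolerance = 1e-10)
  expect_equal(out$r_squared, 1, tolerance = 1e-10)
  # consistent relabeling leaves coefficients unchanged
  perm <- sample(n)
  Y2 <- pairwise_matrix(unclass(Y)[perm, perm], ids[perm])
  X2 <- pairwise_matrix(unclass(X1)[perm, perm], ids[perm])
  out2 <- mmrr(Y2, list(x1 = X2), n_perm = 49, seed = 1)
  expect_equal(out2$coefficients$beta, out$coefficients$beta, tolerance = 1e-10)
  # collinear predictors error, naming the pair
  expect_error(mmrr(Y, list(x1 = X1, x1b = X1), n_perm = 9), "collinear")
})

test_that("MMRR with the distance matrix alone equals the simple Mantel regression", {
  set.seed(65)
  n <- 14
  ids <- sprintf("s%d", 1:n)
  D <- rand_pairwise(n, ids) * 50
  y <- 0.01 + 2e-4 * lower_vec(D) + rnorm(n * (n - 1) / 2, 0, 0.003)
  G <- pairwise_matrix(unfold_to_sym(y, ids), ids)
  out <- mmrr(G, list(distance = D), n_perm = 49, seed = 1)
  o <- oracle_ols(lower_vec(D), lower_vec(G))
  expect_equal(out$coefficients$beta, unname(o), tolerance = 1e-10)
})

test_that("dbRDA partials out the condition and retains a genuine predictor", {
  set.seed(66)
  n <- 40
  ids <- sprintf("s%02d", 1:n)
  lat <- 44 + runif(n); lon <- -69 + runif(n)
  urb <- runif(n, 0, 10)
  # genetic distance driven by the urbanization covariate difference
  gd <- abs(outer(urb, urb, "-")) + unfold_noise(n, 0.3, ids)
  gd[gd < 0] <- 0; diag(gd) <- 0
  G <- pairwise_matrix(gd, ids)
  X <- data.frame(urb = urb, junk = rnorm(n))
  rownames(X) <- ids
  cond <- data.frame(lat = lat, lon = lon); rownames(cond) <- ids
  out <- dbrda(G, X, cond, n_perm = 199, alpha = 0.05, seed = 2)
  expect_true("urb" %in% out$retained$term)
  expect_false("junk" %in% out$retained$term)
  expect_true(all(out$retained$p < 0.05))
  expect_true(out$varpart$combined >= out$varpart$condition - 0.05)
})

test_that("dbRDA term duplicating the condition explains ~nothing after partialling", {
  set.seed(67)
  n <- 30
  ids <- sprintf("s%02d", 1:n)
  lat <- 44 + runif(n); lon <- -69 + runif(n)
  gd <- abs(outer(lat, lat, "-")) * 10 + unfold_noise(n, 0.5, ids)
  gd[gd < 0] <- 0; diag(gd) <- 0
  G <- pairwise_matrix(gd, ids)
  X <- data.frame(lat_copy = lat + rnorm(n, 0, 1e-8))
  rownames(X) <- ids
  cond <- data.frame(lat = lat, lon = lon); rownames(cond) <- ids
  out <- dbrda(G, X, cond, n_perm = 99, alpha = 0.05, seed = 3)
  # the duplicated term adds nothing beyond the condition
  expl <- out$varpart$explanatory
  expect_true(is.na(expl) || expl < 0.01)
})
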