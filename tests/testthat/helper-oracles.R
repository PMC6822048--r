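# Independent oracles and fixture builders. Each oracle is written from the
# textbook definition, not by calling package internals, so agreement is a
# real cross-check.

# quick genotype_dataset builder: geno is a list site -> list locus -> 2-col
# matrix of allele sizes (one row per individual)
make_geno <- function(geno, loci = NULL) {
  sites <- names(geno)
  loci <- loci %||% names(geno[[1]])
  site_v <- character(0); a1 <- NULL; a2 <- NULL; ids <- character(0)
  for (s in sites) {
    n <- nrow(geno[[s]][[1]])
    site_v <- c(site_v, rep(s, n))
    ids <- c(ids, paste0(s, "_", seq_len(n)))
    m1 <- sapply(loci, function(l) geno[[s]][[l]][, 1])
    m2 <- sapply(loci, function(l) geno[[s]][[l]][, 2])
    if (n == 1) { m1 <- matrix(m1, 1); m2 <- matrix(m2, 1) }
    a1 <- rbind(a1, m1); a2 <- rbind(a2, m2)
  }
  genotype_dataset(site_v, ids, loci, a1, a2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random genotypes under HWE at one site
sim_hwe_site <- function(n, p, site = "S", loci = "L1") {
  alle <- as.integer(100 + 2 * seq_along(p))
  draw <- function() matrix(sample(alle, 2 * n, replace = TRUE, prob = p),
                            n, 2)
  g <- stats::setNames(lapply(loci, function(l) draw()), loci)
  make_geno(stats::setNames(list(g), site), loci)
}

# textbook Nei & Chesser (1983) Gst, computed per locus with explicit sums
oracle_gst <- function(data) {
  sites <- unique(data$site)
  hs_all <- ht_all <- numeric(0)
  for (j in seq_along(data$loci)) {
    ps <- list(); ns <- c(); hos <- c()
    for (s in sites) {
      rows <- data$site == s
      x1 <- data$a1[rows, j]; x2 <- data$a2[rows, j]
      ok <- !is.na(x1)
      if (sum(ok) < 2) next
      genes <- c(x1[ok], x2[ok])
      ps[[length(ps) + 1]] <- table(genes) / length(genes)
      ns <- c(ns, sum(ok))
      hos <- c(hos, mean(x1[ok] != x2[ok]))
    }
    k <- length(ns)
    if (k < 2) next
    alleles <- unique(unlist(lapply(ps, names)))
    pm <- sapply(ps, function(p) {
      v <- stats::setNames(numeric(length(alleles)), alleles)
      v[names(p)] <- p; v
    })
    if (is.null(dim(pm))) pm <- matrix(pm, nrow = 1)
    nh <- 1 / mean(1 / ns)
    hobar <- mean(hos)
    hs_raw <- mean(apply(pm, 2, function(p) 1 - sum(p^2)))
    hs <- nh / (nh - 1) * (hs_raw - hobar / (2 * nh))
    pbar <- rowMeans(pm)
    ht <- 1 - sum(pbar^2) + hs / (k * nh) - hobar / (2 * k * nh)
    hs_all <- c(hs_all, hs); ht_all <- c(ht_all, ht)
  }
  (mean(ht_all) - mean(hs_all)) / mean(ht_all)
}

# spherical law-of-haversines distance, km, radius 6378137 m
oracle_haversine <- function(lat1, lon1, lat2, lon2) {
  p <- pi / 180
  a <- sin((lat2 - lat1) * p / 2)^2 +
    cos(lat1 * p) * cos(lat2 * p) * sin((lon2 - lon1) * p / 2)^2
  2 * 6378137 * asin(sqrt(a)) / 1000
}

# effective resistance from a weighted adjacency matrix via the Moore-
# Penrose pseudoinverse of the Laplacian
oracle_resistance <- function(W, i, j) {
  L <- diag(rowSums(W)) - W
  e <- eigen(L, symmetric = TRUE)
  keep <- e$values > 1e-10
  Lp <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / e$values[keep], sum(keep)) %*% t(e$vectors[, keep, drop = FALSE])
  Lp[i, i] + Lp[j, j] - 2 * Lp[i, j]
}

# normal-equation OLS coefficients
oracle_ols <- function(X, y) {
  X <- cbind(1, X)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# exact quantile regression line by pair enumeration (optimum interpolates
# two points); for small n only
oracle_quantile_enum <- function(x, y, tau) {
  n <- length(x)
  loss <- function(a, b) { u <- y - a - b * x; sum(u * (tau - (u < 0))) }
  best <- NULL; best_loss <- Inf
  for (i in 1:(n - 1)) for (k in (i + 1):n) {
    if (x[i] == x[k]) next
    b <- (y[k] - y[i]) / (x[k] - x[i]); a <- y[i] - b * x[i]
    l <- loss(a, b)
    if (l < best_loss) { best <- c(a, b); best_loss <- l }
  }
  list(coef = best, loss = best_loss)
}

# exhaustive Mantel p over all permutations of n sites (n <= 6)
oracle_mantel_exhaustive <- function(A, B) {
  n <- nrow(A)
  perms <- permutations_all(n)
  lt <- lower.tri(A)
  r_obs <- cor(A[lt], B[lt])
  rs <- apply(perms, 1, function(p) cor(A[p, p][lt], B[lt]))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# small random symmetric matrix with zero diagonal
rand_pairwise <- function(n, ids = sprintf("s%d", seq_len(n))) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  pairwise_matrix(m + t(m), ids, "random")
}

# fold a lower-triangle vector into a symmetric matrix with site ids
unfold_to_sym <- function(v, ids) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- v
  m + t(m)
}

# symmetric zero-diagonal noise matrix
unfold_noise <- function(n, sd, ids) {
  unfold_to_sym(rnorm(n * (n - 1) / 2, 0, sd), ids)
}
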