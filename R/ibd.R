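#' Great-circle distance matrix between sites
#'
#' Haversine distances (sphere radius 6,378,137 m, the `geosphere::distm`
#' default) between all site pairs, in kilometres. Duplicate coordinates are
#' allowed (distance 0) and flagged with a warning.
#'
#' @param sites data.frame with columns site, lat, lon (WGS84 decimal
#'   degrees).
#' @return a [pairwise_matrix()] of kind "geographic_km".
#' @export
geo_distance_matrix <- function(sites) {
  validate_site_table(sites)
  m <- geosphere::distm(cbind(sites$lon, sites$lat),
                        fun = geosphere::distHaversine) / 1000
  dm <- pairwise_matrix(m, sites$site, "geographic_km")
  if (any(lower_vec(dm) == 0))
    warning("duplicate coordinates: some pairwise distances are exactly 0")
  dm
}

#' Mantel test of matrix association
#'
#' r is the Pearson correlation of the lower-triangle vectors; the null
#' distribution permutes the row/column order of the first matrix. The
#' p-value is one-tailed (r >= observed) with the add-one rule, the
#' convention of the ecology packages this analysis follows.
#'
#' @param A,B pairwise matrices over the same site set.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list: r, p, n_perm, n_sites, partial = FALSE.
#' @export
mantel_test <- function(A, B, n_perm = 9999, seed = 1) {
  al <- align_pairwise(A, B)
  A <- al[[1]]; B <- al[[2]]
  n <- nrow(A)
  idx <- lower_idx(n)
  av <- A[idx]; bv <- B[idx]
  cc <- stats::complete.cases(av, bv)
  if (stats::sd(av[cc]) == 0 || stats::sd(bv[cc]) == 0)
    stop("Mantel r undefined: constant matrix")
  r_obs <- stats::cor(av[cc], bv[cc])
  hits <- with_seed(seed, {
    h <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      ap <- A[cbind(p[idx[, 1]], p[idx[, 2]])]
      rp <- stats::cor(ap, bv, use = "complete.obs")
      if (rp >= r_obs - 1e-12) h <- h + 1L
    }
    h
  })
  list(r = r_obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm,
       n_sites = n, partial = FALSE)
}

# first-order partial correlation
partial_r <- function(rab, rac, rbc) {
  (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
}

#' Partial Mantel test
#'
#' Correlation between A and B controlling for C, using the first-order
#' partial correlation of lower-triangle vectors. The null permutes the
#' row/column order of A and recomputes the full partial statistic.
#' One-tailed (greater), add-one p.
#'
#' @param A,B,C pairwise matrices over the same site set; C is the
#'   conditioning matrix.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list: r, r_squared, p, n_perm, n_sites, partial = TRUE.
#' @export
partial_mantel <- function(A, B, C, n_perm = 10000, seed = 1) {
  al <- align_pairwise(A, B, C)
  A <- al[[1]]; B <- al[[2]]; C <- al[[3]]
  n <- nrow(A)
  idx <- lower_idx(n)
  av <- A[idx]; bv <- B[idx]; cv <- C[idx]
  pr <- function(a) {
    cc <- stats::complete.cases(a, bv, cv)
    partial_r(stats::cor(a[cc], bv[cc]), stats::cor(a[cc], cv[cc]),
              stats::cor(bv[cc], cv[cc]))
  }
  cc0 <- stats::complete.cases(av, bv, cv)
  if (stats::sd(av[cc0]) == 0 || stats::sd(bv[cc0]) == 0 ||
      stats::sd(cv[cc0]) == 0)
    stop("partial Mantel undefined: constant matrix")
  r_obs <- pr(av)
  hits <- with_seed(seed, {
    h <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      rp <- pr(A[cbind(p[idx[, 1]], p[idx[, 2]])])
      if (rp >= r_obs - 1e-12) h <- h + 1L
    }
    h
  })
  list(r = r_obs, r_squared = r_obs^2, p = (hits + 1) / (n_perm + 1),
       n_perm = n_perm, n_sites = n, partial = TRUE)
}

#' Mantel correlogram over 20-km distance classes
#'
#' Places distance-class breakpoints every `class_width_km` and, per class,
#' runs a Mantel test of the genetic matrix against the class-membership
#' contrast matrix coded so that a positive r means pairs within the class
#' are more genetically similar than pairs outside it (membership is coded
#' 0 inside / 1 outside the class). Classes are retained only while every
#' site appears in at least one pair at a distance within the class upper
#' bound, which avoids bias from under-represented margins. Benjamini-
#' Hochberg FDR is applied across the retained classes.
#'
#' @param G genetic pairwise matrix (e.g. linearized G_ST).
#' @param D geographic pairwise matrix, km.
#' @param class_width_km class width.
#' @param n_perm permutations per class.
#' @param seed RNG seed.
#' @param alpha FDR level for significance flags.
#' @return data.frame: class_lo, class_hi, midpoint, n_pairs, r, p,
#'   p_adjusted, significant, low_power flag.
#' @export
mantel_correlogram <- function(G, D, class_width_km = 20, n_perm = 10000,
                               seed = 1, alpha = 0.05) {
  al <- align_pairwise(G, D)
  G <- al[[1]]; D <- al[[2]]
  n <- nrow(G)
  breaks <- seq(0, max(D) + class_width_km, by = class_width_km)
  rows <- list()
  for (ci in seq_len(length(breaks) - 1)) {
    lo <- breaks[ci]; hi <- breaks[ci + 1]
    inside <- D > lo & D <= hi
    if (ci == 1) inside <- inside | (D >= 0 & D <= hi & row(D) != col(D))
    # retain only while every site has a pair at distance <= class upper bound
    reach <- D; diag(reach) <- Inf
    if (!all(apply(reach <= hi, 1, any))) break
    n_pairs <- sum(inside[lower.tri(inside)])
    if (n_pairs == 0) break
    contrast <- matrix(1, n, n, dimnames = dimnames(G))
    contrast[inside] <- 0
    diag(contrast) <- 0
    fit <- tryCatch(
      mantel_test(G, pairwise_matrix(contrast, rownames(G), "class"),
                  n_perm = n_perm, seed = seed + ci),
      error = function(e) list(r = NA_real_, p = NA_real_))
    rows[[length(rows) + 1]] <- data.frame(
      class_lo = lo, class_hi = hi, midpoint = (lo + hi) / 2,
      n_pairs = n_pairs, r = fit$r, p = fit$p,
      low_power = n_pairs < 10)
  }
  if (!length(rows)) stop("no usable distance class")
  out <- do.call(rbind, rows)
  adj <- fdr_adjust(out$p, alpha = alpha)
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$significant
  out
}
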