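#' Monte Carlo exact test of Hardy-Weinberg proportions
#'
#' Guo-Thompson style test for one locus at one site. The statistic is the
#' conditional probability of the observed genotype table given the allele
#' counts; the null distribution is generated by shuffling the pool of gene
#' copies and re-pairing them into genotypes. The p-value is the add-one
#' fraction of shuffled tables with conditional probability less than or
#' equal to the observed one.
#'
#' @param data a [genotype_dataset()].
#' @param locus locus name.
#' @param site site id.
#' @param n_mc number of Monte Carlo shuffles.
#' @param seed RNG seed.
#' @return list: p, n (individuals used), k (alleles), statistic (log
#'   conditional probability), monomorphic flag.
#' @export
hwe_exact_test <- function(data, locus, site, n_mc = 10000, seed = 1) {
  j <- match(locus, data$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  rows <- data$site == site
  x1 <- data$a1[rows, j]; x2 <- data$a2[rows, j]
  ok <- !is.na(x1)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 5) stop("fewer than 5 individuals called at ", locus, " in ", site)
  genes <- c(x1, x2)
  if (length(unique(genes)) < 2)
    return(list(p = 1, n = n, k = 1L, statistic = 0, monomorphic = TRUE))
  obs <- hwe_log_cond_prob(x1, x2)
  hits <- with_seed(seed, {
    h <- 0L
    for (b in seq_len(n_mc)) {
      g <- sample(genes)
      s1 <- g[seq_len(n)]; s2 <- g[n + seq_len(n)]
      if (hwe_log_cond_prob(s1, s2) <= obs + 1e-12) h <- h + 1L
    }
    h
  })
  list(p = (hits + 1) / (n_mc + 1), n = n, k = length(unique(genes)),
       statistic = obs, monomorphic = FALSE)
}

# log conditional probability of a genotype table given allele counts:
# log[ n! 2^h / prod(n_g!) * prod(n_a!) / (2n)! ]
hwe_log_cond_prob <- function(x1, x2) {
  n <- length(x1)
  het <- sum(x1 != x2)
  geno <- paste(pmin(x1, x2), pmax(x1, x2))
  ng <- table(geno)
  na <- table(c(x1, x2))
  lgamma(n + 1) + het * log(2) - sum(lgamma(ng + 1)) +
    sum(lgamma(na + 1)) - lgamma(2 * n + 1)
}

#' Permutation exact test of linkage disequilibrium (genotypic association)
#'
#' Tests independent assortment of genotypes at two loci within one site.
#' The statistic is the G statistic of the two-locus genotype contingency
#' table; the null is generated by permuting one locus's genotypes among
#' individuals. Genotypic (not gametic) association is used because phase is
#' unknown. Add-one p-value; either locus monomorphic gives p = 1.
#'
#' @param data a [genotype_dataset()].
#' @param locus_pair character vector of two locus names.
#' @param site site id.
#' @param n_mc permutations.
#' @param seed RNG seed.
#' @return list: p, n, statistic (G), monomorphic flag.
#' @export
ld_exact_test <- function(data, locus_pair, site, n_mc = 10000, seed = 1) {
  if (length(locus_pair) != 2) stop("locus_pair must name two loci")
  j1 <- match(locus_pair[1], data$loci); j2 <- match(locus_pair[2], data$loci)
  if (anyNA(c(j1, j2))) stop("unknown locus in pair")
  rows <- data$site == site
  ok <- !is.na(data$a1[rows, j1]) & !is.na(data$a1[rows, j2])
  g1 <- paste(data$a1[rows, j1][ok], data$a2[rows, j1][ok])
  g2 <- paste(data$a1[rows, j2][ok], data$a2[rows, j2][ok])
  n <- length(g1)
  if (n < 5) stop("fewer than 5 individuals called at both loci in ", site)
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2)
    return(list(p = 1, n = n, statistic = 0, monomorphic = TRUE))
  f1 <- factor(g1); f2 <- factor(g2)
  obs <- g_statistic(table(f1, f2))
  hits <- with_seed(seed, {
    h <- 0L
    for (b in seq_len(n_mc)) {
      if (g_statistic(table(f1, sample(f2))) >= obs - 1e-12) h <- h + 1L
    }
    h
  })
  list(p = (hits + 1) / (n_mc + 1), n = n, statistic = obs, monomorphic = FALSE)
}

# G (log-likelihood ratio) statistic of a contingency table
g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / N
  nz <- tab > 0
  2 * sum(tab[nz] * log(tab[nz] / E[nz]))
}

#' Pairwise exact G test of genic differentiation
#'
#' For a pair of sites, computes the per-locus G statistic on the 2 x alleles
#' (genic) contingency table, obtains per-locus add-one permutation p-values
#' by permuting individuals between the two sites, and combines loci by
#' Fisher's method. Loci with no shared polymorphism contribute nothing.
#'
#' @param data a [genotype_dataset()].
#' @param pair character vector of two site ids.
#' @param n_mc permutations.
#' @param seed RNG seed.
#' @return list: p (combined), per_locus (data.frame locus, G, p), n_loci_used.
#' @export
exact_g_test_pairwise <- function(data, pair, n_mc = 10000, seed = 1) {
  if (length(pair) != 2) stop("pair must name two sites")
  sub <- subset_sites(data, pair)
  grp <- factor(sub$site, levels = pair)
  per <- list()
  with_seed(seed, {
    for (j in seq_along(sub$loci)) {
      x1 <- sub$a1[, j]; x2 <- sub$a2[, j]
      ok <- !is.na(x1)
      if (sum(ok & grp == pair[1]) < 1 || sum(ok & grp == pair[2]) < 1) next
      genes <- c(x1[ok], x2[ok])
      if (length(unique(genes)) < 2) next  # monomorphic: no information
      g <- factor(grp[ok])
      if (nlevels(g) < 2) next
      alle <- factor(genes)
      gg <- rep(g, 2)
      obs <- g_statistic(table(gg, alle))
      h <- 0L
      ni <- length(g)
      for (b in seq_len(n_mc)) {
        gp <- rep(sample(g), 2)
        if (g_statistic(table(gp, alle)) >= obs - 1e-12) h <- h + 1L
      }
      per[[length(per) + 1]] <- data.frame(locus = sub$loci[j], G = obs,
                                           p = (h + 1) / (n_mc + 1))
    }
  })
  if (!length(per)) return(list(p = 1, per_locus = NULL, n_loci_used = 0L))
  per <- do.call(rbind, per)
  X <- -2 * sum(log(per$p))
  list(p = stats::pchisq(X, df = 2 * nrow(per), lower.tail = FALSE),
       per_locus = per, n_loci_used = nrow(per))
}
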