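#' Heterozygosity-excess bottleneck test under the two-phase mutation model
#'
#' For each polymorphic locus at a site, simulates coalescent samples of the
#' same gene count under the two-phase microsatellite mutation model (TPM:
#' single-step mutations with probability `p_single_step`, multi-step sizes
#' geometric, total step variance `variance`). The scaled mutation rate
#' theta is tuned by bisection so the expected allele count matches the
#' observed count k, then replicates are retained only when they carry
#' exactly k alleles, giving the equilibrium heterozygosity distribution
#' conditional on k. A locus at mutation-drift equilibrium has observed H_E
#' near the simulated mean; a recent bottleneck inflates H_E relative to the
#' allele count. Site-level significance is a one-tail Wilcoxon signed-rank
#' test across loci for heterozygosity excess.
#'
#' @param data a [genotype_dataset()].
#' @param site site id.
#' @param variance total TPM step variance.
#' @param p_single_step probability of a single-step mutation.
#' @param n_sims retained equilibrium replicates per locus.
#' @param seed RNG seed.
#' @param max_attempts_factor cap on total simulations per locus, as a
#'   multiple of `n_sims`; running out is reported as a failure for the
#'   locus.
#' @return list of class `bottleneck_result`: per_locus (locus, n_genes, k,
#'   he_obs, heq_mean, heq_sd, std_diff, n_retained, failed), p
#'   (one-tail Wilcoxon signed-rank p for heterozygosity excess), n_loci.
#' @export
bottleneck_tpm_test <- function(data, site, variance = 12,
                                p_single_step = 0.95, n_sims = 1000, seed = 1,
                                max_attempts_factor = 60) {
  rows <- which(data$site == site)
  if (!length(rows)) stop("unknown site: ", site)
  q <- tpm_geom_q(p_single_step, variance)
  per <- list()
  with_seed(seed, {
    for (j in seq_along(data$loci)) {
      x1 <- data$a1[rows, j]; x2 <- data$a2[rows, j]
      ok <- !is.na(x1)
      genes <- c(x1[ok], x2[ok])
      n <- length(genes)
      if (n < 4) next
      k <- length(unique(genes))
      if (k < 2) next  # monomorphic: skipped
      he_obs <- unbiased_he(genes)
      theta <- tune_theta(n, k, p_single_step, q)
      heq <- numeric(0)
      attempts <- 0L
      while (length(heq) < n_sims && attempts < max_attempts_factor * n_sims) {
        attempts <- attempts + 1L
        sim <- coalescent_tpm_sample(n, theta, p_single_step, q)
        if (length(unique(sim)) == k) heq <- c(heq, unbiased_he(sim))
      }
      failed <- length(heq) < n_sims
      hm <- mean(heq); hs <- stats::sd(heq)
      per[[length(per) + 1]] <- data.frame(
        locus = data$loci[j], n_genes = n, k = k, he_obs = he_obs,
        heq_mean = hm, heq_sd = hs,
        std_diff = if (is.finite(hs) && hs > 0) (he_obs - hm) / hs else NA_real_,
        n_retained = length(heq), failed = failed)
    }
  })
  if (length(per) < 4)
    stop("bottleneck test needs >= 4 polymorphic loci at ", site)
  per <- do.call(rbind, per)
  d <- per$he_obs - per$heq_mean
  p <- stats::wilcox.test(d, alternative = "greater", exact = FALSE,
                          correct = TRUE)$p.value
  structure(list(per_locus = per, p = p, n_loci = nrow(per)),
            class = "bottleneck_result")
}

# bisection on log(theta) so simulated E[allele count] matches k_obs;
# each evaluation reuses a common random seed stream for monotone behaviour
tune_theta <- function(n, k_obs, p_single, q, n_eval = 120, tol = 0.05,
                       max_iter = 25) {
  expected_k <- function(theta) {
    mean(vapply(seq_len(n_eval), function(b) {
      length(unique(coalescent_tpm_sample(n, theta, p_single, q)))
    }, numeric(1)))
  }
  lo <- 1e-3; hi <- 200
  if (expected_k(lo) > k_obs) return(lo)
  if (expected_k(hi) < k_obs) return(hi)
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    ek <- expected_k(mid)
    if (abs(ek - k_obs) < tol) return(mid)
    if (ek < k_obs) lo <- mid else hi <- mid
    if (hi / lo < 1.02) break
  }
  sqrt(lo * hi)
}

# one coalescent sample of n genes under TPM: random binary coalescent tree,
# Poisson(theta/2 * branch length) mutations per branch, allele state = sum
# of signed TPM steps from the root
coalescent_tpm_sample <- function(n, theta, p_single, q) {
  members <- lapply(seq_len(n), identity)  # leaves under each active lineage
  leaves <- rep(0L, n)                     # accumulated steps per leaf
  active <- seq_len(n)
  nl <- n
  while (nl > 1) {
    t_len <- stats::rexp(1, rate = nl * (nl - 1) / 2)
    # mutations on each active branch during this interval
    n_mut <- stats::rpois(nl, theta / 2 * t_len)
    for (ii in which(n_mut > 0)) {
      steps <- sum(tpm_steps(n_mut[ii], p_single, q))
      leaves[members[[active[ii]]]] <- leaves[members[[active[ii]]]] + steps
    }
    pick <- sample.int(nl, 2)
    a <- active[pick[1]]; b <- active[pick[2]]
    members[[a]] <- c(members[[a]], members[[b]])
    active <- active[-pick[2]]
    nl <- nl - 1L
  }
  leaves
}
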