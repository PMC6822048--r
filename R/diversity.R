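#' Per-site genetic diversity
#'
#' For each site computes the mean number of alleles per locus (A_O),
#' rarefied allelic richness at `rarefaction_genes` gene copies (AR),
#' unbiased expected heterozygosity (H_E), observed heterozygosity (H_O),
#' and F_IS = 1 - mean(H_O)/mean(H_E) (Nei's across-loci form).
#'
#' Rarefaction per locus: AR = sum over alleles a of
#' `1 - choose(N - N_a, g) / choose(N, g)` with N gene copies typed and N_a
#' copies of allele a, averaged over loci. A locus entirely missing at a
#' site is excluded from that site's averages and flagged.
#'
#' @param data a [genotype_dataset()].
#' @param rarefaction_genes number of gene copies `g` for rarefaction; must
#'   not exceed the gene count at any used locus-site combination.
#' @param he_unbiased use Nei's unbiased H_E (default) or raw gene diversity.
#' @return data.frame: site, n, ao, ar, he, ho, fis, loci_used,
#'   loci_excluded.
#' @export
site_diversity <- function(data, rarefaction_genes, he_unbiased = TRUE) {
  g <- rarefaction_genes
  sites <- dataset_sites(data)
  out <- lapply(sites, function(s) {
    rows <- which(data$site == s)
    ao <- ar <- he <- ho <- rep(NA_real_, length(data$loci))
    excluded <- character(0)
    for (j in seq_along(data$loci)) {
      x1 <- data$a1[rows, j]; x2 <- data$a2[rows, j]
      ok <- !is.na(x1)
      if (!sum(ok)) { excluded <- c(excluded, data$loci[j]); next }
      x1 <- x1[ok]; x2 <- x2[ok]
      genes <- c(x1, x2)
      N <- length(genes)
      if (g > N)
        stop("rarefaction_genes = ", g, " exceeds ", N, " genes at locus ",
             data$loci[j], " site ", s)
      cnt <- table(genes)
      ao[j] <- length(cnt)
      ar[j] <- sum(1 - exp(lchoose(N - cnt, g) - lchoose(N, g)))
      p <- cnt / N
      he[j] <- if (he_unbiased) (N / (N - 1)) * (1 - sum(p^2)) else 1 - sum(p^2)
      ho[j] <- mean(x1 != x2)
    }
    mhe <- mean(he, na.rm = TRUE); mho <- mean(ho, na.rm = TRUE)
    data.frame(site = s, n = length(rows),
               ao = mean(ao, na.rm = TRUE), ar = mean(ar, na.rm = TRUE),
               he = mhe, ho = mho,
               fis = if (is.finite(mhe) && mhe > 0) 1 - mho / mhe else NA_real_,
               loci_used = sum(!is.na(ao)),
               loci_excluded = paste(excluded, collapse = ","))
  })
  do.call(rbind, out)
}

#' Nei-Chesser G_ST across sites
#'
#' Sample-size-corrected gene diversity components per locus with k
#' populations and per-locus harmonic mean sample size n~ (individuals typed):
#' \deqn{\hat H_S = \frac{\tilde n}{\tilde n - 1}\left(H_{S,raw} - \frac{\hat H_O}{2\tilde n}\right)}
#' \deqn{\hat H_T = H_{T,raw} + \frac{\hat H_S}{k \tilde n} - \frac{\hat H_O}{2 k \tilde n}}
#' with `H_S_raw` the mean within-population gene diversity and `H_T_raw`
#' computed from allele frequencies averaged (unweighted) across
#' populations. The multilocus estimate averages Hs-hat and Ht-hat across
#' loci before forming the ratio: G_ST = (mean Ht - mean Hs) / mean Ht.
#'
#' @param data a [genotype_dataset()].
#' @param site_subset optional character vector of sites to use (>= 2).
#' @return list: gst, per_locus (data.frame locus, hs, ht, ho, n_harmonic,
#'   k), mean_hs, mean_ht.
#' @export
gst_nei_chesser <- function(data, site_subset = NULL) {
  if (!is.null(site_subset)) data <- subset_sites(data, site_subset)
  sites <- dataset_sites(data)
  if (length(sites) < 2) stop("G_ST needs at least two sites")
  per <- lapply(seq_along(data$loci), function(j) {
    hs_raw <- ho <- ns <- numeric(0)
    freqs <- list()
    for (s in sites) {
      rows <- data$site == s
      x1 <- data$a1[rows, j]; x2 <- data$a2[rows, j]
      ok <- !is.na(x1)
      if (sum(ok) < 2) next
      x1 <- x1[ok]; x2 <- x2[ok]
      genes <- c(x1, x2)
      tabs <- table(genes)
      p <- tabs / length(genes)
      freqs[[length(freqs) + 1]] <- p
      hs_raw <- c(hs_raw, 1 - sum(p^2))
      ho <- c(ho, mean(x1 != x2))
      ns <- c(ns, sum(ok))
    }
    k <- length(ns)
    if (k < 2) return(NULL)
    alleles <- unique(unlist(lapply(freqs, names)))
    pmat <- vapply(freqs, function(p) {
      v <- stats::setNames(rep(0, length(alleles)), alleles)
      v[names(p)] <- p
      v
    }, numeric(length(alleles)))
    if (is.null(dim(pmat))) pmat <- matrix(pmat, nrow = 1)
    pbar <- rowMeans(pmat)
    nh <- k / sum(1 / ns)
    ho_bar <- mean(ho)
    hs_hat <- (nh / (nh - 1)) * (mean(hs_raw) - ho_bar / (2 * nh))
    ht_raw <- 1 - sum(pbar^2)
    ht_hat <- ht_raw + hs_hat / (k * nh) - ho_bar / (2 * k * nh)
    data.frame(locus = data$loci[j], hs = hs_hat, ht = ht_hat, ho = ho_bar,
               n_harmonic = nh, k = k)
  })
  per <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  if (is.null(per) || !nrow(per)) stop("no locus usable for G_ST")
  mean_ht <- mean(per$ht)
  if (!is.finite(mean_ht) || abs(mean_ht) < 1e-15)
    stop("G_ST undefined: all loci monomorphic overall")
  list(gst = (mean_ht - mean(per$hs)) / mean_ht,
       per_locus = per, mean_hs = mean(per$hs), mean_ht = mean_ht)
}

#' Hedrick's standardized G''_ST
#'
#' \deqn{G''_{ST} = \frac{k (\hat H_T - \hat H_S)}{(k \hat H_T - \hat H_S)(1 - \hat H_S)}}
#' The pairwise version uses k = 2.
#'
#' @param hs within-population gene diversity (multilocus mean Hs-hat).
#' @param ht total gene diversity (multilocus mean Ht-hat).
#' @param k number of populations.
#' @return numeric value.
#' @export
g_double_prime_st <- function(hs, ht, k) {
  if (hs >= 1) stop("G''_ST undefined when Hs = 1")
  denom <- (k * ht - hs) * (1 - hs)
  if (abs(denom) < 1e-15) {
    if (abs(ht - hs) < 1e-15) return(0)
    stop("G''_ST undefined: zero denominator")
  }
  k * (ht - hs) / denom
}

#' Pairwise differentiation matrices
#'
#' Recomputes Nei-Chesser G_ST and Hedrick G''_ST on each two-site subset
#' (k = 2), rather than decomposing a global analysis. Negative estimates
#' are retained, not truncated at zero.
#'
#' @param data a [genotype_dataset()].
#' @return list of two pairwise matrices: `gst`, `gst_hedrick`.
#' @export
pairwise_differentiation <- function(data) {
  sites <- dataset_sites(data)
  n <- length(sites)
  G <- H <- matrix(0, n, n, dimnames = list(sites, sites))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    fit <- gst_nei_chesser(data, site_subset = c(sites[a], sites[b]))
    G[a, b] <- G[b, a] <- fit$gst
    H[a, b] <- H[b, a] <- g_double_prime_st(fit$mean_hs, fit$mean_ht, k = 2)
  }
  list(gst = pairwise_matrix(G, sites, "gst"),
       gst_hedrick = pairwise_matrix(H, sites, "gst_hedrick"))
}

#' Slatkin linearization d / (1 - d)
#'
#' The transform under which isolation by distance is expected to be linear
#' in distance. Applied elementwise; values of 1 map to Inf.
#'
#' @param d numeric scalar, vector, or pairwise matrix of differentiation.
#' @return same shape as `d`.
#' @export
linearize <- function(d) {
  out <- d / (1 - d)
  if (is.matrix(d)) diag(out) <- 0
  out
}
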