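#' Remove individuals with too few amplified loci
#'
#' Retains individuals with at least `min_loci` loci successfully called
#' (both alleles present). The default of 5 follows the convention that five
#' microsatellite loci are about as informative as ten for heterozygosity
#' and allelic richness in these amphibians.
#'
#' @param data a [genotype_dataset()].
#' @param min_loci minimum number of called loci (inclusive boundary).
#' @return list with `data` (filtered dataset) and `report` (a qc report
#'   entry: counts and removed ids).
#' @export
filter_by_completeness <- function(data, min_loci = 5) {
  if (min_loci > length(data$loci))
    stop("min_loci exceeds the number of loci")
  nc <- called_loci(data)
  keep <- nc >= min_loci
  list(data = subset_individuals(data, keep),
       report = qc_entry("completeness", data$id[!keep], sum(keep),
                         params = list(min_loci = min_loci)))
}

#' Remove sites with too few genotyped individuals
#'
#' Drops whole sites with fewer than `min_n` individuals; a site with
#' exactly `min_n` is retained.
#'
#' @param data a [genotype_dataset()].
#' @param min_n minimum site sample size.
#' @return list with `data` and `report`.
#' @export
filter_sites_by_n <- function(data, min_n = 10) {
  tab <- table(data$site)
  bad_sites <- names(tab)[tab < min_n]
  keep <- !(data$site %in% bad_sites)
  list(data = subset_individuals(data, keep),
       report = qc_entry("site_n", data$id[!keep], sum(keep),
                         params = list(min_n = min_n,
                                       sites_removed = bad_sites)))
}

#' Remove all but one individual from each full-sibling family
#'
#' "Haphazard" retention is implemented as a seeded uniform random choice of
#' one member per family, so the result is reproducible. Individuals absent
#' from the sibship table (or in singleton families) are untouched.
#'
#' @param data a [genotype_dataset()].
#' @param sibship data.frame with columns `individual` and `family`; families
#'   must not span sites.
#' @param seed RNG seed for the per-family choice.
#' @return list with `data` and `report` (removed ids and the seed used).
#' @export
remove_siblings <- function(data, sibship, seed = 1) {
  if (!all(c("individual", "family") %in% names(sibship)))
    stop("sibship table needs columns `individual` and `family`")
  sib <- sibship[sibship$individual %in% data$id, , drop = FALSE]
  site_of <- data$site[match(sib$individual, data$id)]
  spans <- tapply(site_of, sib$family, function(s) length(unique(s)) > 1)
  if (any(spans))
    stop("full-sib family spans multiple sites: ",
         paste(names(spans)[spans], collapse = ", "))
  drop <- character(0)
  fams <- split(sib$individual, sib$family)
  with_seed(seed, {
    for (members in fams) {
      if (length(members) > 1) {
        keep1 <- sample(members, 1)
        drop <- c(drop, setdiff(members, keep1))
      }
    }
  })
  keep <- !(data$id %in% drop)
  list(data = subset_individuals(data, keep),
       report = qc_entry("siblings", data$id[!keep], sum(keep),
                         params = list(seed = seed, n_families = length(fams))))
}

qc_entry <- function(filter, removed_ids, retained, params = list()) {
  list(filter = filter, removed = length(removed_ids),
       retained = retained, removed_ids = removed_ids, params = params)
}

#' Per-locus null-allele frequency estimates
#'
#' Computes, per locus and site, the Chakraborty (1992) estimator
#' r = (He - Ho) / (He + Ho) and the Brookfield (1996) estimator 1
#' r = (He - Ho) / (1 + He), then averages across sites with at least
#' `min_n` individuals called at the locus. He is the unbiased expected
#' heterozygosity. Both raw and zero-clipped averages are reported;
#' monomorphic locus-site combinations contribute an estimate of 0 and are
#' flagged.
#'
#' @param data a [genotype_dataset()].
#' @param min_n minimum individuals called at the locus within a site.
#' @return data.frame: locus, chakraborty, brookfield1 (clipped >= 0),
#'   chakraborty_raw, brookfield1_raw, n_sites, monomorphic flag.
#' @export
null_allele_estimates <- function(data, min_n = 5) {
  sites <- dataset_sites(data)
  out <- lapply(data$loci, function(loc) {
    j <- match(loc, data$loci)
    cha <- bro <- numeric(0)
    mono <- TRUE
    for (s in sites) {
      rows <- data$site == s
      x1 <- data$a1[rows, j]; x2 <- data$a2[rows, j]
      ok <- !is.na(x1)
      if (sum(ok) < min_n) next
      x1 <- x1[ok]; x2 <- x2[ok]
      he <- unbiased_he(c(x1, x2))
      ho <- mean(x1 != x2)
      if (he > 0) mono <- FALSE
      cha <- c(cha, if (he + ho > 0) (he - ho) / (he + ho) else 0)
      bro <- c(bro, (he - ho) / (1 + he))
    }
    if (!length(cha))
      stop("no site with >= ", min_n, " individuals called at locus ", loc)
    data.frame(locus = loc,
               chakraborty = max(0, mean(cha)),
               brookfield1 = max(0, mean(bro)),
               chakraborty_raw = mean(cha),
               brookfield1_raw = mean(bro),
               n_sites = length(cha),
               monomorphic = mono)
  })
  do.call(rbind, out)
}

# unbiased expected heterozygosity from a vector of genes
# (N/(N-1)) * (1 - sum p^2), N = number of gene copies
unbiased_he <- function(genes) {
  genes <- genes[!is.na(genes)]
  N <- length(genes)
  if (N < 2) return(NA_real_)
  p <- table(genes) / N
  (N / (N - 1)) * (1 - sum(p^2))
}

#' Genotyping error rate from re-genotyped duplicates
#'
#' Rate = mismatching allele calls / compared allele calls over duplicate
#' pairs; calls missing in either copy are excluded. Each genotype
#' contributes up to two allele comparisons (pairs compared as multisets).
#'
#' @param data a [genotype_dataset()] containing both copies.
#' @param duplicate_pairs data.frame with columns `original` and `duplicate`
#'   (individual ids).
#' @return list with `rate`, `mismatches`, `compared`.
#' @export
duplicate_error_rate <- function(data, duplicate_pairs) {
  mism <- 0L; comp <- 0L
  for (r in seq_len(nrow(duplicate_pairs))) {
    i <- match(duplicate_pairs$original[r], data$id)
    k <- match(duplicate_pairs$duplicate[r], data$id)
    if (is.na(i) || is.na(k)) stop("duplicate pair references unknown id")
    for (j in seq_along(data$loci)) {
      g1 <- c(data$a1[i, j], data$a2[i, j])
      g2 <- c(data$a1[k, j], data$a2[k, j])
      if (anyNA(g1) || anyNA(g2)) next
      comp <- comp + 2L
      # multiset comparison of the two unordered calls
      matched <- sum(pmin(table(factor(g1, levels = unique(c(g1, g2)))),
                          table(factor(g2, levels = unique(c(g1, g2))))))
      mism <- mism + (2L - matched)
    }
  }
  list(rate = if (comp > 0) mism / comp else NA_real_,
       mismatches = mism, compared = comp)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values with significance flags at `alpha`.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param alpha significance level for the flags.
#' @return data.frame with p, p_adjusted, significant.
#' @export
fdr_adjust <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues))
    return(data.frame(p = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0)))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adjusted = adj, significant = !is.na(adj) & adj <= alpha)
}
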