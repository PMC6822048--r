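#' Diploid microsatellite genotype dataset
#'
#' Container for diploid microsatellite genotypes grouped by sampling site.
#' Allele calls are stored as two integer matrices (individuals x loci) of
#' allele sizes; a missing call has `NA` in both matrices, never a size of 0.
#' Within a call the pair is unordered and stored with `a1 <= a2`.
#'
#' @param site character vector, one site id per individual.
#' @param id character vector of unique individual ids.
#' @param loci character vector of locus names.
#' @param a1,a2 integer matrices (individuals x loci) of allele sizes;
#'   `NA` marks a missing call and must agree between the two matrices.
#' @return An object of class `genotype_dataset` with elements `site`, `id`,
#'   `loci`, `a1`, `a2`.
#' @export
genotype_dataset <- function(site, id, loci, a1, a2) {
  site <- as.character(site)
  id <- as.character(id)
  loci <- as.character(loci)
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  n <- length(id)
  if (length(site) != n) stop("`site` and `id` lengths differ")
  if (anyDuplicated(id)) stop("duplicate individual ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (nrow(a1) != n || nrow(a2) != n) stop("allele matrices must have one row per individual")
  if (ncol(a1) != length(loci) || ncol(a2) != length(loci))
    stop("allele matrices must have one column per locus")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing calls: a1 and a2 must be NA together")
  ok <- !is.na(a1)
  if (any(a1[ok] <= 0L) || any(a2[!is.na(a2)] <= 0L))
    stop("allele sizes must be positive integers")
  # canonical unordered storage
  swap <- ok & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(id, loci)
  structure(list(site = site, id = id, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$id), "individuals,",
      length(unique(x$site)), "sites,", length(x$loci), "loci\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals in a genotype dataset
#' @param data a `genotype_dataset`.
#' @return integer count.
#' @export
n_individuals <- function(data) length(data$id)

#' Site ids present in a genotype dataset
#' @param data a `genotype_dataset`.
#' @return character vector of site ids in order of first appearance.
#' @export
dataset_sites <- function(data) unique(data$site)

#' Subset a genotype dataset by individuals
#' @param data a `genotype_dataset`.
#' @param keep logical or integer index over individuals.
#' @return a `genotype_dataset`.
#' @export
subset_individuals <- function(data, keep) {
  genotype_dataset(data$site[keep], data$id[keep], data$loci,
                   data$a1[keep, , drop = FALSE], data$a2[keep, , drop = FALSE])
}

#' Subset a genotype dataset by sites
#' @param data a `genotype_dataset`.
#' @param sites character vector of site ids to keep.
#' @return a `genotype_dataset`.
#' @export
subset_sites <- function(data, sites) {
  subset_individuals(data, data$site %in% sites)
}

#' Allele counts at one locus for one site
#'
#' @param data a `genotype_dataset`.
#' @param locus locus name.
#' @param site site id; `NULL` pools all sites.
#' @return named integer vector of gene (allele-copy) counts.
#' @export
allele_counts <- function(data, locus, site = NULL) {
  j <- match(locus, data$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  rows <- if (is.null(site)) rep(TRUE, length(data$id)) else data$site == site
  genes <- c(data$a1[rows, j], data$a2[rows, j])
  genes <- genes[!is.na(genes)]
  if (!length(genes)) return(integer(0))
  tab <- table(genes)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' Per-individual count of successfully called loci
#' @param data a `genotype_dataset`.
#' @return integer vector, one entry per individual.
#' @export
called_loci <- function(data) rowSums(!is.na(data$a1))

# Run an expression with a locally seeded RNG, restoring global state after.
# seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
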