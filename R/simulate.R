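#' Configuration for the stepping-stone genotype simulator
#'
#' Defaults reflect the study conditions this pipeline targets: 8
#' dinucleotide-like microsatellite loci under a two-phase mutation model
#' with total step variance 12 and 95% single-step mutations, tens of demes
#' sampled at 10-40 diploids each.
#'
#' @param n_demes number of demes.
#' @param deme_size diploid individuals per deme (N_e).
#' @param n_loci number of loci.
#' @param n_alleles_init initial equifrequent allele states per locus.
#' @param mutation_rate per-gene per-generation mutation probability.
#' @param p_single_step probability a mutation is a +/-1 repeat step.
#' @param mutation_variance target variance of the signed mutation-step
#'   distribution (multi-step magnitudes are geometric, calibrated so the
#'   total variance matches).
#' @param migration_scale lambda in m_ij proportional to exp(-lambda R_ij).
#' @param self_retention fraction of genes the best-connected deme keeps
#'   each generation (more isolated demes keep more).
#' @param generations forward generations simulated.
#' @param sample_sizes diploids sampled per deme (recycled).
#' @param missing_rate fraction of locus calls masked by [inject_artifacts()].
#' @param null_allele_freq per-gene probability of conversion to a
#'   non-amplifying allele in [inject_artifacts()].
#' @param sib_family_config NULL, or list(n_families, family_size) appended
#'   per deme by [inject_artifacts()].
#' @param seed RNG seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_demes = 12, deme_size = 50, n_loci = 8,
                              n_alleles_init = 6, mutation_rate = 5e-4,
                              p_single_step = 0.95, mutation_variance = 12,
                              migration_scale = 10, self_retention = 0.9,
                              generations = 100, sample_sizes = 20,
                              missing_rate = 0, null_allele_freq = 0,
                              sib_family_config = NULL, seed = 1) {
  cfg <- as.list(environment())
  rates <- c(cfg$mutation_rate, cfg$p_single_step, cfg$missing_rate,
             cfg$null_allele_freq, cfg$self_retention)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$deme_size < 2) stop("deme_size must be >= 2")
  if (cfg$generations < 1) stop("generations must be >= 1")
  if (any(cfg$sample_sizes > cfg$deme_size))
    stop("sample_sizes cannot exceed deme_size")
  if (cfg$mutation_variance < cfg$p_single_step)
    stop("mutation_variance below the single-step floor")
  class(cfg) <- "simulation_config"
  cfg
}

# geometric success probability q so that the signed TPM step variance is v:
# Var = p_single * 1 + (1 - p_single) * E[M^2], M ~ Geometric(q) on {1,2,..}
tpm_geom_q <- function(p_single, v) {
  if (p_single >= 1) return(1)
  v2 <- (v - p_single) / (1 - p_single)  # required E[M^2] = (2 - q)/q^2
  (-1 + sqrt(1 + 8 * v2)) / (2 * v2)
}

# draw n signed TPM step sizes
tpm_steps <- function(n, p_single, q) {
  mag <- ifelse(stats::runif(n) < p_single, 1L, stats::rgeom(n, q) + 1L)
  mag * sample(c(-1L, 1L), n, replace = TRUE)
}

#' Forward-time stepping-stone simulation of microsatellite genotypes
#'
#' Places demes on a landscape, derives per-generation migration from
#' circuit-theory effective resistance (m_ij proportional to
#' exp(-lambda R_ij) on an absolute scale, normalized so the
#' best-connected deme retains `self_retention` of its genes and isolated
#' demes exchange less), and
#' runs a forward-time simulation: each generation the deme allele-frequency
#' vectors are mixed by the migration matrix, drift resamples 2 N_e genes
#' multinomially, and mutation applies two-phase-model steps at rate mu.
#' Allele states are repeat counts on an unbounded ladder, reported as
#' fragment sizes 100 + 2 * count to resemble dinucleotide alleles.
#'
#' @param landscape a `landscape_stack`.
#' @param deme_xy data.frame with columns `row`, `col` (deme raster cells)
#'   and optionally `site` ids.
#' @param config a [simulation_config()].
#' @param true_costs named cost vector used to build the ground-truth
#'   combined resistance surface (see [build_surface()]); NULL for a uniform
#'   landscape.
#' @param tri_offset optional TRI offset entering the ground-truth surface.
#' @return list: `data` (a [genotype_dataset()]), `sites` (site table with
#'   lat/lon from an affine placement near 44 N, -69 E so geodesic code is
#'   exercised), `truth` (true_costs, migration_matrix, resistance matrix,
#'   deme_cells).
#' @export
simulate_genotypes <- function(landscape, deme_xy, config,
                               true_costs = NULL, tri_offset = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  nd <- nrow(deme_xy)
  if (nd != config$n_demes)
    stop("deme_xy rows must equal config$n_demes")
  if (is.null(deme_xy$site))
    deme_xy$site <- sprintf("D%02d", seq_len(nd))
  surf <- build_surface(landscape, cost_assignment = true_costs,
                        tri_offset = tri_offset)
  R <- effective_resistance(surf, data.frame(site = deme_xy$site,
                                             row = deme_xy$row,
                                             col = deme_xy$col))
  if (any(!is.finite(lower_vec(R)))) {
    bad <- which(!is.finite(R) & upper.tri(R), arr.ind = TRUE)[1, ]
    stop("non-finite resistance between demes ",
         rownames(R)[bad[1]], " and ", colnames(R)[bad[2]],
         ": landscape graph disconnected")
  }
  M <- migration_from_resistance(R, config$migration_scale,
                                 config$self_retention)
  n_genes <- 2L * config$deme_size
  samp <- rep_len(config$sample_sizes, nd)

  with_seed(config$seed, {
    q <- tpm_geom_q(config$p_single_step, config$mutation_variance)
    init_states <- 20L + seq_len(config$n_alleles_init) - 1L
    loci <- sprintf("L%02d", seq_len(config$n_loci))
    a1 <- a2 <- matrix(NA_integer_, sum(samp), config$n_loci)
    for (j in seq_len(config$n_loci)) {
      base <- n_genes %/% config$n_alleles_init
      counts0 <- rep(base, config$n_alleles_init)
      counts0[1] <- counts0[1] + (n_genes - sum(counts0))
      cnt <- matrix(rep(counts0, each = nd), nd, config$n_alleles_init)
      colnames(cnt) <- as.character(init_states)
      for (gen in seq_len(config$generations)) {
        freq <- cnt / n_genes
        mixed <- M %*% freq
        for (d in seq_len(nd))
          cnt[d, ] <- stats::rmultinom(1, n_genes, mixed[d, ])
        # mutation
        n_mut <- stats::rbinom(nd, n_genes, config$mutation_rate)
        if (any(n_mut > 0)) {
          states <- as.integer(colnames(cnt))
          new_cols <- list()
          for (d in which(n_mut > 0)) {
            src <- sample.int(ncol(cnt), n_mut[d], replace = TRUE,
                              prob = cnt[d, ] / n_genes)
            steps <- tpm_steps(n_mut[d], config$p_single_step, q)
            dest <- pmax(states[src] + steps, 2L)  # floor: >= 2 repeats
            for (t in seq_along(src)) {
              if (cnt[d, src[t]] == 0L) next  # source emptied by earlier event
              cnt[d, src[t]] <- cnt[d, src[t]] - 1L
              dn <- as.character(dest[t])
              jcol <- match(dn, colnames(cnt))
              if (is.na(jcol)) {
                cnt <- cbind(cnt, 0L)
                colnames(cnt)[ncol(cnt)] <- dn
                jcol <- ncol(cnt)
              }
              cnt[d, jcol] <- cnt[d, jcol] + 1L
            }
          }
        }
        cnt <- cnt[, colSums(cnt) > 0, drop = FALSE]
      }
      # sample diploids per deme without replacement from the gene pool
      row0 <- 0L
      for (d in seq_len(nd)) {
        pool <- rep(as.integer(colnames(cnt)), cnt[d, ])
        genes <- sample(pool, 2L * samp[d])
        a1[row0 + seq_len(samp[d]), j] <- genes[seq_len(samp[d])]
        a2[row0 + seq_len(samp[d]), j] <- genes[samp[d] + seq_len(samp[d])]
        row0 <- row0 + samp[d]
      }
    }
    site_vec <- rep(deme_xy$site, samp)
    ids <- paste0(site_vec, "_", unlist(lapply(samp, seq_len)))
    data <- genotype_dataset(site_vec, ids, loci,
                             100L + 2L * a1, 100L + 2L * a2)
    sites <- deme_cells_to_latlon(deme_xy, landscape$cellsize)
    list(data = data, sites = sites,
         truth = list(true_costs = true_costs, tri_offset = tri_offset,
                      migration_matrix = M, resistance = R,
                      deme_cells = deme_xy))
  })
}

# migration matrix: m_ij proportional to exp(-lambda * R_ij) on an absolute
# scale, normalized so the best-connected deme retains `self_retention` of
# its genes; other demes retain more. Scaling by absolute (not row-relative)
# resistance lets genuinely isolated demes receive and send less gene flow,
# which row-wise normalization would erase. The global shift by the
# smallest off-diagonal resistance is exact (it cancels in the common
# normalization) and avoids underflow at large lambda * R. lambda = 0 gives
# the island model.
migration_from_resistance <- function(R, lambda, self_retention = 0.9) {
  nd <- nrow(R)
  M <- matrix(0, nd, nd, dimnames = dimnames(R))
  if (nd == 1) { M[1, 1] <- 1; return(M) }
  off <- R
  diag(off) <- NA
  shift <- min(off, na.rm = TRUE)
  W <- exp(-lambda * (R - shift))
  diag(W) <- 0
  rs <- rowSums(W)
  M <- W * (1 - self_retention) / max(rs)
  diag(M) <- 1 - rowSums(M)
  M
}

# affine placement of deme cells near 44 N, -69 E: one cell = cellsize metres
deme_cells_to_latlon <- function(deme_xy, cellsize) {
  m_per_deg_lat <- 111320
  m_per_deg_lon <- 111320 * cos(44 * pi / 180)
  data.frame(site = deme_xy$site,
             lat = 44 + (deme_xy$row - 1) * cellsize / m_per_deg_lat,
             lon = -69 + (deme_xy$col - 1) * cellsize / m_per_deg_lon)
}

#' Inject genotyping artifacts into a simulated dataset
#'
#' In order: (1) null alleles - each gene copy is independently converted to
#' a non-amplifying state with probability `null_allele_freq`; heterozygotes
#' carrying one null become apparent homozygotes for the visible allele and
#' null/null genotypes become missing calls; (2) random missingness - each
#' remaining call is masked with probability `missing_rate`; (3) full-sib
#' families - per deme, `n_families` families of `family_size` offspring are
#' generated by Mendelian sampling from two sampled parents and appended.
#' A truth table of the injected families and realized per-locus null-gene
#' fractions is returned.
#'
#' @param data a [genotype_dataset()].
#' @param config a [simulation_config()] (uses missing_rate,
#'   null_allele_freq, sib_family_config, seed).
#' @return list: `data` (modified dataset), `truth` (list with
#'   `null_gene_fraction` per locus, `sib_families` data.frame individual,
#'   family, site).
#' @export
inject_artifacts <- function(data, config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 7919L, {
    a1 <- data$a1; a2 <- data$a2
    null_frac <- stats::setNames(rep(0, length(data$loci)), data$loci)
    if (config$null_allele_freq > 0) {
      for (j in seq_along(data$loci)) {
        ok <- !is.na(a1[, j])
        n1 <- stats::runif(nrow(a1)) < config$null_allele_freq & ok
        n2 <- stats::runif(nrow(a1)) < config$null_allele_freq & ok
        null_frac[j] <- sum(n1 + n2) / (2 * sum(ok))
        both <- n1 & n2
        a1[both, j] <- NA_integer_; a2[both, j] <- NA_integer_
        only1 <- n1 & !n2
        a1[only1, j] <- a2[only1, j]
        only2 <- n2 & !n1
        a2[only2, j] <- a1[only2, j]
      }
    }
    if (config$missing_rate > 0) {
      drop <- matrix(stats::runif(length(a1)) < config$missing_rate,
                     nrow(a1), ncol(a1))
      a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
    }
    site <- data$site; id <- data$id
    fams <- NULL
    sf <- config$sib_family_config
    if (!is.null(sf)) {
      n_fam <- sf[[1]]; fam_size <- sf[[2]]
      fam_i <- 0L
      for (s in unique(data$site)) {
        rows <- which(data$site == s)
        for (f in seq_len(n_fam)) {
          fam_i <- fam_i + 1L
          par <- sample(rows, 2)
          fam_id <- sprintf("F%03d", fam_i)
          for (o in seq_len(fam_size)) {
            kid1 <- kid2 <- rep(NA_integer_, length(data$loci))
            for (j in seq_along(data$loci)) {
              g1 <- c(data$a1[par[1], j], data$a2[par[1], j])
              g2 <- c(data$a1[par[2], j], data$a2[par[2], j])
              if (anyNA(g1) || anyNA(g2)) next
              kid1[j] <- sample(g1, 1); kid2[j] <- sample(g2, 1)
            }
            oid <- paste0(fam_id, "_", o)
            site <- c(site, s); id <- c(id, oid)
            a1 <- rbind(a1, kid1); a2 <- rbind(a2, kid2)
            fams <- rbind(fams, data.frame(individual = oid, family = fam_id,
                                           site = s))
          }
        }
      }
    }
    list(data = genotype_dataset(site, id, data$loci, a1, a2),
         truth = list(null_gene_fraction = null_frac, sib_families = fams))
  })
}

#' Place demes on a grid with jitter
#'
#' Convenience helper: lays `n` demes out on a near-square lattice over the
#' raster interior with one cell of uniform jitter, the usual layout for
#' stepping-stone experiments. When a landscape stack is supplied, demes are
#' moved to the nearest cell free of linear features and developed cover -
#' breeding pools sit in habitat, not on roads or in rivers, and a deme on a
#' high-cost cell would carry a resistance offset to every partner that has
#' no demographic meaning.
#'
#' @param n number of demes.
#' @param height,width raster size in cells.
#' @param seed RNG seed.
#' @param stack optional `landscape_stack` whose linear-feature and
#'   developed (class C) cells are avoided.
#' @return data.frame: site, row, col.
#' @export
place_demes <- function(n, height, width, seed = 1, stack = NULL) {
  avoid <- NULL
  if (!is.null(stack)) {
    avoid <- stack$landcover == "C"
    for (f in c("interstates", "secondary_roads", "light_roads",
                "medium_rivers", "large_rivers", "railroads"))
      if (!is.null(stack[[f]])) avoid <- avoid | stack[[f]] == 1
  }
  with_seed(seed, {
    nx <- ceiling(sqrt(n)); ny <- ceiling(n / nx)
    gx <- round(seq(width * 0.12, width * 0.88, length.out = nx))
    gy <- round(seq(height * 0.12, height * 0.88, length.out = ny))
    grid <- expand.grid(col = gx, row = gy)[seq_len(n), ]
    grid$row <- pmin(pmax(grid$row + sample(-1:1, n, TRUE), 1), height)
    grid$col <- pmin(pmax(grid$col + sample(-1:1, n, TRUE), 1), width)
    if (!is.null(avoid)) {
      clear <- which(!avoid, arr.ind = TRUE)
      if (!nrow(clear)) stop("no feature-free cell available for demes")
      for (i in seq_len(n)) {
        if (!avoid[grid$row[i], grid$col[i]]) next
        d2 <- (clear[, 1] - grid$row[i])^2 + (clear[, 2] - grid$col[i])^2
        nearest <- clear[which.min(d2), ]
        grid$row[i] <- nearest[1]; grid$col[i] <- nearest[2]
      }
    }
    data.frame(site = sprintf("D%02d", seq_len(n)),
               row = grid$row, col = grid$col)
  })
}
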