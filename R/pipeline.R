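#' Default pipeline configuration
#'
#' Stage parameters default to the study settings: completeness filter at 5
#' loci, minimum site size 10, 9,999 Mantel permutations and 10,000 for
#' partial Mantel / MMRR / dbRDA, 1,000 bootstrap replicates, 20-km
#' correlogram classes, TPM variance 12 with 95% single-step mutations.
#'
#' @param out_dir output directory.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param ... overrides for any default element.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed,
    stages = c("simulate", "qc", "stats", "ibd", "resistance", "multivariate"),
    sim = list(width = 48, height = 48, n_demes = 12, deme_size = 50,
               n_loci = 8, generations = 80, sample_sizes = 20,
               migration_scale = 10,
               feature_spec = list(landcover_b = 0.1, landcover_c = 0.08,
                                   interstates = 1, light_roads = 2,
                                   medium_rivers = 1, elevation_relief = 30),
               true_costs = c(interstates = 500, landcover_C = 10),
               missing_rate = 0.01),
    qc = list(min_loci = 5, min_n = 10, fdr_alpha = 0.05),
    stats = list(rarefaction_genes = NULL, exact_test_perms = 2000),
    ibd = list(n_perm = 9999, start_pairs = 20, n_boot = 200,
               class_width_km = 20, profile_step = 1),
    resistance = list(n_perm = 2000,
                      candidates = list(interstates = c(1, 5, 25, 100, 500),
                                        landcover_C = c(1, 5, 15, 50),
                                        light_roads = c(1, 5, 25, 100),
                                        medium_rivers = c(1, 25, 100, 500))),
    multivariate = list(n_perm = 2000, alpha = 0.05, collinearity = 0.7)
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate -> qc -> stats -> ibd -> resistance -> multivariate
#' with explicit data contracts between stages, writing tables under
#' `config$out_dir` and returning a manifest (per-stage outputs, md5
#' checksums, wall time, warnings). Stages run in order; a failure stops the
#' run with a stage-scoped error. All randomness flows from the global seed
#' via per-stage derived seeds, so a rerun with the same config reproduces
#' identical checksums for deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_manifest`: per-stage file lists with
#'   checksums, timings, the config used, and in-memory `results`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, stages = list())
  res <- list()
  t_stage <- function(name, fun) {
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e)
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
    files <- out$files %||% character(0)
    manifest$stages[[name]] <<- list(
      files = files,
      md5 = if (length(files)) as.list(tools::md5sum(files)) else list(),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out$value
  }
  p <- function(...) file.path(config$out_dir, ...)
  seed0 <- config$seed

  if ("simulate" %in% config$stages) {
    res$sim <- t_stage("simulate", function() {
      sc <- config$sim
      land <- generate_landscape(sc$width, sc$height, sc$feature_spec,
                                 seed = seed0)
      demes <- place_demes(sc$n_demes, sc$height, sc$width, seed = seed0 + 1,
                           stack = land)
      cfg <- simulation_config(
        n_demes = sc$n_demes, deme_size = sc$deme_size, n_loci = sc$n_loci,
        generations = sc$generations, sample_sizes = sc$sample_sizes,
        migration_scale = sc$migration_scale,
        missing_rate = sc$missing_rate %||% 0, seed = seed0 + 2)
      sim <- simulate_genotypes(land, demes, cfg, true_costs = sc$true_costs)
      art <- inject_artifacts(sim$data, cfg)
      write_genepop(art$data, p("genotypes.gen"))
      write_genotypes_long(art$data, p("genotypes_long.tsv"))
      write_site_table(sim$sites, p("sites.tsv"))
      write_ascii_grid(build_surface(land, sc$true_costs)$resistance,
                       p("true_resistance.asc"))
      jsonlite::write_json(
        list(true_costs = as.list(sc$true_costs),
             migration_matrix = sim$truth$migration_matrix,
             null_gene_fraction = art$truth$null_gene_fraction),
        p("ground_truth.json"), auto_unbox = TRUE, digits = NA)
      list(value = list(data = art$data, sites = sim$sites, land = land,
                        demes = demes, truth = sim$truth),
           files = p(c("genotypes.gen", "genotypes_long.tsv", "sites.tsv",
                       "true_resistance.asc", "ground_truth.json")))
    })
  }
  if ("qc" %in% config$stages) {
    res$qc <- t_stage("qc", function() {
      if (is.null(res$sim)) stop("missing upstream artifact: run `simulate` first")
      qc <- config$qc
      f1 <- filter_by_completeness(res$sim$data, qc$min_loci)
      f2 <- filter_sites_by_n(f1$data, qc$min_n)
      nulls <- null_allele_estimates(f2$data)
      utils::write.table(nulls, p("null_alleles.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(completeness = f1$report, site_n = f2$report),
                           p("qc_report.json"), auto_unbox = TRUE, digits = NA)
      list(value = list(data = f2$data, nulls = nulls,
                        reports = list(f1$report, f2$report)),
           files = p(c("null_alleles.tsv", "qc_report.json")))
    })
  }
  if ("stats" %in% config$stages) {
    res$stats <- t_stage("stats", function() {
      if (is.null(res$qc)) stop("missing upstream artifact: run `qc` first")
      data <- res$qc$data
      g <- config$stats$rarefaction_genes %||%
        min(vapply(dataset_sites(data), function(s)
          min(vapply(data$loci, function(l)
            sum(allele_counts(data, l, s)), numeric(1))), numeric(1)))
      div <- site_diversity(data, rarefaction_genes = g)
      pw <- pairwise_differentiation(data)
      glob <- gst_nei_chesser(data)
      utils::write.table(div, p("site_diversity.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_pairwise(pw$gst, p("pairwise_gst.tsv"))
      write_pairwise(pw$gst_hedrick, p("pairwise_gst_hedrick.tsv"))
      jsonlite::write_json(
        list(global_gst = glob$gst,
             global_gst_hedrick = g_double_prime_st(
               glob$mean_hs, glob$mean_ht, length(dataset_sites(data)))),
        p("differentiation.json"), auto_unbox = TRUE, digits = NA)
      list(value = list(diversity = div, pairwise = pw, global = glob),
           files = p(c("site_diversity.tsv", "pairwise_gst.tsv",
                       "pairwise_gst_hedrick.tsv", "differentiation.json")))
    })
  }
  if ("ibd" %in% config$stages) {
    res$ibd <- t_stage("ibd", function() {
      if (is.null(res$stats)) stop("missing upstream artifact: run `stats` first")
      sites <- res$sim$sites[res$sim$sites$site %in%
                               dataset_sites(res$qc$data), ]
      D <- geo_distance_matrix(sites)
      Gl <- pairwise_matrix(linearize(res$stats$pairwise$gst[sites$site, sites$site]),
                            sites$site, "linearized_gst")
      mt <- mantel_test(Gl, D, n_perm = config$ibd$n_perm, seed = seed0 + 10)
      fit <- ibd_regression(Gl, D, form = "linear", quantiles = c(0.05, 0.95))
      prof <- ibd_scaling_profile(Gl, D, start_pairs = config$ibd$start_pairs,
                                  n_boot = config$ibd$n_boot, seed = seed0 + 11,
                                  step = config$ibd$profile_step)
      iso <- site_isolation_index(fit)
      utils::write.table(prof, p("scaling_profile.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(iso, p("isolation_index.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_pairwise(D, p("geo_distance_km.tsv"))
      list(value = list(D = D, Gl = Gl, mantel = mt, fit = fit,
                        profile = prof, isolation = iso),
           files = p(c("scaling_profile.tsv", "isolation_index.tsv",
                       "geo_distance_km.tsv")))
    })
  }
  if ("resistance" %in% config$stages) {
    res$resistance <- t_stage("resistance", function() {
      if (is.null(res$ibd)) stop("missing upstream artifact: run `ibd` first")
      rc <- config$resistance
      demes <- res$sim$demes[res$sim$demes$site %in% rownames(res$ibd$Gl), ]
      opts <- list(); best <- list()
      for (f in names(rc$candidates)) {
        o <- optimize_feature_cost(res$sim$land, f, rc$candidates[[f]],
                                   res$ibd$Gl, res$ibd$D, demes,
                                   n_perm = rc$n_perm, seed = seed0 + 20)
        opts[[f]] <- o
        if (isTRUE(o$beats_ibd)) best[[f]] <- o$resistance
      }
      mt <- if (length(best))
        aicc_model_selection(res$ibd$Gl, best, res$ibd$D) else NULL
      if (!is.null(mt))
        utils::write.table(as.data.frame(mt), p("model_table.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        lapply(opts, function(o) list(best_cost = o$best_cost,
                                      beats_ibd = o$beats_ibd,
                                      table = o$table)),
        p("cost_optimization.json"), auto_unbox = TRUE, digits = NA)
      list(value = list(optimized = opts, model_table = mt),
           files = p(c(if (!is.null(mt)) "model_table.tsv",
                       "cost_optimization.json")))
    })
  }
  if ("multivariate" %in% config$stages) {
    res$multivariate <- t_stage("multivariate", function() {
      if (is.null(res$ibd)) stop("missing upstream artifact: run `ibd` first")
      mv <- config$multivariate
      iso <- res$ibd$isolation
      # site-level urbanization stand-in: local developed-cover and road
      # densities in a 5-cell window around each deme
      demes <- res$sim$demes[match(iso$site, res$sim$demes$site), ]
      cov <- local_covariates(res$sim$land, demes)
      keep_col <- vapply(cov[-1], function(v) stats::sd(v) > 0, logical(1))
      cov <- cov[, c(TRUE, keep_col), drop = FALSE]
      pr <- collinearity_prune(cov[, -1, drop = FALSE],
                               threshold = mv$collinearity, seed = seed0 + 30)
      keep <- pr$retained
      reg <- multiple_regression(iso$isolation, cov[, keep, drop = FALSE])
      Xmats <- lapply(keep, function(cn)
        pairwise_matrix(abs(outer(cov[[cn]], cov[[cn]], "-")),
                        iso$site, cn))
      names(Xmats) <- keep
      mm <- mmrr(res$ibd$Gl, c(Xmats, list(distance = res$ibd$D)),
                 n_perm = mv$n_perm, seed = seed0 + 31)
      sites <- res$sim$sites[match(iso$site, res$sim$sites$site), ]
      db <- dbrda(res$stats$pairwise$gst[iso$site, iso$site],
                  stats::setNames(cov[, keep, drop = FALSE], keep),
                  condition = sites[, c("lat", "lon")],
                  n_perm = mv$n_perm, alpha = mv$alpha, seed = seed0 + 32)
      utils::write.table(reg$coefficients, p("isolation_regression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(mm$coefficients, p("mmrr.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(value = list(covariates = cov, pruned = pr, regression = reg,
                        mmrr = mm, dbrda = db),
           files = p(c("isolation_regression.tsv", "mmrr.tsv")))
    })
  }
  manifest$results <- res
  class(manifest) <- "run_manifest"
  manifest
}

#' Site-level landscape covariates in a window around each deme
#'
#' Developed-cover fraction and per-feature road/river cell counts within a
#' square window, the synthetic analogue of buffer-based urbanization
#' metrics.
#'
#' @param land a `landscape_stack`.
#' @param demes data.frame site, row, col.
#' @param radius window half-width in cells.
#' @return data.frame: site, developed, plus one count column per linear
#'   feature present.
#' @export
local_covariates <- function(land, demes, radius = 5) {
  lin <- intersect(names(land),
                   c("interstates", "secondary_roads", "light_roads",
                     "medium_rivers", "large_rivers", "railroads"))
  lin <- lin[vapply(lin, function(f) sum(land[[f]]) > 0, logical(1))]
  out <- data.frame(site = demes$site)
  win <- function(m, r, c) {
    rr <- max(1, r - radius):min(nrow(m), r + radius)
    cc <- max(1, c - radius):min(ncol(m), c + radius)
    m[rr, cc]
  }
  out$developed <- vapply(seq_len(nrow(demes)), function(i)
    mean(win(land$landcover, demes$row[i], demes$col[i]) == "C"), numeric(1))
  for (f in lin) {
    out[[f]] <- vapply(seq_len(nrow(demes)), function(i)
      sum(win(land[[f]], demes$row[i], demes$col[i])), numeric(1))
  }
  out
}
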