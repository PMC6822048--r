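#' Circuit-theory pairwise effective resistance on a raster
#'
#' Treats every non-NA cell as a node. Neighbouring cells i, j are joined by
#' a resistor of (R_i + R_j)/2 for orthogonal neighbours and
#' (R_i + R_j)/2 * sqrt(2) for diagonal neighbours (the average-resistance,
#' diagonal-length convention of circuit-theory connectivity tools).
#' Effective resistance between site cells is obtained from sparse Cholesky
#' solves of the grounded graph Laplacian, one factorization per connected
#' component. Pairs in different components have infinite resistance and are
#' reported as `Inf`.
#'
#' @param surface a `resistance_surface` (or bare numeric matrix of per-cell
#'   resistances >= 0, NA = nodata).
#' @param site_cells data.frame with columns `site`, `row`, `col` (1-based
#'   cell indices).
#' @param neighborhood 8 (default) or 4.
#' @return a [pairwise_matrix()] of kind "resistance" (may contain Inf).
#' @export
effective_resistance <- function(surface, site_cells, neighborhood = 8) {
  r <- if (inherits(surface, "resistance_surface")) surface$resistance else surface
  if (!neighborhood %in% c(4, 8)) stop("neighborhood must be 4 or 8")
  nr <- nrow(r); nc <- ncol(r)
  if (any(site_cells$row < 1 | site_cells$row > nr |
          site_cells$col < 1 | site_cells$col > nc))
    stop("site cell outside raster extent")
  node_id <- matrix(NA_integer_, nr, nc)
  ok <- !is.na(r)
  node_id[ok] <- seq_len(sum(ok))
  n_nodes <- sum(ok)
  s_nodes <- node_id[cbind(site_cells$row, site_cells$col)]
  if (anyNA(s_nodes)) stop("site on a nodata cell: ",
                           paste(site_cells$site[is.na(s_nodes)], collapse = ", "))

  offs <- list(c(0, 1), c(1, 0))
  if (neighborhood == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  ei <- ej <- integer(0); ew <- numeric(0)
  for (d in offs) {
    if (nr - abs(d[1]) < 1 || nc - abs(d[2]) < 1) next
    r1 <- 1:(nr - abs(d[1])) + ifelse(d[1] < 0, abs(d[1]), 0)
    c1 <- 1:(nc - abs(d[2])) + ifelse(d[2] < 0, abs(d[2]), 0)
    a <- node_id[r1, c1, drop = FALSE]
    b <- node_id[r1 + d[1], c1 + d[2], drop = FALSE]
    ra <- r[r1, c1, drop = FALSE]
    rb <- r[r1 + d[1], c1 + d[2], drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    res <- (ra[keep] + rb[keep]) / 2
    if (sum(abs(d)) == 2) res <- res * sqrt(2)
    ei <- c(ei, a[keep]); ej <- c(ej, b[keep]); ew <- c(ew, 1 / res)
  }

  comp <- graph_components(n_nodes, ei, ej)
  ids <- as.character(site_cells$site)
  out <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  diag(out) <- 0
  for (cmp in unique(comp[s_nodes])) {
    members <- which(comp == cmp)
    here <- which(comp[s_nodes] == cmp)
    if (length(here) < 2) next
    remap <- integer(n_nodes)
    remap[members] <- seq_along(members)
    sel <- ew > 0 & comp[ei] == cmp
    i2 <- remap[ei[sel]]; j2 <- remap[ej[sel]]; w2 <- ew[sel]
    m <- length(members)
    L <- Matrix::sparseMatrix(i = c(i2, j2, i2, j2),
                              j = c(j2, i2, i2, j2),
                              x = c(-w2, -w2, w2, w2),
                              dims = c(m, m))
    g <- m  # ground the last node of the component
    Lr <- L[-g, -g, drop = FALSE]
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lr), LDL = FALSE, perm = TRUE)
    q <- remap[s_nodes[here]]
    rhs <- matrix(0, m - 1, length(q))
    for (t in seq_along(q)) if (q[t] != g) rhs[q[t], t] <- 1
    V <- as.matrix(Matrix::solve(ch, rhs))
    for (aa in seq_along(here)) for (bb in seq_along(here)) {
      if (bb <= aa) next
      qa <- q[aa]; qb <- q[bb]
      va_a <- if (qa == g) 0 else V[qa, aa]
      va_b <- if (qb == g) 0 else V[qb, aa]
      vb_a <- if (qa == g) 0 else V[qa, bb]
      vb_b <- if (qb == g) 0 else V[qb, bb]
      rab <- va_a - va_b - vb_a + vb_b
      ia <- here[aa]; ib <- here[bb]
      out[ia, ib] <- out[ib, ia] <- rab
    }
  }
  attr(out, "kind") <- "resistance"
  out
}

# connected components by union-find
graph_components <- function(n, ei, ej) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(ei)) {
    a <- find(ei[e]); b <- find(ej[e])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Optimize a single feature's resistance cost by partial Mantel testing
#'
#' For each candidate cost, builds the single-feature surface (feature cells
#' at the candidate cost, all else 1; for the TRI feature, resistance =
#' TRI + candidate everywhere), computes pairwise effective resistance
#' between sites, and runs a partial Mantel test of resistance against
#' genetic differentiation controlling for geographic distance. The
#' candidate with the largest r-squared wins. A feature "beats IBD" iff the
#' best candidate is not 1 and its r-squared exceeds the cost-1 (pure IBD)
#' candidate's.
#'
#' @param stack a `landscape_stack`.
#' @param feature feature layer name (e.g. "interstates", "landcover_C",
#'   "tri").
#' @param candidates ordered candidate costs (4-7 values, must include 1;
#'   for "tri" they are additive offsets).
#' @param G_linearized pairwise linearized differentiation matrix.
#' @param D_geo pairwise geographic distance matrix.
#' @param site_cells data.frame site, row, col giving each site's raster
#'   cell.
#' @param n_perm permutations for the partial Mantel tests.
#' @param seed RNG seed.
#' @param neighborhood raster graph neighbourhood (8 or 4).
#' @return list: best_cost, beats_ibd, table (cost, r, r_squared, p,
#'   n_infinite_pairs), resistance (pairwise matrix at the best cost).
#' @export
optimize_feature_cost <- function(stack, feature, candidates, G_linearized,
                                  D_geo, site_cells, n_perm = 10000, seed = 1,
                                  neighborhood = 8) {
  if (!1 %in% candidates) stop("candidate costs must include 1")
  rows <- list(); best <- NULL; best_r2 <- -Inf; r2_ibd <- NA_real_
  best_R <- NULL
  for (ci in seq_along(candidates)) {
    cost <- candidates[ci]
    surf <- if (identical(feature, "tri")) {
      build_surface(stack, tri_offset = cost)
    } else {
      build_surface(stack, cost_assignment = stats::setNames(cost, feature))
    }
    R <- effective_resistance(surf, site_cells, neighborhood)
    n_inf <- sum(!is.finite(lower_vec(R)))
    if (n_inf == length(lower_vec(R))) {
      rows[[ci]] <- data.frame(cost = cost, r = NA, r_squared = NA, p = NA,
                               n_infinite_pairs = n_inf)
      next
    }
    Rm <- R; Rm[!is.finite(Rm)] <- NA
    fit <- partial_mantel(pairwise_matrix(Rm, rownames(R), "resistance"),
                          G_linearized, D_geo, n_perm = n_perm,
                          seed = seed + ci)
    rows[[ci]] <- data.frame(cost = cost, r = fit$r, r_squared = fit$r_squared,
                             p = fit$p, n_infinite_pairs = n_inf)
    if (cost == 1) r2_ibd <- fit$r_squared
    if (is.finite(fit$r_squared) && fit$r_squared > best_r2) {
      best_r2 <- fit$r_squared; best <- cost; best_R <- R
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(best)) {
    return(list(best_cost = NA_real_, beats_ibd = FALSE, table = tab,
                resistance = NULL, skipped = TRUE))
  }
  list(best_cost = best,
       beats_ibd = isTRUE(best != 1 && best_r2 > r2_ibd),
       table = tab, resistance = best_R, skipped = FALSE)
}

#' AICc selection over additive resistance models
#'
#' Fits a Gaussian identity-link linear model of unfolded pairwise
#' differentiation on every non-empty subset of the optimized per-feature
#' effective-resistance matrices, plus an IBD-only model (geographic
#' distance alone). AICc = -2 logL + 2k + 2k(k+1)/(n-k-1) with n the number
#' of pairs used and k the number of estimated parameters (coefficients plus
#' the residual variance). Returns the table sorted by AICc with delta
#' values and Akaike weights. Pairs with a non-finite value in any predictor
#' are excluded listwise; models with n <= k + 1 are skipped.
#'
#' @param G_linearized response pairwise matrix.
#' @param resistance_predictors named list of pairwise matrices.
#' @param D_geo geographic distance pairwise matrix (the IBD-only model).
#' @param max_model_size optional cap on the number of predictors per model.
#' @return data.frame of class `model_table`: model, k, n, logL, AICc,
#'   delta_aicc, weight; attribute `n_excluded_pairs`.
#' @export
aicc_model_selection <- function(G_linearized, resistance_predictors, D_geo,
                                 max_model_size = NULL) {
  if (!length(resistance_predictors)) stop("need at least one predictor")
  if (is.null(names(resistance_predictors)) ||
      any(!nzchar(names(resistance_predictors))))
    stop("resistance_predictors must be a named list")
  al <- do.call(align_pairwise, c(list(G_linearized), resistance_predictors,
                                  list(D_geo)))
  G <- al[[1]]
  preds <- al[2:(1 + length(resistance_predictors))]
  names(preds) <- names(resistance_predictors)
  Dg <- al[[length(al)]]
  idx <- lower_idx(nrow(G))
  y <- G[idx]
  X <- vapply(preds, function(m) m[idx], numeric(nrow(idx)))
  dgv <- Dg[idx]
  okrow <- is.finite(y) & apply(is.finite(X), 1, all) & is.finite(dgv)
  y <- y[okrow]; X <- X[okrow, , drop = FALSE]; dgv <- dgv[okrow]
  n <- length(y)
  vars <- colnames(X)
  sizes <- seq_along(vars)
  if (!is.null(max_model_size)) sizes <- sizes[sizes <= max_model_size]
  subsets <- unlist(lapply(sizes, function(s) utils::combn(vars, s, simplify = FALSE)),
                    recursive = FALSE)
  fit_one <- function(label, xmat) {
    k <- ncol(xmat) + 2  # coefficients (incl. intercept) + sigma
    if (n <= k + 1) return(NULL)
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, xmat), y)
    rss <- sum(fit$residuals^2)
    logL <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    aicc <- -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    data.frame(model = label, k = k, n = n, logL = logL, AICc = aicc)
  }
  rows <- lapply(subsets, function(ss)
    fit_one(paste(ss, collapse = " + "), X[, ss, drop = FALSE]))
  rows <- c(rows, list(fit_one("IBD (distance only)",
                               matrix(dgv, ncol = 1,
                                      dimnames = list(NULL, "distance")))))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no model could be fit (n too small)")
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AICc), ]
  tab$delta_aicc <- tab$AICc - tab$AICc[1]
  w <- exp(-tab$delta_aicc / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  attr(tab, "n_excluded_pairs") <- sum(!okrow)
  class(tab) <- c("model_table", class(tab))
  tab
}
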