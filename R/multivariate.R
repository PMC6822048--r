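#' Prune collinear covariates
#'
#' Groups covariate columns whose absolute Pearson correlation exceeds
#' `threshold` (groups are the connected components of the threshold graph,
#' so chains of pairwise-correlated variables collapse into one group) and
#' keeps one seeded-random representative per group.
#'
#' @param covariates data.frame or matrix of numeric site-level covariates.
#' @param threshold absolute correlation cutoff.
#' @param seed RNG seed for the per-group choice.
#' @return list: retained (column names), groups (list of grouped names),
#'   decision_log (data.frame column, group, retained).
#' @export
collinearity_prune <- function(covariates, threshold = 0.7, seed = 1) {
  X <- as.matrix(covariates)
  p <- ncol(X)
  cm <- abs(stats::cor(X, use = "pairwise.complete.obs"))
  adj <- cm > threshold
  diag(adj) <- FALSE
  # connected components of the threshold graph
  comp <- rep(0L, p); cur <- 0L
  for (v in seq_len(p)) {
    if (comp[v] > 0) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] > 0) next
      comp[u] <- cur
      queue <- c(queue, which(adj[u, ] & comp == 0L))
    }
  }
  nm <- colnames(X)
  retained <- character(0)
  groups <- split(nm, comp)
  with_seed(seed, {
    for (g in groups)
      retained <- c(retained, if (length(g) == 1) g else sample(g, 1))
  })
  log <- data.frame(column = nm, group = comp,
                    retained = nm %in% retained)
  list(retained = nm[nm %in% retained], groups = unname(groups),
       decision_log = log)
}

#' Multiple regression of a site-level response on covariates
#'
#' OLS with intercept; two-sided t p-values per coefficient, overall F test
#' and adjusted R-squared. Errors on rank deficiency, naming the aliased
#' columns.
#'
#' @param y numeric response vector (one value per site).
#' @param X data.frame or matrix of covariates.
#' @return list: coefficients (data.frame term, beta, se, t, p),
#'   adj_r_squared, r_squared, f_statistic, model_p, n, model (the lm).
#' @export
multiple_regression <- function(y, X) {
  df <- data.frame(y = y, X, check.names = TRUE)
  fit <- stats::lm(y ~ ., data = df)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; aliased columns: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  sm <- summary(fit)
  ct <- sm$coefficients
  fs <- sm$fstatistic
  list(coefficients = data.frame(term = rownames(ct), beta = ct[, 1],
                                 se = ct[, 2], t = ct[, 3], p = ct[, 4],
                                 row.names = NULL),
       adj_r_squared = sm$adj.r.squared, r_squared = sm$r.squared,
       f_statistic = unname(fs[1]),
       model_p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
       n = length(fit$residuals), model = fit)
}

#' Flag sites whose covariate value dwarfs the rest
#'
#' Flags sites whose value exceeds `factor` times the second-largest value
#' in the column (the rule used to drop a site with over twice the light-road
#' length of the next closest site). Removal is left to the caller.
#'
#' @param covariates data.frame with a `site` column (or rownames).
#' @param column covariate column name.
#' @param factor multiplier on the second-largest value.
#' @return character vector of flagged site ids (possibly empty).
#' @export
outlier_rule_max_covariate <- function(covariates, column, factor = 2) {
  v <- covariates[[column]]
  sites <- covariates$site %||% rownames(covariates)
  ord <- order(v, decreasing = TRUE)
  if (length(v) < 2) return(character(0))
  second <- v[ord[2]]
  flagged <- v > factor * second
  as.character(sites[flagged & !is.na(flagged)])
}

#' Multiple matrix regression with randomization (MMRR)
#'
#' Unstandardized OLS of the unfolded lower triangle of a response distance
#' matrix on the unfolded predictors. Significance comes from simultaneously
#' permuting the rows and columns of the response matrix and recomputing the
#' pseudo-t of each coefficient (add-one, two-sided on |t|); the overall F
#' is tested the same way.
#'
#' @param Y response pairwise matrix.
#' @param X named list of predictor pairwise matrices.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list of class `mmrr_result`: coefficients (term, beta, t, p),
#'   r_squared, f_statistic, f_p, n_perm, n_sites.
#' @export
mmrr <- function(Y, X, n_perm = 10000, seed = 1) {
  if (!length(X)) stop("need at least one predictor matrix")
  if (is.null(names(X)) || any(!nzchar(names(X))))
    stop("X must be a named list")
  al <- do.call(align_pairwise, c(list(Y), X))
  Y <- al[[1]]; X <- al[-1]
  n <- nrow(Y)
  idx <- lower_idx(n)
  Xm <- cbind(`(Intercept)` = 1,
              vapply(X, function(m) m[idx], numeric(nrow(idx))))
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    cm <- stats::cor(Xm[, -1, drop = FALSE])
    bad <- which(abs(cm) > 0.9999 & upper.tri(cm), arr.ind = TRUE)
    stop("collinear predictor matrices",
         if (nrow(bad)) paste0(": ", colnames(cm)[bad[1, 1]], " vs ",
                               colnames(cm)[bad[1, 2]]) else "")
  }
  fit_stats <- function(yv) {
    fit <- stats::lm.fit(Xm, yv)
    rss <- sum(fit$residuals^2)
    dfres <- length(yv) - ncol(Xm)
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(diag(XtXinv) * rss / dfres)
    tss <- sum((yv - mean(yv))^2)
    r2 <- 1 - rss / tss
    f <- (r2 / (ncol(Xm) - 1)) / ((1 - r2) / dfres)
    list(beta = fit$coefficients, t = fit$coefficients / se, r2 = r2, f = f)
  }
  obs <- fit_stats(Y[idx])
  k <- ncol(Xm)
  hits <- with_seed(seed, {
    ht <- rep(0L, k); hf <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      st <- fit_stats(Y[cbind(p[idx[, 1]], p[idx[, 2]])])
      ht <- ht + (abs(st$t) >= abs(obs$t) - 1e-12)
      hf <- hf + (st$f >= obs$f - 1e-12)
    }
    list(t = ht, f = hf)
  })
  hits_t <- hits$t; hits_f <- hits$f
  structure(list(
    coefficients = data.frame(term = colnames(Xm), beta = unname(obs$beta),
                              t = unname(obs$t),
                              p = unname((hits_t + 1) / (n_perm + 1))),
    r_squared = obs$r2, f_statistic = obs$f,
    f_p = (hits_f + 1) / (n_perm + 1),
    n_perm = n_perm, n_sites = n), class = "mmrr_result")
}

#' Distance-based redundancy analysis with conditioning and backward
#' elimination
#'
#' Embeds the response pairwise matrix by principal coordinates (vegan's
#' `capscale`, Lingoes correction for negative eigenvalues, logged when it
#' fires), conditions on the supplied matrix (latitude and longitude in
#' decimal degrees, untransformed), and tests each explanatory term by
#' permutation of residuals under the reduced model. Backward elimination
#' drops the largest-p nonsignificant term, refits, and repeats until all
#' remaining terms have p < alpha. Variance is partitioned via adjusted
#' R-squared: explanatory (given the condition), condition alone, and the
#' combined model.
#'
#' @param G response pairwise matrix (e.g. pairwise G_ST); values are offset
#'   to nonnegative before embedding if needed (logged).
#' @param X data.frame of site-level explanatory covariates.
#' @param condition data.frame (or matrix) of conditioning covariates,
#'   typically lat and lon.
#' @param n_perm permutations for term tests.
#' @param alpha retention threshold.
#' @param seed RNG seed.
#' @return list of class `dbrda_result`: retained (data.frame term, F, p),
#'   eliminated (character), varpart (explanatory, condition, combined
#'   adjusted R-squared), correction_log, model (the final capscale fit, or
#'   NULL when all terms were eliminated).
#' @export
dbrda <- function(G, X, condition, n_perm = 10000, alpha = 0.05, seed = 1) {
  X <- as.data.frame(X)
  condition <- as.data.frame(condition)
  ids <- rownames(G)
  if (!is.null(rownames(X)) && setequal(rownames(X), ids)) X <- X[ids, , drop = FALSE]
  if (!is.null(rownames(condition)) && setequal(rownames(condition), ids))
    condition <- condition[ids, , drop = FALSE]
  correction_log <- character(0)
  gmin <- min(G[lower.tri(G)], na.rm = TRUE)
  Gd <- G
  if (gmin < 0) {
    Gd <- G - gmin
    diag(Gd) <- 0
    correction_log <- c(correction_log,
                        sprintf("offset %.6g added to make dissimilarities nonnegative", -gmin))
  }
  dg <- stats::as.dist(Gd)
  dat <- cbind(X, condition)
  cond_terms <- colnames(condition)
  terms <- colnames(X)
  make_formula <- function(tt) {
    rhs <- if (length(tt)) paste(tt, collapse = " + ") else "1"
    stats::as.formula(paste("dg ~", rhs, "+ Condition(",
                            paste(cond_terms, collapse = " + "), ")"))
  }
  eliminated <- character(0)
  fit <- NULL
  repeat {
    if (!length(terms)) { fit <- NULL; break }
    fit <- with_seed(seed, vegan::capscale(make_formula(terms), data = dat,
                                           add = "lingoes"))
    an <- with_seed(seed, stats::anova(fit, by = "margin",
                                       permutations = n_perm))
    pv <- an[["Pr(>F)"]][seq_along(terms)]
    names(pv) <- rownames(an)[seq_along(terms)]
    if (all(pv < alpha, na.rm = TRUE)) break
    drop_t <- names(pv)[which.max(pv)]
    eliminated <- c(eliminated, drop_t)
    terms <- setdiff(terms, drop_t)
  }
  if (any(vegan::eigenvals(with_seed(seed,
        vegan::capscale(dg ~ 1, add = "lingoes"))) < -1e-10))
    correction_log <- c(correction_log, "negative eigenvalues after Lingoes")
  adj <- function(f) {
    v <- vegan::RsquareAdj(f)$adj.r.squared
    if (is.null(v) || !length(v)) NA_real_ else v
  }
  varpart <- list(explanatory = NA_real_, condition = NA_real_,
                  combined = NA_real_)
  cond_only <- with_seed(seed, vegan::capscale(
    stats::as.formula(paste("dg ~", paste(cond_terms, collapse = " + "))),
    data = dat, add = "lingoes"))
  varpart$condition <- adj(cond_only)
  if (length(terms)) {
    varpart$explanatory <- adj(fit)
    comb <- with_seed(seed, vegan::capscale(
      stats::as.formula(paste("dg ~", paste(c(terms, cond_terms), collapse = " + "))),
      data = dat, add = "lingoes"))
    varpart$combined <- adj(comb)
    an <- with_seed(seed, stats::anova(fit, by = "margin", permutations = n_perm))
    retained <- data.frame(term = terms,
                           F = an$F[seq_along(terms)],
                           p = an[["Pr(>F)"]][seq_along(terms)])
  } else {
    retained <- data.frame(term = character(0), F = numeric(0), p = numeric(0))
    varpart$combined <- varpart$condition
    varpart$explanatory <- 0
  }
  structure(list(retained = retained, eliminated = eliminated,
                 varpart = varpart, correction_log = correction_log,
                 model = fit),
            class = "dbrda_result")
}
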