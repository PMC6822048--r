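#' Isolation-by-distance regression
#'
#' Regresses linearized genetic differentiation on geographic distance over
#' the off-diagonal site pairs. Supported mean-regression forms: `linear`
#' (y ~ x), `quadratic` (y ~ x + x^2), and `log-x` (y ~ log(x), natural
#' log; zero-distance pairs are dropped with a warning). Optional quantile
#' regressions (default 5th and 95th percentiles) are fit by check-loss
#' minimization and describe the envelope of the IBD scatter.
#'
#' @param G_linearized pairwise matrix of linearized differentiation.
#' @param D pairwise matrix of geographic distance (km).
#' @param form one of "linear", "quadratic", "log-x".
#' @param quantiles numeric vector of quantile levels, or NULL to skip.
#' @return object of class `ibd_fit`: form, coefficients, r_squared,
#'   residual_matrix (pairwise), quantile_fits (per-level coefficient rows),
#'   model (the lm fit), n_pairs.
#' @export
ibd_regression <- function(G_linearized, D, form = c("linear", "quadratic", "log-x"),
                           quantiles = NULL) {
  form <- match.arg(form)
  al <- align_pairwise(G_linearized, D)
  G <- al[[1]]; D <- al[[2]]
  idx <- lower_idx(nrow(G))
  y <- G[idx]; x <- D[idx]
  keep <- !is.na(y) & !is.na(x)
  if (form == "log-x" && any(x[keep] <= 0)) {
    warning("dropping ", sum(x[keep] <= 0), " zero-distance pairs for log-x form")
    keep <- keep & x > 0
  }
  need <- if (form == "quadratic") 4 else 3
  if (sum(keep) < need) stop("too few pairs for form ", form)
  df <- data.frame(y = y[keep], x = x[keep])
  fit <- switch(form,
    "linear" = stats::lm(y ~ x, data = df),
    "quadratic" = stats::lm(y ~ x + I(x^2), data = df),
    "log-x" = stats::lm(y ~ log(x), data = df))
  res <- rep(NA_real_, length(y))
  res[keep] <- stats::residuals(fit)
  rmat <- matrix(NA_real_, nrow(G), nrow(G), dimnames = dimnames(G))
  rmat[idx] <- res
  rmat[idx[, c(2, 1)]] <- res
  diag(rmat) <- 0
  qfits <- NULL
  if (!is.null(quantiles)) {
    xq <- if (form == "log-x") log(df$x) else df$x
    qfits <- do.call(rbind, lapply(quantiles, function(tau) {
      cf <- quantile_line_fit(xq, df$y, tau)
      data.frame(tau = tau, intercept = cf[1], slope = cf[2])
    }))
  }
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((df$y - mean(df$y))^2)
  structure(list(form = form, coefficients = stats::coef(fit),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 residual_matrix = pairwise_matrix(rmat, rownames(G), "ibd_residual"),
                 quantile_fits = qfits, model = fit, n_pairs = sum(keep)),
            class = "ibd_fit")
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat("IBD regression (", x$form, "), ", x$n_pairs, " pairs\n", sep = "")
  print(x$coefficients)
  cat(sprintf("R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' Quantile regression line by check-loss minimization
#'
#' Fits `y ~ a + b x` at quantile level `tau` by minimizing the check
#' (pinball) loss. A smoothed iteratively reweighted least-squares pass
#' localises the optimum, which is then polished exactly: an optimal
#' quantile line interpolates two data points, so all point pairs among the
#' low-residual points are enumerated and the pair with minimal check loss
#' is returned.
#'
#' @param x,y numeric vectors.
#' @param tau quantile level in (0, 1).
#' @param polish_k number of smallest-|residual| points enumerated in the
#'   exact polishing step.
#' @return numeric c(intercept, slope).
#' @export
quantile_line_fit <- function(x, y, tau, polish_k = 80) {
  stopifnot(length(x) == length(y), tau > 0, tau < 1)
  n <- length(x)
  check_loss <- function(a, b) {
    u <- y - a - b * x
    sum(u * (tau - (u < 0)))
  }
  # smoothed IRLS (Schlossmacher-type) from the OLS start
  cf <- stats::coef(stats::lm(y ~ x))
  delta <- max(1e-6 * stats::sd(y), 1e-12)
  for (it in 1:60) {
    u <- y - cf[1] - cf[2] * x
    w <- ifelse(u >= 0, tau, 1 - tau) / pmax(abs(u), delta)
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    new <- fit$coefficients
    if (max(abs(new - cf)) < 1e-12) { cf <- new; break }
    cf <- new
  }
  # exact polish: enumerate candidate lines through pairs of nearby points
  u <- y - cf[1] - cf[2] * x
  ord <- order(abs(u))[seq_len(min(polish_k, n))]
  best <- c(cf[1], cf[2]); best_loss <- check_loss(cf[1], cf[2])
  for (ii in seq_along(ord)) for (kk in seq_along(ord)) {
    if (kk <= ii) next
    i <- ord[ii]; k <- ord[kk]
    if (x[i] == x[k]) next
    b <- (y[k] - y[i]) / (x[k] - x[i])
    a <- y[i] - b * x[i]
    l <- check_loss(a, b)
    if (l < best_loss - 1e-12) { best <- c(a, b); best_loss <- l }
  }
  stats::setNames(best, c("intercept", "slope"))
}

#' IBD scaling profile over expanding distance-sorted subsets
#'
#' Sorts site pairs by geographic distance (ties broken by site-id order so
#' profiles are reproducible) and, for each m from `start_pairs` to the
#' total number of pairs, fits an OLS line (its own intercept per window) to
#' the m shortest pairs. Case-resampling bootstrap of the m pairs gives a
#' percentile confidence interval for each slope. The profile is indexed by
#' the m-th (maximum included) distance.
#'
#' @param G_linearized pairwise matrix of linearized differentiation.
#' @param D pairwise matrix of geographic distance (km).
#' @param start_pairs first window size.
#' @param n_boot bootstrap replicates per window.
#' @param ci confidence level.
#' @param seed RNG seed.
#' @param step window-size increment (1 reproduces the full profile; larger
#'   values thin the windows for speed).
#' @return data.frame of class rows: m, max_distance_km, beta, ci_lo, ci_hi,
#'   degenerate flag.
#' @export
ibd_scaling_profile <- function(G_linearized, D, start_pairs = 20,
                                n_boot = 1000, ci = 0.95, seed = 1, step = 1) {
  al <- align_pairwise(G_linearized, D)
  G <- al[[1]]; D <- al[[2]]
  ids <- rownames(G)
  idx <- lower_idx(nrow(G))
  x <- D[idx]; y <- G[idx]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  pi_ <- ids[idx[keep, 1]]; pj <- ids[idx[keep, 2]]
  M <- length(x)
  if (M < start_pairs) stop("fewer pairs than start_pairs")
  ord <- order(x, pmin(pi_, pj), pmax(pi_, pj))
  x <- x[ord]; y <- y[ord]
  a <- (1 - ci) / 2
  ms <- unique(c(seq(start_pairs, M, by = step), M))
  out <- with_seed(seed, {
    rows <- vector("list", length(ms))
    for (w in seq_along(ms)) {
      m <- ms[w]
      xs <- x[seq_len(m)]; ys <- y[seq_len(m)]
      if (stats::var(xs) == 0) {
        rows[[w]] <- data.frame(m = m, max_distance_km = xs[m], beta = NA_real_,
                                ci_lo = NA_real_, ci_hi = NA_real_,
                                degenerate = TRUE)
        next
      }
      beta <- ols_slope(xs, ys)
      bs <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        ii <- sample.int(m, m, replace = TRUE)
        bs[b] <- ols_slope(xs[ii], ys[ii])
      }
      bs <- bs[is.finite(bs)]
      q <- if (length(bs)) stats::quantile(bs, c(a, 1 - a), names = FALSE)
           else c(NA_real_, NA_real_)
      rows[[w]] <- data.frame(m = m, max_distance_km = xs[m], beta = beta,
                              ci_lo = q[1], ci_hi = q[2], degenerate = FALSE)
    }
    do.call(rbind, rows)
  })
  out
}

# slope of y ~ x by moments (NA-free inputs)
ols_slope <- function(x, y) {
  mx <- mean(x)
  vx <- sum((x - mx)^2)
  if (vx == 0) return(NA_real_)
  sum((x - mx) * (y - mean(y))) / vx
}

#' Per-site isolation index from IBD residuals
#'
#' The isolation index of site s is the mean of the IBD regression residuals
#' over all pairs that include s. Larger values indicate more genetic
#' differentiation than geographic distance predicts. With a complete
#' design, the indices sum to approximately zero (an OLS-with-intercept
#' residual property).
#'
#' @param fit an `ibd_fit` from [ibd_regression()], or a residual pairwise
#'   matrix.
#' @return data.frame: site, isolation, n_pairs, all_missing flag.
#' @export
site_isolation_index <- function(fit) {
  rmat <- if (inherits(fit, "ibd_fit")) fit$residual_matrix else fit
  n <- nrow(rmat)
  out <- data.frame(site = rownames(rmat),
                    isolation = NA_real_, n_pairs = 0L, all_missing = FALSE)
  for (s in seq_len(n)) {
    v <- rmat[s, -s]
    ok <- !is.na(v)
    out$n_pairs[s] <- sum(ok)
    if (!any(ok)) { out$all_missing[s] <- TRUE; next }
    out$isolation[s] <- mean(v[ok])
  }
  out
}
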