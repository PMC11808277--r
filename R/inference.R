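# Regression layer: collinearity screening, OLS with backward selection,
# LMG relative importance, the adjusted-R2 scan over the phylogeny weight a,
# and Moran's I spatial autocorrelation.

#' Spearman collinearity screen of environmental covariates
#'
#' Rank correlations (average ranks for ties) among all covariate columns;
#' covariates in at least one pair with `|rho| >= threshold` are flagged.
#' Within each flagged pair the member with the larger number of
#' high-correlation partners (ties broken by larger mean absolute rho) is
#' proposed for removal.  Constant covariates yield undefined correlations
#' and are flagged separately.
#'
#' @param env data.frame of per-site covariates; coordinate columns (per the
#'   `coord_cols` attribute, or `exclude`) are skipped.
#' @param threshold absolute Spearman correlation triggering a flag
#'   (default 0.7).
#' @param exclude column names to skip.
#' @return list: `correlations` (full Spearman matrix), `flagged_pairs`
#'   (data.frame var1, var2, rho), `removal` (proposed covariates to drop),
#'   `constant` (undefined covariates).
#' @export
spearman_screen <- function(env, threshold = 0.7,
                            exclude = attr(env, "coord_cols")) {
  .assert(nrow(env) >= 3, "need at least 3 sites for a correlation screen")
  cols <- setdiff(colnames(env), exclude)
  x <- as.matrix(env[, cols, drop = FALSE])
  const <- cols[apply(x, 2, function(v) var(v) == 0)]
  rho <- suppressWarnings(cor(x, method = "spearman"))
  pairs <- which(upper.tri(rho) & abs(rho) >= threshold & !is.na(rho), arr.ind = TRUE)
  flagged <- data.frame(var1 = cols[pairs[, 1]], var2 = cols[pairs[, 2]],
                        rho = rho[pairs], stringsAsFactors = FALSE)
  removal <- character(0)
  if (nrow(flagged)) {
    involved <- unique(c(flagged$var1, flagged$var2))
    n_partners <- vapply(involved, function(v)
      sum(flagged$var1 == v | flagged$var2 == v), integer(1))
    mean_abs <- vapply(involved, function(v)
      mean(abs(flagged$rho[flagged$var1 == v | flagged$var2 == v])), numeric(1))
    for (i in seq_len(nrow(flagged))) {
      a <- flagged$var1[i]; b <- flagged$var2[i]
      pick <- if (n_partners[a] != n_partners[b]) {
        if (n_partners[a] > n_partners[b]) a else b
      } else if (mean_abs[a] != mean_abs[b]) {
        if (mean_abs[a] > mean_abs[b]) a else b
      } else sort(c(a, b))[1]
      removal <- union(removal, pick)
    }
  }
  list(correlations = rho, flagged_pairs = flagged, removal = removal,
       constant = const, threshold = threshold)
}

#' Ordinary least squares of SES on covariates
#'
#' OLS with intercept via [stats::lm()]; coefficient p-values from the t
#' distribution; adjusted R2 = 1 - (1 - R2)(n - 1)/(n - k - 1).
#'
#' @param y response vector (e.g. per-site SES.MFPD), no NA.
#' @param X data.frame of covariates (rows = sites).
#' @param removal_trace carried through from [backward_select()].
#' @return list of class `regression_result`: `coefficients` (estimate, se,
#'   t, p per term), `r_squared`, `adj_r_squared`, `n`, `covariates`,
#'   `removal_trace`, `model` (the lm fit).
#' @export
fit_ols <- function(y, X, removal_trace = NULL) {
  X <- as.data.frame(X)
  .assert(!anyNA(y), "response contains NA; drop flagged sites first")
  .assert(nrow(X) == length(y), "X and y dimensions differ")
  k <- ncol(X)
  .assert(length(y) > k + 1, "need n > k + 1 observations")
  dat <- cbind(.y = y, X)
  fit <- lm(.y ~ ., data = dat)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  colnames(ct) <- c("estimate", "se", "t", "p")
  structure(list(coefficients = ct, r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared, n = length(y),
                 covariates = colnames(X), removal_trace = removal_trace,
                 model = fit),
            class = "regression_result")
}

#' Backward selection on coefficient significance
#'
#' Starting from the full model, repeatedly removes the covariate with the
#' largest coefficient p-value while any covariate has p > alpha.  The
#' intercept is never removed.  If every covariate falls, an intercept-only
#' model is returned with a warning.
#'
#' @inheritParams fit_ols
#' @param alpha significance level for retention (default 0.05).
#' @return a `regression_result` for the final model; `removal_trace`
#'   records each dropped covariate with its p-value at removal.
#' @export
backward_select <- function(y, X, alpha = 0.05) {
  X <- as.data.frame(X)
  trace <- data.frame(covariate = character(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  repeat {
    if (ncol(X) == 0) {
      warning("all covariates removed; returning intercept-only model", call. = FALSE)
      fit <- lm(y ~ 1)
      sm <- summary(fit)
      ct <- as.data.frame(sm$coefficients)
      colnames(ct) <- c("estimate", "se", "t", "p")
      return(structure(list(coefficients = ct, r_squared = 0,
                            adj_r_squared = 0, n = length(y),
                            covariates = character(0), removal_trace = trace,
                            model = fit),
                       class = "regression_result"))
    }
    res <- fit_ols(y, X, removal_trace = trace)
    p <- res$coefficients$p[-1]  # skip intercept
    if (all(p <= alpha)) return(res)
    worst <- which.max(p)
    trace <- rbind(trace, data.frame(covariate = colnames(X)[worst],
                                     p = p[worst], stringsAsFactors = FALSE))
    X <- X[, -worst, drop = FALSE]
  }
}

#' LMG relative importance decomposition
#'
#' Each covariate's share is its sequential increment to R2 averaged over
#' all orderings of the covariates (computed via the equivalent weighted
#' average over subsets).  Shares sum to the full model's R2; also reported
#' normalized to percent of R2.
#'
#' @inheritParams fit_ols
#' @return data.frame: covariate, share (raw R2 units), pct_of_r2; with
#'   attributes `r_squared` and `adj_r_squared` of the full model.
#' @export
lmg_importance <- function(y, X) {
  X <- as.data.frame(X)
  k <- ncol(X)
  .assert(k >= 1, "need at least one covariate")
  .assert(k <= 10, "LMG enumerates subsets; limited to k <= 10 covariates")
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    summary(lm(.y ~ ., data = cbind(.y = y, X[, cols, drop = FALSE]),
               model = FALSE))$r.squared
  }
  # cache R2 for every subset, keyed by sorted column indices
  cache <- new.env(parent = emptyenv())
  r2c <- function(cols) {
    key <- paste0("k", paste(cols, collapse = ","))
    if (is.null(cache[[key]])) cache[[key]] <- r2(cols)
    cache[[key]]
  }
  shares <- numeric(k)
  for (j in seq_len(k)) {
    others <- setdiff(seq_len(k), j)
    total <- 0
    for (sz in 0:length(others)) {
      w <- factorial(sz) * factorial(k - sz - 1) / factorial(k)
      subs <- if (sz == 0) list(integer(0)) else
        utils::combn(others, sz, simplify = FALSE)
      for (s in subs) total <- total + w * (r2c(sort(c(s, j))) - r2c(sort(s)))
    }
    shares[j] <- total
  }
  full <- fit_ols(y, X)
  out <- data.frame(covariate = colnames(X), share = shares,
                    pct_of_r2 = 100 * shares / full$r_squared,
                    stringsAsFactors = FALSE)
  attr(out, "r_squared") <- full$r_squared
  attr(out, "adj_r_squared") <- full$adj_r_squared
  out
}

#' Scan the phylogeny weight a for the best-explained SES
#'
#' For every `a` in the grid: build FPDist(a), compute SES.MFPD and the
#' competition covariate COMP (= FPDve), regress SES on the full covariate
#' set plus COMP, and record the adjusted R2.  The optimal `a*` maximizes
#' adjusted R2.  One null-randomization stream (fixed seed) is shared across
#' the whole grid so differences in fit reflect `a`, not Monte-Carlo noise.
#'
#' @param comm community matrix, aligned with `fd`/`pd`.
#' @param fd functional distance matrix.
#' @param pd phylogenetic distance matrix.
#' @param env covariate data.frame (coordinate columns excluded
#'   automatically via its `coord_cols` attribute).
#' @param spec a [null_spec()].
#' @param a_grid grid of weights in \[0, 1\] (default 0 to 1 step 0.01).
#' @param p FPDist exponent.
#' @param retention_rule passed to the per-site PCoA inside FPDve.
#' @return object of class `a_scan`: `a_grid`, `adj_r_squared` per a,
#'   `a_star`, `max_adj_r_squared`, `ses` and `comp` matrices
#'   (sites x grid), `sites_used`, `fits` (per-a `regression_result`).
#' @export
scan_a <- function(comm, fd, pd, env, spec = null_spec(),
                   a_grid = seq(0, 1, by = 0.01), p = 2,
                   retention_rule = list(threshold = 0.8)) {
  validate_community(comm)
  .assert(all(a_grid >= 0 & a_grid <= 1), "a_grid must lie in [0, 1]")
  .assert(length(a_grid) >= 1, "empty a_grid")
  cols <- setdiff(colnames(env), attr(env, "coord_cols"))
  Xenv <- as.data.frame(env[, cols, drop = FALSE])
  m <- nrow(comm)
  stack <- .null_stack(comm, spec)
  ses_mat <- matrix(NA_real_, m, length(a_grid),
                    dimnames = list(rownames(comm), paste0("a", a_grid)))
  comp_mat <- ses_mat
  adj <- numeric(length(a_grid))
  fits <- vector("list", length(a_grid))
  for (g in seq_along(a_grid)) {
    d_a <- fpdist(fd, pd, fpdist_spec(a_grid[g], p = p))
    nulls <- .null_mpd(stack, d_a, m)
    s <- ses_mfpd(comm, d_a, spec, null_stats = nulls)
    ev <- fpdve_per_site(comm, d_a, retention_rule)
    ok <- s$flag == "ok" & ev$flag == "ok"
    if (!any(ok))
      stop("a-scan aborted: all sites flagged at a = ", a_grid[g], call. = FALSE)
    ses_mat[, g] <- s$ses
    comp_mat[, g] <- ev$fpdve
    X <- cbind(Xenv[ok, , drop = FALSE], COMP = ev$fpdve[ok])
    fits[[g]] <- fit_ols(s$ses[ok], X)
    adj[g] <- fits[[g]]$adj_r_squared
  }
  g_star <- which.max(adj)
  structure(list(a_grid = a_grid, adj_r_squared = adj,
                 a_star = a_grid[g_star], max_adj_r_squared = adj[g_star],
                 ses = ses_mat, comp = comp_mat,
                 sites_used = rownames(comm), fits = fits,
                 p = p, null = spec),
            class = "a_scan")
}

#' @export
print.a_scan <- function(x, ...) {
  cat("a-scan over", length(x$a_grid), "weights\n")
  cat("  a* =", x$a_star, " max adjusted R2 =",
      formatC(x$max_adj_r_squared, digits = 4, format = "f"), "\n")
  invisible(x)
}

#' Moran's I spatial autocorrelation of SES values
#'
#' Great-circle (haversine, radius 6,378,137 m) distances between sites,
#' inverse-distance weights (diagonal 0, not row-standardized), Moran's I
#' with expectation -1/(n-1) and a two-tailed p-value from the normal
#' approximation (via [ape::Moran.I()]).
#'
#' @param values per-site values (e.g. SES.MFPD), no NA.
#' @param coords two-column matrix/data.frame of longitude, latitude in
#'   decimal degrees.
#' @return list of class `moran_result`: observed, expected, sd, p_value,
#'   n; observed is `NA`-flagged for constant input.
#' @export
morans_i <- function(values, coords) {
  .assert(!anyNA(values), "values contain NA; drop flagged sites first")
  n <- length(values)
  .assert(n >= 4, "need at least 4 sites for Moran's I")
  coords <- as.matrix(coords)
  .assert(ncol(coords) == 2 && nrow(coords) == n, "coords must be n x 2 (lon, lat)")
  dm <- geosphere::distm(coords)
  off <- dm[upper.tri(dm)]
  if (any(off == 0))
    stop("coincident site coordinates give zero distance; jitter or exclude sites",
         call. = FALSE)
  if (var(values) == 0) {
    warning("constant values: Moran's I undefined", call. = FALSE)
    return(structure(list(observed = NA_real_, expected = -1 / (n - 1),
                          sd = NA_real_, p_value = NA_real_, n = n),
                     class = "moran_result"))
  }
  w <- 1 / dm
  diag(w) <- 0
  mi <- ape::Moran.I(values, w, alternative = "two.sided")
  structure(list(observed = mi$observed, expected = mi$expected,
                 sd = mi$sd, p_value = mi$p.value, n = n),
            class = "moran_result")
}
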