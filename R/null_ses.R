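# Mean pairwise distance per site and its standardized effect size against
# occurrence-frequency-preserving null communities.

#' Null-model specification
#'
#' @param algorithm `"frequency"` (permute each species' presences across
#'   sites, preserving species occurrence frequencies; the default),
#'   `"richness"` (permute within sites, preserving site richness), or
#'   `"independentswap"` (both margins preserved, via
#'   [picante::randomizeMatrix()]).
#' @param n_iterations number of randomized communities (>= 1). 999 is the
#'   conventional choice for SES; envelope curves default to 1000.
#' @param seed integer seed for the randomization stream.
#' @return list of class `null_spec`.
#' @export
null_spec <- function(algorithm = "frequency", n_iterations = 999, seed = 1L) {
  algorithm <- match.arg(algorithm, c("frequency", "richness", "independentswap"))
  .assert(is.numeric(n_iterations) && n_iterations >= 1, "n_iterations must be >= 1")
  structure(list(algorithm = algorithm, n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "null_spec")
}

#' Mean pairwise distance of one community
#'
#' Mean of the distance matrix over the unordered pairs of species present
#' at the site.  Undefined (NA, with a warning) below richness 2.
#'
#' @param presence 0/1 (or logical) vector over the species in `d`'s order.
#' @param d labelled distance matrix.
#' @return a single number, or `NA` for richness < 2.
#' @export
mpd <- function(presence, d) {
  .assert(length(presence) == nrow(d), "presence vector length must match d")
  idx <- which(presence > 0)
  if (length(idx) < 2) {
    warning("mpd undefined for richness < 2", call. = FALSE)
    return(NA_real_)
  }
  sub <- d[idx, idx]
  mean(sub[upper.tri(sub)])
}

# vectorised MPD for all sites of a stacked presence matrix X (sites x species):
# sum over ordered present pairs is rowSums((X %*% D) * X); divide by S(S-1).
mpd_all <- function(X, d) {
  s <- rowSums(X)
  tot <- rowSums((X %*% d) * X)
  out <- tot / (s * (s - 1))
  out[s < 2] <- NA_real_
  out
}

#' Randomize a community matrix under a null algorithm
#'
#' `"frequency"` independently permutes each species' column of presences
#' across sites (species occurrence frequencies preserved exactly);
#' `"richness"` permutes within each site row (richness preserved);
#' `"independentswap"` delegates to [picante::randomizeMatrix()].
#' Reproducible under the seed carried by `spec`.
#'
#' @param comm community matrix (sites x species, 0/1).
#' @param spec a [null_spec()].
#' @return randomized community matrix with the same dimnames.
#' @export
randomize <- function(comm, spec) {
  validate_community(comm)
  .assert(inherits(spec, "null_spec"), "spec must be a null_spec")
  set.seed(spec$seed)
  out <- .randomize_once(comm, spec$algorithm)
  attr(out, "richness") <- rowSums(out)
  out
}

.randomize_once <- function(comm, algorithm) {
  out <- switch(algorithm,
    frequency = apply(comm, 2, function(col) col[sample.int(length(col))]),
    richness  = t(apply(comm, 1, function(row) row[sample.int(length(row))])),
    independentswap = picante::randomizeMatrix(comm, null.model = "independentswap")
  )
  dimnames(out) <- dimnames(comm)
  out
}

# Stack of n_iter randomized matrices as one (n_iter*m) x n 0/1 matrix, so a
# single BLAS call per distance matrix yields every null MPD.  The stream is
# a pure function of spec$seed, so the same stack can be rebuilt (or reused)
# across an a-grid.
.null_stack <- function(comm, spec) {
  set.seed(spec$seed)
  m <- nrow(comm)
  do.call(rbind, lapply(seq_len(spec$n_iterations),
                        function(i) .randomize_once(comm, spec$algorithm)))
}

# null MPD matrix (n_iterations x n_sites) from a prebuilt stack
.null_mpd <- function(stack, d, m) {
  matrix(mpd_all(stack, d), ncol = m, byrow = TRUE)
}

#' Standardized effect size of mean functional-phylogenetic distance
#'
#' For every site: observed MFPD, the null distribution of MFPD over
#' `n_iterations` matrix-level randomizations (one shared stream for all
#' sites), SES = (observed - null mean) / null SD (sample SD), the rank
#' quantile of the observation within the null draws, and the two-tailed
#' p-value `2 * min(q, 1 - q)` clipped to (0, 1].  Sites with richness < 2
#' or a degenerate null (SD = 0) are reported but flagged; flagged sites are
#' excluded from downstream regressions.
#'
#' Negative SES marks functional-phylogenetic clustering (co-occurring
#' species more similar than chance), positive SES over-dispersion.
#'
#' @param comm community matrix (sites x species), labels aligned with `d`.
#' @param d interspecific distance matrix (typically [fpdist()]).
#' @param spec a [null_spec()].
#' @param null_stats optional precomputed null MPD matrix
#'   (`n_iterations` x sites) to reuse one randomization stream across many
#'   distance matrices; used by [scan_a()].
#' @return data.frame of class `ses_result`: site, richness, observed_mfpd,
#'   null_mean, null_sd, ses, rank_quantile, p_value, flag.
#' @export
ses_mfpd <- function(comm, d, spec = null_spec(), null_stats = NULL) {
  validate_community(comm)
  validate_distance(d)
  .assert(identical(colnames(comm), rownames(d)),
          "community species and distance labels must match in order")
  m <- nrow(comm)
  obs <- mpd_all(comm, d)
  if (is.null(null_stats)) {
    stack <- .null_stack(comm, spec)
    null_stats <- .null_mpd(stack, d, m)
  }
  null_mean <- colMeans(null_stats, na.rm = TRUE)
  null_sd <- apply(null_stats, 2, sd, na.rm = TRUE)
  ses <- ifelse(null_sd > 0, (obs - null_mean) / null_sd, NA_real_)
  n_it <- nrow(null_stats)
  rq <- vapply(seq_len(m), function(i) {
    if (is.na(obs[i])) return(NA_real_)
    nulls <- null_stats[, i]
    (sum(nulls < obs[i], na.rm = TRUE) + 0.5 * sum(nulls == obs[i], na.rm = TRUE) + 0.5) /
      (sum(!is.na(nulls)) + 1)
  }, numeric(1))
  p <- pmin(pmax(2 * pmin(rq, 1 - rq), .Machine$double.eps), 1)
  flag <- rep("ok", m)
  flag[rowSums(comm) < 2] <- "richness_lt_2"
  flag[flag == "ok" & !(null_sd > 0)] <- "degenerate_null"
  flag[flag == "ok" & is.na(ses)] <- "undefined"
  out <- data.frame(site = rownames(comm), richness = rowSums(comm),
                    observed_mfpd = obs, null_mean = null_mean, null_sd = null_sd,
                    ses = ses, rank_quantile = rq, p_value = p, flag = flag,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_iterations") <- if (is.null(spec)) n_it else spec$n_iterations
  attr(out, "seed") <- if (is.null(spec)) NA_integer_ else spec$seed
  class(out) <- c("ses_result", class(out))
  out
}
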