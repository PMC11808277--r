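# MFPD-versus-a curves with null envelopes, and classification of each
# site's assembly regime from where the observed curve leaves the envelope.

#' Observed MFPD and null envelopes across the a-grid
#'
#' For every site and every `a`: the observed MFPD under FPDist(a) and the
#' quantiles of its null distribution over `n_null` randomized communities.
#' The same randomized matrices are reused across the whole grid.  Bands:
#' outer 95% (0.025-0.975), middle 50% (0.25-0.75) and a central 1% band
#' (0.495-0.505) tracing the null median.  Sites with richness < 2 are
#' omitted with a warning.
#'
#' @param comm community matrix aligned with `fd`/`pd`.
#' @param fd functional distance matrix.
#' @param pd phylogenetic distance matrix.
#' @param a_grid weights in \[0, 1\].
#' @param n_null number of randomized communities (default 1000).
#' @param seed randomization seed.
#' @param algorithm null algorithm, see [null_spec()].
#' @param p FPDist exponent.
#' @return long data.frame of class `envelope_curve`: site, a, observed,
#'   q025, q25, q495, q505, q75, q975; attributes `n_null` and `seed`.
#' @export
envelope <- function(comm, fd, pd, a_grid = seq(0, 1, by = 0.05),
                     n_null = 1000, seed = 1L, algorithm = "frequency", p = 2) {
  validate_community(comm)
  keep <- rowSums(comm) >= 2
  if (!all(keep)) {
    warning("omitting site(s) with richness < 2: ",
            paste(rownames(comm)[!keep], collapse = ", "), call. = FALSE)
    comm <- comm[keep, , drop = FALSE]
  }
  spec <- null_spec(algorithm, n_iterations = n_null, seed = seed)
  stack <- .null_stack(comm, spec)
  m <- nrow(comm)
  probs <- c(0.025, 0.25, 0.495, 0.505, 0.75, 0.975)
  rows <- vector("list", length(a_grid))
  for (g in seq_along(a_grid)) {
    d_a <- fpdist(fd, pd, fpdist_spec(a_grid[g], p = p))
    obs <- mpd_all(comm, d_a)
    nulls <- .null_mpd(stack, d_a, m)
    q <- apply(nulls, 2, quantile, probs = probs, na.rm = TRUE)
    rows[[g]] <- data.frame(site = rownames(comm), a = a_grid[g], observed = obs,
                            q025 = q[1, ], q25 = q[2, ], q495 = q[3, ],
                            q505 = q[4, ], q75 = q[5, ], q975 = q[6, ],
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$site, out$a), ]
  rownames(out) <- NULL
  attr(out, "n_null") <- n_null
  attr(out, "seed") <- seed
  class(out) <- c("envelope_curve", class(out))
  out
}

#' Classify per-site assembly regimes from an envelope curve
#'
#' A grid point is significant when the observed MFPD lies outside the 95%
#' null band.  With `low` = the fraction of significant points over
#' `a` in \[0, 0.25\] and `high` = over \[0.75, 1\]:
#' \describe{
#'   \item{matched_with_signal}{both ends significant: the measured traits
#'     match the assembly process and carry phylogenetic signal.}
#'   \item{trait_matched_weak_signal}{significant only at small `a`:
#'     traits match the process but their phylogenetic signal is weak, so
#'     up-weighting the phylogeny drifts the site toward randomness.}
#'   \item{signal_but_trait_mismatch}{significant only at large `a`:
#'     phylogeny captures the niche axis but the measured traits do not.}
#'   \item{random}{neither end significant.}
#' }
#'
#' @param curve an [envelope()] result.
#' @param frac_threshold fraction of an end-window's grid points that must
#'   be significant to call that end significant (default 0.8).
#' @return data.frame of class `regime_labels`: site, label, frac_low,
#'   frac_high; attribute `frac_threshold`.
#' @export
classify_regime <- function(curve, frac_threshold = 0.8) {
  .assert(inherits(curve, "envelope_curve"), "curve must be an envelope_curve")
  .assert(frac_threshold > 0 && frac_threshold <= 1, "frac_threshold must be in (0, 1]")
  sig <- curve$observed < curve$q025 | curve$observed > curve$q975
  res <- lapply(split(seq_len(nrow(curve)), curve$site), function(idx) {
    a <- curve$a[idx]; s <- sig[idx]
    low <- mean(s[a <= 0.25]); high <- mean(s[a >= 0.75])
    label <- if (low >= frac_threshold && high >= frac_threshold) "matched_with_signal"
      else if (low >= frac_threshold) "trait_matched_weak_signal"
      else if (high >= frac_threshold) "signal_but_trait_mismatch"
      else "random"
    data.frame(label = label, frac_low = low, frac_high = high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- data.frame(site = names(res), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "frac_threshold") <- frac_threshold
  class(out) <- c("regime_labels", class(out))
  out
}

#' Plot an envelope curve (base graphics)
#'
#' Observed MFPD against `a` with the nested null bands shaded, one panel
#' per site.  A thin convenience layer; the classification consumes only
#' the stored numbers.
#'
#' @param x an `envelope_curve`.
#' @param sites subset of sites to draw (default all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.envelope_curve <- function(x, sites = unique(x$site), ...) {
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(sites)))
  on.exit(graphics::par(op))
  for (s in sites) {
    cs <- x[x$site == s, ]
    ylim <- range(cs$observed, cs$q025, cs$q975)
    plot(cs$a, cs$observed, type = "n", xlab = "a", ylab = "MFPD",
         main = s, ylim = ylim, ...)
    graphics::polygon(c(cs$a, rev(cs$a)), c(cs$q025, rev(cs$q975)),
                      col = "grey85", border = NA)
    graphics::polygon(c(cs$a, rev(cs$a)), c(cs$q25, rev(cs$q75)),
                      col = "grey70", border = NA)
    graphics::lines(cs$a, (cs$q495 + cs$q505) / 2, col = "grey30")
    graphics::lines(cs$a, cs$observed, lwd = 2)
  }
  invisible(x)
}
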