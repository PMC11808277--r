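# The interspecific distance layer: patristic PDist, Gower FDist with
# PCoA re-embedding, and the weighted functional-phylogenetic combination
# FPDist(a).

#' Patristic distance matrix
#'
#' Sum of branch lengths along the tree path between every pair of tips.
#'
#' @param phy validated `phylo` tree.
#' @return labelled symmetric distance matrix in the tree's branch-length
#'   units.
#' @export
patristic_distances <- function(phy) {
  validate_phylogeny(phy)
  d <- cophenetic(phy)
  d <- d[phy$tip.label, phy$tip.label]
  validate_distance(d)
}

#' Gower distance for mixed-type trait tables
#'
#' Per pair, the mean over traits observed in both species of the
#' range-scaled absolute difference (continuous traits; ordinal traits are
#' rank-transformed first) or the 0/1 mismatch indicator (nominal and binary
#' traits).  Missing values are handled by pairwise deletion with
#' renormalization over the traits actually compared.  Traits with zero
#' range (or a single level) contribute nothing and are dropped with a
#' warning.
#'
#' @param traits trait data.frame with a `trait_types` attribute (see
#'   [read_traits()]).
#' @return labelled distance matrix with entries in \[0, 1\].
#' @export
gower_distance <- function(traits) {
  validate_traits(traits)
  types <- attr(traits, "trait_types")
  n <- nrow(traits)
  sp <- rownames(traits)
  num <- matrix(0, n, n)   # sum of per-trait dissimilarities
  den <- matrix(0, n, n)   # number of traits compared per pair
  dropped <- character(0)
  for (j in seq_along(traits)) {
    v <- traits[[j]]
    ty <- types[j]
    if (ty %in% c("continuous", "ordinal")) {
      x <- if (ty == "ordinal") rank(as.numeric(v), na.last = "keep") else as.numeric(v)
      rng <- diff(range(x, na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) { dropped <- c(dropped, colnames(traits)[j]); next }
      dj <- abs(outer(x, x, "-")) / rng
    } else {
      x <- as.character(v)
      if (length(unique(x[!is.na(x)])) < 2) { dropped <- c(dropped, colnames(traits)[j]); next }
      dj <- (outer(x, x, "!=")) * 1
    }
    ok <- outer(!is.na(v), !is.na(v), "&")
    dj[!ok] <- 0
    num <- num + dj
    den <- den + ok
  }
  if (length(dropped))
    warning("trait(s) with zero range dropped from Gower distance: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (all(den[upper.tri(den)] == 0) || ncol(traits) - length(dropped) < 1)
    stop("no usable traits for Gower distance", call. = FALSE)
  bad <- which(den == 0 & upper.tri(den), arr.ind = TRUE)
  if (nrow(bad))
    stop("species pair with no shared observed traits: ",
         sp[bad[1, 1]], " / ", sp[bad[1, 2]], call. = FALSE)
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(sp, sp)
  validate_distance(d)
}

#' Principal coordinates analysis with axis retention
#'
#' Classical metric scaling (eigendecomposition of the double-centered
#' squared-distance matrix, via [stats::cmdscale()]).  Axes with
#' non-positive eigenvalues are never retained; among positive axes the
#' retention rule keeps either a fixed count or the smallest prefix whose
#' cumulative share of the positive eigenvalue total reaches a threshold
#' (default 0.80).
#'
#' @param d labelled distance matrix, at least 3 species.
#' @param retention_rule list: `list(threshold = 0.8)` or `list(count = k)`.
#' @param correction `"none"` (default, classical scaling with a warning
#'   when negative eigenvalues appear), `"cailliez"` or `"lingoes"`.
#' @return object of class `pcoa_result`: `eigenvalues` (descending),
#'   `coordinates` (species by retained axes), `retained_axes`,
#'   `relative_eig` (share of the positive-eigenvalue total).
#' @export
pcoa <- function(d, retention_rule = list(threshold = 0.8), correction = "none") {
  validate_distance(d)
  n <- nrow(d)
  .assert(n >= 3, "PCoA needs at least 3 species")
  res <- switch(correction,
    none     = cmdscale(d, k = n - 1, eig = TRUE),
    cailliez = cmdscale(d, k = n - 1, eig = TRUE, add = TRUE),
    lingoes  = {
      e <- eigen(-0.5 * scale(scale(d^2, center = TRUE, scale = FALSE), center = TRUE, scale = FALSE),
                 symmetric = TRUE, only.values = TRUE)$values
      c2 <- max(0, -min(e))
      d2 <- sqrt(d^2 + 2 * c2); diag(d2) <- 0
      cmdscale(d2, k = n - 1, eig = TRUE)
    },
    stop("unknown correction: ", correction)
  )
  eig <- res$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- eig > tol
  if (!any(pos)) stop("degenerate distance matrix: no positive PCoA eigenvalues", call. = FALSE)
  if (correction == "none" && any(eig < -tol))
    warning("negative PCoA eigenvalues present (", sum(eig < -tol),
            "); non-positive axes excluded", call. = FALSE)
  rel <- pmax(eig, 0) / sum(pmax(eig, 0))
  n_pos <- sum(pos)
  k <- if (!is.null(retention_rule$count)) {
    min(retention_rule$count, n_pos)
  } else {
    thr <- if (is.null(retention_rule$threshold)) 0.8 else retention_rule$threshold
    max(1L, which(cumsum(rel[seq_len(n_pos)]) >= thr - 1e-12)[1])
  }
  coords <- res$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(k))
  structure(list(eigenvalues = eig, coordinates = coords, retained_axes = k,
                 relative_eig = rel),
            class = "pcoa_result")
}

#' Euclidean distances in the retained ordination space
#'
#' @param ord a `pcoa_result`.
#' @return labelled distance matrix among species in the retained-axis space.
#' @export
fdist_from_axes <- function(ord) {
  .assert(inherits(ord, "pcoa_result"), "ord must be a pcoa_result")
  .assert(ord$retained_axes >= 1, "no retained axes")
  d <- as.matrix(dist(ord$coordinates))
  validate_distance(d)
}

#' Trait-based functional distance (Gower, PCoA re-embedding)
#'
#' Convenience wrapper chaining [gower_distance()], [pcoa()] and
#' [fdist_from_axes()], the standard route from a mixed trait table to the
#' Euclidean functional distance used in FPDist.
#'
#' @inheritParams gower_distance
#' @inheritParams pcoa
#' @return labelled functional distance matrix.
#' @export
functional_distances <- function(traits, retention_rule = list(threshold = 0.8),
                                 correction = "none") {
  fdist_from_axes(pcoa(gower_distance(traits), retention_rule, correction))
}

#' Specification of the FPDist combination
#'
#' @param a phylogeny weight in \[0, 1\]: 0 = functional distance only,
#'   1 = phylogenetic distance only.
#' @param p combination exponent (> 0); 2 gives the Euclidean-type blend.
#' @param rescale rescaling rule applied to each matrix before combining;
#'   only `"max"` (divide by the maximum entry) is implemented.
#' @return list of class `fpdist_spec`.
#' @export
fpdist_spec <- function(a, p = 2, rescale = "max") {
  .assert(is.numeric(a) && length(a) == 1 && a >= 0 && a <= 1, "a must be in [0, 1]")
  .assert(is.numeric(p) && length(p) == 1 && p > 0, "p must be > 0")
  .assert(identical(rescale, "max"), "only rescale = 'max' is implemented")
  structure(list(a = a, p = p, rescale = rescale), class = "fpdist_spec")
}

#' Weighted functional-phylogenetic distance FPDist(a)
#'
#' Both matrices are rescaled to \[0, 1\] by their maximum entry, then
#' combined entrywise as
#' `(a * PDist'^p + (1 - a) * FDist'^p)^(1/p)`.
#' `a = 0` returns the rescaled functional distances exactly; `a = 1` the
#' rescaled phylogenetic distances.
#'
#' @param fd functional distance matrix.
#' @param pd phylogenetic (patristic) distance matrix, same labels.
#' @param spec an [fpdist_spec()] (or a bare numeric `a`, with defaults).
#' @return labelled FPDist matrix with entries in \[0, 1\].
#' @export
fpdist <- function(fd, pd, spec) {
  if (is.numeric(spec)) spec <- fpdist_spec(spec)
  .assert(inherits(spec, "fpdist_spec"), "spec must be an fpdist_spec")
  validate_distance(fd); validate_distance(pd)
  .assert(identical(rownames(fd), rownames(pd)),
          "fd and pd must have identical species labels in identical order")
  mf <- max(fd); mp <- max(pd)
  .assert(mf > 0, "functional distance matrix is all zero")
  .assert(mp > 0, "phylogenetic distance matrix is all zero")
  out <- (spec$a * (pd / mp)^spec$p + (1 - spec$a) * (fd / mf)^spec$p)^(1 / spec$p)
  diag(out) <- 0
  validate_distance(out)
}
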