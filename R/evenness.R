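# Functional(-phylogenetic) evenness: regularity of species spacing and
# weighting along the minimum spanning tree in ordination space.  Used as
# the interspecific-competition covariate COMP.

# Prim's algorithm, O(S^2), with deterministic lexicographic tie-breaking on
# the sorted species-pair index.  Returns an (S-1) x 2 matrix of edge indices.
.mst_edges <- function(d) {
  s <- nrow(d)
  in_tree <- rep(FALSE, s); in_tree[1] <- TRUE
  min_d <- d[1, ]; min_from <- rep(1L, s)
  edges <- matrix(0L, s - 1, 2)
  for (k in seq_len(s - 1)) {
    cand <- which(!in_tree)
    best <- min(min_d[cand])
    tied <- cand[min_d[cand] <= best + 1e-15]
    if (length(tied) > 1) {
      p1 <- pmin(min_from[tied], tied); p2 <- pmax(min_from[tied], tied)
      tied <- tied[order(p1, p2)]
    }
    j <- tied[1]
    edges[k, ] <- sort(c(min_from[j], j))
    in_tree[j] <- TRUE
    upd <- !in_tree & d[j, ] < min_d
    min_d[upd] <- d[j, upd]
    min_from[upd] <- j
  }
  edges
}

#' Functional evenness (FEve) of weighted points
#'
#' Builds the Euclidean minimum spanning tree over the species points; each
#' of the S-1 edges (i, j) gets weight `EW = dist(i, j) / (w_i + w_j)`,
#' normalized to `PEW = EW / sum(EW)`; then
#' `FEve = (sum(min(PEW, 1/(S-1))) - 1/(S-1)) / (1 - 1/(S-1))`.
#' 1 means perfectly regular spacing/weighting; values shrink toward 0 as
#' edge lengths become uneven.
#'
#' @param coordinates numeric matrix, species in rows, ordination axes in
#'   columns.
#' @param weights per-species non-negative weights summing to 1; equal
#'   weights by default (presence/absence data).
#' @return FEve in \[0, 1\], or `NA` when S < 3 or all points coincide.
#' @export
feve <- function(coordinates, weights = NULL) {
  coordinates <- as.matrix(coordinates)
  s <- nrow(coordinates)
  if (s < 3) {
    warning("FEve undefined for fewer than 3 species", call. = FALSE)
    return(NA_real_)
  }
  if (is.null(weights)) weights <- rep(1 / s, s)
  .assert(length(weights) == s && all(weights >= 0), "invalid weights")
  .assert(abs(sum(weights) - 1) < 1e-9, "weights must sum to 1")
  d <- as.matrix(dist(coordinates))
  edges <- .mst_edges(d)
  ew <- d[edges] / (weights[edges[, 1]] + weights[edges[, 2]])
  if (sum(ew) == 0) {
    warning("FEve undefined: all species coincide in ordination space", call. = FALSE)
    return(NA_real_)
  }
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Per-site functional-phylogenetic evenness (FPDve)
#'
#' For each site, restricts the FPDist matrix to the species present,
#' re-embeds them with a site-level PCoA (same retention rule as the global
#' functional-distance construction), and computes [feve()] with equal
#' weights `1/S`.  Sites with richness < 3 are flagged undefined and
#' excluded from downstream regressions.
#'
#' @param comm community matrix, labels aligned with `fpd`.
#' @param fpd interspecific distance matrix (typically [fpdist()]).
#' @param retention_rule passed to [pcoa()].
#' @return data.frame of class `evenness_result`: site, richness, fpdve,
#'   retained_axes, flag.
#' @export
fpdve_per_site <- function(comm, fpd, retention_rule = list(threshold = 0.8)) {
  validate_community(comm)
  validate_distance(fpd)
  .assert(identical(colnames(comm), rownames(fpd)),
          "community species and distance labels must match in order")
  res <- lapply(seq_len(nrow(comm)), function(i) {
    idx <- which(comm[i, ] > 0)
    if (length(idx) < 3)
      return(list(fpdve = NA_real_, axes = NA_integer_, flag = "richness_lt_3"))
    sub <- fpd[idx, idx]
    if (max(sub) == 0)
      return(list(fpdve = NA_real_, axes = NA_integer_, flag = "coincident_species"))
    ord <- suppressWarnings(pcoa(sub, retention_rule))
    v <- suppressWarnings(feve(ord$coordinates))
    list(fpdve = v, axes = ord$retained_axes,
         flag = if (is.na(v)) "undefined" else "ok")
  })
  out <- data.frame(site = rownames(comm), richness = rowSums(comm),
                    fpdve = vapply(res, `[[`, numeric(1), "fpdve"),
                    retained_axes = vapply(res, `[[`, integer(1), "axes"),
                    flag = vapply(res, `[[`, character(1), "flag"),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("evenness_result", class(out))
  out
}
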