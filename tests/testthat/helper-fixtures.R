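# Fixture builders and independent brute-force oracles.  Oracles deliberately
# use different algorithms/libraries than the implementation they check.

make_traits <- function(df, types) {
  stopifnot(length(types) == ncol(df))
  attr(df, "trait_types") <- unname(types)
  df
}

three_tip_tree <- function() read_newick(text = "((A:1,B:1):1,C:2);")

random_community <- function(n_sites, n_species, seed, p = 0.5) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_sites * n_species, 1, p), n_sites, n_species,
                dimnames = list(sprintf("s%02d", seq_len(n_sites)),
                                sprintf("sp%02d", seq_len(n_species))))
    if (all(colSums(m) >= 1) && all(rowSums(m) >= 2)) return(m)
  }
}

random_distance <- function(n, seed, labels = sprintf("sp%02d", seq_len(n))) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(labels, labels)
  d
}

# --- independent oracles ----------------------------------------------------

# MPD: explicit double loop over present pairs
oracle_mpd <- function(presence, d) {
  idx <- which(presence > 0)
  if (length(idx) < 2) return(NA_real_)
  tot <- 0; np <- 0
  for (i in seq_along(idx)) for (j in seq_along(idx)) if (i < j) {
    tot <- tot + d[idx[i], idx[j]]; np <- np + 1
  }
  tot / np
}

# Gower: per-pair, per-trait evaluation of the definition
oracle_gower <- function(traits, types) {
  n <- nrow(traits)
  scaled <- list()
  for (k in seq_along(traits)) {
    v <- traits[[k]]
    scaled[[k]] <- if (types[k] == "ordinal") rank(as.numeric(v), na.last = "keep")
                   else if (types[k] == "continuous") as.numeric(v) else v
  }
  d <- matrix(0, n, n, dimnames = list(rownames(traits), rownames(traits)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    num <- 0; den <- 0
    for (k in seq_along(traits)) {
      vi <- scaled[[k]][i]; vj <- scaled[[k]][j]
      if (is.na(vi) || is.na(vj)) next
      contrib <- if (types[k] %in% c("continuous", "ordinal")) {
        rng <- diff(range(scaled[[k]], na.rm = TRUE))
        if (rng == 0) next
        abs(vi - vj) / rng
      } else {
        if (length(unique(stats::na.omit(as.character(traits[[k]])))) < 2) next
        as.numeric(as.character(vi) != as.character(vj))
      }
      num <- num + contrib; den <- den + 1
    }
    d[i, j] <- num / den
  }
  d
}

# patristic: shortest weighted paths on the tree's edge graph via igraph
oracle_patristic <- function(phy) {
  g <- igraph::graph_from_edgelist(phy$edge, directed = FALSE)
  igraph::E(g)$weight <- phy$edge.length
  n <- length(phy$tip.label)
  d <- igraph::distances(g, v = seq_len(n), to = seq_len(n))
  dimnames(d) <- list(phy$tip.label, phy$tip.label)
  d
}

# FEve from an igraph MST (independent MST algorithm)
oracle_feve <- function(coordinates, weights = NULL) {
  s <- nrow(coordinates)
  if (is.null(weights)) weights <- rep(1 / s, s)
  d <- as.matrix(dist(coordinates))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
  mt <- igraph::mst(g)
  el <- igraph::as_edgelist(mt, names = FALSE)
  ew <- apply(el, 1, function(e) d[e[1], e[2]] / (weights[e[1]] + weights[e[2]]))
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

# LMG by explicit enumeration of all k! orderings
oracle_lmg <- function(y, X) {
  k <- ncol(X)
  r2 <- function(cols) if (!length(cols)) 0 else
    summary(lm(.y ~ ., data = cbind(.y = y, X[, cols, drop = FALSE])))$r.squared
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  shares <- numeric(k)
  ords <- perms(seq_len(k))
  for (ord in ords) {
    prev <- integer(0)
    for (j in ord) {
      shares[j] <- shares[j] + (r2(c(prev, j)) - r2(prev)) / length(ords)
      prev <- c(prev, j)
    }
  }
  shares
}
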