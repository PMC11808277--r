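test_that("patristic distances are path sums of branch lengths", {
  d <- patristic_distances(three_tip_tree())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(unname(diag(d)), rep(0, 3))
})

test_that("patristic distances match a graph shortest-path oracle on random trees", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:12, 1)
    phy <- ape::rtree(n)
    phy$tip.label <- sprintf("t%02d", seq_len(n))
    d <- patristic_distances(phy)
    expect_equal(d, oracle_patristic(phy)[rownames(d), colnames(d)],
                 tolerance = 1e-10)
  }
})

test_that("ultrametric trees put all cross-root pairs at twice the depth", {
  phy <- read_newick(text = "((A:1,B:1):1,(C:2,D:2):0);")
  d <- patristic_distances(phy)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "D"], 4)
})

test_that("gower distance reproduces the worked mixed-type example", {
  tr <- make_traits(
    data.frame(mass = c(10, 20, 30),
               diet = factor(c("insect", "seed", "insect")),
               row.names = c("A", "B", "C")),
    c("continuous", "nominal"))
  d <- gower_distance(tr)
  expect_equal(d["A", "B"], 0.75)
  expect_equal(d["A", "C"], 0.5)
  expect_equal(d["B", "C"], 0.75)
})

test_that("gower distance edge cases: identical vectors, range endpoints, zero range", {
  tr <- make_traits(data.frame(x = c(0, 10), y = c(1, 1),
                               row.names = c("A", "B")),
                    c("continuous", "continuous"))
  expect_warning(d <- gower_distance(tr), "zero range")
  expect_equal(d["A", "B"], 1)  # single usable trait, species at endpoints

  tr2 <- make_traits(data.frame(x = c(3, 3), z = factor(c("u", "u", "v"))[1:2],
                                row.names = c("A", "B")),
                     c("continuous", "nominal"))
  expect_error(suppressWarnings(gower_distance(tr2)), "no usable traits")

  tr3 <- make_traits(data.frame(x = c(1, 1, 5), w = factor(c("a", "a", "b")),
                                row.names = c("A", "B", "C")),
                     c("continuous", "nominal"))
  d3 <- gower_distance(tr3)
  expect_equal(d3["A", "B"], 0)  # identical trait vectors
})

test_that("gower matches a per-pair per-trait oracle on random mixed tables", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:12, 1)
    df <- data.frame(
      c1 = rnorm(n),
      c2 = runif(n),
      o1 = sample(1:4, n, replace = TRUE),
      n1 = factor(sample(letters[1:3], n, replace = TRUE)),
      b1 = rbinom(n, 1, 0.5),
      row.names = sprintf("sp%02d", seq_len(n)))
    # sprinkle missing values; pairwise deletion must renormalize
    df$c1[sample(n, 2)] <- NA
    df$n1[sample(n, 1)] <- NA
    types <- c("continuous", "continuous", "ordinal", "nominal", "binary")
    tr <- make_traits(df, types)
    d <- suppressWarnings(gower_distance(tr))
    expect_equal(d, oracle_gower(df, types), tolerance = 1e-10)
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("gower agrees with cluster::daisy on complete continuous+nominal data", {
  skip_if_not_installed("cluster")
  set.seed(3)
  df <- data.frame(a = rnorm(8), b = runif(8),
                   g = factor(sample(c("x", "y", "z"), 8, replace = TRUE)),
                   row.names = sprintf("sp%d", 1:8))
  d <- gower_distance(make_traits(df, c("continuous", "continuous", "nominal")))
  dz <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(unname(d), unname(dz), tolerance = 1e-10)
})

test_that("pcoa of the unit-equidistant triple gives eigenvalues {0.5, 0.5, 0}", {
  d <- matrix(1, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(d) <- 0
  ord <- pcoa(d)
  expect_equal(sort(ord$eigenvalues, decreasing = TRUE)[1:2], c(0.5, 0.5),
               tolerance = 1e-8)
  expect_lt(abs(ord$eigenvalues[3]), 1e-8)
  expect_equal(ord$retained_axes, 2L)
})

test_that("pcoa of Euclidean input reconstructs the distances exactly", {
  set.seed(7)
  pts <- matrix(rnorm(16), 8, 2, dimnames = list(sprintf("p%d", 1:8), NULL))
  d <- as.matrix(dist(pts))
  ord <- pcoa(d, retention_rule = list(count = 7))
  expect_equal(fdist_from_axes(ord), d, tolerance = 1e-8)
})

test_that("pcoa warns on and excludes negative eigenvalues", {
  # non-Euclidean: Gower matrices routinely produce negative axes
  set.seed(21)
  n <- 10
  df <- data.frame(n1 = factor(sample(letters[1:2], n, replace = TRUE)),
                   n2 = factor(sample(letters[1:3], n, replace = TRUE)),
                   c1 = rnorm(n),
                   row.names = sprintf("sp%d", 1:n))
  d <- gower_distance(make_traits(df, c("nominal", "nominal", "continuous")))
  expect_warning(ord <- pcoa(d), "negative")
  expect_true(all(ord$eigenvalues[seq_len(ord$retained_axes)] > 0))
})

test_that("fdist_from_axes honours coordinates and label order", {
  ord <- structure(list(eigenvalues = c(1, 0),
                        coordinates = matrix(c(0, 3), 2, 1,
                                             dimnames = list(c("A", "B"), "Axis1")),
                        retained_axes = 1L, relative_eig = c(1, 0)),
                   class = "pcoa_result")
  d <- fdist_from_axes(ord)
  expect_equal(d["A", "B"], 3)
})

test_that("fpdist endpoints and worked value", {
  fd <- random_distance(6, seed = 1)
  pd <- random_distance(6, seed = 2) * 10
  expect_equal(fpdist(fd, pd, fpdist_spec(0)), fd / max(fd), tolerance = 1e-12)
  expect_equal(fpdist(fd, pd, fpdist_spec(1)), pd / max(pd), tolerance = 1e-12)

  # direct formula evaluation at a pair with PDist' = 0.8, FDist' = 0.6
  fd2 <- matrix(c(0, 0.6, 0.6, 0, 1, 1, 1, 1, 0), 3)
  fd2 <- (fd2 + t(fd2)) / 2; diag(fd2) <- 0; fd2[1, 2] <- fd2[2, 1] <- 0.6
  fd2[1, 3] <- fd2[3, 1] <- 1; fd2[2, 3] <- fd2[3, 2] <- 1
  pd2 <- fd2; pd2[1, 2] <- pd2[2, 1] <- 0.8
  dimnames(fd2) <- dimnames(pd2) <- list(LETTERS[1:3], LETTERS[1:3])
  out <- fpdist(fd2, pd2, fpdist_spec(0.5, p = 2))
  expect_equal(out["A", "B"], sqrt(0.5 * 0.64 + 0.5 * 0.36), tolerance = 1e-10)
  expect_equal(out["A", "B"], 0.70711, tolerance = 1e-5)
})

test_that("fpdist is monotone in a pairwise according to the component order", {
  fd <- random_distance(7, seed = 5)
  pd <- random_distance(7, seed = 6)
  grid <- seq(0, 1, by = 0.1)
  mats <- lapply(grid, function(a) fpdist(fd, pd, fpdist_spec(a)))
  fdr <- fd / max(fd); pdr <- pd / max(pd)
  up <- upper.tri(fd)
  for (g in seq_len(length(grid) - 1)) {
    diffm <- (mats[[g + 1]] - mats[[g]])[up]
    expect_true(all(diffm[pdr[up] > fdr[up]] > -1e-12))
    expect_true(all(diffm[pdr[up] < fdr[up]] < 1e-12))
  }
  expect_error(fpdist(fd, pd, fpdist_spec(1.2)), "a must be")
  zero <- fd * 0
  expect_error(fpdist(zero, pd, fpdist_spec(0.5)), "all zero")
})
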