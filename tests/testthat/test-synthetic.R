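test_that("simulate_tree conditions on tip count and is reproducible", {
  expect_equal(length(simulate_tree(2, seed = 1)$tip.label), 2L)
  t1 <- simulate_tree(100, birth_rate = 1, death_rate = 0, seed = 9)
  expect_equal(length(t1$tip.label), 100L)
  t2 <- simulate_tree(100, birth_rate = 1, death_rate = 0, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(simulate_tree(10, birth_rate = 0.5, death_rate = 0.5),
               "birth_rate > death_rate")
})

test_that("simulate_traits is deterministic and typed", {
  phy <- simulate_tree(20, seed = 2)
  tr1 <- simulate_traits(phy, n_continuous = 2, n_nominal = 1, seed = 3)
  tr2 <- simulate_traits(phy, n_continuous = 2, n_nominal = 1, seed = 3)
  expect_identical(tr1, tr2)
  expect_identical(attr(tr1, "trait_types"), c("continuous", "continuous", "nominal"))
  expect_identical(rownames(tr1), phy$tip.label)
  expect_equal(nlevels(tr1$trait_n1), 3L)
})

test_that("lambda = 0 traits are uncorrelated with the phylogeny", {
  phy <- simulate_tree(30, seed = 4)
  pd <- patristic_distances(phy)
  pdv <- pd[upper.tri(pd)]
  cors <- vapply(1:50, function(r) {
    tr <- simulate_traits(phy, n_continuous = 1, n_nominal = 0, lambda = 0,
                          seed = 1000 + r)
    td <- abs(outer(tr[[1]], tr[[1]], "-"))
    cor(pdv, td[upper.tri(td)])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("lambda = 1 sample covariance converges to the Brownian expectation", {
  phy <- simulate_tree(8, seed = 5)
  C <- ape::vcv(phy)
  reps <- 600
  draws <- sapply(1:reps, function(r)
    simulate_traits(phy, n_continuous = 1, n_nominal = 0, lambda = 1,
                    sigma2 = 1, seed = 2000 + r)[[1]])
  S <- draws %*% t(draws) / reps
  expect_lt(max(abs(S - C)) / max(C), 0.25)       # Monte-Carlo tolerance
  expect_gt(cor(S[upper.tri(S)], C[upper.tri(C)]), 0.9)
})

test_that("assemble follows the stated selection rules", {
  tv <- setNames(as.numeric(0:9), paste0("sp", 0:9))
  dd <- abs(outer(tv, tv, "-"))

  # greedy limiting from species at 0: farthest is 9, then the 4/5 tie
  # resolves to the first in pool order
  found_seed <- NULL
  for (s in 1:50) {
    set.seed(s)
    if (sample.int(10, 1) == 1) { found_seed <- s; break }
  }
  sel <- assemble(pool_dist = dd, process = "limiting", S_target = 3,
                  strength = 1, seed = found_seed)
  expect_setequal(names(sel)[sel == 1], c("sp0", "sp9", "sp4"))

  # neutral with S_target = pool size includes everyone
  all_in <- assemble(pool_trait = tv, process = "neutral", S_target = 10, seed = 1)
  expect_true(all(all_in == 1))

  # very weak filtering is indistinguishable from uniform sampling
  counts <- table(factor(unlist(lapply(1:400, function(s)
    names(which(assemble(pool_trait = tv, process = "filtering", S_target = 1,
                         strength = 1e9, env_value = 0, seed = s) == 1)))),
    levels = names(tv)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)

  expect_error(assemble(pool_trait = tv, process = "neutral", S_target = 11),
               "exceeds pool")
})

test_that("filtering selects species near the optimum; strength controls spread", {
  set.seed(70)
  tv <- setNames(rnorm(50), sprintf("sp%02d", 1:50))
  strong <- replicate(20, {
    sel <- assemble(pool_trait = tv, process = "filtering", S_target = 10,
                    strength = 0.1 * diff(range(tv)), env_value = 0,
                    seed = sample.int(1e6, 1))
    sd(tv[sel == 1])
  })
  weak <- replicate(20, {
    sel <- assemble(pool_trait = tv, process = "filtering", S_target = 10,
                    strength = 10 * diff(range(tv)), env_value = 0,
                    seed = sample.int(1e6, 1))
    sd(tv[sel == 1])
  })
  expect_lt(mean(strong), mean(weak))
})

test_that("generate_study bundles are valid, aligned and byte-reproducible", {
  st <- generate_study(n_sites = 10, pool_size = 25, seed = 8,
                       process_mix = c(filtering = 0.5, neutral = 0.5),
                       richness_range = c(6, 12))
  expect_identical(rownames(st$traits), st$phy$tip.label)
  expect_identical(colnames(st$comm), st$phy$tip.label)
  expect_identical(st$truth$site, rownames(st$comm))
  expect_true(all(st$truth$process %in% c("filtering", "limiting", "neutral")))
  # every piece passes the io validators unmodified
  expect_silent(fpdassembly:::validate_phylogeny(st$phy))
  expect_silent(fpdassembly:::validate_traits(st$traits))
  expect_silent(fpdassembly:::validate_community(st$comm))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(st, d1)
  write_study(generate_study(n_sites = 10, pool_size = 25, seed = 8,
                             process_mix = c(filtering = 0.5, neutral = 0.5),
                             richness_range = c(6, 12)), d2)
  for (f in c("tree.nwk", "traits.csv", "community.csv", "env.csv", "truth.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("HII tracks filtering strength under coupling and not otherwise", {
  st <- generate_study(n_sites = 25, pool_size = 40, seed = 12,
                       process_mix = c(filtering = 1),
                       covariate_coupling = "filtering",
                       richness_range = c(8, 20))
  # strength stored is the filter bandwidth: HII must fall as bandwidth grows
  expect_lt(cor(st$env$HII, st$truth$strength), -0.99)
})

test_that("filtering lowers and limiting raises trait-space MPD versus neutral", {
  diffs_f <- numeric(4); diffs_l <- numeric(4)
  for (r in 1:4) {
    stf <- generate_study(n_sites = 12, pool_size = 50, seed = 300 + r,
                          process_mix = c(filtering = 1),
                          strength_range = c(0.15, 0.25),
                          richness_range = c(10, 20))
    stn <- generate_study(n_sites = 12, pool_size = 50, seed = 300 + r,
                          process_mix = c(neutral = 1),
                          richness_range = c(10, 20))
    stl <- generate_study(n_sites = 12, pool_size = 50, seed = 300 + r,
                          process_mix = c(limiting = 1),
                          richness_range = c(10, 20))
    tmpd <- function(st) {
      tv <- st$traits[[1]]
      d <- abs(outer(tv, tv, "-"))
      dimnames(d) <- list(rownames(st$traits), rownames(st$traits))
      mean(apply(st$comm[, rownames(st$traits)], 1, mpd, d = d))
    }
    diffs_f[r] <- tmpd(stf) - tmpd(stn)
    diffs_l[r] <- tmpd(stl) - tmpd(stn)
  }
  expect_lt(mean(diffs_f), 0)
  expect_gt(mean(diffs_l), 0)
})
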