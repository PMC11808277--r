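# Synthetic-data generators: birth-death trees, traits with tunable
# phylogenetic signal (Pagel's lambda), communities assembled by known
# processes, and covariates coupled to assembly strength.  Every generated
# bundle passes the io validators, so the whole pipeline is testable with
# known ground truth and no field data.

#' Simulate a birth-death phylogeny conditioned on tip count
#'
#' @param n_tips number of surviving lineages (>= 2).
#' @param birth_rate speciation rate (> death_rate).
#' @param death_rate extinction rate (>= 0).
#' @param seed integer seed.
#' @return `phylo` tree with `n_tips` tips labelled `sp001, sp002, ...`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, death_rate = 0, seed = 1L) {
  .assert(n_tips >= 2, "n_tips must be >= 2")
  .assert(birth_rate > death_rate && death_rate >= 0,
          "need birth_rate > death_rate >= 0")
  set.seed(seed)
  phy <- ape::rphylo(n_tips, birth = birth_rate, death = death_rate)
  phy$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  validate_phylogeny(phy)
  phy
}

# Pagel lambda transform of a phylogenetic covariance matrix: shared-path
# covariances (off-diagonal) scaled by lambda, tip variances untouched.
.lambda_vcv <- function(phy, lambda) {
  C <- ape::vcv(phy)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

#' Simulate traits with controllable phylogenetic signal
#'
#' Continuous traits are drawn from a zero-mean multivariate normal with
#' covariance `sigma2 * C(lambda)`, where `C(lambda)` is the tree's
#' shared-path covariance with off-diagonals rescaled by Pagel's lambda
#' (lambda = 0: independent tips; lambda = 1: Brownian motion).  Nominal
#' traits discretize an independent lambda-transformed continuous liability
#' into three quantile classes.
#'
#' @param phy `phylo` tree.
#' @param n_continuous,n_nominal numbers of traits of each kind.
#' @param sigma2 Brownian rate (trait variance scale).
#' @param lambda phylogenetic signal in \[0, 1\].
#' @param seed integer seed.
#' @return trait data.frame (species rows in tip order) with a
#'   `trait_types` attribute.
#' @export
simulate_traits <- function(phy, n_continuous = 3, n_nominal = 1,
                            sigma2 = 1, lambda = 1, seed = 1L) {
  validate_phylogeny(phy)
  .assert(lambda >= 0 && lambda <= 1, "lambda must be in [0, 1]")
  set.seed(seed)
  n <- length(phy$tip.label)
  L <- chol(sigma2 * .lambda_vcv(phy, lambda) + diag(1e-10, n))
  draw <- function() as.vector(t(L) %*% rnorm(n))
  out <- list()
  for (j in seq_len(n_continuous)) out[[paste0("trait_c", j)]] <- draw()
  for (j in seq_len(n_nominal)) {
    liab <- draw()
    out[[paste0("trait_n", j)]] <-
      factor(cut(liab, breaks = quantile(liab, c(0, 1/3, 2/3, 1)),
                 labels = c("low", "mid", "high"), include.lowest = TRUE))
  }
  out <- as.data.frame(out, row.names = phy$tip.label)
  attr(out, "trait_types") <- c(rep("continuous", n_continuous),
                                rep("nominal", n_nominal))
  validate_traits(out)
  out
}

#' Assemble one community from a species pool by a known process
#'
#' \describe{
#'   \item{filtering}{sample `S_target` species without replacement with
#'     probability proportional to
#'     `exp(-(trait - env_value)^2 / (2 * strength^2))`; small `strength`
#'     = strong habitat filter around the site optimum.}
#'   \item{limiting}{greedy limiting similarity: seed with a random
#'     species, then repeatedly add the candidate maximizing its
#'     nearest-neighbour distance to the selected set (ties broken by pool
#'     order).  `strength` in (0, 1\] is the per-step probability of
#'     applying the greedy rule rather than a uniform draw; 1 = fully
#'     deterministic greedy.}
#'   \item{neutral}{uniform sample of `S_target` species.}
#' }
#'
#' @param pool_trait numeric trait vector over the pool (filtering), or
#'   `NULL`.
#' @param pool_dist pool distance matrix (limiting), or `NULL`.
#' @param process `"filtering"`, `"limiting"` or `"neutral"`.
#' @param S_target community richness (<= pool size).
#' @param strength process strength (> 0); see above.
#' @param env_value site optimum on the filtered trait.
#' @param seed integer seed.
#' @return named 0/1 presence vector over the pool.
#' @export
assemble <- function(pool_trait = NULL, pool_dist = NULL,
                     process = c("filtering", "limiting", "neutral"),
                     S_target, strength = 1, env_value = 0, seed = 1L) {
  process <- match.arg(process)
  pool <- if (process == "limiting") nrow(pool_dist) else length(pool_trait)
  if (process == "neutral")
    pool <- max(pool, length(pool_trait), nrow(pool_dist))
  .assert(pool >= 1, "empty species pool")
  .assert(S_target <= pool, "S_target exceeds pool size")
  .assert(strength > 0, "strength must be > 0")
  set.seed(seed)
  sel <- switch(process,
    filtering = {
      pr <- exp(-(pool_trait - env_value)^2 / (2 * strength^2))
      pr <- pr / sum(pr)
      sample.int(pool, S_target, prob = pr)
    },
    limiting = {
      sel <- sample.int(pool, 1)
      while (length(sel) < S_target) {
        cand <- setdiff(seq_len(pool), sel)
        if (runif(1) <= strength) {
          nn <- vapply(cand, function(j) min(pool_dist[j, sel]), numeric(1))
          sel <- c(sel, cand[which.max(nn)])
        } else {
          sel <- c(sel, cand[sample.int(length(cand), 1)])
        }
      }
      sel
    },
    neutral = sample.int(pool, S_target)
  )
  out <- numeric(pool)
  out[sel] <- 1
  names(out) <- if (process == "limiting") rownames(pool_dist) else names(pool_trait)
  out
}

#' Generate a complete synthetic study with known ground truth
#'
#' Builds a birth-death tree, traits with the requested phylogenetic
#' signal, per-site assemblages produced by a mix of filtering / limiting /
#' neutral processes, and a covariate table shaped like a field study's
#' (TEMP, PREC, NDVI, NPP, HII, ALT plus LON/LAT).  The HII-like covariate
#' is constructed to increase monotonically with per-site process strength
#' when `covariate_coupling` names a process; the remaining covariates are
#' independent noise.  Assembly can act on the first measured continuous
#' trait (`driver = "measured"`) or on an unmeasured latent trait evolved
#' on the tree with `lambda = 1` (`driver = "latent"`), in which case the
#' measured traits carry no signal about the process.
#'
#' @param n_sites number of communities.
#' @param pool_size species-pool size.
#' @param process_mix named proportions over
#'   `c(filtering, limiting, neutral)`.
#' @param covariate_coupling `"none"`, `"filtering"` or `"limiting"`: which
#'   process strength the HII-like covariate tracks.
#' @param seed master seed; stage-specific child seeds are derived from it.
#' @param trait_lambda phylogenetic signal of the measured traits.
#' @param driver `"measured"` or `"latent"`: which trait assembly acts on.
#' @param richness_range per-site richness drawn uniformly from this range.
#' @param strength_range range of the filtering bandwidth, as a fraction of
#'   the driver-trait range (small = strong filter).
#' @param n_continuous,n_nominal measured trait counts.
#' @return list of class `synthetic_study`: `phy`, `traits`, `comm`, `env`,
#'   `truth` (site, process, strength, env_value), `seed`.
#' @export
generate_study <- function(n_sites = 30, pool_size = 100,
                           process_mix = c(filtering = 1, limiting = 0, neutral = 0),
                           covariate_coupling = c("filtering", "limiting", "none"),
                           seed = 1L, trait_lambda = 0,
                           driver = c("measured", "latent"),
                           richness_range = c(20, 55),
                           strength_range = c(0.05, 0.6),
                           n_continuous = 3, n_nominal = 1) {
  covariate_coupling <- match.arg(covariate_coupling)
  driver <- match.arg(driver)
  .assert(all(process_mix >= 0) && sum(process_mix) > 0, "invalid process mix")
  .assert(all(names(process_mix) %in% c("filtering", "limiting", "neutral")),
          "process_mix names must be filtering/limiting/neutral")
  phy <- simulate_tree(pool_size, seed = child_seed(seed, 1))
  traits <- simulate_traits(phy, n_continuous = n_continuous,
                            n_nominal = n_nominal, lambda = trait_lambda,
                            seed = child_seed(seed, 2))
  set.seed(child_seed(seed, 3))
  driver_trait <- if (driver == "measured") traits[[1]] else {
    as.vector(t(chol(.lambda_vcv(phy, 1) + diag(1e-10, pool_size))) %*%
                rnorm(pool_size))
  }
  names(driver_trait) <- phy$tip.label
  trait_rng <- diff(range(driver_trait))
  pd <- patristic_distances(phy)
  mix <- process_mix / sum(process_mix)
  procs <- sample(rep(names(mix), round(mix * n_sites))[seq_len(n_sites)])
  if (length(procs) < n_sites)
    procs <- c(procs, sample(names(mix), n_sites - length(procs),
                             replace = TRUE, prob = mix))
  rich <- sample(seq(richness_range[1], richness_range[2]), n_sites, replace = TRUE)
  u <- runif(n_sites)                                  # latent strength axis
  filt_sd <- (strength_range[1] + u * diff(strength_range)) * trait_rng
  lim_strength <- pmin(1, 0.2 + 0.8 * u)               # greedy-step probability
  # site optima land where species actually sit on the trait axis, so every
  # filter has material to act on
  env_opt <- as.numeric(quantile(driver_trait, runif(n_sites, 0.1, 0.9)))
  # limiting acts on overall measured niche distance (all continuous traits)
  # or, for a latent driver, on the latent axis itself
  lim_dist <- if (driver == "measured") {
    as.matrix(dist(as.matrix(traits[, seq_len(n_continuous), drop = FALSE])))
  } else {
    abs(outer(driver_trait, driver_trait, "-"))
  }
  comm <- matrix(0, n_sites, pool_size,
                 dimnames = list(sprintf("site%02d", seq_len(n_sites)),
                                 phy$tip.label))
  strength <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    s_i <- child_seed(seed, 100 + i)
    comm[i, ] <- switch(procs[i],
      filtering = {
        strength[i] <- filt_sd[i]
        assemble(pool_trait = driver_trait, process = "filtering",
                 S_target = rich[i], strength = filt_sd[i],
                 env_value = env_opt[i], seed = s_i)
      },
      limiting = {
        strength[i] <- lim_strength[i]
        assemble(pool_dist = lim_dist, process = "limiting",
                 S_target = rich[i], strength = lim_strength[i], seed = s_i)
      },
      neutral = {
        strength[i] <- 0
        assemble(pool_trait = driver_trait, process = "neutral",
                 S_target = rich[i], seed = s_i)
      })
  }
  # drop pool species never drawn (community invariant: every species occurs)
  present <- colSums(comm) >= 1
  comm <- comm[, present, drop = FALSE]
  attr(comm, "richness") <- rowSums(comm)
  phy <- if (all(present)) phy else ape::keep.tip(phy, colnames(comm))
  comm <- comm[, phy$tip.label, drop = FALSE]
  attr(comm, "richness") <- rowSums(comm)
  trait_types <- attr(traits, "trait_types")
  traits <- traits[phy$tip.label, , drop = FALSE]
  attr(traits, "trait_types") <- trait_types
  set.seed(child_seed(seed, 4))
  process_strength <- switch(covariate_coupling,
    none = runif(n_sites),
    # filtering strength grows as the bandwidth shrinks
    filtering = 1 - (filt_sd / trait_rng - strength_range[1]) / diff(strength_range),
    limiting = lim_strength
  )
  env <- data.frame(
    TEMP = rnorm(n_sites, 22, 3),
    PREC = rnorm(n_sites, 1800, 250),
    NDVI = runif(n_sites, 0.3, 0.9),
    NPP  = rnorm(n_sites, 900, 150),
    HII  = if (covariate_coupling == "none") runif(n_sites, 0, 50) else
             50 * process_strength,
    ALT  = runif(n_sites, 5, 900),
    LON  = runif(n_sites, 109, 111),
    LAT  = runif(n_sites, 18.2, 19.8),
    row.names = rownames(comm)
  )
  attr(env, "coord_cols") <- c("LON", "LAT")
  truth <- data.frame(site = rownames(comm), process = procs,
                      strength = strength, env_value = env_opt,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(phy = phy, traits = traits,
                 comm = comm, env = env, truth = truth, seed = seed),
            class = "synthetic_study")
}

#' Write a synthetic study bundle to disk
#'
#' Emits `tree.nwk`, `traits.csv`, `community.csv`, `env.csv`, `truth.csv`
#' and `manifest.json` (parameters, seed, package version) under `dir`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  .assert(inherits(study, "synthetic_study"), "study must be a synthetic_study")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(study$phy, file.path(dir, "tree.nwk"))
  tr <- study$traits
  write.csv(tr, file.path(dir, "traits.csv"))
  write.csv(study$comm, file.path(dir, "community.csv"))
  write.csv(study$env, file.path(dir, "env.csv"))
  write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  manifest <- list(seed = study$seed,
                   n_sites = nrow(study$comm),
                   pool_size = length(study$phy$tip.label),
                   trait_types = attr(tr, "trait_types"),
                   package_version = as.character(packageVersion("fpdassembly")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
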