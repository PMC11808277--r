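# High-level runners: each ties the pipeline stages to files on disk and
# writes a reproducibility manifest.  These are the programmatic equivalents
# of workflow subcommands; users drive them from R scripts.

.write_manifest <- function(dir, stage, params) {
  manifest <- list(stage = stage, params = params,
                   package_version = as.character(packageVersion("fpdassembly")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

.load_inputs <- function(tree, traits, community, env = NULL, types,
                         coord_cols = c("LON", "LAT")) {
  phy <- read_newick(tree)
  tr <- read_traits(traits, types)
  cm <- read_community(community)
  al <- align_labels(phy, tr, cm)
  al$env <- if (!is.null(env)) read_env(env, coord_cols) else NULL
  if (!is.null(al$env))
    .assert(all(rownames(al$comm) %in% rownames(al$env)),
            "community sites missing from the environment table")
  al
}

#' Run the SES.MFPD stage from input files to result CSVs
#'
#' Reads tree/traits/community files, aligns species, builds FDist (Gower +
#' PCoA), PDist (patristic) and FPDist(a), computes SES.MFPD against the
#' null model, and writes `ses.csv` plus a manifest to `out_dir`.
#'
#' @param tree,traits,community,env input file paths (see [read_newick()],
#'   [read_traits()], [read_community()], [read_env()]).
#' @param types named trait-type declarations for `traits`.
#' @param a phylogeny weight.
#' @param p FPDist exponent.
#' @param null a [null_spec()].
#' @param retention_rule PCoA axis retention rule.
#' @param sig_threshold |SES| cutoff recorded for clustered/dispersed calls
#'   (default 1.96; configurable, recorded in the manifest).
#' @param out_dir output directory.
#' @return the `ses_result`, invisibly.
#' @export
run_ses <- function(tree, traits, community, types, a = 0.5, p = 2,
                    null = null_spec(), retention_rule = list(threshold = 0.8),
                    sig_threshold = 1.96, out_dir = ".") {
  al <- .load_inputs(tree, traits, community, types = types)
  fd <- functional_distances(al$traits, retention_rule)
  pd <- patristic_distances(al$phy)
  d <- fpdist(fd, pd, fpdist_spec(a, p))
  res <- ses_mfpd(al$comm, d, null)
  res$classification <- ifelse(is.na(res$ses), NA_character_,
                        ifelse(res$ses < -sig_threshold, "clustered",
                        ifelse(res$ses > sig_threshold, "dispersed", "random")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res, file.path(out_dir, "ses.csv"), row.names = FALSE)
  .write_manifest(out_dir, "ses",
                  list(a = a, p = p, null = unclass(null),
                       retention_rule = retention_rule,
                       sig_threshold = sig_threshold))
  invisible(res)
}

#' Run the a-scan stage from input files to result CSVs
#'
#' Builds the distance components, scans the a-grid with [scan_a()], and
#' writes `a_scan.csv` (a, adjusted R2), `selected_model.json` and a
#' manifest to `out_dir`.
#'
#' @inheritParams run_ses
#' @param a_grid weights to scan.
#' @return the `a_scan`, invisibly.
#' @export
run_scan_a <- function(tree, traits, community, env, types,
                       a_grid = seq(0, 1, by = 0.01), p = 2,
                       null = null_spec(), retention_rule = list(threshold = 0.8),
                       out_dir = ".") {
  al <- .load_inputs(tree, traits, community, env, types = types)
  fd <- functional_distances(al$traits, retention_rule)
  pd <- patristic_distances(al$phy)
  sc <- scan_a(al$comm, fd, pd, al$env[rownames(al$comm), , drop = FALSE],
               spec = null, a_grid = a_grid, p = p,
               retention_rule = retention_rule)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(a = sc$a_grid, adj_r_squared = sc$adj_r_squared),
            file.path(out_dir, "a_scan.csv"), row.names = FALSE)
  best <- sc$fits[[which.max(sc$adj_r_squared)]]
  jsonlite::write_json(
    list(a_star = sc$a_star, max_adj_r_squared = sc$max_adj_r_squared,
         coefficients = cbind(term = rownames(best$coefficients),
                              best$coefficients)),
    file.path(out_dir, "selected_model.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  .write_manifest(out_dir, "scan_a",
                  list(a_grid = range(a_grid), step = if (length(a_grid) > 1)
                         a_grid[2] - a_grid[1] else NA,
                       p = p, null = unclass(null),
                       retention_rule = retention_rule))
  invisible(sc)
}

#' Run the driver-attribution stage: screen, select, decompose
#'
#' Given a fitted a-scan (or SES/COMP vectors), applies the Spearman
#' collinearity screen, backward selection at `alpha`, LMG relative
#' importance, and Moran's I on the site coordinates.  Writes
#' `screen.csv`, `model.csv`, `importance.csv`, `moran.json` and a manifest.
#'
#' @param ses per-site SES values (flagged sites already removed).
#' @param env covariate data.frame for those sites, with a `coord_cols`
#'   attribute.
#' @param comp per-site competition covariate (FPDve), same sites.
#' @param alpha backward-selection significance level.
#' @param rho_threshold collinearity screen threshold.
#' @param auto_remove apply the screen's removal proposals automatically
#'   (the interactive alternative is to inspect `screen.csv` and rerun).
#' @param out_dir output directory.
#' @return list with `screen`, `model` (`regression_result`), `importance`,
#'   `moran`, invisibly.
#' @export
run_fit <- function(ses, env, comp, alpha = 0.05, rho_threshold = 0.7,
                    auto_remove = TRUE, out_dir = ".") {
  screen <- spearman_screen(env, threshold = rho_threshold)
  cols <- setdiff(colnames(env), attr(env, "coord_cols"))
  if (auto_remove) cols <- setdiff(cols, screen$removal)
  X <- cbind(env[, cols, drop = FALSE], COMP = comp)
  model <- backward_select(ses, X, alpha = alpha)
  imp <- if (length(model$covariates))
    lmg_importance(ses, X[, model$covariates, drop = FALSE]) else NULL
  moran <- if (!is.null(attr(env, "coord_cols")))
    morans_i(ses, env[, attr(env, "coord_cols")]) else NULL
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(screen$correlations, file.path(out_dir, "screen.csv"))
  write.csv(cbind(term = rownames(model$coefficients), model$coefficients),
            file.path(out_dir, "model.csv"), row.names = FALSE)
  if (!is.null(imp))
    write.csv(imp, file.path(out_dir, "importance.csv"), row.names = FALSE)
  if (!is.null(moran))
    jsonlite::write_json(unclass(moran), file.path(out_dir, "moran.json"),
                         auto_unbox = TRUE, digits = NA)
  .write_manifest(out_dir, "fit",
                  list(alpha = alpha, rho_threshold = rho_threshold,
                       screened_out = screen$removal, auto_remove = auto_remove))
  invisible(list(screen = screen, model = model, importance = imp, moran = moran))
}

#' Run the envelope/classification stage from input files to result CSVs
#'
#' @inheritParams run_scan_a
#' @param n_null randomized communities for the envelope (default 1000).
#' @param seed envelope randomization seed.
#' @param frac_threshold passed to [classify_regime()].
#' @return list with `curve` and `labels`, invisibly.
#' @export
run_envelope <- function(tree, traits, community, types,
                         a_grid = seq(0, 1, by = 0.05), n_null = 1000,
                         seed = 1L, p = 2,
                         retention_rule = list(threshold = 0.8),
                         frac_threshold = 0.8, out_dir = ".") {
  al <- .load_inputs(tree, traits, community, types = types)
  fd <- functional_distances(al$traits, retention_rule)
  pd <- patristic_distances(al$phy)
  curve <- envelope(al$comm, fd, pd, a_grid = a_grid, n_null = n_null,
                    seed = seed, p = p)
  labels <- classify_regime(curve, frac_threshold)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(curve, file.path(out_dir, "envelope.csv"), row.names = FALSE)
  write.csv(labels, file.path(out_dir, "regimes.csv"), row.names = FALSE)
  .write_manifest(out_dir, "envelope",
                  list(a_grid = range(a_grid), n_null = n_null, seed = seed,
                       p = p, frac_threshold = frac_threshold))
  invisible(list(curve = curve, labels = labels))
}

#' Generate and write a synthetic study bundle
#'
#' @param out_dir output directory for the bundle (see [write_study()]).
#' @param ... passed to [generate_study()].
#' @return the `synthetic_study`, invisibly.
#' @export
run_simulate <- function(out_dir = ".", ...) {
  study <- generate_study(...)
  write_study(study, out_dir)
  invisible(study)
}
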