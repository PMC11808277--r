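# Readers and writers for the external formats: Newick trees, CSV community /
# trait / environment tables, labelled distance matrices.  All readers
# validate; downstream modules never see malformed data.

#' Read and validate a Newick phylogeny
#'
#' Parses a single rooted Newick tree with branch lengths and checks the
#' invariants required downstream: at least two tips, unique non-empty tip
#' labels, non-negative finite branch lengths.  Tip labels are normalized
#' with [normalize_species_names()].
#'
#' @param file path to a Newick file, or `NULL` when `text` is given.
#' @param text the Newick string itself (alternative to `file`).
#' @return an [ape::read.tree()] `phylo` object.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(file = NULL, text = NULL) {
  phy <- tryCatch(
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse failure: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy)) stop("Newick parse failure: no tree found in input", call. = FALSE)
  if (inherits(phy, "multiPhylo")) stop("expected a single tree, found ", length(phy), call. = FALSE)
  phy$tip.label <- normalize_species_names(phy$tip.label)
  validate_phylogeny(phy)
  phy
}

#' Read a site-by-species presence/absence community matrix
#'
#' First CSV column holds the site labels, remaining columns are species.
#' Abundances greater than one are coerced to presence with a warning (the
#' analysis operates on presence/absence).  Species never observed are
#' dropped with a warning.
#'
#' @param file CSV path.
#' @return numeric matrix, sites in rows, species in columns, entries 0/1,
#'   with a `richness` attribute holding per-site species counts.
#' @export
read_community <- function(file) {
  x <- read.csv(file, row.names = 1, check.names = FALSE)
  m <- as.matrix(x)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(x, 2, as.numeric))), arr.ind = TRUE)
    stop("non-numeric community cell(s), e.g. row '", rownames(x)[bad[1, 1]],
         "' column '", colnames(x)[bad[1, 2]], "'", call. = FALSE)
  }
  if (anyNA(m)) stop("missing values in community matrix", call. = FALSE)
  if (any(m < 0)) stop("negative values in community matrix", call. = FALSE)
  if (any(m > 1)) {
    warning(sum(m > 1), " abundance value(s) > 1 coerced to presence", call. = FALSE)
    m[m > 1] <- 1
  }
  colnames(m) <- normalize_species_names(colnames(m))
  if (any(colSums(m) < 1)) {
    empty <- colnames(m)[colSums(m) < 1]
    warning("dropping species with zero occurrences: ", paste(empty, collapse = ", "),
            call. = FALSE)
    m <- m[, colSums(m) >= 1, drop = FALSE]
  }
  validate_community(m)
  attr(m, "richness") <- rowSums(m)
  m
}

#' Read a species-by-trait table with declared trait types
#'
#' @param file CSV path; first column holds species names.
#' @param types named character vector mapping each trait column to one of
#'   `"continuous"`, `"ordinal"`, `"nominal"`, `"binary"`.
#' @return data.frame with species row names, nominal traits stored as
#'   factors, ordinal as ordered factors, and a `trait_types` attribute.
#' @export
read_traits <- function(file, types) {
  x <- read.csv(file, row.names = 1, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(x) <- normalize_species_names(rownames(x))
  missing_decl <- setdiff(colnames(x), names(types))
  if (length(missing_decl))
    stop("no declared type for trait(s): ", paste(missing_decl, collapse = ", "), call. = FALSE)
  types <- types[colnames(x)]
  bad <- setdiff(types, TRAIT_TYPES)
  if (length(bad)) stop("unknown trait type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (j in seq_along(x)) {
    x[[j]] <- switch(types[j],
      continuous = as.numeric(x[[j]]),
      ordinal    = if (is.ordered(x[[j]])) x[[j]] else
                     factor(x[[j]], levels = sort(unique(x[[j]][!is.na(x[[j]])])), ordered = TRUE),
      nominal    = factor(x[[j]]),
      binary     = as.numeric(x[[j]])
    )
    if (types[j] == "binary" && !all(x[[j]] %in% c(0, 1) | is.na(x[[j]])))
      stop("binary trait '", colnames(x)[j], "' has values outside {0,1}", call. = FALSE)
  }
  attr(x, "trait_types") <- unname(types)
  validate_traits(x)
  x
}

#' Read a per-site environmental covariate table
#'
#' @param file CSV path; first column holds site labels.
#' @param coord_cols names of the longitude and latitude columns (decimal
#'   degrees), or `NULL` when no spatial analysis is planned.
#' @return data.frame with site row names; a `coord_cols` attribute records
#'   which columns are coordinates.
#' @export
read_env <- function(file, coord_cols = c("LON", "LAT")) {
  x <- read.csv(file, row.names = 1, check.names = FALSE)
  if (!all(vapply(x, is.numeric, logical(1))))
    stop("non-numeric environmental covariate column(s): ",
         paste(colnames(x)[!vapply(x, is.numeric, logical(1))], collapse = ", "), call. = FALSE)
  if (!all(vapply(x, function(v) all(is.finite(v)), logical(1))))
    stop("non-finite environmental covariate values", call. = FALSE)
  if (!is.null(coord_cols)) {
    miss <- setdiff(coord_cols, colnames(x))
    if (length(miss))
      stop("missing coordinate column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  attr(x, "coord_cols") <- coord_cols
  x
}

#' Restrict tree, traits and community to their shared species
#'
#' Intersects the three species-name sets (after normalization), prunes the
#' tree, subsets the trait table and community matrix, and puts traits and
#' community columns in the pruned tree's tip order so every downstream
#' matrix aligns by construction.  Idempotent.
#'
#' @param phy `phylo` tree.
#' @param traits trait data.frame (species row names).
#' @param comm community matrix (species column names).
#' @return list with elements `phy`, `traits`, `comm`, `dropped` (names
#'   removed from each input).
#' @export
align_labels <- function(phy, traits, comm) {
  validate_phylogeny(phy)
  validate_traits(traits)
  validate_community(comm)
  tr_names <- normalize_species_names(rownames(traits))
  cm_names <- normalize_species_names(colnames(comm))
  rownames(traits) <- tr_names
  colnames(comm) <- cm_names
  shared <- intersect(intersect(phy$tip.label, tr_names), cm_names)
  if (length(shared) == 0L)
    stop("no species shared between tree, traits and community", call. = FALSE)
  if (length(shared) < 2L)
    stop("fewer than 2 species shared between tree, traits and community", call. = FALSE)
  dropped <- list(
    tree = setdiff(phy$tip.label, shared),
    traits = setdiff(tr_names, shared),
    community = setdiff(cm_names, shared)
  )
  if (any(lengths(dropped) > 0))
    message("align_labels: dropped ", sum(lengths(dropped)), " unmatched species name(s)")
  phy2 <- if (length(dropped$tree)) ape::keep.tip(phy, shared) else phy
  ord <- phy2$tip.label
  types <- attr(traits, "trait_types")
  traits2 <- traits[ord, , drop = FALSE]
  attr(traits2, "trait_types") <- types
  comm2 <- comm[, ord, drop = FALSE]
  keep_sites <- rowSums(comm2) >= 0  # sites kept even if emptied; flagged downstream
  comm2 <- comm2[keep_sites, , drop = FALSE]
  attr(comm2, "richness") <- rowSums(comm2)
  list(phy = phy2, traits = traits2, comm = comm2, dropped = dropped)
}

#' Write / read a labelled distance matrix as CSV (full square form)
#' @param d square labelled distance matrix.
#' @param file CSV path.
#' @export
write_distance_csv <- function(d, file) {
  validate_distance(d)
  write.csv(as.data.frame(d), file)
  invisible(file)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(file) {
  x <- as.matrix(read.csv(file, row.names = 1, check.names = FALSE))
  colnames(x) <- rownames(x)  # guard against CSV name mangling of labels
  validate_distance(x)
  x
}
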