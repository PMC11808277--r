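# Internal validators shared by all modules.  Each stops with a clear message
# on violation so downstream code can assume clean objects.

TRAIT_TYPES <- c("continuous", "ordinal", "nominal", "binary")

#' Normalize species names
#'
#' Trims surrounding whitespace and converts internal spaces to underscores,
#' the convention used by Newick tip labels.  Applied uniformly on input so
#' trees, trait tables and community matrices match on names.
#'
#' @param x character vector of species names.
#' @return character vector of normalized names.
#' @export
normalize_species_names <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("^['\"]+|['\"]+$", "", x)   # Newick writers sometimes quote labels
  gsub("[ _]+", "_", x)
}

.assert <- function(ok, ...) if (!isTRUE(ok)) stop(..., call. = FALSE)

validate_phylogeny <- function(phy) {
  .assert(inherits(phy, "phylo"), "phylogeny must be an object of class 'phylo'")
  .assert(length(phy$tip.label) >= 2L, "phylogeny must have at least 2 tips")
  .assert(!anyDuplicated(phy$tip.label), "duplicate tip labels in phylogeny: ",
          paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  .assert(all(nzchar(phy$tip.label)), "empty tip labels in phylogeny")
  .assert(!is.null(phy$edge.length), "phylogeny has no branch lengths")
  .assert(all(is.finite(phy$edge.length)), "non-finite branch lengths in phylogeny")
  .assert(all(phy$edge.length >= 0), "negative branch lengths in phylogeny")
  invisible(phy)
}

validate_community <- function(comm) {
  .assert(is.matrix(comm) && is.numeric(comm), "community must be a numeric matrix")
  .assert(!is.null(rownames(comm)) && !is.null(colnames(comm)),
          "community matrix must have site row names and species column names")
  .assert(all(comm %in% c(0, 1)), "community matrix entries must be 0 or 1")
  .assert(all(colSums(comm) >= 1), "species with zero occurrences in community matrix: ",
          paste(colnames(comm)[colSums(comm) < 1], collapse = ", "))
  invisible(comm)
}

validate_traits <- function(traits) {
  .assert(is.data.frame(traits), "traits must be a data.frame")
  .assert(!anyDuplicated(rownames(traits)), "duplicate species in trait table")
  types <- attr(traits, "trait_types")
  .assert(!is.null(types) && length(types) == ncol(traits),
          "trait table must carry a 'trait_types' attribute, one type per column")
  bad <- setdiff(types, TRAIT_TYPES)
  .assert(length(bad) == 0L, "unknown trait type(s): ", paste(bad, collapse = ", "))
  for (j in seq_along(traits)) {
    if (types[j] %in% c("continuous", "ordinal", "binary")) {
      v <- traits[[j]]
      .assert(is.numeric(v) || is.ordered(v),
              "trait '", colnames(traits)[j], "' declared ", types[j],
              " but is not numeric/ordered")
      if (is.numeric(v))
        .assert(all(is.finite(v) | is.na(v)),
                "non-finite values in trait '", colnames(traits)[j], "'")
    }
  }
  invisible(traits)
}

validate_distance <- function(d) {
  .assert(is.matrix(d) && is.numeric(d) && nrow(d) == ncol(d),
          "distance must be a square numeric matrix")
  .assert(!is.null(rownames(d)) && identical(rownames(d), colnames(d)),
          "distance matrix must have identical row and column labels")
  .assert(all(is.finite(d)), "non-finite entries in distance matrix")
  .assert(all(d >= 0), "negative entries in distance matrix")
  .assert(max(abs(d - t(d))) < 1e-12, "distance matrix is not symmetric")
  .assert(all(abs(diag(d)) < 1e-12), "distance matrix diagonal is not zero")
  invisible(d)
}

# child seed derived from a master seed; kept below 2^31 - 1
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}
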