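#' Assemble a validated riparian diversity dataset
#'
#' Bundles the five objects the pipeline consumes -- a site x species
#' abundance matrix, a species trait table, a rooted phylogeny, a site
#' table with elevation/river structure and environmental predictors, and
#' a species conservation-status map -- and reconciles their species name
#' spaces by exact match (after whitespace trimming). Species missing from
#' any one component are dropped from all of them with a warning.
#'
#' @param community numeric matrix of non-negative abundances, sites in
#'   rows, species in columns, both dimensions named.
#' @param traits data.frame of species traits, row names = species. Column
#'   types are declared via `trait_types` or taken from an existing
#'   `"trait_types"` attribute (numeric -> continuous, ordered factor ->
#'   ordinal, factor/character -> categorical).
#' @param tree rooted `ape::phylo` with branch lengths; tip labels =
#'   species.
#' @param sites data.frame, row names = sites, with at least `elevation`
#'   (m a.s.l.), `river_id` and `river_direction`; environmental predictor
#'   columns (see [rip_env_vars]) are carried along when present.
#' @param status named numeric vector of conservation weights, one per
#'   species, values in \{1, 4, 8\} (unthreatened / class-II / class-I
#'   protected).
#' @param trait_types optional named character vector over trait columns
#'   with values `"continuous"`, `"ordinal"` or `"categorical"`.
#' @return an object of class `rip_dataset`: a list with elements
#'   `community`, `traits`, `tree`, `sites`, `status`.
#' @seealso [load_dataset()], [validate_dataset()], [filter_low_occurrence()]
#' @export
rip_dataset <- function(community, traits, tree, sites, status,
                        trait_types = NULL) {
  community <- as.matrix(community)
  if (is.null(rownames(community)) || is.null(colnames(community)))
    rip_stop("community matrix must have site row names and species column names")
  rownames(community) <- trimws(rownames(community))
  colnames(community) <- trimws(colnames(community))
  storage.mode(community) <- "double"
  if (anyNA(community) || any(community < 0))
    rip_stop("community matrix must be non-negative and complete")
  if (anyDuplicated(rownames(community)) || anyDuplicated(colnames(community)))
    rip_stop("duplicate site or species identifiers in community matrix")

  traits <- as.data.frame(traits)
  rownames(traits) <- trimws(rownames(traits))
  traits <- set_trait_types(traits, trait_types)
  if (anyDuplicated(rownames(traits))) rip_stop("duplicate species in trait table")

  if (!inherits(tree, "phylo")) rip_stop("tree must be an ape 'phylo' object")
  tree$tip.label <- trimws(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) rip_stop("duplicate tip labels in tree")
  if (is.null(tree$edge.length)) rip_stop("tree has no branch lengths")
  if (!ape::is.rooted(tree)) rip_stop("tree must be rooted")

  sites <- as.data.frame(sites)
  rownames(sites) <- trimws(rownames(sites))
  need <- c("elevation", "river_id", "river_direction")
  miss <- setdiff(need, names(sites))
  if (length(miss)) rip_stop("site table lacks column(s): ", paste(miss, collapse = ", "))
  sites$river_id <- factor(sites$river_id)
  sites$river_direction <- factor(sites$river_direction)

  if (is.null(names(status))) rip_stop("status map must be a named vector")
  names(status) <- trimws(names(status))
  status <- unlist(status)

  # reconcile site name spaces
  shared_sites <- intersect(rownames(community), rownames(sites))
  if (!length(shared_sites)) rip_stop("community and site table share no sites")
  drop_s <- setdiff(union(rownames(community), rownames(sites)), shared_sites)
  if (length(drop_s))
    rip_warn("dropping ", length(drop_s), " site(s) absent from community or site table: ",
             paste(utils::head(drop_s, 5), collapse = ", "))
  community <- community[shared_sites, , drop = FALSE]
  sites <- sites[shared_sites, , drop = FALSE]

  # reconcile species name spaces across the four species-indexed objects
  pools <- list(community = colnames(community), traits = rownames(traits),
                tree = tree$tip.label, status = names(status))
  shared <- Reduce(intersect, pools)
  if (!length(shared)) rip_stop("empty intersection of species sets across inputs")
  dropped <- lapply(pools, function(p) setdiff(p, shared))
  n_drop <- sum(lengths(dropped))
  if (n_drop > 0)
    rip_warn("species name reconciliation dropped ", n_drop,
             " name(s) not shared by all inputs (e.g. ",
             paste(utils::head(unlist(dropped), 5), collapse = ", "), ")")
  shared <- colnames(community)[colnames(community) %in% shared] # keep community order
  community <- community[, shared, drop = FALSE]
  tt <- attr(traits, "trait_types")
  traits <- traits[shared, , drop = FALSE]
  attr(traits, "trait_types") <- tt
  tree <- ape::keep.tip(tree, shared)
  status <- status[shared]

  structure(list(community = community, traits = traits, tree = tree,
                 sites = sites, status = status),
            class = "rip_dataset")
}

set_trait_types <- function(traits, trait_types = NULL) {
  if (is.null(trait_types)) trait_types <- attr(traits, "trait_types")
  if (is.null(trait_types)) {
    trait_types <- vapply(traits, function(col) {
      if (is.ordered(col)) "ordinal"
      else if (is.numeric(col)) "continuous"
      else "categorical"
    }, character(1))
  }
  trait_types <- trait_types[names(traits)]
  if (anyNA(names(trait_types)) || length(trait_types) != ncol(traits))
    rip_stop("trait_types must name every trait column")
  bad <- !trait_types %in% c("continuous", "ordinal", "categorical")
  if (any(bad)) rip_stop("unknown trait type(s): ", paste(trait_types[bad], collapse = ", "))
  attr(traits, "trait_types") <- trait_types
  traits
}

#' @export
print.rip_dataset <- function(x, ...) {
  cat("rip_dataset:", nrow(x$community), "sites x", ncol(x$community), "species\n")
  cat("  traits:", ncol(x$traits), "columns (",
      paste(attr(x$traits, "trait_types"), collapse = ", "), ")\n")
  cat("  tree:", length(x$tree$tip.label), "tips;  rivers:",
      nlevels(x$sites$river_id), "\n")
  invisible(x)
}

#' Read a dataset from delimited files and a Newick tree
#'
#' Reads the five components from disk (CSV with header row, UTF-8;
#' Newick with branch lengths) and assembles them with [rip_dataset()],
#' reconciling species name spaces.
#'
#' @param community_path CSV, sites in rows (first column = site id),
#'   species in columns.
#' @param traits_path CSV, first column = species id.
#' @param tree_path Newick file.
#' @param sites_path CSV, first column = site id; must contain
#'   `elevation`, `river_id`, `river_direction`.
#' @param status_path CSV with columns `species` and `weight`.
#' @param trait_types optional named character vector of trait column
#'   types; when `NULL`, numeric columns are treated as continuous and
#'   character columns as categorical.
#' @return a `rip_dataset`.
#' @export
load_dataset <- function(community_path, traits_path, tree_path,
                         sites_path, status_path, trait_types = NULL) {
  for (p in c(community_path, traits_path, tree_path, sites_path, status_path))
    if (!file.exists(p)) rip_stop("file not found: ", p)
  community <- as.matrix(utils::read.csv(community_path, row.names = 1,
                                         check.names = FALSE))
  traits <- utils::read.csv(traits_path, row.names = 1, check.names = FALSE,
                            stringsAsFactors = FALSE)
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) rip_stop("malformed Newick file: ", tree_path)
  sites <- utils::read.csv(sites_path, row.names = 1, check.names = FALSE)
  st <- utils::read.csv(status_path, check.names = FALSE)
  if (!all(c("species", "weight") %in% names(st)))
    rip_stop("status file needs 'species' and 'weight' columns")
  status <- stats::setNames(st$weight, st$species)
  rip_dataset(community, traits, tree, sites, status, trait_types = trait_types)
}

#' Write a dataset to the on-disk formats read by [load_dataset()]
#'
#' @param ds a `rip_dataset`.
#' @param dir output directory (created if needed).
#' @return the five file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("community.csv", "traits.csv", "tree.nwk",
                            "sites.csv", "status.csv"))
  utils::write.csv(ds$community, paths[1])
  utils::write.csv(ds$traits, paths[2])
  ape::write.tree(ds$tree, paths[3])
  utils::write.csv(ds$sites, paths[4])
  utils::write.csv(data.frame(species = names(ds$status), weight = unname(ds$status)),
                   paths[5], row.names = FALSE)
  invisible(paths)
}

#' Drop species detected at too few sites
#'
#' Occurrence filter applied before diversity analysis: a species is
#' retained only if it is present (abundance > 0) at at least `min_sites`
#' sites. The site set is unchanged.
#'
#' @param cm site x species abundance matrix.
#' @param min_sites minimum number of occupied sites (default 3).
#' @return the filtered matrix.
#' @export
filter_low_occurrence <- function(cm, min_sites = 3) {
  cm <- as.matrix(cm)
  if (min_sites < 1) rip_stop("min_sites must be >= 1")
  keep <- colSums(cm > 0) >= min_sites
  if (!any(keep))
    rip_stop("no species detected at >= ", min_sites, " sites; filter removed all species")
  cm[, keep, drop = FALSE]
}

#' Check every dataset invariant and report violations
#'
#' Non-throwing audit of a dataset: abundances non-negative, branch
#' lengths non-negative, continuous traits finite, elevations finite,
#' percentage covers within \[0, 100\], channel sinuosity >= 1 (it is a
#' path-length over straight-line ratio), and conservation weights drawn
#' from \{1, 4, 8\}.
#'
#' @param ds a `rip_dataset`.
#' @return data.frame with columns `component`, `message`; zero rows iff
#'   every invariant holds.
#' @export
validate_dataset <- function(ds) {
  bad <- list()
  note <- function(component, message)
    bad[[length(bad) + 1L]] <<- data.frame(component = component, message = message)

  if (any(ds$community < 0)) note("community", "negative abundance entries")
  if (nrow(ds$community) < 1 || ncol(ds$community) < 1)
    note("community", "needs at least one site and one species")

  tt <- attr(ds$traits, "trait_types")
  for (j in seq_along(ds$traits)) {
    if (identical(tt[[j]], "continuous") && !all(is.finite(ds$traits[[j]])))
      note("traits", paste0("non-finite values in continuous trait '", names(ds$traits)[j], "'"))
  }

  if (any(ds$tree$edge.length < 0)) note("tree", "negative branch lengths")
  if (!all(colnames(ds$community) %in% ds$tree$tip.label))
    note("tree", "community species missing from tree tips")

  if (!all(is.finite(ds$sites$elevation))) note("sites", "non-finite elevation")
  for (v in intersect(rip_pct_vars, names(ds$sites))) {
    x <- ds$sites[[v]]
    if (any(x < 0 | x > 100, na.rm = TRUE))
      note("sites", paste0("percentage column '", v, "' outside [0, 100]"))
  }
  if ("Sinuosity" %in% names(ds$sites) &&
      any(ds$sites$Sinuosity < 1, na.rm = TRUE))
    note("sites", "Sinuosity < 1 (must be a ratio >= 1)")

  if (!all(ds$status %in% c(1, 4, 8)))
    note("status", "conservation weights outside {1, 4, 8}")
  if (!all(colnames(ds$community) %in% names(ds$status)))
    note("status", "community species missing a conservation weight")

  if (length(bad)) do.call(rbind, bad)
  else data.frame(component = character(), message = character())
}
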