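#' Species richness per site
#'
#' Number of species with abundance > 0 at each site.
#'
#' @param cm site x species abundance matrix.
#' @return named integer vector over sites.
#' @export
species_richness <- function(cm) {
  cm <- as.matrix(cm)
  if (any(cm < 0)) rip_stop("negative abundances")
  rowSums(cm > 0)
}

#' Shannon diversity per site
#'
#' H' = -sum p_i log(p_i) over the abundance shares of each site. The
#' default logarithm base is 2 (H' in bits), configurable; sites with no
#' individuals get H' = 0 with a warning.
#'
#' @param cm site x species abundance matrix.
#' @param base logarithm base (default 2).
#' @return named numeric vector over sites.
#' @export
shannon_index <- function(cm, base = 2) {
  cm <- as.matrix(cm)
  if (any(cm < 0)) rip_stop("negative abundances")
  tot <- rowSums(cm)
  if (any(tot == 0)) rip_warn("site(s) with zero total abundance: H' set to 0")
  H <- apply(cm, 1, function(row) {
    s <- sum(row)
    if (s == 0) return(0)
    p <- row[row > 0] / s
    -sum(p * log(p, base = base))
  })
  H
}

#' Gower dissimilarity over a mixed-type trait table
#'
#' Pairwise species dissimilarity in \[0, 1\]: continuous traits
#' contribute |x_i - x_j| / range, categorical traits a 0/1 mismatch, and
#' ordinal traits the range-scaled difference of their level ranks;
#' contributions are averaged over the traits observed for both species.
#' A trait with zero range contributes 0 with a warning.
#'
#' @param traits data.frame with a `trait_types` attribute (see
#'   [rip_dataset()]); columns without one are typed by class.
#' @return symmetric species x species matrix with zero diagonal.
#' @export
gower_dissimilarity <- function(traits) {
  traits <- set_trait_types(as.data.frame(traits))
  types <- attr(traits, "trait_types")
  n <- nrow(traits)
  if (n < 2) rip_stop("need at least 2 species")
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (j in seq_along(traits)) {
    x <- traits[[j]]
    ok <- !is.na(x)
    w <- outer(ok, ok, "&")
    if (types[j] == "categorical") {
      contrib <- outer(as.character(x), as.character(x), "!=") * 1
    } else {
      v <- if (types[j] == "ordinal") as.numeric(as.integer(factor(x, ordered = TRUE)))
           else as.numeric(x)
      rng <- diff(range(v, na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) {
        rip_warn("trait '", names(traits)[j], "' has zero range; contributes 0")
        contrib <- matrix(0, n, n)
      } else {
        contrib <- abs(outer(v, v, "-")) / rng
      }
    }
    contrib[!w] <- 0
    num <- num + contrib
    den <- den + w
  }
  if (any(den == 0)) rip_stop("species pair(s) with no shared non-missing trait")
  D <- num / den
  diag(D) <- 0
  dimnames(D) <- list(rownames(traits), rownames(traits))
  D
}

#' Build a principal-coordinates trait space from a dissimilarity matrix
#'
#' Classical metric scaling of the (Gower) dissimilarity matrix. When
#' negative eigenvalues exceed `tol` relative to the leading eigenvalue,
#' the Cailliez additive constant correction is applied before embedding,
#' and recorded. Up to `m_max` positive-eigenvalue axes are retained.
#'
#' @param D symmetric zero-diagonal dissimilarity matrix.
#' @param m_max maximum number of retained axes (default 4).
#' @param tol relative tolerance on the most negative eigenvalue
#'   (default 1e-8).
#' @return object of class `rip_trait_space`: list with `coords`
#'   (species x m), `eigenvalues`, `correction` ("none" or "cailliez"),
#'   `m`.
#' @export
build_trait_space <- function(D, m_max = 4, tol = 1e-8) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8) || any(abs(diag(D)) > 1e-12))
    rip_stop("D must be symmetric with zero diagonal")
  if (all(D == 0)) rip_stop("degenerate dissimilarity matrix (all zero)")
  n <- nrow(D)
  k_full <- n - 1
  fit <- suppressWarnings(stats::cmdscale(D, k = k_full, eig = TRUE))
  correction <- "none"
  if (min(fit$eig) < -tol * max(fit$eig)) {
    fit <- suppressWarnings(stats::cmdscale(D, k = k_full, eig = TRUE, add = TRUE))
    correction <- "cailliez"
  }
  pos <- which(fit$eig > tol * max(fit$eig))
  m <- min(m_max, length(pos))
  if (m < 1) rip_stop("no positive eigenvalues; cannot embed")
  coords <- fit$points[, seq_len(m), drop = FALSE]
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(m))
  structure(list(coords = coords, eigenvalues = fit$eig,
                 correction = correction, m = m),
            class = "rip_trait_space")
}

#' @export
print.rip_trait_space <- function(x, ...) {
  cat("rip_trait_space:", nrow(x$coords), "species on", x$m,
      "axes (correction:", x$correction, ")\n")
  invisible(x)
}

#' Functional richness (FRic) per site
#'
#' Convex-hull volume of the species present at a site, in the first
#' `m_eff` principal-coordinate axes of the trait space, standardized by
#' the hull volume of the full species pool (so FRic is in \[0, 1\] and
#' equals 1 for the whole pool). By default `m_eff` is the smaller of the
#' space's axis count and (minimum richness over sites with at least two
#' species) - 1. Sites with fewer than `m_eff + 1` species, or with
#' degenerate (affinely dependent) coordinates, get `NA` and are listed
#' in the `undefined` attribute.
#'
#' @param cm site x species abundance matrix.
#' @param space a `rip_trait_space` over (at least) the community species.
#' @param m_eff number of axes used; default as above.
#' @return named numeric vector of hull-volume fractions with attributes
#'   `raw_volume` (unstandardized volumes), `m_eff`, and `undefined`
#'   (site names with undefined FRic).
#' @export
functional_richness <- function(cm, space, m_eff = NULL) {
  cm <- as.matrix(cm)
  spp <- colnames(cm)
  if (!all(spp %in% rownames(space$coords)))
    rip_stop("community species missing from trait space")
  S <- rowSums(cm > 0)
  if (is.null(m_eff)) {
    s2 <- S[S >= 2]
    if (!length(s2)) rip_stop("no site has >= 2 species; cannot form any hull")
    m_eff <- max(1L, min(space$m, min(s2) - 1L))
  }
  if (m_eff < 1) rip_stop("m_eff must be >= 1")
  X <- space$coords[spp, seq_len(m_eff), drop = FALSE]
  pool_vol <- hull_volume(X)
  if (pool_vol <= 0) rip_stop("species pool is degenerate on ", m_eff, " axes")
  raw <- rep(NA_real_, nrow(cm))
  names(raw) <- rownames(cm)
  for (i in seq_len(nrow(cm))) {
    pres <- cm[i, ] > 0
    if (sum(pres) < m_eff + 1) next
    v <- hull_volume(X[pres, , drop = FALSE])
    if (v > 0) raw[i] <- v
  }
  fric <- raw / pool_vol
  undef <- names(raw)[is.na(raw)]
  attr(fric, "raw_volume") <- raw
  attr(fric, "m_eff") <- m_eff
  attr(fric, "undefined") <- undef
  fric
}

#' Faith's phylogenetic diversity per site
#'
#' Sum of the branch lengths of the minimal subtree connecting the
#' species present at a site; by default the path to the root is
#' included. Empty sites get PD = 0 with a warning; a single-species
#' site has PD equal to its root-to-tip distance (with the root) or 0
#' (without).
#'
#' @param cm site x species abundance matrix.
#' @param tree rooted `ape::phylo`; all community species must be tips.
#' @param include_root include the path from the spanning subtree to the
#'   root (default TRUE).
#' @return named numeric vector over sites.
#' @export
faith_pd <- function(cm, tree, include_root = TRUE) {
  cm <- as.matrix(cm)
  spp <- colnames(cm)
  if (!all(spp %in% tree$tip.label))
    rip_stop("species absent from tree: ",
             paste(setdiff(spp, tree$tip.label), collapse = ", "))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  # parent pointer and incident edge index for each node
  parent <- integer(max(tree$edge))
  edge_of <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  tip_idx <- match(spp, tree$tip.label)
  if (any(rowSums(cm > 0) == 0)) rip_warn("empty site(s): PD set to 0")
  pd <- numeric(nrow(cm))
  names(pd) <- rownames(cm)
  for (i in seq_len(nrow(cm))) {
    present <- tip_idx[cm[i, ] > 0]
    S <- length(present)
    if (S == 0) next
    cnt <- integer(nrow(tree$edge))
    for (tip in present) {
      node <- tip
      while (node != root) {
        e <- edge_of[node]
        cnt[e] <- cnt[e] + 1L
        node <- parent[node]
      }
    }
    used <- cnt > 0L
    if (!include_root) used <- used & (cnt < S)  # drop the shared root path
    pd[i] <- sum(tree$edge.length[used])
  }
  pd
}

#' Per-site multifaceted diversity profile
#'
#' Computes the raw diversity columns of the central result table:
#' species richness `S`, Shannon `H` (base `shannon_base`), functional
#' richness `FRic`, and Faith's `PD`.
#'
#' @param ds a `rip_dataset`.
#' @param shannon_base log base for H' (default 2).
#' @param m_eff FRic axis count, see [functional_richness()].
#' @param include_root see [faith_pd()].
#' @return data.frame with row per site and columns `site`, `S`, `H`,
#'   `FRic`, `PD`; the trait space used is attached as attribute
#'   `trait_space`.
#' @export
diversity_profile <- function(ds, shannon_base = 2, m_eff = NULL,
                              include_root = TRUE) {
  D <- gower_dissimilarity(ds$traits)
  space <- build_trait_space(D)
  fric <- functional_richness(ds$community, space, m_eff = m_eff)
  out <- data.frame(
    site = rownames(ds$community),
    S = as.integer(species_richness(ds$community)),
    H = shannon_index(ds$community, base = shannon_base),
    FRic = as.numeric(fric),
    PD = faith_pd(ds$community, ds$tree, include_root = include_root),
    row.names = rownames(ds$community)
  )
  attr(out, "trait_space") <- space
  attr(out, "m_eff") <- attr(fric, "m_eff")
  out
}
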