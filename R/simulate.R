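#' Configuration for the synthetic riparian study generator
#'
#' Defines the study conditions the generator emulates: six submontane
#' rivers with ten sites each spanning 481--912 m a.s.l., a pool of 47
#' species, realized richness peaking near 700 m, six mixed-type traits
#' evolved on a pure-birth phylogeny, and environmental covariates that
#' co-vary with elevation (the habitat-heterogeneity variables `Lnum` and
#' `H_SD` are mid-peaked along the gradient).
#'
#' @param n_rivers number of rivers (default 6).
#' @param sites_per_river sites per river (default 10).
#' @param elevation_range numeric length-2, m a.s.l. (default c(481, 912)).
#' @param n_species species-pool size (default 47).
#' @param richness_peak elevation (m) at which realized richness peaks
#'   (default 700).
#' @param niche_breadth Gaussian niche breadth in metres of elevation
#'   (default 170). With `max_occupancy = 1` and `niche_breadth = Inf`
#'   every species occurs everywhere.
#' @param max_occupancy occupancy probability of a species at its niche
#'   optimum (default 0.25; point counts detect only a fraction of the
#'   pool even in optimal habitat).
#' @param birth_rate speciation rate of the pure-birth tree (default 1).
#' @param trait_count number of traits, first half continuous, remainder
#'   ordinal/categorical via latent thresholds (default 6).
#' @param bm_rate Brownian-motion variance per unit branch length
#'   (default 1).
#' @param status_probs probabilities of conservation weights 1, 4, 8
#'   (default c(0.80, 0.15, 0.05): most species unthreatened).
#' @param driver_effects named numeric: log-scale occupancy effect per SD
#'   of the named environmental column. Defaults place effects on
#'   `Forest`, `H_SD`, `Lnum` and `Sinuosity`, leaving the remaining
#'   predictors null.
#' @param abundance_rate Poisson rate of the zero-truncated abundance
#'   draw for present species (default 2).
#' @param noise_sd relative noise level of the environmental columns
#'   (default 1; 0 gives noiseless deterministic columns).
#' @param seed master seed; all component draws use sub-seeds derived
#'   from it.
#' @return an object of class `rip_sim_config`.
#' @export
sim_config <- function(n_rivers = 6, sites_per_river = 10,
                       elevation_range = c(481, 912),
                       n_species = 47, richness_peak = 700,
                       niche_breadth = 170, max_occupancy = 0.22,
                       birth_rate = 1,
                       trait_count = 6, bm_rate = 1,
                       status_probs = c(0.80, 0.15, 0.05),
                       driver_effects = c(Forest = 0.2, H_SD = 0.2,
                                          Lnum = 0.2, Sinuosity = 0.2),
                       abundance_rate = 2, noise_sd = 1, seed = 1) {
  if (elevation_range[1] >= elevation_range[2])
    rip_stop("elevation_range must be increasing")
  if (abs(sum(status_probs) - 1) > 1e-8) rip_stop("status_probs must sum to 1")
  if (birth_rate <= 0 || bm_rate < 0 || abundance_rate <= 0)
    rip_stop("rates must be positive (bm_rate may be 0)")
  if (n_species < 2) rip_stop("n_species must be >= 2")
  if (max_occupancy <= 0 || max_occupancy > 1)
    rip_stop("max_occupancy must be in (0, 1]")
  structure(list(n_rivers = n_rivers, sites_per_river = sites_per_river,
                 elevation_range = elevation_range, n_species = n_species,
                 richness_peak = richness_peak, niche_breadth = niche_breadth,
                 max_occupancy = max_occupancy,
                 birth_rate = birth_rate, trait_count = trait_count,
                 bm_rate = bm_rate, status_probs = status_probs,
                 driver_effects = driver_effects,
                 abundance_rate = abundance_rate, noise_sd = noise_sd,
                 seed = seed),
            class = "rip_sim_config")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Rooted ultrametric tree with `n_species` tips labelled `sp01`,
#' `sp02`, ...
#'
#' @param n_species number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed RNG seed.
#' @return an `ape::phylo`.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1) {
  if (n_species < 2) rip_stop("n_species must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

#' Simulate continuous traits under Brownian motion on a phylogeny
#'
#' Tip values are drawn from a multivariate normal with covariance
#' `bm_rate * V`, where `V[i, j]` is the shared root-to-tip path length of
#' tips i and j; columns are independent traits with root state 0.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param bm_rate BM variance per unit branch length (0 collapses every
#'   tip to the root state).
#' @param n_traits number of independent traits.
#' @param seed RNG seed.
#' @param trait_names optional column names.
#' @return data.frame, rows = tips, columns = traits.
#' @export
simulate_bm_traits <- function(tree, bm_rate = 1, n_traits = 1, seed = 1,
                               trait_names = NULL) {
  if (is.null(tree$edge.length) || sum(tree$edge.length) == 0)
    rip_stop("tree must have positive branch lengths")
  V <- phylo_vcv(tree)
  n <- nrow(V)
  set.seed(seed)
  if (bm_rate == 0) {
    X <- matrix(0, n, n_traits)
  } else {
    L <- t(chol(bm_rate * V + diag(1e-12 * mean(diag(V)), n)))
    X <- L %*% matrix(stats::rnorm(n * n_traits), n, n_traits)
  }
  out <- as.data.frame(X, row.names = rownames(V))
  names(out) <- trait_names %||% sprintf("trait%02d", seq_len(n_traits))
  out
}

# Mixed-type trait table: continuous traits are BM draws; ordinal and
# categorical traits discretize further latent BM traits, so every column
# carries phylogenetic signal.
simulate_traits <- function(tree, config, seed = 1) {
  k <- config$trait_count
  n_cont <- max(1L, ceiling(k / 2))
  n_disc <- k - n_cont
  lat <- simulate_bm_traits(tree, config$bm_rate, n_traits = k, seed = seed)
  base_names <- c("body_mass", "wing_length", "clutch_size", "trophic_level",
                  "nest_site", "diet_guild")
  nm <- if (k <= length(base_names)) base_names[seq_len(k)]
        else c(base_names, sprintf("trait%02d", seq_len(k - length(base_names))))
  out <- lat[, seq_len(n_cont), drop = FALSE]
  names(out) <- nm[seq_len(n_cont)]
  types <- rep("continuous", n_cont)
  if (n_disc > 0) {
    for (j in seq_len(n_disc)) {
      z <- lat[[n_cont + j]]
      n_lev <- if (j %% 2 == 1L) 3L else 4L
      cuts <- stats::quantile(z, probs = seq_len(n_lev - 1) / n_lev)
      code <- findInterval(z, cuts) + 1L
      if (j %% 2 == 1L) { # ordinal
        out[[nm[n_cont + j]]] <- factor(paste0("L", code),
                                        levels = paste0("L", seq_len(n_lev)),
                                        ordered = TRUE)
        types <- c(types, "ordinal")
      } else {            # categorical
        out[[nm[n_cont + j]]] <- factor(paste0("C", code),
                                        levels = paste0("C", seq_len(n_lev)))
        types <- c(types, "categorical")
      }
    }
  }
  attr(out, "trait_types") <- stats::setNames(types, names(out))
  out
}

#' Simulate a site table along an elevational river gradient
#'
#' Each river carries `sites_per_river` sites with elevations evenly
#' spaced across `elevation_range`. Environmental columns follow the
#' schema in [rip_env_vars]: forest cover rises with elevation while
#' shrub/herb covers decline; the habitat-heterogeneity variables
#' (`Lnum`, `H_SD`) and channel `Sinuosity` are mid-peaked along the
#' gradient; `Width` and `Bar` shrink upstream. Gaussian noise scaled by
#' `noise_sd` is added and range constraints (covers in \[0, 100\],
#' `Sinuosity` >= 1) enforced.
#'
#' @param config a `rip_sim_config`.
#' @param seed RNG seed (defaults to the config's sites sub-stream).
#' @return site data.frame (rows `r1s01`, ...).
#' @export
simulate_sites <- function(config, seed = NULL) {
  set.seed(seed %||% rip_substream(config$seed, "sites"))
  lo <- config$elevation_range[1]; hi <- config$elevation_range[2]
  elev_river <- seq(lo, hi, length.out = config$sites_per_river)
  n <- config$n_rivers * config$sites_per_river
  elevation <- rep(elev_river, config$n_rivers)
  river_id <- rep(sprintf("river%d", seq_len(config$n_rivers)),
                  each = config$sites_per_river)
  river_direction <- rep(ifelse(seq_len(config$n_rivers) %% 2 == 1, "N", "S"),
                         each = config$sites_per_river)
  e01 <- (elevation - lo) / (hi - lo)                   # 0..1 along gradient
  peak01 <- (config$richness_peak - lo) / (hi - lo)
  hump <- 1 - ((e01 - peak01) / max(peak01, 1 - peak01))^2  # 1 at peak, >= ~0 at edges
  ns <- config$noise_sd
  clip <- function(x, a, b) pmin(b, pmax(a, x))
  sites <- data.frame(
    elevation = elevation,
    river_id = river_id,
    river_direction = river_direction,
    Forest = clip(40 + 30 * e01 + stats::rnorm(n, 0, 10 * ns), 0, 100),
    Shrub = clip(28 - 8 * e01 + stats::rnorm(n, 0, 8 * ns), 0, 100),
    Herb = clip(22 - 6 * e01 + stats::rnorm(n, 0, 7 * ns), 0, 100),
    Bared = clip(9 - 3 * e01 + stats::rnorm(n, 0, 4 * ns), 0, 100),
    Lnum = pmax(1, round(5 + 6 * hump + stats::rnorm(n, 0, 2.5 * ns))),
    Bar = pmax(0, 2400 - 500 * e01 + stats::rnorm(n, 0, 900 * ns)),
    Width = pmax(2, 19 - 3 * e01 + stats::rnorm(n, 0, 3 * ns)),
    Sinuosity = pmax(1, 1.1 + 0.35 * hump + stats::rnorm(n, 0, 0.15 * ns)),
    H_SD = pmax(0.1, 1.2 + 3 * hump + stats::rnorm(n, 0, 0.9 * ns)),
    row.names = sprintf("r%ds%02d", rep(seq_len(config$n_rivers),
                                        each = config$sites_per_river),
                        rep(seq_len(config$sites_per_river), config$n_rivers))
  )
  sites
}

#' Assemble communities by Gaussian niche filtering along the gradient
#'
#' Species niche optima are drawn around `richness_peak`, so realized
#' richness is hump-shaped in elevation. Occupancy probability at a site
#' is `max_occupancy` times a Gaussian response
#' `exp(-(elev - opt)^2 / (2 breadth^2))`, optionally multiplied by the
#' centred log-linear driver term `exp(beta' z(env) - mean)` (effects
#' per SD of the named environmental columns; capped at 1). Abundances
#' of present species are zero-truncated Poisson draws.
#'
#' @param sites site table from [simulate_sites()].
#' @param tree phylogeny providing the species labels.
#' @param config a `rip_sim_config`.
#' @param seed RNG seed (defaults to the config's community sub-stream).
#' @return site x species abundance matrix.
#' @export
assemble_communities <- function(sites, tree, config, seed = NULL) {
  set.seed(seed %||% rip_substream(config$seed, "community"))
  spp <- tree$tip.label
  n_sp <- length(spp); n_site <- nrow(sites)
  span <- diff(config$elevation_range)
  opt <- stats::rnorm(n_sp, config$richness_peak, 0.35 * span)
  opt <- pmin(config$elevation_range[2] + 50,
              pmax(config$elevation_range[1] - 50, opt))
  d <- outer(sites$elevation, opt, "-")
  p <- if (is.infinite(config$niche_breadth)) matrix(1, n_site, n_sp)
       else exp(-d^2 / (2 * config$niche_breadth^2))
  p <- config$max_occupancy * p
  de <- config$driver_effects
  de <- de[names(de) %in% names(sites)]
  if (length(de)) {
    Z <- scale(as.matrix(sites[, names(de), drop = FALSE]))
    eta <- drop(Z %*% de)
    p <- pmin(1, p * exp(eta - mean(eta)))
  }
  pres <- matrix(stats::runif(n_site * n_sp), n_site, n_sp) < p
  # zero-truncated Poisson via inverse CDF conditioned away from zero
  ab <- matrix(0, n_site, n_sp, dimnames = list(rownames(sites), spp))
  idx <- which(pres)
  if (length(idx)) {
    lam <- config$abundance_rate
    u <- stats::runif(length(idx), stats::dpois(0, lam), 1)
    ab[idx] <- stats::qpois(u, lam)
  }
  ab
}

#' Generate a complete synthetic study dataset
#'
#' Runs the tree, trait, site, community and conservation-status
#' generators on independent sub-streams of the master seed and bundles
#' the result with [rip_dataset()].
#'
#' @param config a `rip_sim_config` (default `sim_config()`).
#' @param dir optional directory; when given the dataset is also written
#'   in the on-disk formats of [write_dataset()].
#' @return a `rip_dataset`.
#' @export
generate_study <- function(config = sim_config(), dir = NULL) {
  tree <- simulate_tree(config$n_species, config$birth_rate,
                        seed = rip_substream(config$seed, "tree"))
  traits <- simulate_traits(tree, config,
                            seed = rip_substream(config$seed, "traits"))
  sites <- simulate_sites(config)
  community <- assemble_communities(sites, tree, config)
  set.seed(rip_substream(config$seed, "status"))
  status <- stats::setNames(
    sample(c(1, 4, 8), config$n_species, replace = TRUE,
           prob = config$status_probs),
    tree$tip.label)
  ds <- rip_dataset(community, traits, tree, sites, status)
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}
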