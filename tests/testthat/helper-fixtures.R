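# shared fixtures, all built in code

# three-tip tree ((A:1,B:1):1,C:2); total length 5
toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

# star tree with equal branches and an explicit root edge (so ape treats
# the basal polytomy as rooted)
star_tree <- function(n, branch = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(branch, n)
  tr$root.edge <- 0
  tr
}

toy_cm <- function() {
  m <- matrix(c(2, 1, 0,
                0, 3, 1,
                1, 1, 1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("A", "B", "C")))
  m
}

toy_traits <- function() {
  tt <- data.frame(mass = c(10, 20, 30),
                   guild = factor(c("g1", "g1", "g2")),
                   row.names = c("A", "B", "C"))
  attr(tt, "trait_types") <- c(mass = "continuous", guild = "categorical")
  tt
}

toy_sites <- function() {
  data.frame(elevation = c(500, 700, 900),
             river_id = c("r1", "r1", "r2"),
             river_direction = c("N", "N", "S"),
             Sinuosity = c(1.2, 1.5, 1.1),
             Forest = c(40, 60, 80),
             row.names = c("s1", "s2", "s3"))
}

toy_status <- function() c(A = 1, B = 4, C = 8)

toy_dataset <- function() {
  suppressWarnings(rip_dataset(toy_cm(), toy_traits(), toy_tree(),
                               toy_sites(), toy_status()))
}

# small fast simulation config for tests
small_config <- function(seed = 1, ...) {
  sim_config(n_rivers = 3, sites_per_river = 8, n_species = 20, seed = seed, ...)
}

# brute-force Faith PD: union of root-to-tip edge sets
brute_pd <- function(tree, tips, include_root = TRUE) {
  if (!length(tips)) return(0)
  root <- length(tree$tip.label) + 1L
  paths <- lapply(tips, function(tip) {
    node <- match(tip, tree$tip.label)
    edges <- integer()
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  })
  edges <- Reduce(union, paths)
  if (!include_root) {
    shared <- Reduce(intersect, paths)   # path from MRCA up to the root
    edges <- setdiff(edges, shared)
  }
  sum(tree$edge.length[edges])
}
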