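test_that("species richness counts non-zero entries", {
  cm <- rbind(s0 = c(0, 0, 0), s1 = c(2, 1, 0))
  colnames(cm) <- c("A", "B", "C")
  expect_equal(unname(species_richness(cm)), c(0, 2))
  set.seed(31)
  m <- matrix(rpois(20 * 15, 0.7), 20, 15,
              dimnames = list(paste0("s", 1:20), paste0("sp", 1:15)))
  expect_equal(unname(species_richness(m)),
               unname(apply(m, 1, function(r) sum(r > 0))))
})

test_that("Shannon index matches hand values and its evenness bound", {
  one <- matrix(5, 1, 1, dimnames = list("s", "A"))
  expect_equal(unname(shannon_index(one)), 0)
  even <- matrix(c(3, 3), 1, dimnames = list("s", c("A", "B")))
  expect_equal(unname(shannon_index(even, base = 2)), 1)
  mix <- matrix(c(2, 1, 1), 1, dimnames = list("s", c("A", "B", "C")))
  expect_equal(unname(shannon_index(mix, base = 2)), 1.5)

  set.seed(12)
  m <- matrix(rpois(30 * 8, 1), 30, 8,
              dimnames = list(paste0("s", 1:30), paste0("sp", 1:8)))
  m <- m[rowSums(m) > 0, ]
  H <- shannon_index(m, base = 2)
  S <- species_richness(m)
  expect_true(all(H <= log2(pmax(S, 1)) + 1e-12))
  # agreement with the vegan implementation (natural log)
  expect_equal(unname(shannon_index(m, base = exp(1))),
               unname(vegan::diversity(m, index = "shannon")))
})

test_that("Gower dissimilarity matches hand computation and cluster::daisy", {
  tt <- data.frame(mass = c(0, 10, 5), guild = factor(c("x", "x", "y")),
                   row.names = c("A", "B", "C"))
  D <- gower_dissimilarity(tt)
  expect_equal(D["A", "B"], (1 + 0) / 2)     # range-scaled 1, category match 0
  expect_equal(D["A", "C"], (0.5 + 1) / 2)
  expect_equal(diag(D), c(A = 0, B = 0, C = 0))
  expect_equal(D, t(D))

  # identical rows are at distance zero; extremes of one trait at one
  ext <- data.frame(x = c(0, 1), row.names = c("A", "B"))
  expect_equal(gower_dissimilarity(ext)["A", "B"], 1)

  set.seed(5)
  mixed <- data.frame(a = rnorm(12), b = factor(sample(letters[1:3], 12, TRUE)),
                      c = ordered(sample(1:4, 12, TRUE)), d = runif(12),
                      row.names = sprintf("sp%02d", 1:12))
  expect_equal(unname(gower_dissimilarity(mixed)),
               unname(as.matrix(cluster::daisy(mixed, metric = "gower"))),
               tolerance = 1e-12)
})

test_that("trait space embedding reproduces Euclidean dissimilarities", {
  set.seed(9)
  xy <- matrix(rnorm(14 * 2), 14, 2, dimnames = list(sprintf("sp%02d", 1:14), NULL))
  D <- as.matrix(dist(xy))
  sp <- build_trait_space(D, m_max = 2)
  expect_identical(sp$correction, "none")
  expect_equal(unname(as.matrix(dist(sp$coords))), unname(D), tolerance = 1e-8)

  # three equidistant points embed as an equilateral triangle
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  sp3 <- build_trait_space(D3, m_max = 3)
  d3 <- as.matrix(dist(sp3$coords))
  expect_equal(unname(d3[upper.tri(d3)]), rep(1, 3), tolerance = 1e-8)

  sp1 <- build_trait_space(D, m_max = 1)
  expect_identical(ncol(sp1$coords), 1L)

  # mixed-type Gower input is non-Euclidean: the additive correction is
  # applied and the embedding still approximates the dissimilarities
  set.seed(2)
  tt <- data.frame(mass = rnorm(10),
                   guild = factor(sample(c("x", "y"), 10, TRUE)),
                   row.names = sprintf("sp%02d", 1:10))
  Dg <- gower_dissimilarity(tt)
  spc <- build_trait_space(Dg, m_max = 9)
  expect_identical(spc$correction, "cailliez")
  emb <- as.matrix(dist(spc$coords))
  expect_gt(cor(emb[upper.tri(emb)], Dg[upper.tri(Dg)]), 0.95)
})

test_that("convex-hull FRic reproduces shoelace fractions on toy spaces", {
  coords <- rbind(A = c(0, 0), B = c(1, 0), C = c(0, 1))
  space <- structure(list(coords = coords, eigenvalues = c(1, 1),
                          correction = "none", m = 2),
                     class = "rip_trait_space")
  cm <- rbind(all = c(1, 1, 1), two = c(1, 1, 0))
  colnames(cm) <- rownames(coords)
  fr <- functional_richness(cm, space, m_eff = 2)
  expect_equal(unname(fr["all"]), 1.0, tolerance = 1e-9)
  expect_true(is.na(fr["two"]))                  # 2 species cannot span 2-D

  sq <- rbind(A = c(0, 0), B = c(1, 0), C = c(1, 1), D = c(0, 1))
  space4 <- structure(list(coords = sq, eigenvalues = c(1, 1),
                           correction = "none", m = 2),
                      class = "rip_trait_space")
  cm4 <- rbind(tri = c(1, 1, 1, 0), full = c(1, 1, 1, 1))
  colnames(cm4) <- rownames(sq)
  fr4 <- functional_richness(cm4, space4, m_eff = 2)
  expect_equal(unname(fr4["tri"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(fr4["full"]), 1.0, tolerance = 1e-9)
})

test_that("hull volume is exact for hypercubes and simplices up to 4-D", {
  for (d in 2:4) {
    corners <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
    expect_equal(hull_volume(corners), 1, tolerance = 1e-9)
    simplex <- rbind(rep(0, d), diag(d))
    expect_equal(hull_volume(simplex), 1 / factorial(d), tolerance = 1e-9)
    # interior points do not change the hull
    withins <- rbind(corners, matrix(runif(5 * d, 0.2, 0.8), 5, d))
    expect_equal(hull_volume(withins), 1, tolerance = 1e-9)
  }
  # degenerate (affinely dependent) point sets have zero volume
  expect_equal(hull_volume(cbind(0:3, 0:3)), 0)
})

test_that("FRic is monotone under species addition", {
  set.seed(77)
  for (rep in 1:20) {
    n <- 12
    coords <- matrix(rnorm(n * 2), n, 2,
                     dimnames = list(sprintf("sp%02d", 1:n), NULL))
    space <- structure(list(coords = coords, eigenvalues = c(1, 1),
                            correction = "none", m = 2),
                       class = "rip_trait_space")
    sub <- sort(sample(n, sample(3:(n - 1), 1)))
    sup <- sort(union(sub, sample(n, 2)))
    cm <- matrix(0, 2, n, dimnames = list(c("sub", "sup"), rownames(coords)))
    cm[1, sub] <- 1; cm[2, sup] <- 1
    fr <- functional_richness(cm, space, m_eff = 2)
    expect_gte(fr["sup"] + 1e-12, fr["sub"])
  }
})

test_that("Faith's PD matches the toy tree and brute-force edge unions", {
  tr <- toy_tree()
  cm <- rbind(ab = c(1, 1, 0), abc = c(1, 1, 1))
  colnames(cm) <- c("A", "B", "C")
  pd <- faith_pd(cm, tr)
  expect_equal(unname(pd), c(3, 5))

  set.seed(44)
  for (rep in 1:20) {
    tree <- ape::rtree(8)
    cmr <- matrix(rbinom(4 * 8, 1, 0.5), 4, 8,
                  dimnames = list(paste0("s", 1:4), tree$tip.label))
    for (root in c(TRUE, FALSE)) {
      got <- suppressWarnings(faith_pd(cmr, tree, include_root = root))
      want <- apply(cmr, 1, function(r)
        brute_pd(tree, colnames(cmr)[r > 0], include_root = root))
      expect_equal(unname(got), unname(want))
    }
  }
})

test_that("PD is monotone under species addition", {
  set.seed(13)
  tree <- ape::rtree(10)
  for (rep in 1:15) {
    sub <- sample(tree$tip.label, sample(1:8, 1))
    sup <- union(sub, sample(tree$tip.label, 2))
    cm <- matrix(0, 2, 10, dimnames = list(c("sub", "sup"), tree$tip.label))
    cm[1, sub] <- 1; cm[2, sup] <- 1
    pd <- faith_pd(cm, tree)
    expect_gte(pd["sup"], pd["sub"])
  }
})

test_that("raw FD and PD correlate positively with richness on synthetic data", {
  ds <- generate_study(sim_config(seed = 21))
  prof <- suppressWarnings(diversity_profile(ds))
  ct_pd <- cor.test(prof$S, prof$PD)
  expect_gt(ct_pd$estimate, 0)
  expect_lt(ct_pd$p.value, 0.01)
  ok <- !is.na(prof$FRic)
  ct_fd <- cor.test(prof$S[ok], prof$FRic[ok])
  expect_gt(ct_fd$estimate, 0)
  expect_lt(ct_fd$p.value, 0.01)
})
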