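# Exact convex-hull (hyper)volume in low dimension.
#
# d = 1 is a range, d = 2 the shoelace area of the chull() polygon, and
# d >= 3 is computed by facet decomposition: every supporting hyperplane
# through d affinely independent points with all remaining points on one
# side contributes (facet measure) * (distance to the centroid) / d.
# Facets are deduplicated by the index set of points lying on them, and
# facet measures are obtained by recursing on the projection into an
# orthonormal basis of the hyperplane. Intended for the small point sets
# of community trait spaces (n <= ~60, d <= 4).

hull_volume <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  pts <- unique(pts)
  d <- ncol(pts)
  if (nrow(pts) < d + 1) return(0)
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  if (qr(cen)$rank < d) return(0)   # affinely degenerate: zero d-volume
  hull_volume_rec(pts, tol)
}

hull_volume_rec <- function(pts, tol = 1e-9) {
  d <- ncol(pts)
  n <- nrow(pts)
  if (d == 1) return(max(pts[, 1]) - min(pts[, 1]))
  if (d == 2) {
    h <- grDevices::chull(pts)
    if (length(h) < 3) return(0)
    x <- pts[h, 1]; y <- pts[h, 2]
    return(abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2)
  }
  ctr <- colMeans(pts)
  scale_ref <- max(1, max(abs(sweep(pts, 2, ctr))))
  eps <- tol * scale_ref
  combs <- utils::combn(n, d)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  vol <- 0
  for (ci in seq_len(ncol(combs))) {
    id <- combs[, ci]
    P <- pts[id, , drop = FALSE]
    A <- sweep(P[-1, , drop = FALSE], 2, P[1, ])
    qrA <- qr(t(A))
    if (qrA$rank < d - 1) next                      # points not spanning a hyperplane
    Q <- qr.Q(qrA, complete = TRUE)
    nrm <- Q[, d]
    s <- drop(sweep(pts, 2, P[1, ]) %*% nrm)
    if (!(all(s <= eps) || all(s >= -eps))) next    # not a supporting hyperplane
    on_plane <- which(abs(s) <= eps)
    key <- paste(on_plane, collapse = ",")
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    B <- Q[, seq_len(d - 1), drop = FALSE]
    proj <- sweep(pts[on_plane, , drop = FALSE], 2, P[1, ]) %*% B
    facet <- hull_volume_rec(proj, tol)
    height <- abs(drop((ctr - P[1, ]) %*% nrm))
    vol <- vol + facet * height / d
  }
  vol
}
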