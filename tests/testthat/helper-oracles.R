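# Independent brute-force oracles used to cross-check the geometric engine.
# These are deliberately naive (exhaustive enumeration) and share no code
# with the implementation under test.

cross_o <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Exhaustive convex-polytope construction: every triple of points whose plane
# has all other points on one side is a hull facet. Assumes general position
# (random coordinates). Returns volume, surface area and hull vertex indices.
oracle_hull_3d <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  ctr <- colMeans(pts)
  vol <- 0
  area <- 0
  vidx <- integer(0)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
    nv <- cross_o(b - a, cc - a)
    nn <- sqrt(sum(nv^2))
    if (nn < tol) next
    u <- nv / nn
    d <- as.vector(sweep(pts, 2, a) %*% u)
    outward <- NULL
    if (all(d <= tol)) outward <- u
    else if (all(d >= -tol)) outward <- -u
    if (is.null(outward)) next
    h <- sum(outward * (a - ctr))
    vol <- vol + (nn / 2) * h / 3
    area <- area + nn / 2
    vidx <- union(vidx, c(i, j, k))
  }
  list(volume = vol, surface_area = area, vertex_idx = sort(vidx))
}

# Fan-triangulation centroid of a closed CCW polygon ring: area-weighted
# average of triangle centroids.
oracle_centroid <- function(ring) {
  v <- ring[-nrow(ring), , drop = FALSE]
  a <- v[1, ]
  acc <- c(0, 0)
  A <- 0
  for (i in 2:(nrow(v) - 1)) {
    b <- v[i, ]; cc <- v[i + 1, ]
    tri_a <- ((b[1] - a[1]) * (cc[2] - a[2]) -
                (cc[1] - a[1]) * (b[2] - a[2])) / 2
    acc <- acc + tri_a * (a + b + cc) / 3
    A <- A + tri_a
  }
  acc / A
}

# Random convex polygon as a closed CCW ring (points on an ellipse, sorted
# by angle).
random_convex_ring <- function(n = 7) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  rx <- stats::runif(1, 1, 5); ry <- stats::runif(1, 1, 5)
  v <- cbind(rx * cos(th), ry * sin(th))
  rbind(v, v[1, , drop = FALSE])
}

# Pairwise overlap / tangency audit of packed circles.
audit_packing <- function(pc, overlap_tol = 1e-9, tangent_tol = 1e-7) {
  n <- nrow(pc)
  if (n < 2) return(list(overlaps = 0L, untouched = 0L))
  dm <- as.matrix(stats::dist(pc[, c("x", "y")]))
  sr <- outer(pc$r, pc$r, "+")
  overlaps <- sum(dm < sr - overlap_tol & upper.tri(dm))
  untouched <- 0L
  if (n >= 3) {
    for (i in 3:n) {
      if (!any(abs(dm[i, 1:(i - 1)] - sr[i, 1:(i - 1)]) < tangent_tol)) {
        untouched <- untouched + 1L
      }
    }
  }
  list(overlaps = overlaps, untouched = untouched)
}

# Minimal hand-made 3D pore model (unit-scale) for tests that only need the
# pore_model contract, not a simulated track.
fake_pore <- function(id, vertices, volume = NULL) {
  h <- porehull::convex_hull_3d(vertices)
  structure(list(track_id = id, dims = 3L,
                 vertices = vertices[h$vertex_idx, , drop = FALSE],
                 faces = h$faces,
                 volume = volume %||% h$volume,
                 surface_area = h$surface_area,
                 diameter_raw = max(stats::dist(vertices[h$vertex_idx, ])),
                 diameter_corrected = NA_real_,
                 sphericity = NA_real_,
                 centroid = h$centroid),
            class = "pore_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
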