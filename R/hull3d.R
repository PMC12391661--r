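# Convex hull primitives. The 3D hull is the geometric engine of the whole
# package: a pore model is the hull of a track's position cloud. Implemented
# as an incremental hull (initial tetrahedron of extreme points, then for
# each remaining point: find visible faces, replace them by the cone from the
# horizon edges). Points within `tol` of a supporting plane are treated as
# interior, so hull vertices are always a subset of the input points.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Convex hull of a 3D point cloud
#'
#' Returns the minimal convex polytope containing the points, as a
#' triangulated facet list with outward normals, together with its volume and
#' surface area.
#'
#' @param pts Numeric matrix (n x 3), n >= 4, in micrometres (any consistent
#'   unit works; volume and area follow it).
#' @param tol Relative degeneracy tolerance (default 1e-9 of the coordinate
#'   scale).
#' @return List with `vertex_idx` (indices of input points on the hull),
#'   `faces` (m x 3 matrix of input-point indices, outward-oriented),
#'   `face_normals` (m x 3 unit outward normals), `face_offsets` (m, plane
#'   offsets so that inside points satisfy `normal . p <= offset`), `volume`,
#'   `surface_area`.
#' @export
convex_hull_3d <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3) ph_stop("`pts` must be n x 3", "porehull_domain_error")
  n <- nrow(pts)
  if (n < 4) {
    ph_stop("need at least 4 points for a 3D hull",
            "porehull_validation_error")
  }
  scale <- max(1, max(abs(pts)))
  eps <- tol * scale

  # --- initial tetrahedron from extreme points -----------------------------
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (max(pts[, 1]) - min(pts[, 1]) < eps) {
    sp <- apply(pts, 2, function(v) diff(range(v)))
    ax <- which.max(sp)
    i1 <- which.min(pts[, ax]); i2 <- which.max(pts[, ax])
  }
  if (sqrt(sum((pts[i2, ] - pts[i1, ])^2)) < eps) {
    ph_stop("degenerate point cloud (all points coincide)",
            "porehull_degenerate")
  }
  ab <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * ab[3] - rel[, 3] * ab[2],
              rel[, 3] * ab[1] - rel[, 1] * ab[3],
              rel[, 1] * ab[2] - rel[, 2] * ab[1])
  dline <- sqrt(rowSums(cr^2)) / sqrt(sum(ab^2))
  i3 <- which.max(dline)
  if (dline[i3] < eps) {
    ph_stop("degenerate point cloud (collinear)", "porehull_degenerate")
  }
  nrm <- cross3(ab, pts[i3, ] - pts[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  dplane <- abs(as.vector(rel %*% nrm))
  i4 <- which.max(dplane)
  if (dplane[i4] < eps) {
    ph_stop("degenerate point cloud (coplanar)", "porehull_degenerate")
  }

  interior <- colMeans(pts[c(i1, i2, i3, i4), , drop = FALSE])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))

  orient <- function(f) {
    a <- pts[f[1], ]; b <- pts[f[2], ]; c_ <- pts[f[3], ]
    nv <- cross3(b - a, c_ - a)
    nn <- sqrt(sum(nv^2))
    if (nn < eps * eps) return(NULL)
    nv <- nv / nn
    off <- sum(nv * a)
    if (sum(nv * interior) > off) {
      f <- f[c(1, 3, 2)]; nv <- -nv; off <- -off
    }
    list(f = f, n = nv, o = off)
  }

  fl <- lapply(seq_len(4), function(i) orient(faces[i, ]))
  Fm <- do.call(rbind, lapply(fl, `[[`, "f"))
  Nm <- do.call(rbind, lapply(fl, `[[`, "n"))
  Ov <- vapply(fl, `[[`, numeric(1), "o")

  # --- incremental insertion ----------------------------------------------
  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (ip in rest) {
    p <- pts[ip, ]
    d <- as.vector(Nm %*% p) - Ov
    vis <- which(d > eps)
    if (!length(vis)) next
    # horizon: edges of visible faces adjacent to a hidden face; since the
    # face complex is a closed 2-manifold, these are exactly the edges that
    # appear once in the visible subset.
    vf <- Fm[vis, , drop = FALSE]
    e <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    cnt <- table(key)
    horizon <- e[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
    keep <- setdiff(seq_len(nrow(Fm)), vis)
    Fm <- Fm[keep, , drop = FALSE]
    Nm <- Nm[keep, , drop = FALSE]
    Ov <- Ov[keep]
    for (h in seq_len(nrow(horizon))) {
      nf <- orient(c(horizon[h, 1], horizon[h, 2], ip))
      if (is.null(nf)) next
      Fm <- rbind(Fm, nf$f); Nm <- rbind(Nm, nf$n); Ov <- c(Ov, nf$o)
    }
  }

  vidx <- sort(unique(as.vector(Fm)))
  # volume / area from the outward-oriented triangulation
  a <- pts[Fm[, 1], , drop = FALSE]
  b <- pts[Fm[, 2], , drop = FALSE]
  c_ <- pts[Fm[, 3], , drop = FALSE]
  ar <- sweep(a, 2, interior); br <- sweep(b, 2, interior)
  cr_ <- sweep(c_, 2, interior)
  crossm <- cbind(ar[, 2] * br[, 3] - ar[, 3] * br[, 2],
                  ar[, 3] * br[, 1] - ar[, 1] * br[, 3],
                  ar[, 1] * br[, 2] - ar[, 2] * br[, 1])
  vol <- sum(rowSums(crossm * cr_)) / 6
  e1 <- b - a; e2 <- c_ - a
  crossa <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                  e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                  e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sum(sqrt(rowSums(crossa^2))) / 2

  list(vertex_idx = vidx, faces = Fm, face_normals = Nm, face_offsets = Ov,
       volume = abs(vol), surface_area = area,
       centroid = colMeans(pts[vidx, , drop = FALSE]))
}

#' Convex hull of a 2D point cloud
#'
#' Wraps [grDevices::chull()] and canonicalizes the result: vertices in
#' counterclockwise order starting from the lowest-(y, x) vertex, with the
#' ring closed (first vertex repeated last) as the centroid formulas require.
#'
#' @param pts Numeric matrix (n x 2), n >= 3.
#' @param tol Relative degeneracy tolerance.
#' @return List with `vertex_idx` (open ring, CCW), `ring` (closed CCW vertex
#'   coordinate matrix), `area`, `perimeter`, `centroid`.
#' @export
convex_hull_2d <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2) ph_stop("`pts` must be n x 2", "porehull_domain_error")
  if (nrow(pts) < 3) {
    ph_stop("need at least 3 points for a 2D hull",
            "porehull_validation_error")
  }
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(idx) < 3) {
    ph_stop("degenerate point cloud (collinear)", "porehull_degenerate")
  }
  v <- pts[idx, , drop = FALSE]
  a2 <- sum(v[, 1] * v[c(2:nrow(v), 1), 2] - v[c(2:nrow(v), 1), 1] * v[, 2])
  if (a2 < 0) idx <- rev(idx)                      # enforce CCW
  v <- pts[idx, , drop = FALSE]
  a2 <- abs(a2)
  scale <- max(1, max(abs(pts)))
  if (a2 / 2 < tol * scale^2) {
    ph_stop("degenerate point cloud (collinear)", "porehull_degenerate")
  }
  start <- order(v[, 2], v[, 1])[1]                # lowest y, then lowest x
  if (start > 1) {
    idx <- c(idx[start:length(idx)], idx[seq_len(start - 1)])
    v <- pts[idx, , drop = FALSE]
  }
  ring <- rbind(v, v[1, , drop = FALSE])
  per <- sum(sqrt(rowSums((ring[-1, , drop = FALSE] -
                             ring[-nrow(ring), , drop = FALSE])^2)))
  list(vertex_idx = idx, ring = unname(ring), area = a2 / 2, perimeter = per,
       centroid = polygon_centroid(unname(ring)))
}

# Max pairwise distance among a small set of points (hull vertices).
max_pairwise_distance <- function(v) {
  v <- as.matrix(v)
  if (nrow(v) < 2) return(0)
  max(stats::dist(v))
}
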