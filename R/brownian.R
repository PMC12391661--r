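#' Stokes-Einstein diffusion coefficient
#'
#' D = k_B T / (6 pi eta r) for a sphere of radius `bead_radius` in a fluid of
#' viscosity `viscosity` at temperature `temperature`, with
#' k_B = 1.38e-23 J/K.
#'
#' @param temperature Temperature in kelvin.
#' @param viscosity Dynamic viscosity in Pa s.
#' @param bead_radius Bead radius in metres.
#' @return Diffusion coefficient in m^2/s. Multiply by `1e12` for um^2/s.
#' @examples
#' stokes_einstein(300, 0.001, 0.5e-6) * 1e12  # ~0.439 um^2/s
#' @export
stokes_einstein <- function(temperature, viscosity, bead_radius) {
  assert_positive(temperature, "temperature")
  assert_positive(viscosity, "viscosity")
  assert_positive(bead_radius, "bead_radius")
  kb <- 1.38e-23
  kb * temperature / (6 * pi * viscosity * bead_radius)
}

#' Diffusion parameters for the trajectory simulator
#'
#' Bundles the physical and sampling parameters of a tracking assay. Defaults
#' reproduce the usual conditions for 1 um beads in aqueous buffer imaged
#' every 5 s for 15 minutes.
#'
#' @param temperature K (default 300).
#' @param viscosity Pa s (default 0.001).
#' @param bead_radius m (default 0.5e-6, i.e. a 1 um bead).
#' @param frame_interval s (default 5).
#' @param n_steps Number of steps after the initial frame (default 180).
#' @param n_beads Number of independent beads (default 100).
#' @param seed Integer seed fixing the full output.
#' @return List of class `diffusion_params`.
#' @export
diffusion_params <- function(temperature = 300, viscosity = 0.001,
                             bead_radius = 0.5e-6, frame_interval = 5,
                             n_steps = 180, n_beads = 100, seed = 1L) {
  assert_positive(temperature, "temperature")
  assert_positive(viscosity, "viscosity")
  assert_positive(bead_radius, "bead_radius")
  assert_positive(frame_interval, "frame_interval")
  assert_positive(n_steps, "n_steps")
  assert_positive(n_beads, "n_beads")
  structure(list(temperature = temperature, viscosity = viscosity,
                 bead_radius = bead_radius, frame_interval = frame_interval,
                 n_steps = as.integer(n_steps), n_beads = as.integer(n_beads),
                 seed = as.integer(seed)),
            class = "diffusion_params")
}

#' Confinement geometries for the simulator
#'
#' Constructors for the convex, bounded domains a bead can be confined in.
#' All lengths in micrometres. The accessible region for a bead of radius r
#' is the geometry eroded by r (the bead centroid never comes closer than r
#' to a wall).
#'
#' @param radius Sphere or cylinder radius (um).
#' @param depth Cylinder depth along z (um); microwells default to 45.
#' @param half_extents Numeric length-3, box half widths (um).
#' @param vertices Numeric matrix (n x 3) of polyhedron vertices (um); the
#'   domain is their convex hull.
#' @param center Length-3 centre position (um).
#' @return List of class `confinement` with `kind` and shape parameters.
#' @name confinement
NULL

#' @rdname confinement
#' @export
confine_sphere <- function(radius, center = c(0, 0, 0)) {
  assert_positive(radius, "radius")
  structure(list(kind = "sphere", radius = radius, center = center),
            class = "confinement")
}

#' @rdname confinement
#' @export
confine_cylinder <- function(radius, depth = 45, center = c(0, 0, 0)) {
  assert_positive(radius, "radius")
  assert_positive(depth, "depth")
  structure(list(kind = "cylinder", radius = radius, depth = depth,
                 center = center),
            class = "confinement")
}

#' @rdname confinement
#' @export
confine_box <- function(half_extents, center = c(0, 0, 0)) {
  stopifnot(length(half_extents) == 3, all(half_extents > 0))
  structure(list(kind = "box", half_extents = as.numeric(half_extents),
                 center = center),
            class = "confinement")
}

#' @rdname confinement
#' @export
confine_polyhedron <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3, nrow(vertices) >= 4)
  hull <- convex_hull_3d(vertices)
  structure(list(kind = "polyhedron", vertices = vertices, hull = hull,
                 center = colMeans(vertices[hull$vertex_idx, , drop = FALSE])),
            class = "confinement")
}

# Face-plane representation of the eroded (bead-accessible) region, used for
# inside tests and specular reflection. Returns NULL for sphere/cylinder
# (handled analytically).
.eroded_planes <- function(geom, r) {
  if (geom$kind == "polyhedron") {
    h <- geom$hull
    list(normals = h$face_normals, offsets = h$face_offsets - r)
  } else {
    NULL
  }
}

.inside_eroded <- function(p, geom, r, planes = NULL, tol = 1e-12) {
  switch(geom$kind,
         sphere = {
           sum((p - geom$center)^2) <= (geom$radius - r + tol)^2
         },
         cylinder = {
           dz <- p[3] - geom$center[3]
           sum((p[1:2] - geom$center[1:2])^2) <= (geom$radius - r + tol)^2 &&
             abs(dz) <= geom$depth / 2 - r + tol
         },
         box = {
           all(abs(p - geom$center) <= geom$half_extents - r + tol)
         },
         polyhedron = {
           all(planes$normals %*% p - planes$offsets <= tol)
         })
}

# Specular-style fold of a point into the eroded region. For axis-aligned
# bounds the fold is an exact reflection; for curved walls the point is
# reflected across the wall along the surface normal at the crossing radius.
.reflect_into <- function(p, geom, r, planes = NULL) {
  switch(geom$kind,
    sphere = {
      R <- geom$radius - r
      v <- p - geom$center
      d <- sqrt(sum(v^2))
      it <- 0L
      while (d > R && it < 64L) {
        v <- v * (2 * R - d) / d
        d <- abs(2 * R - d)
        it <- it + 1L
      }
      if (d > R) v <- v * (R / d)   # pathological overshoot: clamp to wall
      geom$center + v
    },
    cylinder = {
      R <- geom$radius - r
      H <- geom$depth / 2 - r
      v <- p[1:2] - geom$center[1:2]
      d <- sqrt(sum(v^2))
      it <- 0L
      while (d > R && it < 64L) {
        v <- v * (2 * R - d) / d
        d <- abs(2 * R - d)
        it <- it + 1L
      }
      if (d > R) v <- v * (R / d)
      z <- .fold_interval(p[3] - geom$center[3], H)
      c(geom$center[1:2] + v, geom$center[3] + z)
    },
    box = {
      h <- geom$half_extents - r
      v <- p - geom$center
      for (k in 1:3) v[k] <- .fold_interval(v[k], h[k])
      geom$center + v
    },
    polyhedron = {
      q <- p
      it <- 0L
      repeat {
        s <- as.vector(planes$normals %*% q) - planes$offsets
        j <- which.max(s)
        if (s[j] <= 1e-12 || it >= 64L) break
        q <- q - 2 * s[j] * planes$normals[j, ]
        it <- it + 1L
      }
      if (max(as.vector(planes$normals %*% q) - planes$offsets) > 1e-12) {
        # fall back to pulling toward the centre until inside (rare)
        ctr <- geom$center
        for (k in 1:32) {
          q <- ctr + (q - ctr) * 0.9
          if (all(planes$normals %*% q - planes$offsets <= 1e-12)) break
        }
      }
      q
    })
}

# Exact reflection of a scalar into [-h, h].
.fold_interval <- function(x, h) {
  if (h <= 0) return(0)
  period <- 4 * h
  y <- (x + h) %% period
  if (y < 0) y <- y + period
  if (y > 2 * h) y <- period - y
  y - h
}

# Uniform sample inside the eroded region (rejection from the bounding box).
.sample_inside <- function(geom, r, planes = NULL) {
  bb <- switch(geom$kind,
    sphere = rbind(geom$center - (geom$radius - r),
                   geom$center + (geom$radius - r)),
    cylinder = rbind(geom$center - c(geom$radius - r, geom$radius - r,
                                     geom$depth / 2 - r),
                     geom$center + c(geom$radius - r, geom$radius - r,
                                     geom$depth / 2 - r)),
    box = rbind(geom$center - (geom$half_extents - r),
                geom$center + (geom$half_extents - r)),
    polyhedron = {
      v <- geom$vertices
      rbind(apply(v, 2, min) + r, apply(v, 2, max) - r)
    })
  for (i in 1:10000) {
    p <- stats::runif(3, bb[1, ], bb[2, ])
    if (.inside_eroded(p, geom, r, planes)) return(p)
  }
  geom$center
}

.tracks_from_positions <- function(pos_list, params, dims = 3L) {
  dt <- params$frame_interval
  n <- length(pos_list)
  data <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- pos_list[[i]]
    data.frame(track_id = sprintf("bead_%04d", i),
               t = (seq_len(nrow(m)) - 1) * dt,
               x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  track_set(data, frame_interval = dt,
            bead_diameter = params$bead_radius * 2e6,
            dims = dims)
}

#' Simulate freely diffusing beads
#'
#' Independent Gaussian random walks with per-axis step variance
#' `2 * D * frame_interval`, D from [stokes_einstein()]. Output positions are
#' in micrometres on the frame-interval time grid; the same seed gives an
#' identical track set.
#'
#' @param params A [diffusion_params()].
#' @param noise_sd Optional localization noise: standard deviation (um) of
#'   zero-mean Gaussian noise added to every coordinate. 0 disables (default).
#' @return A [track_set()] with `dims = 3`.
#' @examples
#' ts <- simulate_free(diffusion_params(n_beads = 10, n_steps = 20, seed = 42))
#' @export
simulate_free <- function(params, noise_sd = 0) {
  stopifnot(inherits(params, "diffusion_params"))
  D_um <- stokes_einstein(params$temperature, params$viscosity,
                          params$bead_radius) * 1e12
  sd_step <- sqrt(2 * D_um * params$frame_interval)
  n <- params$n_beads
  k <- params$n_steps
  pos <- with_seed(params$seed, {
    lapply(seq_len(n), function(i) {
      steps <- matrix(stats::rnorm(3 * k, sd = sd_step), ncol = 3)
      m <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
      if (noise_sd > 0) m <- m + matrix(stats::rnorm(length(m), sd = noise_sd),
                                        ncol = 3)
      m
    })
  })
  .tracks_from_positions(pos, params)
}

#' Simulate beads confined in a convex geometry
#'
#' Gaussian random-walk steps with specular reflection at the wall of the
#' geometry eroded by the bead radius: the bead centroid never comes closer
#' to a wall than the bead radius. Initial positions are uniform in the
#' accessible region. Fully determined by the seed.
#'
#' @param params A [diffusion_params()].
#' @param geometry A [confinement] object (sphere, cylinder, box or convex
#'   polyhedron).
#' @param noise_sd Optional localization noise sd in um (default 0). Noise is
#'   added after confinement, so noisy positions may lie slightly outside the
#'   accessible region, as in a real assay.
#' @param z_quantum Optional z-stack quantization step in um (e.g. 1 for
#'   confocal stacks); 0 disables (default).
#' @return A [track_set()] with `dims = 3`.
#' @export
simulate_confined <- function(params, geometry, noise_sd = 0, z_quantum = 0) {
  stopifnot(inherits(params, "diffusion_params"),
            inherits(geometry, "confinement"))
  r_um <- params$bead_radius * 1e6
  if (2 * r_um >= .geometry_gap(geometry)) {
    ph_stop("bead does not fit inside the confinement geometry",
            "porehull_infeasible_geometry")
  }
  D_um <- stokes_einstein(params$temperature, params$viscosity,
                          params$bead_radius) * 1e12
  sd_step <- sqrt(2 * D_um * params$frame_interval)
  planes <- .eroded_planes(geometry, r_um)
  k <- params$n_steps
  pos <- with_seed(params$seed, {
    lapply(seq_len(params$n_beads), function(i) {
      p <- .sample_inside(geometry, r_um, planes)
      steps <- matrix(stats::rnorm(3 * k, sd = sd_step), ncol = 3)
      m <- matrix(0, nrow = k + 1, ncol = 3)
      m[1, ] <- p
      for (s in seq_len(k)) {
        p <- p + steps[s, ]
        if (!.inside_eroded(p, geometry, r_um, planes)) {
          p <- .reflect_into(p, geometry, r_um, planes)
        }
        m[s + 1, ] <- p
      }
      if (noise_sd > 0) m <- m + matrix(stats::rnorm(length(m), sd = noise_sd),
                                        ncol = 3)
      if (z_quantum > 0) m[, 3] <- round(m[, 3] / z_quantum) * z_quantum
      m
    })
  })
  .tracks_from_positions(pos, params)
}

# Smallest wall-to-wall extent of a geometry (um); the bead diameter must be
# below it for the accessible region to be non-empty.
.geometry_gap <- function(geom) {
  switch(geom$kind,
         sphere = 2 * geom$radius,
         cylinder = min(2 * geom$radius, geom$depth),
         box = 2 * min(geom$half_extents),
         polyhedron = {
           h <- geom$hull
           2 * min(h$face_offsets - as.vector(h$face_normals %*% geom$center))
         },
         Inf)
}

#' Simulate a panel of microwells
#'
#' One planar (2D) track set per well diameter: cylindrical confinement of
#' the given depth, observed in projection (z discarded). Per-well seeds are
#' derived deterministically from `params$seed`, so panels are reproducible
#' element-wise.
#'
#' @param diameters Well diameters in um (e.g. `c(9, 12, 30, 55, 175, 250)`).
#' @param params A [diffusion_params()]; `n_steps` may be a single value or a
#'   vector matched to `diameters`.
#' @param depth Well depth in um (default 45).
#' @param n_steps Optional per-well override of `params$n_steps`, recycled to
#'   `length(diameters)`.
#' @return Named list of [track_set()]s, one per diameter, `dims = 2`.
#' @export
simulate_microwell_panel <- function(diameters, params, depth = 45,
                                     n_steps = NULL) {
  stopifnot(inherits(params, "diffusion_params"))
  if (!length(diameters)) return(structure(list(), names = character(0)))
  if (any(diameters <= 0)) {
    ph_stop("well diameters must be positive", "porehull_domain_error")
  }
  steps <- if (is.null(n_steps)) rep(params$n_steps, length(diameters)) else
    rep_len(as.integer(n_steps), length(diameters))
  out <- lapply(seq_along(diameters), function(i) {
    p_i <- params
    p_i$seed <- derive_seed(params$seed, i)
    p_i$n_steps <- steps[i]
    ts <- simulate_confined(p_i, confine_cylinder(diameters[i] / 2, depth))
    ts$data$z <- 0
    ts$dims <- 2L
    ts
  })
  names(out) <- as.character(diameters)
  out
}
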