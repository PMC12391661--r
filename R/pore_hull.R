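#' Convex hull of one track
#'
#' Disregards the time dimension of a track and returns the smallest convex
#' shape enclosing its localizations — the geometric model of the pore the
#' bead diffused in.
#'
#' @param coords Numeric matrix of localizations (n x 3, or n x 2 for planar
#'   data); columns x, y(, z) in micrometres.
#' @param dims 2 or 3.
#' @return For `dims = 3` the list from [convex_hull_3d()]; for `dims = 2`
#'   the list from [convex_hull_2d()].
#' @export
hull_from_track <- function(coords, dims = 3) {
  coords <- as.matrix(coords)
  dims <- as.integer(dims)
  if (dims == 3L) {
    convex_hull_3d(coords[, 1:3, drop = FALSE])
  } else if (dims == 2L) {
    convex_hull_2d(coords[, 1:2, drop = FALSE])
  } else {
    ph_stop("`dims` must be 2 or 3", "porehull_domain_error")
  }
}

#' Feret diameter of a hull
#'
#' The longest distance between any two hull vertices — the reported pore
#' diameter.
#'
#' @param hull A hull from [convex_hull_3d()] / [convex_hull_2d()], or a bare
#'   vertex coordinate matrix.
#' @param pts For a hull object, the original point matrix its `vertex_idx`
#'   indexes into; ignored when `hull` is already a coordinate matrix.
#' @return Diameter in micrometres.
#' @export
feret_diameter <- function(hull, pts = NULL) {
  v <- if (is.matrix(hull)) hull
  else if (!is.null(hull$ring)) hull$ring[-nrow(hull$ring), , drop = FALSE]
  else pts[hull$vertex_idx, , drop = FALSE]
  if (is.null(v)) {
    ph_stop("cannot extract vertices; pass `pts` for a 3D hull",
            "porehull_domain_error")
  }
  max_pairwise_distance(v)
}

#' Bead-diameter correction of a pore diameter
#'
#' Tracking reports the bead centroid, not the bead edge touching the pore
#' wall, so the raw hull diameter under-reports the pore by one bead diameter
#' (one radius on each side). The corrected diameter is
#' `diameter_raw + bead_diameter`.
#'
#' @param diameter_raw Raw hull Feret diameter(s), um.
#' @param bead_diameter Bead diameter, um.
#' @return Corrected diameter(s), um.
#' @examples
#' correct_for_bead(8, 2)  # 10
#' @export
correct_for_bead <- function(diameter_raw, bead_diameter) {
  if (any(diameter_raw < 0) || !is.finite(bead_diameter) || bead_diameter < 0) {
    ph_stop("diameters must be non-negative", "porehull_domain_error")
  }
  diameter_raw + bead_diameter
}

#' Sphericity of a 3D pore
#'
#' `pi^(1/3) * (6 V)^(2/3) / S`: the ratio of the surface area of a sphere of
#' the pore's volume to the pore's surface area. Equal to 1 for a sphere and
#' strictly below 1 for any other shape.
#'
#' @param volume Pore volume, um^3.
#' @param surface_area Pore surface area, um^2.
#' @return Dimensionless sphericity in (0, 1].
#' @examples
#' sphericity(1, 6)  # unit cube, ~0.806
#' @export
sphericity <- function(volume, surface_area) {
  if (any(volume <= 0) || any(surface_area <= 0)) {
    ph_stop("volume and surface area must be positive",
            "porehull_domain_error")
  }
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface_area
}

#' Build pore models from a track set
#'
#' Applies the convex hull to every eligible track and quantifies the
#' resulting geometric model: volume (area in 2D), surface area (perimeter in
#' 2D), raw and bead-corrected Feret diameter, sphericity (3D only) and
#' centroid. Tracks shorter than `tracks$min_track_length` or with degenerate
#' position clouds are skipped, with reasons recorded — never silently
#' repaired or projected to lower dimension.
#'
#' Only the Feret diameter is bead-corrected; volume and surface area are
#' those of the centroid hull and therefore slightly under-report the pore
#' (a full dilation by the bead radius is deliberately not applied).
#'
#' @param tracks A [track_set()].
#' @return Object of class `pore_set`: list with `pores` (list of
#'   `pore_model` objects) and `skipped` (data.frame of track_id + reason).
#' @seealso [as.data.frame.pore_set()] for the tabular summary.
#' @export
build_pore_models <- function(tracks) {
  validate_track_set(tracks)
  mats <- track_matrices(tracks)
  dims <- tracks$dims
  bead <- tracks$bead_diameter
  pores <- list()
  skipped <- data.frame(track_id = character(0), reason = character(0))
  for (id in names(mats)) {
    m <- mats[[id]]
    if (nrow(m) < tracks$min_track_length) {
      skipped <- rbind(skipped, data.frame(track_id = id, reason = "too_short"))
      next
    }
    h <- tryCatch(hull_from_track(m, dims),
                  porehull_degenerate = function(e) NULL,
                  porehull_validation_error = function(e) NULL)
    if (is.null(h)) {
      skipped <- rbind(skipped, data.frame(track_id = id, reason = "degenerate"))
      next
    }
    if (dims == 3L) {
      vmat <- m[h$vertex_idx, , drop = FALSE]
      draw <- max_pairwise_distance(vmat)
      pores[[id]] <- structure(
        list(track_id = id, dims = 3L, vertices = vmat, faces = h$faces,
             volume = h$volume, surface_area = h$surface_area,
             diameter_raw = draw,
             diameter_corrected = correct_for_bead(draw, bead),
             sphericity = sphericity(h$volume, h$surface_area),
             centroid = h$centroid),
        class = "pore_model")
    } else {
      draw <- max_pairwise_distance(h$ring[-nrow(h$ring), , drop = FALSE])
      pores[[id]] <- structure(
        list(track_id = id, dims = 2L, vertices = h$ring,
             volume = h$area, surface_area = h$perimeter,
             diameter_raw = draw,
             diameter_corrected = correct_for_bead(draw, bead),
             sphericity = NA_real_,
             centroid = h$centroid),
        class = "pore_model")
    }
  }
  structure(list(pores = pores, skipped = skipped,
                 bead_diameter = bead, dims = dims),
            class = "pore_set")
}

#' @export
print.pore_model <- function(x, ...) {
  if (x$dims == 3L) {
    cat(sprintf("<pore_model 3D> track %s: V %.4g um^3, S %.4g um^2, D %.4g um (corr %.4g), sphericity %.3f\n",
                x$track_id, x$volume, x$surface_area, x$diameter_raw,
                x$diameter_corrected, x$sphericity))
  } else {
    cat(sprintf("<pore_model 2D> track %s: area %.4g um^2, perimeter %.4g um, D %.4g um (corr %.4g)\n",
                x$track_id, x$volume, x$surface_area, x$diameter_raw,
                x$diameter_corrected))
  }
  invisible(x)
}

#' @export
print.pore_set <- function(x, ...) {
  cat(sprintf("<pore_set> %d pore model(s) (%dD), %d track(s) skipped\n",
              length(x$pores), x$dims, nrow(x$skipped)))
  invisible(x)
}

#' Tabular summary of a pore set
#'
#' @param x A `pore_set` from [build_pore_models()].
#' @param ... Unused.
#' @return data.frame with one row per pore: track_id, dims, volume,
#'   surface_area, diameter_raw, diameter_corrected, sphericity.
#' @export
as.data.frame.pore_set <- function(x, ...) {
  if (!length(x$pores)) {
    return(data.frame(track_id = character(0), dims = integer(0),
                      volume = numeric(0), surface_area = numeric(0),
                      diameter_raw = numeric(0),
                      diameter_corrected = numeric(0),
                      sphericity = numeric(0)))
  }
  df <- do.call(rbind, lapply(x$pores, function(p) {
    data.frame(track_id = p$track_id, dims = p$dims, volume = p$volume,
               surface_area = p$surface_area, diameter_raw = p$diameter_raw,
               diameter_corrected = p$diameter_corrected,
               sphericity = p$sphericity)
  }))
  rownames(df) <- NULL
  df
}
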