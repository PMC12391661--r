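# Pseudo-2D pore maps: polygon centroids, fixed-gap and front-chain
# circle-packed layouts, and rendering of the laid-out pore outlines.

#' Centroid of a closed polygon
#'
#' Area-weighted centroid of a simple polygon from its vertex ring:
#' `Cx = 1/(6A) * sum (x_i + x_{i+1}) (x_i y_{i+1} - x_{i+1} y_i)` and the
#' analogous sum for `Cy`, with `A` the signed (shoelace) polygon area. The
#' ring must be counterclockwise and closed (first vertex repeated last);
#' callers are expected to canonicalize orientation, this function refuses to.
#'
#' @param ring Numeric matrix (n x 2), n >= 4 including the closing vertex.
#' @return Numeric length-2 centroid (um).
#' @examples
#' polygon_centroid(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)))
#' @export
polygon_centroid <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2 || nrow(ring) < 4) {
    ph_stop("`ring` must be an n x 2 matrix with n >= 4 (closed triangle)",
            "porehull_domain_error")
  }
  if (any(ring[1, ] != ring[nrow(ring), ])) {
    ph_stop("polygon ring is not closed (first vertex must equal last)",
            "porehull_orientation_error")
  }
  x <- ring[-nrow(ring), 1]; y <- ring[-nrow(ring), 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (a <= 0) {
    ph_stop("polygon ring must be counterclockwise with nonzero area",
            "porehull_orientation_error")
  }
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# d3-style tangent position: centre for a new circle of radius `r` externally
# tangent to circles (x1,y1,r1) and (x2,y2,r2), on the chain's outer side.
.tangent_pos <- function(x1, y1, r1, x2, y2, r2, r) {
  dx <- x1 - x2; dy <- y1 - y2
  d2 <- dx * dx + dy * dy
  if (d2 > 0) {
    a2 <- (r2 + r)^2
    b2 <- (r1 + r)^2
    if (a2 > b2) {
      xx <- (d2 + b2 - a2) / (2 * d2)
      yy <- sqrt(max(0, b2 / d2 - xx * xx))
      c(x1 - xx * dx - yy * dy, y1 - xx * dy + yy * dx)
    } else {
      xx <- (d2 + a2 - b2) / (2 * d2)
      yy <- sqrt(max(0, a2 / d2 - xx * xx))
      c(x2 + xx * dx - yy * dy, y2 + xx * dy + yy * dx)
    }
  } else {
    c(x2 + r2 + r, y2)
  }
}

#' Pack circles with the front-chain algorithm
#'
#' Places circles one by one, each externally tangent to two circles on the
#' advancing front chain, so that no two circles overlap and every circle
#' after the second touches at least one earlier circle. Deterministic for a
#' given input order (the input order is preserved; pass
#' `order(diameters, decreasing = TRUE)`-sorted input for densest-first
#' placement). A tangent-candidate fallback guards the no-overlap contract in
#' degenerate chain configurations.
#'
#' @param diameters Positive circle diameters (um).
#' @return Data frame with columns `x`, `y`, `r` — one centre per circle, in
#'   input order. A single circle is centred at the origin.
#' @export
pack_circles <- function(diameters) {
  if (!length(diameters)) {
    return(data.frame(x = numeric(0), y = numeric(0), r = numeric(0)))
  }
  if (any(!is.finite(diameters) | diameters <= 0)) {
    ph_stop("circle diameters must be positive", "porehull_domain_error")
  }
  r <- diameters / 2
  n <- length(r)
  x <- numeric(n); y <- numeric(n)
  if (n == 1) return(data.frame(x = 0, y = 0, r = r))
  x[1] <- -r[2]; x[2] <- r[1]
  if (n == 2) return(data.frame(x = x, y = y, r = r))
  p <- .tangent_pos(x[2], y[2], r[2], x[1], y[1], r[1], r[3])
  x[3] <- p[1]; y[3] <- p[2]
  nxt <- integer(n); prv <- integer(n)
  nxt[1] <- 2; nxt[2] <- 3; nxt[3] <- 1
  prv[1] <- 3; prv[2] <- 1; prv[3] <- 2
  A <- 1L; B <- 2L

  eps <- 1e-9
  intersects <- function(i, j) {
    dr <- r[i] + r[j] - eps
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    dr > 0 && dr * dr > dx * dx + dy * dy
  }
  # squared distance from the origin to the weighted midpoint of a front pair
  chain_score <- function(i) {
    j <- nxt[i]
    ab <- r[i] + r[j]
    ((x[i] * r[j] + x[j] * r[i]) / ab)^2 + ((y[i] * r[j] + y[j] * r[i]) / ab)^2
  }
  greedy_place <- function(i) {
    placed <- seq_len(i - 1L)
    cand <- list()
    for (p_ in placed) {
      d0 <- sqrt(x[p_]^2 + y[p_]^2)
      dir <- if (d0 > 0) c(x[p_], y[p_]) / d0 else c(1, 0)
      cand[[length(cand) + 1L]] <- c(x[p_], y[p_]) + dir * (r[p_] + r[i])
    }
    if (length(placed) > 1) {
      pr <- utils::combn(placed, 2)
      for (k in seq_len(ncol(pr))) {
        p1 <- pr[1, k]; p2 <- pr[2, k]
        d <- sqrt((x[p1] - x[p2])^2 + (y[p1] - y[p2])^2)
        r1 <- r[p1] + r[i]; r2 <- r[p2] + r[i]
        if (d > r1 + r2 || d < abs(r1 - r2) || d == 0) next
        a <- (d^2 + r1^2 - r2^2) / (2 * d)
        h2 <- r1^2 - a^2
        if (h2 < 0) next
        h <- sqrt(h2)
        ux <- (x[p2] - x[p1]) / d; uy <- (y[p2] - y[p1]) / d
        mx <- x[p1] + a * ux; my <- y[p1] + a * uy
        cand[[length(cand) + 1L]] <- c(mx - h * uy, my + h * ux)
        cand[[length(cand) + 1L]] <- c(mx + h * uy, my - h * ux)
      }
    }
    best <- NULL; bestd <- Inf
    for (cc in cand) {
      d2 <- (x[placed] - cc[1])^2 + (y[placed] - cc[2])^2
      if (all(d2 >= (r[placed] + r[i] - eps)^2)) {
        dd <- cc[1]^2 + cc[2]^2
        if (dd < bestd - 1e-12 ||
            (abs(dd - bestd) <= 1e-12 && !is.null(best) &&
             (cc[1] < best[1] || (cc[1] == best[1] && cc[2] < best[2])))) {
          best <- cc; bestd <- dd
        }
      }
    }
    best
  }

  i <- 4L
  while (i <= n) {
    tries <- 0L
    repeat {
      p <- .tangent_pos(x[A], y[A], r[A], x[B], y[B], r[B], r[i])
      x[i] <- p[1]; y[i] <- p[2]
      j <- nxt[B]; k <- prv[A]; sj <- r[B]; sk <- r[A]
      hit <- FALSE
      repeat {
        if (sj <= sk) {
          if (intersects(j, i)) {
            B <- j; nxt[A] <- B; prv[B] <- A; hit <- TRUE; break
          }
          sj <- sj + r[j]; j <- nxt[j]
        } else {
          if (intersects(k, i)) {
            A <- k; nxt[A] <- B; prv[B] <- A; hit <- TRUE; break
          }
          sk <- sk + r[k]; k <- prv[k]
        }
        if (j == nxt[k]) break
      }
      tries <- tries + 1L
      if (!hit || tries > 4L * n) break
    }
    placed <- seq_len(i - 1L)
    d2 <- (x[placed] - x[i])^2 + (y[placed] - y[i])^2
    if (any(d2 < (r[placed] + r[i] - eps)^2)) {
      g <- greedy_place(i)
      if (is.null(g)) {
        ph_stop("circle packing failed to find a feasible position",
                "porehull_packing_error")
      }
      x[i] <- g[1]; y[i] <- g[2]
    }
    prv[i] <- A; nxt[i] <- B; nxt[A] <- i; prv[B] <- i; B <- i
    aa <- chain_score(A); cur <- B
    repeat {
      cur <- nxt[cur]
      if (cur == B) break
      ca <- chain_score(cur)
      if (ca < aa) { A <- cur; aa <- ca }
    }
    B <- nxt[A]
    i <- i + 1L
  }
  data.frame(x = x, y = y, r = r)
}

#' Translate a flattened pore to a target centroid
#'
#' Pure (rigid) translation: shape, area and diameter are preserved exactly.
#'
#' @param flat A `flat_pore` from [flatten_pore()].
#' @param target Numeric length-2 target centroid (um).
#' @return The translated `flat_pore`.
#' @export
reposition_pore <- function(flat, target) {
  stopifnot(inherits(flat, "flat_pore"), length(target) == 2)
  shift <- as.numeric(target) - flat$centroid
  flat$vertices_2d <- sweep(flat$vertices_2d, 2, -shift)
  flat$centroid <- as.numeric(target)
  flat
}

#' Lay out flattened pores without overlap
#'
#' Two layouts for pseudo-2D pore images: `"fixed_gap"` places the pores
#' left to right with a fixed gap between consecutive bounding boxes along
#' the x-axis; `"packed"` builds one placeholder circle per pore with
#' diameter equal to the pore's 2D Feret diameter, packs the circles with
#' [pack_circles()], and translates each pore's centroid onto its circle
#' centre (no rotation). Either way each pore is only translated, so shapes,
#' sizes and orientations are intact.
#'
#' @param flats Non-empty list of `flat_pore` objects.
#' @param mode `"fixed_gap"` or `"packed"`.
#' @param gap Gap between bounding boxes in fixed-gap mode, um (default 10).
#' @return List of class `pore_layout`: `mode`, `gap`, `placements` (data
#'   frame id/x/y and circle radius in packed mode), `pores` (repositioned
#'   `flat_pore` list).
#' @export
layout_pores <- function(flats, mode = c("fixed_gap", "packed"), gap = 10) {
  mode <- match.arg(mode)
  if (!length(flats)) {
    ph_stop("no pores to lay out", "porehull_validation_error")
  }
  ids <- vapply(flats, `[[`, character(1), "source_track_id")
  if (mode == "fixed_gap") {
    assert_nonnegative(gap, "gap")
    cursor <- 0
    targets <- matrix(0, nrow = length(flats), ncol = 2)
    out <- vector("list", length(flats))
    for (i in seq_along(flats)) {
      f <- flats[[i]]
      v <- f$vertices_2d
      w <- diff(range(v[, 1]))
      shift_x <- cursor - min(v[, 1])
      targets[i, ] <- f$centroid + c(shift_x, 0)
      out[[i]] <- reposition_pore(f, targets[i, ])
      cursor <- cursor + w + gap
    }
    placements <- data.frame(id = ids, x = targets[, 1], y = targets[, 2])
  } else {
    dia <- vapply(flats, `[[`, numeric(1), "diameter_2d")
    centers <- pack_circles(dia)
    out <- lapply(seq_along(flats), function(i) {
      reposition_pore(flats[[i]], c(centers$x[i], centers$y[i]))
    })
    placements <- data.frame(id = ids, x = centers$x, y = centers$y,
                             r = centers$r)
  }
  structure(list(mode = mode, gap = if (mode == "fixed_gap") gap else NA_real_,
                 placements = placements, pores = out),
            class = "pore_layout")
}

#' @export
print.pore_layout <- function(x, ...) {
  cat(sprintf("<pore_layout> %d pore(s), mode = %s\n",
              length(x$pores), x$mode))
  invisible(x)
}

#' Render a pore layout to SVG or PNG
#'
#' Draws the outlines of repositioned pores at a stated scale with a scale
#' bar. Files ending in `.svg` get a hand-written vector drawing (plain
#' text, deterministic); `.png` uses the standard raster device.
#'
#' @param layout A `pore_layout` (or bare list of `flat_pore`s).
#' @param path Output path ending in `.svg` or `.png`.
#' @param px_per_um Pixels per micrometre (default 2).
#' @param scale_bar_um Scale-bar length (default 10 um).
#' @return `path`, invisibly.
#' @export
render_layout <- function(layout, path, px_per_um = 2, scale_bar_um = 10) {
  pores <- if (inherits(layout, "pore_layout")) layout$pores else layout
  rings <- lapply(pores, `[[`, "vertices_2d")
  if (length(rings)) {
    allv <- do.call(rbind, rings)
    bb <- rbind(apply(allv, 2, min), apply(allv, 2, max))
  } else {
    bb <- rbind(c(0, 0), c(scale_bar_um * 2, scale_bar_um))
  }
  margin <- 5
  w_um <- diff(bb[, 1]) + 2 * margin
  h_um <- diff(bb[, 2]) + 2 * margin
  to_px <- function(v) {
    cbind((v[, 1] - bb[1, 1] + margin) * px_per_um,
          (bb[2, 2] - v[, 2] + margin) * px_per_um)   # flip y for image coords
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    lines_out <- c(
      sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f" viewBox="0 0 %.2f %.2f">',
              ceiling(w_um * px_per_um), ceiling(h_um * px_per_um),
              w_um * px_per_um, h_um * px_per_um),
      '<rect width="100%" height="100%" fill="white"/>')
    for (ring in rings) {
      p <- to_px(ring)
      lines_out <- c(lines_out,
        sprintf('<polygon points="%s" fill="#9ecae1" stroke="#08519c" stroke-width="1"/>',
                paste(sprintf("%.2f,%.2f", p[, 1], p[, 2]), collapse = " ")))
    }
    x0 <- 2 * px_per_um
    y0 <- (h_um - 2) * px_per_um
    lines_out <- c(lines_out,
      sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="black" stroke-width="3"/>',
              x0, y0, x0 + scale_bar_um * px_per_um, y0),
      sprintf('<text x="%.2f" y="%.2f" font-size="10">%g um</text>',
              x0, y0 - 4, scale_bar_um),
      '</svg>')
    ok <- tryCatch({
      writeLines(lines_out, path); TRUE
    }, error = function(e) FALSE)
    if (!ok) ph_stop(sprintf("cannot write `%s`", path), "porehull_io_error")
  } else if (ext == "png") {
    grDevices::png(path, width = ceiling(w_um * px_per_um),
                   height = ceiling(h_um * px_per_um))
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot(NA, xlim = c(bb[1, 1] - margin, bb[2, 1] + margin),
                   ylim = c(bb[1, 2] - margin, bb[2, 2] + margin),
                   asp = 1, axes = FALSE, xlab = "", ylab = "")
    for (ring in rings) {
      graphics::polygon(ring[, 1], ring[, 2], col = "#9ecae1",
                        border = "#08519c")
    }
    graphics::segments(bb[1, 1] - margin + 2, bb[1, 2] - margin + 2,
                       bb[1, 1] - margin + 2 + scale_bar_um,
                       bb[1, 2] - margin + 2, lwd = 3)
  } else {
    ph_stop("`path` must end in .svg or .png", "porehull_io_error")
  }
  invisible(path)
}
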