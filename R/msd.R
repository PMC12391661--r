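#' Ensemble mean squared displacement
#'
#' Computes the displacement-from-origin MSD: for each time t on the frame
#' grid, the mean over beads of the squared distance between the bead's
#' position at t and its own first position,
#' `MSD(t) = (1/N_t) * sum_i ||p_i(t) - p_i(0)||^2`,
#' averaged over the `N_t` tracks that have a localization at t. This is the
#' from-origin convention used for confinement analysis, not the lag-time
#' averaged MSD. Each track's clock is rebased so its first localization sits
#' at t = 0.
#'
#' @param tracks A [track_set()].
#' @return Data frame of class `msd_curve` with columns `t` (s), `msd`
#'   (um^2, `msd[1] == 0`) and `n_beads` (tracks contributing at each time).
#' @examples
#' ts <- simulate_free(diffusion_params(n_beads = 50, n_steps = 30, seed = 7))
#' head(compute_msd(ts))
#' @export
compute_msd <- function(tracks) {
  validate_track_set(tracks)
  d <- tracks$data
  first <- !duplicated(d$track_id)
  ref <- d[first, c("track_id", "t", "x", "y", "z")]
  j <- match(d$track_id, ref$track_id)
  dt_rel <- d$t - ref$t[j]
  disp2 <- (d$x - ref$x[j])^2 + (d$y - ref$y[j])^2 + (d$z - ref$z[j])^2
  # snap to the frame grid to make float times group exactly
  grid <- round(dt_rel / tracks$frame_interval)
  msd <- tapply(disp2, grid, mean)
  nb <- tapply(disp2, grid, length)
  tt <- as.numeric(names(msd)) * tracks$frame_interval
  o <- order(tt)
  out <- data.frame(t = tt[o], msd = as.numeric(msd)[o],
                    n_beads = as.integer(nb)[o])
  rownames(out) <- NULL
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d timepoints, t in [%g, %g] s, max MSD %.4g um^2\n",
              nrow(x), min(x$t), max(x$t), max(x$msd)))
  NextMethod()
}

# Plateau window: the longest suffix of the curve whose log-log slope
# (ordinary least squares over the whole suffix, which is robust to the
# frame-to-frame noise of small ensembles) stays below `slope_max`; it must
# cover at least `min_frac` of the timepoints. Suffix slopes for every start
# index are computed in one pass via reverse cumulative sums.
.detect_plateau <- function(curve, slope_max = 0.1, min_frac = 0.2) {
  use <- curve$t > 0 & curve$msd > 0
  t <- curve$t[use]; m <- curve$msd[use]
  n <- length(t)
  if (n < 3) return(NULL)
  lx <- log(t); ly <- log(m)
  rc <- function(v) rev(cumsum(rev(v)))
  ns <- n - seq_len(n) + 1
  sx <- rc(lx); sy <- rc(ly); sxx <- rc(lx^2); sxy <- rc(lx * ly)
  slope <- (sxy - sx * sy / ns) / (sxx - sx^2 / ns)
  cand <- which(is.finite(slope) & slope < slope_max & ns >= 3)
  if (!length(cand)) return(NULL)
  s <- cand[1]
  if (n - s + 1 < max(3, ceiling(min_frac * n))) return(NULL)
  c(t[s], t[n])
}

#' Diffusion length from the MSD plateau
#'
#' Fits an ordinary least-squares line over the plateau region of a confined
#' MSD curve, extrapolates it to time zero, and takes the square root of the
#' intercept as the diffusion length — the length scale a confined bead
#' explores, proportional to the average pore size.
#'
#' @param curve An [compute_msd()] curve.
#' @param plateau_window Optional numeric length-2 time range (s) to fit
#'   over; when `NULL` the plateau is auto-detected as the longest suffix of
#'   the curve with local log-log slope below 0.1 (at least 20% of the
#'   timepoints).
#' @return Object of class `msd_fit` with `diffusion_length` (um),
#'   `plateau_intercept` (um^2), `plateau_slope`, `plateau_window`.
#' @export
fit_diffusion_length <- function(curve, plateau_window = NULL) {
  stopifnot(inherits(curve, "msd_curve") || is.data.frame(curve))
  if (is.null(plateau_window)) {
    plateau_window <- .detect_plateau(curve)
    if (is.null(plateau_window)) {
      ph_stop("no MSD plateau detected: curve is non-confined",
              "porehull_regime_error")
    }
  }
  sel <- curve$t >= plateau_window[1] & curve$t <= plateau_window[2]
  if (sum(sel) < 2) {
    ph_stop("plateau window contains fewer than 2 points",
            "porehull_fit_error")
  }
  fit <- stats::lm(msd ~ t, data = curve[sel, , drop = FALSE])
  intercept <- unname(stats::coef(fit)[1])
  if (intercept < 0) {
    ph_stop("negative plateau intercept; try a later plateau window",
            "porehull_fit_error")
  }
  structure(list(diffusion_length = sqrt(intercept),
                 plateau_intercept = intercept,
                 plateau_slope = unname(stats::coef(fit)[2]),
                 plateau_window = plateau_window),
            class = "msd_fit")
}

#' Diffusion exponent from the log-log MSD slope
#'
#' Fits `MSD = 6 D t^n` by ordinary least squares of `ln(MSD)` on `ln(t)`:
#' the slope is the diffusion exponent n (1 for free diffusion, < 1 for
#' confined/sub-diffusive motion) and the intercept recovers the effective
#' diffusion coefficient via `exp(intercept) = 6 D`.
#'
#' @param curve An [compute_msd()] curve.
#' @param window Optional time range (s); defaults to the whole curve from
#'   the first frame on (t = 0 is always excluded).
#' @return Object of class `msd_fit` with `diffusion_exponent`,
#'   `effective_D` (um^2/s) and `exponent_window`.
#' @export
fit_diffusion_exponent <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "msd_curve") || is.data.frame(curve))
  use <- curve$t > 0 & curve$msd > 0
  if (!is.null(window)) use <- use & curve$t >= window[1] & curve$t <= window[2]
  if (sum(use) < 3) {
    ph_stop("need at least 3 positive-MSD points to fit the exponent",
            "porehull_fit_error")
  }
  d <- curve[use, , drop = FALSE]
  fit <- stats::lm(log(msd) ~ log(t), data = d)
  n_exp <- unname(stats::coef(fit)[2])
  effD <- exp(unname(stats::coef(fit)[1])) / 6
  structure(list(diffusion_exponent = n_exp,
                 effective_D = effD,
                 exponent_window = range(d$t)),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat("<msd_fit>\n")
  if (!is.null(x$diffusion_length)) {
    cat(sprintf("  diffusion length: %.4g um (plateau intercept %.4g um^2, window %g-%g s)\n",
                x$diffusion_length, x$plateau_intercept,
                x$plateau_window[1], x$plateau_window[2]))
  }
  if (!is.null(x$diffusion_exponent)) {
    cat(sprintf("  diffusion exponent n: %.4g (effective D %.4g um^2/s) -> %s\n",
                x$diffusion_exponent, x$effective_D, classify_regime(x)))
  }
  invisible(x)
}

#' @export
coef.msd_fit <- function(object, ...) {
  out <- c(diffusion_length = object$diffusion_length,
           plateau_intercept = object$plateau_intercept,
           diffusion_exponent = object$diffusion_exponent,
           effective_D = object$effective_D)
  out[!is.na(out)]
}

#' Classify the diffusion regime from a fitted exponent
#'
#' @param fit An `msd_fit` with a `diffusion_exponent`, or a bare number.
#' @param tol Half-width of the "free" band around n = 1 (default 0.05).
#' @return One of `"sub-diffusive"`, `"free"`, `"super-diffusive"`.
#' @export
classify_regime <- function(fit, tol = 0.05) {
  n <- if (is.numeric(fit)) fit else fit$diffusion_exponent
  if (is.null(n) || !is.finite(n)) {
    ph_stop("fit has no finite diffusion exponent", "porehull_fit_error")
  }
  if (abs(n - 1) <= tol) "free" else if (n < 1) "sub-diffusive" else "super-diffusive"
}

#' @export
plot.msd_curve <- function(x, ..., log = "") {
  graphics::plot(x$t, x$msd, type = "l", xlab = "time (s)",
                 ylab = expression(MSD ~ (mu * m^2)), log = log, ...)
  invisible(x)
}
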