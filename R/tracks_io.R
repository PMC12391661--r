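#' Build a track set from a localization table
#'
#' A track set is the package's central container: one row per localization
#' (bead position at one frame) plus the assay metadata every downstream
#' computation needs. Positions are in micrometres and times in seconds
#' throughout the package.
#'
#' @param data data.frame with columns `track_id`, `t` (seconds), `x`, `y`
#'   and optionally `z` (micrometres). A missing or all-`NA` `z` column marks
#'   a planar (2D) assay and is stored as zero.
#' @param frame_interval Time between frames in seconds (default 5, the usual
#'   acquisition interval for hydrogel bead tracking).
#' @param bead_diameter Tracer bead diameter in micrometres (default 1).
#' @param pixel_size Camera pixel size in micrometres; metadata only
#'   (default 0.46).
#' @param dims 2 or 3. Defaults to 3 when a non-degenerate `z` is present,
#'   2 otherwise.
#' @param min_track_length Minimum number of localizations for a track to be
#'   eligible for convex-hull analysis (default 10). Shorter tracks are kept
#'   (they still contribute to the MSD) but flagged.
#'
#' @return An object of class `track_set`: a list with elements `data`
#'   (localization table sorted by track then time), `frame_interval`,
#'   `bead_diameter`, `pixel_size`, `dims`, `min_track_length`.
#' @seealso [read_tracks()], [write_tracks()], [simulate_free()]
#' @export
track_set <- function(data, frame_interval = 5, bead_diameter = 1,
                      pixel_size = 0.46, dims = NULL, min_track_length = 10) {
  assert_positive(frame_interval, "frame_interval")
  assert_positive(bead_diameter, "bead_diameter")
  assert_positive(pixel_size, "pixel_size")
  assert_positive(min_track_length, "min_track_length")
  stopifnot(is.data.frame(data))
  required <- c("track_id", "t", "x", "y")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    ph_stop(sprintf("localization table lacks required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "porehull_format_error")
  }
  has_z <- "z" %in% names(data) && !all(is.na(data$z))
  if (!has_z) data$z <- rep(0, nrow(data))
  if (is.null(dims)) dims <- if (has_z) 3L else 2L
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) {
    ph_stop("`dims` must be 2 or 3", "porehull_domain_error")
  }
  data <- data.frame(track_id = as.character(data$track_id),
                     t = as.numeric(data$t),
                     x = as.numeric(data$x),
                     y = as.numeric(data$y),
                     z = as.numeric(data$z),
                     stringsAsFactors = FALSE)
  if (nrow(data)) {
    if (any(!is.finite(as.matrix(data[c("t", "x", "y", "z")])))) {
      ph_stop("localizations contain non-finite values",
              "porehull_validation_error")
    }
    if (any(data$t < 0)) {
      ph_stop("negative times in localization table",
              "porehull_validation_error")
    }
    data <- data[order(data$track_id, data$t), , drop = FALSE]
    rownames(data) <- NULL
    bad <- vapply(split(data$t, data$track_id),
                  function(tt) any(diff(tt) <= 0), logical(1))
    if (any(bad)) {
      ph_stop(sprintf("non-monotonic time within track(s): %s",
                      paste(names(bad)[bad], collapse = ", ")),
              "porehull_validation_error")
    }
  }
  structure(
    list(data = data,
         frame_interval = frame_interval,
         bead_diameter = bead_diameter,
         pixel_size = pixel_size,
         dims = dims,
         min_track_length = min_track_length),
    class = "track_set"
  )
}

#' @export
print.track_set <- function(x, ...) {
  n_tracks <- length(unique(x$data$track_id))
  cat(sprintf("<track_set> %d track(s), %d localization(s), %dD\n",
              n_tracks, nrow(x$data), x$dims))
  cat(sprintf("  frame interval %g s | bead diameter %g um | pixel %g um\n",
              x$frame_interval, x$bead_diameter, x$pixel_size))
  invisible(x)
}

#' Validate a track set
#'
#' Checks the structural invariants downstream modules rely on: unique track
#' ids with strictly increasing times, at least two localizations per track,
#' finite coordinates and positive metadata. Errors rather than repairing.
#'
#' @param tracks A [track_set()].
#' @param allow_short Logical; allow tracks with fewer than 2 localizations
#'   (default FALSE).
#' @return `tracks`, invisibly.
#' @export
validate_track_set <- function(tracks, allow_short = FALSE) {
  if (!inherits(tracks, "track_set")) {
    ph_stop("expected a `track_set` object", "porehull_validation_error")
  }
  if (nrow(tracks$data) == 0) {
    ph_stop("track set is empty", "porehull_validation_error")
  }
  len <- table(tracks$data$track_id)
  if (!allow_short && any(len < 2)) {
    ph_stop(sprintf("track(s) with fewer than 2 localizations: %s",
                    paste(names(len)[len < 2], collapse = ", ")),
            "porehull_validation_error")
  }
  invisible(tracks)
}

# Column-name normalization: accepts both the package's minimal dialect and
# the usual tracking-software export headers (e.g. "TRACK_ID", "POSITION_X",
# "POSITION_T", "Time", "Frame").
.normalize_columns <- function(df) {
  nm <- tolower(gsub("[^A-Za-z]+", "_", names(df)))
  pick <- function(cands) {
    hit <- which(nm %in% cands)
    if (length(hit)) hit[1] else NA_integer_
  }
  map <- c(track_id = pick(c("track_id", "trackid", "id", "particle", "track")),
           t = pick(c("t", "time", "position_t", "t_s", "time_s")),
           frame = pick(c("frame", "frame_index", "spot_frame")),
           x = pick(c("x", "position_x", "x_um")),
           y = pick(c("y", "position_y", "y_um")),
           z = pick(c("z", "position_z", "z_um")))
  out <- list()
  for (k in names(map)) if (!is.na(map[[k]])) out[[k]] <- df[[map[[k]]]]
  out
}

#' Read particle trajectories from a delimited text file
#'
#' Reads a CSV spot/track export (header row required) with columns for the
#' track identifier, time (seconds) or frame index, and x/y and optionally z
#' positions in micrometres. Frame indices are converted to seconds with
#' `frame_interval`; a file without a z column yields a planar (2D) track set.
#'
#' @param path Path to a CSV file.
#' @param frame_interval,bead_diameter,pixel_size,min_track_length Assay
#'   metadata; see [track_set()].
#' @return A [track_set()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(track_id = 1, frame = 0:2, x = 0:2, y = 0),
#'           f, row.names = FALSE)
#' read_tracks(f, frame_interval = 5)
#' @export
read_tracks <- function(path, frame_interval = 5, bead_diameter = 1,
                        pixel_size = 0.46, min_track_length = 10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- .normalize_columns(df)
  for (k in c("track_id", "x", "y")) {
    if (is.null(cols[[k]])) {
      ph_stop(sprintf("input file `%s` lacks required column `%s`", path, k),
              "porehull_format_error")
    }
  }
  if (is.null(cols[["t"]])) {
    if (is.null(cols[["frame"]])) {
      ph_stop(sprintf("input file `%s` lacks a time or frame column", path),
              "porehull_format_error")
    }
    cols[["t"]] <- as.numeric(cols[["frame"]]) * frame_interval
  }
  data <- data.frame(track_id = cols[["track_id"]], t = cols[["t"]],
                     x = cols[["x"]], y = cols[["y"]])
  if (!is.null(cols[["z"]])) data$z <- cols[["z"]]
  track_set(data,
            frame_interval = frame_interval, bead_diameter = bead_diameter,
            pixel_size = pixel_size, min_track_length = min_track_length)
}

#' Write a track set to CSV
#'
#' Writes the minimal dialect (`track_id,t,x,y[,z]`); the z column is dropped
#' for planar track sets so that reading the file back reproduces `dims`.
#' Round trip through [read_tracks()] preserves ids, times and coordinates to
#' full precision.
#'
#' @param tracks A [track_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (!inherits(tracks, "track_set")) {
    ph_stop("expected a `track_set` object", "porehull_validation_error")
  }
  df <- tracks$data
  if (tracks$dims == 2L) df$z <- NULL
  # full-precision round trip
  for (k in setdiff(names(df), "track_id")) {
    df[[k]] <- sprintf("%.17g", df[[k]])
  }
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) {
             ph_stop(sprintf("cannot write `%s`: %s", path, conditionMessage(e)),
                     "porehull_io_error")
           })
  invisible(path)
}

# Split a track set into per-track coordinate matrices (n x 3), named by id.
track_matrices <- function(tracks) {
  d <- tracks$data
  lapply(split(seq_len(nrow(d)), d$track_id), function(i) {
    m <- as.matrix(d[i, c("x", "y", "z"), drop = FALSE])
    rownames(m) <- NULL
    m
  })
}

#' Read an assay configuration from YAML
#'
#' Reads keys `frame_interval_s`, `bead_diameter_um`, `pixel_size_um`,
#' `min_track_length` (all optional) and returns them merged over defaults.
#'
#' @param path YAML file path.
#' @return Named list of metadata values suitable for [read_tracks()].
#' @export
read_assay_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(frame_interval = cfg$frame_interval_s %||% 5,
       bead_diameter = cfg$bead_diameter_um %||% 1,
       pixel_size = cfg$pixel_size_um %||% 0.46,
       min_track_length = cfg$min_track_length %||% 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
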