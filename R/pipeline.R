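#' Run the full pore-analysis pipeline
#'
#' Orchestrates simulate -> MSD -> pore hulls -> simulated SEM sections ->
#' pseudo-2D layout, writing a deterministic plain-text artifact tree:
#' `tracks.csv`, `msd.csv`, `fit.json`, `pores.csv`, `pores_vertices.json`,
#' `flat_pores.json`, `sem_diameters.csv`, `comparison.json` (when a
#' reference sample is supplied), `layout.json`, `pores.svg` and
#' `run_config.yaml`. Every stochastic stage derives its seed from the global
#' `seed`, so a fixed seed reproduces all numeric outputs byte for byte.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{seed}{global integer seed (default 1)}
#'     \item{out_dir}{output directory (created if missing)}
#'     \item{simulate}{list: `geometry` ("sphere", "cylinder", "box" or
#'       "free"), `diameter_um`, `depth_um`, `bead_um`, `temp_k`,
#'       `viscosity`, `interval_s`, `steps`, `beads`; or `tracks_csv` to use
#'       an existing trajectory file instead}
#'     \item{sem}{list: `volume_budget`, `min_diameter` (required for the
#'       SEM stage), `min_area`, optional `reference_csv` of cross-sectional
#'       diameters to compare against}
#'     \item{layout}{list: `mode` ("fixed_gap" or "packed"), `gap_um`}
#'   }
#' @return The output directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulate %||% list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- tracks --------------------------------------------------------------
  tracks <- stage("simulate", {
    if (!is.null(sim$tracks_csv)) {
      read_tracks(sim$tracks_csv,
                  frame_interval = sim$interval_s %||% 5,
                  bead_diameter = sim$bead_um %||% 1)
    } else {
      params <- diffusion_params(
        temperature = sim$temp_k %||% 300,
        viscosity = sim$viscosity %||% 0.001,
        bead_radius = (sim$bead_um %||% 1) / 2 * 1e-6,
        frame_interval = sim$interval_s %||% 5,
        n_steps = sim$steps %||% 180,
        n_beads = sim$beads %||% 50,
        seed = derive_seed(seed, 1))
      geom_kind <- sim$geometry %||% "sphere"
      if (geom_kind == "free") {
        simulate_free(params)
      } else {
        geom <- switch(geom_kind,
          sphere = confine_sphere((sim$diameter_um %||% 18) / 2),
          cylinder = confine_cylinder((sim$diameter_um %||% 30) / 2,
                                      sim$depth_um %||% 45),
          box = confine_box(rep((sim$diameter_um %||% 18) / 2, 3)),
          ph_stop(sprintf("unknown geometry `%s`", geom_kind),
                  "porehull_config_error"))
        simulate_confined(params, geom)
      }
    }
  })
  write_tracks(tracks, file.path(out_dir, "tracks.csv"))

  # --- MSD -----------------------------------------------------------------
  curve <- stage("msd", compute_msd(tracks))
  utils::write.csv(as.data.frame(unclass(curve)),
                   file.path(out_dir, "msd.csv"), row.names = FALSE)
  fit_exp <- stage("msd", fit_diffusion_exponent(curve))
  fit_len <- tryCatch(fit_diffusion_length(curve), error = function(e) NULL)
  fit_out <- list(diffusion_exponent = fit_exp$diffusion_exponent,
                  effective_D_um2_s = fit_exp$effective_D,
                  regime = classify_regime(fit_exp))
  if (!is.null(fit_len)) {
    fit_out$diffusion_length_um <- fit_len$diffusion_length
    fit_out$plateau_window_s <- fit_len$plateau_window
  }
  jsonlite::write_json(fit_out, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- pore hulls ----------------------------------------------------------
  pores <- stage("pores", build_pore_models(tracks))
  utils::write.csv(as.data.frame(pores), file.path(out_dir, "pores.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(pores$pores, function(p) {
      list(track_id = p$track_id, dims = p$dims,
           vertices = unname(apply(p$vertices, 1, as.numeric,
                                   simplify = FALSE)))
    }),
    file.path(out_dir, "pores_vertices.json"), auto_unbox = TRUE, digits = NA)

  # --- simulated SEM sections ---------------------------------------------
  flats <- NULL
  if (tracks$dims == 3L && length(pores$pores)) {
    semcfg <- config$sem %||% list()
    if (is.null(semcfg$min_diameter)) {
      stop("pipeline stage `sem-sim` failed: sem$min_diameter is required ",
           "(smallest diameter resolvable in the reference micrographs)",
           call. = FALSE)
    }
    policy <- sampling_policy(
      volume_budget = semcfg$volume_budget %||% 300000,
      min_diameter = semcfg$min_diameter,
      min_area = semcfg$min_area %||% 10,
      seed = derive_seed(seed, 2))
    sel <- stage("sem-sim", sample_pores_by_volume(pores, policy))
    flats <- stage("sem-sim", lapply(sel, flatten_pore))
    flats <- apply_resolution_filter(flats, policy)
    dia <- vapply(flats, `[[`, numeric(1), "diameter_2d")
    utils::write.csv(data.frame(
      track_id = vapply(flats, `[[`, character(1), "source_track_id"),
      diameter_2d = dia),
      file.path(out_dir, "sem_diameters.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(flats, function(f) {
        list(source_track_id = f$source_track_id,
             area = f$area, diameter_2d = f$diameter_2d,
             centroid = f$centroid,
             ring = unname(apply(f$vertices_2d, 1, as.numeric,
                                 simplify = FALSE)))
      }),
      file.path(out_dir, "flat_pores.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(semcfg$reference_csv)) {
      ref <- utils::read.csv(semcfg$reference_csv)[[1]]
      cmp <- stage("sem-sim", compare_distributions(dia, ref))
      jsonlite::write_json(cmp, file.path(out_dir, "comparison.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  # --- pseudo-2D layout ----------------------------------------------------
  if (!is.null(flats) && length(flats)) {
    laycfg <- config$layout %||% list()
    lay <- stage("render", layout_pores(
      flats, mode = laycfg$mode %||% "packed", gap = laycfg$gap_um %||% 10))
    jsonlite::write_json(lay$placements, file.path(out_dir, "layout.json"),
                         auto_unbox = TRUE, digits = NA)
    stage("render", render_layout(lay, file.path(out_dir, "pores.svg")))
  }

  yaml::write_yaml(config, file.path(out_dir, "run_config.yaml"))
  invisible(out_dir)
}
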