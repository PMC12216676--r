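#' Default analysis configuration
#'
#' Returns the nested list of tunable parameters used throughout the pipeline.
#' Any subset can be overridden by passing a list with the same structure;
#' unknown keys raise an error so that typos in run configs are caught early.
#'
#' @param overrides optional nested list overriding individual entries.
#'
#' @return A nested list with components `segment`, `planes` and `match`.
#'
#' @details
#' Segmentation (`segment`):
#' \describe{
#'   \item{min_cell_score}{cells scoring below this are treated as empty
#'     (label 0). Separates noise-only cells from crystal diffraction.}
#'   \item{similarity_threshold}{minimum spot-position similarity between
#'     4-adjacent cells for them to join the same crystal region.}
#'   \item{match_radius_px}{pixel radius within which two spots in adjacent
#'     images count as the same reflection.}
#'   \item{similarity_max_spots}{per-cell cap on spots used for the
#'     similarity measure (strongest first).}
#'   \item{min_spots_multipattern}{evidence floor below which a cell is never
#'     flagged as multi-pattern.}
#'   \item{multipattern_fraction}{a cell is multi-pattern when the
#'     difference-vector mass inconsistent with a single projected lattice
#'     exceeds this fraction of the explained mass.}
#'   \item{pairing_tolerance_cells}{maximum rotation-axis centroid offset (in
#'     grid cells) for a cross-scan pair candidate.}
#'   \item{apertures_um}{available beam apertures; the recommendation is the
#'     smallest one at least as large as the region's smaller extent.}
#' }
#'
#' Periodicity search (`planes`):
#' \describe{
#'   \item{n_directions}{size of the quasi-uniform hemisphere direction set.}
#'   \item{bin_width_invA}{projection histogram bin width (1/angstrom).}
#'   \item{smooth_sigma_bins}{sigma of the Gaussian moving average used as
#'     offset/scale in histogram normalisation.}
#'   \item{p_floor}{bins whose moving average is at or below this are dropped
#'     from the normalised histogram.}
#'   \item{g_max}{Fourier components where the moving-average subtraction
#'     passes more than this fraction of the signal are masked (they are not
#'     Rayleigh-calibrated).}
#'   \item{min_period_A}{shortest direct-space period (angstrom) considered.}
#'   \item{top_k}{number of coarse-scan directions carried into refinement.}
#'   \item{refine_step_deg, refine_max_eval}{initial simplex step and
#'     evaluation cap of the direction refinement.}
#'   \item{plane_threshold}{refined Fourier score a direction must exceed to
#'     become a plane vector (unit-Rayleigh scale).}
#'   \item{dedup_angle_deg, dedup_freq_rel}{plane vectors closer than this in
#'     direction (as lines) and relative period are duplicates.}
#'   \item{min_nodes}{fewer nodes than this yields no plane vectors.}
#'   \item{node_cap}{pooled node lists are thinned to this size.}
#' }
#'
#' Cross-scan matching (`match`):
#' \describe{
#'   \item{match_threshold}{check() score above which a candidate pair is
#'     declared the same crystal.}
#'   \item{window_bins}{half-width (Fourier bins) of the frequency window
#'     searched around the rotated plane vector's expected frequency.
#'     Rotation preserves the vector's length, so the window only needs to
#'     absorb the sub-bin interpolation error of the source peak; a wide
#'     window admits near-coincident high-order families of unrelated
#'     crystals and inflates the false-match rate.}
#'   \item{direction_tol_deg}{a winning check is confirmed by refining the
#'     plane direction on the target's own nodes; if the local optimum
#'     sits further than this from the rotated vector the periodicity
#'     belongs to a different (coincidentally aligned) family and the
#'     combination is rejected.}
#' }
#'
#' @examples
#' cfg <- crossmesh_config(list(planes = list(n_directions = 500)))
#' cfg$planes$n_directions
#' @export
crossmesh_config <- function(overrides = NULL) {
  cfg <- list(
    segment = list(
      min_cell_score = 5,
      similarity_threshold = 0.4,
      match_radius_px = 4,
      similarity_max_spots = 200,
      min_spots_multipattern = 20,
      multipattern_fraction = 0.2,
      pairing_tolerance_cells = 1.5,
      apertures_um = c(10, 20, 30, 50)
    ),
    planes = list(
      n_directions = 2500,
      bin_width_invA = 0.002,
      smooth_sigma_bins = 10,
      p_floor = 0.5,
      g_max = 0.02,
      min_period_A = 10,
      top_k = 10,
      refine_step_deg = 0.5,
      refine_max_eval = 40,
      plane_threshold = 7,
      dedup_angle_deg = 2,
      dedup_freq_rel = 0.02,
      min_nodes = 50,
      node_cap = 4000
    ),
    match = list(
      match_threshold = 5,
      window_bins = 1,
      direction_tol_deg = 1.25
    )
  )
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides, "config")
  cfg
}

merge_config <- function(base, over, path) {
  if (!is.list(over)) {
    stop(sprintf("config entry '%s' must be a list", path), call. = FALSE)
  }
  for (nm in names(over)) {
    if (is.null(nm) || !nzchar(nm) || !nm %in% names(base)) {
      stop(sprintf("unknown config key '%s.%s'", path, nm), call. = FALSE)
    }
    if (is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]], paste(path, nm, sep = "."))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}
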