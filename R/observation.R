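# TIRF-like observation model: stochastic labeling of bound molecules,
# optical broadening, and summation of the two grooves into a fluorescence
# level of 0, 1 or 2 per site.  Processing order is fixed:
# label -> broaden -> sum.

#' Observation-model settings
#'
#' @param labeled_fraction Fraction of molecules carrying a dye
#'   (default 0.2: with ~20% labeling, 80% of occupied sites are dark).
#' @param broadening_radius_sites Optical broadening radius in sites
#'   (default 4, i.e. +/- ~100 nm at 21.6 nm per site).
#' @param frame_interval Kymograph frame spacing in seconds.
#' @param labeling_mode `"per-molecule"` assigns each molecule a
#'   persistent label at binding (temporally coherent kymographs);
#'   `"per-snapshot"` redraws the visible subset independently in every
#'   frame (the literal replace-80%-of-occupied-sites post-processing).
#' @return An `observation_settings` object.
#' @export
observation_settings <- function(labeled_fraction = 0.2,
                                 broadening_radius_sites = 4,
                                 frame_interval = 2.5,
                                 labeling_mode = c("per-molecule",
                                                   "per-snapshot")) {
  stopifnot(labeled_fraction >= 0, labeled_fraction <= 1,
            broadening_radius_sites >= 0, frame_interval > 0)
  structure(
    list(labeled_fraction = labeled_fraction,
         broadening_radius_sites = as.integer(broadening_radius_sites),
         frame_interval = frame_interval,
         labeling_mode = match.arg(labeling_mode)),
    class = "observation_settings"
  )
}

#' Draw persistent molecule labels
#'
#' One Bernoulli(labeled_fraction) draw per molecule identity, reused for
#' every snapshot of a trajectory in per-molecule mode.
#'
#' @param n_molecules Number of molecule identities in the trajectory.
#' @param labeled_fraction Probability that a molecule is labeled.
#' @return Logical vector of length `n_molecules`.
#' @export
molecule_labels <- function(n_molecules, labeled_fraction = 0.2) {
  runif(n_molecules) < labeled_fraction
}

#' Apply stochastic labeling to a snapshot
#'
#' Keeps each occupied site visible with probability `labeled_fraction`
#' and darkens the rest; empty sites are unchanged.  In per-molecule mode
#' the snapshot must carry molecule ids and `labels` must be supplied so
#' the same molecule is visible (or dark) in every frame.
#'
#' @param snapshot 2 x N matrix: binary occupancy (per-snapshot mode) or
#'   molecule ids with 0 = empty (per-molecule mode).
#' @param settings An [observation_settings()].
#' @param labels Logical vector from [molecule_labels()] (per-molecule
#'   mode only).
#' @return 2 x N binary matrix of visible fluorophores.
#' @export
apply_labeling <- function(snapshot, settings, labels = NULL) {
  snapshot <- as.matrix(snapshot)
  occ <- snapshot > 0
  if (settings$labeling_mode == "per-molecule") {
    if (is.null(labels))
      abort("per-molecule labeling needs a `labels` vector (see molecule_labels())")
    vis <- occ
    vis[occ] <- labels[snapshot[occ]]
  } else {
    vis <- occ
    vis[occ] <- runif(sum(occ)) < settings$labeled_fraction
  }
  mode(vis) <- "integer"
  vis
}

#' Optical broadening of one groove row
#'
#' Binary dilation: a site is lit iff any visible fluorophore lies within
#' `radius` sites in the same row, clipped at the filament ends.
#'
#' @param row Binary vector (one groove).
#' @param radius Broadening radius in sites.
#' @return Binary vector of the same length.
#' @export
#' @examples
#' broaden(c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0), radius = 4)
broaden <- function(row, radius) {
  n <- length(row)
  if (radius == 0 || n == 0) return(as.integer(row > 0))
  lit <- which(row > 0)
  out <- integer(n)
  for (i in lit) out[max(1, i - radius):min(n, i + radius)] <- 1L
  out
}

#' Sum the two broadened groove rows
#'
#' @param row1,row2 Binary vectors of equal length.
#' @return Integer vector of fluorescence levels 0, 1 or 2.
#' @export
sum_rows <- function(row1, row2) {
  stopifnot(length(row1) == length(row2))
  as.integer(row1) + as.integer(row2)
}

process_snapshot <- function(snapshot, settings, labels = NULL) {
  vis <- apply_labeling(snapshot, settings, labels)
  r <- settings$broadening_radius_sites
  sum_rows(broaden(vis[1, ], r), broaden(vis[2, ], r))
}

#' Raw coverage fractions of a lattice state
#'
#' Computed on the raw (unlabeled, unbroadened) occupancy: total
#' occupancy is the bound length over twice the filament length; single
#' and double fractions are the fractions of filament length covered by
#' exactly one or both cables.  The identity
#' `total = (single + 2 * double) / 2` holds exactly.
#'
#' @param state A [lattice_state()], a 2 x N occupancy matrix, or a
#'   `lattice_trajectory` (its final state is used).
#' @return A tibble with `total_occupancy`, `single_fraction`,
#'   `double_fraction`.
#' @export
#' @examples
#' coverage_summary(rbind(c(1, 1, 0, 0), c(1, 0, 0, 0)))
coverage_summary <- function(state) {
  occ <- if (inherits(state, "lattice_trajectory")) state$final_state$occupancy
         else if (inherits(state, "lattice_state")) state$occupancy
         else as.matrix(state)
  occ <- (occ > 0) + 0L
  N <- ncol(occ)
  if (N == 0) abort("zero-length filament")
  col_sum <- colSums(occ)
  tibble::tibble(
    total_occupancy = sum(occ) / (2 * N),
    single_fraction = mean(col_sum == 1),
    double_fraction = mean(col_sum == 2)
  )
}

#' Simulated coverage at a target filament length
#'
#' Runs `n_rep` independent growing-filament simulations, snapshots each
#' at the first moment the filament reaches `target_length_um`, applies
#' the observation model (label, broaden, sum), and averages the
#' fluorescence level over sites.  Also reports the raw coverage
#' fractions of each snapshot.
#'
#' @param params A [lattice_params()] with `v_grow > 0`; `max_time` must
#'   be large enough to reach the target length.
#' @param settings An [observation_settings()].
#' @param target_length_um Target filament length in micrometres.
#' @param n_rep Number of replicate filaments.
#' @return A `coverage_run`: tibble with one row per replicate
#'   (`mean_fluorescence` in [0, 2], plus raw `total_occupancy`,
#'   `single_fraction`, `double_fraction`), with the parameters attached.
#' @export
coverage_at_length <- function(params, settings = observation_settings(),
                               target_length_um = 6, n_rep = 24) {
  stopifnot(inherits(params, "lattice_params"))
  if (params$v_grow <= 0)
    abort("coverage_at_length() needs a growing filament (v_grow > 0)")
  target_sites <- ceiling(target_length_um * 1000 / params$site_length_nm)
  out <- purrr::map_dfr(seq_len(n_rep), function(r) {
    tr <- simulate_lattice(params, record_events = FALSE,
                           stop_at_sites = target_sites)
    if (tr$status != "target_length")
      abort(sprintf(
        "filament did not reach %g um before max_time = %g s (status: %s)",
        target_length_um, params$max_time, tr$status))
    snap <- tr$final_molecules
    labels <- if (settings$labeling_mode == "per-molecule")
      molecule_labels(tr$n_molecules, settings$labeled_fraction) else NULL
    fluor <- process_snapshot(snap, settings, labels)
    raw <- coverage_summary(snap)
    tibble::tibble(rep = r, mean_fluorescence = mean(fluor),
                   total_occupancy = raw$total_occupancy,
                   single_fraction = raw$single_fraction,
                   double_fraction = raw$double_fraction)
  })
  structure(out, class = c("coverage_run", class(out)),
            params = params, settings = settings,
            target_length_um = target_length_um)
}

#' Render a kymograph from a trajectory
#'
#' Snapshots the trajectory at multiples of `frame_interval` and runs each
#' through the observation model.  Columns beyond the filament's current
#' barbed end carry the sentinel -1 ("no filament", as opposed to
#' "filament, dark" = 0).
#'
#' @param trajectory A `lattice_trajectory` simulated with
#'   `snapshot_times` at the desired frame times, or `NULL` to resimulate.
#' @param settings An [observation_settings()].
#' @return A `kymograph`: list with `intensity` (frames x sites matrix,
#'   values -1, 0, 1, 2), `frame_times`, `site_length_nm`.
#' @export
render_kymograph <- function(trajectory, settings = observation_settings()) {
  stopifnot(inherits(trajectory, "lattice_trajectory"))
  snaps <- trajectory$snapshots
  if (length(snaps) == 0)
    abort("trajectory has no snapshots; simulate with snapshot_times")
  labels <- if (settings$labeling_mode == "per-molecule")
    molecule_labels(trajectory$n_molecules, settings$labeled_fraction) else NULL
  rows <- lapply(snaps, process_snapshot, settings = settings, labels = labels)
  max_n <- max(vapply(rows, length, 1L))
  intensity <- t(vapply(rows, function(r) c(r, rep(-1L, max_n - length(r))),
                        integer(max_n)))
  structure(
    list(intensity = intensity,
         frame_times = trajectory$snapshot_times,
         site_length_nm = trajectory$params$site_length_nm),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d sites (%.1f s x %.2f um)\n",
              nrow(x$intensity), ncol(x$intensity),
              diff(range(x$frame_times)),
              ncol(x$intensity) * x$site_length_nm / 1000))
  invisible(x)
}

#' Estimate cable-edge spreading velocities from a kymograph
#'
#' Tracks the outermost lit site (fluorescence >= `threshold`) of the
#' cable region in each frame and fits a least-squares slope of edge
#' position versus time over the longest contiguous stretch of frames in
#' which a cable is present, separately for the barbed-end-facing and
#' pointed-end-facing edges.  Windows shorter than `min_window_s` are
#' rejected (no qualifying window returns an empty tibble).
#'
#' @param kymograph A [render_kymograph()] result.
#' @param threshold Minimum fluorescence level counted as lit.
#' @param min_window_s Minimum persistence of the cable in seconds.
#' @return A tibble with columns `direction` ("barbed"/"pointed"),
#'   `velocity_sites_per_s` (positive = spreading outward),
#'   `window_s` and `n_frames`.
#' @export
estimate_boundary_velocity <- function(kymograph, threshold = 1,
                                       min_window_s = 15) {
  stopifnot(inherits(kymograph, "kymograph"))
  im <- kymograph$intensity
  tt <- kymograph$frame_times
  edges <- purrr::map_dfr(seq_len(nrow(im)), function(f) {
    lit <- which(im[f, ] >= threshold)
    tibble::tibble(time = tt[f],
                   lead = if (length(lit)) max(lit) else NA_real_,
                   trail = if (length(lit)) min(lit) else NA_real_)
  })
  present <- !is.na(edges$lead)
  if (!any(present)) return(empty_velocity_tbl())
  # longest contiguous run of frames with a visible cable
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]
  idx <- starts[best]:ends[best]
  span <- tt[idx[length(idx)]] - tt[idx[1]]
  if (span < min_window_s) return(empty_velocity_tbl())
  sub <- edges[idx, ]
  fit_b <- lm(lead ~ time, data = sub)
  fit_p <- lm(trail ~ time, data = sub)
  tibble::tibble(
    direction = c("barbed", "pointed"),
    velocity_sites_per_s = c(coef(fit_b)[["time"]], -coef(fit_p)[["time"]]),
    window_s = span,
    n_frames = length(idx)
  )
}

empty_velocity_tbl <- function() {
  tibble::tibble(direction = character(), velocity_sites_per_s = numeric(),
                 window_s = numeric(), n_frames = integer())
}

# saturated lit fraction of one row under labeling p and broadening radius r:
# a site is dark only if none of the 2r+1 sites around it is labeled
saturated_lit_fraction <- function(labeled_fraction, radius) {
  1 - (1 - labeled_fraction)^(2 * radius + 1)
}
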