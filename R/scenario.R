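#' Circular sonar trajectory
#'
#' `n_points` poses equally spaced in angle on a circle of `radius` around
#' `center` at the given `height`, every boresight aimed at `aim` (so a
#' sonar navigating the path keeps firing towards the canopy).
#'
#' @param center Circle centre `c(x, y)` (m).
#' @param radius Circle radius (m), > 0.
#' @param height Sonar height (m).
#' @param n_points Number of poses, >= 1 (pose 1 at angle 0).
#' @param aim Target point `c(x, y, z)` each boresight passes through;
#'   defaults to the circle centre at the same height.
#' @return A tibble of class `sonar_trajectory` with columns `pose`, `x`,
#'   `y`, `z`, `aim_x`, `aim_y`, `aim_z`.
#' @export
circular_path <- function(center, radius, height, n_points,
                          aim = c(center, height)) {
  stopifnot(n_points >= 1, radius > 0, length(center) == 2, length(aim) == 3)
  ang <- 2 * pi * (seq_len(n_points) - 1) / n_points
  out <- tibble::tibble(
    pose = seq_len(n_points),
    x = center[1] + radius * cos(ang),
    y = center[2] + radius * sin(ang),
    z = height,
    aim_x = aim[1], aim_y = aim[2], aim_z = aim[3]
  )
  attr(out, "path_kind") <- "circular"
  class(out) <- c("sonar_trajectory", class(out))
  out
}

#' Figure-eight sonar trajectory
#'
#' Poses sampled uniformly in parameter along a Gerono lemniscate
#' `x = lobe sin t`, `y = lobe sin t cos t` centred on `center` at fixed
#' `height` — a closed-form stand-in for a dynamically followed "8"-shaped
#' flight route, passing through the centre at `t = 0` and `t = pi`. When
#' `aim_targets` (a matrix of canopy centroids, one row each) is supplied,
#' each pose aims at its nearest target; otherwise aims are left `NA` and
#' resolved against the scene by [run_scenario()].
#'
#' @param center Lemniscate centre `c(x, y)` (m).
#' @param lobe Lobe half-length (m), > 0.
#' @param height Sonar height (m).
#' @param n_points Number of poses, >= 1.
#' @param aim_targets Optional numeric matrix with 3 columns.
#' @return A `sonar_trajectory` tibble.
#' @export
figure_eight_path <- function(center, lobe, height, n_points,
                              aim_targets = NULL) {
  stopifnot(n_points >= 1, lobe > 0, length(center) == 2)
  t <- 2 * pi * (seq_len(n_points) - 1) / n_points
  out <- tibble::tibble(
    pose = seq_len(n_points),
    x = center[1] + lobe * sin(t),
    y = center[2] + lobe * sin(t) * cos(t),
    z = height,
    aim_x = NA_real_, aim_y = NA_real_, aim_z = NA_real_
  )
  if (!is.null(aim_targets)) {
    aim_targets <- matrix(as.numeric(aim_targets), ncol = 3)
    for (i in seq_len(n_points)) {
      d2 <- (aim_targets[, 1] - out$x[i])^2 + (aim_targets[, 2] - out$y[i])^2 +
        (aim_targets[, 3] - out$z[i])^2
      k <- which.min(d2)
      out$aim_x[i] <- aim_targets[k, 1]
      out$aim_y[i] <- aim_targets[k, 2]
      out$aim_z[i] <- aim_targets[k, 3]
    }
  }
  attr(out, "path_kind") <- "figure-eight"
  class(out) <- c("sonar_trajectory", class(out))
  out
}

#' Explicit trajectory from pose coordinates
#'
#' @param positions Matrix or data frame with columns x, y, z.
#' @param aims Matrix with 3 columns (one aim point per pose), or `NULL` to
#'   resolve aims against the scene at run time.
#' @return A `sonar_trajectory` tibble.
#' @export
explicit_path <- function(positions, aims = NULL) {
  p <- matrix(as.numeric(as.matrix(as.data.frame(positions))), ncol = 3)
  out <- tibble::tibble(pose = seq_len(nrow(p)),
                        x = p[, 1], y = p[, 2], z = p[, 3],
                        aim_x = NA_real_, aim_y = NA_real_, aim_z = NA_real_)
  if (!is.null(aims)) {
    a <- matrix(as.numeric(aims), ncol = 3)
    out$aim_x <- a[, 1]; out$aim_y <- a[, 2]; out$aim_z <- a[, 3]
  }
  attr(out, "path_kind") <- "explicit"
  class(out) <- c("sonar_trajectory", class(out))
  out
}

#' Scenario configuration
#'
#' Bundles a scene (a `sim_forest` or a single `sim_tree`), a trajectory, a
#' frequency band, a beamwidth schedule and a master seed into a runnable
#' sensing scenario.
#'
#' @param scene A `sim_forest` or `sim_tree`.
#' @param trajectory A `sonar_trajectory`.
#' @param band A [frequency_band()].
#' @param beamwidth Either a fixed full -3 dB beamwidth in degrees, or an
#'   interval `c(lo, hi)` from which each pose's beamwidth is drawn
#'   uniformly (the bat-typical default is `c(30, 65)`).
#' @param A0 Peak beam amplitude.
#' @param seed Master seed; per-pose sub-seeds are derived by counter.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scene, trajectory, band = frequency_band(),
                            beamwidth = c(30, 65), A0 = 1, seed = 1L) {
  if (inherits(scene, "sim_tree")) {
    scene <- tibble::tibble(x = scene$location[1], y = scene$location[2],
                            species = scene$species, tree = list(scene))
    class(scene) <- c("sim_forest", class(scene))
  }
  stopifnot(inherits(scene, "sim_forest"), inherits(trajectory, "sonar_trajectory"),
            inherits(band, "frequency_band"),
            length(beamwidth) %in% 1:2, all(beamwidth > 0), all(beamwidth < 180))
  structure(
    list(scene = scene, trajectory = trajectory, band = band,
         beamwidth = as.numeric(beamwidth), A0 = A0, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Run a sensing scenario
#'
#' Pools the scene's leaf discs once, then for every trajectory pose: derives
#' a per-pose sub-seed from the master seed by counter, draws the beamwidth
#' from the schedule, resolves the aim (poses without an explicit aim target
#' the nearest tree-canopy centroid), synthesizes the echo spectrum over the
#' in-mainlobe discs, and inverts it to an impulse response. Fully
#' deterministic given the master seed, and each pose is independent of the
#' evaluation order.
#'
#' @param config A [scenario_config()].
#' @return A tibble of class `scenario_result`: one row per pose with
#'   columns `pose`, `x`, `y`, `z`, `beamwidth_deg`, `m` (in-mainlobe leaf
#'   count) and list-columns `ir` (impulse responses) and `spectrum`;
#'   attribute `manifest` holds the full resolved configuration.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  scene <- config$scene
  traj <- config$trajectory
  discs <- forest_leaf_discs(scene)
  centroids <- if (nrow(scene) > 0) {
    do.call(rbind, lapply(scene$tree, canopy_centroid))
  } else matrix(numeric(0), ncol = 3)

  rows <- vector("list", nrow(traj))
  pose_meta <- vector("list", nrow(traj))
  for (i in seq_len(nrow(traj))) {
    res <- tryCatch({
      sub_seed <- derive_seed(config$seed, traj$pose[i])
      bw <- if (length(config$beamwidth) == 2) {
        withr::with_seed(sub_seed, stats::runif(1, config$beamwidth[1],
                                                config$beamwidth[2]))
      } else config$beamwidth
      pos <- c(traj$x[i], traj$y[i], traj$z[i])
      aim <- c(traj$aim_x[i], traj$aim_y[i], traj$aim_z[i])
      if (anyNA(aim)) {
        if (nrow(centroids) == 0) stop("no aim target and no trees in scene")
        d2 <- colSums((t(centroids) - pos)^2)
        aim <- centroids[which.min(d2), ]
      }
      beam <- sonar_beam(pos, aim - pos, beamwidth_az = bw * pi / 180,
                         A0 = config$A0)
      spec <- synthesize_spectrum(beam, discs, config$band)
      ir <- impulse_response(spec, config$band)
      list(row = tibble::tibble(
        pose = traj$pose[i], x = pos[1], y = pos[2], z = pos[3],
        beamwidth_deg = bw, m = attr(spec, "m"),
        ir = list(ir), spectrum = list(spec)),
        meta = list(pose = traj$pose[i], seed = sub_seed,
                    beamwidth_deg = bw, m = attr(spec, "m"),
                    position = pos, aim = as.numeric(aim)))
    }, error = function(e) {
      stop(sprintf("pose %d: %s", traj$pose[i], conditionMessage(e)),
           call. = FALSE)
    })
    rows[[i]] <- res$row
    pose_meta[[i]] <- res$meta
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "manifest") <- list(
    seed = config$seed,
    path_kind = attr(traj, "path_kind"),
    n_poses = nrow(traj),
    beamwidth_schedule = config$beamwidth,
    band = list(f_lo = config$band$f_lo, f_hi = config$band$f_hi,
                fs = config$band$fs, n_fft = config$band$n_fft,
                v = config$band$v, taper = config$band$taper),
    n_trees = nrow(scene),
    species = as.list(table(scene$species)),
    poses = pose_meta
  )
  class(out) <- c("scenario_result", class(out))
  out
}

#' Write scenario outputs to a directory
#'
#' Per pose: a float WAV and a CSV of the impulse response; plus a single
#' `manifest.json` capturing the full resolved configuration (seeds,
#' beamwidths, in-mainlobe counts, band, scene summary).
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_scenario_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(result))) {
    stem <- file.path(out_dir, sprintf("pose_%02d", result$pose[i]))
    write_echo_wav(result$ir[[i]], paste0(stem, ".wav"))
    write_impulse_csv(result$ir[[i]], paste0(stem, ".csv"))
  }
  jsonlite::write_json(attr(result, "manifest"),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
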