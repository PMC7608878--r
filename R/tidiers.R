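#' Tidy a simulated tree
#'
#' @param x A `sim_tree`.
#' @param ... Unused.
#' @return The leaf-disc tibble augmented with the species label.
#' @export
tidy.sim_tree <- function(x, ...) {
  d <- tibble::as_tibble(x$leaf_discs)
  d$species <- x$species
  d
}

#' @rdname tidy.sim_tree
#' @export
glance.sim_tree <- function(x, ...) {
  tree <- x
  tibble::tibble(
    species = tree$species,
    x = tree$location[1], y = tree$location[2],
    n_segments = nrow(tree$skeleton),
    n_leaf_discs = nrow(tree$leaf_discs),
    mean_leaf_radius = mean(tree$leaf_discs$radius),
    canopy_height = if (nrow(tree$leaf_discs)) max(tree$leaf_discs$z) else NA_real_,
    seed = tree$seed
  )
}

#' Tidy a simulated forest
#'
#' @param x A `sim_forest`.
#' @param ... Unused.
#' @return One row per tree: location, species, leaf count.
#' @export
tidy.sim_forest <- function(x, ...) {
  forest <- x
  tibble::tibble(
    x = forest$x, y = forest$y, species = forest$species,
    n_leaf_discs = vapply(forest$tree, function(t) nrow(t$leaf_discs), numeric(1))
  )
}

#' @rdname tidy.sim_forest
#' @export
glance.sim_forest <- function(x, ...) {
  tibble::tibble(
    n_trees = nrow(x),
    n_species = length(unique(x$species)),
    n_leaf_discs = sum(vapply(x$tree, function(t) nrow(t$leaf_discs), numeric(1))),
    deleted_by_spacing = attr(x, "deleted") %||% 0L,
    min_spacing = attr(x, "min_spacing") %||% NA_real_,
    seed = attr(x, "seed") %||% NA_integer_
  )
}

#' Tidy an impulse response
#'
#' @param x An `impulse_response`.
#' @param ... Unused.
#' @return Tibble with `time`, `amplitude` and the analytic-signal
#'   `envelope`.
#' @export
tidy.impulse_response <- function(x, ...) {
  tibble::tibble(time = x$time, amplitude = x$amplitude,
                 envelope = echo_envelope(x))
}

#' @rdname tidy.impulse_response
#' @export
glance.impulse_response <- function(x, ...) {
  env <- echo_envelope(x)
  tibble::tibble(
    n = nrow(x),
    fs = attr(x, "fs"),
    m = attr(x, "m") %||% NA_integer_,
    peak_envelope = max(env),
    peak_time = x$time[which.max(env)],
    energy = sum(x$amplitude^2)
  )
}

#' Tidy a scenario result
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return One row per pose with the echo summaries and no list columns.
#' @export
tidy.scenario_result <- function(x, ...) {
  base <- tibble::as_tibble(x)[, c("pose", "x", "y", "z", "beamwidth_deg", "m")]
  base$peak_envelope <- vapply(x$ir, function(ir) max(echo_envelope(ir)),
                               numeric(1))
  base$energy <- vapply(x$ir, function(ir) sum(ir$amplitude^2), numeric(1))
  base
}

#' @rdname tidy.scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  man <- attr(x, "manifest")
  tibble::tibble(
    n_poses = nrow(x),
    n_silent = sum(x$m == 0),
    total_in_mainlobe = sum(x$m),
    path_kind = man$path_kind,
    seed = man$seed
  )
}
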