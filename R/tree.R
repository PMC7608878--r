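#' Convert leaf mesh faces to circular disc reflectors
#'
#' Each triangular leaf facet is approximated by a circular disc: the disc
#' centre is the triangle centroid, the disc normal is the face normal, and
#' the radius is drawn from a normal distribution truncated to positive
#' values by redrawing.
#'
#' @param mesh A [tri_mesh()].
#' @param leaf_faces Integer indices of the faces that represent leaves.
#' @param radius_mean,radius_sd Mean and sd (m) of the leaf disc radius
#'   distribution; `radius_sd = 0` gives every disc radius `radius_mean`.
#' @param seed Integer seed.
#' @return A tibble of class `leaf_discs` with one row per leaf face:
#'   centre `x`, `y`, `z` (m), `radius` (m) and unit normal `nx`, `ny`, `nz`.
#' @export
leaf_discs_from_mesh <- function(mesh, leaf_faces, radius_mean = 0.04,
                                 radius_sd = 0.008, seed = 1L) {
  stopifnot(inherits(mesh, "tri_mesh"), radius_mean > 0, radius_sd >= 0)
  leaf_faces <- as.integer(leaf_faces)
  if (length(leaf_faces) == 0L) {
    warning("no leaf faces: returning an empty disc set", call. = FALSE)
    return(empty_leaf_discs())
  }
  if (min(leaf_faces) < 1L || max(leaf_faces) > nrow(mesh$faces)) {
    stop("leaf_faces out of range", call. = FALSE)
  }
  centres <- face_centroids(mesh, leaf_faces)
  normals <- mesh$normals[leaf_faces, , drop = FALSE]
  radii <- withr::with_seed(as.integer(seed), {
    r <- stats::rnorm(length(leaf_faces), radius_mean, radius_sd)
    while (any(bad <- r <= 0)) {
      r[bad] <- stats::rnorm(sum(bad), radius_mean, radius_sd)
    }
    r
  })
  as_leaf_discs(tibble::tibble(
    x = centres[, 1], y = centres[, 2], z = centres[, 3],
    radius = radii,
    nx = normals[, 1], ny = normals[, 2], nz = normals[, 3]
  ))
}

empty_leaf_discs <- function() {
  as_leaf_discs(tibble::tibble(
    x = numeric(0), y = numeric(0), z = numeric(0), radius = numeric(0),
    nx = numeric(0), ny = numeric(0), nz = numeric(0)
  ))
}

as_leaf_discs <- function(x) {
  class(x) <- unique(c("leaf_discs", class(x)))
  x
}

#' Write a leaf-disc table to CSV
#'
#' @param discs A `leaf_discs` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_leaf_discs_csv <- function(discs, path) {
  utils::write.csv(as.data.frame(discs), path, row.names = FALSE)
  invisible(path)
}

# rotation matrix taking unit vector `from` onto unit vector `to` (Rodrigues)
rotation_between <- function(from, to) {
  from <- vunit(from)
  to <- vunit(to)
  v <- vcross(from, to)
  c_ <- sum(from * to)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees about any axis perpendicular to `from`
    u <- perp_basis(from)$u
    return(2 * outer(u, u) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), nrow = 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# rotation by angle about unit axis
rotation_about <- function(axis, angle) {
  axis <- vunit(axis)
  vx <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                 axis[2], -axis[1], 0), nrow = 3)
  diag(3) + sin(angle) * vx + (1 - cos(angle)) * vx %*% vx
}

# similarity transform of a template: align root_axis with `axis`, spin about
# it, scale isotropically about the root, translate root_point to `attach`
transform_template <- function(template, attach, axis, scale = 1, spin = 0) {
  R <- rotation_about(axis, spin) %*% rotation_between(template$root_axis, axis)
  v <- template$mesh$vertices
  v <- sweep(v, 2, template$root_point)        # move root to origin
  v <- scale * t(R %*% t(v))
  v <- sweep(v, 2, attach, FUN = "+")
  mesh <- tri_mesh(v, template$mesh$faces)
  list(mesh = mesh, leaf_faces = template$leaf_faces)
}

#' Assemble a complete tree from a skeleton and branch templates
#'
#' Attaches branch templates at the first-level branch points of an L-system
#' skeleton. With as many templates as attachment points (`n = N`) and jitter
#' disabled, each template is placed rigidly (root point onto the attachment
#' point, root axis aligned with the skeleton segment direction) in order.
#' Otherwise each branch is built from a randomly selected template with a
#' random similarity transform: isotropic scale drawn log-uniformly from
#' `jitter$scale_range` and a uniform spin about the attachment axis. Leaf
#' facets of the placed templates are converted to disc reflectors with
#' [leaf_discs_from_mesh()].
#'
#' @param skeleton A `branch_skeleton` from [lsys_interpret()].
#' @param templates List of [make_branch_template()] objects (or a single
#'   template).
#' @param seed Integer seed.
#' @param jitter `NULL` to disable randomization; otherwise a list with
#'   `scale_range` (default `c(0.8, 1.25)`) and logical `spin` (default
#'   `TRUE`).
#' @param radius_mean,radius_sd Leaf-disc radius distribution (m), passed to
#'   [leaf_discs_from_mesh()].
#' @param species,location Metadata stored on the tree: species label and
#'   planting location `c(x, y)` in field coordinates (m). The skeleton and
#'   discs stay in tree-local coordinates; [place_tree()] shifts a tree to
#'   its location.
#' @return An object of class `sim_tree`: list with `species`, `location`,
#'   `skeleton`, `leaf_discs`, `mesh` and `seed`.
#' @export
assemble_tree <- function(skeleton, templates, seed = 1L,
                          jitter = list(scale_range = c(0.8, 1.25), spin = TRUE),
                          radius_mean = 0.04, radius_sd = 0.008,
                          species = "tree", location = c(0, 0)) {
  stopifnot(inherits(skeleton, "branch_skeleton"))
  if (inherits(templates, "branch_template")) templates <- list(templates)
  if (length(templates) == 0L) stop("templates must be nonempty", call. = FALSE)
  stopifnot(all(vapply(templates, inherits, logical(1), "branch_template")))

  att <- attachment_points(skeleton)
  N <- nrow(att)
  n <- length(templates)
  one_to_one <- (n == N)

  withr::with_seed(as.integer(seed), {
    placed <- vector("list", N)
    for (i in seq_len(N)) {
      tpl <- if (one_to_one) templates[[i]] else
        templates[[sample.int(n, 1)]]
      if (is.null(jitter)) {
        scale <- 1
        spin <- 0
      } else {
        sr <- jitter$scale_range %||% c(0.8, 1.25)
        scale <- exp(stats::runif(1, log(sr[1]), log(sr[2])))
        spin <- if (isTRUE(jitter$spin %||% TRUE)) stats::runif(1, 0, 2 * pi) else 0
      }
      placed[[i]] <- transform_template(
        tpl, attach = as.numeric(att[i, c("x", "y", "z")]),
        axis = as.numeric(att[i, c("ux", "uy", "uz")]),
        scale = scale, spin = spin
      )
    }
    comb <- combine_meshes(lapply(placed, `[[`, "mesh"))
    leaf_faces <- unlist(lapply(seq_len(N), function(i) {
      placed[[i]]$leaf_faces + comb$face_offsets[i]
    }))
    disc_seed <- stats::runif(1, 0, 2^31 - 1)  # sub-seed from the tree seed
    discs <- if (length(leaf_faces)) {
      leaf_discs_from_mesh(comb$mesh, leaf_faces, radius_mean, radius_sd,
                           seed = as.integer(disc_seed))
    } else empty_leaf_discs()
    structure(
      list(species = species, location = as.numeric(location),
           skeleton = skeleton, leaf_discs = discs, mesh = comb$mesh,
           seed = as.integer(seed)),
      class = "sim_tree"
    )
  })
}

# first-level branch attachment points: start point and unit direction of the
# shallowest above-trunk segments (the trunk itself if nothing is deeper)
attachment_points <- function(skeleton) {
  depth_use <- if (any(skeleton$depth > 0L)) min(skeleton$depth[skeleton$depth > 0L]) else 0L
  seg <- skeleton[skeleton$depth == depth_use, , drop = FALSE]
  d <- cbind(seg$x1 - seg$x0, seg$y1 - seg$y0, seg$z1 - seg$z0)
  d <- d / sqrt(rowSums(d^2))
  tibble::tibble(x = seg$x0, y = seg$y0, z = seg$z0,
                 ux = d[, 1], uy = d[, 2], uz = d[, 3])
}

#' @export
print.sim_tree <- function(x, ...) {
  cat(sprintf("<sim_tree> species '%s' at (%.2f, %.2f): %d leaf discs, %d mesh faces\n",
              x$species, x$location[1], x$location[2],
              nrow(x$leaf_discs), nrow(x$mesh$faces)))
  invisible(x)
}

#' Shift a tree's geometry to its field location
#'
#' Trees are assembled in local coordinates with the trunk rooted at the
#' origin; this returns the leaf discs translated to the tree's `(x, y)`
#' location in the field.
#'
#' @param tree A `sim_tree`.
#' @return The tree's `leaf_discs` tibble in field coordinates.
#' @export
place_tree <- function(tree) {
  stopifnot(inherits(tree, "sim_tree"))
  d <- tree$leaf_discs
  d$x <- d$x + tree$location[1]
  d$y <- d$y + tree$location[2]
  d
}

#' Canopy centroid of a tree in field coordinates
#'
#' @param tree A `sim_tree`.
#' @return Numeric length-3 centre of the leaf discs.
#' @export
canopy_centroid <- function(tree) {
  d <- place_tree(tree)
  if (nrow(d) == 0) return(c(tree$location, 0))
  c(mean(d$x), mean(d$y), mean(d$z))
}

#' Tree metadata as JSON
#'
#' Writes species, location, seed and object counts.
#'
#' @param tree A `sim_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  meta <- list(
    species = tree$species,
    location = tree$location,
    seed = tree$seed,
    n_segments = nrow(tree$skeleton),
    n_leaf_discs = nrow(tree$leaf_discs),
    n_mesh_faces = nrow(tree$mesh$faces)
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
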