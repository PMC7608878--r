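#' Procedural branch template
#'
#' Generates a natural-looking branch mesh to stand in for measured CAD
#' branch assets: a tapered tube swept along a smoothly curving axis, a few
#' thinner sub-branches, and triangular leaf facets scattered near the branch
#' and sub-branch tips. The faces that represent leaves are recorded in
#' `leaf_faces` so they can later be converted to circular disc reflectors.
#'
#' @param length Branch length along its axis (m).
#' @param radius Base tube radius (m).
#' @param curvature Total bend of the branch axis over its length (radians);
#'   0 gives a straight tube.
#' @param taper Tip radius as a fraction of the base radius, in (0, 1].
#' @param sub_branch_count Number of thinner side branches.
#' @param leaf_count Number of triangular leaf facets; 0 produces a bare
#'   branch with a warning.
#' @param leaf_size Leaf triangle edge length (m).
#' @param n_sections,n_sides Tube tessellation (rings along the axis,
#'   vertices per ring).
#' @param seed Integer seed; the template is deterministic per seed.
#' @return An object of class `branch_template`: list with `mesh`
#'   ([tri_mesh()]), integer `leaf_faces`, `root_point` and unit `root_axis`.
#' @export
make_branch_template <- function(length = 0.8,
                                 radius = 0.02,
                                 curvature = 0.4,
                                 taper = 0.35,
                                 sub_branch_count = 3,
                                 leaf_count = 20,
                                 leaf_size = 0.06,
                                 n_sections = 8,
                                 n_sides = 6,
                                 seed = 1L) {
  stopifnot(length > 0, radius > 0, taper > 0, taper <= 1,
            leaf_size > 0, n_sections >= 2, n_sides >= 3)
  if (leaf_count == 0) {
    warning("leaf_count is 0: template is a bare branch with no leaves",
            call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    # main axis: tangent tilts progressively from +z toward +x by `curvature`
    path <- sweep_path(c(0, 0, 0), c(0, 0, 1), length, curvature, n_sections)
    main <- tube_mesh(path, radius, radius * taper, n_sides)
    meshes <- list(main$mesh)
    tips <- list(path[nrow(path), ])
    axes <- list(main$end_tangent)
    for (i in seq_len(sub_branch_count)) {
      t0 <- stats::runif(1, 0.3, 0.9)
      base <- path_point(path, t0)
      tangent <- path_tangent(path, t0)
      b <- perp_basis(tangent)
      az <- stats::runif(1, 0, 2 * pi)
      ang <- stats::runif(1, 0.5, 1.1)
      dir <- vunit(cos(ang) * tangent + sin(ang) * (cos(az) * b$u + sin(az) * b$v))
      sp <- sweep_path(base, dir, 0.4 * length, 0.5 * curvature, max(3, n_sections %/% 2))
      sub <- tube_mesh(sp, 0.4 * radius, 0.4 * radius * taper, n_sides)
      meshes[[length(meshes) + 1]] <- sub$mesh
      tips[[length(tips) + 1]] <- sp[nrow(sp), ]
      axes[[length(axes) + 1]] <- sub$end_tangent
    }
    n_struct <- sum(vapply(meshes, function(m) nrow(m$faces), integer(1)))
    for (i in seq_len(leaf_count)) {
      host <- sample.int(length(tips), 1)
      t0 <- stats::runif(1, 0.5, 1)
      centre <- tips[[host]] - (1 - t0) * 0.4 * length * axes[[host]] +
        stats::rnorm(3, 0, 0.05 * length)
      meshes[[length(meshes) + 1]] <- leaf_facet(centre, leaf_size)
    }
    comb <- combine_meshes(meshes)
    leaf_faces <- if (leaf_count > 0) {
      (n_struct + 1L):nrow(comb$mesh$faces)
    } else integer(0)
    structure(
      list(mesh = comb$mesh, leaf_faces = leaf_faces,
           root_point = c(0, 0, 0), root_axis = c(0, 0, 1),
           seed = as.integer(seed)),
      class = "branch_template"
    )
  })
}

#' @export
print.branch_template <- function(x, ...) {
  cat(sprintf("<branch_template> %d faces (%d leaf), root axis [%.2f %.2f %.2f]\n",
              nrow(x$mesh$faces), length(x$leaf_faces),
              x$root_axis[1], x$root_axis[2], x$root_axis[3]))
  invisible(x)
}

# polyline of n+1 points starting at `origin` with initial tangent `dir`,
# bending in the plane spanned by dir and a perpendicular by `curvature` rad
sweep_path <- function(origin, dir, length, curvature, n) {
  dir <- vunit(dir)
  b <- perp_basis(dir)
  step <- length / n
  pts <- matrix(0, nrow = n + 1, ncol = 3)
  pts[1, ] <- origin
  pos <- origin
  for (i in seq_len(n)) {
    ang <- curvature * (i - 0.5) / n
    tangent <- cos(ang) * dir + sin(ang) * b$u
    pos <- pos + step * tangent
    pts[i + 1, ] <- pos
  }
  pts
}

path_point <- function(path, t) {
  n <- nrow(path) - 1
  i <- pmin(floor(t * n), n - 1)
  frac <- t * n - i
  path[i + 1, ] * (1 - frac) + path[i + 2, ] * frac
}

path_tangent <- function(path, t) {
  n <- nrow(path) - 1
  i <- pmin(floor(t * n), n - 1) + 1
  vunit(path[i + 1, ] - path[i, ])
}

# tapered tube swept along a polyline; returns mesh and the end tangent
tube_mesh <- function(path, r0, r1, n_sides) {
  n <- nrow(path)
  ang <- 2 * pi * (seq_len(n_sides) - 1) / n_sides
  verts <- matrix(0, nrow = n * n_sides, ncol = 3)
  for (i in seq_len(n)) {
    tangent <- if (i < n) vunit(path[i + 1, ] - path[i, ]) else
      vunit(path[i, ] - path[i - 1, ])
    b <- perp_basis(tangent)
    r <- r0 + (r1 - r0) * (i - 1) / (n - 1)
    ring <- t(vapply(ang, function(a) {
      path[i, ] + r * (cos(a) * b$u + sin(a) * b$v)
    }, numeric(3)))
    verts[((i - 1) * n_sides + 1):(i * n_sides), ] <- ring
  }
  faces <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq_len(n_sides)) {
      jn <- j %% n_sides + 1
      a <- (i - 1) * n_sides + j
      b_ <- (i - 1) * n_sides + jn
      c_ <- i * n_sides + j
      d <- i * n_sides + jn
      faces[[length(faces) + 1]] <- c(a, b_, c_)
      faces[[length(faces) + 1]] <- c(b_, d, c_)
    }
  }
  list(mesh = tri_mesh(verts, do.call(rbind, faces)),
       end_tangent = vunit(path[n, ] - path[n - 1, ]))
}

# one equilateral leaf triangle with random orientation, centroid at `centre`
leaf_facet <- function(centre, edge) {
  n <- vunit(stats::rnorm(3))
  b <- perp_basis(n)
  spin <- stats::runif(1, 0, 2 * pi)
  r <- edge / sqrt(3)
  pts <- t(vapply(spin + c(0, 2 * pi / 3, 4 * pi / 3), function(a) {
    centre + r * (cos(a) * b$u + sin(a) * b$v)
  }, numeric(3)))
  tri_mesh(pts, matrix(1:3, ncol = 3))
}
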