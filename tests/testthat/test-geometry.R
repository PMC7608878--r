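single_facet_ascii <- function(path) {
  writeLines(c(
    "solid one",
    "facet normal 0 0 1",
    "  outer loop",
    "    vertex 0 0 0",
    "    vertex 1 0 0",
    "    vertex 0 1 0",
    "  endloop",
    "endfacet",
    "endsolid one"
  ), path)
  path
}

test_that("ASCII STL with one facet parses to the expected mesh", {
  path <- single_facet_ascii(withr::local_tempfile(fileext = ".stl"))
  m <- read_stl(path)
  expect_s3_class(m, "tri_mesh")
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)
  expect_equal(as.numeric(m$normals[1, ]), c(0, 0, 1))
})

test_that("STL round-trips through both dialects up to vertex ordering", {
  tpl <- make_branch_template(leaf_count = 5, sub_branch_count = 1, seed = 3)
  m <- tpl$mesh
  for (dialect in c("binary", "ascii")) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(m, path, dialect)
    back <- read_stl(path)
    expect_equal(nrow(back$faces), nrow(m$faces), info = dialect)
    # compare geometry via sorted face centroids (vertex order may differ)
    key <- function(x) {
      cc <- round(face_centroids(x), 5)
      sort(apply(cc, 1, paste, collapse = ","))
    }
    expect_equal(key(back), key(m), info = dialect)
  }
})

test_that("binary STL files have the standard 84 + 50F byte layout", {
  tpl <- make_branch_template(leaf_count = 3, sub_branch_count = 0, seed = 1)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(tpl$mesh, path, "binary")
  expect_equal(file.size(path), 84 + 50 * nrow(tpl$mesh$faces))
})

test_that("degenerate and empty STL inputs are handled explicitly", {
  empty <- tri_mesh(matrix(numeric(0), ncol = 3), matrix(integer(0), ncol = 3))
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(empty, path, "binary")
  expect_warning(m <- read_stl(path), "zero triangles")
  expect_equal(nrow(m$faces), 0L)

  path2 <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid header_only", "endsolid header_only"), path2)
  expect_warning(m2 <- read_stl(path2), "zero triangles")
  expect_equal(nrow(m2$faces), 0L)

  # truncated binary: claims 10 triangles but stores none
  path3 <- withr::local_tempfile(fileext = ".stl")
  con <- file(path3, "wb")
  writeBin(raw(80), con)
  writeBin(10L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_stl(path3), "truncated at byte")

  expect_error(read_stl(withr::local_tempfile(fileext = ".stl")), "not found")
})

test_that("mesh construction recomputes normals and drops degenerate faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4))  # second face is collinear
  expect_message(m <- tri_mesh(v, f), "1 degenerate")
  expect_equal(nrow(m$faces), 1L)
  expect_equal(sqrt(sum(m$normals[1, ]^2)), 1, tolerance = 1e-9)
  expect_error(tri_mesh(v, rbind(c(1, 2, 9))), "out of range")
})

test_that("branch templates are deterministic and carry the requested leaves", {
  t1 <- make_branch_template(leaf_count = 10, seed = 1)
  t2 <- make_branch_template(leaf_count = 10, seed = 1)
  expect_identical(t1, t2)
  expect_length(t1$leaf_faces, 10L)
  t3 <- make_branch_template(leaf_count = 10, seed = 2)
  expect_false(identical(t1$mesh$vertices, t3$mesh$vertices))
  expect_warning(bare <- make_branch_template(leaf_count = 0, seed = 1),
                 "bare branch")
  expect_length(bare$leaf_faces, 0L)
})

test_that("zero curvature yields a straight tube along the root axis", {
  tpl <- make_branch_template(curvature = 0, sub_branch_count = 0,
                              leaf_count = 1, radius = 0.02, seed = 4)
  tube_verts <- tpl$mesh$vertices[1:(9 * 6), ]  # main tube rings only
  expect_lt(max(abs(tube_verts[, 1:2])), 0.02 + 1e-9)
  expect_equal(tpl$root_axis, c(0, 0, 1))
})

test_that("leaf discs sit at face centroids with face normals", {
  m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), matrix(1:3, ncol = 3))
  d <- leaf_discs_from_mesh(m, 1L, radius_mean = 0.05, radius_sd = 0, seed = 1)
  expect_s3_class(d, "leaf_discs")
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$x, d$y, d$z), c(1 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(d$radius, 0.05)
  expect_equal(c(d$nx, d$ny, d$nz), c(0, 0, 1))
  expect_warning(e <- leaf_discs_from_mesh(m, integer(0)), "empty disc set")
  expect_equal(nrow(e), 0L)
})

test_that("disc radii follow the positively truncated normal", {
  tpl <- make_branch_template(leaf_count = 40, seed = 9)
  reps <- 250  # 40 x 250 = 1e4 draws
  radii <- unlist(lapply(seq_len(reps), function(i) {
    leaf_discs_from_mesh(tpl$mesh, tpl$leaf_faces,
                         radius_mean = 0.05, radius_sd = 0.01, seed = i)$radius
  }))
  expect_true(all(radii > 0))
  # truncated-normal mean oracle: E[X | X > 0] for N(mu, sd)
  mu <- 0.05; sd <- 0.01
  alpha <- (0 - mu) / sd
  tmean <- mu + sd * stats::dnorm(alpha) / (1 - stats::pnorm(alpha))
  se <- sd / sqrt(length(radii))
  expect_lt(abs(mean(radii) - tmean), 3 * se)
})

test_that("rigid placement preserves distances; scaling multiplies them", {
  tpl <- make_branch_template(leaf_count = 5, seed = 2)
  axis <- echoscape:::vunit(c(1, 0.4, 0.8))
  moved <- echoscape:::transform_template(tpl, attach = c(3, -1, 2),
                                          axis = axis, scale = 1, spin = 1.1)
  idx <- seq_len(min(25, nrow(tpl$mesh$vertices)))
  d0 <- stats::dist(tpl$mesh$vertices[idx, ])
  d1 <- stats::dist(moved$mesh$vertices[idx, ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  scaled <- echoscape:::transform_template(tpl, attach = c(0, 0, 0),
                                           axis = axis, scale = 1.7, spin = 0)
  d2 <- stats::dist(scaled$mesh$vertices[idx, ])
  expect_equal(as.numeric(d2), 1.7 * as.numeric(d0), tolerance = 1e-9)
  # unit normals stay unit after rotation
  expect_equal(sqrt(rowSums(moved$mesh$normals^2)),
               rep(1, nrow(moved$mesh$normals)), tolerance = 1e-9)
})

test_that("one-to-one assembly places template roots exactly at attachment points", {
  sk <- lsys_interpret("d(g)[g)+g)", geometry_params(), seed = 2)
  templates <- lapply(1:3, function(s) {
    make_branch_template(leaf_count = 4, sub_branch_count = 0, seed = s)
  })
  att <- echoscape:::attachment_points(sk)
  expect_equal(nrow(att), 3L)
  tree <- assemble_tree(sk, templates, seed = 5, jitter = NULL)
  # with jitter off the transform is rigid, so each template root (origin)
  # maps exactly onto its attachment point
  for (i in 1:3) {
    moved <- echoscape:::transform_template(
      templates[[i]], attach = as.numeric(att[i, c("x", "y", "z")]),
      axis = as.numeric(att[i, c("ux", "uy", "uz")]), scale = 1, spin = 0)
    ref <- sweep(templates[[i]]$mesh$vertices, 2, templates[[i]]$root_point)
    expect_equal(sqrt(sum((moved$mesh$vertices[1, ] -
                             as.numeric(att[i, c("x", "y", "z")]))^2)),
                 sqrt(sum(ref[1, ]^2)), tolerance = 1e-9)
  }
  expect_equal(nrow(tree$leaf_discs), 12L)  # 3 templates x 4 leaves
})

test_that("template recycling covers all branches when counts differ", {
  sk <- lsys_interpret("d(g)[g)+g)[g)[g)", geometry_params(), seed = 2)
  expect_equal(nrow(echoscape:::attachment_points(sk)), 5L)
  tpl <- make_branch_template(leaf_count = 6, sub_branch_count = 0, seed = 1)
  tree <- assemble_tree(sk, list(tpl), seed = 7)
  expect_equal(nrow(tree$leaf_discs), 5L * 6L)
  # distinct similarity transforms: the five placed copies differ
  expect_gt(stats::sd(tree$leaf_discs$x), 0)
  expect_identical(assemble_tree(sk, list(tpl), seed = 7)$leaf_discs,
                   tree$leaf_discs)
})

test_that("a single-branch tree inherits its template's leaf count", {
  sk <- lsys_interpret("d(g)", geometry_params(), seed = 1)
  tpl <- make_branch_template(leaf_count = 10, seed = 3)
  tree <- assemble_tree(sk, list(tpl), seed = 1)
  expect_equal(nrow(tree$leaf_discs), 10L)
  nn <- sqrt(tree$leaf_discs$nx^2 + tree$leaf_discs$ny^2 + tree$leaf_discs$nz^2)
  expect_equal(nn, rep(1, 10), tolerance = 1e-9)
})

test_that("tree assets export to CSV and JSON", {
  sk <- lsys_interpret("d(g)", geometry_params(), seed = 1)
  tree <- assemble_tree(sk, make_branch_template(leaf_count = 5, seed = 1),
                        seed = 2, species = "maple", location = c(4, 9))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_leaf_discs_csv(tree$leaf_discs, csv)
  expect_equal(nrow(utils::read.csv(csv)), 5L)
  js <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tree, js)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$species, "maple")
  expect_equal(meta$n_leaf_discs, 5L)
  placed <- place_tree(tree)
  expect_equal(mean(placed$x) - mean(tree$leaf_discs$x), 4)
})
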