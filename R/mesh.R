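#' Triangle mesh
#'
#' Lightweight container for a triangular surface mesh: an `n x 3` vertex
#' matrix (metres), an `F x 3` integer face matrix indexing vertices, and
#' per-face unit normals. Normals are recomputed from the vertices when
#' absent or when a supplied normal deviates from the geometric one by more
#' than 1e-6 in norm. Degenerate (zero-area) faces are dropped with a
#' message.
#'
#' @param vertices Numeric matrix with 3 columns.
#' @param faces Integer matrix with 3 columns (1-based vertex indices).
#' @param normals Optional numeric matrix of per-face normals.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  geo <- face_normals_raw(vertices, faces)
  degenerate <- geo$area < 1e-12
  if (any(degenerate)) {
    message(sprintf("dropping %d degenerate face(s)", sum(degenerate)))
    faces <- faces[!degenerate, , drop = FALSE]
    geo <- face_normals_raw(vertices, faces)
  }
  use_supplied <- FALSE
  if (!is.null(normals) && nrow(faces) > 0) {
    normals <- matrix(as.numeric(normals), ncol = 3)
    if (nrow(normals) == nrow(faces)) {
      nn <- sqrt(rowSums(normals^2))
      ok <- nn > 0
      normals[ok, ] <- normals[ok, , drop = FALSE] / nn[ok]
      dev <- sqrt(rowSums((normals - geo$normals)^2))
      flip <- sqrt(rowSums((normals + geo$normals)^2))
      use_supplied <- all(ok) && all(pmin(dev, flip) < 1e-6)
    }
  }
  structure(
    list(vertices = vertices, faces = faces,
         normals = if (use_supplied) normals else geo$normals),
    class = "tri_mesh"
  )
}

# normals + areas without degeneracy handling
face_normals_raw <- function(vertices, faces) {
  if (nrow(faces) == 0L) {
    return(list(normals = matrix(numeric(0), ncol = 3), area = numeric(0)))
  }
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nn <- sqrt(rowSums(cr^2))
  normals <- cr
  pos <- nn > 0
  normals[pos, ] <- cr[pos, , drop = FALSE] / nn[pos]
  list(normals = normals, area = nn / 2)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Face centroids of a mesh
#'
#' @param mesh A [tri_mesh()].
#' @param faces Optional subset of face indices.
#' @return Numeric matrix of centroids, one row per face.
#' @export
face_centroids <- function(mesh, faces = seq_len(nrow(mesh$faces))) {
  f <- mesh$faces[faces, , drop = FALSE]
  (mesh$vertices[f[, 1], , drop = FALSE] +
     mesh$vertices[f[, 2], , drop = FALSE] +
     mesh$vertices[f[, 3], , drop = FALSE]) / 3
}

# concatenate meshes; returns list(mesh, offsets) where offsets[i] is the face
# index offset of input i in the combined mesh
combine_meshes <- function(meshes) {
  v_off <- 0L
  f_off <- 0L
  verts <- list()
  faces <- list()
  offsets <- integer(length(meshes))
  for (i in seq_along(meshes)) {
    m <- meshes[[i]]
    verts[[i]] <- m$vertices
    faces[[i]] <- m$faces + v_off
    offsets[i] <- f_off
    v_off <- v_off + nrow(m$vertices)
    f_off <- f_off + nrow(m$faces)
  }
  list(mesh = tri_mesh(do.call(rbind, verts), do.call(rbind, faces)),
       face_offsets = offsets)
}

# weld vertices closer than tol and reindex faces
weld_vertices <- function(vertices, faces, tol = 1e-9) {
  if (nrow(vertices) == 0L) return(list(vertices = vertices, faces = faces))
  key <- apply(round(vertices / tol), 1, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(vertices = vertices[first, , drop = FALSE],
       faces = matrix(map[faces], ncol = 3))
}

#' Read an STL mesh file
#'
#' Handles both the binary and the ASCII STL dialect, auto-detected from the
#' file contents. Duplicate vertices are welded within a 1e-9 m tolerance and
#' face normals are recomputed from the vertex coordinates.
#'
#' @param path Path to an existing `.stl` file.
#' @return A [tri_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  n_bytes <- file.size(path)
  head_raw <- readBin(path, "raw", n = min(n_bytes, 512))
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  Encoding(head_txt) <- "bytes"
  starts_solid <- grepl("^\\s*solid", head_txt, useBytes = TRUE)
  has_facet <- grepl("facet", head_txt, useBytes = TRUE) ||
    grepl("endsolid", head_txt, useBytes = TRUE)
  is_ascii <- starts_solid && (has_facet || n_bytes < 84)
  if (is_ascii) read_stl_ascii(path)
  else if (n_bytes < 84) {
    stop(sprintf("invalid binary STL: file has %d bytes, need at least 84",
                 n_bytes), call. = FALSE)
  } else read_stl_binary(path, n_bytes)
}

read_stl_binary <- function(path, n_bytes) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  count <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (count == 0L) {
    warning("binary STL contains zero triangles", call. = FALSE)
    return(tri_mesh(matrix(numeric(0), ncol = 3), matrix(integer(0), ncol = 3)))
  }
  expected <- 84 + 50 * count
  if (n_bytes < expected) {
    stop(sprintf(
      "invalid binary STL: truncated at byte %d (expected %d bytes for %d triangles)",
      n_bytes, expected, count), call. = FALSE)
  }
  data <- readBin(con, "raw", n = 50 * count)
  rec <- rep(seq(0L, by = 50L, length.out = count), each = 48L)
  float_bytes <- rec + rep(1:48, times = count)
  vals <- readBin(data[float_bytes], "numeric", size = 4, n = 12 * count,
                  endian = "little")
  m <- matrix(vals, ncol = 12, byrow = TRUE)
  verts <- rbind_interleave(m[, 4:6, drop = FALSE],
                            m[, 7:9, drop = FALSE],
                            m[, 10:12, drop = FALSE])
  faces <- matrix(seq_len(3 * count), ncol = 3, byrow = TRUE)
  w <- weld_vertices(verts, faces)
  tri_mesh(w$vertices, w$faces, normals = m[, 1:3, drop = FALSE])
}

# stack rows of a, b, c as (a1,b1,c1,a2,b2,c2,...)
rbind_interleave <- function(a, b, c_) {
  out <- matrix(0, nrow = 3 * nrow(a), ncol = 3)
  out[seq(1, by = 3, length.out = nrow(a)), ] <- a
  out[seq(2, by = 3, length.out = nrow(a)), ] <- b
  out[seq(3, by = 3, length.out = nrow(a)), ] <- c_
  out
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L) {
    if (any(grepl("^\\s*solid", lines))) {
      warning("ASCII STL contains zero triangles", call. = FALSE)
      return(tri_mesh(matrix(numeric(0), ncol = 3), matrix(integer(0), ncol = 3)))
    }
    stop("invalid ASCII STL: no vertex records found", call. = FALSE)
  }
  if (length(vlines) %% 3 != 0L) {
    stop(sprintf("invalid ASCII STL: %d vertex records (not a multiple of 3)",
                 length(vlines)), call. = FALSE)
  }
  nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(x) as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  if (anyNA(verts)) stop("invalid ASCII STL: malformed vertex line", call. = FALSE)
  count <- nrow(verts) / 3
  faces <- matrix(seq_len(3 * count), ncol = 3, byrow = TRUE)
  w <- weld_vertices(verts, faces)
  tri_mesh(w$vertices, w$faces)
}

#' Write an STL mesh file
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path.
#' @param dialect `"binary"` (84 + 50 bytes per facet) or `"ascii"`.
#' @return `path`, invisibly. Reading the file back with [read_stl()]
#'   reproduces the mesh up to vertex ordering.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(mesh, "tri_mesh"))
  f <- mesh$faces
  tri <- function(i) mesh$vertices[f[, i], , drop = FALSE]
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "echoscape binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    if (nrow(f) > 0) {
      rec <- cbind(mesh$normals, tri(1), tri(2), tri(3))
      for (i in seq_len(nrow(f))) {
        writeBin(as.numeric(rec[i, ]), con, size = 4, endian = "little")
        writeBin(as.integer(0), con, size = 2, endian = "little")
      }
    }
  } else {
    out <- c("solid echoscape")
    if (nrow(f) > 0) {
      a <- tri(1); b <- tri(2); c_ <- tri(3)
      fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
      out <- c(out, as.vector(rbind(
        paste("facet normal", fmt(mesh$normals)),
        "  outer loop",
        paste("    vertex", fmt(a)),
        paste("    vertex", fmt(b)),
        paste("    vertex", fmt(c_)),
        "  endloop",
        "endfacet"
      )))
    }
    out <- c(out, "endsolid echoscape")
    writeLines(out, path)
  }
  invisible(path)
}
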