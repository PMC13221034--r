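# Triangle-mesh construction: closed primitives with consistently outward
# winding, rigid transforms, part merging, and Wavefront OBJ I/O (vertices
# and triangular faces only). All meshes in the package are built from
# these parts and normalized to unit bounding-sphere radius.

new_mesh <- function(vertices, faces, front_axis = c(1, 0, 0),
                     category_id = NA_character_, model_id = NA_integer_) {
  storage.mode(faces) <- "integer"
  structure(
    list(vertices = vertices, faces = faces,
         front_axis = front_axis, category_id = category_id,
         model_id = as.integer(model_id)),
    class = "cc_mesh")
}

#' @export
print.cc_mesh <- function(x, ...) {
  cat(sprintf("<cc_mesh> %s/%s: %d vertices, %d faces\n",
              x$category_id, x$model_id, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Validate a triangle mesh
#'
#' Checks the structural invariants every generated mesh must satisfy:
#' all face indices reference existing vertices, the front axis has unit
#' norm (tolerance 1e-9), there are at least 4 non-degenerate triangles,
#' and the winding is consistently outward (positive total signed volume
#' via the divergence theorem).
#'
#' @param mesh a mesh as returned by [generate_category_family()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (any(f < 1L) || any(f > nrow(v))) stop("face index out of range")
  if (abs(vnorm(mesh$front_axis) - 1) > 1e-9) stop("front_axis must be unit norm")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  n <- cross_mat(b - a, cc - a)
  areas <- 0.5 * sqrt(rowSums(n^2))
  if (sum(areas > 1e-12) < 4) stop("mesh needs at least 4 non-degenerate triangles")
  if (mesh_volume(mesh) <= 0) stop("mesh winding is not consistently outward")
  invisible(TRUE)
}

# Signed volume via sum of tetrahedra against the origin; positive for
# closed meshes with outward-facing normals.
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# ---- primitives (outward winding by construction) --------------------------

# Latitude/longitude sphere, radius 1, centred at origin.
prim_sphere <- function(n_lat = 10, n_lon = 16) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 1)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  verts <- list(); idx <- matrix(0L, n_lat + 1, n_lon)
  k <- 0L
  for (i in seq_len(n_lat + 1)) for (j in seq_len(n_lon)) {
    k <- k + 1L
    verts[[k]] <- c(cos(lat[i]) * cos(lon[j]), cos(lat[i]) * sin(lon[j]), sin(lat[i]))
    idx[i, j] <- k
  }
  faces <- list(); m <- 0L
  for (i in seq_len(n_lat)) for (j in seq_len(n_lon)) {
    j2 <- if (j == n_lon) 1L else j + 1L
    v00 <- idx[i, j]; v01 <- idx[i, j2]; v10 <- idx[i + 1, j]; v11 <- idx[i + 1, j2]
    if (i > 1) { m <- m + 1L; faces[[m]] <- c(v00, v01, v11) }
    if (i < n_lat) { m <- m + 1L; faces[[m]] <- c(v00, v11, v10) }
  }
  list(vertices = do.call(rbind, verts), faces = do.call(rbind, faces))
}

# Axis-aligned box with half-extents hx, hy, hz.
prim_box <- function(hx = 1, hy = 1, hz = 1) {
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- cbind(s$x * hx, s$y * hy, s$z * hz)
  # indices: 1:(-,-,-) 2:(+,-,-) 3:(-,+,-) 4:(+,+,-) 5:(-,-,+) 6:(+,-,+) 7:(-,+,+) 8:(+,+,+)
  quads <- rbind(
    c(1, 3, 4, 2),   # bottom  (z-)
    c(5, 6, 8, 7),   # top     (z+)
    c(1, 2, 6, 5),   # front   (y-)
    c(3, 7, 8, 4),   # back    (y+)
    c(1, 5, 7, 3),   # left    (x-)
    c(2, 4, 8, 6))   # right   (x+)
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  list(vertices = v, faces = f)
}

# Closed cylinder along z in [-h/2, h/2], radius r.
prim_cylinder <- function(r = 1, h = 1, n = 16) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  bot <- cbind(r * cos(th), r * sin(th), -h / 2)
  top <- cbind(r * cos(th), r * sin(th), h / 2)
  v <- rbind(bot, top, c(0, 0, -h / 2), c(0, 0, h / 2))
  cb <- 2L * n + 1L; ct <- 2L * n + 2L
  faces <- list(); m <- 0L
  for (j in seq_len(n)) {
    j2 <- if (j == n) 1L else j + 1L
    m <- m + 1L; faces[[m]] <- c(j, j2, n + j2)
    m <- m + 1L; faces[[m]] <- c(j, n + j2, n + j)
    m <- m + 1L; faces[[m]] <- c(cb, j2, j)         # bottom cap, normal -z
    m <- m + 1L; faces[[m]] <- c(ct, n + j, n + j2) # top cap, normal +z
  }
  list(vertices = v, faces = do.call(rbind, faces))
}

# Closed cone: base disc of radius r at z = 0, apex at z = h.
prim_cone <- function(r = 1, h = 1, n = 16) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  base <- cbind(r * cos(th), r * sin(th), 0)
  v <- rbind(base, c(0, 0, h), c(0, 0, 0))
  apex <- n + 1L; cb <- n + 2L
  faces <- list(); m <- 0L
  for (j in seq_len(n)) {
    j2 <- if (j == n) 1L else j + 1L
    m <- m + 1L; faces[[m]] <- c(j, j2, apex)
    m <- m + 1L; faces[[m]] <- c(cb, j2, j)
  }
  list(vertices = v, faces = do.call(rbind, faces))
}

# Torus around the z axis: major radius R, tube radius r.
prim_torus <- function(R = 1, r = 0.3, n_major = 18, n_minor = 10) {
  u <- seq(0, 2 * pi, length.out = n_major + 1)[-(n_major + 1)]
  w <- seq(0, 2 * pi, length.out = n_minor + 1)[-(n_minor + 1)]
  idx <- matrix(0L, n_major, n_minor); verts <- list(); k <- 0L
  for (i in seq_len(n_major)) for (j in seq_len(n_minor)) {
    k <- k + 1L
    verts[[k]] <- c((R + r * cos(w[j])) * cos(u[i]),
                    (R + r * cos(w[j])) * sin(u[i]),
                    r * sin(w[j]))
    idx[i, j] <- k
  }
  faces <- list(); m <- 0L
  for (i in seq_len(n_major)) for (j in seq_len(n_minor)) {
    i2 <- if (i == n_major) 1L else i + 1L
    j2 <- if (j == n_minor) 1L else j + 1L
    m <- m + 1L; faces[[m]] <- c(idx[i, j], idx[i2, j], idx[i2, j2])
    m <- m + 1L; faces[[m]] <- c(idx[i, j], idx[i2, j2], idx[i, j2])
  }
  list(vertices = do.call(rbind, verts), faces = do.call(rbind, faces))
}

# ---- transforms and assembly ----------------------------------------------

part_transform <- function(part, scale = c(1, 1, 1), rotate = NULL, translate = c(0, 0, 0)) {
  v <- part$vertices
  v <- sweep(v, 2, scale, `*`)
  if (!is.null(rotate)) v <- v %*% t(rotate)
  v <- sweep(v, 2, translate, `+`)
  # a negative-determinant transform would flip winding; scales here are positive
  list(vertices = v, faces = part$faces)
}

rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))

merge_parts <- function(parts) {
  off <- 0L; vs <- list(); fs <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    vs[[i]] <- p$vertices
    fs[[i]] <- p$faces + off
    off <- off + nrow(p$vertices)
  }
  list(vertices = do.call(rbind, vs), faces = do.call(rbind, fs))
}

# Centre at the bounding-box centre and scale to unit bounding-sphere radius,
# so camera framing is independent of the shape family.
normalize_mesh <- function(part) {
  v <- part$vertices
  ctr <- (apply(v, 2, max) + apply(v, 2, min)) / 2
  v <- sweep(v, 2, ctr, `-`)
  r <- max(sqrt(rowSums(v^2)))
  part$vertices <- v / r
  part
}

# ---- OBJ I/O ----------------------------------------------------------------

#' Write a mesh as Wavefront OBJ
#'
#' Writes vertices (`v`) and triangular faces (`f`) only.
#'
#' @param mesh a mesh object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# %s model %d", mesh$category_id, mesh$model_id), con)
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' Supports the vertex/triangular-face subset written by [write_obj()].
#' Polygonal faces with more than 3 vertices are fan-triangulated; texture
#' and normal indices (`f v/vt/vn`) are ignored.
#'
#' @param path OBJ file path.
#' @param category_id,model_id,front_axis metadata to attach.
#' @return a mesh object.
#' @export
read_obj <- function(path, category_id = NA_character_, model_id = NA_integer_,
                     front_axis = c(1, 0, 0)) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  if (!length(vl) || !length(fl)) stop("OBJ file has no vertices or faces")
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(x) {
    ix <- as.integer(vapply(strsplit(x, "/"), `[`, "", 1))
    if (length(ix) < 3) stop("face with fewer than 3 vertices")
    cbind(ix[1], ix[2:(length(ix) - 1)], ix[3:length(ix)])
  }))
  new_mesh(v, f, front_axis = front_axis, category_id = category_id,
           model_id = model_id)
}
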