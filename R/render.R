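# Software renderer: perspective rasterization with a depth buffer,
# per-pixel barycentric normal interpolation, Lambertian shading with a
# small ambient term, and attached shadows by per-pixel shadow rays
# against the full triangle set (vectorized Moller-Trumbore). Objects are
# rendered white-on-black; the figure mask is shared between shaded and
# silhouette renders so matched 3D/2D stimuli differ only in shading and
# attached-shadow cues inside the silhouette.

#' Construct a camera
#'
#' The camera sits at spherical coordinates `(azimuth, elevation,
#' distance)` around `target` and looks at it, world +z up. Azimuth 0
#' looks down the +x axis toward the object, so a model whose front axis
#' is +x faces the viewer at azimuth 0.
#'
#' @param azimuth degrees in [0, 360).
#' @param elevation degrees above the horizontal plane.
#' @param distance camera distance (length units; must exceed the unit
#'   bounding-sphere radius of normalized meshes).
#' @param target look-at point (default origin).
#' @param resolution square image side in pixels (>= 32).
#' @param fov half-angle of the vertical field of view in radians;
#'   default frames the unit sphere with a small margin.
#' @return a camera object.
#' @export
new_camera <- function(azimuth, elevation = 15, distance = 3,
                       target = c(0, 0, 0), resolution = 224,
                       fov = atan(1.25 / distance)) {
  if (resolution < 32) stop("resolution must be >= 32")
  if (distance <= 1) stop("distance must exceed the unit bounding-sphere radius")
  structure(list(azimuth = azimuth %% 360, elevation = elevation,
                 distance = distance, target = target,
                 resolution = as.integer(resolution), fov = fov),
            class = "cc_camera")
}

#' Build an orbit of cameras
#'
#' Cameras at azimuths `0, step, 2*step, ...` sharing elevation, distance
#' and target; the standard orbit is 12 views in 30-degree increments.
#'
#' @param n_views number of cameras.
#' @param step azimuth increment in degrees (> 0); `n_views * step` must
#'   not exceed 360.
#' @param elevation,distance,resolution shared camera parameters.
#' @param target look-at point.
#' @return list of cameras.
#' @export
orbit_cameras <- function(n_views = 12, step = 30, elevation = 15,
                          distance = 3, resolution = 224, target = c(0, 0, 0)) {
  if (step <= 0) stop("step must be > 0")
  if (n_views * step > 360) stop("n_views * step must not exceed 360")
  lapply(seq_len(n_views) - 1L, function(i)
    new_camera(i * step, elevation, distance, target, resolution))
}

#' Construct a directional light
#'
#' @param direction unit 3-vector pointing from the light toward the
#'   scene.
#' @param ambient ambient coefficient in [0, 1).
#' @return a light object.
#' @export
new_light <- function(direction, ambient = 0.1) {
  if (ambient < 0 || ambient >= 1) stop("ambient must be in [0, 1)")
  structure(list(direction = unitize(direction), ambient = ambient),
            class = "cc_light")
}

#' Default light for a camera
#'
#' A directional light offset from the camera axis by fixed azimuth and
#' elevation angles (default 30/30 degrees), pointing at the target; the
#' offset guarantees oblique shading and nonempty attached shadows on
#' concave shapes.
#'
#' @param camera a camera object.
#' @param az_offset,el_offset angular offsets in degrees.
#' @param ambient ambient coefficient.
#' @return a light object.
#' @export
default_light <- function(camera, az_offset = 30, el_offset = 30, ambient = 0.1) {
  az <- (camera$azimuth + az_offset) * pi / 180
  el <- (camera$elevation + el_offset) * pi / 180
  from <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  new_light(-from, ambient)
}

camera_frame <- function(camera) {
  az <- camera$azimuth * pi / 180
  el <- camera$elevation * pi / 180
  eye <- camera$target + camera$distance *
    c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  fwd <- unitize(camera$target - eye)
  up <- if (abs(fwd[3]) > 0.999) c(1, 0, 0) else c(0, 0, 1)
  right <- unitize(cross3(fwd, up))
  cup <- cross3(right, fwd)
  list(eye = eye, forward = fwd, right = right, up = cup)
}

# Area-weighted smooth vertex normals.
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  fn <- cross_mat(b - a, cc - a)  # magnitude = 2 * area
  vn <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (ch in 1:3) {
      s <- rowsum(fn[, ch], f[, k])
      vn[as.integer(rownames(s)), ch] <- vn[as.integer(rownames(s)), ch] + s
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len < 1e-12] <- 1
  vn / len
}

# Rasterize a mesh: depth buffer plus interpolated world position and
# normal per covered pixel. Buffers are res x res matrices, row 1 = image
# top. Returns NULL-filled buffers (empty mask) for degenerate meshes.
rasterize_mesh <- function(mesh, camera) {
  res <- camera$resolution
  frame <- camera_frame(camera)
  v <- mesh$vertices
  rel <- sweep(v, 2, frame$eye, `-`)
  zc <- rel %*% frame$forward
  xc <- rel %*% frame$right
  yc <- rel %*% frame$up
  tanf <- tan(camera$fov)
  col_f <- ((xc / zc) / tanf + 1) / 2 * res + 0.5
  row_f <- (1 - (yc / zc) / tanf) / 2 * res + 0.5
  vn <- vertex_normals(mesh)

  npix <- res * res
  depth <- rep(Inf, npix)
  pos <- matrix(NA_real_, npix, 3)
  nrm <- matrix(NA_real_, npix, 3)

  f <- mesh$faces
  for (t in seq_len(nrow(f))) {
    i1 <- f[t, 1]; i2 <- f[t, 2]; i3 <- f[t, 3]
    if (zc[i1] <= 0.05 || zc[i2] <= 0.05 || zc[i3] <= 0.05) next
    x1 <- col_f[i1]; x2 <- col_f[i2]; x3 <- col_f[i3]
    y1 <- row_f[i1]; y2 <- row_f[i2]; y3 <- row_f[i3]
    cmin <- max(1L, as.integer(ceiling(min(x1, x2, x3) - 0.5)))
    cmax <- min(res, as.integer(floor(max(x1, x2, x3) + 0.5)))
    rmin <- max(1L, as.integer(ceiling(min(y1, y2, y3) - 0.5)))
    rmax <- min(res, as.integer(floor(max(y1, y2, y3) + 0.5)))
    if (cmin > cmax || rmin > rmax) next
    denom <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(denom) < 1e-12) next
    cols <- rep(cmin:cmax, each = rmax - rmin + 1L)
    rows <- rep(rmin:rmax, times = cmax - cmin + 1L)
    px <- as.numeric(cols); py <- as.numeric(rows)
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / denom
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / denom
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(inside)) next
    idx <- rows[inside] + (cols[inside] - 1L) * res
    z <- l1[inside] * zc[i1] + l2[inside] * zc[i2] + l3[inside] * zc[i3]
    closer <- z < depth[idx] - 1e-9
    if (!any(closer)) next
    idx <- idx[closer]
    li1 <- l1[inside][closer]; li2 <- l2[inside][closer]; li3 <- l3[inside][closer]
    depth[idx] <- z[closer]
    pos[idx, ] <- li1 %o% v[i1, ] + li2 %o% v[i2, ] + li3 %o% v[i3, ]
    nrm[idx, ] <- li1 %o% vn[i1, ] + li2 %o% vn[i2, ] + li3 %o% vn[i3, ]
  }
  mask <- is.finite(depth)
  list(mask = matrix(mask, res, res), depth = depth, pos = pos, nrm = nrm,
       res = res)
}

# Which of the rays (rows of `origins`, common direction `dir`) hit any
# triangle of the mesh? Vectorized Moller-Trumbore, looping over
# triangles with an active-ray set.
rays_occluded <- function(origins, dir, mesh, t_min = 1e-4) {
  n <- nrow(origins)
  occluded <- rep(FALSE, n)
  if (n == 0) return(occluded)
  v <- mesh$vertices; f <- mesh$faces
  active <- seq_len(n)
  for (t in seq_len(nrow(f))) {
    if (!length(active)) break
    v0 <- v[f[t, 1], ]; e1 <- v[f[t, 2], ] - v0; e2 <- v[f[t, 3], ] - v0
    h <- cross3(dir, e2)
    a <- sum(e1 * h)
    if (abs(a) < 1e-12) next
    O <- origins[active, , drop = FALSE]
    s1 <- O[, 1] - v0[1]; s2 <- O[, 2] - v0[2]; s3 <- O[, 3] - v0[3]
    u <- (s1 * h[1] + s2 * h[2] + s3 * h[3]) / a
    # inclusive barycentric bounds so rays through shared edges register a
    # hit regardless of floating-point evaluation order
    keep <- u >= -1e-9 & u <= 1 + 1e-9
    if (!any(keep)) next
    qx <- s2 * e1[3] - s3 * e1[2]
    qy <- s3 * e1[1] - s1 * e1[3]
    qz <- s1 * e1[2] - s2 * e1[1]
    w <- (dir[1] * qx + dir[2] * qy + dir[3] * qz) / a
    tt <- (e2[1] * qx + e2[2] * qy + e2[3] * qz) / a
    hit <- keep & w >= -1e-9 & (u + w) <= 1 + 1e-9 & tt > t_min
    if (any(hit)) {
      occluded[active[hit]] <- TRUE
      active <- active[!hit]
    }
  }
  occluded
}

#' Render a mesh with Lambertian shading and attached shadows
#'
#' Off-figure pixels are 0 (black background). On-figure pixels take the
#' value `ambient + (1 - ambient) * max(0, n . (-l)) * visibility`, where
#' `n` is the barycentric-interpolated unit surface normal, `l` the light
#' direction, and visibility is 0 when a shadow ray from the surface
#' point toward the light hits the mesh (an attached shadow) and 1
#' otherwise. The `shadow` field marks visibility-0 pixels whose surface
#' faces the light; back-facing points receive only the ambient term and
#' are not counted as attached shadow.
#'
#' @param mesh a mesh object.
#' @param camera a camera object.
#' @param light a light object; default [default_light()] for the camera.
#' @return a `shaded_render`: list with `gray`, `mask`, `shadow`
#'   (res x res matrices), `camera`, `light`.
#' @export
render_shaded <- function(mesh, camera, light = default_light(camera)) {
  rast <- rasterize_mesh(mesh, camera)
  res <- rast$res
  gray <- matrix(0, res, res)
  shadow <- matrix(FALSE, res, res)
  idx <- which(is.finite(rast$depth))
  if (!length(idx)) {
    warning("degenerate mesh: no pixels covered")
    return(structure(list(gray = gray, mask = rast$mask, shadow = shadow,
                          camera = camera, light = light),
                     class = "shaded_render"))
  }
  N <- rast$nrm[idx, , drop = FALSE]
  len <- sqrt(rowSums(N^2)); len[len < 1e-12] <- 1
  N <- N / len
  l <- light$direction
  lam <- pmax(0, -(N %*% l)[, 1])
  vis <- rep(1, length(idx))
  lit <- which(lam > 1e-9)
  if (length(lit)) {
    to_light <- -l
    orig <- rast$pos[idx[lit], , drop = FALSE] +
      matrix(to_light, length(lit), 3, byrow = TRUE) * 5e-3
    occ <- rays_occluded(orig, to_light, mesh)
    vis[lit][occ] <- 0
  }
  a <- light$ambient
  gray[idx] <- a + (1 - a) * lam * vis
  shadow[idx] <- lam > 1e-9 & vis == 0
  structure(list(gray = gray, mask = rast$mask, shadow = shadow,
                 camera = camera, light = light),
            class = "shaded_render")
}

#' Render a binary silhouette
#'
#' Shares the rasterization path of [render_shaded()], so the silhouette
#' equals the shaded render's figure mask pixel for pixel.
#'
#' @param mesh a mesh object.
#' @param camera a camera object.
#' @return res x res logical matrix.
#' @export
render_silhouette <- function(mesh, camera) {
  rast <- rasterize_mesh(mesh, camera)
  if (!any(rast$mask)) warning("degenerate mesh: no pixels covered")
  rast$mask
}

#' @export
print.shaded_render <- function(x, ...) {
  cat(sprintf("<shaded_render> %dx%d, %d figure px, %d shadow px\n",
              nrow(x$gray), ncol(x$gray), sum(x$mask), sum(x$shadow)))
  invisible(x)
}

#' Write a grayscale render or binary mask as PNG
#' @param img numeric or logical matrix in [0,1].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(img * 1, path)
  invisible(path)
}
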