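# Texture substitution and dataset assembly. The 3D operator multiplies
# the shaded grayscale render pixelwise with the RGB texture; the 2D
# operator does the same with the binary silhouette, so matched 3D/2D
# stimuli share the figure mask exactly and differ only in shading and
# attached-shadow cues. Texture application is in image space: the
# texture is tiled over the full frame and then multiplied.

# Tile (wrap) a texture's pixel grid to h x w; for non-tileable textures
# the tiling is integer repetition followed by a center crop.
tile_texture <- function(tex, h, w = h) {
  px <- tex$pixels
  th <- dim(px)[1]; tw <- dim(px)[2]
  if (isTRUE(tex$tileable) || th >= h && tw >= w) {
    ri <- ((seq_len(h) - 1L) %% th) + 1L
    ci <- ((seq_len(w) - 1L) %% tw) + 1L
  } else {
    reps_r <- ceiling(h / th); reps_c <- ceiling(w / tw)
    off_r <- (reps_r * th - h) %/% 2; off_c <- (reps_c * tw - w) %/% 2
    ri <- ((seq_len(h) + off_r - 1L) %% th) + 1L
    ci <- ((seq_len(w) + off_c - 1L) %% tw) + 1L
  }
  px[ri, ci, , drop = FALSE]
}

#' Retexture a shaded render (3D condition)
#'
#' Per pixel and channel, output = grayscale shading value times texture
#' RGB. The background stays black and shading modulates the texture
#' inside the figure, preserving shading and attached-shadow cues.
#'
#' @param shaded a `shaded_render` from [render_shaded()].
#' @param texture a texture object, tiled/cropped to the render size.
#' @return H x W x 3 RGB array in [0, 1].
#' @export
retexture_3d <- function(shaded, texture) {
  g <- shaded$gray
  tx <- tile_texture(texture, nrow(g), ncol(g))
  if (!all(dim(tx)[1:2] == dim(g)))
    stop("texture resolution does not match the render after tiling")
  out <- tx
  for (ch in 1:3) out[, , ch] <- g * tx[, , ch]
  out
}

#' Retexture a silhouette (2D condition)
#'
#' Output equals the texture inside the figure mask and black outside;
#' identical to [retexture_3d()] applied to a render whose grayscale
#' image is the binary mask itself.
#'
#' @param mask binary figure mask (logical or 0/1 matrix).
#' @param texture a texture object.
#' @return H x W x 3 RGB array in [0, 1].
#' @export
retexture_2d <- function(mask, texture) {
  g <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  tx <- tile_texture(texture, nrow(g), ncol(g))
  if (!all(dim(tx)[1:2] == dim(g)))
    stop("texture resolution does not match the render after tiling")
  out <- tx
  for (ch in 1:3) out[, , ch] <- g * tx[, , ch]
  out
}

#' Build a cue-conflict stimulus dataset
#'
#' Crosses meshes x cameras x textures x conditions into a stimulus
#' manifest, one record per combination. Records where the shape and
#' texture category coincide are flagged `congruent` (generated, but
#' excluded from bias metrics by default downstream). In lazy mode only
#' the manifest is built; with `out_dir` set, base renders are computed
#' once per (mesh, camera) and each retextured PNG is written to disk.
#'
#' @param meshes list of mesh objects (distinct (category, model_id)).
#' @param textures list of texture objects (distinct (category, texture_id)).
#' @param cameras list of cameras, typically [orbit_cameras()].
#' @param conditions subset of `c("3D", "2D")`.
#' @param seed integer seed recorded in the config (rendering itself is
#'   deterministic).
#' @param out_dir directory for PNG output, or `NULL` for lazy mode.
#' @param profile_tolerance canonicality band half-width in degrees.
#' @param light_fn function(camera) -> light; default [default_light()].
#' @return a `stim_manifest`: data.frame of stimulus records with a
#'   `config` attribute (counts, seed, renderer settings) and per-
#'   condition/canonicality totals.
#' @export
build_dataset <- function(meshes, textures, cameras, conditions = c("3D", "2D"),
                          seed = 1, out_dir = NULL, profile_tolerance = 31,
                          light_fn = default_light) {
  if (!length(meshes) || !length(textures) || !length(cameras))
    stop("meshes, textures and cameras must be nonempty")
  if (!all(conditions %in% c("3D", "2D")) || !length(conditions))
    stop("conditions must be a nonempty subset of c('3D', '2D')")
  mesh_key <- vapply(meshes, function(m) paste(m$category_id, m$model_id), "")
  tex_key <- vapply(textures, function(t) paste(t$category_id, t$texture_id), "")
  if (anyDuplicated(mesh_key)) stop("duplicate model ids in meshes")
  if (anyDuplicated(tex_key)) stop("duplicate texture ids in textures")

  mi <- seq_along(meshes); ti <- seq_along(textures); vi <- seq_along(cameras)
  grid <- expand.grid(mesh = mi, view = vi, tex = ti, condition = conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  shape_cat <- vapply(meshes, function(m) m$category_id, "")
  shape_mid <- vapply(meshes, function(m) m$model_id, 0L)
  tex_cat <- vapply(textures, function(t) t$category_id, "")
  tex_tid <- vapply(textures, function(t) t$texture_id, 0L)
  az <- vapply(cameras, function(cm) cm$azimuth, 0)
  el <- vapply(cameras, function(cm) cm$elevation, 0)

  man <- data.frame(
    shape_category = shape_cat[grid$mesh],
    shape_model_id = shape_mid[grid$mesh],
    texture_category = tex_cat[grid$tex],
    texture_id = tex_tid[grid$tex],
    viewpoint_index = grid$view - 1L,
    condition = as.character(grid$condition),
    stringsAsFactors = FALSE)
  canon_mat <- vapply(vi, function(v) vapply(mi, function(m)
    label_canonicality(az[v], el[v], meshes[[m]]$front_axis, profile_tolerance),
    ""), character(length(mi)))
  canon_mat <- matrix(canon_mat, nrow = length(mi))
  man$canonicality <- canon_mat[cbind(grid$mesh, grid$view)]
  man$congruent <- man$shape_category == man$texture_category
  man$stimulus_id <- sprintf("%s_%d_%s_%d_v%02d_%s",
                             man$shape_category, man$shape_model_id,
                             man$texture_category, man$texture_id,
                             man$viewpoint_index, man$condition)
  if (anyDuplicated(man$stimulus_id)) stop("duplicate stimulus records")
  man$image_path <- NA_character_

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in mi) for (v in vi) {
      cam <- cameras[[v]]
      sr <- render_shaded(meshes[[m]], cam, light_fn(cam))
      sel <- grid$mesh == m & grid$view == v
      for (r in which(sel)) {
        img <- if (man$condition[r] == "3D") retexture_3d(sr, textures[[grid$tex[r]]])
               else retexture_2d(sr$mask, textures[[grid$tex[r]]])
        p <- file.path(out_dir, paste0(man$stimulus_id[r], ".png"))
        png::writePNG(img, p)
        man$image_path[r] <- p
      }
    }
  }

  res <- cameras[[1]]$resolution
  config <- list(n_meshes = length(meshes), n_textures = length(textures),
                 n_views = length(cameras), conditions = conditions,
                 seed = seed, resolution = res,
                 profile_tolerance = profile_tolerance,
                 lazy = is.null(out_dir))
  totals <- list(
    by_condition = table(man$condition),
    by_canonicality = table(man$canonicality),
    n_base_renders = length(meshes) * length(cameras),
    n_records = nrow(man))
  structure(man, config = config, totals = totals,
            class = c("stim_manifest", "data.frame"))
}

#' Manifest totals
#'
#' Per-condition and per-canonicality record counts plus the number of
#' base renders (mesh x camera) behind the manifest.
#'
#' @param manifest a `stim_manifest`.
#' @return list of totals.
#' @export
manifest_totals <- function(manifest) attr(manifest, "totals")

#' Write / read a manifest as CSV (+ JSON config sidecar)
#'
#' @param manifest a `stim_manifest`.
#' @param path CSV path; the config sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  cfg <- attr(manifest, "config")
  if (!is.null(cfg))
    jsonlite::write_json(cfg, sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  cfgp <- sub("\\.csv$", ".json", path)
  cfg <- if (file.exists(cfgp)) jsonlite::fromJSON(cfgp) else NULL
  totals <- list(by_condition = table(man$condition),
                 by_canonicality = table(man$canonicality),
                 n_records = nrow(man))
  structure(man, config = cfg, totals = totals,
            class = c("stim_manifest", "data.frame"))
}
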