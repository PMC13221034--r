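# Procedural texture families. Each of the ten categories is bound to a
# distinct periodic pattern family with a category-specific base hue;
# texture instances within a category vary in frequency, phase, and
# secondary color. Every pixel is pattern content (no background), and
# patterns are evaluated on u,v in [0, 1] with integer frequencies so the
# opposite edges of a tileable texture match exactly.

texture_family_table <- function() {
  data.frame(
    category_id = cc_categories(),
    family = c("checkerboard", "blob_noise", "diagonal_stripes", "polka_dots",
               "wrinkle_noise", "horizontal_stripes", "smooth_grating",
               "vertical_stripes", "weave", "zigzag"),
    # base hues evenly spaced on the color circle so category palettes
    # stay distinguishable under the per-texture jitter
    hue = c(0.5, 0.1, 0.3, 0.8, 0.0, 0.6, 0.2, 0.7, 0.4, 0.9),
    stringsAsFactors = FALSE)
}

#' Texture-family registry
#'
#' Fixed binding from category id to procedural texture family and base
#' hue, read from the JSON registry shipped with the package.
#'
#' @return named list of family descriptors.
#' @export
texture_registry <- function() {
  path <- system.file("extdata", "texture_families.json", package = "cueconflict3d")
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

# soft square wave in [0,1]; sharpness controls edge softness
soft_square <- function(x, sharp = 25) plogis(sharp * sin(x))

# pattern field generators; u, v are matrices in [0, 1]
texture_field <- function(family, u, v) {
  k <- sample(3:6, 1)        # integer cycles -> exact periodicity on [0,1]
  ph <- 2 * pi * runif(2)
  switch(family,
    checkerboard = soft_square(2 * pi * k * u + ph[1]) *
                   soft_square(2 * pi * k * v + ph[2]) +
                   (1 - soft_square(2 * pi * k * u + ph[1])) *
                   (1 - soft_square(2 * pi * k * v + ph[2])),
    blob_noise = {
      f <- 0
      for (i in 1:4) {
        kk <- sample(1:4, 2, replace = TRUE)
        f <- f + runif(1, 0.5, 1) * sin(2 * pi * kk[1] * u + 2 * pi * runif(1)) *
                                    sin(2 * pi * kk[2] * v + 2 * pi * runif(1))
      }
      (f - min(f)) / (max(f) - min(f))
    },
    diagonal_stripes = soft_square(2 * pi * k * (u + v) + ph[1]),
    polka_dots = {
      n <- sample(4:6, 1)
      du <- (u * n) %% 1 - 0.5
      dv <- (v * n) %% 1 - 0.5
      r <- runif(1, 0.22, 0.3)
      plogis(-40 * (sqrt(du^2 + dv^2) - r))
    },
    wrinkle_noise = {
      f <- sin(2 * pi * k * u + 3 * sin(2 * pi * 2 * v + ph[1]) + ph[2])
      (f + 1) / 2
    },
    horizontal_stripes = soft_square(2 * pi * k * v + ph[1]),
    smooth_grating = (sin(2 * pi * k * u + ph[1]) + 1) / 2,
    vertical_stripes = soft_square(2 * pi * k * u + ph[1]),
    weave = (sin(2 * pi * k * u + ph[1]) * sin(2 * pi * k * v + ph[2]) + 1) / 2,
    zigzag = {
      tri <- function(x) 2 * abs(x / (2 * pi) - floor(x / (2 * pi) + 0.5))
      soft_square(2 * pi * k * v + 4 * tri(2 * pi * k * u + ph[1]) + ph[2])
    },
    stop(sprintf("unknown texture family '%s'", family)))
}

#' Generate a procedural texture image
#'
#' Deterministic under `(category_id, texture_id, size, seed)`. The
#' pattern family and base hue are fixed per category; frequency, phase
#' and secondary color vary with the texture id. All pixels are pattern
#' content and values lie in [0, 1].
#'
#' @param category_id one of [cc_categories()].
#' @param texture_id integer 0-9 within category.
#' @param size image side in pixels (>= 16).
#' @param seed integer seed.
#' @return a texture object: list with `pixels` (size x size x 3 array in
#'   [0,1]), `category_id`, `texture_id`, `tileable`.
#' @export
generate_texture <- function(category_id, texture_id, size = 256, seed = 1) {
  if (size < 16) stop("size must be >= 16")
  tab <- texture_family_table()
  row <- tab[tab$category_id == category_id, ]
  if (nrow(row) != 1) stop(sprintf("unknown category_id '%s'", category_id))
  cat_ix <- match(category_id, cc_categories())
  local_seed(derive_seed(seed, 31L * cat_ix, texture_id), {
    # u = v = 0 at the first pixel and 1 at the last: opposite edges equal
    g <- seq(0, 1, length.out = size)
    u <- matrix(g, size, size, byrow = TRUE)   # column coordinate
    v <- matrix(g, size, size, byrow = FALSE)  # row coordinate
    f <- texture_field(row$family, u, v)
    hue <- (row$hue + runif(1, -0.015, 0.015)) %% 1
    c1 <- grDevices::hsv(hue, runif(1, 0.6, 0.8), runif(1, 0.8, 0.95))
    c2 <- grDevices::hsv((hue + runif(1, 0.03, 0.06)) %% 1,
                         runif(1, 0.25, 0.45), runif(1, 0.25, 0.45))
    rgb1 <- grDevices::col2rgb(c1) / 255
    rgb2 <- grDevices::col2rgb(c2) / 255
    px <- array(0, c(size, size, 3))
    for (ch in 1:3) px[, , ch] <- rgb2[ch] + (rgb1[ch] - rgb2[ch]) * f
    structure(list(pixels = px, category_id = category_id,
                   texture_id = as.integer(texture_id), tileable = TRUE),
              class = "cc_texture")
  })
}

#' Generate the full texture set
#'
#' @param n_textures textures per category.
#' @param size image side in pixels.
#' @param seed integer seed.
#' @param categories category ids.
#' @return flat list of texture objects (10 x 10 = 100 at defaults).
#' @export
generate_all_textures <- function(n_textures = 10, size = 256, seed = 1,
                                  categories = cc_categories()) {
  unlist(lapply(categories, function(cid)
    lapply(seq_len(n_textures) - 1L, function(tid)
      generate_texture(cid, tid, size = size, seed = seed))),
    recursive = FALSE)
}

#' Validate a texture image
#'
#' Checks value range and, for tileable textures, that opposite edges
#' match within 1e-6.
#'
#' @param tex a texture object.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_texture <- function(tex) {
  px <- tex$pixels
  if (min(px) < 0 || max(px) > 1) stop("texture values must lie in [0, 1]")
  if (isTRUE(tex$tileable)) {
    n <- dim(px)[1]
    if (max(abs(px[1, , ] - px[n, , ])) > 1e-6 ||
        max(abs(px[, 1, ] - px[, n, ])) > 1e-6)
      stop("tileable texture edges do not match")
  }
  invisible(TRUE)
}

#' Write a texture as 8-bit RGB PNG
#' @param tex texture object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_texture_png <- function(tex, path) {
  png::writePNG(tex$pixels, path)
  invisible(path)
}
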