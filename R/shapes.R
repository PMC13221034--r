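# Procedural part-based shape families. Ten categories, each bound to a
# distinct arrangement of primitive parts (spheres, boxes, cylinders,
# cones, tori), standing in for the ten entry-level object categories.
# Within a category, models share the part structure and differ in shape
# parameters sampled deterministically from the seed. Every mesh has a
# unit front axis (+x in model coordinates) used for canonicality
# labeling, and is normalized to unit bounding-sphere radius.

#' Entry-level category labels
#'
#' The ten entry-level categories used throughout the package: five
#' biological and five non-biological.
#'
#' @return character vector of 10 category ids, in lexicographic order.
#' @export
cc_categories <- function() {
  c("bathtub", "bear", "bird", "butterfly", "elephant",
    "fish", "helmet", "mailbox", "mug", "phone")
}

# jitter helper: multiplicative, +/- frac around 1
jit <- function(frac = 0.15) 1 + runif(1, -frac, frac)

# Each family builder draws its shape parameters from the current RNG
# stream and returns a merged, unnormalized part list. Front is +x.
shape_family_builders <- function() {
  list(
    fish = function() {
      body <- part_transform(prim_sphere(8, 12),
                             scale = c(1.1 * jit(), 0.35 * jit(), 0.6 * jit()))
      tail <- part_transform(prim_cone(0.45 * jit(), 0.8 * jit(), 10),
                             rotate = rot_y(pi / 2),
                             translate = c(-1.6, 0, 0))
      merge_parts(list(body, tail))
    },
    elephant = function() {
      body <- part_transform(prim_box(1.0 * jit(), 0.55 * jit(), 0.5 * jit()),
                             translate = c(0, 0, 0.45))
      legs <- lapply(list(c(0.6, 0.35), c(0.6, -0.35), c(-0.6, 0.35), c(-0.6, -0.35)),
                     function(p) part_transform(prim_cylinder(0.14 * jit(), 0.9, 8),
                                                translate = c(p[1], p[2], -0.45)))
      trunk <- part_transform(prim_cylinder(0.1 * jit(), 0.9 * jit(), 8),
                              rotate = rot_y(pi / 2 + 0.5),
                              translate = c(1.25, 0, 0.35))
      merge_parts(c(list(body), legs, list(trunk)))
    },
    butterfly = function() {
      a <- 0.45 * jit(0.25)  # wing sweep angle
      wing <- function(sgn) part_transform(
        prim_box(0.75 * jit(), 0.7 * jit(), 0.05),
        rotate = rot_x(sgn * a),
        translate = c(0, sgn * 0.75, 0.18))
      body <- part_transform(prim_cylinder(0.12 * jit(), 1.5 * jit(), 8),
                             rotate = rot_y(pi / 2))
      merge_parts(list(body, wing(1), wing(-1)))
    },
    bird = function() {
      body <- part_transform(prim_sphere(8, 12),
                             scale = c(0.85 * jit(), 0.45 * jit(), 0.5 * jit()))
      head <- part_transform(prim_sphere(6, 8),
                             scale = rep(0.32 * jit(), 3),
                             translate = c(0.75, 0, 0.45))
      beak <- part_transform(prim_cone(0.12 * jit(), 0.5 * jit(), 8),
                             rotate = rot_y(pi / 2),
                             translate = c(1.0, 0, 0.45))
      tail <- part_transform(prim_box(0.45 * jit(), 0.18, 0.04),
                             rotate = rot_y(-0.4),
                             translate = c(-1.0, 0, 0.15))
      merge_parts(list(body, head, beak, tail))
    },
    bear = function() {
      body <- part_transform(prim_sphere(8, 12),
                             scale = c(0.8 * jit(), 0.6 * jit(), 0.65 * jit()))
      head <- part_transform(prim_sphere(6, 10),
                             scale = rep(0.42 * jit(), 3),
                             translate = c(0.75, 0, 0.5))
      legs <- lapply(list(c(0.45, 0.3), c(0.45, -0.3), c(-0.45, 0.3), c(-0.45, -0.3)),
                     function(p) part_transform(prim_cylinder(0.16 * jit(), 0.7, 8),
                                                translate = c(p[1], p[2], -0.55)))
      merge_parts(c(list(body, head), legs))
    },
    helmet = function() {
      dome <- part_transform(prim_sphere(8, 14),
                             scale = c(0.85 * jit(), 0.85 * jit(), 0.6 * jit()),
                             translate = c(0, 0, 0.25))
      brim <- part_transform(prim_cylinder(1.05 * jit(), 0.1, 14),
                             translate = c(0, 0, -0.1))
      merge_parts(list(dome, brim))
    },
    mailbox = function() {
      bodyw <- 0.45 * jit()
      box <- part_transform(prim_box(0.8 * jit(), bodyw, 0.35),
                            translate = c(0, 0, 0.55))
      roof <- part_transform(prim_cylinder(bodyw, 1.6 * jit(), 12),
                             rotate = rot_y(pi / 2),
                             translate = c(0, 0, 0.9))
      post <- part_transform(prim_cylinder(0.12 * jit(), 1.6, 8),
                             translate = c(0, 0, -0.6))
      merge_parts(list(box, roof, post))
    },
    bathtub = function() {
      L <- 1.1 * jit(); W <- 0.55 * jit(); H <- 0.45 * jit(); t <- 0.09
      bottom <- part_transform(prim_box(L, W, t), translate = c(0, 0, -H))
      side <- function(sgn) part_transform(prim_box(L, t, H),
                                           translate = c(0, sgn * (W - t), 0))
      end <- function(sgn) part_transform(prim_box(t, W, H),
                                          translate = c(sgn * (L - t), 0, 0))
      merge_parts(list(bottom, side(1), side(-1), end(1), end(-1)))
    },
    mug = function() {
      cup <- part_transform(prim_cylinder(0.55 * jit(), 1.3 * jit(), 14))
      handle <- part_transform(prim_torus(0.38 * jit(), 0.09, 12, 8),
                               rotate = rot_y(pi / 2),
                               translate = c(0.85, 0, 0))
      merge_parts(list(cup, handle))
    },
    phone = function() {
      slab <- prim_box(0.55 * jit(), 1.05 * jit(), 0.07 * jit(0.3))
      bump <- part_transform(prim_box(0.18, 0.22, 0.05),
                             translate = c(-0.25, 0.6, 0.08))
      merge_parts(list(slab, bump))
    }
  )
}

#' Shape-family registry
#'
#' The fixed binding from category id to procedural part family, loaded
#' from the JSON registry shipped with the package so category identity is
#' stable across runs.
#'
#' @return named list of family descriptors (part structure, front axis).
#' @export
shape_registry <- function() {
  path <- system.file("extdata", "shape_families.json", package = "cueconflict3d")
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Generate all models of one shape category
#'
#' Produces `n_models` procedural meshes of the given category. Models
#' within a category share the family's part structure but differ in the
#' shape parameters sampled per model; the whole output is a pure function
#' of `(category_id, n_models, seed)`.
#'
#' @param category_id one of [cc_categories()].
#' @param n_models number of models to generate (>= 1).
#' @param seed integer seed.
#' @return list of mesh objects with `model_id` 0..n_models-1.
#' @export
generate_category_family <- function(category_id, n_models, seed) {
  if (!is.numeric(n_models) || n_models < 1) stop("n_models must be >= 1")
  builders <- shape_family_builders()
  if (!category_id %in% names(builders))
    stop(sprintf("unknown category_id '%s'", category_id))
  cat_ix <- match(category_id, cc_categories())
  lapply(seq_len(n_models) - 1L, function(mid) {
    local_seed(derive_seed(seed, cat_ix, mid), {
      part <- normalize_mesh(builders[[category_id]]())
      m <- new_mesh(part$vertices, part$faces, front_axis = c(1, 0, 0),
                    category_id = category_id, model_id = mid)
      validate_mesh(m)
      m
    })
  })
}

#' Generate the full shape-model set
#'
#' Convenience wrapper generating `n_models` meshes for every category
#' (10 x 10 = 100 at the defaults).
#'
#' @param n_models models per category.
#' @param seed integer seed.
#' @param categories category ids (default all 10).
#' @return flat list of meshes.
#' @export
generate_all_shapes <- function(n_models = 10, seed = 1,
                                categories = cc_categories()) {
  unlist(lapply(categories, generate_category_family,
                n_models = n_models, seed = seed),
         recursive = FALSE)
}

#' Label a viewpoint as canonical or noncanonical
#'
#' A view is canonical when the camera azimuth is within
#' `profile_tolerance` degrees of the object's front direction or of
#' either profile (+/-90 degrees from front); views facing the object's
#' back are noncanonical. This operationalizes "facing toward the viewer
#' or in profile" as a reproducible angular rule. Elevation is accepted
#' for interface completeness but does not enter the rule, which is
#' purely azimuthal.
#'
#' @param azimuth camera azimuth in degrees, in [0, 360).
#' @param elevation camera elevation in degrees (unused by the rule).
#' @param front_axis unit 3-vector giving the model's front direction.
#' @param profile_tolerance half-width in degrees of the canonical bands,
#'   in (0, 45]. The default 31 makes each front/profile direction capture
#'   its adjacent 30-degree orbit neighbors.
#' @return `"canonical"` or `"noncanonical"`.
#' @export
label_canonicality <- function(azimuth, elevation = 0, front_axis = c(1, 0, 0),
                               profile_tolerance = 31) {
  if (abs(vnorm(front_axis) - 1) > 1e-9) stop("front_axis must be a unit vector")
  if (profile_tolerance <= 0 || profile_tolerance > 45)
    stop("profile_tolerance must be in (0, 45]")
  if (any(azimuth < 0 | azimuth >= 360)) stop("azimuth must be in [0, 360)")
  front_az <- atan2(front_axis[2], front_axis[1]) * 180 / pi
  d <- abs(((azimuth - front_az) %% 360 + 360) %% 360)
  d <- ifelse(d > 180, 360 - d, d)  # fold to [0, 180]
  canonical <- d <= profile_tolerance | abs(d - 90) <= profile_tolerance
  ifelse(canonical, "canonical", "noncanonical")
}
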