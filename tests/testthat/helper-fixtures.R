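# Shared fixtures and independent oracles, built in code at test time.

# Small mesh/texture/camera sets, memoized across tests.
.fix <- new.env(parent = emptyenv())

fix_meshes <- function(n_models = 2, seed = 7) {
  key <- paste("m", n_models, seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- generate_all_shapes(n_models, seed = seed)
  .fix[[key]]
}

fix_textures <- function(n_tex = 2, size = 32, seed = 7) {
  key <- paste("t", n_tex, size, seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- generate_all_textures(n_tex, size = size, seed = seed)
  .fix[[key]]
}

fix_cameras <- function(res = 64) orbit_cameras(12, 30, elevation = 15,
                                                distance = 3, resolution = res)

# Lazy manifest over the small fixture set (both conditions).
fix_manifest <- function(n_models = 2, n_tex = 2, res = 64) {
  key <- paste("man", n_models, n_tex, res)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- build_dataset(fix_meshes(n_models), fix_textures(n_tex),
                                 fix_cameras(res), conditions = c("3D", "2D"))
  .fix[[key]]
}

# Reproducible row sampling without touching the session RNG stream.
local_seed_sample <- function(n, k, seed) {
  withr::with_seed(seed, sample(n, k, replace = k > n))
}

# Constant-color texture for closed-form retexture checks.
const_texture <- function(rgb, size = 64) {
  px <- array(0, c(size, size, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  structure(list(pixels = px, category_id = "probe", texture_id = 0L,
                 tileable = TRUE), class = "cc_texture")
}

# Independent scalar ray-triangle oracle (straightforward Moller-Trumbore,
# one ray and one triangle at a time), used to cross-check the renderer's
# vectorized shadow test.
oracle_ray_hits_triangle <- function(orig, dir, v0, v1, v2, t_min = 1e-4) {
  e1 <- v1 - v0; e2 <- v2 - v0
  h <- c(dir[2] * e2[3] - dir[3] * e2[2],
         dir[3] * e2[1] - dir[1] * e2[3],
         dir[1] * e2[2] - dir[2] * e2[1])
  a <- sum(e1 * h)
  if (abs(a) < 1e-12) return(FALSE)
  s <- orig - v0
  u <- sum(s * h) / a
  if (u < -1e-9 || u > 1 + 1e-9) return(FALSE)
  q <- c(s[2] * e1[3] - s[3] * e1[2],
         s[3] * e1[1] - s[1] * e1[3],
         s[1] * e1[2] - s[2] * e1[1])
  v <- sum(dir * q) / a
  if (v < -1e-9 || u + v > 1 + 1e-9) return(FALSE)
  t <- sum(e2 * q) / a
  t > t_min
}

oracle_ray_occluded <- function(orig, dir, mesh) {
  f <- mesh$faces; v <- mesh$vertices
  for (t in seq_len(nrow(f))) {
    if (oracle_ray_hits_triangle(orig, dir, v[f[t, 1], ], v[f[t, 2], ],
                                 v[f[t, 3], ])) return(TRUE)
  }
  FALSE
}

# L-shaped two-block mesh: a standing slab next to a lying slab, so an
# oblique light casts part of the standing block's shadow onto the other.
l_shape_mesh <- function() {
  a <- cueconflict3d:::prim_box(0.9, 0.9, 0.12)
  a <- cueconflict3d:::part_transform(a, translate = c(0, 0, -0.5))
  b <- cueconflict3d:::prim_box(0.12, 0.9, 0.6)
  b <- cueconflict3d:::part_transform(b, translate = c(-0.7, 0, 0.15))
  p <- cueconflict3d:::normalize_mesh(cueconflict3d:::merge_parts(list(a, b)))
  cueconflict3d:::new_mesh(p$vertices, p$faces, category_id = "probe",
                           model_id = 0L)
}

unit_sphere_mesh <- function(n_lat = 24, n_lon = 32) {
  sp <- cueconflict3d:::prim_sphere(n_lat, n_lon)
  cueconflict3d:::new_mesh(sp$vertices, sp$faces, category_id = "probe",
                           model_id = 0L)
}

# Brute-force within-subject sums-of-squares oracle computed from the
# textbook cell-mean formulas, independent of rm_anova_2x2's internals.
oracle_rm_anova <- function(data) {
  la <- sort(unique(data$A)); lb <- sort(unique(data$B))
  subj <- sort(unique(data$subject)); S <- length(subj)
  y <- function(s, a, b) data$value[data$subject == s & data$A == a & data$B == b]
  gm <- mean(data$value)
  SSa <- 0; SSb <- 0; SSab <- 0; SSas <- 0; SSbs <- 0; SSabs <- 0
  ma <- unname(sapply(la, function(a) mean(data$value[data$A == a])))
  mb <- unname(sapply(lb, function(b) mean(data$value[data$B == b])))
  ms <- unname(sapply(subj, function(s) mean(data$value[data$subject == s])))
  for (a in 1:2) SSa <- SSa + 2 * S * (ma[a] - gm)^2
  for (b in 1:2) SSb <- SSb + 2 * S * (mb[b] - gm)^2
  for (a in 1:2) for (b in 1:2) {
    mab <- mean(data$value[data$A == la[a] & data$B == lb[b]])
    SSab <- SSab + S * (mab - ma[a] - mb[b] + gm)^2
  }
  for (s in 1:S) for (a in 1:2) {
    msa <- mean(data$value[data$subject == subj[s] & data$A == la[a]])
    SSas <- SSas + 2 * (msa - ms[s] - ma[a] + gm)^2
  }
  for (s in 1:S) for (b in 1:2) {
    msb <- mean(data$value[data$subject == subj[s] & data$B == lb[b]])
    SSbs <- SSbs + 2 * (msb - ms[s] - mb[b] + gm)^2
  }
  for (s in 1:S) for (a in 1:2) for (b in 1:2) {
    msa <- mean(data$value[data$subject == subj[s] & data$A == la[a]])
    msb <- mean(data$value[data$subject == subj[s] & data$B == lb[b]])
    mab <- mean(data$value[data$A == la[a] & data$B == lb[b]])
    SSabs <- SSabs + (y(subj[s], la[a], lb[b]) - msa - msb - mab +
                        ms[s] + ma[a] + mb[b] - gm)^2
  }
  list(F_A = (SSa / 1) / (SSas / (S - 1)),
       F_B = (SSb / 1) / (SSbs / (S - 1)),
       F_AB = (SSab / 1) / (SSabs / (S - 1)),
       SS = c(A = SSa, B = SSb, AB = SSab, AS = SSas, BS = SSbs, ABS = SSabs))
}

# Scripted model whose validation error follows a prescribed sequence,
# for exercising the early-stopping loop end to end.
scripted_model <- function(val_errors) {
  structure(list(errors = val_errors, epoch = 0L), class = "scripted_model")
}
model_predict.scripted_model <- function(model, X) {
  # "validation" sets are tagged with attr 'scripted_n_wrong' by the test;
  # here we emit predictions wrong for the first k rows per current epoch
  n <- nrow(X)
  err <- model$errors[min(model$epoch, length(model$errors))]
  k <- round(err * n)
  P <- matrix(0, n, 2)
  truth <- attr(X, "truth")
  wrong <- 3 - truth
  pick <- ifelse(seq_len(n) <= k, wrong, truth)
  P[cbind(seq_len(n), pick)] <- 1
  P
}
model_update.scripted_model <- function(model, X, y, lr, freeze = "all_unfrozen") {
  model$epoch <- model$epoch + 1L
  model
}
model_supports_freeze.scripted_model <- function(model) TRUE

registerS3method("model_predict", "scripted_model", model_predict.scripted_model,
                 envir = asNamespace("cueconflict3d"))
registerS3method("model_update", "scripted_model", model_update.scripted_model,
                 envir = asNamespace("cueconflict3d"))
registerS3method("model_supports_freeze", "scripted_model",
                 model_supports_freeze.scripted_model,
                 envir = asNamespace("cueconflict3d"))
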