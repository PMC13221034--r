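# Finetuning protocol: four curricula crossing an image filter
# (all viewpoints vs canonical-only) with a freeze policy (all weights
# vs decision head only), an 80/20 stratified train/validation split,
# epoch-level early stopping that adopts the minimum-validation-error
# checkpoint, and the post-training 2x2 generalization table. The
# trainable model is pluggable through three generics; the package ships
# a small two-stage reference classifier (random-feature hidden layer +
# softmax decision head) exercising the identical curriculum logic.

curriculum_table <- function() {
  data.frame(
    id = 1:4,
    image_filter = c("all_views", "all_views", "canonical_only", "canonical_only"),
    freeze_policy = c("all_unfrozen", "head_only", "all_unfrozen", "head_only"),
    learning_rate = c(2e-5, 1e-3, 2e-5, 1e-3),
    stringsAsFactors = FALSE)
}

#' Build a finetuning curriculum and its train/validation split
#'
#' Training is restricted to the 3D condition. The image filter
#' (curricula 3 and 4 keep canonical viewpoints only) is applied before
#' splitting; the split holds out 20% for validation, stratified by
#' shape category, and is deterministic under the seed. Learning rate is
#' 2e-5 for the all-unfrozen curricula (1 and 3) and 1e-3 for the
#' head-only curricula (2 and 4); batch size 96.
#'
#' @param id curriculum id 1-4.
#' @param manifest a `stim_manifest` with 3D records.
#' @param seed integer seed.
#' @param batch_size training batch size.
#' @param train_fraction fraction of the filtered set used for training.
#' @return list with `curriculum` (id, image_filter, freeze_policy,
#'   learning_rate, batch_size, train_fraction, condition, seed),
#'   `train` and `validation` (disjoint manifest subsets whose union is
#'   the filtered set).
#' @export
make_curriculum <- function(id, manifest, seed = 1, batch_size = 96,
                            train_fraction = 0.8) {
  tab <- curriculum_table()
  if (!id %in% tab$id) stop("curriculum id must be 1, 2, 3 or 4")
  row <- tab[tab$id == id, ]
  pool <- manifest[manifest$condition == "3D", , drop = FALSE]
  if (!nrow(pool)) stop("manifest has no 3D records")
  if (row$image_filter == "canonical_only") {
    pool <- pool[pool$canonicality == "canonical", , drop = FALSE]
    if (!nrow(pool)) stop("manifest has no canonical 3D records")
  }
  # the split depends only on (filtered pool, seed), not the curriculum id,
  # so curricula sharing a filter and seed train on identical data
  local_seed(derive_seed(seed, nrow(pool), 11L), {
    train_ix <- unlist(lapply(split(seq_len(nrow(pool)), pool$shape_category),
                              function(ix) sample(ix, round(train_fraction * length(ix)))),
                       use.names = FALSE)
  })
  train <- pool[sort(train_ix), , drop = FALSE]
  validation <- pool[setdiff(seq_len(nrow(pool)), train_ix), , drop = FALSE]
  list(curriculum = list(id = id, image_filter = row$image_filter,
                         freeze_policy = row$freeze_policy,
                         learning_rate = row$learning_rate,
                         batch_size = batch_size,
                         train_fraction = train_fraction,
                         condition = "3D", seed = as.integer(seed)),
       train = train, validation = validation)
}

# ---- pluggable model contract ----------------------------------------------

#' Model generics for the finetuning protocol
#'
#' Any trainable classifier can be plugged into
#' [train_with_early_stop()] by implementing three generics:
#' `model_predict(model, X)` returning an n x K probability matrix,
#' `model_update(model, X, y, lr, freeze)` returning the updated model
#' after one gradient step on a batch (honoring `freeze = "head_only"`
#' by updating only the final decision layer), and
#' `model_supports_freeze(model)` saying whether a head-only policy is
#' available.
#'
#' @param model a model object.
#' @param X feature matrix (rows = examples).
#' @param y integer class labels in 1..K.
#' @param lr learning rate.
#' @param freeze `"all_unfrozen"` or `"head_only"`.
#' @name model-contract
NULL

#' @rdname model-contract
#' @export
model_predict <- function(model, X) UseMethod("model_predict")

#' @rdname model-contract
#' @export
model_update <- function(model, X, y, lr, freeze = "all_unfrozen")
  UseMethod("model_update")

#' @rdname model-contract
#' @export
model_supports_freeze <- function(model) UseMethod("model_supports_freeze")

#' @export
model_supports_freeze.default <- function(model) FALSE

# ---- reference classifier ---------------------------------------------------

#' Small trainable reference classifier
#'
#' A two-stage network: a tanh hidden layer (the "backbone") followed by
#' a softmax decision head, trained by plain gradient descent on the
#' cross-entropy loss. Under the head-only freeze policy the backbone
#' parameters are left bit-identical. It stands in for a large
#' pretrained network so the curriculum, early-stopping and freezing
#' logic can be exercised at desk scale; a real network can be plugged
#' in through the model generics.
#'
#' @param input_dim feature dimension.
#' @param n_classes number of classes.
#' @param hidden_dim hidden width.
#' @param seed seed for the weight initialization.
#' @return a `ref_classifier`.
#' @export
ref_classifier <- function(input_dim, n_classes, hidden_dim = 32, seed = 1) {
  local_seed(derive_seed(seed, input_dim, 13L), {
    structure(list(
      W1 = matrix(stats::rnorm(input_dim * hidden_dim, sd = 1 / sqrt(input_dim)),
                  input_dim, hidden_dim),
      b1 = rep(0, hidden_dim),
      W2 = matrix(stats::rnorm(hidden_dim * n_classes, sd = 1 / sqrt(hidden_dim)),
                  hidden_dim, n_classes),
      b2 = rep(0, n_classes),
      n_classes = n_classes),
      class = "ref_classifier")
  })
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' @export
model_predict.ref_classifier <- function(model, X) {
  H <- tanh(sweep(X %*% model$W1, 2, model$b1, `+`))
  softmax_rows(sweep(H %*% model$W2, 2, model$b2, `+`))
}

#' @export
model_update.ref_classifier <- function(model, X, y, lr, freeze = "all_unfrozen") {
  n <- nrow(X)
  A1 <- sweep(X %*% model$W1, 2, model$b1, `+`)
  H <- tanh(A1)
  P <- softmax_rows(sweep(H %*% model$W2, 2, model$b2, `+`))
  T <- matrix(0, n, model$n_classes)
  T[cbind(seq_len(n), y)] <- 1
  dZ2 <- (P - T) / n
  model$W2 <- model$W2 - lr * crossprod(H, dZ2)
  model$b2 <- model$b2 - lr * colSums(dZ2)
  if (freeze != "head_only") {
    dH <- dZ2 %*% t(model$W2)
    dA1 <- dH * (1 - H^2)
    model$W1 <- model$W1 - lr * crossprod(X, dA1)
    model$b1 <- model$b1 - lr * colSums(dA1)
  }
  model
}

#' @export
model_supports_freeze.ref_classifier <- function(model) TRUE

# ---- training loop ----------------------------------------------------------

classification_error <- function(model, X, y) {
  P <- model_predict(model, X)
  mean(max.col(P, ties.method = "first") != y)
}

#' Train with epoch-level early stopping
#'
#' Runs full passes over the training set in shuffled batches (batch
#' order reshuffled each epoch from the run seed; the last partial batch
#' is kept), evaluating the validation error rate once per epoch.
#' Training stops at the first epoch whose validation error exceeds the
#' previous epoch's (or at `max_epochs`), and the adopted model is the
#' checkpoint with the minimum validation error.
#'
#' @param model a model implementing the model generics.
#' @param curriculum result of [make_curriculum()] (or a bare curriculum
#'   list) providing learning rate, batch size, freeze policy and seed.
#' @param train_xy list(X, y) training features/labels.
#' @param val_xy list(X, y) validation features/labels.
#' @param max_epochs maximum number of epochs.
#' @param on_batch optional callback, called with the row indices of
#'   every training batch (used e.g. to audit curriculum purity).
#' @return list with `model` (adopted checkpoint) and `log` (a
#'   `train_log`: per-epoch train/validation error, `stopped_epoch`,
#'   `adopted_epoch`).
#' @export
train_with_early_stop <- function(model, curriculum, train_xy, val_xy,
                                  max_epochs = 20, on_batch = NULL) {
  cur <- curriculum$curriculum %||% curriculum
  if (cur$freeze_policy == "head_only" && !model_supports_freeze(model))
    stop("model does not support the head_only freeze policy")
  n <- nrow(train_xy$X)
  bs <- cur$batch_size
  errs <- data.frame(epoch = integer(), train_error = numeric(),
                     val_error = numeric())
  best <- NULL; best_err <- Inf; best_epoch <- NA_integer_
  epoch <- 0L
  repeat {
    epoch <- epoch + 1L
    ord <- local_seed(derive_seed(cur$seed, epoch, 19L), sample(n))
    starts <- seq(1, n, by = bs)
    for (s in starts) {
      ix <- ord[s:min(s + bs - 1, n)]
      if (!is.null(on_batch)) on_batch(ix)
      model <- model_update(model, train_xy$X[ix, , drop = FALSE],
                            train_xy$y[ix], cur$learning_rate,
                            cur$freeze_policy)
    }
    tr_err <- classification_error(model, train_xy$X, train_xy$y)
    va_err <- classification_error(model, val_xy$X, val_xy$y)
    errs <- rbind(errs, data.frame(epoch = epoch, train_error = tr_err,
                                   val_error = va_err))
    if (va_err < best_err) { best <- model; best_err <- va_err; best_epoch <- epoch }
    if (epoch >= max_epochs) break
    if (epoch >= 2 && va_err > errs$val_error[epoch - 1]) break
  }
  log <- structure(list(epochs = errs, stopped_epoch = epoch,
                        adopted_epoch = best_epoch),
                   class = "train_log")
  list(model = best, log = log)
}

#' Apply the early-stopping rule to a scripted error sequence
#'
#' The pure decision rule, separated so it can be checked against known
#' sequences: stop at the first validation-error increase (or the end),
#' adopt the epoch with the minimum error among those run.
#'
#' @param val_errors numeric vector of per-epoch validation errors.
#' @return list with `stopped_epoch`, `adopted_epoch`.
#' @export
early_stop_rule <- function(val_errors) {
  stopped <- length(val_errors)
  for (e in seq_along(val_errors)) {
    if (e >= 2 && val_errors[e] > val_errors[e - 1]) { stopped <- e; break }
  }
  run <- val_errors[seq_len(stopped)]
  list(stopped_epoch = stopped, adopted_epoch = which.min(run))
}

#' Post-training 2x2 generalization table
#'
#' Classification accuracy per (condition x canonicality) cell over a
#' full manifest, rows ordered {3D, 2D} and columns
#' {canonical, noncanonical}, plus the canonicality gap
#' (canonical minus noncanonical accuracy) per condition -- the
#' humanlike signature is a larger gap for 2D than for 3D images.
#'
#' @param model a trained model.
#' @param manifest a `stim_manifest` with all four cells.
#' @param featurize function(manifest rows) -> list(X, y) mapping
#'   records to features and true shape-category labels.
#' @return list with `accuracy` (2x2 matrix), `gap` (named length-2
#'   vector), `n` (per-cell counts).
#' @export
evaluate_generalization <- function(model, manifest, featurize) {
  conds <- c("3D", "2D"); canons <- c("canonical", "noncanonical")
  acc <- matrix(NA_real_, 2, 2, dimnames = list(conds, canons))
  nn <- matrix(0L, 2, 2, dimnames = list(conds, canons))
  for (cd in conds) for (cn in canons) {
    sub <- manifest[manifest$condition == cd & manifest$canonicality == cn, ,
                    drop = FALSE]
    nn[cd, cn] <- nrow(sub)
    if (!nrow(sub)) next
    xy <- featurize(sub)
    acc[cd, cn] <- 1 - classification_error(model, xy$X, xy$y)
  }
  gap <- acc[, "canonical"] - acc[, "noncanonical"]
  list(accuracy = acc, gap = gap, n = nn)
}

#' Featurizer for rendered stimuli
#'
#' Maps manifest records to feature vectors by rendering (or re-reading)
#' each stimulus and average-pooling the RGB image onto a coarse grid.
#' Used to train and evaluate the reference classifier on the package's
#' own stimuli. Rendering is cached per (shape, viewpoint, condition).
#'
#' @param meshes,textures,cameras the generators' outputs used to build
#'   the manifest.
#' @param pool output grid side; features are pool x pool x 3.
#' @param light_fn function(camera) -> light.
#' @return function(manifest rows) -> list(X, y) with `y` the shape
#'   category index in [cc_categories()].
#' @export
make_render_featurizer <- function(meshes, textures, cameras, pool = 8,
                                   light_fn = default_light) {
  mesh_key <- vapply(meshes, function(m) paste(m$category_id, m$model_id), "")
  tex_key <- vapply(textures, function(t) paste(t$category_id, t$texture_id), "")
  cache <- new.env(parent = emptyenv())
  pool_img <- function(img) {
    res <- dim(img)[1]
    f <- res %/% pool
    v <- numeric(0)
    for (ch in 1:3) {
      m <- img[seq_len(f * pool), seq_len(f * pool), ch]
      dim(m) <- c(f, pool, f, pool)
      v <- c(v, as.vector(apply(m, c(2, 4), mean)))
    }
    v
  }
  function(records) {
    X <- matrix(NA_real_, nrow(records), pool * pool * 3)
    for (r in seq_len(nrow(records))) {
      mk <- paste(records$shape_category[r], records$shape_model_id[r])
      m <- match(mk, mesh_key)
      v <- records$viewpoint_index[r] + 1L
      key <- paste(mk, v)
      sr <- cache[[key]]
      if (is.null(sr)) {
        cam <- cameras[[v]]
        sr <- render_shaded(meshes[[m]], cam, light_fn(cam))
        cache[[key]] <- sr
      }
      tx <- textures[[match(paste(records$texture_category[r],
                                  records$texture_id[r]), tex_key)]]
      img <- if (records$condition[r] == "3D") retexture_3d(sr, tx)
             else retexture_2d(sr$mask, tx)
      X[r, ] <- pool_img(img)
    }
    list(X = X, y = match(records$shape_category, cc_categories()))
  }
}
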