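test_that("curricula filter and split the manifest as specified", {
  man <- fix_manifest(3, 3)
  # id 3: canonical 3D only, 80/20 partition stratified by shape category
  c3 <- make_curriculum(3, man, seed = 5)
  pool_n <- sum(man$condition == "3D" & man$canonicality == "canonical")
  expect_equal(nrow(c3$train) + nrow(c3$validation), pool_n)
  expect_equal(nrow(c3$train), round(0.8 * pool_n), tolerance = 2)
  expect_true(all(c3$train$condition == "3D"))
  expect_true(all(c3$train$canonicality == "canonical"))
  expect_true(all(c3$validation$canonicality == "canonical"))
  expect_length(intersect(c3$train$stimulus_id, c3$validation$stimulus_id), 0)
  expect_setequal(c(c3$train$stimulus_id, c3$validation$stimulus_id),
                  man$stimulus_id[man$condition == "3D" &
                                  man$canonicality == "canonical"])
  # id 1 vs id 2: same filter and seed give the same split, different policy
  c1 <- make_curriculum(1, man, seed = 5)
  c2 <- make_curriculum(2, man, seed = 5)
  expect_equal(c1$curriculum$freeze_policy, "all_unfrozen")
  expect_equal(c2$curriculum$freeze_policy, "head_only")
  expect_equal(c1$curriculum$learning_rate, 2e-5)
  expect_equal(c2$curriculum$learning_rate, 1e-3)
  expect_equal(make_curriculum(4, man, seed = 5)$curriculum$learning_rate, 1e-3)
  expect_error(make_curriculum(7, man), "id must be")
  expect_error(make_curriculum(1, man[man$condition == "2D", ]), "no 3D")
})

test_that("curriculum 1 and 2 share the data split given the same seed", {
  man <- fix_manifest(3, 3)
  c1 <- make_curriculum(1, man, seed = 5)
  c2 <- make_curriculum(2, man, seed = 5)
  expect_identical(c1$train$stimulus_id, c2$train$stimulus_id)
  expect_identical(c1$validation$stimulus_id, c2$validation$stimulus_id)
})

test_that("early stopping adopts the minimum-validation checkpoint", {
  expect_equal(early_stop_rule(c(0.30, 0.20, 0.25)),
               list(stopped_epoch = 3L, adopted_epoch = 2L))
  expect_equal(early_stop_rule(c(0.5, 0.4, 0.3, 0.2)),
               list(stopped_epoch = 4L, adopted_epoch = 4L))
  expect_equal(early_stop_rule(c(0.2)), list(stopped_epoch = 1L, adopted_epoch = 1L))

  # end-to-end through the training loop with a scripted model
  mk_xy <- function(n) {
    X <- matrix(0, n, 2)
    attr(X, "truth") <- rep(1:2, length.out = n)
    list(X = X, y = rep(1:2, length.out = n))
  }
  cur <- list(curriculum = list(id = 1, image_filter = "all_views",
                                freeze_policy = "all_unfrozen",
                                learning_rate = 0.1, batch_size = 50,
                                train_fraction = 0.8, condition = "3D", seed = 1))
  res <- train_with_early_stop(scripted_model(c(0.30, 0.20, 0.25)), cur,
                               mk_xy(20), mk_xy(20), max_epochs = 10)
  expect_equal(res$log$stopped_epoch, 3L)
  expect_equal(res$log$adopted_epoch, 2L)
  expect_equal(res$log$epochs$val_error, c(0.30, 0.20, 0.25))
  expect_equal(min(res$log$epochs$val_error),
               res$log$epochs$val_error[res$log$adopted_epoch])

  # monotonically decreasing: runs to max_epochs, adopts the last epoch
  res2 <- train_with_early_stop(scripted_model(seq(0.5, 0.05, length.out = 10)),
                                cur, mk_xy(20), mk_xy(20), max_epochs = 6)
  expect_equal(res2$log$stopped_epoch, 6L)
  expect_equal(res2$log$adopted_epoch, 6L)
})

test_that("head-only freezing leaves backbone parameters bit-identical", {
  set.seed(1)
  X <- matrix(rnorm(200 * 12), 200, 12)
  y <- sample(1:4, 200, replace = TRUE)
  model <- ref_classifier(12, 4, hidden_dim = 8, seed = 3)
  cur <- list(curriculum = list(id = 2, image_filter = "all_views",
                                freeze_policy = "head_only",
                                learning_rate = 0.5, batch_size = 32,
                                train_fraction = 0.8, condition = "3D", seed = 2))
  res <- train_with_early_stop(model, cur, list(X = X, y = y),
                               list(X = X, y = y), max_epochs = 3)
  expect_identical(res$model$W1, model$W1)
  expect_identical(res$model$b1, model$b1)
  expect_false(identical(res$model$W2, model$W2))
  # unfrozen policy moves the backbone
  cur$curriculum$freeze_policy <- "all_unfrozen"
  res2 <- train_with_early_stop(model, cur, list(X = X, y = y),
                                list(X = X, y = y), max_epochs = 3)
  expect_false(identical(res2$model$W1, model$W1))
  # capability error for models without freeze support
  nofreeze <- structure(list(), class = "nofreeze_model")
  cur$curriculum$freeze_policy <- "head_only"
  expect_error(train_with_early_stop(nofreeze, cur, list(X = X, y = y),
                                     list(X = X, y = y)), "head_only")
})

test_that("canonical-only curricula never train on noncanonical or 2D records", {
  man <- fix_manifest(3, 3)
  c3 <- make_curriculum(3, man, seed = 5, batch_size = 16)
  feat <- withr::with_seed(8, matrix(rnorm(nrow(c3$train) * 6), ncol = 6))
  xy <- list(X = feat, y = match(c3$train$shape_category, cc_categories()))
  vxy <- list(X = feat[1:20, ], y = xy$y[1:20])
  seen <- integer(0)
  model <- ref_classifier(6, 10, hidden_dim = 8, seed = 1)
  train_with_early_stop(model, c3, xy, vxy, max_epochs = 2,
                        on_batch = function(ix) seen <<- union(seen, ix))
  batch_records <- c3$train[seen, ]
  expect_true(all(batch_records$condition == "3D"))
  expect_true(all(batch_records$canonicality == "canonical"))
  # every training row is visited within an epoch
  expect_setequal(seen, seq_len(nrow(c3$train)))
})

test_that("the reference model learns a separable 10-class problem", {
  # 10 well-separated Gaussian clusters in feature space
  mk <- function(n_per, seed) {
    withr::with_seed(seed, {
      centers <- matrix(rnorm(10 * 16, sd = 3), 10, 16)
      X <- do.call(rbind, lapply(1:10, function(k)
        matrix(rnorm(n_per * 16, mean = 0, sd = 0.4), n_per, 16) +
          matrix(centers[k, ], n_per, 16, byrow = TRUE)))
      list(X = X, y = rep(1:10, each = n_per))
    })
  }
  train <- mk(40, 31); val <- mk(10, 31)  # same centers, fresh draws
  val$X <- val$X + withr::with_seed(32, matrix(rnorm(length(val$X), sd = 0.05),
                                               nrow(val$X)))
  model <- ref_classifier(16, 10, hidden_dim = 32, seed = 2)
  cur <- list(curriculum = list(id = 1, image_filter = "all_views",
                                freeze_policy = "all_unfrozen",
                                learning_rate = 0.5, batch_size = 96,
                                train_fraction = 0.8, condition = "3D", seed = 3))
  res <- train_with_early_stop(model, cur, train, val, max_epochs = 5)
  expect_gt(1 - min(res$log$epochs$val_error), 0.95)
})

test_that("training is deterministic under seed and logs are consistent", {
  X <- withr::with_seed(4, matrix(rnorm(300 * 8), 300, 8))
  y <- rep(1:3, each = 100)
  cur <- function(seed) list(curriculum = list(
    id = 1, image_filter = "all_views", freeze_policy = "all_unfrozen",
    learning_rate = 0.2, batch_size = 64, train_fraction = 0.8,
    condition = "3D", seed = seed))
  r1 <- train_with_early_stop(ref_classifier(8, 3, seed = 9), cur(5),
                              list(X = X, y = y), list(X = X, y = y), 4)
  r2 <- train_with_early_stop(ref_classifier(8, 3, seed = 9), cur(5),
                              list(X = X, y = y), list(X = X, y = y), 4)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$model, r2$model)
  expect_lte(r1$log$adopted_epoch, r1$log$stopped_epoch)
})

test_that("generalization tables cover the 2x2 design with fixed ordering", {
  man <- fix_manifest(2, 2)
  # stand-in oracle model: features are one-hot true labels
  oracle <- structure(list(), class = "onehot_oracle")
  registerS3method("model_predict", "onehot_oracle",
                   function(model, X) X,
                   envir = asNamespace("cueconflict3d"))
  featurize <- function(records) {
    y <- match(records$shape_category, cc_categories())
    X <- matrix(0, nrow(records), 10)
    X[cbind(seq_along(y), y)] <- 1
    list(X = X, y = y)
  }
  res <- evaluate_generalization(oracle, man, featurize)
  expect_equal(rownames(res$accuracy), c("3D", "2D"))
  expect_equal(colnames(res$accuracy), c("canonical", "noncanonical"))
  expect_true(all(res$accuracy == 1))
  expect_equal(unname(res$gap), c(0, 0))
})

test_that("unfreezing helps generalization to 2D noncanonical stimuli", {
  man <- fix_manifest(2, 2)
  meshes <- fix_meshes(2); textures <- fix_textures(2, 32); cams <- fix_cameras(64)
  featurize <- make_render_featurizer(meshes, textures, cams, pool = 6)
  c3 <- make_curriculum(3, man, seed = 2, batch_size = 96)
  # subsample the split for speed; evaluation covers all four cells
  tr <- c3$train[local_seed_sample(nrow(c3$train), 400, seed = 1), ]
  va <- c3$validation[local_seed_sample(nrow(c3$validation), 120, seed = 2), ]
  xy_tr <- featurize(tr)
  xy_va <- featurize(va)
  eval_sub <- man[local_seed_sample(nrow(man), 600, seed = 3), ]
  run <- function(policy, lr) {
    cur <- c3
    cur$curriculum$freeze_policy <- policy
    cur$curriculum$learning_rate <- lr
    # a narrow random backbone is a genuine bottleneck: reweighting its
    # frozen features cannot separate 10 classes, so feature learning must help
    m0 <- ref_classifier(ncol(xy_tr$X), 10, hidden_dim = 8, seed = 4)
    train_with_early_stop(m0, cur, xy_tr, xy_va, max_epochs = 8)$model
  }
  frozen <- run("head_only", 1)
  unfrozen <- run("all_unfrozen", 1)
  gf <- evaluate_generalization(frozen, eval_sub, featurize)
  gu <- evaluate_generalization(unfrozen, eval_sub, featurize)
  expect_gte(gu$accuracy["2D", "noncanonical"], gf$accuracy["2D", "noncanonical"])
})
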