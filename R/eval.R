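# Classifier evaluation: entry-level softmax aggregation, cue-conflict
# scoring, and the texture-bias statistic. A classifier here is anything
# that yields one probability vector over a label vocabulary per
# stimulus; fine-grained output labels (ImageNet-style subcategories) are
# summed into the ten entry-level categories before the decision.

#' Load a subcategory-to-entry-level label map
#'
#' The default is the mapping from ImageNet-style subcategory labels to
#' the ten entry-level categories shipped with the package (e.g. Indian
#' and African elephant both map to "elephant").
#'
#' @param path two-column CSV (`subcategory_label`, `entry_category`);
#'   default the shipped fixture.
#' @return a `label_map` data.frame.
#' @export
load_label_map <- function(path = system.file("extdata", "imagenet_entry_map.csv",
                                              package = "cueconflict3d")) {
  lm <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_label_map(lm)
  class(lm) <- c("label_map", "data.frame")
  lm
}

validate_label_map <- function(lm) {
  if (!all(c("subcategory_label", "entry_category") %in% names(lm)))
    stop("label map needs columns subcategory_label, entry_category")
  if (anyDuplicated(lm$subcategory_label))
    stop("each output label may map to at most one entry-level category")
  if (any(!cc_categories() %in% lm$entry_category))
    stop("every entry-level category needs at least one mapped label")
  invisible(TRUE)
}

#' Aggregate classifier output to entry-level scores
#'
#' Sums the probability mass of every output label mapped to each
#' entry-level category; the decision is the category with the highest
#' summed probability. Ties are broken lexicographically (and flagged);
#' if no probability mass falls on mapped labels the decision is
#' `"none"`.
#'
#' @param probabilities named nonnegative vector over the classifier's
#'   label vocabulary, summing to 1 (tolerance 1e-6).
#' @param label_map a `label_map`.
#' @return list with `scores` (named vector over the 10 categories),
#'   `decision`, and `tie` flag.
#' @export
aggregate_entry_level <- function(probabilities, label_map) {
  if (is.null(names(probabilities))) stop("probabilities must be named by label")
  if (any(probabilities < -1e-12)) stop("probabilities must be nonnegative")
  if (abs(sum(probabilities) - 1) > 1e-6) stop("probabilities must sum to 1")
  cats <- cc_categories()
  ix <- match(names(probabilities), label_map$subcategory_label)
  mapped <- !is.na(ix)
  scores <- stats::setNames(numeric(length(cats)), cats)
  if (any(mapped)) {
    s <- rowsum(probabilities[mapped], label_map$entry_category[ix[mapped]])
    scores[rownames(s)] <- s[, 1]
  }
  if (all(scores == 0)) return(list(scores = scores, decision = "none", tie = FALSE))
  top <- which(scores == max(scores))
  list(scores = scores, decision = cats[top[1]], tie = length(top) > 1)
}

# Matrix version: rows = stimuli, columns = vocabulary labels.
aggregate_entry_level_matrix <- function(prob_matrix, label_map) {
  cats <- cc_categories()
  ix <- match(colnames(prob_matrix), label_map$subcategory_label)
  mapped <- which(!is.na(ix))
  scores <- matrix(0, nrow(prob_matrix), length(cats),
                   dimnames = list(NULL, cats))
  for (j in mapped) {
    cat_j <- label_map$entry_category[ix[j]]
    scores[, cat_j] <- scores[, cat_j] + prob_matrix[, j]
  }
  decision <- cats[max.col(scores, ties.method = "first")]
  decision[rowSums(scores) == 0] <- "none"
  list(scores = scores, decision = decision)
}

#' Score cue-conflict outcomes
#'
#' An entry-level decision counts as `shape_correct` when it matches the
#' stimulus's shape category, `texture_correct` when it matches the
#' texture category, and `other` otherwise. On incongruent stimuli the
#' first two are mutually exclusive. Congruent records (shape category ==
#' texture category) are dropped by default since shape- and
#' texture-correct coincide there.
#'
#' @param decisions character vector of entry-level decisions, one per
#'   manifest record.
#' @param manifest a `stim_manifest`.
#' @param exclude_congruent drop congruent records (default TRUE).
#' @return data.frame of outcome records (`stimulus_id`, `decision`,
#'   `outcome`) joined with the manifest's condition/canonicality fields.
#' @export
score_cue_conflict <- function(decisions, manifest, exclude_congruent = TRUE) {
  if (length(decisions) != nrow(manifest))
    stop("need exactly one decision per manifest record")
  out <- data.frame(
    stimulus_id = manifest$stimulus_id,
    decision = decisions,
    outcome = ifelse(decisions == manifest$shape_category, "shape_correct",
              ifelse(decisions == manifest$texture_category, "texture_correct",
                     "other")),
    condition = manifest$condition,
    canonicality = manifest$canonicality,
    shape_category = manifest$shape_category,
    texture_category = manifest$texture_category,
    viewpoint_index = manifest$viewpoint_index,
    congruent = manifest$congruent,
    stringsAsFactors = FALSE)
  if (exclude_congruent) out <- out[!out$congruent, , drop = FALSE]
  out
}

#' Compute shape/texture bias from outcomes
#'
#' Texture bias is the proportion of correct texture classifications
#' among all cue-correct (shape or texture) classifications:
#' `texture / (texture + shape)`; shape bias is its complement. Values
#' above 0.5 indicate texture bias. Both are `NA` when no classification
#' followed either cue. The statistic is invariant to the number of
#' `other` outcomes.
#'
#' @param outcomes outcome records from [score_cue_conflict()], or any
#'   data.frame with an `outcome` column.
#' @return a `bias_summary` list: counts, `texture_bias`, `shape_bias`,
#'   `shape_accuracy`, `texture_accuracy`.
#' @export
compute_bias <- function(outcomes) {
  if (!nrow(outcomes)) stop("outcomes must be nonempty")
  n_shape <- sum(outcomes$outcome == "shape_correct")
  n_tex <- sum(outcomes$outcome == "texture_correct")
  n_other <- sum(outcomes$outcome == "other")
  denom <- n_shape + n_tex
  tb <- if (denom > 0) n_tex / denom else NA_real_
  structure(list(
    n_shape_correct = n_shape, n_texture_correct = n_tex, n_other = n_other,
    texture_bias = tb, shape_bias = if (is.na(tb)) NA_real_ else 1 - tb,
    shape_accuracy = n_shape / nrow(outcomes),
    texture_accuracy = n_tex / nrow(outcomes)),
    class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf(paste0("<bias_summary> shape %d / texture %d / other %d\n",
                     "  texture bias %s%%, shape bias %s%%\n"),
              x$n_shape_correct, x$n_texture_correct, x$n_other,
              format_percent(x$texture_bias), format_percent(x$shape_bias)))
  invisible(x)
}

#' Format a proportion as an integer percent
#'
#' Rounds half away from zero, the convention used for printed
#' percentages (0.435 -> "44" at the default 0 digits).
#'
#' @param p proportion in [0, 1] (or NA).
#' @param digits decimal places.
#' @return character.
#' @export
format_percent <- function(p, digits = 0) {
  ifelse(is.na(p), "NA", formatC(round_half_away(100 * p, digits),
                                 format = "f", digits = digits))
}

#' Condition-by-canonicality metrics
#'
#' Shape accuracy, texture accuracy and texture bias per (condition x
#' canonicality) cell, plus the 3D gain (shape accuracy 3D minus 2D)
#' per canonicality stratum, computed on matched stimulus pairs (same
#' shape, texture, viewpoint in both conditions). Marginal rows pooled
#' over canonicality (`canonicality = "all"`) are included; their counts
#' equal [compute_bias()] on the pooled outcomes.
#'
#' @param outcomes outcome records from [score_cue_conflict()].
#' @return list with `cells` (data.frame) and `gain` (per-canonicality
#'   3D - 2D shape-accuracy difference on matched pairs; `NA` when a
#'   condition is missing).
#' @export
condition_metrics <- function(outcomes) {
  cell_stats <- function(df) {
    b <- if (nrow(df)) compute_bias(df) else NULL
    data.frame(n = nrow(df),
               shape_accuracy = if (nrow(df)) b$shape_accuracy else NA_real_,
               texture_accuracy = if (nrow(df)) b$texture_accuracy else NA_real_,
               texture_bias = if (nrow(df)) b$texture_bias else NA_real_)
  }
  conds <- c("3D", "2D"); canons <- c("canonical", "noncanonical")
  rows <- list()
  for (cd in conds) for (cn in c(canons, "all")) {
    sel <- outcomes$condition == cd & (cn == "all" | outcomes$canonicality == cn)
    rows[[paste(cd, cn)]] <- cbind(condition = cd, canonicality = cn,
                                   cell_stats(outcomes[sel, , drop = FALSE]))
  }
  cells <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  # 3D gain on matched (shape, texture, viewpoint) pairs
  key <- function(df) paste(df$shape_category, df$texture_category,
                            df$viewpoint_index, df$canonicality)
  gain <- sapply(canons, function(cn) {
    d3 <- outcomes[outcomes$condition == "3D" & outcomes$canonicality == cn, ]
    d2 <- outcomes[outcomes$condition == "2D" & outcomes$canonicality == cn, ]
    if (!nrow(d3) || !nrow(d2)) return(NA_real_)
    k3 <- key(d3); k2 <- key(d2)
    common <- intersect(k3, k2)
    if (!length(common)) return(NA_real_)
    acc3 <- mean(d3$outcome[k3 %in% common] == "shape_correct")
    acc2 <- mean(d2$outcome[k2 %in% common] == "shape_correct")
    acc3 - acc2
  })
  list(cells = cells, gain = gain)
}

#' Oracle classifiers for the pluggable model interface
#'
#' Test doubles producing probability vectors over the label-map
#' vocabulary: `shape_oracle` answers with the stimulus's shape category,
#' `texture_oracle` with its texture category, `mixture` answers by shape
#' with probability `p` and otherwise by texture, `uniform_random` picks
#' an entry-level category uniformly. With `noise > 0` the answer is
#' replaced by a uniformly random category with that probability. The
#' returned classifier maps a manifest to a probability matrix (rows =
#' records, columns = vocabulary labels) and is deterministic under the
#' seed.
#'
#' @param kind one of `"shape_oracle"`, `"texture_oracle"`, `"mixture"`,
#'   `"uniform_random"`.
#' @param label_map a `label_map`.
#' @param p mixture weight on the shape answer (for `kind = "mixture"`).
#' @param noise lapse probability in [0, 1].
#' @param seed integer seed.
#' @return function(manifest) -> probability matrix.
#' @export
oracle_classifier <- function(kind = c("shape_oracle", "texture_oracle",
                                       "mixture", "uniform_random"),
                              label_map = load_label_map(),
                              p = 0.5, noise = 0, seed = 1) {
  kind <- match.arg(kind)
  if (p < 0 || p > 1) stop("mixture weight p must be in [0, 1]")
  vocab <- label_map$subcategory_label
  # first mapped subcategory per entry category carries the mass
  rep_label <- vapply(cc_categories(), function(cc)
    vocab[label_map$entry_category == cc][1], "")
  function(manifest) {
    n <- nrow(manifest)
    local_seed(derive_seed(seed, n, 17L), {
      answer <- switch(kind,
        shape_oracle = manifest$shape_category,
        texture_oracle = manifest$texture_category,
        mixture = ifelse(stats::runif(n) < p, manifest$shape_category,
                         manifest$texture_category),
        uniform_random = sample(cc_categories(), n, replace = TRUE))
      if (noise > 0) {
        lapse <- stats::runif(n) < noise
        answer[lapse] <- sample(cc_categories(), sum(lapse), replace = TRUE)
      }
      probs <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
      probs[cbind(seq_len(n), match(rep_label[answer], vocab))] <- 1
      probs
    })
  }
}

#' Run a classifier over a manifest and summarize bias
#'
#' Applies the classifier, aggregates its output to entry-level
#' decisions, scores cue-conflict outcomes and returns the bias summary
#' together with per-cell metrics.
#'
#' @param classifier function(manifest) -> probability matrix (columns
#'   named by vocabulary labels), e.g. from [oracle_classifier()].
#' @param manifest a `stim_manifest`.
#' @param label_map a `label_map`.
#' @param exclude_congruent drop congruent records before scoring.
#' @return list with `outcomes`, `bias` ([compute_bias()]), and
#'   `metrics` ([condition_metrics()]).
#' @export
run_evaluation <- function(classifier, manifest, label_map = load_label_map(),
                           exclude_congruent = TRUE) {
  probs <- classifier(manifest)
  agg <- aggregate_entry_level_matrix(probs, label_map)
  outcomes <- score_cue_conflict(agg$decision, manifest, exclude_congruent)
  list(outcomes = outcomes, bias = compute_bias(outcomes),
       metrics = condition_metrics(outcomes))
}
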