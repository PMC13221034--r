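# Behavioral-experiment machinery: trial schedules for the two
# experiments, simulated observers with per-cell accuracy and log-normal
# response times, and the 2x2 within-subject ANOVA (sums-of-squares
# decomposition with subject-by-effect error strata) with paired
# contrasts and Cohen's d.

sample_rows <- function(df, n) df[sample(nrow(df), n), , drop = FALSE]

#' Build the Experiment-1 trial schedule
#'
#' Two blocks. Shape block: for each condition (3D, 2D) and each of the
#' 10 shape categories, `n_per_category` incongruent stimuli with random
#' texture and orientation (8 x 10 x 2 = 160 trials at the default),
#' randomly interleaved; the correct response is the shape category.
#' Texture block: built symmetrically over texture categories with the
#' shape drawn from the other nine categories; the correct response is
#' the texture category. The shape and texture category differ on every
#' trial. Practice trials (10 per block) are generated and flagged so
#' analyses can exclude them.
#'
#' @param manifest a `stim_manifest` containing both conditions.
#' @param n_per_category stimuli per (category x condition) cell.
#' @param seed integer seed.
#' @param n_practice flagged practice trials per block.
#' @return data.frame of trial specs with columns `trial_index`, `block`,
#'   `stimulus_id`, `condition`, `canonicality`, `correct_response`,
#'   `cell`, `practice`.
#' @export
build_exp1_trials <- function(manifest, n_per_category = 8, seed = 1,
                              n_practice = 10) {
  man <- manifest[!manifest$congruent, , drop = FALSE]
  local_seed(derive_seed(seed, 1L), {
    pick <- function(block) {
      cat_col <- if (block == "shape_task") "shape_category" else "texture_category"
      resp_col <- cat_col
      rows <- list()
      for (cond in c("3D", "2D")) for (cc in cc_categories()) {
        pool <- man[man$condition == cond & man[[cat_col]] == cc, , drop = FALSE]
        if (nrow(pool) < n_per_category)
          stop(sprintf("insufficient stimuli for %s cell (%s, %s): %d < %d",
                       block, cc, cond, nrow(pool), n_per_category))
        sel <- sample_rows(pool, n_per_category)
        rows[[paste(cond, cc)]] <- data.frame(
          block = block, stimulus_id = sel$stimulus_id,
          condition = sel$condition, canonicality = sel$canonicality,
          shape_category = sel$shape_category,
          texture_category = sel$texture_category,
          correct_response = sel[[resp_col]],
          stringsAsFactors = FALSE)
      }
      out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
      out[sample(nrow(out)), , drop = FALSE]  # randomly interleave
    }
    shape_block <- pick("shape_task")
    texture_block <- pick("texture_task")
    practice <- function(block_df, block) {
      pr <- sample_rows(block_df, min(n_practice, nrow(block_df)))
      pr$practice <- TRUE
      pr
    }
    shape_block$practice <- FALSE; texture_block$practice <- FALSE
    trials <- rbind(practice(shape_block, "shape_task"), shape_block,
                    practice(texture_block, "texture_task"), texture_block)
    trials$trial_index <- seq_len(nrow(trials))
    trials$cell <- paste(trials$block, trials$condition, sep = ":")
    rownames(trials) <- NULL
    trials
  })
}

#' Build the Experiment-2 trial schedule
#'
#' Shape task only, crossing condition (3D/2D) with viewpoint
#' canonicality: `n_per_condition` incongruent stimuli per cell (20 x 4 =
#' 80 at the default), randomly interleaved, plus 16 flagged practice
#' trials.
#'
#' @param manifest a `stim_manifest` with all four cells populated.
#' @param n_per_condition trials per (condition x canonicality) cell.
#' @param seed integer seed.
#' @param n_practice flagged practice trials.
#' @return data.frame of trial specs as in [build_exp1_trials()].
#' @export
build_exp2_trials <- function(manifest, n_per_condition = 20, seed = 1,
                              n_practice = 16) {
  man <- manifest[!manifest$congruent, , drop = FALSE]
  local_seed(derive_seed(seed, 2L), {
    rows <- list()
    for (cond in c("3D", "2D")) for (cn in c("canonical", "noncanonical")) {
      pool <- man[man$condition == cond & man$canonicality == cn, , drop = FALSE]
      if (!nrow(pool))
        stop(sprintf("empty (condition, canonicality) cell (%s, %s)", cond, cn))
      sel <- sample_rows(pool, min(n_per_condition, nrow(pool)))
      if (nrow(sel) < n_per_condition)  # sample with replacement if scarce
        sel <- pool[sample(nrow(pool), n_per_condition, replace = TRUE), ]
      rows[[paste(cond, cn)]] <- data.frame(
        block = "shape_task", stimulus_id = sel$stimulus_id,
        condition = sel$condition, canonicality = sel$canonicality,
        shape_category = sel$shape_category,
        texture_category = sel$texture_category,
        correct_response = sel$shape_category,
        stringsAsFactors = FALSE)
    }
    main <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    main <- main[sample(nrow(main)), , drop = FALSE]
    main$practice <- FALSE
    pr <- sample_rows(main, min(n_practice, nrow(main)))
    pr$practice <- TRUE
    trials <- rbind(pr, main)
    trials$trial_index <- seq_len(nrow(trials))
    trials$cell <- paste(trials$condition, trials$canonicality, sep = ":")
    rownames(trials) <- NULL
    trials
  })
}

#' Observer parameters
#'
#' Per-cell accuracy probabilities, a lapse rate, and a log-normal
#' response-time model per cell. The default accuracies follow the
#' Experiment-2 pattern reported for human observers: 3D/2D canonical
#' .95/.95, 3D/2D noncanonical .94/.85.
#'
#' @param accuracy named vector of per-cell probabilities in [0, 1];
#'   names match the `cell` column of the trial schedule.
#' @param lapse lapse rate in [0, 1): probability of a uniform random
#'   response regardless of cell accuracy.
#' @param rt_meanlog,rt_sdlog log-normal location/scale; scalars or named
#'   per-cell vectors (`rt_sdlog > 0`).
#' @param seed integer seed.
#' @return an `observer_params` list.
#' @export
observer_params <- function(accuracy = c("3D:canonical" = 0.95,
                                         "2D:canonical" = 0.95,
                                         "3D:noncanonical" = 0.94,
                                         "2D:noncanonical" = 0.85),
                            lapse = 0, rt_meanlog = log(0.9), rt_sdlog = 0.35,
                            seed = 1) {
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracies must lie in [0, 1]")
  if (any(rt_sdlog <= 0)) stop("rt_sdlog must be > 0")
  structure(list(accuracy = accuracy, lapse = lapse,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 seed = as.integer(seed)),
            class = "observer_params")
}

#' Simulate an observer over a trial schedule
#'
#' On each trial the response is correct with the cell's accuracy
#' probability, otherwise a uniformly chosen wrong category; with
#' probability `lapse` the response is uniform over all 10 categories.
#' Response times are drawn log-normal per cell. Deterministic under the
#' parameter seed.
#'
#' @param params an [observer_params()] object.
#' @param trials trial schedule from a `build_*_trials` function.
#' @return `trials` with added `response`, `correct`, `rt` columns.
#' @export
simulate_observer <- function(params, trials) {
  missing_cells <- setdiff(unique(trials$cell), names(params$accuracy))
  if (length(missing_cells))
    stop("no accuracy parameter for cell(s): ",
         paste(missing_cells, collapse = ", "))
  per_cell <- function(x, cell) if (length(x) == 1) x else x[[cell]]
  local_seed(derive_seed(params$seed, nrow(trials), 3L), {
    n <- nrow(trials)
    acc <- params$accuracy[trials$cell]
    cats <- cc_categories()
    hit <- stats::runif(n) < acc
    wrong <- vapply(trials$correct_response, function(cr)
      sample(setdiff(cats, cr), 1), "")
    response <- ifelse(hit, trials$correct_response, wrong)
    if (params$lapse > 0) {
      lp <- stats::runif(n) < params$lapse
      response[lp] <- sample(cats, sum(lp), replace = TRUE)
    }
    ml <- if (length(params$rt_meanlog) == 1) rep(params$rt_meanlog, n)
          else params$rt_meanlog[trials$cell]
    sl <- if (length(params$rt_sdlog) == 1) rep(params$rt_sdlog, n)
          else params$rt_sdlog[trials$cell]
    trials$response <- response
    trials$correct <- response == trials$correct_response
    trials$rt <- stats::rlnorm(n, ml, sl)
    trials
  })
}

#' Simulate a population of observers and tabulate cell accuracies
#'
#' Each simulated subject contributes one accuracy proportion per cell
#' (binomial draws at the cell's true accuracy over `n_trials_per_cell`
#' trials), the per-subject cell means the 2x2 ANOVA consumes.
#'
#' @param n_subjects number of observers.
#' @param cell_accuracy named per-cell true accuracies; names of the form
#'   `"A:B"` (factor levels separated by a colon).
#' @param n_trials_per_cell trials per cell per subject.
#' @param seed integer seed.
#' @return long data.frame: `subject`, `A`, `B`, `value`.
#' @export
simulate_population <- function(n_subjects,
                                cell_accuracy = observer_params()$accuracy,
                                n_trials_per_cell = 20, seed = 1) {
  cells <- names(cell_accuracy)
  ab <- do.call(rbind, strsplit(cells, ":", fixed = TRUE))
  local_seed(derive_seed(seed, n_subjects, 5L), {
    do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      k <- stats::rbinom(length(cells), n_trials_per_cell, cell_accuracy)
      data.frame(subject = s, A = ab[, 1], B = ab[, 2],
                 value = k / n_trials_per_cell, stringsAsFactors = FALSE)
    }))
  })
}

#' Two-by-two repeated-measures ANOVA
#'
#' Standard within-subject decomposition for a complete, balanced
#' S x 2 x 2 table of per-subject cell means: main effects and the
#' interaction, each tested against its own subject-by-effect error
#' stratum with df (1, S-1). Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`. Paired contrasts (each factor's
#' marginal contrast and its simple effects within the other factor's
#' levels) report the mean difference, t with df S-1, p, and Cohen's d
#' (mean difference over the SD of the paired differences). Sphericity
#' is not at issue for 1-df effects.
#'
#' @param data long data.frame with columns `subject`, `A`, `B`, `value`;
#'   exactly one value per subject x A x B cell, S >= 3 subjects.
#' @return an `anova_2x2` list: `effects` (data.frame with SS, df, F, p,
#'   partial eta squared per effect) and `contrasts`.
#' @export
rm_anova_2x2 <- function(data) {
  need <- c("subject", "A", "B", "value")
  if (!all(need %in% names(data))) stop("data needs columns subject, A, B, value")
  la <- sort(unique(data$A)); lb <- sort(unique(data$B))
  if (length(la) != 2 || length(lb) != 2) stop("A and B must each have 2 levels")
  tab <- table(data$subject, data$A, data$B)
  if (any(tab != 1)) stop("design must be complete and balanced (one value per cell)")
  S <- length(unique(data$subject))
  if (S < 3) stop("need at least 3 subjects")

  Y <- array(NA_real_, c(S, 2, 2))
  subj <- sort(unique(data$subject))
  for (r in seq_len(nrow(data)))
    Y[match(data$subject[r], subj),
      match(data$A[r], la), match(data$B[r], lb)] <- data$value[r]

  gm <- mean(Y)
  m_s <- apply(Y, 1, mean)                 # subject means
  m_a <- apply(Y, 2, mean); m_b <- apply(Y, 3, mean)
  m_ab <- apply(Y, c(2, 3), mean)
  m_sa <- apply(Y, c(1, 2), mean); m_sb <- apply(Y, c(1, 3), mean)

  ss_a <- 2 * S * sum((m_a - gm)^2)
  ss_b <- 2 * S * sum((m_b - gm)^2)
  ss_ab <- S * sum((m_ab - outer(m_a, rep(1, 2)) - outer(rep(1, 2), m_b) + gm)^2)
  ss_as <- 2 * sum((m_sa - outer(m_s, rep(1, 2)) - outer(rep(1, S), m_a) + gm)^2)
  ss_bs <- 2 * sum((m_sb - outer(m_s, rep(1, 2)) - outer(rep(1, S), m_b) + gm)^2)
  resid <- Y
  for (i in seq_len(S)) for (j in 1:2) for (k in 1:2)
    resid[i, j, k] <- Y[i, j, k] - m_sa[i, j] - m_sb[i, k] - m_ab[j, k] +
      m_s[i] + m_a[j] + m_b[k] - gm
  ss_abs <- sum(resid^2)

  eff <- function(name, ss_e, ss_err) {
    Fv <- if (ss_err > 0) (ss_e / 1) / (ss_err / (S - 1)) else
      if (ss_e > 0) Inf else 0
    data.frame(effect = name, ss = ss_e, ss_error = ss_err,
               df1 = 1, df2 = S - 1, F = Fv,
               p = stats::pf(Fv, 1, S - 1, lower.tail = FALSE),
               pes = if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err) else 0,
               stringsAsFactors = FALSE)
  }
  effects <- rbind(eff("A", ss_a, ss_as), eff("B", ss_b, ss_bs),
                   eff("A:B", ss_ab, ss_abs))

  paired <- function(x, y, label) {
    d <- x - y
    sdd <- stats::sd(d)
    tv <- if (sdd > 0) mean(d) / (sdd / sqrt(S)) else ifelse(mean(d) == 0, 0, Inf)
    data.frame(contrast = label, delta = mean(d), t = tv, df = S - 1,
               p = 2 * stats::pt(abs(tv), S - 1, lower.tail = FALSE),
               cohens_d = if (sdd > 0) mean(d) / sdd else 0,
               stringsAsFactors = FALSE)
  }
  contrasts <- rbind(
    paired(m_sa[, 1], m_sa[, 2], sprintf("A: %s - %s", la[1], la[2])),
    paired(m_sb[, 1], m_sb[, 2], sprintf("B: %s - %s", lb[1], lb[2])),
    paired(Y[, 1, 1], Y[, 2, 1], sprintf("A within %s: %s - %s", lb[1], la[1], la[2])),
    paired(Y[, 1, 2], Y[, 2, 2], sprintf("A within %s: %s - %s", lb[2], la[1], la[2])),
    paired(Y[, 1, 1], Y[, 1, 2], sprintf("B within %s: %s - %s", la[1], lb[1], lb[2])),
    paired(Y[, 2, 1], Y[, 2, 2], sprintf("B within %s: %s - %s", la[2], lb[1], lb[2])))

  structure(list(effects = effects, contrasts = contrasts,
                 levels = list(A = la, B = lb), n_subjects = S),
            class = "anova_2x2")
}

#' @export
print.anova_2x2 <- function(x, ...) {
  cat(sprintf("<anova_2x2> %d subjects\n", x$n_subjects))
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-4s F(%d,%d) = %.2f, p = %.3g, pes = %.3f\n",
                e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i], e$pes[i]))
  invisible(x)
}
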