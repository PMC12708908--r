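#' Signed per-interval estimation error
#'
#' @param estimate estimated rating.
#' @param reference reported rating.
#' @return `estimate - reference`; mean-absolute and root-mean-square errors
#'   aggregate its absolute value and square over a unit's intervals.
#' @export
interval_error <- function(estimate, reference) estimate - reference

ma_error <- function(e) mean(abs(e))
rms_error <- function(e) sqrt(mean(e^2))

#' Default model configurations for the four estimation methods
#'
#' @param seed base seed placed in each configuration.
#' @return named list of [model_config()] objects for `mlp`, `linear`, `svm`.
#'   (The median-based estimator needs no configuration and is always run.)
#' @export
default_methods <- function(seed = 1L) {
  list(mlp = model_config("mlp", seed = seed),
       linear = model_config("linear", penalty = "ridge",
                             penalty_strength = 0.1, seed = seed),
       svm = model_config("svm", seed = seed))
}

#' Crossvalidation fold plan
#'
#' Goal 1 splits each participant's conversation intervals 8:1:1 (10 folds
#' per participant, validation = the interval after the test one,
#' cyclically). Goals 2 and 3 leave one dyad out as test and the cyclically
#' next dyad as validation: 39:1:1 over 41 dyads (goal 2) or 33:1:1 over 35
#' dyads (goal 3). The test unit never appears in training or validation.
#'
#' @param goal 1, 2 or 3.
#' @param dyads vector of dyad ids in the table.
#' @param n_intervals number of conversation intervals per dyad.
#' @return data frame of folds with columns `fold`, `test`, `valid` (interval
#'   indices for goal 1, dyad ids otherwise).
#' @export
fold_plan <- function(goal, dyads, n_intervals = 10) {
  if (goal == 1) {
    test <- seq_len(n_intervals)
    valid <- test %% n_intervals + 1
    return(data.frame(fold = test, test = test, valid = valid))
  }
  dyads <- sort(unique(dyads))
  n <- length(dyads)
  valid <- dyads[seq_len(n) %% n + 1]
  data.frame(fold = seq_len(n), test = dyads, valid = valid)
}

expand_selectors <- function(selectors, ks, n_feat) {
  cands <- list()
  for (k in unique(ks)) {
    if (k > n_feat) next
    for (s in selectors)
      cands[[length(cands) + 1]] <- selector_config(s, k)
  }
  if (length(cands) == 0) stop("no valid selector candidates")
  cands
}

# fit all selector candidates for one method, pick by validation RMS
# (ties: fewer features, then earlier candidate), return test estimates
fit_select_predict <- function(mcfg, cands, train, valid, test, feature_cols) {
  Xtr <- train[, feature_cols, drop = FALSE]
  best <- NULL; best_rms <- Inf; best_k <- Inf
  for (ci in seq_along(cands)) {
    fm <- fit_estimator(mcfg, cands[[ci]], Xtr, train$label)
    est_v <- predict(fm, valid[, feature_cols, drop = FALSE])
    v_rms <- rms_error(interval_error(est_v, valid$label))
    k <- length(fm$feature_names)
    if (v_rms < best_rms - 1e-12 ||
        (abs(v_rms - best_rms) <= 1e-12 && k < best_k)) {
      best <- fm; best_rms <- v_rms; best_k <- k
    }
  }
  est_test <- predict(best, test[, feature_cols, drop = FALSE])
  est_train <- predict(best, Xtr)
  tr_err <- interval_error(est_train, train$label)
  list(estimates = est_test, model = best, valid_rms = best_rms,
       train_ma = ma_error(tr_err), train_rms = rms_error(tr_err))
}

#' Run one estimation goal end to end
#'
#' Executes the goal's crossvalidation: for every fold, each machine-learning
#' method's selector candidates are fitted on the training rows, the
#' candidate with the lowest validation RMS is chosen, and the finalized
#' model is applied to the test rows; the median-based estimator is computed
#' by its goal-specific definition. Every stochastic fit is seeded from
#' (master seed, goal, fold, method).
#'
#' @param table a `feature_table` (normally baseline-normalized).
#' @param goal 1, 2 or 3.
#' @param target `"valence"` or `"arousal"`.
#' @param methods named list of [model_config()]s; see [default_methods()].
#' @param selectors selector methods to enter as candidates.
#' @param ks candidate numbers of selected features.
#' @param include_characteristics append participant characteristics to the
#'   inputs (goals 2 and 3).
#' @param feature_subset `"all"` or `"individual_only"` (synchrony ablation).
#' @param master_seed integer master seed.
#' @return object of class `evaluation_run`: list with `results` (one row per
#'   method x unit x interval: estimate, reference), `summary` (per
#'   unit x method MA/RMS), `train_errors`, and the run metadata.
#' @export
run_goal <- function(table, goal, target = c("valence", "arousal"),
                     methods = default_methods(),
                     selectors = c("mrmr", "laplacian"), ks = 5:10,
                     include_characteristics = FALSE,
                     feature_subset = c("all", "individual_only"),
                     master_seed = 1L) {
  target <- match.arg(target)
  feature_subset <- match.arg(feature_subset)
  if (include_characteristics && goal == 1)
    stop("characteristics augmentation is not defined for dyad-specific estimation")
  design <- build_design(table, goal, target,
                         include_characteristics = include_characteristics)
  feature_cols <- attr(design, "feature_cols")
  if (feature_subset == "individual_only")
    feature_cols <- setdiff(feature_cols, attr(design, "sync_cols"))
  n_int <- length(unique(design$interval_index))
  results <- list(); train_rows <- list()
  add_res <- function(method, rows, est, fold) {
    results[[length(results) + 1]] <<- data.frame(
      goal = goal, target = target, method = method, fold = fold,
      dyad_id = rows$dyad_id, interval_index = rows$interval_index,
      participant = rows$participant, unit = rows$unit,
      estimate = est, reference = rows$label)
  }
  if (goal == 1) {
    plan <- fold_plan(1, NULL, n_int)
    if (nrow(plan) != n_int) stop("fold-plan invariant violation")
    for (u in unique(design$unit)) {
      du <- design[design$unit == u, ]
      du <- du[order(du$interval_index), ]
      if (nrow(du) != n_int) stop("fold-plan invariant violation: unit ", u)
      for (f in seq_len(nrow(plan))) {
        test <- du[du$interval_index == plan$test[f], ]
        valid <- du[du$interval_index == plan$valid[f], ]
        train <- du[!du$interval_index %in% c(plan$test[f], plan$valid[f]), ]
        cands <- expand_selectors(selectors, pmin(ks, nrow(train) - 1),
                                  length(feature_cols))
        for (mi in seq_along(methods)) {
          mcfg <- methods[[mi]]
          mcfg$seed <- derive_seed(master_seed, goal * 100000 + f * 100 + mi)
          r <- fit_select_predict(mcfg, cands, train, valid, test, feature_cols)
          add_res(names(methods)[mi], test, r$estimates, f)
          train_rows[[length(train_rows) + 1]] <- data.frame(
            method = names(methods)[mi], fold = f, unit = u,
            train_ma = r$train_ma, train_rms = r$train_rms)
        }
        mbe <- mbe_dyad_specific(du$label, which(du$interval_index == plan$test[f]))
        add_res("mbe", test, mbe, f)
      }
    }
  } else {
    dyads <- sort(unique(design$dyad_id))
    plan <- fold_plan(goal, dyads, n_int)
    if (any(plan$test == plan$valid) && length(dyads) > 1)
      stop("fold-plan invariant violation")
    cands <- expand_selectors(selectors, ks, length(feature_cols))
    for (f in seq_len(nrow(plan))) {
      test <- design[design$dyad_id == plan$test[f], ]
      valid <- design[design$dyad_id == plan$valid[f], ]
      train <- design[!design$dyad_id %in% c(plan$test[f], plan$valid[f]), ]
      if (any(train$dyad_id %in% test$dyad_id))
        stop("fold-plan invariant violation: leakage")
      if (nrow(train) == 0 && length(methods) > 0)
        stop("fold-plan invariant violation: empty training set (need >= 3 dyads)")
      for (mi in seq_along(methods)) {
        mcfg <- methods[[mi]]
        mcfg$seed <- derive_seed(master_seed, goal * 100000 + f * 100 + mi)
        r <- fit_select_predict(mcfg, cands, train, valid, test, feature_cols)
        add_res(names(methods)[mi], test, r$estimates, f)
        train_rows[[length(train_rows) + 1]] <- data.frame(
          method = names(methods)[mi], fold = f, unit = NA,
          train_ma = r$train_ma, train_rms = r$train_rms)
      }
      pool <- design$label[design$dyad_id != plan$test[f]]
      add_res("mbe", test, mbe_dyad_nonspecific(pool), f)
    }
  }
  results <- do.call(rbind, results)
  out <- structure(list(results = results,
                        summary = summarize_results(results),
                        train_errors = if (length(train_rows) > 0)
                          do.call(rbind, train_rows) else NULL,
                        goal = goal, target = target,
                        feature_subset = feature_subset,
                        include_characteristics = include_characteristics,
                        master_seed = master_seed),
                   class = "evaluation_run")
  out
}

#' Per-unit error summary
#'
#' Aggregates per-interval estimates into each unit's mean-absolute and
#' root-mean-square error per method, asserting the power-mean inequality
#' `RMS >= MA` on every row.
#'
#' @param results the `results` data frame of an `evaluation_run`.
#' @return data frame with columns `method`, `unit`, `n`, `ma`, `rms`.
#' @export
summarize_results <- function(results) {
  key <- interaction(results$method, results$unit, drop = TRUE)
  rows <- lapply(split(results, key), function(df) {
    e <- interval_error(df$estimate, df$reference)
    data.frame(method = df$method[1], unit = df$unit[1], n = nrow(df),
               ma = ma_error(e), rms = rms_error(e))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$rms < out$ma - 1e-9))
    stop("internal error: RMS < MA violates the power-mean inequality")
  out
}

#' Holm-Sidak step-down adjustment
#'
#' @param p vector of raw p-values.
#' @return adjusted p-values, monotone non-decreasing in the raw p rank.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    a <- 1 - (1 - p[ord[i]])^(m - i + 1)
    run <- max(run, a)
    adj[ord[i]] <- min(1, run)
  }
  adj
}

#' Compare methods with a repeated-measures omnibus test
#'
#' One-way repeated-measures ANOVA of the chosen per-unit error across
#' methods (units as subjects), followed by Holm-Sidak-adjusted paired
#' t-tests for all method pairs, with effect directions.
#'
#' @param summary a [summarize_results()] data frame containing at least two
#'   methods with matched units.
#' @param error `"rms"` or `"ma"`.
#' @return list with `omnibus_p`, and `pairwise` (data frame with raw and
#'   adjusted p-values and the mean error difference).
#' @export
compare_methods <- function(summary, error = c("rms", "ma")) {
  error <- match.arg(error)
  methods <- sort(unique(summary$method))
  if (length(methods) < 2) stop("need at least 2 methods")
  wide <- lapply(methods, function(m) {
    s <- summary[summary$method == m, ]
    stats::setNames(s[[error]], s$unit)
  })
  units <- Reduce(intersect, lapply(wide, names))
  if (length(units) < length(unique(summary$unit)))
    stop("unmatched units across methods")
  mat <- sapply(wide, function(v) v[units])
  colnames(mat) <- methods
  long <- data.frame(err = as.vector(mat),
                     method = factor(rep(methods, each = length(units))),
                     unit = factor(rep(units, times = length(methods))))
  fit <- aov(err ~ method + Error(unit / method), data = long)
  tab <- summary(fit)[["Error: unit:method"]][[1]]
  omnibus_p <- tab["method", "Pr(>F)"]
  pairs <- utils::combn(methods, 2)
  pw <- data.frame(method_a = pairs[1, ], method_b = pairs[2, ],
                   mean_diff = NA_real_, p_raw = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- mat[, pairs[1, i]]; b <- mat[, pairs[2, i]]
    pw$mean_diff[i] <- mean(a - b)
    pw$p_raw[i] <- if (sd(a - b) == 0) {
      # a constant paired difference: identical vectors are indistinguishable,
      # a constant nonzero shift is unambiguous
      if (mean(a - b) == 0) 1 else 0
    } else t.test(a, b, paired = TRUE)$p.value
  }
  pw$p_adj <- holm_sidak(pw$p_raw)
  pw$direction <- ifelse(pw$mean_diff < 0,
                         paste(pw$method_a, "<", pw$method_b),
                         paste(pw$method_a, ">", pw$method_b))
  list(omnibus_p = omnibus_p, pairwise = pw, error = error)
}

paired_comparison <- function(x, y, alpha = 0.05) {
  d <- x - y
  if (sd(d) == 0)
    return(list(test = "degenerate", p = 1, mean_diff = mean(d)))
  sw <- tryCatch(shapiro.test(d)$p.value, error = function(e) 0)
  if (sw >= alpha) {
    list(test = "paired t", p = t.test(x, y, paired = TRUE)$p.value,
         mean_diff = mean(d))
  } else {
    list(test = "wilcoxon", p = wilcox.test(x, y, paired = TRUE,
                                            exact = FALSE)$p.value,
         mean_diff = mean(d))
  }
}

#' Synchrony ablation
#'
#' Runs the same goal twice with the MLP -- once with all features, once with
#' the 36 synchrony features removed -- and compares per-unit errors with a
#' paired test (t-test when the paired differences pass Shapiro-Wilk
#' normality at alpha = 0.05, Wilcoxon otherwise).
#'
#' @inheritParams run_goal
#' @param ... further arguments passed to [run_goal()] (methods default to
#'   MLP only).
#' @return list with both `evaluation_run`s and `comparison` per error type.
#' @export
ablate_synchrony <- function(table, goal, target = c("valence", "arousal"),
                             methods = default_methods()["mlp"], ...) {
  target <- match.arg(target)
  with_sync <- run_goal(table, goal, target, methods = methods,
                        feature_subset = "all", ...)
  no_sync <- run_goal(table, goal, target, methods = methods,
                      feature_subset = "individual_only", ...)
  cmp <- lapply(c(rms = "rms", ma = "ma"), function(err) {
    a <- with_sync$summary[with_sync$summary$method == names(methods)[1], ]
    b <- no_sync$summary[no_sync$summary$method == names(methods)[1], ]
    b <- b[match(a$unit, b$unit), ]
    paired_comparison(a[[err]], b[[err]])
  })
  list(with_sync = with_sync, no_sync = no_sync, comparison = cmp)
}

#' Characteristics augmentation
#'
#' Runs dyad-nonspecific estimation with and without participant
#' characteristics (age, gender, trait scores) appended to the inputs and
#' compares per-unit errors; not defined for dyad-specific estimation
#' (goal 1 raises an error).
#'
#' @inheritParams ablate_synchrony
#' @return list with both runs and `comparison` per error type.
#' @export
augment_characteristics <- function(table, goal,
                                    target = c("valence", "arousal"),
                                    methods = default_methods()["mlp"], ...) {
  if (!goal %in% c(2, 3))
    stop("characteristics augmentation applies to dyad-nonspecific goals (2, 3) only")
  target <- match.arg(target)
  plain <- run_goal(table, goal, target, methods = methods,
                    include_characteristics = FALSE, ...)
  augmented <- run_goal(table, goal, target, methods = methods,
                        include_characteristics = TRUE, ...)
  cmp <- lapply(c(rms = "rms", ma = "ma"), function(err) {
    a <- augmented$summary[augmented$summary$method == names(methods)[1], ]
    b <- plain$summary[plain$summary$method == names(methods)[1], ]
    b <- b[match(a$unit, b$unit), ]
    paired_comparison(a[[err]], b[[err]])
  })
  list(plain = plain, augmented = augmented, comparison = cmp)
}

#' Most important features by Laplacian ranking on the full dataset
#'
#' Ranks all candidate features (no crossvalidation split) by Laplacian
#' score on the full design for the dyad-nonspecific goal and returns the
#' top `k`.
#'
#' @param table a `feature_table`.
#' @param target `"valence"` or `"arousal"`.
#' @param rater `"self"` (goal-2 design) or `"observer"` (goal-3 design).
#' @param k number of features to report.
#' @return character vector of `k` feature names, most important first.
#' @export
top_features <- function(table, target = c("valence", "arousal"),
                         rater = c("self", "observer"), k = 5) {
  target <- match.arg(target)
  rater <- match.arg(rater)
  goal <- if (rater == "self") 2 else 3
  design <- build_design(table, goal, target)
  X <- median_impute(design[, attr(design, "feature_cols"), drop = FALSE])$X
  laplacian_rank(X, k)
}

#' Descriptive statistics of the ratings
#'
#' For each target and the self stream: pooled mean and SD over all collected
#' conversation intervals; mean and SD over participants of each
#' participant's highest-minus-lowest rating; mean and SD over intervals of
#' the absolute inter-partner rating difference; and an extreme-value audit
#' (whether ratings 1 and 9 occur, and counts of intervals where both
#' partners gave 9 or both gave 1). Observer-stream pooled statistics are
#' included when present.
#'
#' @param table a `feature_table` (only its ratings are used).
#' @return nested list of descriptive statistics.
#' @export
describe_ratings <- function(table) {
  rt <- table$ratings
  self <- rt[rt$rater == "self", ]
  obs <- rt[rt$rater == "observer", ]
  one_target <- function(tgt) {
    v <- self[[tgt]]
    rng <- vapply(split(self, interaction(self$dyad_id, self$participant,
                                          drop = TRUE)),
                  function(df) max(df[[tgt]]) - min(df[[tgt]]), numeric(1))
    key <- interaction(self$dyad_id, self$interval_index, drop = TRUE)
    pd <- vapply(split(self, key), function(df) {
      if (nrow(df) != 2) return(NA_real_)
      abs(diff(df[[tgt]]))
    }, numeric(1))
    both9 <- sum(vapply(split(self, key), function(df)
      nrow(df) == 2 && all(df[[tgt]] == 9), logical(1)))
    both1 <- sum(vapply(split(self, key), function(df)
      nrow(df) == 2 && all(df[[tgt]] == 1), logical(1)))
    list(pooled_mean = mean(v), pooled_sd = safe_sd(v),
         range_mean = mean(rng), range_sd = safe_sd(rng),
         partner_diff_mean = mean(pd, na.rm = TRUE),
         partner_diff_sd = safe_sd(pd[!is.na(pd)]),
         has_1 = any(v == 1), has_9 = any(v == 9),
         mutual_9_intervals = both9, mutual_1_intervals = both1,
         observer_mean = if (nrow(obs) > 0) mean(obs[[tgt]]) else NA_real_,
         observer_sd = if (nrow(obs) > 0) safe_sd(obs[[tgt]]) else NA_real_)
  }
  list(n_intervals = nrow(self) / 2,
       valence = one_target("valence"),
       arousal = one_target("arousal"))
}

#' @exportS3Method base::print
print.evaluation_run <- function(x, ...) {
  cat(sprintf("<evaluation_run goal %d, %s: %d units, methods %s>\n",
              x$goal, x$target, length(unique(x$summary$unit)),
              paste(unique(x$summary$method), collapse = "/")))
  agg <- stats::aggregate(cbind(ma, rms) ~ method, data = x$summary, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
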