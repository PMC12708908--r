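#' Feature-selector configuration
#'
#' @param method `"mrmr"` (supervised) or `"laplacian"` (unsupervised).
#' @param k number of features to keep.
#' @return a `selector_config`.
#' @export
selector_config <- function(method = c("mrmr", "laplacian"), k = 10) {
  method <- match.arg(method)
  if (k < 1) stop("k must be >= 1")
  structure(list(method = method, k = as.integer(k)), class = "selector_config")
}

#' Regression-model configuration
#'
#' @param method `"mlp"`, `"linear"`, `"svm"` or `"mbe"`.
#' @param hidden hidden units for the MLP.
#' @param epochs maximum training epochs for the MLP.
#' @param learning_rate learning rate used by the gradient optimizer (the
#'   Levenberg-Marquardt optimizer adapts its damping instead).
#' @param optimizer `"levenberg-marquardt"` or `"gradient"`.
#' @param penalty `"none"`, `"lasso"` or `"ridge"` for the linear model.
#' @param penalty_strength regularization strength for lasso/ridge.
#' @param svm_cost,svm_epsilon SVM regularization and epsilon-tube width.
#' @param svm_gamma Gaussian kernel precision; `NULL` uses the median
#'   pairwise-distance heuristic on the training rows.
#' @param seed integer seed for stochastic initialization.
#' @return a `model_config`.
#' @export
model_config <- function(method = c("mlp", "linear", "svm", "mbe"),
                         hidden = 10, epochs = 1000, learning_rate = 0.1,
                         optimizer = c("levenberg-marquardt", "gradient"),
                         penalty = c("none", "lasso", "ridge"),
                         penalty_strength = 0.1,
                         svm_cost = 1, svm_epsilon = 0.1, svm_gamma = NULL,
                         seed = 1L) {
  method <- match.arg(method)
  if (epochs <= 0) stop("epochs must be > 0")
  if (penalty_strength < 0) stop("penalties must be >= 0")
  structure(list(method = method, hidden = hidden, epochs = epochs,
                 learning_rate = learning_rate,
                 optimizer = match.arg(optimizer),
                 penalty = match.arg(penalty),
                 penalty_strength = penalty_strength,
                 svm_cost = svm_cost, svm_epsilon = svm_epsilon,
                 svm_gamma = svm_gamma, seed = as.integer(seed)),
            class = "model_config")
}

# univariate F-statistic of a linear fit y ~ x
f_relevance <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  r <- cor(x, y)
  n <- length(y)
  if (!is.finite(r)) return(0)
  r2 <- min(r^2, 1 - 1e-12)
  (n - 2) * r2 / (1 - r2)
}

#' MRMR feature ranking
#'
#' Greedy maximum-relevance-minimum-redundancy ordering: relevance is the
#' univariate F-statistic of each feature against the label, mapped to its
#' equivalent squared correlation `F / (F + n - 2)` so it shares the `[0, 1]`
#' scale of the redundancy term (the mean absolute correlation with
#' already-selected features); each step adds the feature maximizing
#' relevance minus redundancy, so an exact duplicate of a selected feature
#' is pushed behind any independently informative one.
#'
#' @param X data frame or matrix of candidate features (named columns).
#' @param y numeric label.
#' @param k number of features to return.
#' @return character vector of the first `k` feature names in MRMR order.
#' @export
mrmr_rank <- function(X, y, k) {
  X <- as.data.frame(X)
  if (nrow(X) < 2) stop("need at least 2 rows")
  if (k > ncol(X)) stop("k exceeds the number of candidate features")
  n <- length(y)
  rel <- vapply(X, f_relevance, numeric(1), y = y)
  rel <- rel / (rel + n - 2)   # back to the r^2 scale
  rel[vapply(X, function(v) sd(v) == 0 || anyNA(v), logical(1))] <- -Inf
  selected <- character(0)
  remaining <- names(X)
  while (length(selected) < k) {
    if (length(selected) == 0) {
      pick <- remaining[which.max(rel[remaining])]
    } else {
      score <- vapply(remaining, function(f) {
        red <- mean(vapply(selected, function(s) {
          r <- suppressWarnings(cor(X[[f]], X[[s]]))
          if (is.finite(r)) abs(r) else 0
        }, numeric(1)))
        rel[[f]] - red
      }, numeric(1))
      pick <- remaining[which.max(score)]
    }
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' Laplacian-score feature ranking
#'
#' Unsupervised ranking on a nearest-neighbor similarity graph: rows are
#' connected to their `k_graph` nearest neighbors (Euclidean distance on
#' standardized columns) with heat-kernel weights, and each feature's
#' Laplacian score measures how smoothly it varies over the graph. Features
#' are returned in ascending score order (locality-preserving first);
#' constant features score worst and are ranked last.
#'
#' @param X data frame or matrix of features.
#' @param k number of features to return.
#' @param k_graph neighbors per row in the similarity graph.
#' @param heat_t heat-kernel bandwidth; `NULL` uses the mean squared
#'   neighbor distance.
#' @return character vector of the first `k` feature names.
#' @export
laplacian_rank <- function(X, k, k_graph = 5, heat_t = NULL) {
  X <- as.data.frame(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 rows")
  if (k > ncol(X)) stop("k exceeds the number of candidate features")
  Z <- scale(as.matrix(X))
  Z[!is.finite(Z)] <- 0
  D2 <- as.matrix(stats::dist(Z))^2
  k_graph <- min(k_graph, n - 1)
  S <- matrix(0, n, n)
  nn2 <- numeric(0)
  for (i in seq_len(n)) {
    ord <- order(D2[i, ])
    nb <- setdiff(ord, i)[seq_len(k_graph)]
    S[i, nb] <- 1
    nn2 <- c(nn2, D2[i, nb])
  }
  S <- pmax(S, t(S))
  if (is.null(heat_t)) heat_t <- max(mean(nn2), 1e-12)
  W <- S * exp(-D2 / heat_t)
  d <- rowSums(W)
  score <- vapply(names(X), function(f) {
    fr <- X[[f]]
    if (anyNA(fr) || sd(fr) == 0) return(Inf)
    frt <- fr - sum(fr * d) / sum(d)
    den <- sum(frt^2 * d)
    if (den <= 0) return(Inf)
    num <- sum(W * outer(frt, frt, function(a, b) (a - b)^2)) / 2
    num / den
  }, numeric(1))
  names(sort(score))[seq_len(k)]
}

median_impute <- function(X, medians = NULL) {
  X <- as.data.frame(X)
  if (is.null(medians))
    medians <- vapply(X, function(v) {
      m <- median(v, na.rm = TRUE)
      if (is.finite(m)) m else 0
    }, numeric(1))
  for (j in names(X)) {
    v <- X[[j]]
    v[!is.finite(v)] <- medians[[j]]
    X[[j]] <- v
  }
  list(X = X, medians = medians)
}

#' Fit a regression estimator with embedded feature selection
#'
#' Training-only pipeline: median-impute missing feature values, run the
#' configured selector on the training rows, standardize the selected
#' columns by training statistics, and fit the configured model. Degenerate
#' training labels (all equal) produce a constant model for every method.
#' Nothing outside `X`/`y` influences the fit.
#'
#' @param model a [model_config()].
#' @param selector a [selector_config()], or `NULL` to use all features.
#' @param X data frame of training features.
#' @param y numeric labels in `[1, 9]`.
#' @return a `fitted_model`.
#' @export
fit_estimator <- function(model, selector, X, y) {
  stopifnot(inherits(model, "model_config"))
  X <- as.data.frame(X)
  if (model$method == "mbe")
    stop("the median-based estimator has its own entry points; see mbe_dyad_specific")
  if (length(y) != nrow(X)) stop("X and y sizes differ")
  if (nrow(X) < 2) stop("need at least 2 training rows")
  if (var(y) == 0) {
    fm <- structure(list(method = "constant", value = y[1],
                         feature_names = character(0)),
                    class = "fitted_model")
    return(fm)
  }
  imp <- median_impute(X)
  Xi <- imp$X
  feats <- if (is.null(selector)) names(Xi)
  else if (selector$method == "mrmr") mrmr_rank(Xi, y, selector$k)
  else laplacian_rank(Xi, selector$k)
  Xs <- as.matrix(Xi[, feats, drop = FALSE])
  ctr <- colMeans(Xs)
  scl <- apply(Xs, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xz <- sweep(sweep(Xs, 2, ctr, "-"), 2, scl, "/")
  fitted <- switch(
    model$method,
    mlp = mlp_train(Xz, y, hidden = model$hidden, epochs = model$epochs,
                    optimizer = model$optimizer,
                    learning_rate = model$learning_rate, seed = model$seed),
    linear = {
      if (model$penalty == "none") {
        df <- data.frame(y = y, Xz)
        lm(y ~ ., data = df)
      } else {
        glmnet::glmnet(Xz, y, alpha = if (model$penalty == "lasso") 1 else 0,
                       lambda = model$penalty_strength)
      }
    },
    svm = {
      gamma <- model$svm_gamma
      if (is.null(gamma)) {
        idx <- seq_len(min(nrow(Xz), 200))
        med <- median(stats::dist(Xz[idx, , drop = FALSE]))
        if (!is.finite(med) || med <= 0) med <- 1
        gamma <- 1 / (2 * med^2)
      }
      set.seed(model$seed)
      e1071::svm(Xz, y, type = "eps-regression", kernel = "radial",
                 gamma = gamma, cost = model$svm_cost,
                 epsilon = model$svm_epsilon, scale = FALSE)
    })
  obj <- structure(list(method = model$method, config = model,
                        feature_names = feats, impute_medians = imp$medians,
                        center = ctr, scale = scl, fit = fitted),
                   class = "fitted_model")
  obj$train_rmse <- sqrt(mean((predict(obj, X) - y)^2))
  obj
}

#' Predict from a fitted model
#'
#' Applies the stored imputation medians and standardization, evaluates the
#' model, and clips estimates to the 1-9 rating scale. A missing selected
#' feature column is an error naming the column.
#'
#' @param object a `fitted_model`.
#' @param newdata data frame containing the selected feature columns.
#' @param ... unused.
#' @return numeric vector of clipped estimates, one per row.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (object$method == "constant")
    return(rep(object$value, nrow(newdata)))
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss) > 0)
    stop("missing selected feature(s): ", paste(miss, collapse = ", "))
  Xi <- median_impute(newdata[, names(object$impute_medians), drop = FALSE],
                      object$impute_medians)$X
  Xs <- as.matrix(Xi[, object$feature_names, drop = FALSE])
  Xz <- sweep(sweep(Xs, 2, object$center, "-"), 2, object$scale, "/")
  raw <- switch(
    object$method,
    mlp = mlp_forward(object$fit, Xz)$yhat,
    linear = {
      if (inherits(object$fit, "lm"))
        as.numeric(predict(object$fit, newdata = as.data.frame(Xz)))
      else as.numeric(predict(object$fit, newx = Xz))
    },
    svm = as.numeric(predict(object$fit, Xz)))
  pmin(9, pmax(1, raw))
}

#' Dyad-specific median-based estimate
#'
#' The baseline for dyad-specific regression: a participant's rating in the
#' held-out interval is estimated as the median of the same participant's
#' ratings in the other intervals of that dyad.
#'
#' @param ratings numeric vector of the participant's per-interval ratings
#'   (length = number of conversation intervals, default protocol 10).
#' @param holdout_index index (1-based) of the held-out interval.
#' @return the median of the remaining ratings.
#' @export
mbe_dyad_specific <- function(ratings, holdout_index) {
  if (anyNA(ratings)) stop("missing rating")
  if (holdout_index < 1 || holdout_index > length(ratings))
    stop("holdout_index out of range")
  median(ratings[-holdout_index])
}

#' Dyad-nonspecific median-based estimate
#'
#' The baseline for dyad-nonspecific regression: a single constant estimate
#' for all of the held-out unit's intervals, computed as the median over all
#' pooled per-interval ratings of the other dyads (even counts use the mean
#' of the two central values).
#'
#' @param pool numeric vector of the other dyads' per-interval ratings (the
#'   held-out dyad excluded by the caller).
#' @return the pooled median.
#' @export
mbe_dyad_nonspecific <- function(pool) {
  pool <- pool[!is.na(pool)]
  if (length(pool) == 0) stop("empty rating pool")
  median(pool)
}
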