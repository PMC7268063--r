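# Nested cross-validation machinery. Outer folds are sorted round-robin:
# subjects ordered by trait value are dealt into k folds cyclically, so all
# folds share the trait distribution and the partition is deterministic.
# Feature selection and hyperparameter tuning see only the outer-training
# subjects of each fold.

MODEL_KINDS <- c("cpm_p", "cpm_n", "svr", "lasso", "ridge")

#' Sorted round-robin fold assignment
#'
#' Subjects are stably sorted by trait value (ties keep input order) and the
#' subject at sorted position `i` goes to fold `((i - 1) mod k) + 1`. Fold
#' sizes differ by at most one and every fold inherits the full trait range.
#'
#' @param y trait vector.
#' @param k fold count (`2 <= k <= length(y)`).
#' @return object of class `fold_assignment` with `fold_of` (labels
#'   `1..k` per subject) and `k`.
#' @export
sorted_partition <- function(y, k) {
  n <- length(y)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("need 2 <= k <= n")
  ord <- order(y) # radix sort: stable in ties
  fold_of <- integer(n)
  fold_of[ord] <- rep_len(seq_len(k), n)
  structure(list(fold_of = fold_of, k = k), class = "fold_assignment")
}

#' Prediction metrics: Pearson R and mean squared error
#'
#' @param pred predicted values.
#' @param actual observed values (non-constant).
#' @return list with `R`, `MSE` and `flagged` (`TRUE` when `pred` was
#'   constant, in which case `R` is recorded as 0).
#' @export
evaluate_predictions <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("length mismatch")
  if (length(pred) < 3L) stop("need at least 3 pairs")
  if (max(actual) == min(actual)) stop("actual values are constant")
  flagged <- max(pred) == min(pred)
  R <- if (flagged) 0 else cor(pred, actual)
  list(R = R, MSE = mean((pred - actual)^2), flagged = flagged)
}

# Feature selection on a training split. `selection` is "baseline" (single
# full-training-sample screen at `alpha`) or a bootstrap_config (the config
# carries its own alpha and seed; resample streams are keyed by fold).
select_features <- function(X, y, selection, alpha = 0.05, fold = 0L) {
  if (identical(selection, "baseline"))
    return(spearman_screen(X, y, alpha)$sets)
  stopifnot(inherits(selection, "bootstrap_config"))
  snap <- stability_counts(X, y, selection$scheme, selection$bp,
                           nb_grid = selection$nb, alpha = selection$alpha,
                           seed = selection$seed, fold = fold)
  threshold_stability(snap[[as.character(selection$nb)]], selection$fp)
}

# Inner-CV hyperparameter tuning: sorted round-robin inner folds on the
# training subjects, candidates scored by mean inner-fold Pearson R
# (constant predictions score 0). Ties prefer the simpler model: the grid is
# walked from smallest C (SVR) / largest lambda (LASSO, ridge) and only a
# strictly larger mean R displaces the incumbent.
tune_penalized <- function(X, y, kind, inner_k = 5L, epsilon = 0.1) {
  grid <- if (kind == "svr") PAPER_C_GRID
          else sort(PAPER_LAMBDA_GRID, decreasing = TRUE)
  inner <- sorted_partition(y, inner_k)$fold_of
  scores <- matrix(NA_real_, length(grid), inner_k)
  for (f in seq_len(inner_k)) {
    te <- inner == f
    Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
    Xte <- X[te, , drop = FALSE];  yte <- y[te]
    if (sum(te) < 3L || max(yte) == min(yte)) next
    if (kind == "svr") {
      # one warm-started dual coordinate-descent path over the C grid
      st <- standardize_stats(Xtr)
      Xs <- sweep(sweep(Xtr, 2L, st$center), 2L, st$scale, "/")
      y_c <- mean(ytr); y_s <- sd(ytr); if (y_s == 0) y_s <- 1
      # looser solve for model selection; the chosen C is refit tightly
      path <- .svr_dual_cd_path(cbind(Xs, 1), (ytr - y_c) / y_s, grid,
                                epsilon, tol = 0.05, max_iter = 150L)
      Xts <- sweep(sweep(Xte, 2L, st$center), 2L, st$scale, "/")
      for (g in seq_along(grid)) {
        wg <- path$w[, g]
        pred <- y_c + y_s *
          (as.vector(Xts %*% wg[seq_len(ncol(Xts))]) + wg[ncol(Xts) + 1L])
        scores[g, f] <- evaluate_predictions(pred, yte)$R
      }
    } else if (kind == "lasso" && ncol(Xtr) == 1L) {
      for (g in seq_along(grid)) {
        m <- fit_penalized(Xtr, ytr, "lasso", lambda = grid[g])
        scores[g, f] <- evaluate_predictions(predict(m, Xte), yte)$R
      }
    } else if (kind == "lasso") {
      st <- standardize_stats(Xtr)
      Xs <- sweep(sweep(Xtr, 2L, st$center), 2L, st$scale, "/")
      lam_g <- grid / (2 * nrow(Xtr))
      fit <- glmnet::glmnet(Xs, ytr, alpha = 1, lambda = lam_g,
                            standardize = FALSE, thresh = 1e-9, maxit = 1e6)
      Xts <- sweep(sweep(Xte, 2L, st$center), 2L, st$scale, "/")
      preds <- predict(fit, Xts, s = lam_g)
      for (g in seq_along(grid))
        scores[g, f] <- evaluate_predictions(preds[, g], yte)$R
    } else { # ridge: one factorization pattern per fold, 16 solves
      st <- standardize_stats(Xtr)
      Xs <- sweep(sweep(Xtr, 2L, st$center), 2L, st$scale, "/")
      xc <- colMeans(Xs)
      Xc <- sweep(Xs, 2L, xc)
      A0 <- crossprod(Xc)
      Xty <- crossprod(Xc, ytr - mean(ytr))
      Xts <- sweep(sweep(Xte, 2L, st$center), 2L, st$scale, "/")
      for (g in seq_along(grid)) {
        beta <- as.vector(solve(A0 + diag(grid[g], ncol(Xs)), Xty))
        pred <- as.vector(sweep(Xts, 2L, xc) %*% beta) + mean(ytr)
        scores[g, f] <- evaluate_predictions(pred, yte)$R
      }
    }
  }
  mean_scores <- rowMeans(scores, na.rm = TRUE)
  mean_scores[is.nan(mean_scores)] <- -Inf
  best <- which.max(mean_scores) # first max: simplest model wins ties
  if (kind == "svr") list(C = grid[best], epsilon = epsilon)
  else list(lambda = grid[best])
}

# Fit one model kind on a training split given the selected sets, tune where
# needed, and predict the test split. Returns NULL on a degenerate fold
# (empty feature set or constant CPM summary).
fit_and_predict <- function(kind, Xtr, ytr, Xte, sets, inner_k,
                            epsilon = 0.1) {
  set_used <- switch(kind, cpm_p = sets$positive, cpm_n = sets$negative,
                     sets$combined)
  if (!length(set_used)) return(NULL)
  if (kind %in% c("cpm_p", "cpm_n")) {
    s <- cpm_summary(Xtr, set_used)
    if (max(s) == min(s)) return(NULL)
    model <- fit_cpm(Xtr, ytr, set_used, kind)
    hyper <- list()
  } else {
    Xsel <- Xtr[, set_used, drop = FALSE]
    hyper <- tune_penalized(Xsel, ytr, kind, inner_k, epsilon)
    model <- fit_penalized(Xsel, ytr, kind,
                           C = hyper$C %||% 1, lambda = hyper$lambda %||% 1,
                           epsilon = epsilon, features = set_used)
  }
  list(model = model, hyper = hyper, pred = predict(model, Xte))
}

# Assemble a prediction_result from per-fold pieces.
make_prediction_result <- function(kind, selection, per_fold, counts, k) {
  R <- vapply(per_fold, function(p) if (is.null(p)) NA_real_ else p$R,
              numeric(1))
  MSE <- vapply(per_fold, function(p) if (is.null(p)) NA_real_ else p$MSE,
                numeric(1))
  flagged <- vapply(per_fold, function(p) !is.null(p) && isTRUE(p$flagged),
                    logical(1))
  ok <- !is.na(R)
  if (!any(ok)) stop("all ", k, " folds failed for model '", kind, "'")
  structure(list(
    model = kind, selection = selection,
    per_fold_R = R, per_fold_MSE = MSE,
    mean_R = mean(R[ok]), mean_MSE = mean(MSE[ok]),
    per_fold_feature_count = counts,
    hyperparams_chosen = lapply(per_fold, function(p) p$hyper),
    selected_sets = lapply(per_fold, function(p) p$sets),
    flagged_constant = flagged,
    failed_folds = which(!ok), k = k), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  sel <- if (identical(x$selection, "baseline")) "baseline"
         else paste0(x$selection$scheme, " NB=", x$selection$nb,
                     if (!is.na(x$selection$bp))
                       paste0(" BP=", x$selection$bp) else "",
                     " FP=", x$selection$fp)
  cat("prediction_result [", x$model, ", ", sel, "]: mean R = ",
      round(x$mean_R, 4), ", mean MSE = ", round(x$mean_MSE, 4),
      " over ", x$k - length(x$failed_folds), "/", x$k, " folds\n", sep = "")
  invisible(x)
}

#' Run the nested cross-validation for one selection method
#'
#' For each outer fold: select features on the nine training folds (baseline
#' screen or bootstrap-stability selection), route the positive set to CPM-P,
#' the negative set to CPM-N and the combined set to SVR/LASSO/ridge, tune C
#' or lambda by inner sorted 5-fold CV on the training folds, refit on the
#' full training folds and predict the held-out fold. R and MSE are averaged
#' over non-degenerate folds. The whole procedure is deterministic given the
#' selection config (its seed drives the resample streams).
#'
#' @param dataset a [connectome_dataset()] or feature matrix.
#' @param trait trait name or numeric vector.
#' @param selection `"baseline"` or a [bootstrap_config()].
#' @param models character vector from `cpm_p, cpm_n, svr, lasso, ridge`.
#' @param k outer fold count (default 10).
#' @param inner_k inner fold count for hyperparameter tuning (default 5).
#' @param alpha baseline screening level (a bootstrap config carries its own).
#' @param epsilon SVR tube width on the standardized target.
#' @param folds optional precomputed [sorted_partition()]; by default the
#'   partition is built from the full trait vector once, so all selection
#'   methods compared on this dataset share identical folds.
#' @return a `prediction_result` for a single model, or a named list of them.
#' @export
run_cv <- function(dataset, trait, selection = "baseline",
                   models = "ridge", k = 10L, inner_k = 5L, alpha = 0.05,
                   epsilon = 0.1, folds = NULL) {
  xy <- resolve_features_trait(dataset, trait)
  X <- xy$X; y <- xy$y
  models <- match.arg(models, MODEL_KINDS, several.ok = TRUE)
  folds <- folds %||% sorted_partition(y, k)
  stopifnot(inherits(folds, "fold_assignment"))
  k <- folds$k
  fold_of <- folds$fold_of

  per_fold <- lapply(models, function(m) vector("list", k))
  names(per_fold) <- models
  counts <- matrix(0L, k, 3L,
                   dimnames = list(NULL, c("positive", "negative", "combined")))
  for (f in seq_len(k)) {
    te <- fold_of == f
    Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
    Xte <- X[te, , drop = FALSE];  yte <- y[te]
    sets <- select_features(Xtr, ytr, selection, alpha, fold = f)
    counts[f, ] <- c(length(sets$positive), length(sets$negative),
                     length(sets$combined))
    for (m in models) {
      fp <- fit_and_predict(m, Xtr, ytr, Xte, sets, inner_k, epsilon)
      if (is.null(fp)) next
      ev <- evaluate_predictions(fp$pred, yte)
      per_fold[[m]][[f]] <- list(R = ev$R, MSE = ev$MSE,
                                 flagged = ev$flagged, hyper = fp$hyper,
                                 sets = sets)
    }
  }
  out <- lapply(models, function(m)
    make_prediction_result(m, selection, per_fold[[m]], counts, k))
  names(out) <- models
  if (length(models) == 1L) out[[1L]] else out
}
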