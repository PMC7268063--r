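# Grid search over the resampling parameters, feature-dimension accounting,
# and the discovery-to-validation transfer protocol.

NB_GRID <- c(10L, 20L, 50L, 100L, 500L, 1000L)
BP_GRID <- c(0.25, 0.5, 0.6, 0.7, 0.8)
FP_GRID <- c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)

#' Enumerate a bootstrap parameter grid
#'
#' The full protocol grid is NB x FP x BP = 6 x 6 x 5 = 180 combinations
#' without replacement and NB x FP = 36 with replacement (216 in total).
#'
#' @param scheme resampling scheme.
#' @param nb_grid,bp_grid,fp_grid parameter levels (defaults are the protocol
#'   grids; `bp_grid` is ignored with replacement).
#' @return data.frame with columns `scheme`, `nb`, `bp`, `fp`.
#' @export
param_grid <- function(scheme = c("without_replacement", "with_replacement"),
                       nb_grid = NB_GRID, bp_grid = BP_GRID,
                       fp_grid = FP_GRID) {
  scheme <- match.arg(scheme)
  if (scheme == "with_replacement") bp_grid <- NA_real_
  g <- expand.grid(fp = fp_grid, nb = nb_grid, bp = bp_grid,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(scheme = scheme, nb = as.integer(g$nb), bp = g$bp, fp = g$fp,
             stringsAsFactors = FALSE)
}

config_label <- function(scheme, nb, bp, fp) {
  paste0(scheme, "_nb", nb,
         ifelse(is.na(bp), "", paste0("_bp", bp)), "_fp", fp)
}

#' Grid search over bootstrap parameters inside the outer CV
#'
#' Runs the nested CV of [run_cv()] for every (NB, BP, FP) cell of the grid,
#' on outer folds fixed once from the full trait vector so every cell and
#' the baseline are compared on identical partitions. Within each outer fold
#' the per-resample screens are shared across the grid: resample `b` is the
#' same for every NB (streams are keyed by `(seed, fold, b)`), frequencies
#' are snapshot at each NB and thresholded at each FP, and identical feature
#' sets reuse cached model fits.
#'
#' @inheritParams run_cv
#' @param scheme resampling scheme.
#' @param nb_grid,bp_grid,fp_grid parameter levels (protocol defaults).
#' @param seed seed for the resample streams.
#' @param include_baseline also evaluate the single full-training-sample
#'   screen under the label `"baseline"` (default `TRUE`).
#' @param verbose emit per-fold progress to `stderr`.
#' @return object of class `grid_result`: `table` (one row per config x
#'   model), `results` (config label -> model -> `prediction_result`),
#'   `best` (per model, the config with the largest mean R; ties prefer
#'   smallest NB, then largest FP, then smallest BP), `baseline`.
#' @export
grid_search <- function(dataset, trait, models = "ridge",
                        scheme = c("without_replacement", "with_replacement"),
                        nb_grid = NB_GRID, bp_grid = BP_GRID,
                        fp_grid = FP_GRID, k = 10L, inner_k = 5L,
                        alpha = 0.05, epsilon = 0.1, seed = 1L,
                        include_baseline = TRUE, verbose = FALSE) {
  scheme <- match.arg(scheme)
  xy <- resolve_features_trait(dataset, trait)
  X <- xy$X; y <- xy$y
  models <- match.arg(models, MODEL_KINDS, several.ok = TRUE)
  folds <- sorted_partition(y, k)
  fold_of <- folds$fold_of
  k <- folds$k
  nb_grid <- sort(unique(as.integer(nb_grid)))
  fp_grid <- sort(unique(fp_grid))
  bp_levels <- if (scheme == "with_replacement") NA_real_
               else sort(unique(bp_grid))
  grid <- param_grid(scheme, nb_grid,
                     if (scheme == "with_replacement") NULL else bp_levels,
                     fp_grid)
  labels <- config_label(grid$scheme, grid$nb, grid$bp, grid$fp)
  n_cfg <- nrow(grid)

  slots <- c(labels, if (include_baseline) "baseline")
  per_fold <- lapply(slots, function(l)
    lapply(models, function(m) vector("list", k)))
  names(per_fold) <- slots
  counts <- lapply(slots, function(l) matrix(0L, k, 3L,
    dimnames = list(NULL, c("positive", "negative", "combined"))))
  names(counts) <- slots

  t0 <- proc.time()[3L]
  for (f in seq_len(k)) {
    te <- fold_of == f
    Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
    Xte <- X[te, , drop = FALSE];  yte <- y[te]
    cache <- new.env(parent = emptyenv())
    eval_sets <- function(label, sets) {
      counts[[label]][f, ] <<- c(length(sets$positive),
                                 length(sets$negative),
                                 length(sets$combined))
      for (m in models) {
        set_used <- switch(m, cpm_p = sets$positive, cpm_n = sets$negative,
                           sets$combined)
        key <- paste(m, paste(set_used, collapse = ","), sep = ":")
        hit <- get0(key, envir = cache, inherits = FALSE)
        if (is.null(hit)) {
          fp_res <- fit_and_predict(m, Xtr, ytr, Xte, sets, inner_k, epsilon)
          hit <- if (is.null(fp_res)) list(failed = TRUE)
                 else c(fp_res, list(failed = FALSE))
          assign(key, hit, envir = cache)
        }
        if (hit$failed) next
        ev <- evaluate_predictions(hit$pred, yte)
        per_fold[[label]][[m]][[f]] <<- list(R = ev$R, MSE = ev$MSE,
                                             flagged = ev$flagged,
                                             hyper = hit$hyper, sets = sets)
      }
    }
    for (bp in bp_levels) {
      snaps <- stability_counts(Xtr, ytr, scheme, bp, nb_grid, alpha,
                                seed = seed, fold = f)
      for (nb in nb_grid) for (fp in fp_grid)
        eval_sets(config_label(scheme, nb, bp, fp),
                  threshold_stability(snaps[[as.character(nb)]], fp))
    }
    if (include_baseline)
      eval_sets("baseline", spearman_screen(Xtr, ytr, alpha)$sets)
    if (verbose)
      message(sprintf("fold %d/%d done (%.1fs elapsed)", f, k,
                      proc.time()[3L] - t0))
  }

  results <- lapply(seq_len(n_cfg), function(ci) {
    sel <- bootstrap_config(scheme, nb = grid$nb[ci],
                            bp = if (is.na(grid$bp[ci])) NULL else grid$bp[ci],
                            fp = grid$fp[ci], alpha = alpha, seed = seed)
    out <- lapply(models, function(m)
      make_prediction_result(m, sel, per_fold[[labels[ci]]][[m]],
                             counts[[labels[ci]]], k))
    names(out) <- models
    out
  })
  names(results) <- labels
  baseline <- NULL
  if (include_baseline) {
    baseline <- lapply(models, function(m)
      make_prediction_result(m, "baseline", per_fold[["baseline"]][[m]],
                             counts[["baseline"]], k))
    names(baseline) <- models
  }

  tab <- do.call(rbind, lapply(seq_len(n_cfg), function(ci) {
    do.call(rbind, lapply(models, function(m) {
      r <- results[[ci]][[m]]
      data.frame(config = labels[ci], scheme = scheme, nb = grid$nb[ci],
                 bp = grid$bp[ci], fp = grid$fp[ci], model = m,
                 mean_R = r$mean_R, mean_MSE = r$mean_MSE,
                 mean_combined = mean(r$per_fold_feature_count[, "combined"]),
                 mean_positive = mean(r$per_fold_feature_count[, "positive"]),
                 mean_negative = mean(r$per_fold_feature_count[, "negative"]),
                 n_failed_folds = length(r$failed_folds),
                 stringsAsFactors = FALSE)
    }))
  }))

  best <- lapply(models, function(m) {
    tm <- tab[tab$model == m, ]
    ord <- order(-tm$mean_R, tm$nb, -tm$fp, tm$bp)
    top <- tm[ord[1L], ]
    list(config = results[[top$config]][[m]]$selection,
         result = results[[top$config]][[m]])
  })
  names(best) <- models

  structure(list(table = tab, results = results, best = best,
                 baseline = baseline, folds = folds, scheme = scheme),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("grid_result: ", length(x$results), " configs (", x$scheme, ") x ",
      length(x$best), " model(s)\n", sep = "")
  for (m in names(x$best)) {
    b <- x$best[[m]]
    cat("  best ", m, ": NB=", b$config$nb,
        if (!is.na(b$config$bp)) paste0(" BP=", b$config$bp) else "",
        " FP=", b$config$fp, " (mean R = ", round(b$result$mean_R, 4), ")",
        if (!is.null(x$baseline))
          paste0(" vs baseline ", round(x$baseline[[m]]$mean_R, 4)),
        "\n", sep = "")
  }
  invisible(x)
}

#' Feature-dimension accounting across traits
#'
#' For each trait and method, the selected-feature count is averaged over
#' the outer folds; the cross-trait mean summarizes each method's effective
#' dimensionality the way the reference protocol reports it.
#'
#' @param results named list: trait -> named list: method ->
#'   `prediction_result`.
#' @param set_type which count to report: `"combined"`, `"positive"` or
#'   `"negative"`.
#' @return list with `per_trait` (data.frame trait x method) and
#'   `cross_trait_mean` (named numeric, one entry per method).
#' @export
feature_dimension_report <- function(results, set_type = "combined") {
  set_type <- match.arg(set_type, c("combined", "positive", "negative"))
  traits <- names(results)
  methods <- names(results[[1L]])
  per <- sapply(methods, function(m) vapply(traits, function(tr)
    mean(results[[tr]][[m]]$per_fold_feature_count[, set_type]),
    numeric(1)))
  per <- matrix(per, nrow = length(traits),
                dimnames = list(traits, methods))
  list(per_trait = as.data.frame(per),
       cross_trait_mean = colMeans(per))
}

#' Default configuration list for external validation
#'
#' The eight predefined without-replacement combinations used for the
#' discovery-to-validation transfer: NB in \{50, 100\}, BP in \{0.7, 0.8\},
#' FP in \{0.8, 0.9\}.
#'
#' @param alpha screening level; @param seed resample-stream seed.
#' @return list of [bootstrap_config()]s, length 8.
#' @export
validation_configs <- function(alpha = 0.05, seed = 1L) {
  g <- expand.grid(fp = c(0.8, 0.9), bp = c(0.7, 0.8), nb = c(50L, 100L))
  lapply(seq_len(nrow(g)), function(i)
    bootstrap_config("without_replacement", nb = g$nb[i], bp = g$bp[i],
                     fp = g$fp[i], alpha = alpha, seed = seed))
}

#' Discovery-to-validation transfer
#'
#' For each configuration: features are selected on the entire training
#' (discovery) dataset, hyperparameters tuned by inner sorted 5-fold CV on
#' that dataset, the model fitted once on all training subjects and applied
#' to the held-out validation dataset. Per-model performance is also
#' averaged across the configurations, mirroring how the transfer protocol
#' aggregates its predefined parameter settings.
#'
#' @param train_dataset,test_dataset [connectome_dataset()]s (or matrices)
#'   with identical edge dimensionality.
#' @param trait trait name (present in both datasets) or a list with
#'   elements `train` and `test` holding numeric vectors.
#' @param configs list of [bootstrap_config()]s and/or the string
#'   `"baseline"`; defaults to [validation_configs()] plus `"baseline"`.
#' @param models model kinds to fit.
#' @param inner_k inner fold count; @param alpha baseline screening level;
#'   @param epsilon SVR tube width.
#' @return list with `table` (data.frame: config x model R/MSE and feature
#'   counts) and `mean_over_configs` (data.frame: model, mean R/MSE across
#'   the bootstrap configs).
#' @export
external_validate <- function(train_dataset, test_dataset, trait,
                              configs = NULL, models = "ridge",
                              inner_k = 5L, alpha = 0.05, epsilon = 0.1) {
  tr <- if (is.list(trait) && !is.character(trait))
    list(train = trait$train, test = trait$test)
  else list(train = trait, test = trait)
  xy_tr <- resolve_features_trait(train_dataset, tr$train)
  xy_te <- resolve_features_trait(test_dataset, tr$test)
  if (ncol(xy_tr$X) != ncol(xy_te$X))
    stop("edge dimensionality mismatch: ", ncol(xy_tr$X), " vs ",
         ncol(xy_te$X))
  models <- match.arg(models, MODEL_KINDS, several.ok = TRUE)
  configs <- configs %||% c(list("baseline"), validation_configs(alpha))

  rows <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    label <- if (identical(cfg, "baseline")) "baseline"
             else config_label(cfg$scheme, cfg$nb, cfg$bp, cfg$fp)
    sets <- select_features(xy_tr$X, xy_tr$y, cfg, alpha, fold = 0L)
    for (m in models) {
      fp_res <- fit_and_predict(m, xy_tr$X, xy_tr$y, xy_te$X, sets,
                                inner_k, epsilon)
      if (is.null(fp_res)) {
        rows[[length(rows) + 1L]] <- data.frame(
          config = label, model = m, R = NA_real_, MSE = NA_real_,
          n_features = 0L, failed = TRUE, stringsAsFactors = FALSE)
        next
      }
      ev <- evaluate_predictions(fp_res$pred, xy_te$y)
      nf <- length(switch(m, cpm_p = sets$positive, cpm_n = sets$negative,
                          sets$combined))
      rows[[length(rows) + 1L]] <- data.frame(
        config = label, model = m, R = ev$R, MSE = ev$MSE,
        n_features = nf, failed = FALSE, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  boot <- tab[tab$config != "baseline" & !tab$failed, ]
  mean_over <- if (nrow(boot)) {
    agg <- aggregate(cbind(R, MSE) ~ model, data = boot, FUN = mean)
    names(agg) <- c("model", "mean_R", "mean_MSE")
    agg
  } else NULL
  list(table = tab, mean_over_configs = mean_over)
}
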