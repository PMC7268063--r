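# The four downstream regression models. CPM summarizes the selected edges
# into a single network-strength score and fits a univariate OLS; SVR, LASSO
# and ridge are multivariate fits on the combined edge set. Penalized models
# operate on features standardized with training statistics; the stored
# coefficients are always mapped back to the raw edge scale so prediction is
# plainly affine: y-hat = intercept + X[, features] %*% beta.

PAPER_C_GRID <- 2^(-5:10)      # SVR penalty C
PAPER_LAMBDA_GRID <- 2^(-10:5) # LASSO / ridge penalty lambda

#' Hyperparameter grids used by the tuning protocol
#'
#' @return list with `C` (SVR, 2^-5 .. 2^10) and `lambda`
#'   (LASSO/ridge, 2^-10 .. 2^5).
#' @export
hyperparameter_grids <- function() {
  list(C = PAPER_C_GRID, lambda = PAPER_LAMBDA_GRID)
}

#' CPM network-strength summary
#'
#' Per-subject sum of edge weights over a selected edge set (positive and
#' negative sets are summarized separately by the caller). The sum, rather
#' than the mean, is used; for a fixed set the two differ by a constant
#' factor absorbed by the regression slope.
#'
#' @param dataset a [connectome_dataset()] or feature matrix.
#' @param feature_set nonempty integer vector of edge indices.
#' @return numeric vector, one summary score per subject.
#' @export
cpm_summary <- function(dataset, feature_set) {
  X <- if (inherits(dataset, "connectome_dataset")) dataset$features
       else as.matrix(dataset)
  if (!length(feature_set))
    stop("degenerate CPM model: empty feature set")
  rowSums(X[, feature_set, drop = FALSE])
}

#' Univariate CPM regression
#'
#' Ordinary least squares of the trait on the network-strength summary.
#'
#' @param summary_score numeric vector from [cpm_summary()].
#' @param y trait values.
#' @return list with `beta` (slope) and `intercept`.
#' @export
cpm_fit <- function(summary_score, y) {
  if (length(summary_score) != length(y)) stop("length mismatch")
  if (length(y) < 3L) stop("need at least 3 observations")
  if (max(summary_score) == min(summary_score))
    stop("degenerate CPM model: constant summary score")
  fit <- stats::lm.fit(cbind(1, summary_score), y)
  list(beta = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]))
}

# Column means/sds for training-fold standardization; zero-variance columns
# get scale 1 (their centered values are all zero, so they carry nothing).
standardize_stats <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

#' Fit a penalized linear model on a feature matrix
#'
#' Fits the stated objective for the chosen model on features standardized
#' to training mean 0 / sd 1, with an unpenalized intercept, and returns
#' coefficients mapped back to the raw feature scale:
#' \describe{
#'   \item{ridge}{`min RSS + lambda * sum(beta^2)`, solved exactly by the
#'     penalized normal equations on centered data.}
#'   \item{lasso}{`min RSS + lambda * sum(|beta|)` via \pkg{glmnet}
#'     (`alpha = 1`, `lambda_glmnet = lambda / (2n)`).}
#'   \item{svr}{epsilon-insensitive linear SVR
#'     `min 0.5*||beta||^2 + C * sum(xi + xi-hat)` by dual coordinate
#'     descent (the liblinear algorithm), which stays fast across the whole
#'     C grid; the target is additionally standardized so the tube width
#'     `epsilon` (default 0.1) is on the standardized-trait scale. The
#'     intercept rides on an appended constant feature; with a centered
#'     target its own ridge term is negligible.}
#' }
#'
#' @param X numeric matrix restricted to the feature set in use.
#' @param y trait values.
#' @param kind `"svr"`, `"lasso"` or `"ridge"`.
#' @param C SVR penalty (ignored otherwise).
#' @param lambda LASSO/ridge penalty on the scale of the objectives above.
#' @param epsilon SVR tube width on the standardized target (default 0.1).
#' @param features optional edge indices the columns of `X` refer to
#'   (defaults to `1:ncol(X)`); stored for prediction-time slicing.
#' @return object of class `fitted_model` with `kind`, `features`, `beta`
#'   (raw scale), `intercept`, `standardization` and `hyperparams`.
#' @export
fit_penalized <- function(X, y, kind = c("svr", "lasso", "ridge"),
                          C = 1, lambda = 1, epsilon = 0.1,
                          features = NULL) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (nrow(X) < 5L) stop("need at least 5 training subjects")
  if (!ncol(X)) stop("degenerate model: empty feature matrix")
  features <- features %||% seq_len(ncol(X))
  st <- standardize_stats(X)
  Xs <- sweep(sweep(X, 2L, st$center), 2L, st$scale, "/")
  n <- nrow(X)

  if (kind == "ridge") {
    b_std <- ridge_normal_equations(Xs, y, lambda)
    beta <- b_std$beta / st$scale
    intercept <- b_std$intercept - sum(beta * st$center)
    hyper <- list(lambda = lambda)
  } else if (kind == "lasso") {
    if (ncol(Xs) == 1L) {
      # univariate soft threshold (glmnet requires >= 2 columns)
      xc <- Xs[, 1L] - mean(Xs[, 1L])
      yc0 <- y - mean(y)
      num <- sum(xc * yc0)
      den <- sum(xc^2)
      b_std <- if (den <= 0) 0
               else sign(num) * max(0, abs(num) - lambda / 2) / den
      a0 <- mean(y) - b_std * mean(Xs[, 1L])
      beta <- b_std / st$scale
      intercept <- a0 - sum(beta * st$center)
    } else {
      lam_g <- lambda / (2 * n)
      path <- sort(unique(c(lam_g, lam_g * c(64, 16, 4))), decreasing = TRUE)
      fit <- glmnet::glmnet(Xs, y, alpha = 1, lambda = path,
                            standardize = FALSE, thresh = 1e-10,
                            maxit = 1e6)
      cf <- as.vector(coef(fit, s = lam_g))
      beta <- cf[-1L] / st$scale
      intercept <- cf[1L] - sum(beta * st$center)
    }
    hyper <- list(lambda = lambda)
  } else { # svr
    y_c <- mean(y)
    y_s <- sd(y)
    if (y_s == 0) y_s <- 1
    ys <- (y - y_c) / y_s
    fit <- .svr_dual_cd_path(cbind(Xs, 1), ys, C, epsilon,
                             tol = 1e-3, max_iter = 1000L)
    w <- fit$w[seq_len(ncol(Xs)), 1L] # weights on standardized X
    beta <- y_s * w / st$scale
    intercept <- y_c + y_s * fit$w[ncol(Xs) + 1L, 1L] - sum(beta * st$center)
    hyper <- list(C = C, epsilon = epsilon)
  }
  structure(list(kind = kind, features = as.integer(features),
                 beta = as.numeric(beta), intercept = as.numeric(intercept),
                 standardization = st, hyperparams = hyper),
            class = "fitted_model")
}

# Exact ridge on already-standardized X: centered normal equations with an
# unpenalized intercept. lambda = 0 reduces to OLS (requires full rank).
ridge_normal_equations <- function(Xs, y, lambda) {
  p <- ncol(Xs)
  xc <- colMeans(Xs)
  Xc <- sweep(Xs, 2L, xc)
  yc <- y - mean(y)
  A <- crossprod(Xc) + diag(lambda, p)
  beta <- tryCatch(solve(A, crossprod(Xc, yc)),
                   error = function(e)
                     stop("ridge solve failed (lambda = ", lambda, "): ",
                          conditionMessage(e)))
  beta <- as.vector(beta)
  list(beta = beta, intercept = mean(y) - sum(beta * xc))
}

#' Fit a CPM model as a `fitted_model`
#'
#' Wraps [cpm_summary()] + [cpm_fit()] into the common model container, so
#' CPM-P (positive set) and CPM-N (negative set) share the prediction
#' interface of the penalized models.
#'
#' @param X training feature matrix (all edges).
#' @param y trait values.
#' @param feature_set edge indices to summarize (the positive set for CPM-P,
#'   the negative set for CPM-N).
#' @param kind `"cpm_p"` or `"cpm_n"` (a label; the computation is identical).
#' @return a `fitted_model` whose `beta` is the single slope on the summary.
#' @export
fit_cpm <- function(X, y, feature_set, kind = c("cpm_p", "cpm_n")) {
  kind <- match.arg(kind)
  s <- cpm_summary(X, feature_set)
  fit <- cpm_fit(s, y)
  structure(list(kind = kind, features = as.integer(feature_set),
                 beta = fit$beta, intercept = fit$intercept,
                 standardization = NULL, hyperparams = list()),
            class = "fitted_model")
}

#' Predict from a fitted model
#'
#' CPM kinds first reduce the test subjects to their network-strength
#' summary; all kinds then apply the stored affine map.
#'
#' @param object a `fitted_model`.
#' @param newdata feature matrix over all edges, or a [connectome_dataset()].
#' @param ... unused.
#' @return numeric vector of predicted trait values.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "connectome_dataset")) newdata$features
       else as.matrix(newdata)
  if (max(object$features) > ncol(X))
    stop("feature-set mismatch: model uses edge ", max(object$features),
         " but newdata has ", ncol(X), " columns")
  if (object$kind %in% c("cpm_p", "cpm_n")) {
    s <- cpm_summary(X, object$features)
    return(object$intercept + object$beta * s)
  }
  as.vector(X[, object$features, drop = FALSE] %*% object$beta) +
    object$intercept
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("fitted_model [", x$kind, "] on ", length(x$features),
      " feature(s)\n", sep = "")
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Captures kind, feature indices, coefficients, intercept, standardization
#' constants and hyperparameters, so a model fitted on a discovery cohort
#' can be shipped and applied to a validation cohort.
#'
#' @param model a `fitted_model`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
serialize_model <- function(model, path = NULL) {
  obj <- list(kind = model$kind, features = model$features,
              beta = model$beta, intercept = model$intercept,
              standardization = model$standardization,
              hyperparams = model$hyperparams)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore a fitted model from JSON
#'
#' @param path file path or JSON string produced by [serialize_model()].
#' @return a `fitted_model`.
#' @export
deserialize_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(kind = obj$kind, features = as.integer(obj$features),
                 beta = as.numeric(obj$beta),
                 intercept = as.numeric(obj$intercept),
                 standardization = obj$standardization,
                 hyperparams = as.list(obj$hyperparams)),
            class = "fitted_model")
}
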