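# Spearman screening: every edge is rank-correlated against the trait and
# split by sign at a significance level alpha. The heavy loop (midranks for
# every column) lives in src/spearman_rank.cpp.

#' Spearman rank correlation
#'
#' Pearson correlation of the midrank vectors (ties receive average ranks).
#' If either argument has zero variance after ranking, the coefficient is
#' defined as 0 and flagged degenerate.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return the correlation; attribute `degenerate` is `TRUE` when a zero
#'   variance input forced the 0 convention.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  res <- .spearman_rho_matrix(matrix(as.double(x), ncol = 1L), as.double(y))
  structure(res$rho[1L], degenerate = res$degenerate[1L])
}

#' Two-sided p-value for a Spearman coefficient
#'
#' Uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom; `|rho| = 1` maps to `p = 0`. Adequate for
#' screening at the coarse .05 level with the sample sizes used here; the
#' test suite keeps a permutation oracle against it.
#'
#' @param rho coefficient(s) in `[-1, 1]`.
#' @param n sample size, `n >= 4`.
#' @return p-value(s) in `[0, 1]`.
#' @export
spearman_pvalue <- function(rho, n) {
  if (n < 4L) stop("insufficient sample: need n >= 4")
  if (any(abs(rho) > 1 + 1e-12)) stop("|rho| must be <= 1")
  rho <- pmin(1, pmax(-1, rho))
  p <- numeric(length(rho))
  exact <- abs(rho) >= 1
  p[exact] <- 0
  tt <- rho[!exact] * sqrt((n - 2) / (1 - rho[!exact]^2))
  p[!exact] <- 2 * pt(-abs(tt), df = n - 2)
  p
}

# Internal workhorse: rho, p and degeneracy flags for every column of X
# against y. Degenerate (zero-variance) columns get rho = 0, p = 1.
screen_matrix <- function(X, y, alpha = 0.05) {
  n <- nrow(X)
  if (n < 4L) stop("insufficient sample: need n >= 4 subjects")
  res <- .spearman_rho_matrix(X, as.double(y))
  rho <- res$rho
  pval <- spearman_pvalue(rho, n)
  pval[res$degenerate] <- 1
  rho[res$degenerate] <- 0
  list(rho = rho, pval = pval, degenerate = res$degenerate, n = n,
       alpha = alpha)
}

#' Assemble positive/negative/combined feature sets
#'
#' @param positive,negative integer index vectors over edges; they must be
#'   disjoint. `combined` is their union.
#' @return object of class `feature_sets`.
#' @export
feature_sets <- function(positive = integer(), negative = integer()) {
  positive <- sort(unique(as.integer(positive)))
  negative <- sort(unique(as.integer(negative)))
  if (length(intersect(positive, negative)))
    stop("positive and negative sets must be disjoint")
  structure(list(positive = positive, negative = negative,
                 combined = sort(union(positive, negative))),
            class = "feature_sets")
}

#' @export
print.feature_sets <- function(x, ...) {
  cat("feature_sets: ", length(x$positive), " positive, ",
      length(x$negative), " negative, ", length(x$combined),
      " combined\n", sep = "")
  invisible(x)
}

#' Baseline Spearman screen of a connectome dataset
#'
#' Correlates every edge with the trait over all subjects and partitions the
#' significant edges (two-sided p strictly below `alpha`) by the sign of rho
#' into positive, negative and combined sets. This single full-sample screen
#' is the baseline that the bootstrap-stability methods refine.
#'
#' @param dataset a [connectome_dataset()], or a numeric feature matrix.
#' @param trait trait name (when `dataset` carries traits) or a numeric
#'   vector aligned with the rows.
#' @param alpha significance level (default 0.05).
#' @return list with `result` (class `edge_screen`: `rho`, `pval`, `alpha`,
#'   `n`) and `sets` (a [feature_sets()]).
#' @export
spearman_screen <- function(dataset, trait, alpha = 0.05) {
  xy <- resolve_features_trait(dataset, trait)
  sc <- screen_matrix(xy$X, xy$y, alpha)
  sig <- sc$pval < alpha
  sets <- feature_sets(positive = which(sig & sc$rho > 0),
                       negative = which(sig & sc$rho < 0))
  result <- structure(list(rho = sc$rho, pval = sc$pval, alpha = alpha,
                           n = sc$n, degenerate = sc$degenerate),
                      class = "edge_screen")
  list(result = result, sets = sets)
}

#' @export
print.edge_screen <- function(x, ...) {
  cat("edge_screen over ", length(x$rho), " edges (n = ", x$n,
      ", alpha = ", x$alpha, "): ", sum(x$pval < x$alpha),
      " significant\n", sep = "")
  invisible(x)
}

#' Export an edge screen as a data frame
#'
#' One row per edge with node labels (when the parcellation is known), rho,
#' p-value and the significance sign at `alpha`; suitable for `write.csv`.
#'
#' @param screen an `edge_screen` from [spearman_screen()].
#' @param edge_index optional two-column node-pair matrix.
#' @return data.frame with columns `edge`, `node_i`, `node_j`, `rho`,
#'   `pval`, `sign`.
#' @export
screen_table <- function(screen, edge_index = NULL) {
  sig <- screen$pval < screen$alpha
  sgn <- ifelse(!sig, "ns", ifelse(screen$rho > 0, "positive", "negative"))
  out <- data.frame(edge = seq_along(screen$rho),
                    node_i = NA_integer_, node_j = NA_integer_,
                    rho = screen$rho, pval = screen$pval, sign = sgn)
  if (!is.null(edge_index)) {
    out$node_i <- edge_index[, 1L]
    out$node_j <- edge_index[, 2L]
  }
  out
}

# Accept either (connectome_dataset, trait name/vector) or (matrix, vector).
resolve_features_trait <- function(dataset, trait) {
  if (inherits(dataset, "connectome_dataset")) {
    X <- dataset$features
    if (is.character(trait)) {
      if (!trait %in% names(dataset$traits))
        stop("trait '", trait, "' not attached to the dataset")
      y <- dataset$traits[[trait]]
    } else y <- as.numeric(trait)
  } else {
    X <- as.matrix(dataset)
    y <- as.numeric(trait)
  }
  if (length(y) != nrow(X))
    stop("trait length (", length(y), ") does not match subject count (",
         nrow(X), ")")
  if (anyNA(y))
    stop("trait has missing values; use attach_traits() to drop them first")
  list(X = X, y = y)
}
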