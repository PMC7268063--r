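# Bootstrap-stability feature selection: repeat the Spearman screen over
# resampled subject sets and keep edges that are significant, with a
# consistent sign, in at least a fraction FP of the resamples.

#' Bootstrap selection configuration
#'
#' @param scheme `"without_replacement"` (subsamples of `floor(bp * n)`
#'   distinct subjects) or `"with_replacement"` (classic bootstrap resamples
#'   of size `n`; `bp` is ignored).
#' @param nb number of resamples (NB). Grid used in the reference protocol:
#'   10, 20, 50, 100, 500, 1000.
#' @param bp bootstrap percentage in (0, 1]: fraction of subjects per
#'   without-replacement resample (protocol grid 0.25, 0.5, 0.6, 0.7, 0.8).
#' @param fp frequency-percentage stability threshold in (0, 1]: an edge must
#'   be significant in at least `fp` of the resamples (protocol grid 0.5 to
#'   1.0). The comparison is inclusive so that `fp = 1` is attainable.
#' @param alpha per-resample screening level (default 0.05).
#' @param seed integer seed; per-resample streams are derived from it so that
#'   increasing `nb` extends, rather than reshuffles, the resample sequence.
#' @return object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(scheme = c("without_replacement",
                                        "with_replacement"),
                             nb, bp = NULL, fp, alpha = 0.05, seed = 1L) {
  scheme <- match.arg(scheme)
  nb <- as.integer(nb)
  if (nb < 1L) stop("nb must be >= 1")
  if (scheme == "without_replacement") {
    if (is.null(bp)) stop("bp is required without replacement")
    if (bp <= 0 || bp > 1) stop("bp must be in (0, 1]")
  } else bp <- NA_real_
  if (fp <= 0 || fp > 1) stop("fp must be in (0, 1]")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  structure(list(scheme = scheme, nb = nb, bp = bp, fp = fp,
                 alpha = alpha, seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' @export
print.bootstrap_config <- function(x, ...) {
  cat("bootstrap_config: ", x$scheme, ", NB = ", x$nb,
      if (x$scheme == "without_replacement") paste0(", BP = ", x$bp) else "",
      ", FP = ", x$fp, ", alpha = ", x$alpha, ", seed = ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Draw a without-replacement subsample
#'
#' `floor(bp * n)` distinct subject indices, uniformly without replacement,
#' from the current RNG stream.
#'
#' @param n subject count (`n >= 4`).
#' @param bp fraction in (0, 1].
#' @return integer vector of distinct indices in `1:n`.
#' @export
draw_subsample <- function(n, bp) {
  m <- floor(bp * n)
  if (m < 4L) stop("subsample size floor(bp * n) = ", m,
                   " is too small to screen (need >= 4)")
  sample.int(n, size = m, replace = FALSE)
}

#' Draw a with-replacement bootstrap resample
#'
#' `n` indices drawn iid uniformly with replacement from `1:n`; duplicates
#' are expected and are treated as genuine repeated observations downstream.
#'
#' @param n subject count.
#' @return integer vector of length `n`.
#' @export
draw_bootstrap <- function(n) {
  sample.int(n, size = n, replace = TRUE)
}

# Critical |rho| for the two-sided t screen: p < alpha  <=>  |rho| > r_crit.
critical_rho <- function(alpha, m) {
  if (alpha <= 0) return(Inf)
  if (alpha >= 1) return(-1) # every non-degenerate edge passes
  tcrit <- stats::qt(1 - alpha / 2, df = m - 2)
  tcrit / sqrt(m - 2 + tcrit^2)
}

# Shared engine: run the per-resample screen for b = 1..max(nb_grid) and
# snapshot sign-specific selection counts at every NB in nb_grid. Each
# resample b uses the stream derived from (seed, fold, b), so a run at a
# single NB reproduces the prefix of a longer run. Edge ranks within a
# resample are obtained by scanning per-column sort orders computed once,
# which keeps the per-resample cost linear in the training size.
stability_counts <- function(X, y, scheme, bp, nb_grid, alpha, seed,
                             fold = 0L) {
  nb_grid <- sort(unique(as.integer(nb_grid)))
  max_nb <- max(nb_grid)
  n <- nrow(X)
  if (n < 4L) stop("insufficient sample: need n >= 4 subjects")
  E <- ncol(X)
  pos <- numeric(E)
  neg <- numeric(E)
  ord <- .col_order(X)
  m <- if (scheme == "without_replacement") floor(bp * n) else n
  r_crit <- critical_rho(alpha, m)
  mu <- (m + 1) / 2
  snapshots <- vector("list", length(nb_grid))
  names(snapshots) <- as.character(nb_grid)
  for (b in seq_len(max_nb)) {
    idx <- with_seed(stream_seed(seed, fold, b), {
      if (scheme == "without_replacement") draw_subsample(n, bp)
      else draw_bootstrap(n)
    })
    cnt <- tabulate(idx, nbins = n)
    ry_draw <- rank(y[idx]) # duplicates of a subject share one midrank
    ry <- numeric(n)
    ry[idx] <- ry_draw
    syy <- sum((ry_draw - mu)^2)
    sig <- .stability_screen(X, ord, cnt, ry, m, syy, r_crit)
    pos <- pos + (sig > 0L)
    neg <- neg + (sig < 0L)
    if (b %in% nb_grid)
      snapshots[[as.character(b)]] <- list(pos_freq = pos / b,
                                           neg_freq = neg / b)
  }
  snapshots
}

#' Sign-specific stability frequencies across bootstrap resamples
#'
#' For each resample, a Spearman screen at `config$alpha` is run on the
#' resampled subjects and each edge's positive or negative counter is
#' incremented according to its significant sign (an edge significant with
#' opposite signs in different resamples accrues to both counters, so
#' neither may reach a high threshold). Frequencies are counters / NB.
#'
#' @param dataset a [connectome_dataset()] or feature matrix.
#' @param trait trait name or numeric vector.
#' @param config a [bootstrap_config()].
#' @return object of class `stability_freqs` with `pos_freq`, `neg_freq`
#'   (each in `[0, 1]`, multiples of `1/nb`) and the config.
#' @export
stability_frequencies <- function(dataset, trait, config) {
  stopifnot(inherits(config, "bootstrap_config"))
  xy <- resolve_features_trait(dataset, trait)
  snap <- stability_counts(xy$X, xy$y, config$scheme, config$bp,
                           nb_grid = config$nb, alpha = config$alpha,
                           seed = config$seed)[[as.character(config$nb)]]
  structure(list(pos_freq = snap$pos_freq, neg_freq = snap$neg_freq,
                 config = config),
            class = "stability_freqs")
}

#' @export
print.stability_freqs <- function(x, ...) {
  cat("stability_freqs over ", length(x$pos_freq), " edges (NB = ",
      x$config$nb, ")\n", sep = "")
  invisible(x)
}

#' Threshold stability frequencies into feature sets
#'
#' Edges whose positive (negative) frequency is at least `fp` form the
#' positive (negative) set; `combined` is their union. The comparison is
#' inclusive (`>=`) so the 100 percent threshold of the protocol grid is
#' attainable. In the rare event an edge passes both signs (possible only
#' for `fp <= 0.5`), it is assigned to the sign with the larger frequency
#' (positive on an exact tie) to keep the sets disjoint.
#'
#' @param freqs a `stability_freqs` object, or a list with `pos_freq` and
#'   `neg_freq`.
#' @param fp stability threshold in (0, 1].
#' @return a [feature_sets()].
#' @export
threshold_stability <- function(freqs, fp) {
  if (fp <= 0 || fp > 1) stop("fp must be in (0, 1]")
  pos <- freqs$pos_freq >= fp
  neg <- freqs$neg_freq >= fp
  both <- pos & neg
  if (any(both)) {
    pos[both] <- freqs$pos_freq[both] >= freqs$neg_freq[both]
    neg[both] <- !pos[both]
  }
  feature_sets(positive = which(pos), negative = which(neg))
}

#' Export stability frequencies as a data frame
#'
#' @param freqs a `stability_freqs` object.
#' @return data.frame with columns `edge`, `pos_freq`, `neg_freq`.
#' @export
frequency_table <- function(freqs) {
  data.frame(edge = seq_along(freqs$pos_freq),
             pos_freq = freqs$pos_freq, neg_freq = freqs$neg_freq)
}
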