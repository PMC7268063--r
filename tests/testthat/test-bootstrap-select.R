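test_that("bootstrap_config validates its fields", {
  cfg <- bootstrap_config("without_replacement", nb = 100, bp = 0.7, fp = 0.8)
  expect_s3_class(cfg, "bootstrap_config")
  expect_error(bootstrap_config("without_replacement", nb = 0, bp = 0.5,
                                fp = 0.5), "nb")
  expect_error(bootstrap_config("without_replacement", nb = 10, fp = 0.5),
               "bp is required")
  expect_error(bootstrap_config("without_replacement", nb = 10, bp = 1.2,
                                fp = 0.5), "bp")
  expect_error(bootstrap_config("with_replacement", nb = 10, fp = 0), "fp")
  # bp is ignored (and not required) with replacement
  cfg2 <- bootstrap_config("with_replacement", nb = 10, bp = 0.5, fp = 0.5)
  expect_true(is.na(cfg2$bp))
})

test_that("subsampling draws floor(bp*n) distinct indices", {
  set.seed(1)
  s <- draw_subsample(10, 0.5)
  expect_length(s, 5)
  expect_length(unique(s), 5)
  expect_true(all(s %in% 1:10))

  s2 <- draw_subsample(812, 0.25)
  expect_length(s2, 203) # floor(0.25 * 812)
  expect_length(unique(s2), 203)

  expect_setequal(draw_subsample(10, 1.0), 1:10)
  expect_error(draw_subsample(10, 0.3), "too small")
})

test_that("bootstrap resamples draw n with replacement", {
  set.seed(2)
  b <- draw_bootstrap(812)
  expect_length(b, 812)
  expect_true(any(duplicated(b))) # virtually certain at n = 812
  expect_equal(draw_bootstrap(1), 1L)
})

test_that("stability frequencies are deterministic, bounded and 1/NB-granular", {
  set.seed(31)
  n <- 60; E <- 120
  X <- matrix(rnorm(n * E), n, E)
  y <- X[, 5] + rnorm(n, sd = 0.3)
  cfg <- bootstrap_config("without_replacement", nb = 25, bp = 0.7, fp = 0.6,
                          seed = 99)
  f1 <- stability_frequencies(X, y, cfg)
  f2 <- stability_frequencies(X, y, cfg)
  expect_identical(f1$pos_freq, f2$pos_freq)
  expect_identical(f1$neg_freq, f2$neg_freq)

  expect_true(all(f1$pos_freq + f1$neg_freq <= 1 + 1e-12))
  expect_true(all(abs(f1$pos_freq * cfg$nb - round(f1$pos_freq * cfg$nb)) <
                  1e-9))
  # a trait identical to an edge is significant in every resample
  fr <- stability_frequencies(X, X[, 5],
                              bootstrap_config("without_replacement", nb = 10,
                                               bp = 0.7, fp = 0.5, seed = 4))
  expect_equal(fr$pos_freq[5], 1.0)
})

test_that("frequency counting agrees with explicitly re-run per-resample screens", {
  # dual route: reconstruct each resample from its (seed, fold=0, b) stream
  # and count significant signs with the baseline screen machinery
  set.seed(12)
  n <- 40; E <- 60
  X <- matrix(rnorm(n * E), n, E)
  y <- X[, 1] - X[, 2] + rnorm(n, sd = 0.7)
  for (scheme in c("without_replacement", "with_replacement")) {
    cfg <- bootstrap_config(scheme, nb = 15, bp = 0.6, fp = 0.5,
                            alpha = 0.1, seed = 77)
    fr <- stability_frequencies(X, y, cfg)
    pos <- neg <- numeric(E)
    for (b in seq_len(cfg$nb)) {
      idx <- stableconn:::with_seed(stableconn:::stream_seed(77, 0, b), {
        if (scheme == "without_replacement") draw_subsample(n, 0.6)
        else draw_bootstrap(n)
      })
      sc <- spearman_screen(X[idx, , drop = FALSE], y[idx], alpha = 0.1)
      pos[sc$sets$positive] <- pos[sc$sets$positive] + 1
      neg[sc$sets$negative] <- neg[sc$sets$negative] + 1
    }
    expect_equal(fr$pos_freq, pos / cfg$nb, tolerance = 1e-12)
    expect_equal(fr$neg_freq, neg / cfg$nb, tolerance = 1e-12)
  }
})

test_that("with-replacement duplicates enter the screen as repeated rows", {
  # a hand-built multiset: compare the fast path against screening the
  # expanded matrix with repeated rows
  set.seed(8)
  n <- 20; E <- 10
  X <- matrix(rnorm(n * E), n, E)
  y <- rnorm(n)
  idx <- c(1, 1, 2, 3, 3, 3, 5:18) # explicit duplicates
  sc_expanded <- spearman_screen(X[idx, ], y[idx], alpha = 0.2)
  cnt <- tabulate(idx, nbins = n)
  ry <- numeric(n); ry[idx] <- rank(y[idx])
  mu <- (length(idx) + 1) / 2
  sig <- stableconn:::.stability_screen(
    X, stableconn:::.col_order(X), cnt, ry, length(idx),
    sum((rank(y[idx]) - mu)^2), stableconn:::critical_rho(0.2, length(idx)))
  expect_equal(which(sig > 0), sc_expanded$sets$positive)
  expect_equal(which(sig < 0), sc_expanded$sets$negative)
})

test_that("thresholding is inclusive and monotone in FP", {
  fr <- list(pos_freq = c(1.0, 0.4), neg_freq = c(0, 0))
  expect_equal(threshold_stability(fr, 0.5)$positive, 1L)

  # FP = 1.0 must be attainable (inclusive comparison)
  fr2 <- list(pos_freq = c(1.0, 0.99), neg_freq = c(0, 0))
  expect_equal(threshold_stability(fr2, 1.0)$positive, 1L)

  # nested feature sets as FP sweeps upward
  set.seed(21)
  pos <- runif(300, 0, 0.8); neg <- pmin(runif(300, 0, 0.8), 1 - pos)
  fr3 <- list(pos_freq = pos, neg_freq = neg)
  grid <- c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  sets <- lapply(grid, function(fp) threshold_stability(fr3, fp))
  for (i in seq_along(grid)[-1]) {
    expect_true(all(sets[[i]]$positive %in% sets[[i - 1]]$positive))
    expect_true(all(sets[[i]]$negative %in% sets[[i - 1]]$negative))
    expect_true(all(sets[[i]]$combined %in% sets[[i - 1]]$combined))
  }
  expect_error(threshold_stability(fr3, 0), "fp")
})

test_that("stability selection is more precise than the baseline screen on
          contaminated data", {
  # planted-signal recovery precision, bootstrap (NB=100, BP=0.7, FP=0.8)
  # vs single full-sample screen, on the contaminated default generator
  wins <- 0
  for (seed in 1:10) {
    g <- generate_connectome(synthetic_spec(seed = seed))
    truth <- g$truth$signal_edges
    X <- g$dataset$features; y <- g$dataset$traits$score
    base <- spearman_screen(X, y, 0.05)$sets$combined
    cfg <- bootstrap_config("without_replacement", nb = 100, bp = 0.7,
                            fp = 0.8, seed = seed)
    boot <- threshold_stability(stability_frequencies(X, y, cfg), 0.8)$combined
    prec_base <- mean(base %in% truth)
    prec_boot <- if (length(boot)) mean(boot %in% truth) else 0
    if (prec_boot > prec_base) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("bootstrap-selected features largely overlap the baseline selection", {
  overlaps <- vapply(1:5, function(seed) {
    g <- generate_connectome(synthetic_spec(seed = seed))
    X <- g$dataset$features; y <- g$dataset$traits$score
    base <- spearman_screen(X, y, 0.05)$sets$combined
    cfg <- bootstrap_config("without_replacement", nb = 100, bp = 0.7,
                            fp = 0.8, seed = seed)
    boot <- threshold_stability(stability_frequencies(X, y, cfg), 0.8)$combined
    if (!length(boot)) return(NA_real_)
    mean(boot %in% base)
  }, numeric(1))
  expect_gt(mean(overlaps, na.rm = TRUE), 0.9)
})
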