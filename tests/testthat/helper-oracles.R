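# Independent oracle implementations used to check the package's fast
# paths. These deliberately use definitional formulas and brute-force
# counting, not the code under test.

# Midranks by definitional counting: rank_i = 1 + #{x_j < x_i} + ties/2.
oracle_midrank <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    below <- sum(x < x[i])
    ties <- sum(x == x[i]) # includes i itself
    below + (ties + 1) / 2
  }, numeric(1))
}

# Pearson correlation by the definitional sum formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# OLS slope/intercept by definitional covariance sums.
oracle_ols <- function(x, y) {
  n <- length(x)
  b <- (sum(x * y) - sum(x) * sum(y) / n) / (sum(x^2) - sum(x)^2 / n)
  list(beta = b, intercept = mean(y) - b * mean(x))
}

# Ridge checked through predictions: an augmented least-squares QR solve
# (rows sqrt(lambda) * I appended to the centered standardized design),
# numerically independent of the package's normal-equations path.
oracle_ridge_predict <- function(Xtr, ytr, Xte, lambda) {
  st_center <- colMeans(Xtr)
  st_scale <- apply(Xtr, 2, sd)
  st_scale[st_scale == 0] <- 1
  Xs <- scale(Xtr, st_center, st_scale)
  xc <- colMeans(Xs)
  Xc <- sweep(Xs, 2, xc)
  yc <- ytr - mean(ytr)
  p <- ncol(Xtr)
  beta_std <- qr.solve(rbind(Xc, sqrt(lambda) * diag(p)), c(yc, rep(0, p)))
  Xts <- sweep(scale(Xte, st_center, st_scale), 2, xc)
  as.vector(Xts %*% beta_std) + mean(ytr)
}

# Monte-Carlo permutation p-value for the Spearman coefficient: fraction of
# label shuffles whose |rho| is at least the observed |rho|. Vectorized in
# chunks; rho under permutation is a dot product of centered rank vectors.
oracle_perm_pvalue <- function(x, y, n_perm, seed = 1, chunk = 20000L) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  obs <- abs(sum(rxc * ryc) / denom)
  hits <- 0
  done <- 0
  set.seed(seed)
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    P <- vapply(seq_len(b), function(i) sample(ryc), numeric(n))
    rho_perm <- abs(as.vector(crossprod(rxc, P)) / denom)
    hits <- hits + sum(rho_perm >= obs - 1e-12)
    done <- done + b
  }
  hits / n_perm
}

# Small deterministic dataset builders -------------------------------------

# Linear trait on planted edges, optionally noiseless; returns matrix form.
make_linear_data <- function(n, E, signal, betas, noise_sd, seed) {
  stopifnot(length(signal) == length(betas))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  X <- matrix(rnorm(n * E, sd = 0.3), n, E)
  y <- as.vector(X[, signal, drop = FALSE] %*% betas) +
    rnorm(n, sd = noise_sd)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(X = X, y = y)
}
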