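# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# KMO via regression residuals: the partial correlation of columns i and j
# given the rest is the correlation of the residuals from regressing each on
# the remaining columns (textbook route, no matrix inversion).
kmo_oracle <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  r <- stats::cor(x)
  pc <- matrix(0, p, p)
  for (i in 1:(p - 1)) {
    for (j in (i + 1):p) {
      others <- setdiff(seq_len(p), c(i, j))
      if (length(others) == 0) {
        pc[i, j] <- pc[j, i] <- r[i, j]
      } else {
        ri <- stats::resid(stats::lm(x[, i] ~ x[, others]))
        rj <- stats::resid(stats::lm(x[, j] ~ x[, others]))
        pc[i, j] <- pc[j, i] <- stats::cor(ri, rj)
      }
    }
  }
  r2 <- r^2; diag(r2) <- 0
  p2 <- pc^2
  sum(r2) / (sum(r2) + sum(p2))
}

# Coarse-to-fine grid search over the log-likelihood surface; independent of
# any gradient information.
grid_ml_logit <- function(X, y, lower, upper, levels = 50, pts = 11,
                          sweeps = 3) {
  k <- ncol(X)
  best <- (lower + upper) / 2
  width <- (upper - lower) / 2
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  for (lev in seq_len(levels)) {
    for (s in seq_len(sweeps)) {
      for (j in seq_len(k)) {
        grid <- seq(best[j] - width[j], best[j] + width[j], length.out = pts)
        vals <- vapply(grid, function(g) {
          b <- best; b[j] <- g; ll(b)
        }, 0)
        best[j] <- grid[which.max(vals)]
      }
    }
    width <- width * 0.6             # zoom around the coordinate-wise optimum
  }
  best
}

# Small deterministic two-regressor fixture with a known bent likelihood.
make_fixture_50 <- function() {
  set.seed(4242)
  x1 <- stats::rnorm(50)
  x2 <- stats::rbinom(50, 1, 0.4)
  eta <- -0.3 + 0.8 * x1 - 0.5 * x2
  y <- stats::rbinom(50, 1, stats::plogis(eta))
  data.frame(y = y, x1 = x1, x2 = x2)
}

# 2x2 cell-count design: outcome by binary regressor with cells
# (a, b, c, d) = (y1x1, y0x1, y1x0, y0x0).
make_2x2 <- function(a, b, c, d) {
  data.frame(
    y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    x = c(rep(1, a + b), rep(0, c + d))
  )
}

default_true_coefs <- function() generator_config()$true_logit_coefs

# Refit the exact data-generating specification on a generated sample.
refit_dgp <- function(data) {
  d <- add_indices(data)$data
  fit_binary(d, model_spec("care_all",
                           c("hosnet_R", "hosnet_F", "medical",
                             care_controls())))
}
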