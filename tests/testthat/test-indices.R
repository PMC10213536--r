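test_that("kinship index matches closed-form values", {
  expect_identical(kinship_index(rep(0, 5), rep(0, 5)), 0)
  expect_equal(kinship_index(c(exp(1) - 1, 0, 0, 0, 0), rep(0, 5)), 1)
  # a transfer total in the millions lands near the observed index maximum
  give <- c(1209427, 0, 0, 0, 0)
  expect_equal(kinship_index(give, rep(0, 5)), log1p(1209427))
  expect_equal(kinship_index(give, rep(0, 5)), 14.005658, tolerance = 1e-6)
  expect_error(kinship_index(c(-1, 0, 0, 0, 0), rep(0, 5)), "negative")
})

test_that("kinship index is monotone nondecreasing in every amount", {
  set.seed(11)
  for (rep in 1:20) {
    give <- matrix(rexp(5, 1 / 100), 1)
    receive <- matrix(rexp(5, 1 / 100), 1)
    base <- kinship_index(give, receive)
    j <- sample(5, 1)
    give2 <- give; give2[j] <- give2[j] + rexp(1, 1 / 50)
    receive2 <- receive; receive2[j] <- receive2[j] + rexp(1, 1 / 50)
    expect_gte(kinship_index(give2, receive), base)
    expect_gte(kinship_index(give, receive2), base)
  }
})

test_that("clan indicator flags any positive transaction and hits its mean", {
  expect_identical(clan_indicator(rep(0, 5), rep(0, 5)), 0L)
  expect_identical(clan_indicator(c(0, 0, 0.01, 0, 0), rep(0, 5)), 1L)
  d <- generate_population(generator_config(n = 20000, seed = 808))
  cl <- add_indices(d)$data$clan
  expect_lt(abs(mean(cl) - 0.546), 3 * sqrt(0.546 * 0.454 / 20000))
  # clan = 1 iff hosnet_R > 0
  hr <- add_indices(d)$data$hosnet_R
  expect_identical(cl == 1L, hr > 0)
})

test_that("contact frequency is validated to the 0-6 questionnaire scale", {
  expect_identical(friend_frequency(c(0, 6, 3)), c(0L, 6L, 3L))
  expect_error(friend_frequency(7), "0, 6")
  expect_error(friend_frequency(-1), "0, 6")
  expect_error(friend_frequency(2.5), "0, 6")
})

test_that("KMO matches the closed form for the equicorrelated design", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  res <- kmo(R)
  # partial correlation of an equicorrelated triple is rho/(1+rho) = 1/3
  expect_equal(res$kmo_overall, 0.25 / (0.25 + (1 / 3)^2),
               tolerance = 1e-12)
  expect_equal(res$kmo_overall, 0.692307692307692, tolerance = 1e-12)
  # symmetry: per-item MSA identical across items
  expect_equal(unname(res$kmo_per_item), rep(res$kmo_overall, 3),
               tolerance = 1e-12)
})

test_that("KMO degenerates to 0 with a warning for orthogonal indicators", {
  expect_warning(res <- kmo(diag(3)), "zero")
  expect_identical(res$kmo_overall, 0)
})

test_that("KMO agrees with the regression-residual oracle on random designs", {
  set.seed(321)
  for (rep in 1:20) {
    p <- sample(3:6, 1)
    n <- 200
    L <- matrix(rnorm(p * p), p)
    x <- matrix(rnorm(n * p), n) %*% L
    expect_equal(kmo(x)$kmo_overall, kmo_oracle(x), tolerance = 1e-10)
  }
})

test_that("KMO input validation catches degenerate matrices", {
  expect_error(kmo(matrix(rnorm(20), 10, 2)), "3 indicator")
  x <- cbind(a = rnorm(50), b = rnorm(50), c = 1)
  expect_error(kmo(x), "constant")
  expect_error(kmo(matrix(rnorm(6), 2, 3)), "more rows")
})

test_that("friendship index satisfies the PCA identities", {
  set.seed(42)
  x <- cbind(social_spend = rlnorm(400, 6, 1.5) * rbinom(400, 1, 0.5),
             guest_meals = rpois(400, 2),
             social_activity = rpois(400, 1))
  fi <- friendship_index(x)
  dg <- fi$diagnostics
  expect_equal(sum(dg$eigenvalues), 3, tolerance = 1e-10)
  expect_equal(sum(dg$proportions), 1, tolerance = 1e-10)
  expect_equal(dg$cumulative[3], 1, tolerance = 1e-10)
  expect_true(all(diff(dg$cumulative) >= 0))
  expect_lt(abs(mean(fi$scores)), 1e-8)
  expect_gt(sd(fi$scores), 0)
  # loadings orthonormal (components x indicators)
  expect_equal(dg$loadings %*% t(dg$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: spending loads positively on the scored component
  expect_gt(dg$loadings[1, "social_spend"], 0)
  expect_gte(dg$n_retained, 1)
})

test_that("friendship scores are invariant to affine rescaling of inputs", {
  set.seed(43)
  x <- cbind(rlnorm(300, 5, 1), rpois(300, 3), rpois(300, 1))
  colnames(x) <- c("social_spend", "guest_meals", "social_activity")
  s1 <- friendship_index(x)$scores
  x2 <- x
  x2[, 1] <- 1000 * x2[, 1] + 5   # change units and origin
  x2[, 3] <- 0.01 * x2[, 3] - 2
  s2 <- friendship_index(x2)$scores
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("friendship first PC matches an independent eigensolver route", {
  set.seed(44)
  n <- 5000
  x <- matrix(rnorm(3 * n), n, 3)
  colnames(x) <- c("social_spend", "guest_meals", "social_activity")
  fi <- friendship_index(x)
  # independent route: prcomp on standardised data
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expect_equal(fi$diagnostics$eigenvalues, unname(pr$sdev^2),
               tolerance = 1e-10)
  ref <- pr$x[, 1]
  if (stats::cor(ref, fi$scores) < 0) ref <- -ref
  expect_equal(fi$scores, unname(ref), tolerance = 1e-8)
  # i.i.d. indicators: top eigenvalue near 1 (sampling noise ~ sqrt(1/n))
  expect_lt(abs(fi$diagnostics$eigenvalues[1] - 1), 5 * sqrt(3 / n))
})

test_that("friendship index rejects unusable input", {
  x <- cbind(social_spend = rnorm(10), guest_meals = rnorm(10),
             social_activity = 2)
  expect_error(friendship_index(x), "constant")
  expect_error(friendship_index(matrix(rnorm(4), 2, 2)), "3 indicator")
  expect_error(friendship_index(matrix(rnorm(6), 2, 3)), "3 usable rows")
  xna <- matrix(rnorm(30), 10, 3); xna[1, 1] <- NA
  expect_error(friendship_index(xna), "complete cases")
})
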