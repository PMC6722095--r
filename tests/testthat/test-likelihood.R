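test_that("independent observed pairs factorize into univariate densities", {
  ll <- pair_loglik(540, 528, FALSE, FALSE, 535, 534, 81, 64, 0, 550)
  expect_equal(ll, dnorm(540, 535, 9, log = TRUE) +
                 dnorm(528, 534, 8, log = TRUE), tolerance = 1e-12)
})

test_that("with the threshold at infinity the pair density is the plain bivariate normal", {
  y <- c(545, 548); mu <- c(540, 541); v <- c(70, 80); cv <- 40
  ll <- pair_loglik(y[1], y[2], FALSE, FALSE, mu[1], mu[2], v[1], v[2], cv,
                    threshold = Inf)
  # independent closed-form bivariate normal log-density
  S <- matrix(c(v[1], cv, cv, v[2]), 2)
  d <- y - mu
  ref <- -log(2 * pi) - 0.5 * log(det(S)) -
    0.5 * drop(t(d) %*% solve(S) %*% d)
  expect_equal(ll, ref, tolerance = 1e-12)
})

test_that("both-censored pairs match the frozen Monte-Carlo oracle", {
  # P(Y1 > 550, Y2 > 550) for mu = (548, 548), v = 81, cov = 40.5:
  # 1e7-draw Monte-Carlo estimate 0.2498646 (SE 1.369e-4), seed 424242
  ll <- pair_loglik(550, 550, TRUE, TRUE, 548, 548, 81, 81, 40.5, 550)
  expect_lt(abs(exp(ll) - 0.2498646), 3 * 1.369e-4)
})

test_that("one-censored pairs use the conditional normal tail", {
  ll <- pair_loglik(546, 550, FALSE, TRUE, 540, 540, 81, 81, 40.5, 550)
  cond_mu <- 540 + 0.5 * (546 - 540)
  cond_sd <- 9 * sqrt(1 - 0.25)
  ref <- dnorm(546, 540, 9, log = TRUE) +
    pnorm((550 - cond_mu) / cond_sd, lower.tail = FALSE, log.p = TRUE)
  expect_equal(ll, ref, tolerance = 1e-12)
})

test_that("singletons contribute univariate density or survival", {
  expect_equal(pair_loglik(538, NA, FALSE, FALSE, 535, 535, 81, 81, 30, 550),
               dnorm(538, 535, 9, log = TRUE), tolerance = 1e-12)
  expect_equal(pair_loglik(NA, 550, FALSE, TRUE, 535, 535, 81, 81, 30, 550),
               pnorm((550 - 535) / 9, lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-12)
})

test_that("invalid pairs and moments are rejected", {
  expect_error(pair_loglik(NA, NA, FALSE, FALSE, 535, 535, 81, 81, 0, 550),
               "both scores missing")
  expect_error(pair_loglik(540, 541, FALSE, FALSE, 535, 535, 81, 81, 90, 550),
               "positive definite")
  expect_error(pair_loglik(540, 549, FALSE, TRUE, 535, 535, 81, 81, 40, 550),
               "equal the threshold")
})

make_pairs <- function(n, seed = 1, rho = 0.6, mu = 535, sd = 9) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  as_twin_data(data.frame(
    family_id = sprintf("f%03d", 1:n), zygosity = "MZ", ses = 1,
    sex1 = "F", sex2 = "F",
    ea1 = pmin(pmax(mu + sd * z1, 501), 550),
    ea2 = pmin(pmax(mu + sd * z2, 501), 550)))
}

test_that("dataset deviance is additive and order/swap invariant", {
  d <- make_pairs(80)
  mom <- data.frame(mu1 = 535, mu2 = 535, v1 = 81, v2 = 81, cov = 48)[rep(1, 80), ]
  base <- twin_minus2ll(d, mom)
  expect_equal(twin_minus2ll(d[0, ], mom[0, ]), 0)
  d2 <- rbind(d, d); class(d2) <- class(d)
  expect_equal(twin_minus2ll(d2, rbind(mom, mom)), 2 * base,
               tolerance = 1e-10)
  perm <- sample(nrow(d))
  expect_equal(twin_minus2ll(d[perm, ], mom[perm, ]), base, tolerance = 1e-10)
  # swapping twin 1 and twin 2 together with their moments
  dsw <- d; dsw$ea1 <- d$ea2; dsw$ea2 <- d$ea1
  dsw$cens1 <- d$cens2; dsw$cens2 <- d$cens1
  expect_equal(twin_minus2ll(dsw, mom), base, tolerance = 1e-10)
})

test_that("uncensored datasets match a direct bivariate-density oracle", {
  d <- make_pairs(60, seed = 3, mu = 520)   # far from the ceiling
  expect_false(any(d$cens1 | d$cens2))
  mom <- data.frame(mu1 = 521, mu2 = 519, v1 = 75, v2 = 85, cov = 40)[rep(1, 60), ]
  S <- matrix(c(75, 40, 40, 85), 2)
  Sinv <- solve(S)
  oracle <- -2 * sum(vapply(seq_len(60), function(i) {
    dd <- c(d$ea1[i] - 521, d$ea2[i] - 519)
    -log(2 * pi) - 0.5 * log(det(S)) - 0.5 * drop(t(dd) %*% Sinv %*% dd)
  }, numeric(1)))
  expect_equal(twin_minus2ll(d, mom), oracle, tolerance = 1e-8)
})

test_that("the pair likelihood is continuous in the mean across the ceiling", {
  # slide the mean so mass crosses the threshold; successive deviances on a
  # fine grid must change smoothly (no jump at any boundary crossing)
  d <- make_pairs(40, seed = 5, mu = 548)
  grid <- seq(540, 556, by = 0.02)
  vals <- vapply(grid, function(m) {
    mom <- data.frame(mu1 = m, mu2 = m, v1 = 81, v2 = 81, cov = 48)[rep(1, 40), ]
    twin_minus2ll(d, mom)
  }, numeric(1))
  steps <- abs(diff(vals))
  expect_lt(max(steps), 4 * stats::median(steps) + 1)
})
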