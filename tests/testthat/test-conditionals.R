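test_that("rtnorm draws respect their support and closed-form means", {
  set.seed(101)
  # support is never violated, even far from the interval
  expect_true(all(rtnorm(2000, mean = 5, upper = 0) < 0))
  expect_true(all(rtnorm(2000, mean = -4, lower = 0) > 0))

  m <- 1e5
  # half normal: E = sqrt(2/pi)
  x <- rtnorm(m, 0, lower = 0)
  expect_lt(abs(mean(x) - sqrt(2 / pi)), 3 * sd(x) / sqrt(m))
  # shifted: E = 2 + phi(2)/Phi(2)
  x <- rtnorm(m, 2, lower = 0)
  expect_lt(abs(mean(x) - tnorm_mean_lower(2, 0)), 3 * sd(x) / sqrt(m))
  # far-tail location (rejection path): E = -3 + phi(3)/(1 - Phi(3))
  x <- rtnorm(m, -8, lower = 0)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - tnorm_mean_lower(-8, 0)), 3 * sd(x) / sqrt(m))
})

test_that("rtnorm marginal law matches the analytic truncated-normal CDF at deciles", {
  set.seed(102)
  m <- 1e5
  cases <- list(c(mu = 0.3, a = 0, b = Inf),
                c(mu = -0.5, a = -Inf, b = 0),
                c(mu = 1, a = -1, b = 2))
  for (cs in cases) {
    x <- rtnorm(m, cs[["mu"]], cs[["a"]], cs[["b"]])
    q <- tnorm_quantile(seq(0.1, 0.9, by = 0.1), cs[["mu"]], cs[["a"]], cs[["b"]])
    emp <- vapply(q, function(qq) mean(x <= qq), numeric(1))
    expect_true(all(abs(emp - seq(0.1, 0.9, by = 0.1)) < 4 * sqrt(0.1 * 0.9 / m)))
  }
})

test_that("rtnorm rejects invalid and degenerate intervals and is stream-pure", {
  expect_error(rtnorm(1, 0, lower = 1, upper = 1), "lower bound")
  expect_error(rtnorm(1, 0, lower = 2, upper = -2), "lower bound")
  # two-sided interval with no representable mass
  expect_error(rtnorm(1, 0, lower = 39, upper = 40), "tail-degenerate")
  expect_error(rtnorm(1, 0, lower = -40, upper = -39), "tail-degenerate")
  # same stream state, same draws
  set.seed(7); a <- rtnorm(50, c(-6, 0, 6), lower = 0)
  set.seed(7); b <- rtnorm(50, c(-6, 0, 6), lower = 0)
  expect_identical(a, b)
})

test_that("update_z draws signs matching y with the right conditional law", {
  items <- item_parameters(c(0.8, 1.1), c(-0.2, 0.5))
  set.seed(11)
  y <- response_matrix(matrix(rbinom(40, 1, 0.5), 20, 2))
  z <- update_z(y, rnorm(20), items)
  expect_true(all((z > 0) == (unclass(y) == 1)))
  expect_true(all(z != 0))

  # all-ones matrix at eta = 0: every cell is half normal
  n <- 500; k <- 100
  y1 <- response_matrix(matrix(1, n, k))
  z1 <- update_z(y1, rep(0, n), item_parameters(rep(1, k), rep(0, k)))
  expect_lt(abs(mean(z1) - sqrt(2 / pi)), 3 * sd(z1) / sqrt(n * k))

  # constant eta = 0.3 cells against the analytic truncated CDF at deciles
  z2 <- update_z(y1, rep(0.3, n), item_parameters(rep(1, k), rep(0, k)))
  q <- tnorm_quantile(seq(0.1, 0.9, by = 0.1), 0.3, 0, Inf)
  emp <- vapply(q, function(qq) mean(z2 <= qq), numeric(1))
  expect_true(all(abs(emp - seq(0.1, 0.9, by = 0.1)) < 4 * sqrt(0.09 / (n * k))))

  expect_error(update_z(y, rnorm(19), items), "length")
  expect_error(update_z(y, rnorm(20), item_parameters(1, 0)), "item count")
})

test_that("theta_posterior_params implements both conditional variants exactly", {
  # k = 1 collapse
  z1 <- matrix(c(0.7, 0.7), 2, 1)
  it1 <- item_parameters(1, 0)
  p <- theta_posterior_params(z1, it1, "as-printed")
  expect_equal(p$mean, c(0.7, 0.7))
  expect_equal(p$variance, 1)
  p <- theta_posterior_params(z1, it1, "conjugate")
  expect_equal(p$mean, c(0.35, 0.35))
  expect_equal(p$variance, 0.5)

  # k = 2 hand-checked case: alpha (1,2), beta (0,1), z row (0.5, -0.3)
  z2 <- matrix(c(0.5, -0.3), 1, 2)
  it2 <- item_parameters(c(1, 2), c(0, 1))
  p <- theta_posterior_params(z2, it2, "as-printed")
  expect_equal(p$mean, 0.38)
  expect_equal(p$variance, 0.2)
  p <- theta_posterior_params(z2, it2, "conjugate")
  expect_equal(p$mean, 1.9 / 6)
  expect_equal(p$variance, 1 / 6)

  # prior recovery: slopes to zero in conjugate mode recovers N(0, 1)
  tiny <- item_parameters(rep(1e-8, 3), rep(0, 3))
  p <- theta_posterior_params(matrix(rnorm(30), 10, 3), tiny, "conjugate")
  expect_lt(max(abs(p$mean)), 1e-6)
  expect_equal(p$variance, 1, tolerance = 1e-10)
})

test_that("sample_theta draws the stated normals reproducibly", {
  post <- theta_posterior_params(matrix(c(0.5, -0.3), 1, 2),
                                 item_parameters(c(1, 2), c(0, 1)), "as-printed")
  set.seed(5); a <- sample_theta(post)
  set.seed(5); b <- sample_theta(post)
  expect_identical(a, b)

  # sampled variance matches the conditional variance (mean 0.38, var 0.2)
  big <- structure(list(mean = rep(0.38, 1e5), variance = 0.2,
                        prior_mode = "as-printed"), class = "theta_posterior")
  set.seed(6)
  x <- sample_theta(big)
  expect_lt(abs(var(x) - 0.2), 3 * 0.2 * sqrt(2 / 1e5))
  expect_lt(abs(mean(x) - 0.38), 3 * sqrt(0.2 / 1e5))

  # vanishing variance collapses to the mean
  small <- structure(list(mean = c(1, 2), variance = 1e-30,
                          prior_mode = "as-printed"), class = "theta_posterior")
  expect_equal(sample_theta(small), c(1, 2), tolerance = 1e-10)
})

test_that("compute_xtx builds x'x and its inverse correctly", {
  xp <- compute_xtx(c(1, -1))
  expect_equal(xp$xtx, matrix(c(2, 0, 0, 2), 2, 2))
  expect_equal(xp$inv, matrix(c(0.5, 0, 0, 0.5), 2, 2))

  expect_error(compute_xtx(c(1, 1)), "identical")
  expect_error(compute_xtx(1), "at least 2")

  set.seed(33)
  th <- rnorm(100)
  xp <- compute_xtx(th)
  x <- cbind(th, -1)
  expect_lt(max(abs(xp$inv - solve(crossprod(x)))), 1e-10)
  ev <- eigen(xp$inv, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(xp$inv, t(xp$inv))
})

test_that("update_items samples the slope-truncated bivariate conditional", {
  # fixed 4-person, single-item instance vs an independent 2-D quadrature
  theta <- c(-1.2, -0.3, 0.5, 1.4)
  zj <- c(-0.8, -0.1, 0.6, 1.1)
  oracle <- quad_item_conditional(zj, theta)
  expect_lt(oracle$edge_mass, 1e-6)  # grid captures the conditional
  set.seed(44)
  m <- 4e4
  draws <- matrix(NA_real_, m, 2)
  z <- matrix(zj, 4, 1)
  for (r in seq_len(m)) {
    it <- update_items(z, theta)
    draws[r, ] <- c(it$alpha, it$beta)
  }
  expect_lt(abs(mean(draws[, 1]) - oracle$mean_alpha),
            3 * sd(draws[, 1]) / sqrt(m))
  expect_lt(abs(mean(draws[, 2]) - oracle$mean_beta),
            3 * sd(draws[, 2]) / sqrt(m))
  expect_true(all(draws[, 1] > 0))
})

test_that("update_items at a zero conditional slope yields a half-normal slope", {
  # sum(z) = 0 and sum(theta * z) = 0 put the proposal mean at the origin
  theta <- c(1, -1, 2, -2)
  z <- matrix(c(1, 1, -1, -1), 4, 1)
  xp <- compute_xtx(theta)
  sd_a <- sqrt(xp$inv[1, 1])
  set.seed(45)
  m <- 2e4
  draws <- t(vapply(seq_len(m), function(r) {
    it <- update_items(z, theta)
    c(it$alpha, it$beta)
  }, numeric(2)))
  # accepted slope marginal is half normal with scale sd_a
  expect_lt(abs(mean(draws[, 1]) - sd_a * sqrt(2 / pi)),
            3 * sd(draws[, 1]) / sqrt(m))
  # x'x is diagonal here, so the intercept stays symmetric around 0
  expect_lt(abs(mean(draws[, 2])), 3 * sd(draws[, 2]) / sqrt(m))
})

test_that("update_items reports a truncation stall with diagnostics", {
  theta <- c(1, -1, 2, -2)
  z <- matrix(-8 * theta, 4, 1)  # strongly negative conditional slope
  set.seed(46)
  err <- expect_error(update_items(z, theta, max_rejects = 50L),
                      "truncation stall in item 1")
  expect_match(conditionMessage(err), "acceptance probability")
})

test_that("conditional samplers are pure functions of inputs and stream state", {
  items <- item_parameters(c(0.8, 1.1), c(-0.2, 0.5))
  set.seed(77)
  y <- response_matrix(matrix(rbinom(24, 1, 0.6), 12, 2))
  th <- rnorm(12)
  set.seed(99); z1 <- update_z(y, th, items); i1 <- update_items(z1, th)
  set.seed(99); z2 <- update_z(y, th, items); i2 <- update_items(z2, th)
  expect_identical(z1, z2)
  expect_identical(i1, i2)
})
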