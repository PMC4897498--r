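# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Standard normal CDF through the complementary error function.
phi_erf <- function(x) 0.5 * pracma::erfc(-x / sqrt(2))

# Mean of N(mu, 1) truncated below at `a`: mu + phi(a - mu) / (1 - Phi(a - mu)).
tnorm_mean_lower <- function(mu, a) {
  s <- a - mu
  mu + stats::dnorm(s) / stats::pnorm(-s)
}

# CDF of N(mu, 1) truncated to (a, b).
tnorm_cdf <- function(x, mu, a, b) {
  pa <- stats::pnorm(a - mu)
  pb <- stats::pnorm(b - mu)
  (stats::pnorm(x - mu) - pa) / (pb - pa)
}

# Quantile of N(mu, 1) truncated to (a, b).
tnorm_quantile <- function(p, mu, a, b) {
  pa <- stats::pnorm(a - mu)
  pb <- stats::pnorm(b - mu)
  mu + stats::qnorm(pa + p * (pb - pa))
}

# 2-D grid quadrature of the single-item conditional
# p(alpha, beta | z, theta) propto exp(-0.5 * sum_i (z_i - (alpha*theta_i - beta))^2) * I(alpha > 0),
# written from the likelihood directly (no reuse of the package's x'x route).
quad_item_conditional <- function(zj, theta, n_a = 400, n_b = 401, a_max = NULL, b_lim = NULL) {
  fit <- stats::lm.fit(cbind(theta, -1), zj)
  ctr <- fit$coefficients
  spread <- 6 / sqrt(length(zj))  # generous scale for a unit-variance regression
  if (is.null(a_max)) a_max <- max(ctr[1], 0) + 8 * spread
  if (is.null(b_lim)) b_lim <- abs(ctr[2]) + 8 * spread
  ag <- seq(a_max / n_a / 2, a_max - a_max / n_a / 2, length.out = n_a)
  bg <- seq(-b_lim, b_lim, length.out = n_b)
  ll <- outer(ag, bg, function(a, b) {
    s <- 0
    for (i in seq_along(theta)) s <- s + (zj[i] - (a * theta[i] - b))^2
    -0.5 * s
  })
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  list(mean_alpha = sum(w * matrix(ag, n_a, n_b)),
       mean_beta = sum(w * matrix(bg, n_a, n_b, byrow = TRUE)),
       edge_mass = sum(w[n_a, ]))
}

# Dense-grid quadrature of the unnormalized joint posterior of a k = 2
# instance: prod_ij Phi(a_j t_i - b_j)^y (1-Phi)^(1-y) * prod_i phi(t_i),
# flat beta, flat positive alpha. Exploits that, given the item grid, the
# trait integrals factor person by person; accumulates person factors on the
# log scale. Returns first two moments of (alpha_1, beta_1, theta_1).
quad_joint_k2 <- function(y, n_t = 101, t_lim = 6, n_a = 64, a_max = 6,
                          n_b = 81, b_lim = 6) {
  stopifnot(ncol(y) == 2)
  n <- nrow(y)
  tg <- seq(-t_lim, t_lim, length.out = n_t)
  wt <- rep(diff(tg)[1L], n_t)
  wt[c(1L, n_t)] <- wt[1L] / 2
  ag <- seq(a_max / n_a / 2, a_max - a_max / n_a / 2, length.out = n_a)
  bg <- seq(-b_lim, b_lim, length.out = n_b)
  xi <- expand.grid(a = ag, b = bg)
  nxi <- nrow(xi)
  G <- function(i, j) {
    p <- stats::pnorm(outer(tg, xi$a) - matrix(xi$b, n_t, nxi, byrow = TRUE))
    if (y[i, j] == 1) p else 1 - p
  }
  phi_w <- wt * stats::dnorm(tg)
  logJ <- 0
  h1 <- h1t <- h1t2 <- NULL
  for (i in seq_len(n)) {
    G1 <- G(i, 1L)
    G2 <- G(i, 2L)
    hi <- crossprod(G1 * phi_w, G2)
    if (i == 1L) {
      h1 <- hi
      h1t <- crossprod(G1 * (phi_w * tg), G2)
      h1t2 <- crossprod(G1 * (phi_w * tg^2), G2)
    }
    logJ <- logJ + log(hi)
  }
  J <- exp(logJ - max(logJ))
  Z <- sum(J)
  m1 <- rowSums(J) / Z
  mb <- matrix(m1, n_a, n_b)
  et1 <- sum(J * (h1t / h1)) / Z
  list(
    alpha1 = c(mean = sum(m1 * xi$a), var = sum(m1 * xi$a^2) - sum(m1 * xi$a)^2),
    beta1 = c(mean = sum(m1 * xi$b), var = sum(m1 * xi$b^2) - sum(m1 * xi$b)^2),
    theta1 = c(mean = et1, var = sum(J * (h1t2 / h1)) / Z - et1^2),
    edge_alpha_mass = sum(mb[n_a, ]) / sum(mb)
  )
}
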