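#' Sample from a unit-variance truncated normal distribution
#'
#' Draws from \eqn{N(\mu, 1)} restricted to the open interval
#' \code{(lower, upper)}. This is the primitive behind the augmented-data
#' update, where each \eqn{Z_{ij}} is a unit-variance normal truncated to the
#' positive or negative half line according to \eqn{y_{ij}}.
#'
#' For moderate standardized bounds (within 5 SD of the location) the draw is
#' the inverse CDF applied to a uniform on the truncated probability mass.
#' Beyond 5 SD the inverse-CDF route loses precision, so a shifted-exponential
#' rejection sampler (Robert 1995) is used instead. Draws are strictly inside
#' the interval. Arguments are recycled to length \code{n}.
#'
#' @param n Number of draws.
#' @param mean Location \eqn{\mu} (the variance is fixed at 1).
#' @param lower,upper Truncation bounds; \code{-Inf} / \code{Inf} allowed.
#' @return Numeric vector of \code{n} draws, each in \code{(lower, upper)}.
#' @examples
#' set.seed(1)
#' mean(rtnorm(1e4, 0, lower = 0))  # approaches sqrt(2/pi)
#' @export
rtnorm <- function(n, mean = 0, lower = -Inf, upper = Inf) {
  n <- as.integer(n)
  if (n < 0L) stop("`n` must be non-negative")
  if (n == 0L) return(numeric(0))
  mean <- rep_len(as.numeric(mean), n)
  lower <- rep_len(as.numeric(lower), n)
  upper <- rep_len(as.numeric(upper), n)
  if (any(!is.finite(mean))) stop("`mean` must be finite")
  if (any(lower >= upper)) {
    bad <- which(lower >= upper)[1L]
    stop(sprintf("lower bound must be below upper bound (element %d: [%g, %g])",
                 bad, lower[bad], upper[bad]))
  }
  a <- lower - mean
  b <- upper - mean

  # one uniform per element, consumed in element order; elements routed to the
  # rejection path draw further variates afterwards, in ascending index order
  u <- stats::runif(n)
  x <- numeric(n)

  extreme <- (is.finite(a) & a > 5) | (is.finite(b) & b < -5)
  mod <- !extreme

  if (any(mod)) {
    am <- a[mod]; bm <- b[mod]
    pa <- stats::pnorm(am)  # pnorm(-Inf) = 0, pnorm(Inf) = 1
    pb <- stats::pnorm(bm)
    mass <- pb - pa
    if (any(mass <= 0)) {
      bad <- which(mod)[which(mass <= 0)[1L]]
      stop(sprintf(
        "tail-degenerate truncation: interval [%g, %g] around mean %g has no representable probability mass",
        lower[bad], upper[bad], mean[bad]))
    }
    xm <- stats::qnorm(pa + u[mod] * mass)
    # qnorm can land on a bound through rounding; redraw those few strictly inside
    off <- which(!(xm > am & xm < bm) | !is.finite(xm))
    for (idx in off) {
      repeat {
        cand <- stats::qnorm(pa[idx] + stats::runif(1L) * mass[idx])
        if (is.finite(cand) && cand > am[idx] && cand < bm[idx]) break
      }
      xm[idx] <- cand
    }
    x[mod] <- xm
  }

  if (any(extreme)) {
    for (idx in which(extreme)) {
      ai <- a[idx]; bi <- b[idx]
      flip <- FALSE
      if (is.finite(bi) && bi < -5) {  # mirror the left tail onto the right
        tmp <- ai; ai <- -bi; bi <- if (is.finite(tmp)) -tmp else Inf
        flip <- TRUE
      }
      # right-tail mass check for finite two-sided intervals
      if (is.finite(bi)) {
        m <- stats::pnorm(ai, lower.tail = FALSE) - stats::pnorm(bi, lower.tail = FALSE)
        if (m <= 0) {
          stop(sprintf(
            "tail-degenerate truncation: interval [%g, %g] around mean %g has no representable probability mass",
            lower[idx], upper[idx], mean[idx]))
        }
      }
      x[idx] <- (if (flip) -1 else 1) * rtail_robert(ai, bi) + 0
    }
  }
  x + mean
}

# Robert (1995) shifted-exponential rejection for the standardized right tail
# (a > 0 large, possibly finite upper bound b). Returns a draw in (a, b).
rtail_robert <- function(a, b = Inf) {
  lambda <- (a + sqrt(a * a + 4)) / 2
  repeat {
    z <- a + stats::rexp(1L, rate = lambda)
    if (z >= b) next
    d <- z - lambda
    if (stats::runif(1L) <= exp(-d * d / 2)) return(z)
  }
}

#' Update the augmented data matrix Z
#'
#' First transition step of the Gibbs sampler: each cell is drawn from a
#' unit-variance normal centred at the linear predictor
#' \eqn{\alpha_j \theta_i - \beta_j}, truncated to \eqn{(0, \infty)} where
#' \eqn{y_{ij} = 1} and to \eqn{(-\infty, 0)} where \eqn{y_{ij} = 0}. Cells
#' are drawn in row-major order (all items of person 1, then person 2, ...).
#'
#' @param y A \code{\link{response_matrix}} (or coercible matrix).
#' @param theta Trait vector of length \code{n}.
#' @param items An \code{\link{item_parameters}} object with \code{k} items.
#' @return An \code{n x k} numeric matrix of augmented values whose signs
#'   agree with \code{y} everywhere.
#' @export
update_z <- function(y, theta, items) {
  y <- as_response_matrix(y)
  stopifnot(inherits(items, "item_parameters"))
  n <- nrow(y); k <- ncol(y)
  theta <- trait_vector(theta, n)
  if (items$k != k) stop("item count does not match ncol(y)")
  z <- draw_z_block(unclass(y), theta, items$alpha, items$beta)
  check_augmented(z, y)
  z
}

# Core augmented-data draw on a plain submatrix (any number of rows);
# cells are drawn in row-major order within the block.
draw_z_block <- function(ymat, theta, alpha, beta) {
  n <- nrow(ymat); k <- ncol(ymat)
  eta <- tcrossprod(theta, alpha)
  eta <- sweep(eta, 2L, beta, "-")
  ev <- as.vector(t(eta))
  yv <- as.vector(t(ymat))
  zv <- rtnorm(n * k,
               mean  = ev,
               lower = ifelse(yv == 1, 0, -Inf),
               upper = ifelse(yv == 1, Inf, 0))
  matrix(zv, n, k, byrow = TRUE)
}

#' Full-conditional parameters of the person traits
#'
#' Given the augmented data and current item parameters, each trait's full
#' conditional is normal. Two variants are provided:
#' \describe{
#'   \item{\code{"as-printed"}}{mean \eqn{\sum_j (z_{ij}+\beta_j)\alpha_j /
#'     \sum_j \alpha_j^2}, variance \eqn{1/\sum_j \alpha_j^2} — the update as
#'     commonly printed, which omits the prior-precision term.}
#'   \item{\code{"conjugate"}}{mean \eqn{\sum_j (z_{ij}+\beta_j)\alpha_j /
#'     (1+\sum_j \alpha_j^2)}, variance \eqn{1/(1+\sum_j \alpha_j^2)} — the
#'     exact conjugate update under the stated \eqn{\theta_i \sim N(0,1)}
#'     prior, recommended for identifiability.}
#' }
#'
#' @param z Augmented \code{n x k} matrix.
#' @param items An \code{\link{item_parameters}} object.
#' @param prior_mode \code{"as-printed"} or \code{"conjugate"}.
#' @return A list with \code{mean} (length \code{n}) and scalar
#'   \code{variance}, class \code{"theta_posterior"}.
#' @export
theta_posterior_params <- function(z, items, prior_mode = c("as-printed", "conjugate")) {
  prior_mode <- match.arg(prior_mode)
  stopifnot(inherits(items, "item_parameters"))
  z <- as.matrix(z)
  if (ncol(z) != items$k) stop("ncol(z) does not match item count")
  a2 <- sum(items$alpha^2)
  if (a2 <= 0) stop("degenerate trait conditional: sum of squared slopes is zero")
  s <- as.vector(sweep(z, 2L, items$beta, "+") %*% items$alpha)
  prec <- a2 + if (prior_mode == "conjugate") 1 else 0
  structure(list(mean = s / prec, variance = 1 / prec, prior_mode = prior_mode),
            class = "theta_posterior")
}

#' Draw person traits from their full conditional
#'
#' Independent normal draws, one per person, in ascending person order.
#'
#' @param post A \code{"theta_posterior"} object from
#'   \code{\link{theta_posterior_params}}.
#' @return Numeric trait vector.
#' @export
sample_theta <- function(post) {
  stopifnot(inherits(post, "theta_posterior"))
  stats::rnorm(length(post$mean), mean = post$mean, sd = sqrt(post$variance))
}

#' Cross-product matrix of the item-update design
#'
#' The item full conditional regresses each augmented column on the design
#' \eqn{x = [\theta, -1]}; its cross-product is
#' \eqn{x'x = [[\sum\theta^2, -\sum\theta], [-\sum\theta, n]]}.
#'
#' @param theta Trait vector (length at least 2, not all identical).
#' @return List with \code{xtx}, its inverse \code{inv}, and the upper
#'   Cholesky factor \code{chol_inv} of the inverse.
#' @export
compute_xtx <- function(theta) {
  theta <- trait_vector(theta)
  n <- length(theta)
  if (n < 2L) stop("need at least 2 persons")
  if (stats::var(theta) == 0) {
    stop("degenerate design: all person traits are identical, x'x is singular")
  }
  make_xtx_from_sums(sum(theta), sum(theta^2), n)
}

#' Draw item parameters from their full conditional
#'
#' Third transition step: for each item \code{j} independently, the pair
#' \eqn{\xi_j = (\alpha_j, \beta_j)'} is bivariate normal with mean
#' \eqn{(x'x)^{-1} x' Z_j} and covariance \eqn{(x'x)^{-1}}, restricted to
#' \eqn{\alpha_j > 0}. The restriction is realized by joint rejection: the
#' bivariate pair is redrawn until the slope is positive.
#'
#' @param z Augmented \code{n x k} matrix.
#' @param theta Trait vector of length \code{n}.
#' @param max_rejects Per-item rejection budget per call (default 10000).
#' @return An \code{\link{item_parameters}} object.
#' @export
update_items <- function(z, theta, max_rejects = 10000L) {
  z <- as.matrix(z)
  n <- nrow(z); k <- ncol(z)
  theta <- trait_vector(theta, n)
  xp <- compute_xtx(theta)
  alpha <- numeric(k)
  beta <- numeric(k)
  for (j in seq_len(k)) {
    xi <- draw_item(z[, j], theta, xp, max_rejects, j)
    alpha[j] <- xi[1L]
    beta[j] <- xi[2L]
  }
  item_parameters(alpha, beta)
}

# One item's truncated bivariate-normal draw (joint rejection on the slope).
draw_item <- function(zj, theta, xp, max_rejects, j_label) {
  xz <- c(sum(theta * zj), -sum(zj))
  m <- as.vector(xp$inv %*% xz)
  draws <- 0L
  repeat {
    draws <- draws + 1L
    if (draws > max_rejects) {
      acc <- stats::pnorm(m[1L] / sqrt(xp$inv[1L, 1L]))
      stop(sprintf(
        "truncation stall in item %d: %d proposals rejected (estimated acceptance probability %.3g)",
        j_label, max_rejects, acc))
    }
    xi <- m + as.vector(crossprod(xp$chol_inv, stats::rnorm(2L)))
    if (xi[1L] > 0) return(xi)
  }
}

# x'x pieces from precomputed sums (shared by the serial and blocked paths).
make_xtx_from_sums <- function(s1, s2, n) {
  xtx <- matrix(c(s2, -s1, -s1, n), 2L, 2L)
  det <- n * s2 - s1 * s1
  if (det <= 0) {
    stop("degenerate design: all person traits are identical, x'x is singular")
  }
  inv <- matrix(c(n, s1, s1, s2), 2L, 2L) / det
  structure(list(xtx = xtx, inv = inv, chol_inv = chol(inv)), class = "xtx")
}
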