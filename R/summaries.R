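#' Posterior means and Monte Carlo standard errors
#'
#' Summarizes kept draws: per-item posterior means of slope and intercept
#' with batch-means MCSEs and the difficulty ratio
#' \eqn{\hat\beta_j/\hat\alpha_j} (an item's curve is centred at trait
#' \eqn{\theta = \beta/\alpha}, so larger ratios mean harder items), and
#' per-person trait means with MCSEs. Ratios are carried at full precision;
#' rounding (4 decimals, half-even) happens only at report time.
#'
#' @param samples A \code{"chain_samples"} object from
#'   \code{\link{run_chain}} / \code{\link{run_chain_blocked}}.
#' @return A list of class \code{"posterior_summary"}: \code{items}
#'   (data.frame with \code{item}, \code{alpha_hat}, \code{alpha_mcse},
#'   \code{beta_hat}, \code{beta_mcse}, \code{ratio}), \code{persons}
#'   (data.frame with \code{person}, \code{theta_hat}, \code{theta_mcse})
#'   and \code{kept}.
#' @export
posterior_means <- function(samples) {
  stopifnot(inherits(samples, "chain_samples"))
  m <- samples$kept
  if (is.null(m) || m < 2L || nrow(samples$alpha_draws) < 2L) {
    stop("need at least 2 kept draws to summarize")
  }
  mcse_or_na <- function(col) if (m >= 4L) mcse(col) else NA_real_
  alpha_hat <- colMeans(samples$alpha_draws)
  beta_hat <- colMeans(samples$beta_draws)
  items <- data.frame(
    item = seq_along(alpha_hat),
    alpha_hat = alpha_hat,
    alpha_mcse = apply(samples$alpha_draws, 2L, mcse_or_na),
    beta_hat = beta_hat,
    beta_mcse = apply(samples$beta_draws, 2L, mcse_or_na),
    ratio = difficulty_ratio(alpha_hat, beta_hat)
  )
  persons <- data.frame(
    person = seq_len(ncol(samples$theta_draws)),
    theta_hat = colMeans(samples$theta_draws),
    theta_mcse = apply(samples$theta_draws, 2L, mcse_or_na)
  )
  structure(list(items = items, persons = persons, kept = m),
            class = "posterior_summary")
}

#' Batch-means Monte Carlo standard error
#'
#' Uncertainty of a posterior-mean estimate due to finite (autocorrelated)
#' chain length, estimated by non-overlapping batch means:
#' \eqn{\lfloor\sqrt{M}\rfloor} batches of equal size (trailing remainder
#' dropped), \code{SE = sd(batch means)/sqrt(#batches)}.
#'
#' @param draws Numeric vector of at least 4 kept draws.
#' @return Non-negative scalar standard error.
#' @export
mcse <- function(draws) {
  draws <- as.numeric(draws)
  m <- length(draws)
  if (m < 4L) stop("need at least 4 draws for a batch-means MCSE")
  b <- floor(sqrt(m))
  s <- m %/% b
  means <- colMeans(matrix(draws[seq_len(b * s)], nrow = s, ncol = b))
  stats::sd(means) / sqrt(b)
}

#' Difficulty ratio
#'
#' \eqn{\hat\beta/\hat\alpha}: the trait value at which the item response
#' curve crosses 0.5, i.e. the item's difficulty location. Computed at full
#' precision; round only when reporting (4 decimals, half-even, as
#' conventional in published item tables).
#'
#' @param alpha_hat Positive slope estimate(s).
#' @param beta_hat Intercept estimate(s).
#' @return \code{beta_hat / alpha_hat}, recycled elementwise.
#' @examples
#' round(difficulty_ratio(0.4280, -0.5273), 4)  # -1.2320
#' @export
difficulty_ratio <- function(alpha_hat, beta_hat) {
  if (any(!is.finite(alpha_hat)) || any(!is.finite(beta_hat))) {
    stop("estimates must be finite")
  }
  if (any(alpha_hat <= 0)) stop("`alpha_hat` must be positive")
  beta_hat / alpha_hat
}

#' Trait density table
#'
#' Gaussian kernel density estimate (Silverman's rule-of-thumb bandwidth) of
#' posterior trait estimates over a grid — the tabular analogue of the
#' posterior trait density plot. The default grid spans the mean ± 4 SD,
#' widened to cover the data range, so the density integrates to 1 within
#' 1e-3 by the trapezoid rule.
#'
#' @param theta_hat Numeric vector of at least 10 posterior trait means, or
#'   a \code{"posterior_summary"} (its \code{theta_hat} column is used).
#' @param grid Optional numeric grid; default 512 equispaced points.
#' @return data.frame with columns \code{theta} and \code{density}.
#' @export
trait_density_table <- function(theta_hat, grid = NULL) {
  if (inherits(theta_hat, "posterior_summary")) {
    theta_hat <- theta_hat$persons$theta_hat
  }
  theta_hat <- as.numeric(theta_hat)
  if (length(theta_hat) < 10L) stop("need at least 10 persons for a density estimate")
  s <- stats::sd(theta_hat)
  if (s == 0) stop("degenerate trait estimates: zero variance")
  if (is.null(grid)) {
    m <- mean(theta_hat)
    bw <- stats::bw.nrd0(theta_hat)
    lo <- min(m - 4 * s, min(theta_hat) - 3 * bw)
    hi <- max(m + 4 * s, max(theta_hat) + 3 * bw)
    grid <- seq(lo, hi, length.out = 512L)
  } else {
    grid <- sort(as.numeric(grid))
  }
  d <- stats::density(theta_hat, bw = "nrd0", kernel = "gaussian",
                      from = min(grid), to = max(grid), n = length(grid))
  data.frame(theta = d$x, density = d$y)
}

#' Write a posterior summary as tidy CSV
#'
#' One row per item (\code{alpha_hat}, \code{alpha_mcse}, \code{beta_hat},
#' \code{beta_mcse}, \code{ratio}) and, optionally, one row per person.
#'
#' @param summary A \code{"posterior_summary"}.
#' @param items_path Output CSV path for the item table.
#' @param persons_path Optional output CSV path for the person table.
#' @return Invisibly, the item table.
#' @export
write_posterior_summary <- function(summary, items_path, persons_path = NULL) {
  stopifnot(inherits(summary, "posterior_summary"))
  data.table::fwrite(summary$items, items_path)
  if (!is.null(persons_path)) data.table::fwrite(summary$persons, persons_path)
  invisible(summary$items)
}

#' @export
print.posterior_summary <- function(x, digits = 4, ...) {
  cat(sprintf("2PNO posterior summary (%d kept draws)\n", x$kept))
  it <- x$items
  num <- vapply(it, is.numeric, logical(1L)) & names(it) != "item"
  it[num] <- lapply(it[num], round, digits = digits)
  print(it, row.names = FALSE)
  cat(sprintf("traits: %d persons, mean theta_hat %.3f, sd %.3f\n",
              nrow(x$persons), mean(x$persons$theta_hat),
              stats::sd(x$persons$theta_hat)))
  invisible(x)
}
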