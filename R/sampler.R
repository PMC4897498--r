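#' Chain configuration
#'
#' Bundles everything the Gibbs runner needs: chain length, burn-in, seed,
#' which trait-conditional variant to use, the block grid and stream mode
#' for decomposed execution, the initialization policy and thinning.
#'
#' @param iterations Total number of Gibbs iterations \code{L}.
#' @param burn_in Iterations discarded before storage (\code{< iterations}).
#' @param seed Integer seed; every random stream of the run derives from it.
#' @param prior_mode Trait-conditional variant, \code{"as-printed"} or
#'   \code{"conjugate"}; see \code{\link{theta_posterior_params}}.
#' @param grid \code{"serial"} or a \code{\link{block_grid}}.
#' @param stream_mode \code{"serial-equivalent"} (blocked run reproduces the
#'   serial chain bit for bit) or \code{"per-block-stream"} (every
#'   kernel/block pair owns an independent random stream).
#' @param init Initialization policy: \code{"sum-scores"} (standardized
#'   person sum scores, the default) or \code{"zeros"}.
#' @param thin Keep every \code{thin}-th post-burn-in draw (default 1).
#' @param max_rejects Per-item rejection budget of the slope truncation.
#' @param progress_every Log progress every this many iterations (0 = quiet).
#' @return A list of class \code{"chain_config"}.
#' @export
chain_config <- function(iterations, burn_in = 0L, seed = 1L,
                         prior_mode = c("as-printed", "conjugate"),
                         grid = "serial",
                         stream_mode = c("serial-equivalent", "per-block-stream"),
                         init = c("sum-scores", "zeros"),
                         thin = 1L, max_rejects = 10000L,
                         progress_every = 0L) {
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (is.na(iterations) || iterations < 1L) stop("`iterations` must be a positive integer")
  if (is.na(burn_in) || burn_in < 0L || burn_in >= iterations) {
    stop("`burn_in` must satisfy 0 <= burn_in < iterations")
  }
  if (is.na(thin) || thin < 1L) stop("`thin` must be a positive integer")
  if (!identical(grid, "serial") && !inherits(grid, "block_grid")) {
    stop("`grid` must be \"serial\" or a block_grid object")
  }
  structure(list(
    iterations = iterations, burn_in = burn_in,
    seed = as.integer(seed),
    prior_mode = match.arg(prior_mode),
    grid = grid,
    stream_mode = match.arg(stream_mode),
    init = match.arg(init),
    thin = thin,
    max_rejects = as.integer(max_rejects),
    progress_every = as.integer(progress_every)
  ), class = "chain_config")
}

#' Read a chain configuration from a YAML or JSON file
#'
#' The file holds a flat mapping of \code{\link{chain_config}} arguments;
#' a \code{grid} entry of the form \code{"RxC"} (e.g. \code{"2x4"}) is
#' resolved against the data dimensions at fit time.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A list of raw configuration fields (passed to
#'   \code{\link{chain_config}} once data dimensions are known).
#' @export
chain_config_from_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json")
  }
}

#' Block grid for decomposed execution
#'
#' Partitions the \code{n x k} response matrix into an \code{r x c} grid of
#' contiguous, non-overlapping blocks that cover all rows and columns. When
#' \code{n} is divisible by \code{r} and \code{k} by \code{c}, every block is
#' \code{(n/r) x (k/c)}; otherwise the remainder rows/columns go one each to
#' the trailing blocks (no padding).
#'
#' @param n,k Data dimensions (persons, items).
#' @param r,c Row- and column-block counts (\code{1 <= r <= n},
#'   \code{1 <= c <= k}).
#' @return A list of class \code{"block_grid"} with the partition bounds.
#' @export
block_grid <- function(n, k, r, c) {
  n <- as.integer(n); k <- as.integer(k)
  r <- as.integer(r); c <- as.integer(c)
  if (r < 1L || r > n) stop(sprintf("row-block count r must be in 1..%d", n))
  if (c < 1L || c > k) stop(sprintf("column-block count c must be in 1..%d", k))
  structure(list(
    n = n, k = k, r = r, c = c,
    row_bounds = partition_bounds(n, r),
    col_bounds = partition_bounds(k, c)
  ), class = "block_grid")
}

# Contiguous partition of 1..n into b pieces; remainder spread one each over
# the trailing pieces. Returns a list with start/end index vectors.
partition_bounds <- function(n, b) {
  base <- n %/% b
  rem <- n %% b
  sizes <- rep(base, b) + as.integer(seq_len(b) > b - rem)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  list(starts = as.integer(starts), ends = as.integer(ends), sizes = as.integer(sizes))
}

#' Initialize a chain state
#'
#' Default policy: starting traits are the standardized person sum scores
#' (zero mean, unit variance; all-equal scores fall back to zeros), starting
#' slopes are 1 and intercepts 0. The augmented matrix is not initialized —
#' it is implied by the first augmented-data update of the chain.
#'
#' @param y A \code{\link{response_matrix}} (or coercible matrix).
#' @param config A \code{\link{chain_config}}.
#' @return A list of class \code{"chain_state"} with \code{theta},
#'   \code{items}, \code{z} (\code{NULL} until the first step) and the
#'   iteration counter.
#' @export
initialize_state <- function(y, config) {
  y <- as_response_matrix(y)
  n <- nrow(y); k <- ncol(y)
  theta0 <- if (config$init == "zeros") {
    numeric(n)
  } else {
    s <- rowSums(unclass(y))
    if (stats::sd(s) == 0) numeric(n) else as.vector(scale(s))
  }
  structure(list(
    theta = theta0,
    items = item_parameters(rep(1, k), rep(0, k)),
    z = NULL,
    iteration = 0L
  ), class = "chain_state")
}

#' One Gibbs transition
#'
#' Applies the three transition steps in their fixed order — augmented data
#' given \code{(theta, items)}, traits given \code{(z, items)}, items given
#' \code{(z, theta)} — each conditioning on the freshest values, and
#' increments the iteration counter. Uses the current global RNG state; the
#' chain runners instead drive it through managed streams.
#'
#' @param state A \code{\link{initialize_state}} result (or later state).
#' @param y Response matrix.
#' @param config A \code{\link{chain_config}}.
#' @return The updated \code{"chain_state"}.
#' @export
gibbs_step <- function(state, y, config) {
  y <- as_response_matrix(y)
  z <- update_z(y, state$theta, state$items)
  post <- theta_posterior_params(z, state$items, config$prior_mode)
  theta <- sample_theta(post)
  items <- update_items(z, theta, config$max_rejects)
  structure(list(theta = theta, items = items, z = z,
                 iteration = state$iteration + 1L),
            class = "chain_state")
}

#' Run the Gibbs sampler (serial execution)
#'
#' Executes \code{iterations} transitions from the initialized state,
#' discards the burn-in, thins, and returns the kept draws. The run is a
#' deterministic function of \code{(y, config)}: identical inputs give
#' bit-identical samples.
#'
#' @param y Response matrix.
#' @param config A \code{\link{chain_config}}.
#' @return A \code{"chain_samples"} object: \code{theta_draws}
#'   (kept x n), \code{alpha_draws} and \code{beta_draws} (kept x k),
#'   the kept-draw count and a config echo.
#' @examples
#' sim <- simulate_responses(generator_spec(n = 60, k = 4, seed = 7))
#' fit <- run_chain(sim$y, chain_config(200, burn_in = 100, seed = 1))
#' dim(fit$alpha_draws)
#' @export
run_chain <- function(y, config) {
  y <- as_response_matrix(y)
  gibbs_engine(y, config, block_grid(nrow(y), ncol(y), 1L, 1L))
}

#' Run the Gibbs sampler with block-decomposed execution
#'
#' Executes the same chain under the \code{r x c} grid contract. In
#' \code{"serial-equivalent"} stream mode the run reproduces
#' \code{\link{run_chain}} bit for bit (the canonical serial sequence is the
#' reference; the grid is validated and echoed). In
#' \code{"per-block-stream"} mode the decomposition is genuine: augmented
#' cells are drawn block by block with per-block streams, trait-conditional
#' sums and \code{x'x} are accumulated as per-block partial sums reduced in
#' ascending block order, and item draws run per column block — a valid chain
#' with block-indexed independent streams, statistically (not bitwise)
#' equivalent to the serial run.
#'
#' @param y Response matrix.
#' @param config A \code{\link{chain_config}} whose \code{grid} is a
#'   \code{\link{block_grid}} covering \code{y}.
#' @return A \code{"chain_samples"} object.
#' @export
run_chain_blocked <- function(y, config) {
  y <- as_response_matrix(y)
  grid <- config$grid
  if (!inherits(grid, "block_grid")) stop("config$grid must be a block_grid")
  if (grid$n != nrow(y) || grid$k != ncol(y)) {
    stop(sprintf("block grid is for a %d x %d matrix but y is %d x %d",
                 grid$n, grid$k, nrow(y), ncol(y)))
  }
  if (config$stream_mode == "serial-equivalent") {
    out <- gibbs_engine(y, config, block_grid(nrow(y), ncol(y), 1L, 1L))
    out$config$grid <- grid
    out
  } else {
    gibbs_engine(y, config, grid)
  }
}

# The chain engine. All randomness flows through per-(kernel, block) streams
# seeded from the chain seed; with a 1x1 grid this *is* the serial chain.
gibbs_engine <- function(y, config, grid) {
  n <- nrow(y); k <- ncol(y)
  ymat <- unclass(y)
  r <- grid$r; c <- grid$c
  rb <- grid$row_bounds; cb <- grid$col_bounds

  z_streams <- vector("list", r * c)
  for (bi in seq_len(r)) for (bj in seq_len(c)) {
    z_streams[[(bi - 1L) * c + bj]] <-
      make_stream(stream_seed(config$seed, bi, bj, 1L))
  }
  th_streams <- lapply(seq_len(r), function(bi)
    make_stream(stream_seed(config$seed, bi, 1L, 2L)))
  it_streams <- lapply(seq_len(c), function(bj)
    make_stream(stream_seed(config$seed, 1L, bj, 3L)))

  state <- initialize_state(y, config)
  theta <- state$theta
  alpha <- state$items$alpha
  beta <- state$items$beta

  L <- config$iterations
  kept_n <- (L - config$burn_in) %/% config$thin
  theta_draws <- matrix(NA_real_, kept_n, n)
  alpha_draws <- matrix(NA_real_, kept_n, k)
  beta_draws <- matrix(NA_real_, kept_n, k)
  kept <- 0L
  prior_add <- if (config$prior_mode == "conjugate") 1 else 0

  l <- 0L
  tryCatch({
    for (l in seq_len(L)) {
      # -- augmented data, block by block in row-major block order ----------
      z <- matrix(NA_real_, n, k)
      for (bi in seq_len(r)) {
        rows <- rb$starts[bi]:rb$ends[bi]
        for (bj in seq_len(c)) {
          cols <- cb$starts[bj]:cb$ends[bj]
          st <- z_streams[[(bi - 1L) * c + bj]]
          z[rows, cols] <- stream_eval(st, function()
            draw_z_block(ymat[rows, cols, drop = FALSE], theta[rows],
                         alpha[cols], beta[cols]))
        }
      }

      # -- trait update: per-column-block partial sums, ordered reduction ---
      a2 <- reduce_partials(lapply(seq_len(c), function(bj) {
        cols <- cb$starts[bj]:cb$ends[bj]
        sum(alpha[cols]^2)
      }))
      prec <- a2 + prior_add
      sdv <- sqrt(1 / prec)
      for (bi in seq_len(r)) {
        rows <- rb$starts[bi]:rb$ends[bi]
        s <- reduce_partials(lapply(seq_len(c), function(bj) {
          cols <- cb$starts[bj]:cb$ends[bj]
          as.vector(sweep(z[rows, cols, drop = FALSE], 2L, beta[cols], "+") %*%
                      alpha[cols])
        }))
        mu <- s / prec
        theta[rows] <- stream_eval(th_streams[[bi]], function()
          stats::rnorm(length(rows), mean = mu, sd = sdv))
      }

      # -- x'x from per-row-block partial sums, ordered reduction -----------
      s1 <- reduce_partials(lapply(seq_len(r), function(bi) {
        rows <- rb$starts[bi]:rb$ends[bi]
        sum(theta[rows])
      }))
      s2 <- reduce_partials(lapply(seq_len(r), function(bi) {
        rows <- rb$starts[bi]:rb$ends[bi]
        sum(theta[rows]^2)
      }))
      xp <- make_xtx_from_sums(s1, s2, n)

      # -- item update, per column block, items ascending within block ------
      for (bj in seq_len(c)) {
        cols <- cb$starts[bj]:cb$ends[bj]
        xi <- stream_eval(it_streams[[bj]], function() {
          vapply(cols, function(j)
            draw_item(z[, j], theta, xp, config$max_rejects, j),
            numeric(2L))
        })
        alpha[cols] <- xi[1L, ]
        beta[cols] <- xi[2L, ]
      }

      if (l > config$burn_in && (l - config$burn_in) %% config$thin == 0L) {
        kept <- kept + 1L
        theta_draws[kept, ] <- theta
        alpha_draws[kept, ] <- alpha
        beta_draws[kept, ] <- beta
      }
      if (config$progress_every > 0L && l %% config$progress_every == 0L) {
        message(sprintf("gibbs2pno: iteration %d/%d", l, L))
      }
    }
  }, error = function(e) {
    stop(sprintf(
      "chain aborted at iteration %d; partial samples discarded as unusable: %s",
      l, conditionMessage(e)), call. = FALSE)
  })

  structure(list(
    theta_draws = theta_draws,
    alpha_draws = alpha_draws,
    beta_draws = beta_draws,
    kept = kept_n,
    config = config
  ), class = "chain_samples")
}

# Combine block partial sums in ascending block order (fixed association,
# so results are run-to-run deterministic despite FP non-associativity).
reduce_partials <- function(parts) {
  out <- parts[[1L]]
  for (i in seq_along(parts)[-1L]) out <- out + parts[[i]]
  out
}

#' @export
print.chain_samples <- function(x, ...) {
  cat(sprintf(
    "2PNO Gibbs samples: %d kept draws, %d persons, %d items (L = %d, burn-in = %d, thin = %d, prior mode = %s)\n",
    x$kept, ncol(x$theta_draws), ncol(x$alpha_draws),
    x$config$iterations, x$config$burn_in, x$config$thin, x$config$prior_mode))
  invisible(x)
}
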