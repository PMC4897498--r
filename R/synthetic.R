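#' Specification for a synthetic 2PNO data set
#'
#' Describes how to generate a response matrix with known truth: sizes,
#' the item-parameter laws and a seed. The default slope law, uniform on
#' [0.3, 1.3], brackets the slope range typically reported for broad
#' achievement tests while allowing steeper items; intercepts default to
#' standard normal and traits are always standard normal.
#'
#' Supported laws: \code{list(dist = "uniform", min =, max =)},
#' \code{list(dist = "normal", mean =, sd =)} and
#' \code{list(dist = "fixed", values =)} (recycled to length \code{k}).
#' The slope law's support must be strictly positive.
#'
#' @param n,k Persons (>= 2) and items (>= 1).
#' @param alpha_law Distribution spec for slopes.
#' @param beta_law Distribution spec for intercepts.
#' @param seed Integer seed.
#' @return A list of class \code{"generator_spec"}.
#' @export
generator_spec <- function(n, k,
                           alpha_law = list(dist = "uniform", min = 0.3, max = 1.3),
                           beta_law = list(dist = "normal", mean = 0, sd = 1),
                           seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 2L) stop("need n >= 2 persons")
  if (k < 1L) stop("need k >= 1 items")
  check_law(alpha_law, positive = TRUE, what = "alpha_law")
  check_law(beta_law, positive = FALSE, what = "beta_law")
  structure(list(n = n, k = k, alpha_law = alpha_law, beta_law = beta_law,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

check_law <- function(law, positive, what) {
  if (!is.list(law) || is.null(law$dist)) {
    stop(sprintf("`%s` must be a list with a `dist` field", what))
  }
  switch(law$dist,
    uniform = {
      if (is.null(law$min) || is.null(law$max) || law$min >= law$max) {
        stop(sprintf("`%s`: uniform law needs min < max", what))
      }
      if (positive && law$min <= 0) {
        stop(sprintf("`%s` support must be strictly positive", what))
      }
    },
    normal = {
      if (positive) {
        stop(sprintf("`%s` support must be strictly positive; a normal law is not", what))
      }
      if (is.null(law$mean) || is.null(law$sd) || law$sd < 0) {
        stop(sprintf("`%s`: normal law needs mean and sd >= 0", what))
      }
    },
    fixed = {
      if (is.null(law$values) || length(law$values) < 1L) {
        stop(sprintf("`%s`: fixed law needs `values`", what))
      }
      if (positive && any(law$values <= 0)) {
        stop(sprintf("`%s` support must be strictly positive", what))
      }
    },
    stop(sprintf("`%s`: unknown distribution \"%s\"", what, law$dist))
  )
  invisible(law)
}

draw_law <- function(law, k) {
  switch(law$dist,
    uniform = stats::runif(k, law$min, law$max),
    normal = stats::rnorm(k, law$mean, law$sd),
    fixed = rep_len(as.numeric(law$values), k)
  )
}

#' Simulate 2PNO responses with known truth
#'
#' Draws traits \eqn{\theta_i \sim N(0,1)}, item parameters from their laws,
#' then responses \eqn{y_{ij} \sim \mathrm{Bernoulli}(\Phi(\alpha_j\theta_i -
#' \beta_j))} independently. Draw order is fixed (traits, slopes, intercepts,
#' response uniforms), so a given seed always yields the same data set. The
#' generating truth is returned alongside the data so recovery studies never
#' re-derive it.
#'
#' @param spec A \code{\link{generator_spec}}.
#' @return List with \code{y} (a \code{\link{response_matrix}}),
#'   \code{items} (true \code{\link{item_parameters}}) and \code{theta}
#'   (true trait vector).
#' @export
simulate_responses <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  theta <- stats::rnorm(spec$n)
  alpha <- draw_law(spec$alpha_law, spec$k)
  beta <- draw_law(spec$beta_law, spec$k)
  p <- response_probability(rep(alpha, each = spec$n),
                            rep(beta, each = spec$n),
                            rep(theta, times = spec$k))
  y <- matrix(as.numeric(stats::runif(spec$n * spec$k) < p), spec$n, spec$k)
  list(y = response_matrix(y),
       items = item_parameters(alpha, beta),
       theta = theta)
}

#' Fully crossed condition grid of generator specs
#'
#' Builds one \code{\link{generator_spec}} per (n, k) combination, row-major
#' by \code{n} then \code{k} — the usual layout of a sample-size by
#' test-length simulation design. Duplicates are preserved.
#'
#' @param n_list,k_list Non-empty integer vectors.
#' @param ... Passed on to \code{\link{generator_spec}} (laws, seed).
#' @return List of \code{generator_spec} objects, length
#'   \code{length(n_list) * length(k_list)}.
#' @export
condition_grid <- function(n_list, k_list, ...) {
  if (length(n_list) < 1L || length(k_list) < 1L) {
    stop("`n_list` and `k_list` must be non-empty")
  }
  out <- vector("list", length(n_list) * length(k_list))
  i <- 0L
  for (n in n_list) for (k in k_list) {
    i <- i + 1L
    out[[i]] <- generator_spec(n = n, k = k, ...)
  }
  out
}

#' Write a simulated data set and its truth sidecars
#'
#' The response matrix goes to \code{data_path} as CSV; the generating truth
#' goes next to it (item truth: \code{alpha}, \code{beta}; person truth:
#' \code{theta}).
#'
#' @param sim Result of \code{\link{simulate_responses}}.
#' @param data_path Response-matrix CSV path.
#' @param item_truth_path,person_truth_path Sidecar CSV paths; default
#'   \code{<data>_items.csv} / \code{<data>_persons.csv}.
#' @return Invisibly, the three paths.
#' @export
write_simulation <- function(sim, data_path,
                             item_truth_path = NULL, person_truth_path = NULL) {
  stem <- tools::file_path_sans_ext(data_path)
  if (is.null(item_truth_path)) item_truth_path <- paste0(stem, "_items.csv")
  if (is.null(person_truth_path)) person_truth_path <- paste0(stem, "_persons.csv")
  write_response_matrix(sim$y, data_path)
  data.table::fwrite(data.frame(item = seq_len(sim$items$k),
                                alpha = sim$items$alpha,
                                beta = sim$items$beta),
                     item_truth_path)
  data.table::fwrite(data.frame(person = seq_along(sim$theta),
                                theta = sim$theta),
                     person_truth_path)
  invisible(c(data = data_path, items = item_truth_path,
              persons = person_truth_path))
}
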