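#' Construct and validate a binary response matrix
#'
#' The observed data for the 2PNO model: an \code{n x k} matrix \code{y} with
#' \code{y[i, j] = 1} if person \code{i} answered item \code{j} correctly and
#' \code{0} otherwise. Persons index rows, items index columns.
#'
#' @param values Numeric or integer matrix whose entries are all exactly 0
#'   or 1. At least 2 rows (persons) and 1 column (items).
#' @param person_ids Optional character vector of length \code{n} with person
#'   labels; stored as row names.
#' @param item_ids Optional character vector of length \code{k} with item
#'   labels; stored as column names.
#' @return The validated matrix with class \code{"response_matrix"}.
#' @examples
#' y <- response_matrix(matrix(c(1, 1, 1, 0, 0, 0), nrow = 3, byrow = TRUE))
#' attr(y, "n")
#' @export
response_matrix <- function(values, person_ids = NULL, item_ids = NULL) {
  if (!is.matrix(values)) {
    stop("`values` must be a matrix (persons in rows, items in columns)")
  }
  storage.mode(values) <- "double"
  bad <- which(!(values == 0 | values == 1) | !is.finite(values))
  if (length(bad) > 0L) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    stop(sprintf(
      "response matrix entries must be 0 or 1; found %s at row %d, column %d",
      format(values[i, j]), i, j
    ))
  }
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2L) stop("need at least 2 persons (rows)")
  if (k < 1L) stop("need at least 1 item (column)")
  if (!is.null(person_ids)) {
    if (length(person_ids) != n) stop("`person_ids` must have length n")
    rownames(values) <- as.character(person_ids)
  }
  if (!is.null(item_ids)) {
    if (length(item_ids) != k) stop("`item_ids` must have length k")
    colnames(values) <- as.character(item_ids)
  }
  structure(values, n = n, k = k, class = c("response_matrix", "matrix"))
}

# Coerce plain matrices on entry to user-facing functions.
as_response_matrix <- function(y) {
  if (inherits(y, "response_matrix")) return(y)
  response_matrix(as.matrix(y))
}

#' Construct and validate item parameters
#'
#' Per-item slope (discrimination) \eqn{\alpha_j > 0} and intercept
#' \eqn{\beta_j} of the 2PNO linear predictor \eqn{\alpha_j \theta_i -
#' \beta_j}. The pair \eqn{\xi_j = (\alpha_j, \beta_j)'} is what the item
#' full conditional updates jointly.
#'
#' @param alpha Numeric vector of positive slopes, length \code{k}.
#' @param beta Numeric vector of intercepts, length \code{k}.
#' @return A list with components \code{alpha}, \code{beta}, \code{k}, of
#'   class \code{"item_parameters"}.
#' @export
item_parameters <- function(alpha, beta) {
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  if (length(alpha) != length(beta)) {
    stop("`alpha` and `beta` must have equal length")
  }
  if (length(alpha) < 1L) stop("need at least one item")
  if (any(!is.finite(alpha)) || any(!is.finite(beta))) {
    stop("item parameters must be finite")
  }
  if (any(alpha <= 0)) {
    stop(sprintf("all slopes must be positive; alpha[%d] = %g",
                 which(alpha <= 0)[1L], alpha[which(alpha <= 0)[1L]]))
  }
  structure(list(alpha = alpha, beta = beta, k = length(alpha)),
            class = "item_parameters")
}

#' Validate a latent trait vector
#'
#' @param theta Numeric vector of person traits on the standard-normal scale.
#' @param n Optional expected length (the person count of the response
#'   matrix the traits belong to).
#' @return The validated numeric vector.
#' @export
trait_vector <- function(theta, n = NULL) {
  theta <- as.numeric(theta)
  if (any(!is.finite(theta))) stop("traits must be finite")
  if (!is.null(n) && length(theta) != n) {
    stop(sprintf("trait vector has length %d, expected %d", length(theta), n))
  }
  theta
}

# Sign agreement between augmented data and responses: z > 0 where y = 1,
# z < 0 where y = 0; exact zeros have probability zero and are rejected.
check_augmented <- function(z, y) {
  if (!all(dim(z) == dim(y))) stop("augmented matrix dimensions do not match y")
  if (any(z == 0)) stop("augmented variable is exactly zero (probability-zero event); rejected")
  ok <- (z > 0) == (unclass(y) == 1)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    i <- ((bad - 1L) %% nrow(z)) + 1L
    j <- ((bad - 1L) %/% nrow(z)) + 1L
    stop(sprintf("sign(z) disagrees with y at row %d, column %d", i, j))
  }
  invisible(z)
}

#' 2PNO response probability
#'
#' Probability of a correct response under the two-parameter normal ogive
#' model, \eqn{P(y_{ij} = 1) = \Phi(\alpha_j \theta_i - \beta_j)}, where
#' \eqn{\Phi} is the standard normal CDF (evaluated through the numerically
#' stable erf/erfc route of \code{stats::pnorm}, so extreme linear predictors
#' return probabilities strictly inside (0,1) up to double-precision limits).
#'
#' Inputs are recycled elementwise, so scalars and vectors mix freely.
#'
#' @param alpha Slope(s), strictly positive.
#' @param beta Intercept(s).
#' @param theta Trait value(s).
#' @return Probabilities in (0, 1), strictly increasing in \code{theta}.
#' @examples
#' response_probability(1, 0, 0)                 # 0.5 by symmetry
#' response_probability(0.4280, -0.5273, -1.2320) # the item's 50% point
#' @export
response_probability <- function(alpha, beta, theta) {
  if (any(!is.finite(alpha)) || any(!is.finite(beta)) || any(!is.finite(theta))) {
    stop("all inputs must be finite")
  }
  if (any(alpha <= 0)) stop("slope `alpha` must be positive")
  stats::pnorm(alpha * theta - beta)
}

#' Item response curve
#'
#' Evaluates one item's 2PNO response probability along a grid of trait
#' values; the curve is monotone nondecreasing along an increasing grid.
#'
#' @param params An \code{\link{item_parameters}} object.
#' @param item_index Which item (1-based column index).
#' @param theta_grid Numeric vector of trait values.
#' @return Numeric vector of probabilities, same length as \code{theta_grid}.
#' @export
item_response_curve <- function(params, item_index, theta_grid) {
  stopifnot(inherits(params, "item_parameters"))
  item_index <- as.integer(item_index)
  if (length(item_index) != 1L || is.na(item_index) ||
      item_index < 1L || item_index > params$k) {
    stop(sprintf("item_index out of range 1..%d", params$k))
  }
  response_probability(params$alpha[item_index], params$beta[item_index],
                       trait_vector(theta_grid))
}
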