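#' Rescale a criterion surface to a desirability in [0, 1]
#'
#' Linear-ramp desirability: with `L = min(values)` and `U = max(values)`
#' taken over the evaluated surface itself (so desirabilities are relative
#' to the screening run, and the user need not supply limits),
#' a maximized criterion maps as `(x - L)/(U - L)` and a minimized one as
#' `(U - x)/(U - L)`, clipped to [0, 1]. A constant surface carries no
#' information for discrimination and maps to 1 everywhere. Fixed limits can
#' be supplied to override the run-relative ones.
#'
#' @param values Numeric surface (matrix or vector), finite.
#' @param direction `"maximize"` or `"minimize"`.
#' @param limits Optional length-2 `c(L, U)` overriding the observed range.
#' @return Surface of the same shape with values in [0, 1].
#' @examples
#' scale_criterion(c(0, 5, 10), "maximize")   # 0.0 0.5 1.0
#' scale_criterion(c(10, 20), "minimize")     # 1 0
#' @export
scale_criterion <- function(values, direction = c("maximize", "minimize"),
                            limits = NULL) {
  direction <- match.arg(direction)
  if (!length(values) || any(!is.finite(values)))
    stop("criterion values must be non-empty and finite", call. = FALSE)
  if (is.null(limits)) limits <- range(values)
  L <- limits[1]; U <- limits[2]
  if (U <= L) {
    d <- values * 0 + 1          # non-discriminating criterion
  } else {
    d <- (values - L) / (U - L)
    if (direction == "minimize") d <- 1 - d
    d <- pmin(pmax(d, 0), 1)
  }
  d
}

#' Weighted geometric-mean desirability index
#'
#' Combines per-criterion desirabilities into one index,
#' \deqn{D = \prod_i d_i^{\,w_i / \sum_j w_j},}
#' a true weighted geometric mean: weights are normalized to sum to one, so
#' `D` stays in [0, 1], equals the common value when all `d_i` agree, and is
#' zero whenever any criterion with positive weight is fully undesirable —
#' the veto property that makes the geometric mean stricter than the
#' arithmetic one.
#'
#' `d_values` may be a vector (one condition) or a matrix with one column
#' per criterion (many conditions at once).
#'
#' @param d_values Desirabilities in [0, 1]; vector of length k or an
#'   n x k matrix.
#' @param weights Non-negative weights of length k, not all zero. Default
#'   `c(1, 0.5, 0.1)` — separation is the "must have", sensitivity matters
#'   half as much, a short analysis time is "nice to have".
#' @return Numeric vector of index values in [0, 1].
#' @examples
#' desirability_index(c(0.8, 0.8, 0.8))                  # 0.8
#' desirability_index(c(1, 1, 0))                        # 0 (veto)
#' desirability_index(c(1, 1, 0.5))                      # 0.5^(0.1/1.6)
#' @export
desirability_index <- function(d_values, weights = c(1, 0.5, 0.1)) {
  if (is.null(dim(d_values))) d_values <- matrix(d_values, nrow = 1)
  if (any(weights < 0) || !any(weights > 0))
    stop("weights must be non-negative with at least one positive",
         call. = FALSE)
  if (length(weights) != ncol(d_values))
    stop("need one weight per criterion (", ncol(d_values), ")",
         call. = FALSE)
  if (any(d_values < 0 | d_values > 1))
    stop("desirabilities must lie in [0, 1]", call. = FALSE)
  w <- weights / sum(weights)
  # contributions w_i * log d_i, with the d^0 = 1 convention for dropped
  # (zero-weight) criteria even at d = 0
  contrib <- sweep(log_zero_safe(d_values), 2, w, `*`)
  contrib[, w == 0] <- 0
  drop(exp(.rowSums(contrib, nrow(d_values), length(w))))
}

# log with log(0) = -Inf kept (exp later maps it back to 0); avoids NaN
# warnings from negative rounding noise
log_zero_safe <- function(x) {
  out <- suppressWarnings(log(x))
  out[x <= 0] <- -Inf
  out
}

#' Sample criterion-weight vectors from a Dirichlet distribution
#'
#' The user states relative weights; their exact values are uncertain. That
#' uncertainty is modeled by a Dirichlet distribution on the weight simplex
#' with concentration \eqn{\alpha_i = w_i \times c}, where `c` is a
#' confidence factor: the ratios of the weights fix the location
#' (\eqn{E[w_i] = \alpha_i/\sum\alpha}) and `c` fixes the spread — larger
#' `c`, tighter draws around the stated weights. At the defaults
#' (weights 1, 0.5, 0.1 and confidence 100) the concentration is
#' (100, 50, 10).
#'
#' Sampling uses the standard gamma construction: independent
#' Gamma(\eqn{\alpha_i}, 1) variates normalized by their sum.
#'
#' @param n Number of weight vectors to draw.
#' @param weights Base relative weights, all strictly positive (drop a
#'   criterion explicitly rather than zeroing its weight — a zero
#'   concentration parameter is degenerate).
#' @param confidence_factor Positive scalar, default 100.
#' @param seed Optional integer seed (caller's RNG state preserved).
#' @return n x k matrix, each row on the simplex (sums to 1).
#' @export
sample_weights <- function(n, weights = c(1, 0.5, 0.1),
                           confidence_factor = 100, seed = NULL) {
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  if (!is_scalar_number(confidence_factor) || confidence_factor <= 0)
    stop("'confidence_factor' must be a positive number", call. = FALSE)
  alpha <- weights * confidence_factor
  if (any(alpha <= 0))
    stop("all weights must be strictly positive; drop a criterion ",
         "explicitly instead of setting its weight to 0", call. = FALSE)
  if (!is.null(seed)) {
    rng_state <- get_rng_state()
    on.exit(restore_rng_state(rng_state))
    set.seed(seed)
  }
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Per-criterion desirability surfaces and the index surface
#'
#' Applies [scale_criterion()] to each criterion (separation and sensitivity
#' maximized, analysis time minimized) and combines them with
#' [desirability_index()] at the base weights.
#'
#' @param criteria A [criteria_surfaces()] object.
#' @param weights Base criterion weights `(separation, sensitivity,
#'   analysis time)`; default `c(1, 0.5, 0.1)`.
#' @return Object of class `desirability_surfaces`: matrices `d_separation`,
#'   `d_sensitivity`, `d_analysis_time`, `index`, plus `weights` and `grid`.
#' @export
desirability_surfaces <- function(criteria, weights = c(1, 0.5, 0.1)) {
  stopifnot(inherits(criteria, "criteria_surfaces"))
  d_sep <- scale_criterion(criteria$separation, "maximize")
  d_sen <- scale_criterion(criteria$sensitivity, "maximize")
  d_ana <- scale_criterion(criteria$analysis_time, "minimize")
  idx <- desirability_index(
    cbind(as.vector(d_sep), as.vector(d_sen), as.vector(d_ana)), weights)
  index <- matrix(idx, nrow(d_sep), ncol(d_sep), dimnames = dimnames(d_sep))
  structure(list(d_separation = d_sep, d_sensitivity = d_sen,
                 d_analysis_time = d_ana, index = index,
                 weights = weights, grid = criteria$grid),
            class = "desirability_surfaces")
}

#' @export
print.desirability_surfaces <- function(x, ...) {
  cat("Desirability surfaces (weights ",
      paste(format(x$weights), collapse = "/"), "):\n", sep = "")
  cat(sprintf("  index D: [%.3g, %.3g], %d condition(s) at D = 0\n",
              min(x$index), max(x$index), sum(x$index == 0)))
  invisible(x)
}

#' Probability of reaching the desirability threshold under weight draws
#'
#' Robustness of the desirability map to the stated weights: the
#' per-criterion desirabilities are computed once and frozen (retention
#' Monte-Carlo is not resampled — only the weights vary, isolating weight
#' uncertainty), then for each sampled weight vector the index is
#' recomputed, and per condition the fraction of weight draws with
#' `D >= threshold` is reported. A condition at exactly the threshold counts
#' as reaching it.
#'
#' @param desirability A [desirability_surfaces()] object (or an n x k
#'   matrix of per-criterion desirabilities).
#' @param weight_draws Matrix of weight vectors from [sample_weights()].
#' @param threshold Desirability-index threshold in (0, 1).
#' @return Matrix (same shape as the index surface) of probabilities in
#'   [0, 1], or a vector if a bare matrix of desirabilities was supplied.
#' @export
probability_surface <- function(desirability, weight_draws, threshold) {
  if (!is.matrix(weight_draws) || !nrow(weight_draws))
    stop("'weight_draws' must be a non-empty matrix of weight vectors",
         call. = FALSE)
  # threshold 0 is the degenerate lower limit (always reached); it arises
  # when the auto rule finds every condition admissible
  if (threshold < 0 || threshold >= 1)
    stop("'threshold' must be in [0, 1)", call. = FALSE)
  shaped <- inherits(desirability, "desirability_surfaces")
  d_mat <- if (shaped) {
    cbind(as.vector(desirability$d_separation),
          as.vector(desirability$d_sensitivity),
          as.vector(desirability$d_analysis_time))
  } else desirability
  if (ncol(d_mat) != ncol(weight_draws))
    stop("criterion count mismatch between desirabilities and weight draws",
         call. = FALSE)
  # D for all (condition, draw) pairs in one product: rows of weight_draws
  # already sum to 1, so no renormalization is needed
  log_d <- log_zero_safe(d_mat)                 # n_cond x k
  log_D <- log_d %*% t(weight_draws)            # n_cond x n_draws
  log_D[is.nan(log_D)] <- -Inf                  # 0 * -Inf guard
  p <- .rowMeans(log_D >= log(threshold), nrow(log_D), ncol(log_D))
  if (shaped) {
    matrix(p, nrow(desirability$index), ncol(desirability$index),
           dimnames = dimnames(desirability$index))
  } else p
}
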