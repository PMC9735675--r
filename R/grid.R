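#' Uniform grid of screening conditions
#'
#' The screening criteria are evaluated over a rectangular, uniformly spaced
#' grid of mobile-phase pH and gradient-time values. Uniform spacing per axis
#' is required by the finite-difference sensitivity criterion, and at least
#' three levels per axis are needed for interior central differences. The
#' default grid (pH 2.7-8.0 in steps of 0.1, tG 20-60 min in steps of 2 min)
#' covers the instrument ranges of the study design at a resolution fine
#' enough to localize co-elution bands.
#'
#' @param ph_values Ascending numeric vector of pH levels (uniformly spaced,
#'   length >= 3).
#' @param tg_values Ascending numeric vector of gradient times in minutes
#'   (uniformly spaced, length >= 3).
#' @return Object of class `condition_grid`: list with `ph_values`,
#'   `tg_values`, and `conditions`, a data frame of all grid points in
#'   pH-major order (ph varies slowest).
#' @examples
#' g <- condition_grid()
#' dim(g$conditions)   # 1134 conditions at the default 54 x 21 resolution
#' @export
condition_grid <- function(ph_values = seq(2.7, 8, by = 0.1),
                           tg_values = seq(20, 60, by = 2)) {
  check_axis(ph_values, "ph_values")
  check_axis(tg_values, "tg_values")
  conditions <- expand.grid(gradient_time_min = tg_values, ph = ph_values,
                            KEEP.OUT.ATTRS = FALSE)[, c("ph",
                                                        "gradient_time_min")]
  structure(list(ph_values = ph_values, tg_values = tg_values,
                 conditions = conditions),
            class = "condition_grid")
}

check_axis <- function(x, label) {
  if (length(x) < 3L)
    stop("'", label, "' needs at least 3 levels", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE))
    stop("'", label, "' must be strictly ascending", call. = FALSE)
  steps <- diff(x)
  if (diff(range(steps)) > 1e-8 * mean(steps))
    stop("'", label, "' must be uniformly spaced", call. = FALSE)
  invisible(x)
}

#' @export
print.condition_grid <- function(x, ...) {
  cat("Condition grid: ", length(x$ph_values), " pH levels [",
      min(x$ph_values), ", ", max(x$ph_values), "] x ",
      length(x$tg_values), " gradient times [", min(x$tg_values), ", ",
      max(x$tg_values), " min] = ", nrow(x$conditions), " conditions\n",
      sep = "")
  invisible(x)
}

#' Monte-Carlo retention-time draws of all compounds over a grid
#'
#' Builds the predictive sample cube: for every compound and every grid
#' condition, `n_draws` Student-t retention-time draws from the fitted
#' models (see [simulate.rsm_model()]), plus the deterministic point
#' predictions used to fix elution order. Each compound gets an independent
#' noise stream derived from `seed`.
#'
#' @param models Named list of `rsm_model` fits, one per compound.
#' @param grid A [condition_grid()].
#' @param n_draws Draws per (compound, condition); default 1000.
#' @param seed Integer seed for reproducibility.
#' @return Object of class `sample_cube`: list with `draws` (3-d array,
#'   compound x condition x draw, minutes), `point_pred` (matrix compound x
#'   condition, minutes), `compounds`, `grid`, `n_draws`, `seed`.
#' @export
sample_cube <- function(models, grid, n_draws = 1000, seed = NULL) {
  if (!length(models)) stop("no models supplied", call. = FALSE)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("'models' must be a named list", call. = FALSE)
  stopifnot(inherits(grid, "condition_grid"))
  nm <- names(models)
  nc <- nrow(grid$conditions)
  draws <- array(NA_real_, dim = c(length(nm), nc, n_draws),
                 dimnames = list(compound = nm, NULL, NULL))
  point <- matrix(NA_real_, length(nm), nc, dimnames = list(nm, NULL))
  for (i in seq_along(nm)) {
    m <- models[[i]]
    point[i, ] <- predict(m, grid$conditions, type = "response",
                          warn_extrapolation = FALSE)
    comp_seed <- if (is.null(seed)) NULL else seed + i
    draws[i, , ] <- simulate(m, nsim = n_draws, seed = comp_seed,
                             newdata = grid$conditions)
  }
  structure(list(draws = draws, point_pred = point, compounds = nm,
                 grid = grid, n_draws = n_draws, seed = seed),
            class = "sample_cube")
}

#' @export
print.sample_cube <- function(x, ...) {
  cat("Predictive sample cube: ", length(x$compounds), " compounds x ",
      nrow(x$grid$conditions), " conditions x ", x$n_draws, " draws\n",
      sep = "")
  invisible(x)
}
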