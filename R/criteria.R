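#' Screening criteria surfaces
#'
#' The three per-condition criteria that drive condition selection, each
#' computed from the Monte-Carlo retention draws of a [sample_cube()]:
#'
#' * **Separation** `S` — baseline separation of the critical pair. Per
#'   condition, compounds are ordered by decreasing point-predicted
#'   retention; for each adjacent pair the per-draw gap
#'   \eqn{t_{R,i} - t_{R,i+1} - w_{0,i,l} - w_{0,i+1,r}} (later peak's left
#'   half-width and earlier peak's right half-width subtracted) is formed,
#'   its lower quantile (default 10%) taken over draws, and the minimum over
#'   pairs kept. Negative values flag predicted co-elution at baseline.
#' * **Sensitivity** `R` — the mean absolute rate of change of `S` along the
#'   two experimental axes, a robustness-of-prediction measure. Central
#'   finite differences on coded axes (each mapped linearly to [-1, 1] so pH
#'   and tG contribute comparably), one-sided at the grid borders.
#' * **Analysis time** `A` — per condition, the maximum over compounds of
#'   the upper quantile (default 90%) of each compound's draws: the run time
#'   needed to elute everything with high probability.
#'
#' Surfaces are matrices with pH in rows and gradient time in columns.
#'
#' @param cube A [sample_cube()].
#' @param specs Named list of [compound_spec()] covering every compound in
#'   the cube (order irrelevant); supplies the baseline half-widths.
#' @param quantile_level Quantile of the per-pair gap distribution
#'   (separation, default 0.10) or of the per-compound retention
#'   distribution (analysis time, default 0.90).
#' @return A numeric matrix `length(ph_values)` x `length(tg_values)`.
#' @name criteria_surfaces
NULL

#' @rdname criteria_surfaces
#' @export
separation_surface <- function(cube, specs, quantile_level = 0.10) {
  stopifnot(inherits(cube, "sample_cube"))
  if (length(cube$compounds) < 2L)
    stop("separation needs at least 2 compounds", call. = FALSE)
  if (quantile_level <= 0 || quantile_level >= 1)
    stop("'quantile_level' must be in (0, 1)", call. = FALSE)
  specs <- match_specs(specs, cube$compounds)
  hw_l <- vapply(specs, `[[`, numeric(1), "half_width_left")
  hw_r <- vapply(specs, `[[`, numeric(1), "half_width_right")

  nc <- nrow(cube$grid$conditions)
  s <- numeric(nc)
  for (j in seq_len(nc)) {
    ord <- order(cube$point_pred[, j], decreasing = TRUE)
    pair_q <- numeric(length(ord) - 1L)
    for (k in seq_len(length(ord) - 1L)) {
      i1 <- ord[k]; i2 <- ord[k + 1L]
      gaps <- cube$draws[i1, j, ] - cube$draws[i2, j, ] - hw_l[i1] - hw_r[i2]
      pair_q[k] <- stats::quantile(gaps, quantile_level, names = FALSE)
    }
    s[j] <- min(pair_q)
  }
  vec_to_surface(s, cube$grid)
}

#' @rdname criteria_surfaces
#' @param separation Separation surface matrix from [separation_surface()].
#' @param grid The [condition_grid()] the surface was computed on.
#' @export
sensitivity_surface <- function(separation, grid) {
  stopifnot(inherits(grid, "condition_grid"))
  np <- length(grid$ph_values); nt <- length(grid$tg_values)
  if (!is.matrix(separation) || nrow(separation) != np ||
      ncol(separation) != nt)
    stop("'separation' must be a ", np, " x ", nt,
         " matrix matching the grid", call. = FALSE)
  d_ph <- axis_derivative(separation, margin = 1L)
  d_tg <- axis_derivative(separation, margin = 2L)
  (abs(d_ph) + abs(d_tg)) / 2
}

# first derivative along one margin of a matrix, on the axis coded to
# [-1, 1]: central second-order differences inside, one-sided at borders
axis_derivative <- function(S, margin) {
  if (margin == 2L) return(t(axis_derivative(t(S), 1L)))
  n <- nrow(S)
  h <- 2 / (n - 1)                     # coded-axis step
  D <- matrix(NA_real_, n, ncol(S))
  D[1, ] <- (S[2, ] - S[1, ]) / h
  D[n, ] <- (S[n, ] - S[n - 1, ]) / h
  if (n > 2L) {
    idx <- 2:(n - 1)
    D[idx, ] <- (S[idx + 1L, , drop = FALSE] -
                 S[idx - 1L, , drop = FALSE]) / (2 * h)
  }
  D
}

#' @rdname criteria_surfaces
#' @export
analysis_time_surface <- function(cube, quantile_level = 0.90) {
  stopifnot(inherits(cube, "sample_cube"))
  if (quantile_level <= 0 || quantile_level >= 1)
    stop("'quantile_level' must be in (0, 1)", call. = FALSE)
  q <- apply(cube$draws, c(1, 2), stats::quantile, probs = quantile_level,
             names = FALSE)
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)   # single compound
  a <- apply(q, 2, max)
  vec_to_surface(a, cube$grid)
}

#' Compute all three criteria surfaces at once
#'
#' @inheritParams separation_surface
#' @param separation_quantile,analysis_quantile Quantile levels for the
#'   separation (default 0.10) and analysis-time (default 0.90) criteria.
#' @return Object of class `criteria_surfaces`: list with matrices
#'   `separation`, `sensitivity`, `analysis_time` and the `grid`.
#' @export
criteria_surfaces <- function(cube, specs, separation_quantile = 0.10,
                              analysis_quantile = 0.90) {
  S <- separation_surface(cube, specs, separation_quantile)
  structure(
    list(separation = S,
         sensitivity = sensitivity_surface(S, cube$grid),
         analysis_time = analysis_time_surface(cube, analysis_quantile),
         grid = cube$grid),
    class = "criteria_surfaces"
  )
}

#' @export
print.criteria_surfaces <- function(x, ...) {
  cat("Criteria surfaces over ", nrow(x$separation), " pH x ",
      ncol(x$separation), " tG conditions:\n", sep = "")
  cat(sprintf("  separation S: [%.3g, %.3g] min (%d condition(s) < 0)\n",
              min(x$separation), max(x$separation), sum(x$separation < 0)))
  cat(sprintf("  sensitivity R: [%.3g, %.3g]\n",
              min(x$sensitivity), max(x$sensitivity)))
  cat(sprintf("  analysis time A: [%.3g, %.3g] min\n",
              min(x$analysis_time), max(x$analysis_time)))
  invisible(x)
}

match_specs <- function(specs, compounds) {
  if (inherits(specs, "compound_spec")) specs <- list(specs)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, `[[`, character(1), "name")
  missing_specs <- setdiff(compounds, names(specs))
  if (length(missing_specs))
    stop("no compound spec for: ", paste(missing_specs, collapse = ", "),
         call. = FALSE)
  specs[compounds]
}

# grid conditions are stored pH-major (tg fastest); surfaces are ph x tg
vec_to_surface <- function(v, grid) {
  m <- t(matrix(v, nrow = length(grid$tg_values),
                ncol = length(grid$ph_values)))
  dimnames(m) <- list(ph = format(grid$ph_values),
                      tg = format(grid$tg_values))
  m
}

surface_to_vec <- function(m) as.vector(t(m))
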