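#' Screening configuration
#'
#' Collects every tunable of the screening pipeline with the study defaults:
#' criterion weights 1 / 0.5 / 0.1 (separation / sensitivity / analysis
#' time), Dirichlet confidence factor 100, desirability threshold chosen
#' automatically so that selected conditions always separate (or a fixed
#' value such as 0.5), probability threshold 30%, pH grid 2.7-8.0 step 0.1,
#' gradient-time grid 20-60 min step 2 min, 1000 retention draws and 1000
#' weight draws.
#'
#' @param ph_range,ph_step,tg_range,tg_step Grid specification.
#' @param n_draws Monte-Carlo retention draws per (compound, condition).
#' @param weights Criterion weights `(separation, sensitivity, analysis
#'   time)`, all > 0.
#' @param confidence_factor Dirichlet confidence factor (> 0).
#' @param n_weight_draws Number of Dirichlet weight vectors.
#' @param desirability_threshold `"auto"` (default; smallest index value
#'   whose super-level set has separation > 0 everywhere) or a fixed value
#'   in (0, 1).
#' @param probability_threshold Region-admissibility probability in (0, 1).
#' @param connectivity Region connectivity, 8 (default) or 4.
#' @param separation_quantile,analysis_quantile Criterion quantile levels.
#' @param ph_fit_range pH range used for equation selection (defaults to
#'   `ph_range`).
#' @param edge_margin,outside_margin [select_equation()] margins (pH units).
#' @param seed Master seed; retention-draw and weight-draw seeds are derived
#'   from it deterministically.
#' @return Object of class `lc_config` (a list).
#' @export
lc_config <- function(ph_range = c(2.7, 8), ph_step = 0.1,
                      tg_range = c(20, 60), tg_step = 2,
                      n_draws = 1000,
                      weights = c(1, 0.5, 0.1),
                      confidence_factor = 100,
                      n_weight_draws = 1000,
                      desirability_threshold = "auto",
                      probability_threshold = 0.30,
                      connectivity = 8,
                      separation_quantile = 0.10,
                      analysis_quantile = 0.90,
                      ph_fit_range = ph_range,
                      edge_margin = 1, outside_margin = 1,
                      seed = 1L) {
  if (!identical(desirability_threshold, "auto") &&
      !(is_scalar_number(desirability_threshold) &&
        desirability_threshold > 0 && desirability_threshold < 1))
    stop("'desirability_threshold' must be \"auto\" or a value in (0, 1)",
         call. = FALSE)
  cfg <- list(ph_range = ph_range, ph_step = ph_step,
              tg_range = tg_range, tg_step = tg_step,
              n_draws = n_draws, weights = weights,
              confidence_factor = confidence_factor,
              n_weight_draws = n_weight_draws,
              desirability_threshold = desirability_threshold,
              probability_threshold = probability_threshold,
              connectivity = connectivity,
              separation_quantile = separation_quantile,
              analysis_quantile = analysis_quantile,
              ph_fit_range = ph_fit_range,
              edge_margin = edge_margin, outside_margin = outside_margin,
              seed = as.integer(seed))
  class(cfg) <- "lc_config"
  cfg
}

#' @export
print.lc_config <- function(x, ...) {
  cat("Screening configuration:\n")
  cat(sprintf("  grid: pH [%g, %g] step %g; tG [%g, %g] min step %g\n",
              x$ph_range[1], x$ph_range[2], x$ph_step,
              x$tg_range[1], x$tg_range[2], x$tg_step))
  cat(sprintf("  draws: %d retention, %d weight; seed %d\n",
              x$n_draws, x$n_weight_draws, x$seed))
  cat(sprintf("  weights %s; confidence %g; D threshold %s; P threshold %g\n",
              paste(format(x$weights), collapse = "/"),
              x$confidence_factor,
              if (identical(x$desirability_threshold, "auto")) "auto"
              else format(x$desirability_threshold),
              x$probability_threshold))
  invisible(x)
}

#' Run the full in silico screening pipeline
#'
#' From a retention table and compound metadata to candidate chromatographic
#' conditions: per compound, select the retention-model equation from the
#' pKa and fit it ([rsm_fit()]); draw Student-t retention samples over the
#' condition grid ([sample_cube()]); compute the separation, sensitivity and
#' analysis-time criteria ([criteria_surfaces()]); rescale and combine them
#' into the desirability index ([desirability_surfaces()]); sample criterion
#' weights from the Dirichlet distribution and compute the probability of
#' reaching the desirability threshold ([probability_surface()]); segment
#' the grid into robust candidate regions ([segment_regions()]) and report
#' the global and largest-region optima ([select_optima()]).
#'
#' @param retention Data frame with columns `compound`, `ph`,
#'   `gradient_time_min`, `retention_time_min`.
#' @param metadata Compound metadata: a data frame in the on-disk format
#'   (see [read_compound_metadata()]) or a (named) list of
#'   [compound_spec()].
#' @param config An [lc_config()].
#' @return Object of class `lc_screen`: list with `models` (named list of
#'   `rsm_model`), `cases` (named character), `grid`, `criteria`,
#'   `desirability`, `probability`, `threshold_used`, `regions`,
#'   `region_table`, `global_optimum`, `largest_region_optimum`, `config`.
#' @examples
#' \donttest{
#' mix <- demo_mixture(seed = 1)
#' res <- lc_screen(mix$retention, mix$metadata,
#'                  lc_config(n_draws = 200, n_weight_draws = 200))
#' res
#' }
#' @export
lc_screen <- function(retention, metadata, config = lc_config()) {
  stopifnot(inherits(config, "lc_config"))
  retention <- validate_retention_table(retention)
  specs <- if (is.data.frame(metadata)) as_compound_specs(metadata)
           else match_specs(metadata, unique(retention$compound))
  compounds <- unique(retention$compound)
  missing_meta <- setdiff(compounds, names(specs))
  if (length(missing_meta))
    stop("no metadata for compound(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  specs <- specs[compounds]

  models <- vector("list", length(compounds)); names(models) <- compounds
  for (cm in compounds) {
    rows <- retention[retention$compound == cm,
                      c("ph", "gradient_time_min", "retention_time_min")]
    models[[cm]] <- tryCatch(
      rsm_fit(rows, compound = specs[[cm]],
              ph_range = config$ph_fit_range,
              edge_margin = config$edge_margin,
              outside_margin = config$outside_margin),
      error = function(e) stop("fit failed for compound '", cm, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  cases <- vapply(models, `[[`, character(1), "case")

  grid <- condition_grid(
    seq(config$ph_range[1], config$ph_range[2], by = config$ph_step),
    seq(config$tg_range[1], config$tg_range[2], by = config$tg_step))
  cube <- sample_cube(models, grid, n_draws = config$n_draws,
                      seed = config$seed)
  criteria <- criteria_surfaces(cube, specs,
                                separation_quantile = config$separation_quantile,
                                analysis_quantile = config$analysis_quantile)
  desirability <- desirability_surfaces(criteria, config$weights)

  threshold <- if (identical(config$desirability_threshold, "auto"))
    auto_threshold(desirability$index, criteria$separation)
  else config$desirability_threshold

  wdraws <- sample_weights(config$n_weight_draws, config$weights,
                           config$confidence_factor,
                           seed = config$seed + 104729L)
  probability <- probability_surface(desirability, wdraws, threshold)
  regions <- segment_regions(probability, config$probability_threshold,
                             config$connectivity)
  optima <- select_optima(desirability$index, regions, grid)

  structure(
    list(models = models, cases = cases, specs = specs, grid = grid,
         criteria = criteria, desirability = desirability,
         probability = probability, threshold_used = threshold,
         regions = regions, region_table = optima$region_table,
         global_optimum = optima$global_optimum,
         largest_region_optimum = optima$largest_region_optimum,
         config = config),
    class = "lc_screen"
  )
}

validate_retention_table <- function(retention) {
  if (!"compound" %in% names(retention))
    stop("retention table needs a 'compound' column", call. = FALSE)
  retention$compound <- as.character(retention$compound)
  validate_retention_rows(retention[c("ph", "gradient_time_min",
                                      "retention_time_min")])
  retention
}

#' @export
print.lc_screen <- function(x, ...) {
  cat("In silico LC screening of", length(x$models), "compounds over",
      nrow(x$grid$conditions), "conditions\n")
  cat("Model cases:", paste(sprintf("%s (%s)", names(x$cases), x$cases),
                            collapse = ", "), "\n")
  cat(sprintf("Desirability threshold used: %.4g; %d robust region(s)\n",
              x$threshold_used, length(x$regions)))
  g <- x$global_optimum
  cat(sprintf("Global optimum: pH %.2f, tG %g min (D = %.3f)\n",
              g$ph, g$tg, g$value))
  if (!is.null(x$largest_region_optimum)) {
    l <- x$largest_region_optimum
    cat(sprintf(
      "Largest-region optimum: pH %.2f, tG %g min (D = %.3f, %d cells)\n",
      l$ph, l$tg, l$value, x$regions[[1]]$size))
  } else {
    cat("No region reaches the probability threshold\n")
  }
  invisible(x)
}

#' @export
summary.lc_screen <- function(object, ...) {
  model_table <- data.frame(
    compound = names(object$models),
    case = object$cases,
    r_squared = vapply(object$models,
                       function(m) m$diagnostics$r_squared, numeric(1)),
    rmsec_min = vapply(object$models,
                       function(m) m$diagnostics$rmse, numeric(1)),
    mapec_pct = vapply(object$models,
                       function(m) m$diagnostics$mape, numeric(1)),
    row.names = NULL)
  structure(list(result = object, model_table = model_table),
            class = "summary.lc_screen")
}

#' @export
print.summary.lc_screen <- function(x, digits = 3, ...) {
  print(x$result)
  cat("\nPer-compound calibration:\n")
  print(x$model_table, digits = digits, row.names = FALSE)
  if (nrow(x$result$region_table)) {
    cat("\nRobust regions (P >=",
        x$result$config$probability_threshold, "):\n")
    print(x$result$region_table, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Heatmap of the desirability index with robust regions and optima
#'
#' Renders the screening map: the desirability index over the (pH, tG)
#' grid, a contour delimiting cells whose probability of reaching the
#' desirability threshold meets the probability threshold (drawn on raw
#' cell values, no smoothing), and markers for the global (star) and
#' largest-region (circle) optima. Dark bands are predicted co-elutions.
#'
#' @param x An `lc_screen` result.
#' @param ... Passed to [graphics::image()].
#' @export
plot.lc_screen <- function(x, ...) {
  g <- x$grid
  graphics::image(g$ph_values, g$tg_values, x$desirability$index,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "pH", ylab = "gradient time [min]",
                  main = "Desirability index", ...)
  graphics::contour(g$ph_values, g$tg_values, x$probability,
                    levels = x$config$probability_threshold,
                    add = TRUE, drawlabels = FALSE, lwd = 2)
  go <- x$global_optimum
  graphics::points(go$ph, go$tg, pch = 8, cex = 2, col = "white", lwd = 2)
  if (!is.null(x$largest_region_optimum)) {
    lo <- x$largest_region_optimum
    graphics::points(lo$ph, lo$tg, pch = 1, cex = 2, col = "white", lwd = 2)
  }
  invisible(x)
}
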