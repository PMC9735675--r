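#' Read and write screening input tables
#'
#' The interchange formats are plain CSV:
#' * retention table — header `compound,ph,gradient_time_min,
#'   retention_time_min`, one row per observation;
#' * compound metadata — header `name,pka_values,half_width_left_min,
#'   half_width_right_min`, with `pka_values` a semicolon-separated list
#'   (empty for neutral compounds).
#'
#' Reading validates types and positivity and reports offending line numbers
#' (header = line 1). Unknown extra columns are accepted with a warning, for
#' forward compatibility. Numeric values are written with enough digits for
#' an exact read-back round trip.
#'
#' @param path File path.
#' @return `read_retention_table()`: the validated retention data frame;
#'   `read_compound_metadata()`: the metadata data frame.
#' @name screening_io
NULL

#' @rdname screening_io
#' @export
read_retention_table <- function(path) {
  x <- read_checked_csv(path,
                        c("compound", "ph", "gradient_time_min",
                          "retention_time_min"))
  check_numeric_csv(x, path, c("ph", "gradient_time_min",
                               "retention_time_min"))
  bad <- which(x$retention_time_min <= 0)
  if (length(bad))
    stop("non-positive retention time in '", path, "' at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  x$compound <- as.character(x$compound)
  x
}

#' @rdname screening_io
#' @export
read_compound_metadata <- function(path) {
  x <- read_checked_csv(path,
                        c("name", "pka_values", "half_width_left_min",
                          "half_width_right_min"))
  check_numeric_csv(x, path, c("half_width_left_min",
                               "half_width_right_min"))
  bad <- which(x$half_width_left_min <= 0 | x$half_width_right_min <= 0)
  if (length(bad))
    stop("non-positive half-width in '", path, "' at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  x$name <- as.character(x$name)
  x$pka_values <- as.character(x$pka_values)
  x$pka_values[is.na(x$pka_values)] <- ""
  x
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path))
    stop("file not found: '", path, "'", call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("'", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(x), required)
  if (length(extra))
    warning("'", path, "' has unknown column(s) ",
            paste(extra, collapse = ", "), "; ignored", call. = FALSE)
  x
}

check_numeric_csv <- function(x, path, cols) {
  for (col in cols) {
    v <- x[[col]]
    if (is.character(v) || is.factor(v))
      v <- suppressWarnings(as.numeric(as.character(v)))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("non-numeric or missing '", col, "' in '", path,
           "' at line(s) ", paste(bad + 1L, collapse = ", "),
           call. = FALSE)
    x[[col]] <- v
  }
  invisible(x)
}

#' @rdname screening_io
#' @param x Data frame to write.
#' @export
write_retention_table <- function(x, path) {
  write_precise_csv(x[c("compound", "ph", "gradient_time_min",
                        "retention_time_min")], path)
}

#' @rdname screening_io
#' @export
write_compound_metadata <- function(x, path) {
  write_precise_csv(x[c("name", "pka_values", "half_width_left_min",
                        "half_width_right_min")], path)
}

# CSV writer with round-trip-exact numeric formatting (17 significant
# digits suffice to reproduce any double)
write_precise_csv <- function(x, path) {
  y <- x
  for (col in names(y)) {
    if (is.double(y[[col]]))
      y[[col]] <- formatC(y[[col]], digits = 17, format = "g")
  }
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export fitted models and screening surfaces
#'
#' `write_model_table()` exports one row per compound (case, the six
#' possible coefficients with empty cells for terms absent from the case,
#' residual sd/df, n, calibration metrics). `write_surfaces()` exports the
#' long-format surface table `ph,gradient_time_min,separation_min,
#' sensitivity,analysis_time_min,d_separation,d_sensitivity,
#' d_analysis_time,desirability_index,probability`.
#' `write_screening()` writes everything for a run into a directory:
#' `models.csv`, `surfaces.csv`, `regions.csv` (cell membership),
#' `report.txt` (human-readable summary) and `provenance.dcf`
#' (configuration, seeds, package version — sufficient to reproduce the run
#' exactly). Outputs are bit-stable given identical inputs.
#'
#' @param result An [lc_screen()] result.
#' @param path Output file (`write_model_table`, `write_surfaces`) or
#'   directory (`write_screening`).
#' @return The path, invisibly.
#' @name screening_export
NULL

#' @rdname screening_export
#' @export
write_model_table <- function(result, path) {
  all_terms <- rsm_terms("TWO_PLATEAU")
  rows <- lapply(result$models, function(m) {
    beta <- setNames(rep(NA_real_, length(all_terms)), all_terms)
    beta[names(coef(m))] <- coef(m)
    data.frame(compound = m$compound$name, case = m$case,
               beta0 = beta[["(Intercept)"]], beta1_ph = beta[["ph"]],
               beta2_tg = beta[["tg"]], beta11_ph2 = beta[["ph2"]],
               beta111_ph3 = beta[["ph3"]], beta12_phtg = beta[["ph_tg"]],
               residual_sd = m$residual_sd, residual_df = m$residual_df,
               n_train = m$n_train,
               r_squared = m$diagnostics$r_squared,
               rmsec_min = m$diagnostics$rmse,
               mapec_pct = m$diagnostics$mape)
  })
  write_precise_csv(do.call(rbind, c(rows, make.row.names = FALSE)), path)
}

#' @rdname screening_export
#' @export
write_surfaces <- function(result, path) {
  g <- result$grid
  d <- data.frame(
    ph = g$conditions$ph,
    gradient_time_min = g$conditions$gradient_time_min,
    separation_min = surface_to_vec(result$criteria$separation),
    sensitivity = surface_to_vec(result$criteria$sensitivity),
    analysis_time_min = surface_to_vec(result$criteria$analysis_time),
    d_separation = surface_to_vec(result$desirability$d_separation),
    d_sensitivity = surface_to_vec(result$desirability$d_sensitivity),
    d_analysis_time = surface_to_vec(result$desirability$d_analysis_time),
    desirability_index = surface_to_vec(result$desirability$index),
    probability = surface_to_vec(result$probability))
  write_precise_csv(d, path)
}

#' @rdname screening_export
#' @export
write_screening <- function(result, path) {
  stopifnot(inherits(result, "lc_screen"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_model_table(result, file.path(path, "models.csv"))
  write_surfaces(result, file.path(path, "surfaces.csv"))

  g <- result$grid
  membership <- if (length(result$regions)) {
    do.call(rbind, lapply(seq_along(result$regions), function(i) {
      cells <- result$regions[[i]]$cells
      data.frame(ph = g$ph_values[cells$ph_idx],
                 gradient_time_min = g$tg_values[cells$tg_idx],
                 region_id = i)
    }))
  } else {
    data.frame(ph = numeric(0), gradient_time_min = numeric(0),
               region_id = integer(0))
  }
  write_precise_csv(membership, file.path(path, "regions.csv"))

  cfg <- result$config
  dcf <- data.frame(
    package_version = as.character(utils::packageVersion("lcscreen")),
    seed = cfg$seed, n_draws = cfg$n_draws,
    n_weight_draws = cfg$n_weight_draws,
    weights = paste(cfg$weights, collapse = ";"),
    confidence_factor = cfg$confidence_factor,
    desirability_threshold = as.character(cfg$desirability_threshold),
    threshold_used = result$threshold_used,
    probability_threshold = cfg$probability_threshold,
    connectivity = cfg$connectivity,
    ph_range = paste(cfg$ph_range, collapse = ";"), ph_step = cfg$ph_step,
    tg_range = paste(cfg$tg_range, collapse = ";"), tg_step = cfg$tg_step,
    separation_quantile = cfg$separation_quantile,
    analysis_quantile = cfg$analysis_quantile,
    edge_margin = cfg$edge_margin, outside_margin = cfg$outside_margin)
  write.dcf(dcf, file.path(path, "provenance.dcf"))

  report <- file.path(path, "report.txt")
  con <- file(report, open = "wt")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(summary(result))
  invisible(path)
}
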