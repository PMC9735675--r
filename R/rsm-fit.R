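#' Fit a response-surface retention model for one compound
#'
#' Fits, by ordinary least squares, the natural logarithm of retention time
#' against the polynomial in mobile-phase pH and gradient time selected by
#' [select_equation()]:
#'
#' \deqn{\mathrm{NO\_PH}:\quad \log t_R = \beta_0 + \beta_2 t_G}
#' \deqn{\mathrm{ONE\_PLATEAU}:\quad \log t_R = \beta_0 + \beta_1 pH +
#'   \beta_2 t_G + \beta_{11} pH^2 + \beta_{12}\, pH \cdot t_G}
#' \deqn{\mathrm{TWO\_PLATEAU}:\quad \log t_R = \beta_0 + \beta_1 pH +
#'   \beta_2 t_G + \beta_{11} pH^2 + \beta_{111} pH^3 +
#'   \beta_{12}\, pH \cdot t_G}
#'
#' The residual standard deviation and residual degrees of freedom (n minus
#' the number of coefficients) are retained on the log scale; they
#' parameterize the Student-t predictive distribution used by
#' [simulate.rsm_model()] for Monte-Carlo error propagation. Calibration
#' diagnostics (R², RMSE, MAPE) are computed on retention times in minutes
#' after back-transforming predictions by exponentiation.
#'
#' @param data Data frame with columns `ph`, `gradient_time_min`,
#'   `retention_time_min` (all numeric, retention times > 0), the
#'   observations for a single compound.
#' @param compound Optional [compound_spec()]; used to pick `case` when
#'   `case = NULL` and stored in the fit.
#' @param case Model case, one of `"NO_PH"`, `"ONE_PLATEAU"`,
#'   `"TWO_PLATEAU"`; if `NULL`, chosen from `compound`'s pKa via
#'   [select_equation()].
#' @param ph_range,edge_margin,outside_margin Passed to [select_equation()]
#'   when `case` is not given.
#' @return An object of class `rsm_model`: list with `coefficients` (named,
#'   on the log-minute scale), `case`, `residual_sd`, `residual_df`,
#'   `n_train`, `compound`, `diagnostics` (a `fit_diagnostics` object, see
#'   [prediction_metrics()]), `data`, and the training ranges of pH and tG.
#' @examples
#' obs <- data.frame(ph = rep(c(2.7, 3.5, 5, 6.5, 8), 2),
#'                   gradient_time_min = rep(c(20, 60), each = 5))
#' obs$retention_time_min <- exp(2 + 0.012 * obs$gradient_time_min)
#' fit <- rsm_fit(obs, case = "NO_PH")
#' coef(fit)
#' predict(fit, data.frame(ph = 4, gradient_time_min = 40))
#' @seealso [predict.rsm_model()], [simulate.rsm_model()],
#'   [prediction_metrics()]
#' @export
rsm_fit <- function(data, compound = NULL, case = NULL,
                    ph_range = c(2.7, 8), edge_margin = 1,
                    outside_margin = 1) {
  data <- validate_retention_rows(data)
  if (is.null(case)) {
    if (is.null(compound))
      stop("supply either 'case' or a 'compound' spec with pKa values",
           call. = FALSE)
    case <- select_equation(compound, ph_range, edge_margin, outside_margin)
  }
  case <- match.arg(case, c("NO_PH", "ONE_PLATEAU", "TWO_PLATEAU"))
  check_design(data, case)

  X <- rsm_design(data$ph, data$gradient_time_min, case)
  y <- log(data$retention_time_min)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient design for case ", case, ": term(s) ",
         paste(dropped, collapse = ", "), " not estimable", call. = FALSE)
  }
  beta <- qr.coef(qr_x, y)
  fitted_log <- drop(X %*% beta)
  res <- y - fitted_log
  df <- length(y) - ncol(X)
  sigma <- sqrt(sum(res^2) / df)

  fit <- structure(
    list(coefficients = beta, case = case,
         residual_sd = sigma, residual_df = df, n_train = length(y),
         compound = compound,
         data = data,
         ph_train_range = range(data$ph),
         tg_train_range = range(data$gradient_time_min)),
    class = "rsm_model"
  )
  fit$diagnostics <- prediction_metrics(fit, data, warn_extrapolation = FALSE)
  fit
}

check_design <- function(data, case) {
  p <- length(rsm_terms(case))
  if (nrow(data) <= p)
    stop("need more than ", p, " observations to fit case ", case,
         " (got ", nrow(data), ")", call. = FALSE)
  if (length(unique(data$gradient_time_min)) < 2L)
    stop("design needs at least 2 distinct gradient times", call. = FALSE)
  need_ph <- switch(case, NO_PH = 0L, ONE_PLATEAU = 3L, TWO_PLATEAU = 4L)
  if (need_ph && length(unique(data$ph)) < need_ph)
    stop("case ", case, " needs at least ", need_ph,
         " distinct pH levels (got ", length(unique(data$ph)), ")",
         call. = FALSE)
  invisible(data)
}

validate_retention_rows <- function(data) {
  required <- c("ph", "gradient_time_min", "retention_time_min")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("retention data missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in required) {
    if (!is.numeric(data[[col]]) || anyNA(data[[col]]) ||
        any(!is.finite(data[[col]])))
      stop("column '", col, "' must be finite numeric", call. = FALSE)
  }
  bad <- which(data$retention_time_min <= 0)
  if (length(bad))
    stop("non-positive retention time(s) at row(s) ",
         paste(bad, collapse = ", "),
         " (log transform undefined)", call. = FALSE)
  data
}

#' Predict log or back-transformed retention time
#'
#' Evaluates the fitted polynomial at new (pH, gradient time) conditions.
#' Predictions outside the training box are allowed with a warning — the
#' strategy routinely interpolates/extrapolates mildly, e.g. predicting at an
#' intermediate gradient time from a two-level training design.
#'
#' @param object An `rsm_model`.
#' @param newdata Data frame with columns `ph` and `gradient_time_min`;
#'   defaults to the training data.
#' @param type `"log"` for log-minutes (the model scale) or `"response"` for
#'   minutes.
#' @param warn_extrapolation Warn when conditions fall outside the training
#'   ranges (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rsm_model <- function(object, newdata = NULL,
                              type = c("response", "log"),
                              warn_extrapolation = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  if (!all(c("ph", "gradient_time_min") %in% names(newdata)))
    stop("'newdata' needs columns 'ph' and 'gradient_time_min'",
         call. = FALSE)
  ph <- newdata$ph
  tg <- newdata$gradient_time_min
  if (warn_extrapolation) {
    out <- ph < object$ph_train_range[1] | ph > object$ph_train_range[2] |
           tg < object$tg_train_range[1] | tg > object$tg_train_range[2]
    if (any(out))
      warning(sum(out), " condition(s) outside the training pH/tG box; ",
              "extrapolating", call. = FALSE)
  }
  eta <- drop(rsm_design(ph, tg, object$case) %*% object$coefficients)
  if (type == "log") eta else exp(eta)
}

#' Monte-Carlo retention-time draws from a fitted retention model
#'
#' Propagates model error by sampling the predictive distribution of
#' retention time: a Student-t variate with the model's residual degrees of
#' freedom is scaled by the residual standard deviation and located at the
#' predicted value on the log scale, then exponentiated,
#' \eqn{t_R = \exp(\hat\mu + \hat\sigma\, T_{df})}. Locating and scaling on
#' the log (model) scale keeps every draw positive.
#'
#' @param object An `rsm_model` with `residual_df >= 1`.
#' @param nsim Number of draws per condition (>= 1).
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @param newdata Data frame of conditions (`ph`, `gradient_time_min`);
#'   defaults to the training conditions.
#' @param ... Unused.
#' @return Numeric matrix, `nrow(newdata)` x `nsim`, of retention times in
#'   minutes.
#' @export
simulate.rsm_model <- function(object, nsim = 1000, seed = NULL,
                               newdata = NULL, ...) {
  if (object$residual_df < 1L)
    stop("model has fewer than 1 residual degree of freedom; ",
         "predictive distribution undefined", call. = FALSE)
  if (nsim < 1L) stop("'nsim' must be >= 1", call. = FALSE)
  if (is.null(newdata)) newdata <- object$data
  mu <- predict(object, newdata, type = "log", warn_extrapolation = FALSE)
  if (!is.null(seed)) {
    rng_state <- get_rng_state()
    on.exit(restore_rng_state(rng_state))
    set.seed(seed)
  }
  n <- length(mu)
  t_draws <- matrix(stats::rt(n * nsim, df = object$residual_df),
                    nrow = n, ncol = nsim)
  exp(mu + object$residual_sd * t_draws)
}

#' @export
residuals.rsm_model <- function(object, ...) {
  log(object$data$retention_time_min) -
    predict(object, type = "log", warn_extrapolation = FALSE)
}

#' @export
fitted.rsm_model <- function(object, ...) {
  predict(object, type = "response", warn_extrapolation = FALSE)
}

#' @export
coef.rsm_model <- function(object, ...) object$coefficients

#' @export
print.rsm_model <- function(x, digits = 4, ...) {
  name <- if (!is.null(x$compound)) x$compound$name else "<unnamed>"
  cat("Retention response-surface model (", x$case, ") for ", name, "\n",
      sep = "")
  cat("log(tR) coefficients:\n")
  print(round(x$coefficients, digits))
  cat("residual sd (log scale):", format(x$residual_sd, digits = digits),
      "on", x$residual_df, "df;", x$n_train, "observations\n")
  invisible(x)
}

#' @export
summary.rsm_model <- function(object, ...) {
  structure(list(fit = object, diagnostics = object$diagnostics),
            class = "summary.rsm_model")
}

#' @export
print.summary.rsm_model <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  d <- x$diagnostics
  cat("Calibration (minute scale): R² = ", format(d$r_squared, digits = 3),
      ", RMSE = ", format(d$rmse, digits = 3),
      " min, MAPE = ", format(d$mape, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' Prediction diagnostics of a retention model on held-out conditions
#'
#' Computes, on the minute scale, the per-condition absolute error
#' (predicted - observed, minutes) and relative error
#' (100 x (predicted - observed)/observed, percent), together with their
#' aggregates: RMSE, MAPE (mean of |relative error|), and R²
#' (1 - SS_res/SS_tot on minutes). Used both for calibration (on the
#' training conditions, where it is stored in the fit) and for prediction at
#' new external conditions.
#'
#' @param model An `rsm_model`.
#' @param observations Data frame with `ph`, `gradient_time_min`,
#'   `retention_time_min`; need not be training conditions.
#' @param warn_extrapolation Passed to [predict.rsm_model()].
#' @return An object of class `fit_diagnostics`: list with `r_squared`,
#'   `rmse` (min), `mape` (%), and `per_condition` (data frame with the
#'   conditions, predictions, and absolute/relative errors).
#' @export
prediction_metrics <- function(model, observations,
                               warn_extrapolation = TRUE) {
  observations <- validate_retention_rows(observations)
  if (!nrow(observations))
    stop("no observations supplied", call. = FALSE)
  pred <- predict(model, observations, type = "response",
                  warn_extrapolation = warn_extrapolation)
  obs <- observations$retention_time_min
  abs_err <- pred - obs
  rel_err <- 100 * abs_err / obs
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot > 0) 1 - sum(abs_err^2) / ss_tot else NA_real_
  structure(
    list(r_squared = r2,
         rmse = sqrt(mean(abs_err^2)),
         mape = mean(abs(rel_err)),
         per_condition = data.frame(
           ph = observations$ph,
           gradient_time_min = observations$gradient_time_min,
           observed_min = obs,
           predicted_min = pred,
           abs_error_min = abs_err,
           rel_error_pct = rel_err)),
    class = "fit_diagnostics"
  )
}

#' @export
print.fit_diagnostics <- function(x, digits = 4, ...) {
  cat("Fit diagnostics (minute scale):\n",
      " R² = ", format(x$r_squared, digits = digits),
      ", RMSE = ", format(x$rmse, digits = digits),
      " min, MAPE = ", format(x$mape, digits = digits), "%\n", sep = "")
  print(x$per_condition, digits = digits)
  invisible(x)
}
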