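#' Ground truth for synthetic retention data: two-state ionization model
#'
#' Generates retention behavior with the structure the screening strategy
#' assumes: retention versus pH follows a sigmoid between a neutral-form and
#' an ionized-form plateau centered at the pKa, log retention is linear in
#' gradient time on each plateau, and observation noise is multiplicative
#' (additive on the log scale). The ionized fraction is
#' \eqn{f = 1/(1 + 10^{s\,k\,(pH - pK_a)})} with `s = +1` for acids (the
#' ionized, less-retained form dominates above the pKa) and `s = -1` for
#' bases, and `k` the Hill-type steepness; log retention interpolates the
#' two linear forms, \eqn{\log t_R = f\,(a_n + b_n t_G) +
#' (1-f)(a_i + b_i t_G)}.
#'
#' This is deliberately not a mechanistic gradient-elution solver: it only
#' reproduces the qualitative shape the polynomial retention models
#' approximate.
#'
#' @param compound A [compound_spec()]; its first pKa centers the sigmoid
#'   (a compound with no pKa is pH-independent and the ionized coefficients
#'   are ignored).
#' @param neutral_intercept,neutral_slope Intercept (log minutes) and
#'   gradient-time slope (log minutes per minute) of the neutral form.
#' @param ionized_intercept,ionized_slope Same for the ionized form.
#' @param hill_slope Sigmoid steepness per pH unit, > 0 (1 = ideal
#'   monoprotic Henderson-Hasselbalch behavior).
#' @param acid_or_base `"acid"` or `"base"`.
#' @param noise_sd Log-scale observation noise standard deviation, >= 0.
#' @return Object of class `sigmoid_truth`.
#' @export
sigmoid_truth <- function(compound, neutral_intercept, neutral_slope,
                          ionized_intercept = neutral_intercept,
                          ionized_slope = neutral_slope,
                          hill_slope = 1, acid_or_base = c("acid", "base"),
                          noise_sd = 0.03) {
  stopifnot(inherits(compound, "compound_spec"))
  acid_or_base <- match.arg(acid_or_base)
  if (hill_slope <= 0) stop("'hill_slope' must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(
    list(compound = compound,
         neutral_intercept = neutral_intercept,
         neutral_slope = neutral_slope,
         ionized_intercept = ionized_intercept,
         ionized_slope = ionized_slope,
         pka = if (length(compound$pka)) compound$pka[1] else NA_real_,
         hill_slope = hill_slope,
         acid_or_base = acid_or_base,
         noise_sd = noise_sd),
    class = "sigmoid_truth"
  )
}

#' Noiseless log retention time under a synthetic ground truth
#'
#' @param truth A [sigmoid_truth()].
#' @param conditions Data frame with `ph` and `gradient_time_min`.
#' @return Numeric vector of log retention times.
#' @export
true_log_tr <- function(truth, conditions) {
  stopifnot(inherits(truth, "sigmoid_truth"))
  ph <- conditions$ph
  tg <- conditions$gradient_time_min
  neutral <- truth$neutral_intercept + truth$neutral_slope * tg
  if (is.na(truth$pka)) return(neutral)
  s <- if (truth$acid_or_base == "acid") 1 else -1
  f <- 1 / (1 + 10^(s * truth$hill_slope * (ph - truth$pka)))
  ionized <- truth$ionized_intercept + truth$ionized_slope * tg
  f * neutral + (1 - f) * ionized
}

#' The default experimental design of the screening study
#'
#' Five pH levels (2.7, 3.5, 5.0, 6.5, 8.0) crossed with two gradient times
#' (20 and 60 min): ten training conditions per compound.
#'
#' @param ph_values,tg_values Design levels.
#' @param replicates Replicates per condition (>= 1).
#' @return Data frame of conditions (`ph`, `gradient_time_min`), replicated.
#' @export
training_design <- function(ph_values = c(2.7, 3.5, 5, 6.5, 8),
                            tg_values = c(20, 60), replicates = 1) {
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  d <- expand.grid(ph = ph_values, gradient_time_min = tg_values,
                   KEEP.OUT.ATTRS = FALSE)
  d[rep(seq_len(nrow(d)), each = replicates), , drop = FALSE]
}

#' Simulate retention observations for one compound
#'
#' `tR = exp(true log tR + e)`, `e ~ N(0, noise_sd)` independently per
#' observation — multiplicative lognormal noise, so every retention time is
#' positive.
#'
#' @param truth A [sigmoid_truth()].
#' @param design Data frame of conditions (see [training_design()]).
#' @param seed Optional integer seed (caller's RNG state preserved).
#' @return Data frame `compound`, `ph`, `gradient_time_min`,
#'   `retention_time_min`.
#' @export
generate_observations <- function(truth, design, seed = NULL) {
  stopifnot(inherits(truth, "sigmoid_truth"))
  if (!nrow(design)) stop("empty design", call. = FALSE)
  mu <- true_log_tr(truth, design)
  if (!is.null(seed)) {
    rng_state <- get_rng_state()
    on.exit(restore_rng_state(rng_state))
    set.seed(seed)
  }
  eps <- if (truth$noise_sd > 0)
    stats::rnorm(length(mu), sd = truth$noise_sd) else 0
  data.frame(compound = truth$compound$name,
             ph = design$ph,
             gradient_time_min = design$gradient_time_min,
             retention_time_min = exp(mu + eps),
             row.names = NULL)
}

#' Simulate a multi-compound mixture
#'
#' Concatenates per-compound observation tables (independent noise streams
#' derived from `seed`) and builds the companion compound-metadata table.
#'
#' @param truths List of [sigmoid_truth()] with distinct compound names.
#' @param design Data frame of conditions.
#' @param seed Integer seed.
#' @return List with `retention` (observation table) and `metadata`
#'   (compound metadata table in the on-disk format, see
#'   [read_compound_metadata()]).
#' @export
generate_mixture <- function(truths, design = training_design(),
                             seed = NULL) {
  if (length(truths) < 2L)
    stop("a mixture needs at least 2 compounds", call. = FALSE)
  nm <- vapply(truths, function(t) t$compound$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate compound name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  obs <- do.call(rbind, lapply(seq_along(truths), function(i) {
    generate_observations(truths[[i]], design,
                          seed = if (is.null(seed)) NULL else seed + 1000L * i)
  }))
  metadata <- data.frame(
    name = nm,
    pka_values = vapply(truths, function(t) {
      paste(t$compound$pka, collapse = ";")
    }, character(1)),
    half_width_left_min = vapply(truths, function(t)
      t$compound$half_width_left, numeric(1)),
    half_width_right_min = vapply(truths, function(t)
      t$compound$half_width_right, numeric(1)))
  list(retention = obs, metadata = metadata)
}

#' The packaged seven-compound demonstration mixture
#'
#' A synthetic stand-in for a realistic pharmaceutical screening sample:
#' seven compounds spanning all three retention-model cases — two neutral
#' (no pKa near the range), two with a pKa within a unit of a range edge,
#' three with a mid-range pKa. Retention spans roughly 3-60 min over the
#' default grid; the compounds are spread out around pH 6 at moderate
#' gradient times and their elution orders cross elsewhere, so the
#' desirability map shows both a well-separated pocket and dark co-elution
#' bands. Ionization transitions are broad (Hill slope 0.5 per pH unit, as
#' for partially buffered methanol-water gradients) so the polynomial
#' models track them closely. Log-scale noise sd 0.03 (~3% multiplicative
#' error). All half-widths 0.5 min.
#'
#' @param noise_sd Log-scale noise sd, default 0.03.
#' @return List of seven [sigmoid_truth()] objects.
#' @export
demo_truths <- function(noise_sd = 0.03) {
  hw <- function(name, pka) compound_spec(name, pka, 0.5, 0.5)
  list(
    # neutral, early eluter
    sigmoid_truth(hw("neutralA", numeric(0)), 1.10, 0.010,
                  noise_sd = noise_sd),
    # neutral, moderately retained
    sigmoid_truth(hw("neutralB", numeric(0)), 1.88, 0.013,
                  noise_sd = noise_sd),
    # weak acid, pKa just below the lower pH edge: one plateau visible
    sigmoid_truth(hw("acidEdge", 2.3), 1.95, 0.013, 1.51, 0.011,
                  hill_slope = 0.5, acid_or_base = "acid",
                  noise_sd = noise_sd),
    # base, pKa beyond the upper edge but within a unit of it
    sigmoid_truth(hw("baseEdge", 8.6), 4.10, 0.015, 3.59, 0.012,
                  hill_slope = 0.5, acid_or_base = "base",
                  noise_sd = noise_sd),
    # mid-range acid
    sigmoid_truth(hw("acidMid", 4.6), 3.10, 0.011, 2.39, 0.008,
                  hill_slope = 0.5, acid_or_base = "acid",
                  noise_sd = noise_sd),
    # mid-range base
    sigmoid_truth(hw("baseMid", 6.2), 3.75, 0.012, 2.92, 0.009,
                  hill_slope = 0.5, acid_or_base = "base",
                  noise_sd = noise_sd),
    # second mid-range acid with a steeper gradient response
    sigmoid_truth(hw("acidMid2", 5.4), 3.30, 0.014, 2.66, 0.009,
                  hill_slope = 0.5, acid_or_base = "acid",
                  noise_sd = noise_sd)
  )
}

#' @rdname demo_truths
#' @param seed Integer seed for the observation noise.
#' @param design Training design, default the 5 pH x 2 tG study design.
#' @return `demo_mixture()`: list with `retention` and `metadata` tables
#'   (see [generate_mixture()]).
#' @export
demo_mixture <- function(seed = 20221128, design = training_design(),
                         noise_sd = 0.03) {
  generate_mixture(demo_truths(noise_sd), design, seed = seed)
}
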