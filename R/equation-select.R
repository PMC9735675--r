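#' Select the retention-model equation from a compound's pKa
#'
#' Retention in reversed-phase LC follows a sigmoidal curve in pH around each
#' pKa, but only the part of the sigmoid inside the working pH range is ever
#' observed. Three fixed polynomial equations in log retention time cover the
#' possible shapes, and the right one is chosen from chemistry rather than by
#' stepwise regression:
#'
#' * `"NO_PH"` — no pKa anywhere near the pH range: retention is
#'   pH-independent and the model is linear in gradient time only.
#' * `"ONE_PLATEAU"` — a pKa close to one edge of the range: only one plateau
#'   of the sigmoid is visible; quadratic in pH plus a pH x tG interaction.
#' * `"TWO_PLATEAU"` — a pKa well inside the range: both plateaus visible;
#'   cubic in pH plus the interaction.
#'
#' The decision rule: if no pKa lies in the extended range
#' `[lower - outside_margin, upper + outside_margin]` the pH has no effect
#' (`NO_PH`); if any pKa lies in the interior window
#' `[lower + edge_margin, upper - edge_margin]` both plateaus are observable
#' (`TWO_PLATEAU`); otherwise the relevant pKa sits near an edge
#' (`ONE_PLATEAU`). One pH unit changes the ionized fraction roughly tenfold,
#' about one sigmoid shoulder, hence the default margins of 1.
#'
#' @param compound A [compound_spec()] (or a bare numeric vector of pKa
#'   values).
#' @param ph_range Length-2 numeric, lower and upper pH of the screening
#'   range. Default `c(2.7, 8)`.
#' @param edge_margin,outside_margin Margins in pH units (> 0) defining
#'   "well inside" and "near" the range. Defaults 1.
#' @return One of `"NO_PH"`, `"ONE_PLATEAU"`, `"TWO_PLATEAU"`.
#' @examples
#' select_equation(compound_spec("neutral", numeric(0)))        # "NO_PH"
#' select_equation(compound_spec("mid", 5.0))                   # "TWO_PLATEAU"
#' select_equation(compound_spec("edge", 2.9))                  # "ONE_PLATEAU"
#' @export
select_equation <- function(compound, ph_range = c(2.7, 8),
                            edge_margin = 1, outside_margin = 1) {
  pka <- if (inherits(compound, "compound_spec")) compound$pka
         else as.numeric(compound)
  if (length(ph_range) != 2L || !all(is.finite(ph_range)) ||
      ph_range[1] >= ph_range[2])
    stop("'ph_range' must be c(lower, upper) with lower < upper",
         call. = FALSE)
  if (edge_margin <= 0 || outside_margin <= 0)
    stop("margins must be positive", call. = FALSE)
  lo <- ph_range[1]; hi <- ph_range[2]
  if (!length(pka) ||
      !any(pka >= lo - outside_margin & pka <= hi + outside_margin))
    return("NO_PH")
  if (any(pka >= lo + edge_margin & pka <= hi - edge_margin))
    return("TWO_PLATEAU")
  "ONE_PLATEAU"
}

# design-matrix term names per equation case; order fixes coefficient layout
rsm_terms <- function(case) {
  switch(case,
    NO_PH       = c("(Intercept)", "tg"),
    ONE_PLATEAU = c("(Intercept)", "ph", "tg", "ph2", "ph_tg"),
    TWO_PLATEAU = c("(Intercept)", "ph", "tg", "ph2", "ph3", "ph_tg"),
    stop("unknown model case '", case, "'", call. = FALSE)
  )
}

# expand (ph, tg) into the design matrix of the selected equation
rsm_design <- function(ph, tg, case) {
  cols <- list(
    "(Intercept)" = rep(1, length(tg)),
    ph    = ph,
    tg    = tg,
    ph2   = ph^2,
    ph3   = ph^3,
    ph_tg = ph * tg
  )
  terms <- rsm_terms(case)
  X <- do.call(cbind, cols[terms])
  colnames(X) <- terms
  X
}
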