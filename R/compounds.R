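#' Compound specification for screening
#'
#' Bundles the per-compound information the screening strategy needs beyond
#' retention data: the acid-dissociation constants (pKa) that drive selection
#' of the retention-model equation, and the expected left/right baseline peak
#' half-widths entering the separation criterion. Allowing different left and
#' right half-widths lets peak asymmetry (e.g. an API peak much wider than
#' trace impurity peaks) be taken into account.
#'
#' @param name Compound name (non-empty string); used to join against the
#'   retention table.
#' @param pka Numeric vector of pKa values in pH units. May be empty
#'   (`numeric(0)`) for compounds that are neutral over any chromatographic
#'   pH. Stored sorted ascending.
#' @param half_width_left,half_width_right Expected baseline peak half-widths
#'   in minutes, strictly positive.
#' @return An object of class `compound_spec`: a list with elements `name`,
#'   `pka`, `half_width_left`, `half_width_right`.
#' @examples
#' compound_spec("ibuprofen", pka = 4.4, half_width_left = 0.5,
#'               half_width_right = 0.5)
#' compound_spec("biphenyl", pka = numeric(0), 0.4, 0.4)
#' @export
compound_spec <- function(name, pka = numeric(0),
                          half_width_left = 0.5, half_width_right = 0.5) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string", call. = FALSE)
  pka <- as.numeric(pka)
  if (anyNA(pka) || any(!is.finite(pka)))
    stop("pKa values must be finite for compound '", name, "'", call. = FALSE)
  hl <- as.numeric(half_width_left)
  hr <- as.numeric(half_width_right)
  if (length(hl) != 1L || length(hr) != 1L || !is.finite(hl) || !is.finite(hr) ||
      hl <= 0 || hr <= 0)
    stop("half-widths must be single positive numbers for compound '",
         name, "'", call. = FALSE)
  structure(
    list(name = name, pka = sort(pka),
         half_width_left = hl, half_width_right = hr),
    class = "compound_spec"
  )
}

#' @export
print.compound_spec <- function(x, ...) {
  pka <- if (length(x$pka)) paste(format(x$pka), collapse = ", ") else "none"
  cat("Compound:", x$name, "\n",
      " pKa:", pka, "\n",
      " baseline half-widths (L/R, min):",
      format(x$half_width_left), "/", format(x$half_width_right), "\n")
  invisible(x)
}

#' Build a list of compound specs from a metadata table
#'
#' @param metadata Data frame with columns `name`, `pka_values`
#'   (semicolon-separated string, may be empty), `half_width_left_min`,
#'   `half_width_right_min` — the on-disk metadata format.
#' @return Named list of [compound_spec()] objects.
#' @seealso [read_compound_metadata()]
#' @export
as_compound_specs <- function(metadata) {
  required <- c("name", "pka_values", "half_width_left_min",
                "half_width_right_min")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("compound metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(metadata$name))
    stop("duplicate compound name(s) in metadata: ",
         paste(unique(metadata$name[duplicated(metadata$name)]),
               collapse = ", "), call. = FALSE)
  specs <- lapply(seq_len(nrow(metadata)), function(i) {
    pka <- parse_pka_field(metadata$pka_values[i])
    compound_spec(as.character(metadata$name[i]), pka,
                  metadata$half_width_left_min[i],
                  metadata$half_width_right_min[i])
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

parse_pka_field <- function(x) {
  if (is.na(x)) return(numeric(0))
  x <- trimws(as.character(x))
  if (!nzchar(x)) return(numeric(0))
  vals <- suppressWarnings(as.numeric(strsplit(x, ";", fixed = TRUE)[[1]]))
  if (anyNA(vals))
    stop("could not parse pKa field '", x, "'", call. = FALSE)
  vals
}
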