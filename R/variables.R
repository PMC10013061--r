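#' The seven clinical variables used for network construction
#'
#' Returns the fixed, ordered set of variable codes analysed by the package:
#' serum albumin (`ALB`, g/L), total bilirubin (`Bil`, umol/L), prothrombin
#' time (`PT`, s), serum creatinine (`Cr`, umol/L), ammonia (`NH4`, umol/L),
#' serum sodium (`Na`, mmol/L) and hepatic encephalopathy grade (`HE`,
#' ordinal 0/1/2).
#'
#' The order is part of the package contract: for any variable pair the
#' earlier variable is the regression predictor (x) and the later one the
#' response (y). Orthogonal distance to a least-squares line depends on
#' which variable is regressed on which, so a fixed orientation makes
#' deviations reproducible.
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' clinical_variables()
clinical_variables <- function() {
  c("ALB", "Bil", "PT", "Cr", "NH4", "Na", "HE")
}

# display names for report tables
variable_labels <- function() {
  c(ALB = "Albumin", Bil = "Bilirubin", PT = "Prothrombin Time",
    Cr = "Creatinine", NH4 = "Ammonia", Na = "Sodium",
    HE = "Hepatic Encephalopathy")
}

#' All unordered variable pairs in canonical orientation
#'
#' Enumerates the p(p-1)/2 variable pairs with the earlier variable (in
#' [clinical_variables()] order) as predictor `x_var` and the later as
#' response `y_var`. Pair identifiers are `"x_y"` (e.g. `"ALB_Bil"`).
#'
#' @param vars Character vector of variable names (default the full set).
#' @return A data frame with columns `x_var`, `y_var`, `pair`, `label`.
#' @export
all_variable_pairs <- function(vars = clinical_variables()) {
  idx <- utils::combn(seq_along(vars), 2)
  x <- vars[idx[1L, ]]
  y <- vars[idx[2L, ]]
  lab <- variable_labels()
  lx <- ifelse(x %in% names(lab), lab[x], x)
  ly <- ifelse(y %in% names(lab), lab[y], y)
  data.frame(x_var = x, y_var = y,
             pair = paste(x, y, sep = "_"),
             label = paste(lx, ly, sep = "-"),
             stringsAsFactors = FALSE)
}

#' Encode hepatic encephalopathy grade as an ordinal integer
#'
#' Maps the clinical HE classification to the ordinal scale used throughout
#' the analysis: unimpaired = 0, minimal = 1, overt = 2. Matching is
#' case-insensitive; integers 0/1/2 (or their string forms) pass through;
#' missing values stay missing.
#'
#' @param x Character or numeric vector of HE grades.
#' @return Integer vector with values in `{0, 1, 2}` or `NA`.
#' @export
#' @examples
#' encode_he(c("unimpaired", "Minimal", "overt"))
encode_he <- function(x) {
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% c(0, 1, 2))
    if (any(bad)) {
      stop("unrecognized HE grade(s): ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
    return(as.integer(x))
  }
  lut <- c(unimpaired = 0L, minimal = 1L, overt = 2L,
           "0" = 0L, "1" = 1L, "2" = 2L)
  key <- tolower(trimws(as.character(x)))
  out <- unname(lut[key])
  bad <- !is.na(x) & !(key %in% names(lut))
  if (any(bad)) {
    stop("unrecognized HE grade(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}
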