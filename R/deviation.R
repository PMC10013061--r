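#' Orthogonal residual deviation from a reference line
#'
#' The parenclitic deviation of a point (x0, y0) from the line
#' `y = intercept + slope * x` is the orthogonal (perpendicular) residual.
#' With the vertical residual v = |y0 - (a + b x0)| and the horizontal
#' residual h = v / |b|, the deviation is the altitude of the right
#' triangle formed by the two residual legs, v.h / sqrt(v^2 + h^2), which
#' is algebraically identical to the perpendicular distance
#' v / sqrt(1 + b^2). The closed form is used here: it is exact for points
#' on the line (where the leg-product quotient is 0/0) and for horizontal
#' lines (b = 0, where it reduces to v).
#'
#' @param x0,y0 Numeric vectors: predictor and response values.
#' @param slope,intercept Reference line parameters.
#' @return Non-negative deviations; `NA` where either input is missing.
#' @export
#' @examples
#' orthogonal_delta(0, 3, slope = 0.75, intercept = 0) # 2.4
orthogonal_delta <- function(x0, y0, slope, intercept) {
  if (any(is.infinite(x0)) || any(is.infinite(y0)) ||
      any(is.nan(x0[!is.na(x0)])) || any(is.nan(y0[!is.na(y0)]))) {
    stop("non-finite coordinates supplied", call. = FALSE)
  }
  stopifnot(is.finite(slope), is.finite(intercept))
  v <- abs(y0 - (intercept + slope * x0))
  v / sqrt(1 + slope^2)
}

#' Parenclitic profile of one patient
#'
#' Computes the orthogonal deviation of a patient from every reference
#' pair's regression line. Pairs with a missing member variable are absent
#' from the profile (the corresponding network edge does not form); missing
#' data degrade the profile, they never fail it.
#'
#' @param patient A one-row data frame (or named list) with the clinical
#'   variables.
#' @param refset A [build_reference_set()] result.
#' @return Named numeric vector of deviations, one entry per reference pair
#'   whose two variables are both observed.
#' @export
compute_profile <- function(patient, refset) {
  stopifnot(inherits(refset, "parenclitic_refset"))
  pairs <- refset$pairs
  if (!nrow(pairs)) return(stats::setNames(numeric(0), character(0)))
  out <- vapply(seq_len(nrow(pairs)), function(i) {
    x0 <- patient[[pairs$x_var[i]]]
    y0 <- patient[[pairs$y_var[i]]]
    if (is.null(x0) || is.null(y0) || is.na(x0) || is.na(y0)) {
      return(NA_real_)
    }
    orthogonal_delta(x0, y0, pairs$slope[i], pairs$intercept[i])
  }, numeric(1))
  names(out) <- pairs$pair
  out[!is.na(out)]
}

#' Parenclitic profiles for a whole cohort
#'
#' Applies [compute_profile()] to every patient, including the reference
#' patients themselves, in deterministic order by `patient_id`.
#'
#' @param cohort A validated cohort data frame.
#' @param refset A [build_reference_set()] result.
#' @return Data frame: `patient_id` plus one deviation column per reference
#'   pair, `NA` where a member variable is missing.
#' @export
compute_cohort_profiles <- function(cohort, refset) {
  stopifnot(inherits(refset, "parenclitic_refset"))
  cohort <- cohort[order(cohort$patient_id), , drop = FALSE]
  out <- data.frame(patient_id = cohort$patient_id,
                    stringsAsFactors = FALSE)
  pairs <- refset$pairs
  for (i in seq_len(nrow(pairs))) {
    x0 <- cohort[[pairs$x_var[i]]]
    y0 <- cohort[[pairs$y_var[i]]]
    d <- orthogonal_delta(x0, y0, pairs$slope[i], pairs$intercept[i])
    d[is.na(x0) | is.na(y0)] <- NA_real_
    out[[pairs$pair[i]]] <- d
  }
  rownames(out) <- NULL
  out
}
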