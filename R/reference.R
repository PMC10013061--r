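#' Number of unordered variable pairs
#'
#' @param p Number of variables (>= 2).
#' @return p(p-1)/2.
#' @export
#' @examples
#' count_variable_pairs(7) # 21
count_variable_pairs <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1)
  if (p < 2) stop("need at least 2 variables", call. = FALSE)
  p * (p - 1) / 2
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m` at full precision. With alpha = 0.05 over the 21
#'   pairs of 7 variables this is 0.0023809..., conventionally displayed
#'   as 0.0024.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  stopifnot(is.numeric(m), length(m) == 1)
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  alpha / m
}

#' Spearman correlation for one variable pair with pairwise deletion
#'
#' Computes Spearman's rho and a two-sided p-value on the rows where both
#' variables are observed (pair matching). Ties are handled by midranks and
#' the p-value uses the large-sample t approximation. Pairs with fewer than
#' `min_pair_n` complete observations, or with a constant member, are
#' flagged `insufficient` (rho and p set to `NA`) rather than tested.
#'
#' @param data Data frame holding the reference-class rows.
#' @param x_var,y_var Column names of the pair.
#' @param min_pair_n Minimum number of complete pairs (default 10).
#' @return One-row data frame: `x_var`, `y_var`, `pair`, `rho`, `p_value`,
#'   `n_complete`, `insufficient`.
#' @export
spearman_pairwise <- function(data, x_var, y_var, min_pair_n = 10) {
  x <- data[[x_var]]
  y <- data[[y_var]]
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  res <- data.frame(x_var = x_var, y_var = y_var,
                    pair = paste(x_var, y_var, sep = "_"),
                    rho = NA_real_, p_value = NA_real_,
                    n_complete = n, insufficient = TRUE,
                    stringsAsFactors = FALSE)
  if (n < min_pair_n) return(res)
  x <- x[ok]
  y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(res)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  res$rho <- unname(ct$estimate)
  res$p_value <- ct$p.value
  res$insufficient <- FALSE
  res
}

#' Ordinary least squares fit for one variable pair
#'
#' Fits `y = intercept + slope * x` by least squares on the complete pairs
#' of the supplied (reference-class) rows.
#'
#' @param data Data frame of reference rows.
#' @param x_var,y_var Column names (predictor, response).
#' @return List with `slope`, `intercept`, `n`.
#' @export
fit_pair_model <- function(data, x_var, y_var) {
  x <- data[[x_var]]
  y <- data[[y_var]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    stop("need at least 3 complete pairs to fit ", x_var, "-", y_var,
         call. = FALSE)
  }
  vx <- stats::var(x)
  if (vx == 0) {
    stop("degenerate fit: predictor ", x_var, " is constant", call. = FALSE)
  }
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  list(slope = slope, intercept = intercept, n = length(x))
}

#' Build the reference model set from the survivor class
#'
#' Screens all pairs of the seven clinical variables by Spearman
#' correlation in the survivor rows (`event == 0`), keeps the pairs
#' significant at the Bonferroni-corrected level `alpha / m` with m = 21
#' (the full pair count, regardless of missingness), and fits the
#' least-squares reference line for each retained pair. Pairs that fail
#' the threshold are recorded but excluded from further analysis.
#'
#' @param cohort A validated cohort data frame.
#' @param config An [analysis_config()].
#' @return An object of class `parenclitic_refset`: list with `alpha`, `m`,
#'   `threshold`, `screening` (one row per pair: correlation, p, flags,
#'   fitted slope/intercept for significant pairs) and `pairs` (the
#'   significant subset).
#' @export
build_reference_set <- function(cohort, config = analysis_config()) {
  validate_cohort(cohort)
  ref <- cohort[cohort$event == 0, , drop = FALSE]
  if (nrow(ref) < 2) {
    stop("reference class needs at least 2 survivors", call. = FALSE)
  }
  pairs <- all_variable_pairs()
  m <- count_variable_pairs(length(clinical_variables()))
  threshold <- bonferroni_threshold(config$alpha, m)

  screening <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    spearman_pairwise(ref, pairs$x_var[i], pairs$y_var[i],
                      min_pair_n = config$min_pair_n)
  }))
  screening$label <- pairs$label
  screening$significant <- !screening$insufficient &
    screening$p_value <= threshold
  screening$slope <- NA_real_
  screening$intercept <- NA_real_

  for (i in which(screening$significant)) {
    fit <- tryCatch(
      fit_pair_model(ref, screening$x_var[i], screening$y_var[i]),
      error = function(e) {
        warning("dropping pair ", screening$pair[i], ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(fit)) {
      screening$significant[i] <- FALSE
    } else {
      screening$slope[i] <- fit$slope
      screening$intercept[i] <- fit$intercept
    }
  }

  if (!any(screening$significant)) {
    warning("no variable pair passed the Bonferroni-corrected screening; ",
            "network layer will be empty", call. = FALSE)
  }
  structure(list(alpha = config$alpha, m = m, threshold = threshold,
                 n_reference = nrow(ref),
                 screening = screening,
                 pairs = screening[screening$significant, , drop = FALSE]),
            class = "parenclitic_refset")
}

#' @export
print.parenclitic_refset <- function(x, ...) {
  cat("Parenclitic reference model set\n")
  cat(sprintf("  reference class: %d survivors\n", x$n_reference))
  cat(sprintf("  screening: %d pairs at threshold %.3g (alpha %.3g / m %d)\n",
              nrow(x$screening), x$threshold, x$alpha, x$m))
  cat(sprintf("  significant pairs: %d\n", nrow(x$pairs)))
  if (nrow(x$pairs)) {
    print(x$pairs[, c("pair", "rho", "p_value", "n_complete",
                      "slope", "intercept")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}
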