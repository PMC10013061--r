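#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline.
#'
#' @param alpha Family-wise significance level for the Bonferroni-corrected
#'   pair screening (default 0.05).
#' @param horizon_days Follow-up horizon in days; events after the horizon
#'   are administratively censored at the horizon (default 365).
#' @param min_pair_n Minimum number of complete observation pairs required
#'   to compute a pair correlation (default 10). Pairs below this are
#'   flagged "insufficient data" and excluded from screening but still
#'   counted in the Bonferroni denominator.
#' @param seed Integer seed for any stochastic step (default 1).
#' @return A list of class `parenclitic_config`.
#' @export
analysis_config <- function(alpha = 0.05, horizon_days = 365,
                            min_pair_n = 10, seed = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  stopifnot(is.numeric(horizon_days), length(horizon_days) == 1,
            horizon_days > 0)
  stopifnot(is.numeric(min_pair_n), length(min_pair_n) == 1, min_pair_n >= 3)
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(alpha = alpha, horizon_days = horizon_days,
                 min_pair_n = as.integer(min_pair_n),
                 seed = as.integer(seed)),
            class = "parenclitic_config")
}
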