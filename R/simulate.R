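#' Default generative axis specifications
#'
#' Four generative linear axes define the survivor correlation structure:
#' bilirubin, prothrombin time and a latent (continuous) hepatic
#' encephalopathy severity are driven by albumin, and ammonia by the
#' albumin-independent component of the latent HE severity (`HEresid`, the
#' ALB_HE axis noise), so the ammonia-HE relation is its own physiological
#' axis rather than another spoke of the albumin hub. The observed HE
#' grade is the latent severity discretised into 0/1/2. Further correlated
#' axes seen in survivor cohorts (Bil-PT, PT-HE, Bil-HE) arise from this
#' structure as induced correlations through the shared albumin hub, while
#' creatinine, sodium, and ammonia-vs-albumin/bilirubin/PT stay
#' unconnected.
#'
#' Slopes and noise are on raw clinical scales: bilirubin falls by
#' 2.5 umol/L per g/L albumin around a 120 umol/L intercept, etc. Noise
#' SDs are sized so survivor deviations are of order 1-10 raw units.
#'
#' @return Data frame with columns `pair`, `x_var`, `y_var`, `slope`,
#'   `intercept`, `noise_sd`. `HEstar` denotes the latent HE severity and
#'   `HEresid` its albumin-independent component.
#' @export
default_pair_specs <- function() {
  data.frame(
    pair = c("ALB_Bil", "ALB_PT", "ALB_HE", "NH4_HE"),
    x_var = c("ALB", "ALB", "ALB", "HEresid"),
    y_var = c("Bil", "PT", "HEstar", "NH4"),
    slope = c(-2.5, -0.45, -0.055, 90),
    intercept = c(120, 30, 2.4, 40),
    noise_sd = c(8, 2.5, 0.35, 6),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic cirrhosis cohort generator. Two latent
#' groups are drawn: a reference-structure group whose variable pairs
#' follow the generative axes with nominal noise, and a disrupted group
#' whose noise on `disrupted_axes` is inflated by `deviation_inflation`.
#' Event times follow an exponential model whose log-hazard is
#' `log(baseline_hazard)` plus `hazard_coeffs` times the absolute true
#' deviation on each axis, censored administratively at `censor_day`, so
#' mortality rises with deviation magnitude and the disrupted group
#' supplies most non-survivors.
#'
#' @param n_survivors Size of the reference-structure group (default 400).
#' @param n_nonsurvivors Size of the disrupted group (default 100).
#' @param pair_specs Generative axis table, see [default_pair_specs()].
#' @param deviation_inflation Multiplier on `noise_sd` for the disrupted
#'   group on `disrupted_axes` (default 3).
#' @param disrupted_axes Pair ids disrupted in the second group.
#' @param hazard_coeffs Named per-axis log-hazard slope per raw unit of
#'   absolute deviation. Defaults are 0.8 per noise SD on each axis.
#' @param baseline_hazard Baseline hazard, events/day (default 1e-5).
#' @param severity_coeff Log-hazard slope per unit of the noiseless
#'   severity signal underlying MELD (default 0.2), giving conventional
#'   severity scores prognostic value alongside the deviation path.
#' @param severity_shift Downward shift of albumin (g/L) in the disrupted
#'   group (default 4), so that group is sicker on conventional severity
#'   as well as more deviant. Level shifts move patients along the
#'   reference lines, not away from them, so deviations are unaffected.
#' @param censor_day Follow-up horizon in days (default 365).
#' @param missing_rate Per-cell probability that a clinical value is
#'   missing, completely at random (default 0.02).
#' @param seed Default seed used by [generate_cohort()].
#' @return A list of class `parenclitic_sim_config`.
#' @export
synthetic_config <- function(n_survivors = 400,
                             n_nonsurvivors = 100,
                             pair_specs = default_pair_specs(),
                             deviation_inflation = 3,
                             disrupted_axes = c("ALB_Bil", "ALB_PT",
                                                "ALB_HE", "NH4_HE"),
                             hazard_coeffs = c(ALB_Bil = 0.10,
                                               ALB_PT = 0.32,
                                               ALB_HE = 2.29,
                                               NH4_HE = 0.133),
                             baseline_hazard = 1e-5,
                             severity_coeff = 0.2,
                             severity_shift = 4,
                             censor_day = 365,
                             missing_rate = 0.02,
                             seed = 1L) {
  stopifnot(n_survivors >= 0, n_nonsurvivors >= 0,
            all(pair_specs$noise_sd > 0),
            deviation_inflation >= 1,
            missing_rate >= 0, missing_rate < 1,
            baseline_hazard > 0, censor_day > 0,
            severity_coeff >= 0, severity_shift >= 0)
  stopifnot(all(disrupted_axes %in% pair_specs$pair))
  stopifnot(all(pair_specs$pair %in% names(hazard_coeffs)))
  structure(list(n_survivors = as.integer(n_survivors),
                 n_nonsurvivors = as.integer(n_nonsurvivors),
                 pair_specs = pair_specs,
                 deviation_inflation = deviation_inflation,
                 disrupted_axes = disrupted_axes,
                 hazard_coeffs = hazard_coeffs,
                 baseline_hazard = baseline_hazard,
                 severity_coeff = severity_coeff,
                 severity_shift = severity_shift,
                 censor_day = censor_day,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "parenclitic_sim_config")
}

#' Generate a synthetic cirrhosis cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes: linearly correlated variable pairs in the reference-structure
#' group, inflated deviations from those lines in the disrupted group, and
#' hazard increasing with true deviation magnitude. MELD and Child-Pugh
#' scores are monotone noisy functions of bilirubin, prothrombin time and
#' albumin (plus HE grade for Child-Pugh), so conventional severity
#' correlates with outcome. Values are rounded to reporting precision
#' (0.1 units for laboratory values, whole days for follow-up time).
#'
#' The generator requires the four default generative axes (the table in
#' [default_pair_specs()]); their slopes, intercepts and noise SDs may be
#' changed freely, including to zero slope for null-structure cohorts.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (default taken from the config).
#' @return A validated cohort data frame (see [read_cohort()] for columns).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(), seed = 1)
#' table(cohort$event)
generate_cohort <- function(config = synthetic_config(),
                            seed = config$seed) {
  stopifnot(inherits(config, "parenclitic_sim_config"))
  spec <- config$pair_specs
  stopifnot(setequal(spec$pair, default_pair_specs()$pair))
  rownames(spec) <- spec$pair
  set.seed(seed)

  n_ref <- config$n_survivors
  n_dis <- config$n_nonsurvivors
  n <- n_ref + n_dis
  if (n == 0) stop("empty cohort requested", call. = FALSE)
  disrupted <- rep(c(FALSE, TRUE), c(n_ref, n_dis))

  # per-axis noise draws; these are the true deviations feeding the hazard
  draw_noise <- function(id) {
    mult <- ifelse(disrupted & id %in% config$disrupted_axes,
                   config$deviation_inflation, 1)
    stats::rnorm(n, 0, spec[id, "noise_sd"]) * mult
  }
  e <- sapply(spec$pair, draw_noise)
  if (n == 1L) e <- matrix(e, nrow = 1, dimnames = list(NULL, spec$pair))

  # the HE-axis noise splits into a component shared with ammonia and, for
  # disrupted patients, an extra independent component: inflation then
  # reflects HE being driven by factors other than ammonia, breaking the
  # NH4-HE relation instead of sliding points along it
  he_sd <- spec["ALB_HE", "noise_sd"]
  he_mult <- ifelse(disrupted & "ALB_HE" %in% config$disrupted_axes,
                    config$deviation_inflation, 1)
  u_shared <- stats::rnorm(n, 0, he_sd)
  u_extra <- stats::rnorm(n, 0, he_sd) * sqrt(pmax(he_mult^2 - 1, 0))
  e[, "ALB_HE"] <- u_shared + u_extra

  ALB <- stats::runif(n, 20, 45) - config$severity_shift * disrupted
  Bil <- spec["ALB_Bil", "intercept"] + spec["ALB_Bil", "slope"] * ALB +
    e[, "ALB_Bil"]
  PT <- spec["ALB_PT", "intercept"] + spec["ALB_PT", "slope"] * ALB +
    e[, "ALB_PT"]
  HEstar <- spec["ALB_HE", "intercept"] + spec["ALB_HE", "slope"] * ALB +
    e[, "ALB_HE"]
  # ammonia couples to the shared albumin-independent HE component,
  # keeping it unconnected to the albumin hub as in the survivor map
  NH4 <- spec["NH4_HE", "intercept"] +
    spec["NH4_HE", "slope"] * u_shared + e[, "NH4_HE"]
  # latent severity discretised into unimpaired / minimal / overt
  HE <- findInterval(HEstar, c(0.5, 1.1))
  Cr <- pmax(stats::rnorm(n, 85, 25), 20)
  Na <- stats::rnorm(n, 137, 4)
  Bil <- pmax(Bil, 2)
  PT <- pmax(PT, 8)
  NH4 <- pmax(NH4, 5)

  # proportional-hazards link: log-hazard linear in |true deviation| plus
  # a conventional-severity path (noiseless MELD signal, centred)
  severity <- 1.2 * log(Bil) + 0.8 * (PT - 10) + 0.15 * (45 - ALB)
  lp <- as.vector(abs(e) %*% config$hazard_coeffs[spec$pair]) +
    config$severity_coeff * (severity - 10)
  lambda <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate = lambda)
  event <- as.integer(t_event <= config$censor_day)
  time <- pmax(1, ceiling(pmin(t_event, config$censor_day)))

  # conventional severity scores: monotone noisy functions of Bil, PT, ALB
  meld <- round(pmin(pmax(severity + stats::rnorm(n, 0, 1.5), 6), 40))
  child_pugh <- round(pmin(pmax(
    5 + 0.015 * Bil + 0.2 * (PT - 12) + 0.08 * (45 - ALB) + 0.5 * HE +
      stats::rnorm(n, 0, 0.7), 5), 15))

  cohort <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    ALB = round(ALB, 1), Bil = round(Bil, 1), PT = round(PT, 1),
    Cr = round(Cr, 1), NH4 = round(NH4, 1), Na = round(Na, 1),
    HE = as.integer(HE),
    event = event, time = as.numeric(time),
    meld = as.numeric(meld), child_pugh = as.numeric(child_pugh),
    stringsAsFactors = FALSE
  )

  if (config$missing_rate > 0) {
    for (v in clinical_variables()) {
      drop <- stats::runif(n) < config$missing_rate
      cohort[[v]][drop] <- NA
    }
  }
  validate_cohort(cohort)
  cohort
}
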