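# Small deterministic cohort for IO and pipeline tests: 12 patients whose
# values are arbitrary but fixed, with some missingness.
make_small_cohort <- function() {
  data.frame(
    patient_id = sprintf("S%02d", 1:12),
    ALB = c(32.5, 28.1, 41.0, NA, 25.3, 36.7, 30.0, 22.8, 39.4, 27.5,
            33.3, 24.9),
    Bil = c(38.2, 55.0, 17.5, 44.1, 70.3, 29.8, NA, 88.0, 21.2, 60.5,
            35.1, 75.7),
    PT = c(15.2, 18.0, 11.9, 16.4, 20.8, 13.5, 15.0, 22.1, 12.3, 17.7,
           14.6, 21.0),
    Cr = c(80, 95, 70, 110, 130, 75, 88, 150, 68, 102, 85, 120),
    NH4 = c(45.5, 60.2, 32.1, 55.0, NA, 40.3, 50.8, 95.5, 30.6, 70.1,
            48.2, 85.3),
    Na = c(138, 135, 140, 133, 130, 139, 137, 128, 141, 134, 136, 131),
    HE = c(0L, 1L, 0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 0L, 2L),
    event = c(0, 0, 0, 0, 1, 0, 0, 1, 0, 0, 0, 1),
    time = c(365, 365, 365, 365, 120, 365, 365, 60, 365, 365, 365, 200),
    meld = c(12, 16, 8, 14, 22, 10, 13, 28, 7, 17, 11, 24),
    child_pugh = c(7, 9, 5, 8, 11, 6, 8, 13, 5, 9, 7, 12),
    stringsAsFactors = FALSE
  )
}

# 20-patient survival fixture with tied event times, for Cox oracle checks
cox_fixture <- function() {
  data.frame(
    time = c(5, 8, 8, 12, 12, 12, 20, 25, 25, 30, 40, 45, 50, 60, 60, 80,
             90, 100, 100, 100),
    event = c(1, 1, 1, 1, 0, 1, 1, 1, 0, 1, 0, 1, 1, 0, 1, 1, 0, 0, 1, 0),
    x = c(2.1, 1.8, 2.5, 1.2, 0.6, 1.9, 1.4, 1.1, 0.9, 1.6, 0.4, 1.0, 0.8,
          0.3, 0.7, 0.5, 0.2, 0.1, 0.6, 0.2))
}

# reference set built directly from given pair fits, bypassing screening,
# for deviation/topology unit tests
make_refset <- function(pairs_df) {
  screening <- pairs_df
  screening$label <- screening$pair
  screening$rho <- 1
  screening$p_value <- 0
  screening$n_complete <- 100L
  screening$insufficient <- FALSE
  screening$significant <- TRUE
  structure(list(alpha = 0.05, m = 21, threshold = 0.05 / 21,
                 n_reference = 100L, screening = screening,
                 pairs = screening),
            class = "parenclitic_refset")
}

# the six-axis reference set spanning ALB, Bil, PT, NH4, HE with simple
# line parameters, used where the pair structure (not the fit) matters
six_pair_refset <- function() {
  make_refset(data.frame(
    x_var = c("ALB", "ALB", "ALB", "Bil", "PT", "NH4"),
    y_var = c("Bil", "PT", "HE", "PT", "HE", "HE"),
    pair = c("ALB_Bil", "ALB_PT", "ALB_HE", "Bil_PT", "PT_HE", "NH4_HE"),
    slope = c(-2.5, -0.45, -0.06, 0.15, 0.1, 0.013),
    intercept = c(120, 30, 2.5, 9.5, -0.7, 0.14),
    stringsAsFactors = FALSE
  ))
}

# variant whose six lines all pass through the single point
# (ALB, Bil, PT, NH4, HE) = (30, 45, 16.5, 43, 0.7)
consistent_refset <- function() {
  make_refset(data.frame(
    x_var = c("ALB", "ALB", "ALB", "Bil", "PT", "NH4"),
    y_var = c("Bil", "PT", "HE", "PT", "HE", "HE"),
    pair = c("ALB_Bil", "ALB_PT", "ALB_HE", "Bil_PT", "PT_HE", "NH4_HE"),
    slope = c(-2.5, -0.45, -0.06, 0.15, 0.1, 0.013),
    intercept = c(120, 30, 2.5, 9.75, -0.95, 0.7 - 0.013 * 43),
    stringsAsFactors = FALSE
  ))
}
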