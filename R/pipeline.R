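empty_comparison <- function() {
  data.frame(feature = character(0), median_a = numeric(0),
             q1_a = numeric(0), q3_a = numeric(0), median_b = numeric(0),
             q1_b = numeric(0), q3_b = numeric(0), U = numeric(0),
             p_value = numeric(0), stringsAsFactors = FALSE)
}

empty_cox <- function() {
  data.frame(feature = character(0), term = character(0), beta = numeric(0),
             sem = numeric(0), hr = numeric(0), ci_lower = numeric(0),
             ci_upper = numeric(0), p_value = numeric(0),
             stringsAsFactors = FALSE)
}

empty_auc <- function() {
  data.frame(score = character(0), auc = numeric(0), ci_lower = numeric(0),
             ci_upper = numeric(0), cutoff = numeric(0),
             sensitivity = numeric(0), specificity = numeric(0),
             flipped = logical(0), stringsAsFactors = FALSE)
}

empty_km_summary <- function() {
  data.frame(score = character(0), cutoff = numeric(0),
             n_predicted_nonsurvivor = integer(0),
             n_predicted_survivor = integer(0), chisq = numeric(0),
             p_value = numeric(0), stringsAsFactors = FALSE)
}

#' Run the full parenclitic prognosis pipeline
#'
#' Orchestrates the analysis end to end on one cohort:
#' \enumerate{
#'   \item administrative censoring at the follow-up horizon;
#'   \item Bonferroni-corrected Spearman screening and reference-line
#'     fitting in the survivor class ([build_reference_set()]);
#'   \item per-patient orthogonal deviations
#'     ([compute_cohort_profiles()]) and deviation-weighted topology
#'     indices ([compute_cohort_topology()]);
#'   \item survivor vs non-survivor Mann-Whitney comparisons of every
#'     deviation and topology index;
#'   \item univariate Cox models per deviation axis and topology index,
#'     and bivariate models adjusting for MELD and for Child-Pugh;
#'   \item ROC analysis (AUC, Youden cutoff) of each deviation, of MELD,
#'     and of combined MELD-deviation indices for axes whose deviation
#'     stays significant alongside MELD; Kaplan-Meier/log-rank tests of
#'     every cutoff-dichotomised score.
#' }
#' The run is a pure function of `(cohort, config)`: no randomness is
#' involved, so repeated runs give identical output. A cohort without
#' non-survivors yields empty survival contrasts with a warning; a cohort
#' in which no pair passes screening yields an empty network layer with a
#' warning; a cohort without survivors is an error (no reference class).
#'
#' @param cohort A validated cohort data frame.
#' @param config An [analysis_config()].
#' @return List of class `parenclitic_result` with elements `config`,
#'   `cohort` (censored, ordered by patient id), `refset`, `deltas`,
#'   `topology`, `deviation_comparison`, `topology_comparison`,
#'   `cox_univariate`, `cox_bivariate_meld`, `cox_bivariate_childpugh`,
#'   `auc`, `km_summary`, `km` (list of [km_logrank()] results by score).
#' @export
run_pipeline <- function(cohort, config = analysis_config()) {
  validate_cohort(cohort)
  cohort <- censor_at_horizon(cohort, config$horizon_days)
  cohort <- cohort[order(cohort$patient_id), , drop = FALSE]
  rownames(cohort) <- NULL

  is_event <- cohort$event == 1
  if (sum(!is_event) < 2) {
    stop("no reference class: need at least 2 survivors", call. = FALSE)
  }

  refset <- build_reference_set(cohort, config)
  out <- list(config = config, cohort = cohort, refset = refset,
              deltas = NULL, topology = NULL,
              deviation_comparison = empty_comparison(),
              topology_comparison = empty_comparison(),
              cox_univariate = empty_cox(),
              cox_bivariate_meld = empty_cox(),
              cox_bivariate_childpugh = empty_cox(),
              auc = empty_auc(),
              km_summary = empty_km_summary(),
              km = list())
  class(out) <- "parenclitic_result"
  if (nrow(refset$pairs) == 0) {
    out$deltas <- data.frame(patient_id = cohort$patient_id,
                             stringsAsFactors = FALSE)
    return(out)
  }

  deltas <- compute_cohort_profiles(cohort, refset)
  topology <- compute_cohort_topology(deltas, refset)
  out$deltas <- deltas
  out$topology <- topology

  if (!any(is_event)) {
    warning("cohort has no non-survivors; survival contrasts are empty",
            call. = FALSE)
    return(out)
  }

  pair_ids <- refset$pairs$pair
  topo_ids <- c("mean_centrality", "sd_centrality", "char_path_length",
                "diameter", "global_efficiency")
  surv_rows <- !is_event

  cmp_rows <- lapply(pair_ids, function(p) {
    mann_whitney_compare(deltas[[p]][surv_rows], deltas[[p]][!surv_rows],
                         feature = p)
  })
  out$deviation_comparison <- do.call(rbind, cmp_rows)

  topo_rows <- lapply(topo_ids, function(p) {
    mann_whitney_compare(topology[[p]][surv_rows], topology[[p]][!surv_rows],
                         feature = p)
  })
  out$topology_comparison <- do.call(rbind, topo_rows)

  fit_rows <- function(feature, covs) {
    res <- tryCatch(cox_fit(cohort$time, cohort$event, covs),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    cbind(data.frame(feature = feature, stringsAsFactors = FALSE), res)
  }

  uni <- lapply(c(pair_ids, topo_ids), function(p) {
    src <- if (p %in% pair_ids) deltas else topology
    fit_rows(p, stats::setNames(data.frame(src[[p]]), p))
  })
  out$cox_univariate <- do.call(rbind, uni)

  bi_meld <- lapply(pair_ids, function(p) {
    fit_rows(p, stats::setNames(data.frame(deltas[[p]], cohort$meld),
                                c(p, "meld")))
  })
  out$cox_bivariate_meld <- do.call(rbind, bi_meld)

  bi_cp <- lapply(c(pair_ids, "sd_centrality"), function(p) {
    src <- if (p %in% pair_ids) deltas else topology
    fit_rows(p, stats::setNames(data.frame(src[[p]], cohort$child_pugh),
                                c(p, "child_pugh")))
  })
  out$cox_bivariate_childpugh <- do.call(rbind, bi_cp)

  # scores entering the ROC/KM layer: every deviation axis, MELD, and the
  # combined MELD-deviation index for axes independent of MELD
  scores <- stats::setNames(
    lapply(pair_ids, function(p) deltas[[p]]), pair_ids)
  scores$MELD <- cohort$meld

  bm <- out$cox_bivariate_meld
  indep <- unique(bm$feature[bm$term != "meld" & bm$p_value < 0.05 &
                               bm$hr > 1])
  for (p in indep) {
    b_delta <- bm$beta[bm$feature == p & bm$term == p]
    b_meld <- bm$beta[bm$feature == p & bm$term == "meld"]
    scores[[paste0("MELD_d_", p)]] <-
      combined_index(b_meld, cohort$meld, b_delta, deltas[[p]])
  }

  auc_rows <- list()
  for (s in names(scores)) {
    roc <- tryCatch(roc_with_cutoff(scores[[s]], cohort$event),
                    error = function(e) NULL)
    if (is.null(roc)) next
    auc_rows[[s]] <- data.frame(
      score = s, auc = roc$auc, ci_lower = roc$ci_lower,
      ci_upper = roc$ci_upper, cutoff = roc$cutoff,
      sensitivity = roc$sensitivity, specificity = roc$specificity,
      flipped = roc$flipped, stringsAsFactors = FALSE)

    pred_pos <- if (roc$flipped) scores[[s]] <= roc$cutoff
                else scores[[s]] >= roc$cutoff
    grp <- ifelse(pred_pos, "predicted_nonsurvivor", "predicted_survivor")
    km <- tryCatch(km_logrank(cohort$time, cohort$event, grp),
                   error = function(e) NULL)
    if (!is.null(km)) {
      out$km[[s]] <- km
      out$km_summary <- rbind(out$km_summary, data.frame(
        score = s, cutoff = roc$cutoff,
        n_predicted_nonsurvivor = sum(pred_pos, na.rm = TRUE),
        n_predicted_survivor = sum(!pred_pos, na.rm = TRUE),
        chisq = km$chisq, p_value = km$p_value,
        stringsAsFactors = FALSE))
    }
  }
  out$auc <- do.call(rbind, c(auc_rows, list(make.row.names = FALSE)))
  if (is.null(out$auc)) out$auc <- empty_auc()
  rownames(out$km_summary) <- NULL
  out
}

#' @export
print.parenclitic_result <- function(x, ...) {
  cat("Parenclitic pipeline result\n")
  cat(sprintf("  cohort: %d patients (%d non-survivors)\n",
              nrow(x$cohort), sum(x$cohort$event == 1)))
  cat(sprintf("  reference pairs: %d of %d screened\n",
              nrow(x$refset$pairs), nrow(x$refset$screening)))
  if (nrow(x$deviation_comparison)) {
    cat("  deviation comparison (survivors vs non-survivors):\n")
    print(x$deviation_comparison[, c("feature", "median_a", "median_b",
                                     "p_value")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write pipeline result tables to CSV files
#'
#' Writes one CSV per result table into `outdir` (created if needed):
#' screening report, per-patient deviations and topology indices, the
#' group-comparison and Cox tables, the AUC table, the log-rank summary
#' and the Kaplan-Meier step functions.
#'
#' @param result A [run_pipeline()] result.
#' @param outdir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(result, outdir) {
  stopifnot(inherits(result, "parenclitic_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  emit(result$refset$screening, "screening.csv")
  if (!is.null(result$deltas)) emit(result$deltas, "deltas.csv")
  if (!is.null(result$topology)) emit(result$topology, "topology.csv")
  emit(result$deviation_comparison, "deviation_comparison.csv")
  emit(result$topology_comparison, "topology_comparison.csv")
  emit(result$cox_univariate, "cox_univariate.csv")
  emit(result$cox_bivariate_meld, "cox_bivariate_meld.csv")
  emit(result$cox_bivariate_childpugh, "cox_bivariate_childpugh.csv")
  emit(result$auc, "auc.csv")
  emit(result$km_summary, "km_summary.csv")
  if (length(result$km)) {
    curves <- do.call(rbind, lapply(names(result$km), function(s) {
      cbind(data.frame(score = s, stringsAsFactors = FALSE),
            result$km[[s]]$curves)
    }))
    emit(curves, "km_curves.csv")
  }
  invisible(paths)
}
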