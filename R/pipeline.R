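# End-to-end scoring pipeline: exclusions -> outcome ascertainment ->
# features -> staged stratum models (raw-age stage, then race-centered age
# with Wald retention) -> dual-threshold tuning -> tiers -> evaluation.

#' Ascertain the two-year LTI outcome from outcome-period stays
#'
#' A person is LTI-positive when a qualifying spell *starts* within the
#' two-year outcome window; NH-day accumulation may continue past the
#' window end up to `horizon_days` after the index date. Timelines end at
#' the death date.
#'
#' @param cohort a `pli_cohort`.
#' @param rule a [spell_rule()].
#' @param window_days outcome window length in days (default 730).
#' @param horizon_days data horizon for day accumulation (default 910).
#' @return data.frame `person_id`, `lti` (0/1) for every person.
#' @export
ascertain_lti <- function(cohort, rule = spell_rule(), window_days = 730L,
                          horizon_days = 910L) {
  idx <- cohort$index_date
  deaths <- data.frame(person_id = cohort$truth$person_id,
                       death_date = cohort$truth$death_date)
  spells <- detect_lti_cohort(cohort$stays_outcome,
                              c(idx, idx + horizon_days - 1L), rule, deaths)
  pos <- unique(spells$person_id[spells$qualifying &
                                   spells$spell_start < idx + window_days])
  data.frame(person_id = cohort$persons$person_id,
             lti = as.integer(cohort$persons$person_id %in% pos))
}

#' Run the full LTI risk pipeline on a cohort
#'
#' Applies cohort exclusions, ascertains the two-year LTI outcome with the
#' spell detector, builds feature rows (complete or production mode), fits
#' the staged stratum models (a raw-age stage whose Wald-significant
#' covariates are retained, then a final fit with race-centered age),
#' optimizes high-tier thresholds under the NNS budget, derives moderate
#' thresholds from a wider budget, assigns tiers, and computes the full
#' evaluation report.
#'
#' @param cohort a `pli_cohort`.
#' @param mode `"complete"` or `"production"` (lagged non-VA data,
#'   24-month look-back).
#' @param link `"logit"` or `"probit"`.
#' @param nns_max pooled NNS budget for the high tier (default 8).
#' @param nns_moderate budget defining the moderate tier (default 25).
#' @param rule [spell_rule()].
#' @param with_facility_effects include facility fixed effects.
#' @param retention_alpha Wald retention level (default 0.05).
#' @param age_variable final-stage age covariate (`"race_centered_age"` or
#'   `"age"`, for bias comparisons).
#' @param lag_months production-mode data lag.
#' @param seed seed for the auxiliary-model slice and missingness draws.
#' @return object of class `pli_result`.
#' @export
pli_pipeline <- function(cohort, mode = c("complete", "production"),
                         link = "logit", nns_max = 8, nns_moderate = 25,
                         rule = spell_rule(), with_facility_effects = TRUE,
                         retention_alpha = 0.05,
                         age_variable = c("race_centered_age", "age"),
                         lag_months = 9L, seed = 1L) {
  mode <- match.arg(mode)
  age_variable <- match.arg(age_variable)
  deaths <- data.frame(person_id = cohort$truth$person_id,
                       death_date = cohort$truth$death_date)
  excl <- apply_cohort_exclusions(cohort$persons, cohort$stays_baseline,
                                  deaths, cohort$index_date, rule)
  out <- ascertain_lti(cohort, rule)
  features <- build_feature_rows(cohort, excl$eligible, mode = mode,
                                 lag_months = lag_months, rule = rule,
                                 can_seed = seed)
  y <- out$lti[match(features$person_id, out$person_id)]

  stage1_covs <- c("age", setdiff(model_covariates(), "race_centered_age"))
  final_covs_of <- function(retained) {
    unique(c(age_variable, setdiff(retained, c("age", "race_centered_age"))))
  }
  rows_by <- split(features, features$stratum)
  y_by <- split(y, features$stratum)
  stage1 <- list()
  for (s in names(rows_by)) {
    stage1[[s]] <- suppressWarnings(
      fit_stratum_model(rows_by[[s]], y_by[[s]], stratum = s, link = link,
                        with_facility_effects = with_facility_effects,
                        covariates = stage1_covs))
  }
  retained <- suppressWarnings(variable_retention(stage1, retention_alpha))
  final_covs <- final_covs_of(retained)
  models <- list()
  for (s in names(rows_by)) {
    models[[s]] <- suppressWarnings(
      fit_stratum_model(rows_by[[s]], y_by[[s]], stratum = s, link = link,
                        with_facility_effects = with_facility_effects,
                        covariates = final_covs))
  }
  scores <- do.call(rbind, lapply(names(models), function(s)
    predict_risk(models[[s]], rows_by[[s]])))
  scores <- scores[match(features$person_id, scores$person_id), ]
  rownames(scores) <- NULL
  scores$outcome <- y

  high <- optimize_thresholds(scores, nns_max = nns_max)
  moderate <- moderate_thresholds(scores, high = high,
                                  nns_moderate = nns_moderate)
  tiers <- assign_tiers(scores, high, moderate)
  flagged <- tiers$tier == "high"

  idx <- cohort$index_date
  tr <- cohort$truth[match(features$person_id, cohort$truth$person_id), ]
  died2y <- !is.na(tr$death_date) & tr$death_date < idx + 730L
  report <- list(
    confusion = confusion_metrics(flagged, y),
    c_statistic = vapply(names(models), function(s)
      c_statistic(scores$p_lti[scores$stratum == s],
                  y[scores$stratum == s]), numeric(1L)),
    pseudo_r2 = vapply(models, pseudo_r2, numeric(1L)),
    calibration = lapply(stats::setNames(names(models), names(models)),
      function(s) {
        i <- scores$stratum == s
        calibration_by_decile(scores$p_lti[i], y[i], scores$person_id[i])
      }),
    fnr = fnr_equity_audit(flagged, y, features$race_group,
                           features$stratum),
    tier_table = tier_outcome_table(tiers, y, died2y, tr$cost_outcome,
                                    list(nic_use = tr$nic_use,
                                         pcs_use = tr$pcs_use)),
    facility_nns = facility_nns_distribution(flagged, y,
                                             features$facility_id),
    er_prevalence = mean(features$stratum == "ER"))

  structure(list(mode = mode, link = link, exclusions = excl$tally,
                 features = features, outcome = y, models = models,
                 stage1_models = stage1, retained = retained,
                 scores = scores, thresholds = list(high = high,
                                                    moderate = moderate),
                 tiers = tiers, report = report),
            class = "pli_result")
}

#' @export
print.pli_result <- function(x, ...) {
  cm <- x$report$confusion
  cat(sprintf("<pli_result> mode=%s link=%s  n=%d eligible\n",
              x$mode, x$link, nrow(x$features)))
  cat(sprintf("  ER share %.1f%% | high tier %d (NNS %.2f, sens %.1f%%, spec %.1f%%)\n",
              100 * x$report$er_prevalence, sum(x$tiers$tier == "high"),
              cm$nns, 100 * cm$sensitivity, 100 * cm$specificity))
  cat(sprintf("  c-statistic: %s\n",
              paste(sprintf("%s %.3f", names(x$report$c_statistic),
                            x$report$c_statistic), collapse = ", ")))
  invisible(x)
}

#' Write the evaluation report and tier tables to a directory
#'
#' Writes `report.json` (metrics), `calibration.csv`, `tiers.csv`, and
#' `facility_nns.csv`.
#'
#' @param result a `pli_result`.
#' @param directory output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(result, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  rep <- result$report
  metrics <- c(rep$confusion[c("sensitivity", "specificity", "ppv", "nns")],
               list(c_statistic = as.list(rep$c_statistic),
                    pseudo_r2 = as.list(rep$pseudo_r2),
                    er_prevalence = rep$er_prevalence,
                    fnr_gap = as.list(rep$fnr$gap),
                    thresholds = list(
                      tau_er = result$thresholds$high$tau_er,
                      tau_cr = result$thresholds$high$tau_cr)))
  jsonlite::write_json(metrics, file.path(directory, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  cal <- do.call(rbind, lapply(names(rep$calibration), function(s)
    cbind(stratum = s, rep$calibration[[s]])))
  data.table::fwrite(cal, file.path(directory, "calibration.csv"))
  data.table::fwrite(result$tiers, file.path(directory, "tiers.csv"))
  data.table::fwrite(rep$facility_nns,
                     file.path(directory, "facility_nns.csv"))
  invisible(file.path(directory, c("report.json", "calibration.csv",
                                   "tiers.csv", "facility_nns.csv")))
}

#' Calibration plot (observed vs predicted by decile)
#'
#' @param result a `pli_result`.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_calibration <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_calibration() requires ggplot2")
  }
  cal <- do.call(rbind, lapply(names(result$report$calibration), function(s)
    cbind(stratum = s, result$report$calibration[[s]])))
  ggplot2::ggplot(cal, ggplot2::aes(x = .data$mean_predicted,
                                    y = .data$observed_rate,
                                    colour = .data$stratum)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "Mean predicted LTI risk (decile)",
                  y = "Observed LTI rate", colour = "Stratum") +
    ggplot2::theme_minimal()
}

#' Histogram of per-facility number needed to screen
#'
#' @param result a `pli_result`.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_facility_nns <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_facility_nns() requires ggplot2")
  }
  fx <- result$report$facility_nns
  ggplot2::ggplot(fx[!is.na(fx$nns), ], ggplot2::aes(x = .data$nns)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "Facility-level NNS", y = "Facilities") +
    ggplot2::theme_minimal()
}
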