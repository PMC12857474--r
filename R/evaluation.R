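# Accuracy, calibration, fairness, cross-validation, and descriptive
# outputs: confusion metrics and number needed to screen, concordance
# statistic, decile calibration, false-negative-rate equity audit,
# k-fold cross-validation of the full pipeline, facility-level NNS, and
# tier-level outcome tables.

#' Confusion metrics and number needed to screen
#'
#' Standard definitions: sensitivity = TP / positives, specificity =
#' TN / negatives, PPV = TP / flagged, NNS = flagged / TP (the reciprocal
#' of PPV). With zero positives, sensitivity is undefined and reported as
#' `NA` with a message.
#'
#' @param flagged logical/0-1 high-tier indicator.
#' @param outcome logical/0-1 outcome indicator, same length.
#' @return list `sensitivity`, `specificity`, `ppv`, `nns`, plus the raw
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_metrics <- function(flagged, outcome) {
  stopifnot(length(flagged) == length(outcome))
  f <- isTRUE_vec(flagged); y <- isTRUE_vec(outcome)
  tp <- sum(f & y); fp <- sum(f & !y); fn <- sum(!f & y); tn <- sum(!f & !y)
  confusion_from_counts(n_flagged = tp + fp, tp = tp, positives = tp + fn,
                        n = length(f))
}

#' Confusion metrics from aggregate counts
#'
#' The same arithmetic as [confusion_metrics()], computed from published
#' aggregate counts (persons flagged, true positives among them, total
#' positives, cohort size) rather than person-level vectors.
#'
#' @param n_flagged persons flagged high-risk.
#' @param tp flagged persons who experienced the outcome.
#' @param positives total persons who experienced the outcome.
#' @param n cohort size.
#' @return list as in [confusion_metrics()].
#' @export
confusion_from_counts <- function(n_flagged, tp, positives, n) {
  fp <- n_flagged - tp
  fn <- positives - tp
  tn <- n - positives - fp
  sens <- if (positives > 0) tp / positives else {
    message("no positive outcomes: sensitivity undefined")
    NA_real_
  }
  spec <- if (n - positives > 0) tn / (n - positives) else NA_real_
  ppv <- if (n_flagged > 0) tp / n_flagged else NA_real_
  nns <- if (tp > 0) n_flagged / tp else NA_real_
  list(sensitivity = sens, specificity = spec, ppv = ppv, nns = nns,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Concordance (c-) statistic of a risk score
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half; computed by the rank-sum
#' (Mann-Whitney) identity.
#'
#' @param scores numeric risk scores.
#' @param outcomes logical/0-1 outcomes; needs at least one positive and
#'   one negative.
#' @return value in \[0, 1\].
#' @export
c_statistic <- function(scores, outcomes) {
  y <- isTRUE_vec(outcomes)
  np <- sum(y); nn <- sum(!y)
  if (np == 0L || nn == 0L) {
    stop("degenerate outcome vector: need at least one positive and one negative")
  }
  r <- rank(scores)
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

#' Calibration by predicted-risk decile
#'
#' Persons are ranked by predicted score (stable sort on `person_id` within
#' ties), split into `bins` equal-count groups, and each group reports mean
#' predicted risk versus observed outcome rate.
#'
#' @param scores numeric predicted probabilities.
#' @param outcomes logical/0-1 outcomes.
#' @param person_id ids for stable tie ordering (default index order).
#' @param bins number of bins (default 10; requires `n >= bins`).
#' @return data.frame `decile`, `n`, `mean_predicted`, `observed_rate`.
#' @export
calibration_by_decile <- function(scores, outcomes, person_id = NULL,
                                  bins = 10L) {
  n <- length(scores)
  stopifnot(n >= bins)
  if (is.null(person_id)) person_id <- seq_len(n)
  y <- as.integer(isTRUE_vec(outcomes))
  ord <- order(scores, person_id)
  bin <- ceiling(seq_len(n) * bins / n)
  data.frame(
    decile = seq_len(bins),
    n = as.integer(tabulate(bin, bins)),
    mean_predicted = as.numeric(tapply(scores[ord], bin, mean)),
    observed_rate = as.numeric(tapply(y[ord], bin, mean)))
}

#' False-negative-rate equity audit
#'
#' FNR = outcome cases not flagged high / all outcome cases, per race group
#' within each stratum; the gap is the spread (max minus min) of the FNRs
#' across groups within a stratum, i.e. the between-group absolute
#' difference when there are two groups. Groups with zero cases report
#' `NA`.
#'
#' @param flagged logical/0-1 high-tier indicator.
#' @param outcomes logical/0-1 outcome indicator.
#' @param race_group character group labels.
#' @param stratum character stratum labels ("ER"/"CR").
#' @return list with `fnr` (data.frame stratum x group) and `gap` (named
#'   numeric per stratum).
#' @export
fnr_equity_audit <- function(flagged, outcomes, race_group, stratum) {
  f <- isTRUE_vec(flagged); y <- isTRUE_vec(outcomes)
  dt <- data.table::data.table(f = f, y = y, g = as.character(race_group),
                               s = as.character(stratum))
  tab <- dt[dt$y == TRUE, list(cases = .N, missed = sum(!f)), by = c("s", "g")]
  # groups with zero cases in a stratum appear as NA rows
  grid <- data.table::CJ(s = unique(dt$s), g = unique(dt$g))
  tab <- merge(grid, tab, by = c("s", "g"), all.x = TRUE)
  tab$fnr <- ifelse(is.na(tab$cases) | tab$cases == 0, NA_real_,
                    tab$missed / tab$cases)
  fnr <- as.data.frame(tab[, c("s", "g", "cases", "fnr")])
  names(fnr) <- c("stratum", "race_group", "cases", "fnr")
  gap <- vapply(split(fnr$fnr, fnr$stratum), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else max(v) - min(v)
  }, numeric(1L))
  list(fnr = fnr, gap = gap)
}

#' Tier-level outcome table
#'
#' Per tier: persons, outcome (LTI) count and rate, death count and rate,
#' mean cost, and count and rate for each supplied service-use flag.
#'
#' @param tiers data.frame from [assign_tiers()] (needs `person_id`,
#'   `tier`).
#' @param outcomes logical/0-1 LTI indicator aligned with `tiers`.
#' @param deaths logical/0-1 death indicator.
#' @param costs numeric cost per person.
#' @param service_flags optional named list of logical/0-1 vectors.
#' @return data.frame, one row per tier plus column-wise shares of the
#'   cohort totals.
#' @export
tier_outcome_table <- function(tiers, outcomes, deaths = NULL, costs = NULL,
                               service_flags = NULL) {
  tier <- factor(tiers$tier, levels = c("high", "moderate", "low"))
  y <- as.integer(isTRUE_vec(outcomes))
  out <- data.frame(tier = levels(tier),
                    n = as.integer(table(tier)))
  out$pct_of_cohort <- 100 * out$n / sum(out$n)
  out$lti <- as.integer(tapply(y, tier, sum, default = 0L))
  out$lti_pct <- 100 * out$lti / out$n
  if (!is.null(deaths)) {
    d <- as.integer(isTRUE_vec(deaths))
    out$deaths <- as.integer(tapply(d, tier, sum, default = 0L))
    out$death_pct <- 100 * out$deaths / out$n
  }
  if (!is.null(costs)) {
    out$mean_cost <- as.numeric(tapply(as.numeric(costs), tier, mean))
    out$mean_cost[is.na(out$mean_cost)] <- 0
  }
  for (nm in names(service_flags)) {
    v <- as.integer(isTRUE_vec(service_flags[[nm]]))
    out[[nm]] <- as.integer(tapply(v, tier, sum, default = 0L))
    out[[paste0(nm, "_pct")]] <- 100 * out[[nm]] / out$n
  }
  out$lti_pct[out$n == 0] <- NA_real_
  if (!is.null(deaths)) out$death_pct[out$n == 0] <- NA_real_
  out
}

#' Percentages implied by a published tier count table
#'
#' Recomputes the within-tier rates and tier shares implied by aggregate
#' counts (tier sizes and per-tier event counts).
#'
#' @param n_tier integer vector of tier sizes.
#' @param events named list of integer vectors (per-tier event counts).
#' @return data.frame with tier shares (% of cohort) and one rate column
#'   (% within tier) per event type.
#' @export
tier_table_percentages <- function(n_tier, events = list()) {
  out <- data.frame(n = n_tier, pct_of_cohort = 100 * n_tier / sum(n_tier))
  for (nm in names(events)) {
    out[[paste0(nm, "_pct")]] <- 100 * events[[nm]] / n_tier
  }
  out
}

#' Per-facility number needed to screen
#'
#' NNS among each facility's flagged persons; facilities whose flagged set
#' contains no true positive report `NA`.
#'
#' @param flagged logical/0-1 high-tier indicator.
#' @param outcomes logical/0-1 outcome indicator.
#' @param facility_id facility assignment per person.
#' @return data.frame `facility_id`, `n_flagged`, `tp`, `nns`.
#' @export
facility_nns_distribution <- function(flagged, outcomes, facility_id) {
  f <- isTRUE_vec(flagged); y <- isTRUE_vec(outcomes)
  dt <- data.table::data.table(f = f, y = y, fac = as.character(facility_id))
  tab <- dt[, list(n_flagged = sum(f), tp = sum(f & y)), by = "fac"]
  tab$nns <- ifelse(tab$tp > 0, tab$n_flagged / tab$tp, NA_real_)
  out <- as.data.frame(tab)
  names(out)[1L] <- "facility_id"
  out[order(out$facility_id), , drop = FALSE]
}

#' Stratified k-fold cross-validation of the scoring pipeline
#'
#' Folds are assigned within outcome-by-stratum cells (seeded), so every
#' fold carries positives from both strata when possible. For each fold the
#' full pipeline runs on the training folds - stratum models are fit and
#' high-risk thresholds re-optimized - and the held-out fold is scored and
#' evaluated. Folds whose test set has no positives are skipped with a
#' warning.
#'
#' @param features feature rows (with `stratum` column).
#' @param outcome binary outcome vector.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param nns_max NNS budget passed to the threshold optimizer.
#' @param link model link.
#' @param covariates model covariates.
#' @param with_facility_effects passed to [fit_stratum_model()].
#' @return list with `folds` (per-fold metric rows) and `range` (min-max of
#'   NNS and sensitivity across folds).
#' @export
kfold_cv <- function(features, outcome, k = 10L, seed = 1L, nns_max = 8,
                     link = "logit", covariates = model_covariates(),
                     with_facility_effects = FALSE) {
  stopifnot(k >= 2L)
  y <- as.integer(isTRUE_vec(outcome))
  n <- nrow(features)
  fold <- integer(n)
  cells <- interaction(features$stratum, y, drop = TRUE)
  fold <- withr_seed(seed, {
    f <- integer(n)
    for (cl in levels(cells)) {
      i <- which(cells == cl)
      f[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    f
  })
  rows <- list()
  for (fd in seq_len(k)) {
    test <- fold == fd
    if (sum(y[test]) == 0L) {
      warning("fold ", fd, " has no positive outcomes in its test set; skipped")
      next
    }
    tr_feat <- features[!test, , drop = FALSE]
    tr_y <- y[!test]
    models <- list()
    for (s in c("ER", "CR")) {
      si <- tr_feat$stratum == s
      if (!any(si) || sum(tr_y[si]) == 0L || sum(1 - tr_y[si]) == 0L) next
      models[[s]] <- suppressWarnings(
        fit_stratum_model(tr_feat[si, , drop = FALSE], tr_y[si], stratum = s,
                          link = link, covariates = covariates,
                          with_facility_effects = with_facility_effects))
    }
    score_set <- function(feat) {
      parts <- lapply(names(models), function(s) {
        si <- feat$stratum == s
        if (!any(si)) return(NULL)
        predict_risk(models[[s]], feat[si, , drop = FALSE])
      })
      do.call(rbind, parts)
    }
    tr_scores <- score_set(tr_feat)
    tr_scores$outcome <- tr_y[match(tr_scores$person_id, tr_feat$person_id)]
    pair <- optimize_thresholds(tr_scores, nns_max = nns_max)
    te_feat <- features[test, , drop = FALSE]
    te_scores <- score_set(te_feat)
    te_y <- y[test][match(te_scores$person_id, te_feat$person_id)]
    flag <- te_scores$p_lti >= .tau_for(pair, te_scores$stratum)
    cm <- confusion_metrics(flag, te_y)
    rows[[length(rows) + 1L]] <- data.frame(
      fold = fd, n_test = length(te_y), sensitivity = cm$sensitivity,
      specificity = cm$specificity, ppv = cm$ppv, nns = cm$nns,
      c_statistic = c_statistic(te_scores$p_lti, te_y))
  }
  folds <- do.call(rbind, rows)
  list(folds = folds, assignment = fold,
       range = list(nns = range(folds$nns, na.rm = TRUE),
                    sensitivity = range(folds$sensitivity, na.rm = TRUE)))
}
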