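# Claims-based covariate construction: frailty index proxy, auxiliary
# death-or-hospitalization risk proxy, monthly IAH-Q / HNHR indicators,
# ER/CR stratum assignment, race-centered age, and the feature-row builder
# (complete-data and production/lagged variants).

#' The diagnosis conditions carried by the model
#'
#' Eighteen condition flags used as model covariates; four additional
#' generic frailty-domain diagnoses contribute to the frailty index only.
#' @export
CONDITIONS <- c(
  "amputation", "cancer", "dementia", "diabetes", "fracture", "head_injury",
  "heart_failure", "malnutrition", "multiple_sclerosis", "obesity",
  "parkinsons", "pressure_ulcer", "schizophrenia", "spinal_cord_injury",
  "seizure", "sepsis", "stroke", "substance_use_disorder")

#' @rdname CONDITIONS
#' @export
FRAILTY_DOMAIN_CONDITIONS <- c(
  "mobility_impairment", "adl_dependence", "sensory_impairment",
  "incontinence")

#' Default chronic-condition subset used by the IAH-Q indicator
#' (all model conditions except the acute events sepsis and fracture).
#' @export
CHRONIC_CONDITIONS <- setdiff(CONDITIONS, c("sepsis", "fracture"))

#' Frailty-index condition-group map
#'
#' The frailty index proxy is a transparent count: the number of disjoint
#' condition groups with at least one qualifying diagnosis in the look-back
#' window. Each group contributes at most 1; the score is bounded by the
#' number of groups (13 by default).
#'
#' @param groups named list mapping group name to a character vector of
#'   contributing diagnosis conditions.
#' @return object of class `frailty_map` with attribute `max_score`.
#' @export
frailty_map <- function(groups = NULL) {
  if (is.null(groups)) {
    groups <- list(
      dementia = "dementia",
      stroke = "stroke",
      neuro_degenerative = c("parkinsons", "multiple_sclerosis"),
      malnutrition = "malnutrition",
      pressure_ulcer = "pressure_ulcer",
      musculoskeletal_injury = c("fracture", "amputation",
                                 "spinal_cord_injury"),
      heart_failure = "heart_failure",
      seizure = "seizure",
      schizophrenia = "schizophrenia",
      mobility_impairment = "mobility_impairment",
      adl_dependence = "adl_dependence",
      sensory_impairment = "sensory_impairment",
      incontinence = "incontinence")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("frailty map groups must be named")
  }
  all_conds <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_conds)) {
    stop("frailty map groups must be disjoint in contribution")
  }
  structure(groups, class = "frailty_map", max_score = length(groups))
}

#' Compute the frailty-index proxy
#'
#' Counts, per person, the number of frailty groups with at least one
#' qualifying diagnosis among the supplied records (the caller pre-filters
#' records to the intended look-back window and data sources; see
#' [filter_diagnoses()]).
#'
#' @param diagnoses data.frame with columns `person_id`, `condition`.
#' @param map a [frailty_map()].
#' @return data.frame `person_id`, `jfi` (persons with no qualifying
#'   diagnosis among the rows are absent; treat as 0).
#' @export
compute_jfi <- function(diagnoses, map = frailty_map()) {
  known <- c(CONDITIONS, FRAILTY_DOMAIN_CONDITIONS)
  unknown <- setdiff(unique(diagnoses$condition), known)
  if (length(unknown)) {
    warning("ignoring unknown condition code(s): ",
            paste(unknown, collapse = ", "))
  }
  cond2group <- rep(names(map), lengths(map))
  names(cond2group) <- unlist(map, use.names = FALSE)
  g <- cond2group[diagnoses$condition]
  keep <- !is.na(g)
  if (!any(keep)) return(data.frame(person_id = character(), jfi = integer()))
  dt <- data.table::data.table(person_id = diagnoses$person_id[keep],
                               group = g[keep])
  out <- dt[, list(jfi = data.table::uniqueN(group)), by = "person_id"]
  out <- as.data.frame(out)
  out$jfi <- pmin(out$jfi, attr(map, "max_score"))
  out[order(out$person_id), , drop = FALSE]
}

#' Filter diagnosis records to a look-back window and available sources
#'
#' Diagnosis records carry `month`, the number of whole months before the
#' index date in which they were recorded (1 = the month just before the
#' index). Production-mode scoring suppresses non-VA records from the most
#' recent `lag_months` months, emulating claims-data lag.
#'
#' @param diagnoses data.frame with `person_id`, `condition`, `month`,
#'   `source` ("VA"/"Medicare").
#' @param window integer length-2, first and last month (inclusive) of the
#'   look-back.
#' @param va_only keep VA-source records only.
#' @param lag_months suppress non-VA records with `month <= lag_months`.
#' @return filtered data.frame.
#' @export
filter_diagnoses <- function(diagnoses, window = c(1L, 12L), va_only = FALSE,
                             lag_months = 0L) {
  keep <- diagnoses$month >= window[1L] & diagnoses$month <= window[2L]
  if (va_only) {
    keep <- keep & diagnoses$source == "VA"
  } else if (lag_months > 0L) {
    keep <- keep & (diagnoses$source == "VA" | diagnoses$month > lag_months)
  }
  diagnoses[keep, , drop = FALSE]
}

#' Fit the auxiliary one-year death-or-hospitalization model
#'
#' A transparent stand-in for an external one-year death-or-hospitalization
#' risk score: a logistic model of death or any hospitalization within 365
#' days of the index date, trained on a seeded held-out slice of the cohort
#' so downstream scoring is (approximately) out-of-sample.
#'
#' @param cohort a `pli_cohort` (needs `truth` and `stays_outcome`).
#' @param train_frac fraction of persons used for training (default 0.2).
#' @param seed integer seed for the training-slice draw.
#' @return fitted `glm` object with the training design recipe attached.
#' @export
fit_can_model <- function(cohort, train_frac = 0.2, seed = 1L) {
  stopifnot(inherits(cohort, "pli_cohort"))
  idx <- cohort$index_date
  one_year <- idx + 365L
  dd <- as.Date(cohort$truth$death_date)
  died_1y <- !is.na(dd) & dd >= idx & dd < one_year
  so <- cohort$stays_outcome
  hosp_ids <- unique(so$person_id[so$setting == "hospital" &
                                    as.Date(so$start) < one_year])
  y <- died_1y | (cohort$truth$person_id %in% hosp_ids)
  des <- .can_design(cohort)
  stopifnot(identical(des$person_id, cohort$truth$person_id))
  n <- nrow(des)
  train <- withr_seed(seed, sample.int(n, size = max(2L, round(train_frac * n))))
  df <- cbind(des[train, -1L, drop = FALSE], .y = y[train])
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  attr(fit, "can_design") <- TRUE
  fit
}

# small fixed design for the auxiliary risk model
.can_design <- function(cohort) {
  p <- cohort$persons
  dx12 <- filter_diagnoses(cohort$diagnoses, c(1L, 12L))
  jfi <- compute_jfi(dx12)
  j <- jfi$jfi[match(p$person_id, jfi$person_id)]
  j[is.na(j)] <- 0L
  sb <- cohort$stays_baseline
  hosp <- p$person_id %in% unique(sb$person_id[sb$setting == "hospital" &
                                                 as.Date(sb$end) >= cohort$index_date - 365L])
  data.frame(person_id = p$person_id, age = p$age, jfi = j,
             prior_hospitalization = as.integer(hosp))
}

#' Score the auxiliary risk proxy with configurable missingness
#'
#' Applies the auxiliary model to every person, then flags a configurable
#' fraction as missing (emulating a score that is not produced for everyone)
#' and imputes the cohort median for flagged persons, retaining the
#' missingness indicator.
#'
#' @param cohort a `pli_cohort`.
#' @param aux_model a model from [fit_can_model()] (or any object with a
#'   `predict` method returning probabilities for the `.can_design` columns).
#' @param missing_rate fraction of persons flagged missing (default 0.045).
#' @param seed integer seed for the missingness draw.
#' @return data.frame `person_id`, `can` (in \[0,1\]), `can_missing` (0/1).
#' @export
compute_can_proxy <- function(cohort, aux_model, missing_rate = 0.045,
                              seed = 2L) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  des <- .can_design(cohort)
  p <- as.numeric(stats::predict(aux_model, newdata = des, type = "response"))
  n <- length(p)
  miss <- withr_seed(seed, stats::runif(n) < missing_rate)
  med <- stats::median(p[!miss])
  if (!is.finite(med)) med <- stats::median(p)
  can <- ifelse(miss, med, p)
  data.frame(person_id = des$person_id, can = can,
             can_missing = as.integer(miss))
}

#' Monthly Independence-at-Home qualification indicator
#'
#' Pure conjunction over 12-month look-back facts: at least one acute
#' hospitalization AND at least one post-acute skilled-nursing stay AND two
#' or more chronic conditions AND frailty index >= 6. All arguments are
#' vectors over person-months.
#'
#' @param hospitalization logical/0-1, any acute hospitalization in the
#'   look-back.
#' @param post_acute logical/0-1, any post-acute SNF stay in the look-back.
#' @param n_chronic integer count of chronic conditions in the look-back.
#' @param jfi frailty index over the look-back.
#' @param jfi_threshold frailty threshold standing in for the 2+ ADL
#'   criterion (default 6).
#' @return logical vector.
#' @export
monthly_iahq <- function(hospitalization, post_acute, n_chronic, jfi,
                         jfi_threshold = 6L) {
  isTRUE_vec(hospitalization) & isTRUE_vec(post_acute) &
    n_chronic >= 2L & jfi >= jfi_threshold
}

#' Monthly High-Need/High-Risk indicator
#'
#' Requires a hospitalization in the look-back and a VA-data frailty index
#' of at least 5, and excludes persons in (or referred to) hospice or
#' palliative care, persons in home-based primary care or a community living
#' center, and persons with end-stage renal disease.
#'
#' @param hospitalization logical/0-1 any hospitalization in look-back.
#' @param jfi_va frailty index computed from VA-source diagnoses only.
#' @param hospice_or_palliative logical/0-1 exclusion flag.
#' @param hbpc_or_clc logical/0-1 exclusion flag.
#' @param esrd logical/0-1 end-stage renal disease flag.
#' @param jfi_threshold VA-data frailty threshold (default 5).
#' @return logical vector.
#' @export
monthly_hnhr <- function(hospitalization, jfi_va, hospice_or_palliative,
                         hbpc_or_clc, esrd, jfi_threshold = 5L) {
  isTRUE_vec(hospitalization) & jfi_va >= jfi_threshold &
    !isTRUE_vec(hospice_or_palliative) & !isTRUE_vec(hbpc_or_clc) &
    !isTRUE_vec(esrd)
}

#' Assign the elevated-risk / common-risk stratum
#'
#' A person is elevated-risk (ER) if either monthly indicator is true in any
#' baseline month, else common-risk (CR).
#'
#' @param iahq logical matrix or data.frame, persons x months.
#' @param hnhr logical matrix or data.frame, persons x months (same shape).
#' @return character vector, "ER" or "CR" per person.
#' @export
assign_stratum <- function(iahq, hnhr) {
  iahq <- as.matrix(iahq); hnhr <- as.matrix(hnhr)
  stopifnot(identical(dim(iahq), dim(hnhr)))
  any_flag <- rowSums(iahq, na.rm = TRUE) + rowSums(hnhr, na.rm = TRUE) > 0
  ifelse(any_flag, "ER", "CR")
}

#' Race-centered age
#'
#' The residual of a person's age from the mean age of their racial-ethnic
#' group; mitigates differential false-negative rates that arise when the
#' outcome occurs at systematically younger ages in one group.
#'
#' @param age numeric years.
#' @param race_group character group labels.
#' @param group_means optional named numeric vector of group mean ages; when
#'   `NULL`, means are computed over the supplied vectors (the analysis
#'   cohort).
#' @return numeric vector `age - mean(age | race_group)`, with the means
#'   used attached as attribute `group_means`.
#' @export
race_centered_age <- function(age, race_group, group_means = NULL) {
  stopifnot(length(age) == length(race_group))
  race_group <- as.character(race_group)
  if (is.null(group_means)) {
    group_means <- tapply(age, race_group, mean)
    group_means <- stats::setNames(as.numeric(group_means), names(group_means))
  }
  unknown <- setdiff(unique(race_group), names(group_means))
  if (length(unknown)) {
    stop("unknown race group(s): ", paste(unknown, collapse = ", "))
  }
  out <- age - group_means[race_group]
  out <- as.numeric(out)
  attr(out, "group_means") <- group_means
  out
}

# months-before-index of a date vector: month 1 is the calendar month
# ending the day before the index date
month_before_index <- function(dates, index_date, n_months = 24L) {
  bounds <- seq(index_date, by = "-1 month", length.out = n_months + 1L)
  # bounds decreasing; month m covers [bounds[m+1], bounds[m])
  m <- rep(NA_integer_, length(dates))
  d <- as.Date(dates)
  for (k in seq_len(n_months)) {
    hit <- !is.na(d) & d < bounds[k] & d >= bounds[k + 1L]
    m[hit] <- k
  }
  m
}

#' Build model feature rows for the eligible cohort
#'
#' Derives one covariate row per eligible person from the raw tables. In
#' `complete` mode every variable uses a 12-month look-back ending at the
#' index date with full data. In `production` mode the most recent
#' `lag_months` of non-VA records are suppressed (claims lag), the
#' look-back for diagnoses and utilization extends to 24 months, the
#' frailty index is the maximum of the monthly scores over the baseline
#' year, and prior long-term institutionalization is ascertained only in
#' months 13-24 before the index date.
#'
#' @param cohort a `pli_cohort`.
#' @param eligible character vector of eligible person ids (e.g. from
#'   [apply_cohort_exclusions()]); default all persons.
#' @param mode `"complete"` or `"production"`.
#' @param lag_months months of suppressed non-VA data in production mode.
#' @param rule [spell_rule()] for prior-LTI ascertainment.
#' @param can_model auxiliary risk model; fitted via [fit_can_model()] when
#'   `NULL`.
#' @param can_missing_rate,can_seed passed to [compute_can_proxy()].
#' @param map [frailty_map()].
#' @param chronic_conditions condition subset counted as chronic for IAH-Q.
#' @return data.frame of feature rows (one per eligible person) with
#'   demographics, `race_centered_age`, risk scores, prior-utilization
#'   flags, the 18 condition flags, `facility_id`, and `stratum`.
#' @export
build_feature_rows <- function(cohort, eligible = NULL,
                               mode = c("complete", "production"),
                               lag_months = 9L, rule = spell_rule(),
                               can_model = NULL, can_missing_rate = 0.045,
                               can_seed = 2L, map = frailty_map(),
                               chronic_conditions = CHRONIC_CONDITIONS) {
  stopifnot(inherits(cohort, "pli_cohort"))
  mode <- match.arg(mode)
  idx <- cohort$index_date
  persons <- as.data.frame(cohort$persons)
  if (is.null(eligible)) eligible <- persons$person_id
  persons <- persons[persons$person_id %in% eligible, , drop = FALSE]
  persons <- persons[order(persons$person_id), , drop = FALSE]
  if (any(is.na(persons$age) | persons$age < 0)) {
    stop("impossible ages for person(s): ",
         paste(utils::head(persons$person_id[is.na(persons$age) | persons$age < 0], 5L),
               collapse = ", "))
  }
  ids <- persons$person_id
  n <- length(ids)
  lag <- if (mode == "production") as.integer(lag_months) else 0L
  dx_window <- if (mode == "production") c(1L, 24L) else c(1L, 12L)

  dx <- cohort$diagnoses
  dx <- dx[dx$person_id %in% ids, , drop = FALSE]
  sb <- validate_stays(cohort$stays_baseline)
  sb <- sb[sb$person_id %in% ids, , drop = FALSE]
  sb$month_start <- month_before_index(sb$start, idx)
  sb$month_end <- month_before_index(sb$end, idx)
  # stays can straddle month boundaries / the window edge; a stay occupies
  # months month_end .. month_start (month_end may be NA if end >= index)
  sb$m_lo <- ifelse(is.na(sb$month_end), 1L, sb$month_end)
  sb$m_hi <- ifelse(is.na(sb$month_start), 24L, sb$month_start)

  stay_in <- function(setting, w_lo, w_hi, payer = NULL, suppress_lag = lag) {
    k <- sb$setting %in% setting & sb$m_lo <= w_hi & sb$m_hi >= w_lo
    if (!is.null(payer)) k <- k & sb$payer %in% payer
    if (suppress_lag > 0L) {
      k <- k & (sb$payer == "VA" | sb$m_lo > suppress_lag)
    }
    ids %in% unique(sb$person_id[k])
  }

  # condition flags over the mode's window
  dx_avail <- filter_diagnoses(dx, dx_window, va_only = FALSE, lag_months = lag)
  cond_flags <- matrix(0L, n, length(CONDITIONS),
                       dimnames = list(NULL, CONDITIONS))
  if (nrow(dx_avail)) {
    dtc <- unique(data.table::data.table(person_id = dx_avail$person_id,
                                         condition = dx_avail$condition))
    dtc <- dtc[dtc$condition %in% CONDITIONS, ]
    if (nrow(dtc)) {
      i <- match(dtc$person_id, ids)
      j <- match(dtc$condition, CONDITIONS)
      cond_flags[cbind(i, j)] <- 1L
    }
  }

  jfi_window <- function(w_lo, w_hi, va_only) {
    d <- filter_diagnoses(dx, c(w_lo, w_hi), va_only = va_only,
                          lag_months = lag)
    sc <- suppressWarnings(compute_jfi(d, map))
    out <- sc$jfi[match(ids, sc$person_id)]
    out[is.na(out)] <- 0L
    out
  }
  chronic_window <- function(w_lo, w_hi) {
    d <- filter_diagnoses(dx, c(w_lo, w_hi), lag_months = lag)
    d <- d[d$condition %in% chronic_conditions, , drop = FALSE]
    if (!nrow(d)) return(integer(n))
    dtc <- unique(data.table::data.table(person_id = d$person_id,
                                         condition = d$condition))
    cnt <- dtc[, list(k = .N), by = "person_id"]
    out <- cnt$k[match(ids, cnt$person_id)]
    out[is.na(out)] <- 0L
    out
  }

  # headline frailty index
  if (mode == "complete") {
    jfi <- jfi_window(1L, 12L, va_only = FALSE)
  } else {
    jfi <- integer(n)
    for (m in 1:12) jfi <- pmax(jfi, jfi_window(m, m + 11L, va_only = FALSE))
  }

  # monthly ER/CR indicator inputs over the 12 baseline months
  iahq_m <- matrix(FALSE, n, 12L)
  hnhr_m <- matrix(FALSE, n, 12L)
  hosp_excl <- isTRUE_vec(persons$palliative) |
    stay_in("hospice", 1L, 24L, suppress_lag = 0L)
  hbpc <- isTRUE_vec(persons$hbpc)
  esrd <- isTRUE_vec(persons$esrd)
  for (m in 1:12) {
    hosp_m <- stay_in("hospital", m, m + 11L)
    snf_m <- stay_in("NH", m, m + 11L)
    nchr_m <- chronic_window(m, m + 11L)
    jfi_all_m <- jfi_window(m, m + 11L, va_only = FALSE)
    jfi_va_m <- jfi_window(m, m + 11L, va_only = TRUE)
    iahq_m[, m] <- monthly_iahq(hosp_m, snf_m, nchr_m, jfi_all_m)
    hnhr_m[, m] <- monthly_hnhr(hosp_m, jfi_va_m, hosp_excl, hbpc, esrd)
  }
  stratum <- assign_stratum(iahq_m, hnhr_m)

  # prior utilization
  prior_hosp <- stay_in("hospital", 1L, if (mode == "production") 24L else 12L)
  prior_snf <- stay_in("NH", 13L, 24L, payer = "Medicare", suppress_lag = 0L)
  lti_range <- if (mode == "production") c(idx - 730L, idx - 366L) else
    c(idx - 365L, idx - 1L)
  sp <- detect_lti_cohort(sb[sb$end >= lti_range[1L] & sb$start <= lti_range[2L], ,
                             drop = FALSE],
                          lti_range, rule)
  prior_lti <- ids %in% unique(sp$person_id[sp$qualifying])

  if (is.null(can_model)) can_model <- fit_can_model(cohort, seed = can_seed)
  can <- compute_can_proxy(cohort, can_model, missing_rate = can_missing_rate,
                           seed = can_seed)
  can <- can[match(ids, can$person_id), , drop = FALSE]

  out <- data.frame(
    person_id = ids,
    facility_id = persons$facility_id,
    race_group = persons$race_group,
    age = persons$age,
    race_centered_age = race_centered_age(persons$age, persons$race_group),
    male = as.integer(isTRUE_vec(persons$male)),
    married = as.integer(isTRUE_vec(persons$married)),
    rural = as.integer(isTRUE_vec(persons$rural)),
    priority_group_1 = as.integer(isTRUE_vec(persons$priority_group_1)),
    homeless = as.integer(isTRUE_vec(persons$homeless)),
    jfi = jfi,
    can = can$can,
    can_missing = can$can_missing,
    prior_hospitalization = as.integer(prior_hosp),
    prior_snf = as.integer(prior_snf),
    prior_lti = as.integer(prior_lti),
    prior_cost = persons$baseline_cost / 1e4,
    stratum = stratum,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cond_flags))
  rownames(out) <- NULL
  out
}

#' Default model covariate names
#'
#' The covariates entered into the stratum models (demographics with
#' race-centered age, risk scores, prior utilization, cost in $10,000
#' units, and the 18 condition flags).
#' @return character vector of column names in feature rows.
#' @export
model_covariates <- function() {
  c("race_centered_age", "male", "married", "rural", "priority_group_1",
    "homeless", "jfi", "can", "can_missing", "prior_hospitalization",
    "prior_snf", "prior_lti", "prior_cost", CONDITIONS)
}

# evaluate `expr` under a temporary seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
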