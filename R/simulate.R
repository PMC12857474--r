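# Synthetic claims cohort generator: demographics, monthly diagnosis
# records, baseline-year stays (with exclusion-triggering patterns),
# outcome-period trajectories (death, nursing-home spells,
# hospitalizations), and known ground-truth LTI risk.

abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("pli_config_error", "error",
                                             "condition")))
}

#' Simulation configuration
#'
#' Defaults emulate a large community-dwelling veteran population: a rare
#' two-year LTI outcome (about 1.1% overall), non-LTI deaths outnumbering
#' LTI events about 5:1, an elevated-need subpopulation (about 9% of the
#' cohort once the IAH-Q/HNHR rules are applied) with much higher condition
#' prevalence, and LTI entry occurring at younger ages in the comparison
#' race group.
#'
#' @param n_persons cohort size (>= 1).
#' @param seed integer RNG seed; identical configs are byte-reproducible.
#' @param index_date prediction index date (fiscal-year start).
#' @param race_mix named proportions over race groups (sums to 1).
#' @param age_dist_by_race named list of `c(mean, sd)` in years per group.
#' @param lti_age_shift_by_race named years by which LTI entry is shifted
#'   younger per group (added to age inside the true risk model).
#' @param high_need_frac latent elevated-need class fraction.
#' @param lti_target named true LTI rates `c(high, common)` for the latent
#'   classes (defaults chosen so the overall rate is about 1.1%).
#' @param nonlti_death_ratio target ratio of non-LTI deaths to LTI events.
#' @param death_rate_lti death probability among LTI persons.
#' @param condition_prevalence data.frame `condition`, `base_rate`,
#'   `er_multiplier` for conditions drawn independently of the frailty
#'   count (rates in \[0,1\]).
#' @param frailty_count named list of `c(mean, sd)` for the latent frailty
#'   domain count per class.
#' @param true_coefficients named list (`high`, `common`) of named
#'   coefficient vectors for the latent LTI model (names: `age`, `jfi`,
#'   `prior_hospitalization`, `prior_snf`, `prior_lti`, `dementia`,
#'   `stroke`); intercepts are calibrated to `lti_target`.
#' @param n_facilities number of parent facilities.
#' @param lag_months months of most-recent non-VA data suppressed by the
#'   production-mode feature builder.
#' @param exclusion_rates named rates for baseline hospice, missing
#'   face-to-face care, baseline death, and inpatient-on-last-day patterns.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 20000L, seed = 1L,
                       index_date = as.Date("2017-10-01"),
                       race_mix = c(White = 0.8, Black = 0.2),
                       age_dist_by_race = list(White = c(mean = 62, sd = 16),
                                               Black = c(mean = 56, sd = 14)),
                       lti_age_shift_by_race = c(White = 0, Black = 6),
                       high_need_frac = 0.14,
                       lti_target = c(high = 0.05, common = 0.0047),
                       nonlti_death_ratio = 5,
                       death_rate_lti = 0.30,
                       condition_prevalence = NULL,
                       frailty_count = list(high = c(mean = 7.8, sd = 1.66),
                                            common = c(mean = 2.9, sd = 1.89)),
                       true_coefficients = NULL,
                       n_facilities = 15L,
                       lag_months = 9L,
                       exclusion_rates = c(hospice = 0.008,
                                           no_face_to_face = 0.035,
                                           died_baseline = 0.024,
                                           inpatient_last_day = 0.02)) {
  n_persons <- as.integer(n_persons)
  if (is.na(n_persons) || n_persons < 1L) abort_config("n_persons must be >= 1")
  if (as.integer(lag_months) < 0L) abort_config("lag_months must be >= 0")
  if (abs(sum(race_mix) - 1) > 1e-8) abort_config("race_mix must sum to 1")
  if (any(race_mix < 0)) abort_config("race_mix proportions must be >= 0")
  if (length(race_mix) < 2L) abort_config("need at least two race groups")
  if (!all(names(race_mix) %in% names(age_dist_by_race))) {
    abort_config("age_dist_by_race must cover every race group")
  }
  if (!all(names(race_mix) %in% names(lti_age_shift_by_race))) {
    abort_config("lti_age_shift_by_race must cover every race group")
  }
  if (is.null(condition_prevalence)) {
    condition_prevalence <- data.frame(
      condition = c("cancer", "diabetes", "head_injury", "obesity",
                    "substance_use_disorder", "sepsis"),
      base_rate = c(0.081, 0.248, 0.038, 0.159, 0.089, 0.0042),
      er_multiplier = c(3.2, 2.0, 1.34, 1.78, 2.1, 30))
  }
  if (any(condition_prevalence$base_rate < 0 |
          condition_prevalence$base_rate > 1)) {
    abort_config("condition base rates must be in [0, 1]")
  }
  if (any(pmin(1, condition_prevalence$base_rate *
                 condition_prevalence$er_multiplier) < 0)) {
    abort_config("elevated-risk rates must be non-negative")
  }
  if (is.null(true_coefficients)) {
    true_coefficients <- list(
      high = c(age = 0.045, jfi = 0.18, prior_hospitalization = 0.25,
               prior_snf = 0.6, prior_lti = 1.0, dementia = 0.8,
               stroke = 0.3),
      common = c(age = 0.06, jfi = 0.30, prior_hospitalization = 0.6,
                 prior_snf = 1.2, prior_lti = 1.3, dementia = 1.2,
                 stroke = 0.5))
  }
  if (any(lti_target <= 0 | lti_target >= 1)) {
    abort_config("lti_target rates must be in (0, 1)")
  }
  if (nonlti_death_ratio < 0) abort_config("nonlti_death_ratio must be >= 0")
  structure(list(
    n_persons = n_persons, seed = as.integer(seed),
    index_date = as.Date(index_date), race_mix = race_mix,
    age_dist_by_race = age_dist_by_race,
    lti_age_shift_by_race = lti_age_shift_by_race,
    high_need_frac = high_need_frac, lti_target = lti_target,
    nonlti_death_ratio = nonlti_death_ratio,
    death_rate_lti = death_rate_lti,
    condition_prevalence = condition_prevalence,
    frailty_count = frailty_count,
    true_coefficients = true_coefficients,
    n_facilities = as.integer(n_facilities),
    lag_months = as.integer(lag_months),
    exclusion_rates = exclusion_rates),
    class = "sim_config")
}

# frailty-domain draw weights (relative pattern: common custodial-risk
# domains heavier) and sub-members of composite domains
.frailty_domains <- data.frame(
  domain = c("dementia", "stroke", "neuro_degenerative", "malnutrition",
             "pressure_ulcer", "musculoskeletal_injury", "heart_failure",
             "seizure", "schizophrenia", "mobility_impairment",
             "adl_dependence", "sensory_impairment", "incontinence"),
  weight = c(0.15, 0.15, 0.05, 0.07, 0.12, 0.12, 0.34, 0.07, 0.035,
             0.30, 0.28, 0.22, 0.18))

.domain_member <- function(domain, n) {
  # pick a concrete diagnosis for composite domains
  switch(domain,
    neuro_degenerative = ifelse(stats::runif(n) < 0.83, "parkinsons",
                                "multiple_sclerosis"),
    musculoskeletal_injury = sample(c("fracture", "amputation",
                                      "spinal_cord_injury"), n, TRUE),
    rep(domain, n))
}

.rint <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1L))

# diagnosis records for present conditions: onset month uniform in 1..24,
# re-coded quarterly from onset toward the index; per-record source VA or
# Medicare according to the person's predominant payer
.make_dx_records <- function(person_id, condition, medicare_user) {
  n <- length(person_id)
  if (!n) {
    return(data.frame(person_id = character(), condition = character(),
                      month = integer(), source = character()))
  }
  onset <- .rint(n, 1L, 24L)
  n_rec <- (onset - 1L) %/% 3L + 1L
  i <- rep.int(seq_len(n), n_rec)
  rec_k <- sequence(n_rec) - 1L
  month <- onset[i] - 3L * rec_k
  p_medicare <- ifelse(medicare_user[i], 0.7, 0.15)
  source <- ifelse(stats::runif(length(i)) < p_medicare, "Medicare", "VA")
  data.frame(person_id = person_id[i], condition = condition[i],
             month = month, source = source, stringsAsFactors = FALSE)
}

.make_stays <- function(person_id, setting, start, len, payer,
                        face_to_face = FALSE) {
  if (!length(person_id)) {
    return(data.frame(person_id = character(), setting = character(),
                      start = as.Date(character()), end = as.Date(character()),
                      payer = character(), face_to_face = logical()))
  }
  data.frame(person_id = person_id, setting = setting,
             start = start, end = start + pmax(0L, len - 1L),
             payer = payer, face_to_face = face_to_face,
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic veteran cohort
#'
#' Deterministic given the config (including its seed). Persons are drawn
#' with a latent elevated-need class driving condition prevalence, frailty,
#' utilization, and baseline cost; the true two-year LTI probability is a
#' class-specific logistic model whose intercept is calibrated so realized
#' rates match the configured targets; deaths are drawn so non-LTI deaths
#' outnumber LTI events by the configured ratio; and outcome-period stay
#' records are constructed so the spell detector reproduces the realized
#' LTI indicator exactly (LTI persons receive qualifying nursing-home
#' sequences with randomized hospital interludes and short community gaps;
#' non-LTI persons at most short post-acute stays).
#'
#' @param config a [sim_config()].
#' @return object of class `pli_cohort`: list of `persons`, `diagnoses`,
#'   `stays_baseline`, `stays_outcome`, `truth`, plus `index_date` and the
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_persons
  idx <- cfg$index_date
  ids <- sprintf("p%07d", seq_len(n))

  race <- sample(names(cfg$race_mix), n, TRUE, prob = cfg$race_mix)
  age <- numeric(n)
  for (g in names(cfg$race_mix)) {
    i <- race == g
    pars <- cfg$age_dist_by_race[[g]]
    age[i] <- stats::rnorm(sum(i), pars[["mean"]], pars[["sd"]])
  }
  age <- pmin(pmax(age, 21), 100)
  high <- stats::runif(n) < cfg$high_need_frac

  bprob <- function(p_high, p_common) ifelse(high, p_high, p_common)
  male <- stats::runif(n) < bprob(0.953, 0.912)
  married <- stats::runif(n) < bprob(0.616, 0.691)
  rural <- stats::runif(n) < bprob(0.252, 0.333)
  pg1 <- stats::runif(n) < bprob(0.427, 0.437)
  homeless <- stats::runif(n) < bprob(0.048, 0.025)
  esrd <- stats::runif(n) < bprob(0.03, 0.004)
  palliative <- stats::runif(n) < bprob(0.015, 0.001)
  hbpc <- stats::runif(n) < bprob(0.03, 0.002)
  medicare_user <- stats::runif(n) < ifelse(age >= 65, 0.8, 0.2)
  # facility sizes roughly power-law
  fac_w <- 1 / seq_len(cfg$n_facilities)
  facility <- sprintf("F%02d", sample.int(cfg$n_facilities, n, TRUE,
                                          prob = fac_w / sum(fac_w)))
  baseline_cost <- stats::rlnorm(n,
                                 meanlog = ifelse(high, log(38410), log(7610)) - 0.5,
                                 sdlog = 1)

  # frailty domains: latent count K per class, realized as independent
  # domain draws with probabilities proportional to the domain weights
  fc <- cfg$frailty_count
  K <- ifelse(high,
              stats::rnorm(n, fc$high[["mean"]], fc$high[["sd"]]),
              stats::rnorm(n, fc$common[["mean"]], fc$common[["sd"]]))
  K <- pmin(pmax(round(K), 0L), nrow(.frailty_domains))
  w <- .frailty_domains$weight / sum(.frailty_domains$weight)
  dom_p <- pmin(outer(K, w), 0.97)  # n x 13
  dom_hit <- matrix(stats::runif(length(dom_p)), nrow(dom_p)) < dom_p
  colnames(dom_hit) <- .frailty_domains$domain
  jfi_true <- rowSums(dom_hit)

  dx_parts <- list()
  for (d in .frailty_domains$domain) {
    i <- which(dom_hit[, d])
    if (!length(i)) next
    dx_parts[[d]] <- .make_dx_records(ids[i], .domain_member(d, length(i)),
                                      medicare_user[i])
  }
  cond_present <- matrix(FALSE, n, length(CONDITIONS),
                         dimnames = list(NULL, CONDITIONS))
  # conditions implied by frailty domains
  for (d in names(dx_parts)) {
    recs <- dx_parts[[d]]
    firsts <- !duplicated(recs$person_id)
    ii <- match(recs$person_id[firsts], ids)
    jj <- match(recs$condition[firsts], CONDITIONS)
    ok <- !is.na(jj)
    cond_present[cbind(ii[ok], jj[ok])] <- TRUE
  }
  # independent conditions patterned on published prevalence contrasts
  cp <- cfg$condition_prevalence
  for (k in seq_len(nrow(cp))) {
    p <- ifelse(high, pmin(cp$base_rate[k] * cp$er_multiplier[k], 0.95),
                cp$base_rate[k])
    hit <- stats::runif(n) < p
    cond_present[, cp$condition[k]] <- cond_present[, cp$condition[k]] | hit
    i <- which(hit)
    if (length(i)) {
      dx_parts[[cp$condition[k]]] <-
        .make_dx_records(ids[i], rep(cp$condition[k], length(i)),
                         medicare_user[i])
    }
  }
  diagnoses <- do.call(rbind, dx_parts)
  rownames(diagnoses) <- NULL

  ## ---- baseline stays -------------------------------------------------
  b_start <- idx - 365L      # baseline year start
  b2_start <- idx - 730L     # extended look-back start
  sb <- list()
  ex <- cfg$exclusion_rates

  # face-to-face encounters for everyone except a small fraction
  has_ftf <- stats::runif(n) >= ex[["no_face_to_face"]]
  i <- which(has_ftf)
  n_enc <- .rint(length(i), 1L, 3L)
  j <- rep.int(i, n_enc)
  sb$enc <- .make_stays(ids[j], "encounter",
                        b_start + .rint(length(j), 0L, 364L), 1L, "VA", TRUE)

  # FY-recent hospitalizations (months 1-12)
  hosp <- stats::runif(n) < bprob(0.683, 0.047)
  i <- which(hosp)
  n_h <- .rint(length(i), 1L, 2L)
  j <- rep.int(i, n_h)
  sb$hosp <- .make_stays(ids[j], "hospital",
                         b_start + .rint(length(j), 0L, 350L),
                         .rint(length(j), 2L, 10L),
                         ifelse(stats::runif(length(j)) < 0.7, "VA", "Medicare"))

  # earlier-year hospitalizations (months 13-24)
  hosp2 <- stats::runif(n) < bprob(0.5, 0.04)
  i <- which(hosp2)
  sb$hosp2 <- .make_stays(ids[i], "hospital",
                          b2_start + .rint(length(i), 0L, 350L),
                          .rint(length(i), 2L, 9L),
                          ifelse(stats::runif(length(i)) < 0.7, "VA", "Medicare"))

  # Medicare-paid SNF in months 13-24 (the prior-SNF covariate)
  snf_prior <- stats::runif(n) < bprob(0.18, 0.006)
  i <- which(snf_prior)
  sb$snf_prior <- .make_stays(ids[i], "NH",
                              b2_start + .rint(length(i), 0L, 320L),
                              .rint(length(i), 15L, 40L), "Medicare")

  # recent post-acute SNF following a hospitalization (drives IAH-Q)
  snf_recent <- hosp & (stats::runif(n) < bprob(0.5, 0.08))
  i <- which(snf_recent)
  sb$snf_recent <- .make_stays(ids[i], "NH",
                               b_start + .rint(length(i), 0L, 300L),
                               .rint(length(i), 10L, 30L), "Medicare")

  # qualifying LTI spell wholly inside months 13-24 (prior-LTI covariate);
  # ends well before the baseline year so it triggers no exclusion
  prior_lti <- stats::runif(n) < bprob(0.012, 0.0008)
  i <- which(prior_lti)
  sb$prior_lti <- .make_stays(ids[i], "NH",
                              b2_start + .rint(length(i), 0L, 100L),
                              .rint(length(i), 101L, 150L), "Medicare")

  # exclusion-triggering patterns
  hospice_b <- stats::runif(n) < ex[["hospice"]]
  i <- which(hospice_b)
  sb$hospice <- .make_stays(ids[i], "hospice",
                            b_start + .rint(length(i), 0L, 330L),
                            .rint(length(i), 5L, 30L), "VA")
  inpat_last <- stats::runif(n) < ex[["inpatient_last_day"]]
  i <- which(inpat_last)
  sb$last_day <- .make_stays(ids[i],
                             ifelse(stats::runif(length(i)) < 0.5, "hospital", "NH"),
                             idx - .rint(length(i), 1L, 10L), 30L,
                             "VA")
  died_base <- stats::runif(n) < ex[["died_baseline"]]
  death_base_date <- rep(as.Date(NA), n)
  death_base_date[died_base] <- b_start + .rint(sum(died_base), 0L, 364L)

  stays_baseline <- do.call(rbind, sb)
  rownames(stays_baseline) <- NULL

  ## ---- true LTI probability and realized outcome ----------------------
  shift <- cfg$lti_age_shift_by_race[race]
  eff_age <- age + shift
  lin <- function(sel, b) {
    b[["age"]] * (eff_age[sel] - 65) + b[["jfi"]] * jfi_true[sel] +
      b[["prior_hospitalization"]] * hosp[sel] +
      b[["prior_snf"]] * snf_prior[sel] + b[["prior_lti"]] * prior_lti[sel] +
      b[["dementia"]] * cond_present[sel, "dementia"] +
      b[["stroke"]] * cond_present[sel, "stroke"]
  }
  p_lti <- numeric(n)
  for (cl in c("high", "common")) {
    sel <- if (cl == "high") which(high) else which(!high)
    eta <- lin(sel, cfg$true_coefficients[[cl]])
    target <- cfg$lti_target[[cl]]
    c0 <- tryCatch(stats::uniroot(function(cc) mean(stats::plogis(eta + cc)) - target,
                                  interval = c(-30, 10), tol = 1e-10)$root,
                   error = function(e) stats::qlogis(target) - mean(eta))
    p_lti[sel] <- stats::plogis(eta + c0)
  }
  lti <- stats::runif(n) < p_lti
  lti[died_base] <- FALSE   # no outcome events after a baseline death

  ## ---- deaths in the outcome window -----------------------------------
  n_lti <- sum(lti)
  death <- rep(FALSE, n)
  death[lti] <- stats::runif(n_lti) < cfg$death_rate_lti
  nonlti <- which(!lti & !died_base)
  target_deaths <- cfg$nonlti_death_ratio * n_lti
  if (length(nonlti) && target_deaths > 0) {
    eta_d <- 0.06 * (age[nonlti] - 70) + 0.12 * jfi_true[nonlti]
    d0 <- tryCatch(stats::uniroot(function(cc)
      sum(stats::plogis(eta_d + cc)) - target_deaths,
      interval = c(-30, 10), tol = 1e-8)$root,
      error = function(e) -30)
    death[nonlti] <- stats::runif(length(nonlti)) < stats::plogis(eta_d + d0)
  }

  ## ---- outcome stays ---------------------------------------------------
  so <- list()
  death_date <- rep(as.Date(NA), n)

  # LTI persons: a qualifying spell starting inside the two-year window,
  # with randomized interruption patterns exercising the detector
  i_lti <- which(lti)
  if (length(i_lti)) {
    m <- length(i_lti)
    s_off <- .rint(m, 0L, 600L)
    s_date <- idx + s_off
    L <- 91L + stats::rpois(m, 45L)          # total NH days, always > 90
    pat <- sample(c("single", "hosp", "gap"), m, TRUE, prob = c(.5, .3, .2))
    a <- pmin(.rint(m, 30L, 60L), L - 1L)    # first-segment NH days
    gap_h <- .rint(m, 2L, 10L)               # hospital interlude length
    gap_c <- .rint(m, 1L, 7L)                # community gap (never > 7)
    seg <- list()
    sgl <- pat == "single"
    seg$a <- .make_stays(ids[i_lti][sgl], "NH", s_date[sgl], L[sgl],
                         ifelse(stats::runif(sum(sgl)) < 0.5, "VA", "Medicare"))
    hs <- pat == "hosp"
    seg$b1 <- .make_stays(ids[i_lti][hs], "NH", s_date[hs], a[hs], "VA")
    seg$b2 <- .make_stays(ids[i_lti][hs], "hospital", s_date[hs] + a[hs],
                          gap_h[hs], "VA")
    seg$b3 <- .make_stays(ids[i_lti][hs], "NH",
                          s_date[hs] + a[hs] + gap_h[hs],
                          L[hs] - a[hs], "Medicare")
    gp <- pat == "gap"
    seg$c1 <- .make_stays(ids[i_lti][gp], "NH", s_date[gp], a[gp], "VA")
    seg$c2 <- .make_stays(ids[i_lti][gp], "NH",
                          s_date[gp] + a[gp] + gap_c[gp],
                          L[gp] - a[gp], "VA")
    so$lti <- do.call(rbind, seg)
    # spell end date per person, for death placement
    spell_len <- ifelse(pat == "single", L,
                 ifelse(pat == "hosp", L + gap_h, L + gap_c))
    d_l <- death[i_lti]
    death_date[i_lti[d_l]] <- s_date[d_l] + spell_len[d_l] +
      stats::rpois(sum(d_l), 40L)
  }

  # non-LTI persons: hospitalizations and short post-acute SNF stays
  i_non <- which(!lti & !died_base)
  if (length(i_non)) {
    d_n <- death[i_non]
    dd <- idx + .rint(sum(d_n), 30L, 729L)
    death_date[i_non[d_n]] <- dd
    horizon <- rep(idx + 729L, length(i_non))
    horizon[d_n] <- dd - 1L
    span <- pmax(as.integer(horizon - idx), 1L)

    h_o <- stats::runif(length(i_non)) < bprob(0.45, 0.07)[i_non]
    j <- which(h_o)
    so$hosp <- .make_stays(ids[i_non][j], "hospital",
                           idx + (.rint(length(j), 0L, 10000L) %% span[j]),
                           .rint(length(j), 2L, 9L), "VA")
    s_o <- stats::runif(length(i_non)) < bprob(0.12, 0.008)[i_non]
    j <- which(s_o & span > 50L)
    so$snf <- .make_stays(ids[i_non][j], "NH",
                          idx + (.rint(length(j), 0L, 10000L) %% pmax(span[j] - 46L, 1L)),
                          .rint(length(j), 10L, 45L), "Medicare")
    # clip at death so no event follows the death date
    for (nm in c("hosp", "snf")) {
      if (is.null(so[[nm]])) next
      hz <- horizon[match(so[[nm]]$person_id, ids[i_non])]
      so[[nm]]$end <- pmin(so[[nm]]$end, hz)
      so[[nm]] <- so[[nm]][so[[nm]]$start <= so[[nm]]$end, , drop = FALSE]
    }
  }
  stays_outcome <- do.call(rbind, so)
  if (is.null(stays_outcome)) {
    stays_outcome <- .make_stays(character(), character(), as.Date(character()),
                                 integer(), character())
  }
  rownames(stays_outcome) <- NULL

  death_date[died_base] <- death_base_date[died_base]

  # secondary outcomes for tier tables: outcome-year cost and service use
  cost_outcome <- stats::rlnorm(n, meanlog = log(6000) - 0.5 +
                                  1.1 * high + 18 * p_lti, sdlog = 0.9)
  nic_use <- stats::runif(n) < stats::plogis(-3.6 + 1.8 * high + 25 * p_lti)
  pcs_use <- stats::runif(n) < stats::plogis(-4.4 + 1.6 * high + 22 * p_lti)

  persons <- data.frame(
    person_id = ids, age = age, male = as.integer(male), race_group = race,
    married = as.integer(married), rural = as.integer(rural),
    priority_group_1 = as.integer(pg1), homeless = as.integer(homeless),
    esrd = as.integer(esrd), palliative = as.integer(palliative),
    hbpc = as.integer(hbpc), facility_id = facility,
    baseline_cost = baseline_cost, stringsAsFactors = FALSE)
  truth <- data.frame(
    person_id = ids, high_need = as.integer(high), p_lti = p_lti,
    lti = as.integer(lti), death_date = death_date,
    cost_outcome = cost_outcome, nic_use = as.integer(nic_use),
    pcs_use = as.integer(pcs_use), stringsAsFactors = FALSE)

  structure(list(persons = persons, diagnoses = diagnoses,
                 stays_baseline = stays_baseline,
                 stays_outcome = stays_outcome, truth = truth,
                 index_date = idx, config = cfg),
            class = "pli_cohort")
}

#' @export
print.pli_cohort <- function(x, ...) {
  cat(sprintf(
    "<pli_cohort> %d persons, index %s | LTI %.2f%%, deaths %.2f%%\n",
    nrow(x$persons), format(x$index_date),
    100 * mean(x$truth$lti), 100 * mean(!is.na(x$truth$death_date))))
  invisible(x)
}

#' Write a cohort to CSV tables
#'
#' Writes the five cohort tables (`persons`, `diagnoses`, `stays_baseline`,
#' `stays_outcome`, `truth`) plus a `manifest.csv` with row counts and a
#' `config.yaml`; round-trips losslessly through [read_cohort()].
#'
#' @param cohort a `pli_cohort`.
#' @param directory output directory (created if absent).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "pli_cohort"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  tables <- c("persons", "diagnoses", "stays_baseline", "stays_outcome",
              "truth")
  manifest <- data.frame(table = tables,
                         file = paste0(tables, ".csv"),
                         rows = vapply(cohort[tables], nrow, integer(1L)))
  for (tb in tables) {
    ok <- tryCatch({
      data.table::fwrite(cohort[[tb]], file.path(directory, paste0(tb, ".csv")))
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop("failed writing table '", tb, "' to ",
           file.path(directory, paste0(tb, ".csv")), ": ",
           conditionMessage(ok))
    }
  }
  data.table::fwrite(manifest, file.path(directory, "manifest.csv"))
  cfg <- cohort$config
  cfg$index_date <- format(cfg$index_date)
  cfg$condition_prevalence <- as.list(cfg$condition_prevalence)
  yaml::write_yaml(lapply(unclass(cfg), function(v)
    if (is.numeric(v) || is.character(v)) as.list(v) else v),
    file.path(directory, "config.yaml"))
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  rd <- function(f, date_cols = character()) {
    x <- as.data.frame(data.table::fread(file.path(directory, f)))
    for (dc in intersect(date_cols, names(x))) x[[dc]] <- as.Date(x[[dc]])
    x
  }
  persons <- rd("persons.csv")
  diagnoses <- rd("diagnoses.csv")
  stays_baseline <- rd("stays_baseline.csv", c("start", "end"))
  stays_outcome <- rd("stays_outcome.csv", c("start", "end"))
  truth <- rd("truth.csv", "death_date")
  if (nrow(truth) && !inherits(truth$death_date, "Date")) {
    truth$death_date <- as.Date(truth$death_date)
  }
  cfg <- yaml::read_yaml(file.path(directory, "config.yaml"))
  index_date <- as.Date(unlist(cfg$index_date))
  structure(list(persons = persons, diagnoses = diagnoses,
                 stays_baseline = stays_baseline,
                 stays_outcome = stays_outcome, truth = truth,
                 index_date = index_date, config = cfg),
            class = "pli_cohort")
}
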