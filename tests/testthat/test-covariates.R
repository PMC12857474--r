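# Frailty index, risk-proxy, monthly indicators, stratum assignment,
# race-centered age, and the feature-row builder.

dx_row <- function(id, condition, month = 1L, source = "VA") {
  data.frame(person_id = id, condition = condition, month = month,
             source = source, stringsAsFactors = FALSE)
}

test_that("frailty index counts condition groups, saturating at the map size", {
  empty <- data.frame(person_id = character(), condition = character(),
                      month = integer(), source = character())
  expect_equal(nrow(compute_jfi(empty)), 0L)
  # three conditions in three distinct groups
  d <- rbind(dx_row("a", "dementia"), dx_row("a", "stroke"),
             dx_row("a", "malnutrition"))
  expect_equal(compute_jfi(d)$jfi, 3L)
  # repeated and same-group diagnoses add nothing
  d2 <- rbind(d, dx_row("a", "dementia", month = 5L),
              dx_row("a", "parkinsons"), dx_row("a", "multiple_sclerosis"))
  expect_equal(compute_jfi(d2)$jfi, 4L)
  # every group present saturates at max_score
  map <- frailty_map()
  all_groups <- vapply(map, `[`, character(1L), 1L)
  d3 <- do.call(rbind, lapply(all_groups, dx_row, id = "a"))
  expect_equal(compute_jfi(d3)$jfi, attr(map, "max_score"))
  expect_warning(compute_jfi(dx_row("a", "gout")), "unknown condition")
  expect_error(frailty_map(list(g1 = "dementia", g2 = "dementia")),
               "disjoint")
})

test_that("diagnosis filtering respects window, source, and claims lag", {
  d <- rbind(dx_row("a", "dementia", 2L, "Medicare"),
             dx_row("a", "stroke", 8L, "VA"),
             dx_row("a", "cancer", 14L, "Medicare"))
  expect_equal(nrow(filter_diagnoses(d, c(1L, 12L))), 2L)
  expect_equal(filter_diagnoses(d, c(1L, 12L), va_only = TRUE)$condition,
               "stroke")
  # a 6-month lag hides the recent Medicare record but not the VA one
  got <- filter_diagnoses(d, c(1L, 24L), lag_months = 6L)
  expect_setequal(got$condition, c("stroke", "cancer"))
})

test_that("IAH-Q is the stated four-way conjunction", {
  expect_true(monthly_iahq(1, 1, 3L, 6L))
  expect_false(monthly_iahq(1, 1, 3L, 5L))   # frailty below threshold
  expect_false(monthly_iahq(0, 1, 3L, 8L))   # no hospitalization
  expect_false(monthly_iahq(1, 0, 3L, 8L))   # SNF without hospitalization
  expect_false(monthly_iahq(1, 1, 1L, 8L))   # fewer than 2 chronic conditions
})

test_that("HNHR requires hospitalization and VA frailty, minus exclusions", {
  expect_true(monthly_hnhr(1, 5L, 0, 0, 0))
  expect_false(monthly_hnhr(1, 5L, 0, 0, 1))  # ESRD excluded
  expect_false(monthly_hnhr(1, 5L, 1, 0, 0))  # hospice/palliative excluded
  expect_false(monthly_hnhr(1, 5L, 0, 1, 0))  # HBPC/CLC excluded
  expect_false(monthly_hnhr(0, 9L, 0, 0, 0))  # no hospitalization
  expect_false(monthly_hnhr(1, 4L, 0, 0, 0))  # VA frailty below 5
})

test_that("any qualifying month in either indicator assigns ER", {
  iahq <- matrix(FALSE, 3, 12)
  hnhr <- matrix(FALSE, 3, 12)
  iahq[1, 3] <- TRUE         # IAH-Q in month 3 only
  hnhr[2, 12] <- TRUE        # HNHR in month 12 only
  expect_equal(assign_stratum(iahq, hnhr), c("ER", "ER", "CR"))
  # monotone: adding a qualifying month never demotes ER to CR
  set.seed(9)
  for (k in 1:50) {
    a <- matrix(runif(36) < 0.2, 3); b <- matrix(runif(36) < 0.2, 3)
    s0 <- assign_stratum(a, b)
    a2 <- a; a2[sample(36, 1)] <- TRUE
    s1 <- assign_stratum(a2, b)
    expect_true(all(!(s0 == "ER" & s1 == "CR")))
  }
})

test_that("race-centered age is the within-group residual", {
  expect_equal(as.numeric(race_centered_age(70.4, "W", c(W = 60.4))), 10.0)
  # a degenerate group centers to exactly zero
  expect_equal(as.numeric(race_centered_age(rep(55, 4), rep("W", 4))),
               rep(0, 4))
  # two groups with means 60 and 55: same age, different residuals
  age <- c(62, 58, 58, 52)
  grp <- c("A", "A", "B", "B")
  got <- race_centered_age(c(58, 58), c("A", "B"),
                           group_means = c(A = 60, B = 55))
  expect_equal(as.numeric(got), c(-2, 3))
  expect_error(race_centered_age(50, "X", c(W = 60)), "unknown race group")
  # residuals average to ~0 within every group on random data
  set.seed(10)
  age <- rnorm(500, 60, 15)
  grp <- sample(c("A", "B", "C"), 500, TRUE)
  rc <- race_centered_age(age, grp)
  for (g in unique(grp)) {
    expect_lt(abs(mean(rc[grp == g])), 1e-9)
  }
})

test_that("risk proxy applies the model, flags missingness, imputes the median", {
  co <- shared_cohort()
  # intercept-only auxiliary model returns its prevalence for everyone
  const <- glm(y ~ 1, data = data.frame(y = rep(c(1, 0, 0, 0, 0), 20)),
               family = binomial())
  got <- compute_can_proxy(co, const, missing_rate = 0)
  expect_true(all(abs(got$can - 0.2) < 1e-12))
  expect_true(all(got$can_missing == 0L))
  # missingness draws at the configured rate and imputes the median
  got2 <- compute_can_proxy(co, fit_can_model(co, seed = 3), seed = 4,
                            missing_rate = 0.045)
  n <- nrow(got2)
  expect_true(all(got2$can >= 0 & got2$can <= 1))
  expect_lt(abs(sum(got2$can_missing) - 0.045 * n),
            4 * sqrt(n * 0.045 * 0.955))
  med <- median(got2$can[got2$can_missing == 0L])
  expect_true(all(got2$can[got2$can_missing == 1L] == med))
})

test_that("feature rows: production equals complete when nothing is lagged or early", {
  co <- shared_cohort()
  # restrict to persons whose records all sit inside months 1-12 and who
  # have no nursing-home or hospice history at all
  dx_late <- unique(co$diagnoses$person_id[co$diagnoses$month > 12L])
  sb <- co$stays_baseline
  b0 <- co$index_date - 365L
  stay_bad <- unique(sb$person_id[sb$setting %in% c("NH", "hospice") |
                                    as.Date(sb$start) < b0])
  ids <- setdiff(co$persons$person_id, union(dx_late, stay_bad))
  ids <- head(sort(ids), 400L)
  cm <- fit_can_model(co, seed = 5)
  fc <- build_feature_rows(co, ids, mode = "complete", can_model = cm,
                           can_seed = 6)
  fp <- build_feature_rows(co, ids, mode = "production", lag_months = 0L,
                           can_model = cm, can_seed = 6)
  expect_equal(fc, fp)
})

test_that("production mode lags non-VA data and windows prior LTI to months 13-24", {
  co <- shared_cohort()
  idx <- co$index_date
  base <- co[c("persons", "diagnoses", "stays_baseline", "stays_outcome",
               "truth")]
  # person A: qualifying spell ending ~3 months before the index;
  # person B: qualifying spell wholly inside months 13-24
  pick <- head(co$persons$person_id, 2L)
  extra <- data.frame(
    person_id = pick,
    setting = "NH",
    start = c(idx - 200L, idx - 700L),
    end = c(idx - 95L, idx - 560L),
    payer = "Medicare", face_to_face = FALSE)
  co2 <- co
  co2$stays_baseline <- rbind(co$stays_baseline, extra)
  cm <- fit_can_model(co, seed = 5)
  fc <- build_feature_rows(co2, pick, mode = "complete", can_model = cm)
  fp <- build_feature_rows(co2, pick, mode = "production", lag_months = 9L,
                           can_model = cm)
  a <- which(fc$person_id == pick[1L]); b <- which(fc$person_id == pick[2L])
  expect_equal(fc$prior_lti[a], 1L)   # recent spell seen with complete data
  expect_equal(fp$prior_lti[a], 0L)   # ...but outside months 13-24
  expect_equal(fc$prior_lti[b], 0L)   # early spell outside the 12-month window
  expect_equal(fp$prior_lti[b], 1L)   # ...and inside months 13-24
})

test_that("production frailty is the maximum of monthly look-back scores", {
  co <- shared_cohort()
  pid <- co$persons$person_id[1L]
  # six frailty domains recorded only at month 13: invisible to the
  # 12-month complete look-back, visible to shifted monthly windows
  doms <- c("dementia", "stroke", "malnutrition", "pressure_ulcer",
            "seizure", "heart_failure")
  co2 <- co
  co2$diagnoses <- rbind(
    co$diagnoses[co$diagnoses$person_id != pid, ],
    do.call(rbind, lapply(doms, function(d) dx_row(pid, d, 13L, "VA"))))
  cm <- fit_can_model(co, seed = 5)
  fc <- build_feature_rows(co2, pid, mode = "complete", can_model = cm)
  fp <- build_feature_rows(co2, pid, mode = "production", lag_months = 0L,
                           can_model = cm)
  expect_equal(fc$jfi, 0L)
  expect_equal(fp$jfi, 6L)
})

test_that("ER prevalence on the default configuration is near 9.3%", {
  co <- shared_cohort()
  deaths <- data.frame(person_id = co$truth$person_id,
                       death_date = co$truth$death_date)
  excl <- apply_cohort_exclusions(co$persons, co$stays_baseline, deaths,
                                  co$index_date)
  f <- build_feature_rows(co, excl$eligible, can_seed = 7)
  expect_gt(mean(f$stratum == "ER"), 0.073)
  expect_lt(mean(f$stratum == "ER"), 0.113)
})
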