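# Residential-history timeline construction and LTI spell detection.

test_that("build_timeline fills uncovered days with community and applies priority", {
  tl <- build_timeline(data.frame(), c("2018-01-01", "2018-01-10"))
  expect_equal(nrow(tl), 10L)
  expect_true(all(tl$setting == "community"))

  # NH days 1-5 overlapping hospital days 3-4: acute care wins on overlap
  stays <- data.frame(
    person_id = "p1",
    setting = c("NH", "hospital"),
    start = as.Date(c("2018-01-01", "2018-01-03")),
    end = as.Date(c("2018-01-05", "2018-01-04")),
    payer = "VA", face_to_face = FALSE)
  tl <- build_timeline(stays, c("2018-01-01", "2018-01-06"))
  expect_equal(tl$setting,
               c("NH", "NH", "hospital", "hospital", "NH", "community"))
})

test_that("abutting NH stays with different payers form one unbroken run", {
  stays <- data.frame(
    person_id = "p1", setting = "NH",
    start = as.Date(c("2018-01-01", "2018-01-11")),
    end = as.Date(c("2018-01-10", "2018-01-20")),
    payer = c("VA", "Medicare"), face_to_face = FALSE)
  tl <- build_timeline(stays, c("2018-01-01", "2018-01-20"))
  expect_true(all(tl$setting == "NH"))
  sp <- detect_lti_spells(tl)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$nh_days, 20L)
})

test_that("malformed stays and ranges are rejected with context", {
  bad <- data.frame(person_id = "p1", setting = "NH",
                    start = as.Date("2018-02-01"),
                    end = as.Date("2018-01-01"), payer = "VA")
  expect_error(build_timeline(bad, c("2018-01-01", "2018-03-01")),
               "end < start")
  expect_error(build_timeline(data.frame(), c("2018-01-02", "2018-01-01")),
               "range")
  two <- data.frame(person_id = c("a", "b"), setting = "NH",
                    start = as.Date("2018-01-01"),
                    end = as.Date("2018-01-02"), payer = "VA")
  expect_error(build_timeline(two, c("2018-01-01", "2018-01-05")),
               "single person")
  unk <- data.frame(person_id = "p1", setting = "spa",
                    start = as.Date("2018-01-01"),
                    end = as.Date("2018-01-02"), payer = "VA")
  expect_error(build_timeline(unk, c("2018-01-01", "2018-01-05")),
               "unknown setting")
})

test_that("the >90-day boundary separates qualifying from non-qualifying spells", {
  mk <- function(n_days) {
    build_timeline(
      data.frame(person_id = "p1", setting = "NH",
                 start = as.Date("2018-01-01"),
                 end = as.Date("2018-01-01") + n_days - 1L, payer = "VA"),
      c(as.Date("2018-01-01"), as.Date("2018-01-01") + n_days + 20L))
  }
  sp91 <- detect_lti_spells(mk(91L))
  expect_equal(sp91$nh_days, 91L)
  expect_true(sp91$qualifying)
  sp90 <- detect_lti_spells(mk(90L))
  expect_equal(sp90$nh_days, 90L)
  expect_false(sp90$qualifying)
})

test_that("acute interruptions extend a spell but community gaps > 7 break it", {
  # 50 NH + 30 hospital + 45 NH: one spell of 95 NH days
  tl <- build_timeline(
    stays_from_runs(list(run("NH", 50), run("hospital", 30), run("NH", 45))),
    c("2018-01-01", "2018-12-31"))
  sp <- detect_lti_spells(tl)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$nh_days, 95L)
  expect_true(sp$qualifying)
  expect_equal(sp[, -1], oracle_spells(tl), ignore_attr = TRUE)

  # 50 NH + 8 community + 45 NH: the gap exceeds 7, two separate spells
  tl2 <- build_timeline(
    stays_from_runs(list(run("NH", 50), run("community", 8), run("NH", 45))),
    c("2018-01-01", "2018-12-31"))
  sp2 <- detect_lti_spells(tl2)
  expect_equal(sp2$nh_days, c(50L, 45L))
  expect_false(any(sp2$qualifying))
  expect_equal(sp2[, -1], oracle_spells(tl2), ignore_attr = TRUE)

  # a 7-day gap does not break
  tl3 <- build_timeline(
    stays_from_runs(list(run("NH", 50), run("community", 7), run("NH", 45))),
    c("2018-01-01", "2018-12-31"))
  expect_equal(detect_lti_spells(tl3)$nh_days, 95L)
})

test_that("hospice days neither break a spell nor add NH days by default", {
  tl <- build_timeline(
    stays_from_runs(list(run("NH", 50), run("hospice", 20), run("NH", 45))),
    c("2018-01-01", "2018-12-31"))
  sp <- detect_lti_spells(tl)
  expect_equal(sp$nh_days, 95L)
  # with hospice removed from the interrupting set, it behaves as a break
  rule2 <- spell_rule(interrupting_settings = c("hospital", "ED"))
  sp2 <- detect_lti_spells(tl, rule2)
  expect_equal(sp2$nh_days, c(50L, 45L))
})

test_that("detector matches the brute-force day scanner on random timelines", {
  set.seed(71)
  n_checked <- 0L
  for (k in 1:1000) {
    tl <- random_timeline(n_days = sample(60:320, 1L))
    rule <- spell_rule(day_threshold = sample(c(30L, 90L, 100L), 1L),
                       max_community_gap = sample(0:9, 1L))
    got <- detect_lti_spells(
      structure(tl, class = c("pli_timeline", "data.frame"),
                person_id = "px"), rule)
    want <- oracle_spells(tl, rule)
    expect_identical(got$nh_days, want$nh_days)
    expect_identical(got$qualifying, want$qualifying)
    expect_identical(got$spell_start, want$spell_start)
    expect_identical(got$spell_end, want$spell_end)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 1000L)
})

test_that("spells are disjoint, ordered, and monotone in the rule parameters", {
  set.seed(72)
  for (k in 1:60) {
    tl <- random_timeline(n_days = 250)
    tl <- structure(tl, class = c("pli_timeline", "data.frame"),
                    person_id = "px")
    base <- detect_lti_spells(tl, spell_rule(max_community_gap = 3L))
    if (nrow(base) > 1L) {
      expect_true(all(base$spell_start[-1L] > base$spell_end[-nrow(base)]))
    }
    # widening the allowed community gap can only merge spells
    wide <- detect_lti_spells(tl, spell_rule(max_community_gap = 8L))
    expect_gte(sum(wide$nh_days), sum(base$nh_days))
    expect_gte(max(c(0L, wide$nh_days)), max(c(0L, base$nh_days)))
    expect_lte(any(wide$qualifying) - any(base$qualifying), 1L)
    expect_gte(any(wide$qualifying) - any(base$qualifying), 0L)
    # raising the day threshold can only reduce qualifying spells
    lo <- detect_lti_spells(tl, spell_rule(day_threshold = 90L))
    hi <- detect_lti_spells(tl, spell_rule(day_threshold = 100L))
    expect_lte(sum(hi$qualifying), sum(lo$qualifying))
  }
})

test_that("spells are invariant to NH payer relabeling", {
  set.seed(73)
  stays <- stays_from_runs(list(run("NH", 40), run("hospital", 5),
                                run("NH", 60), run("community", 10),
                                run("NH", 20)))
  a <- detect_lti_cohort(stays, c("2018-01-01", "2018-12-31"))
  stays$payer <- sample(c("VA", "Medicare", "other"), nrow(stays), TRUE)
  b <- detect_lti_cohort(stays, c("2018-01-01", "2018-12-31"))
  expect_identical(a, b)
})

test_that("death truncates the timeline but a past-threshold spell stays qualifying", {
  stays <- data.frame(person_id = "p1", setting = "NH",
                      start = as.Date("2018-01-01"),
                      end = as.Date("2018-12-31"), payer = "VA",
                      face_to_face = FALSE)
  deaths <- data.frame(person_id = "p1", death_date = as.Date("2018-04-15"))
  sp <- detect_lti_cohort(stays, c("2018-01-01", "2018-12-31"),
                          deaths = deaths)
  expect_equal(sp$nh_days, as.integer(as.Date("2018-04-15") - as.Date("2018-01-01")) + 1L)
  expect_true(sp$qualifying)
  expect_equal(sp$spell_end, as.Date("2018-04-15"))
  # death before the threshold leaves the spell non-qualifying
  deaths$death_date <- as.Date("2018-02-01")
  sp2 <- detect_lti_cohort(stays, c("2018-01-01", "2018-12-31"),
                           deaths = deaths)
  expect_false(sp2$qualifying)
})

test_that("cohort exclusions apply ordered rules and tally each person once", {
  idx <- as.Date("2017-10-01")
  enc <- function(id, d = "2017-06-01") {
    data.frame(person_id = id, setting = "encounter", start = as.Date(d),
               end = as.Date(d), payer = "VA", face_to_face = TRUE)
  }
  stays <- rbind(
    enc("ok"), enc("hospice_p"), enc("died_p"), enc("lastday_p"), enc("lti_p"),
    data.frame(person_id = "hospice_p", setting = "hospice",
               start = as.Date("2017-05-01"), end = as.Date("2017-05-10"),
               payer = "VA", face_to_face = FALSE),
    # qualifying baseline spell AND in NH on the last day: rule (a) wins
    data.frame(person_id = "lti_p", setting = "NH",
               start = as.Date("2017-06-01"), end = as.Date("2017-09-30"),
               payer = "VA", face_to_face = FALSE),
    data.frame(person_id = "lastday_p", setting = "NH",
               start = as.Date("2017-09-25"), end = as.Date("2017-10-05"),
               payer = "VA", face_to_face = FALSE))
  persons <- data.frame(person_id = c("ok", "hospice_p", "no_ftf_p",
                                      "died_p", "lastday_p", "lti_p"))
  deaths <- data.frame(person_id = persons$person_id,
                       death_date = as.Date(NA))
  deaths$death_date[deaths$person_id == "died_p"] <- as.Date("2017-03-01")
  res <- apply_cohort_exclusions(persons, stays, deaths, idx)
  expect_setequal(res$eligible, "ok")
  expect_equal(res$tally$n_excluded,
               c(2L, 1L, 1L, 1L))  # (a) hospice+lti, (b), (c), (d)
  expect_error(apply_cohort_exclusions(persons, stays, NULL, idx),
               "data-contract")
})

test_that("a person with only a face-to-face visit and no stays is eligible", {
  idx <- as.Date("2017-10-01")
  stays <- data.frame(person_id = "solo", setting = "encounter",
                      start = as.Date("2017-04-01"),
                      end = as.Date("2017-04-01"), payer = "VA",
                      face_to_face = TRUE)
  deaths <- data.frame(person_id = "solo", death_date = as.Date(NA))
  res <- apply_cohort_exclusions(data.frame(person_id = "solo"), stays,
                                 deaths, idx)
  expect_equal(res$eligible, "solo")
  expect_equal(sum(res$tally$n_excluded), 0L)
})
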