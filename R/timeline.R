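# Residential-history construction: resolve overlapping stay records into a
# daily-location timeline, detect long-term institutionalization (LTI)
# spells, and apply cohort eligibility exclusions.

#' Recognised care settings for stay records
#'
#' `"encounter"` denotes an outpatient community-care encounter; it carries a
#' `face_to_face` flag and never contributes residential days.
#'
#' @export
STAY_SETTINGS <- c("NH", "hospital", "ED", "hospice", "encounter")

#' Recognised payers for stay records
#' @export
STAY_PAYERS <- c("VA", "Medicare", "other")

# Daily resolution priority when stays overlap: acute care supersedes
# custodial location, so an NH resident hospitalized for two days is
# "in hospital" those days. Higher value wins.
.setting_priority <- c(hospice = 1, NH = 2, ED = 3, hospital = 4)

#' Validate a table of stay records
#'
#' @param stays data.frame with columns `person_id`, `setting`, `start`,
#'   `end` (coercible to `Date`), and optionally `payer`, `face_to_face`.
#' @return the validated table with `Date` columns, invisibly usable.
#' @keywords internal
validate_stays <- function(stays) {
  stays <- as.data.frame(stays)
  req <- c("person_id", "setting", "start", "end")
  miss <- setdiff(req, names(stays))
  if (length(miss)) {
    stop("stay table is missing column(s): ", paste(miss, collapse = ", "))
  }
  stays$start <- as.Date(stays$start)
  stays$end <- as.Date(stays$end)
  bad_set <- !(stays$setting %in% STAY_SETTINGS)
  if (any(bad_set)) {
    stop("unknown setting(s) in stay records: ",
         paste(unique(stays$setting[bad_set]), collapse = ", "))
  }
  bad <- which(stays$end < stays$start)
  if (length(bad)) {
    stop("stay record(s) with end < start at row index ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  stays
}

#' Build a daily residential timeline for one person
#'
#' Resolves a set of possibly overlapping stay records into exactly one
#' setting per calendar day over `range`. Stay intervals are inclusive of
#' both endpoints. Days covered by no stay resolve to `"community"`.
#' Overlaps resolve by priority hospital > ED > NH > hospice; outpatient
#' encounters never contribute residential days.
#'
#' @param stays stay records for a single person (see [validate_stays()]).
#' @param range length-2 vector of dates, the first and last day to resolve.
#' @return an object of class `pli_timeline`: a data.frame with columns
#'   `date` and `setting`, one row per calendar day, plus attribute
#'   `person_id`.
#' @examples
#' tl <- build_timeline(
#'   data.frame(person_id = 1, setting = "NH",
#'              start = "2018-01-01", end = "2018-01-05"),
#'   range = c("2018-01-01", "2018-01-10"))
#' table(tl$setting)
#' @export
build_timeline <- function(stays, range) {
  range <- as.Date(range)
  if (length(range) != 2L || is.na(range[1L]) || is.na(range[2L]) ||
      range[2L] < range[1L]) {
    stop("`range` must be two dates with range[1] <= range[2]")
  }
  days <- seq(range[1L], range[2L], by = "day")
  setting <- rep("community", length(days))
  person_id <- NA
  if (NROW(stays)) {
    stays <- validate_stays(stays)
    if (length(unique(stays$person_id)) > 1L) {
      stop("build_timeline() expects stays for a single person")
    }
    person_id <- stays$person_id[1L]
    res <- stays[stays$setting %in% names(.setting_priority), , drop = FALSE]
    if (nrow(res)) {
      # apply in increasing priority so higher-priority settings overwrite
      res <- res[order(.setting_priority[res$setting]), , drop = FALSE]
      for (i in seq_len(nrow(res))) {
        lo <- max(res$start[i], range[1L])
        hi <- min(res$end[i], range[2L])
        if (lo <= hi) {
          idx <- as.integer(lo - range[1L] + 1L):as.integer(hi - range[1L] + 1L)
          setting[idx] <- res$setting[i]
        }
      }
    }
  }
  out <- data.frame(date = days, setting = setting)
  class(out) <- c("pli_timeline", "data.frame")
  attr(out, "person_id") <- person_id
  out
}

#' Rule object for LTI spell detection
#'
#' An LTI spell accumulates nursing-home (NH) days; it survives runs of
#' *interrupting* settings (acute care) of any length and community runs of
#' at most `max_community_gap` consecutive days, and qualifies as long-term
#' institutionalization when cumulative NH days exceed `day_threshold`.
#' Hospice days are treated like acute interruptions by default: they never
#' break a spell but contribute no NH days.
#'
#' @param day_threshold cumulative NH days strictly above which a spell
#'   qualifies (default 90; 100 matches an alternative published footnote).
#' @param max_community_gap longest run of consecutive community days a
#'   spell survives (default 7).
#' @param interrupting_settings settings that never break a spell.
#' @return object of class `spell_rule`.
#' @export
spell_rule <- function(day_threshold = 90L, max_community_gap = 7L,
                       interrupting_settings = c("hospital", "ED", "hospice")) {
  day_threshold <- as.integer(day_threshold)
  max_community_gap <- as.integer(max_community_gap)
  if (is.na(day_threshold) || day_threshold < 1L) {
    stop("day_threshold must be >= 1")
  }
  if (is.na(max_community_gap) || max_community_gap < 0L) {
    stop("max_community_gap must be >= 0")
  }
  bad <- setdiff(interrupting_settings, STAY_SETTINGS)
  if (length(bad)) stop("unknown interrupting setting(s): ", paste(bad, collapse = ", "))
  structure(list(day_threshold = day_threshold,
                 max_community_gap = max_community_gap,
                 interrupting_settings = interrupting_settings),
            class = "spell_rule")
}

#' Detect LTI spells on a resolved timeline
#'
#' Scans the daily timeline for maximal spells: a spell starts at an NH day,
#' accumulates NH days, survives interrupting-setting runs of any length and
#' community runs of at most `rule$max_community_gap` days, and ends at its
#' last NH day before a longer community run (or the end of the timeline).
#' A spell qualifies when its cumulative NH days exceed `rule$day_threshold`.
#'
#' @param timeline a `pli_timeline` from [build_timeline()], or any
#'   data.frame with `date` and `setting` columns (one row per day).
#' @param rule a [spell_rule()].
#' @return data.frame with columns `person_id`, `spell_start`, `spell_end`,
#'   `nh_days`, `qualifying`; zero rows when no NH days are present.
#' @export
detect_lti_spells <- function(timeline, rule = spell_rule()) {
  stopifnot(inherits(rule, "spell_rule"))
  person_id <- attr(timeline, "person_id")
  if (is.null(person_id)) person_id <- NA
  n <- NROW(timeline)
  empty <- data.frame(person_id = person_id[0], spell_start = as.Date(character()),
                      spell_end = as.Date(character()), nh_days = integer(),
                      qualifying = logical())
  if (!n) return(empty)
  s <- timeline$setting
  dts <- as.Date(timeline$date)
  # run-length scan: classify each run as NH / interrupting / breaking-capable
  r <- rle(s)
  kind <- ifelse(r$values == "NH", "NH",
          ifelse(r$values %in% rule$interrupting_settings, "int", "comm"))
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  out <- list()
  i <- 1L
  nr <- length(r$lengths)
  while (i <= nr) {
    if (kind[i] != "NH") { i <- i + 1L; next }
    spell_start <- run_start[i]
    nh <- 0L
    last_nh_end <- NA_integer_
    j <- i
    while (j <= nr) {
      if (kind[j] == "NH") {
        nh <- nh + r$lengths[j]
        last_nh_end <- run_end[j]
      } else if (kind[j] == "comm" && r$lengths[j] > rule$max_community_gap) {
        break
      }
      j <- j + 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      person_id = person_id,
      spell_start = dts[spell_start],
      spell_end = dts[last_nh_end],
      nh_days = nh,
      qualifying = nh > rule$day_threshold)
    i <- j
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Detect LTI spells for every person in a stays table
#'
#' Convenience wrapper: builds a per-person timeline over `range` (truncated
#' at the person's death date when supplied) and runs [detect_lti_spells()].
#' Persons with no NH stay are skipped (they cannot have a spell).
#'
#' @param stays multi-person stay table.
#' @param range length-2 date vector; timeline range per person.
#' @param rule a [spell_rule()].
#' @param deaths optional data.frame `person_id`, `death_date`; a person's
#'   timeline ends on the death date (a spell already past the threshold
#'   remains qualifying).
#' @return data.frame of spells across persons (possibly zero rows).
#' @export
detect_lti_cohort <- function(stays, range, rule = spell_rule(), deaths = NULL) {
  range <- as.Date(range)
  stays <- validate_stays(stays)
  nh_persons <- unique(stays$person_id[stays$setting == "NH"])
  res <- list()
  if (length(nh_persons)) {
    death_map <- NULL
    if (!is.null(deaths) && NROW(deaths)) {
      death_map <- stats::setNames(as.Date(deaths$death_date), deaths$person_id)
    }
    keep <- stays$person_id %in% nh_persons
    sp <- split(stays[keep, , drop = FALSE], stays$person_id[keep])
    for (pid in names(sp)) {
      rng <- range
      if (!is.null(death_map) && pid %in% names(death_map) &&
          !is.na(death_map[[pid]])) {
        rng[2L] <- min(rng[2L], death_map[[pid]])
      }
      if (rng[2L] < rng[1L]) next
      tl <- build_timeline(sp[[pid]], rng)
      res[[pid]] <- detect_lti_spells(tl, rule)
    }
  }
  if (!length(res)) {
    return(data.frame(person_id = character(), spell_start = as.Date(character()),
                      spell_end = as.Date(character()), nh_days = integer(),
                      qualifying = logical()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$person_id, out$spell_start), , drop = FALSE]
}

#' Apply cohort eligibility exclusions
#'
#' Removes persons who, during the 12-month baseline year ending the day
#' before `index_date`, (a) had a qualifying LTI spell or any hospice stay,
#' (b) had no face-to-face encounter, (c) died, or (d) were resolved to a
#' hospital or nursing-home setting on the last baseline day. Rules are
#' applied in that order and each person is tallied at most once.
#'
#' @param persons data.frame with a `person_id` column.
#' @param stays_baseline baseline stay/encounter records.
#' @param deaths data.frame `person_id`, `death_date` (NA for alive).
#' @param index_date the prediction index date; baseline year is the 365
#'   days ending the day before it.
#' @param rule [spell_rule()] used for exclusion (a).
#' @return list with `eligible` (character vector of person_ids) and
#'   `tally` (data.frame of exclusion counts in application order).
#' @export
apply_cohort_exclusions <- function(persons, stays_baseline, deaths,
                                    index_date, rule = spell_rule()) {
  if (is.null(deaths) || !all(c("person_id", "death_date") %in% names(deaths))) {
    stop("data-contract error: `deaths` must have person_id and death_date")
  }
  stays_baseline <- validate_stays(stays_baseline)
  index_date <- as.Date(index_date)
  b0 <- index_date - 365L
  b1 <- index_date - 1L
  ids <- as.character(persons$person_id)
  excluded <- character(0)

  in_year <- stays_baseline$end >= b0 & stays_baseline$start <= b1
  sb <- stays_baseline[in_year, , drop = FALSE]

  # (a) qualifying LTI spell or any hospice stay in the baseline year
  spells <- detect_lti_cohort(sb, c(b0, b1), rule)
  lti_ids <- unique(as.character(spells$person_id[spells$qualifying]))
  hospice_ids <- unique(as.character(sb$person_id[sb$setting == "hospice"]))
  ex_a <- intersect(ids, union(lti_ids, hospice_ids))
  excluded <- ex_a

  # (b) no face-to-face utilization in the baseline year
  ftf <- rep(FALSE, nrow(sb))
  if ("face_to_face" %in% names(sb)) ftf <- isTRUE_vec(sb$face_to_face)
  ftf_ids <- unique(as.character(sb$person_id[sb$setting == "encounter" & ftf]))
  ex_b <- setdiff(setdiff(ids, ftf_ids), excluded)
  excluded <- c(excluded, ex_b)

  # (c) death during the baseline year
  dd <- as.Date(deaths$death_date)
  died_ids <- as.character(deaths$person_id[!is.na(dd) & dd >= b0 & dd <= b1])
  ex_c <- setdiff(intersect(ids, died_ids), excluded)
  excluded <- c(excluded, ex_c)

  # (d) in hospital or NH on the last baseline day
  on_last <- sb$start <= b1 & sb$end >= b1 & sb$setting %in% c("hospital", "NH")
  last_ids <- unique(as.character(sb$person_id[on_last]))
  # resolved setting: hospital/NH stays dominate community by priority,
  # so covering the last day in either setting is sufficient
  ex_d <- setdiff(intersect(ids, last_ids), excluded)
  excluded <- c(excluded, ex_d)

  tally <- data.frame(
    rule = c("lti_or_hospice", "no_face_to_face", "died_baseline",
             "inpatient_last_day"),
    n_excluded = c(length(ex_a), length(ex_b), length(ex_c), length(ex_d)))
  list(eligible = setdiff(ids, excluded), tally = tally)
}

# logical coercion tolerant of 0/1 and NA
isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  !is.na(x) & (x == 1 | x == TRUE | x == "TRUE")
}
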