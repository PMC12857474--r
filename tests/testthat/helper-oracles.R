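# Independent oracles and fixture builders used across the suite.
# Each oracle is a deliberately naive implementation kept separate from the
# package's code paths.

# --- brute-force day-by-day spell scanner ------------------------------
# Walks the timeline one day at a time with an explicit state machine and
# counts NH runs directly.
oracle_spells <- function(timeline, rule = spell_rule()) {
  s <- timeline$setting
  d <- as.Date(timeline$date)
  spells <- list()
  in_spell <- FALSE
  nh <- 0L; start <- NA_integer_; last_nh <- NA_integer_; comm_run <- 0L
  close_spell <- function() {
    spells[[length(spells) + 1L]] <<- data.frame(
      spell_start = d[start], spell_end = d[last_nh], nh_days = nh,
      qualifying = nh > rule$day_threshold)
  }
  for (t in seq_along(s)) {
    if (!in_spell) {
      if (s[t] == "NH") {
        in_spell <- TRUE; nh <- 1L; start <- t; last_nh <- t; comm_run <- 0L
      }
    } else {
      if (s[t] == "NH") {
        nh <- nh + 1L; last_nh <- t; comm_run <- 0L
      } else if (s[t] %in% rule$interrupting_settings) {
        comm_run <- 0L
      } else {
        comm_run <- comm_run + 1L
        if (comm_run > rule$max_community_gap) {
          close_spell(); in_spell <- FALSE
        }
      }
    }
  }
  if (in_spell) close_spell()
  if (!length(spells)) {
    return(data.frame(spell_start = as.Date(character()),
                      spell_end = as.Date(character()),
                      nh_days = integer(), qualifying = logical()))
  }
  do.call(rbind, spells)
}

# random daily timeline as a run sequence of settings
random_timeline <- function(n_days = 200L,
                            settings = c("community", "NH", "hospital",
                                         "ED", "hospice"),
                            probs = c(0.35, 0.3, 0.15, 0.1, 0.1)) {
  out <- character(0)
  while (length(out) < n_days) {
    out <- c(out, rep(sample(settings, 1L, prob = probs),
                      sample.int(15L, 1L)))
  }
  data.frame(date = as.Date("2018-01-01") + seq_len(n_days) - 1L,
             setting = out[seq_len(n_days)])
}

# stays table for a single person from (setting, length) runs, back to back
stays_from_runs <- function(runs, person_id = "p1",
                            start = as.Date("2018-01-01"), payer = "VA") {
  cur <- start
  rows <- list()
  for (r in runs) {
    if (r$setting != "community") {
      rows[[length(rows) + 1L]] <- data.frame(
        person_id = person_id, setting = r$setting, start = cur,
        end = cur + r$len - 1L, payer = payer, face_to_face = FALSE)
    }
    cur <- cur + r$len
  }
  do.call(rbind, rows)
}
run <- function(setting, len) list(setting = setting, len = len)

# --- exhaustive threshold-pair search ----------------------------------
# Full grid over candidate thresholds per stratum (all distinct observed
# scores plus a flag-nobody sentinel), vectorized outer enumeration, same
# total order as the optimizer: max TP, then fewest flagged, then higher
# tau_er, then higher tau_cr.
oracle_thresholds <- function(scores, outcome, nns_max = 8, grid = NULL) {
  y <- as.integer(outcome)
  prep <- function(str) {
    i <- scores$stratum == str
    s <- scores$p_lti[i]; yy <- y[i]
    taus <- if (is.null(grid)) c(sort(unique(s), decreasing = TRUE), 1)
            else sort(unique(c(grid[[str]], 1)), decreasing = TRUE)
    taus <- unique(c(1, taus))
    flag <- vapply(taus, function(tt) sum(s >= tt), integer(1L))
    tp <- vapply(taus, function(tt) sum(yy[s >= tt]), integer(1L))
    list(tau = taus, flag = flag, tp = tp)
  }
  er <- prep("ER"); cr <- prep("CR")
  TP <- outer(er$tp, cr$tp, `+`)
  FL <- outer(er$flag, cr$flag, `+`)
  ok <- TP > 0 & FL <= nns_max * TP
  if (!any(ok)) stop("oracle: infeasible")
  tp <- TP[ok]; fl <- FL[ok]
  tau_er <- outer(er$tau, cr$tau, function(a, b) a)[ok]
  tau_cr <- outer(er$tau, cr$tau, function(a, b) b)[ok]
  best <- order(-tp, fl, -tau_er, -tau_cr)[1L]
  list(tp = tp[best], flagged = fl[best], nns = fl[best] / tp[best],
       tau_er = tau_er[best], tau_cr = tau_cr[best])
}

# --- all-pairs concordance ---------------------------------------------
oracle_cstat <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# synthetic risk scores with outcomes drawn from the scores themselves
score_frame <- function(n, seed = 1, p_er = 0.3, base = -4.5) {
  withr::with_seed(seed, {
    stratum <- ifelse(runif(n) < p_er, "ER", "CR")
    eta <- base + rnorm(n, sd = 1.4) + 1.2 * (stratum == "ER")
    p <- plogis(eta)
    data.frame(person_id = sprintf("s%06d", seq_len(n)), stratum = stratum,
               p_lti = p, outcome = as.integer(runif(n) < p))
  })
}

# --- tiny deterministic feature fixtures --------------------------------
# minimal feature rows usable by fit_stratum_model / kfold_cv
toy_features <- function(n, seed = 1, p_er = 0.3) {
  withr::with_seed(seed, {
    data.frame(
      person_id = sprintf("t%05d", seq_len(n)),
      facility_id = sample(c("A", "B", "C"), n, TRUE),
      race_group = sample(c("White", "Black"), n, TRUE, prob = c(.8, .2)),
      x1 = rnorm(n), x2 = rbinom(n, 1, 0.4),
      stratum = ifelse(runif(n) < p_er, "ER", "CR"),
      stringsAsFactors = FALSE)
  })
}
toy_outcome <- function(features, beta = c(-2, 0.8, 0.6), seed = 2) {
  eta <- beta[1] + beta[2] * features$x1 + beta[3] * features$x2
  withr::with_seed(seed, as.integer(runif(nrow(features)) < plogis(eta)))
}

# shared small cohort, built once per test run
shared_cohort <- local({
  cache <- NULL
  function(n = 12000L, seed = 402L) {
    if (is.null(cache)) cache <<- simulate_cohort(sim_config(n_persons = n,
                                                             seed = seed))
    cache
  }
})
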