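# Dual-threshold selection under a number-needed-to-screen budget, and
# high / moderate / low tier assignment.

# per-stratum candidate summary: for each achievable true-positive count,
# the minimal flagged prefix (flagging rule is score >= tau, so candidate
# thresholds are the distinct observed score values plus "flag nobody").
# Restricting each stratum to its minimal-flagged prefix per TP value is
# lossless for the optimizer: for a fixed TP split, extra flagged persons
# can only hurt the budget and the tie-breaks.
.stratum_frontier <- function(scores, outcomes, grid = NULL) {
  y <- as.integer(isTRUE_vec(outcomes))
  ord <- order(-scores)
  s <- scores[ord]; y <- y[ord]
  n <- length(s)
  if (!is.null(grid)) {
    # coarsen: only prefixes whose threshold is a grid point are allowed
    grid <- sort(unique(as.numeric(grid)), decreasing = TRUE)
    ks <- vapply(grid, function(g) sum(s >= g), integer(1L))
    ks <- unique(ks[ks > 0L])
  } else {
    # prefixes must end at a tie boundary (threshold = observed value)
    ks <- which(c(s[-n] > s[-1L], TRUE))
  }
  cum_tp <- cumsum(y)
  tp <- cum_tp[ks]
  flag <- ks
  # minimal flagged per distinct TP value, plus the empty prefix
  o <- order(tp, flag)
  tp <- tp[o]; flag <- flag[o]; ks <- ks[o]
  first <- !duplicated(tp)
  data.frame(tp = c(0L, tp[first]), flagged = c(0L, flag[first]),
             tau = c(1, s[ks[first]]))
}

#' Optimize stratum-specific high-risk thresholds under an NNS budget
#'
#' Searches candidate threshold pairs (one per stratum; candidates are the
#' distinct observed score values, optionally coarsened to a supplied grid)
#' for the pair maximizing total captured LTI events subject to a pooled
#' number-needed-to-screen of at most `nns_max`. Flagging is inclusive
#' (`score >= tau`). Ties are broken by lower pooled NNS, then fewer
#' persons flagged, then higher ER threshold.
#'
#' @param scores data.frame with columns `person_id`, `stratum`
#'   ("ER"/"CR"), `p_lti`, and `outcome` (or pass `outcome` separately).
#' @param outcome optional binary vector aligned with `scores`.
#' @param nns_max pooled NNS budget (default 8).
#' @param grid optional list with elements `ER` and `CR` of candidate
#'   threshold values; default all distinct observed scores per stratum.
#' @return object of class `threshold_pair`: `tau_er`, `tau_cr`,
#'   `achieved_nns`, `achieved_sensitivity`, `n_flagged`, `n_tp`.
#' @export
optimize_thresholds <- function(scores, outcome = NULL, nns_max = 8,
                                grid = NULL) {
  stopifnot(nns_max >= 1)
  if (is.null(outcome)) outcome <- scores$outcome
  stopifnot(length(outcome) == nrow(scores))
  y <- as.integer(isTRUE_vec(outcome))
  er <- scores$stratum == "ER"
  total_pos <- sum(y)
  if (total_pos == 0L) {
    stop("infeasible: no positive outcomes; every threshold pair has TP = 0")
  }
  fr_er <- if (any(er)) .stratum_frontier(scores$p_lti[er], y[er],
                                          grid = grid$ER)
           else data.frame(tp = 0L, flagged = 0L, tau = 1)
  fr_cr <- if (any(!er)) .stratum_frontier(scores$p_lti[!er], y[!er],
                                           grid = grid$CR)
           else data.frame(tp = 0L, flagged = 0L, tau = 1)
  # exhaustive over the reduced frontiers (small: one point per TP value)
  i <- rep(seq_len(nrow(fr_er)), times = nrow(fr_cr))
  j <- rep(seq_len(nrow(fr_cr)), each = nrow(fr_er))
  tp <- fr_er$tp[i] + fr_cr$tp[j]
  fl <- fr_er$flagged[i] + fr_cr$flagged[j]
  ok <- tp > 0L & fl <= nns_max * tp
  if (!any(ok)) {
    pos <- tp > 0L
    stop(sprintf(
      "infeasible: no threshold pair meets NNS <= %g (best achievable NNS = %.3f)",
      nns_max, min(fl[pos] / tp[pos])))
  }
  tp_ok <- tp[ok]; fl_ok <- fl[ok]
  tau_er_ok <- fr_er$tau[i[ok]]; tau_cr_ok <- fr_cr$tau[j[ok]]
  best <- order(-tp_ok, fl_ok, -tau_er_ok, -tau_cr_ok)[1L]
  structure(list(
    tau_er = tau_er_ok[best], tau_cr = tau_cr_ok[best],
    achieved_nns = fl_ok[best] / tp_ok[best],
    achieved_sensitivity = tp_ok[best] / total_pos,
    n_flagged = fl_ok[best], n_tp = tp_ok[best]),
    class = "threshold_pair")
}

#' Construct a threshold pair by hand
#'
#' @param tau_er,tau_cr stratum thresholds in (0, 1\].
#' @return object of class `threshold_pair` (achieved fields unset).
#' @export
threshold_pair <- function(tau_er, tau_cr) {
  stopifnot(tau_er >= 0, tau_er <= 1, tau_cr >= 0, tau_cr <= 1)
  structure(list(tau_er = tau_er, tau_cr = tau_cr, achieved_nns = NA_real_,
                 achieved_sensitivity = NA_real_, n_flagged = NA_integer_,
                 n_tp = NA_integer_), class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf(
    "<threshold_pair> tau_ER=%.4f tau_CR=%.4f  NNS=%.2f sens=%.3f flagged=%d TP=%d\n",
    x$tau_er, x$tau_cr, x$achieved_nns, x$achieved_sensitivity,
    x$n_flagged, x$n_tp))
  invisible(x)
}

# threshold lookup per stratum vector
.tau_for <- function(pair, stratum) {
  ifelse(stratum == "ER", pair$tau_er, pair$tau_cr)
}

#' Assign high / moderate / low risk tiers
#'
#' A person is high-tier when their predicted risk is at or above their
#' stratum's high threshold; moderate when below high but at or above the
#' moderate threshold; else low. The partition is exhaustive and exclusive.
#'
#' @param scores data.frame `person_id`, `stratum`, `p_lti`.
#' @param high a `threshold_pair` for the high tier.
#' @param moderate a `threshold_pair` for the moderate tier; each moderate
#'   threshold must not exceed the corresponding high threshold.
#' @return data.frame `person_id`, `stratum`, `p_lti`, `tier`.
#' @export
assign_tiers <- function(scores, high, moderate) {
  if (moderate$tau_er > high$tau_er || moderate$tau_cr > high$tau_cr) {
    stop("crossed thresholds: moderate thresholds must not exceed high thresholds")
  }
  tau_h <- .tau_for(high, scores$stratum)
  tau_m <- .tau_for(moderate, scores$stratum)
  tier <- ifelse(scores$p_lti >= tau_h, "high",
          ifelse(scores$p_lti >= tau_m, "moderate", "low"))
  out <- scores[, c("person_id", "stratum", "p_lti")]
  out$tier <- factor(tier, levels = c("high", "moderate", "low"))
  out
}

#' Moderate-tier thresholds from a wider screening budget
#'
#' The moderate tier is defined by re-running the threshold optimizer at a
#' larger NNS budget (default 25) and clamping at the high-tier thresholds
#' so tiers nest. This is a configurable extrapolation: the moderate tier
#' captures additional likely-LTI persons at a lower screening yield.
#'
#' @param scores,outcome as in [optimize_thresholds()].
#' @param high the high-tier `threshold_pair`.
#' @param nns_moderate NNS budget for the moderate tier (default 25).
#' @return a `threshold_pair` with thresholds clamped to the high pair.
#' @export
moderate_thresholds <- function(scores, outcome = NULL, high,
                                nns_moderate = 25) {
  pair <- optimize_thresholds(scores, outcome, nns_max = nns_moderate)
  pair$tau_er <- min(pair$tau_er, high$tau_er)
  pair$tau_cr <- min(pair$tau_cr, high$tau_cr)
  pair
}
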