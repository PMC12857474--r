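# Stratum-specific binary-outcome regression: maximum-likelihood logistic
# (or probit) fits per risk stratum, predicted probabilities, average
# marginal effects, Wald-based variable retention, and fit statistics.

.linkinv <- function(link) if (link == "logit") stats::plogis else stats::pnorm
.linkden <- function(link) if (link == "logit") stats::dlogis else stats::dnorm

# assemble the design data.frame: sanitized covariate columns plus
# reference-coded facility dummies (largest facility = reference)
.model_design <- function(rows, covariates, facility_levels = NULL,
                          reference_facility = NULL) {
  miss <- setdiff(covariates, names(rows))
  if (length(miss)) {
    stop("missing covariate(s): ", paste(miss, collapse = ", "))
  }
  X <- rows[, covariates, drop = FALSE]
  for (j in seq_along(X)) X[[j]] <- as.numeric(X[[j]])
  if (!is.null(facility_levels)) {
    fac <- as.character(rows$facility_id)
    for (lev in setdiff(facility_levels, reference_facility)) {
      X[[paste0("facility_", lev)]] <- as.numeric(fac == lev)
    }
  }
  X
}

#' Fit a stratum-specific LTI model
#'
#' Maximum-likelihood logistic (default) or probit regression of a binary
#' outcome on the model covariates, optionally with facility fixed effects
#' (reference-coded, largest facility as reference). Rows are sorted by
#' `person_id` before fitting so results are bit-stable under input
#' reordering. Constant covariate columns are dropped with a warning;
#' perfect separation and non-convergence raise explicit errors.
#'
#' @param rows feature rows for one stratum (see [build_feature_rows()]).
#' @param outcome binary outcome vector aligned with `rows`.
#' @param stratum label stored on the model ("ER"/"CR").
#' @param link `"logit"` or `"probit"`.
#' @param with_facility_effects include facility fixed effects.
#' @param covariates covariate column names (default [model_covariates()]).
#' @return object of class `stratum_model`: coefficient map, intercept,
#'   facility effects, standard errors and Wald p-values, log-likelihoods
#'   (fitted and null), `n_obs`, `converged`.
#' @export
fit_stratum_model <- function(rows, outcome, stratum = "CR", link = "logit",
                              with_facility_effects = FALSE,
                              covariates = model_covariates()) {
  link <- match.arg(link, c("logit", "probit"))
  stopifnot(length(outcome) == nrow(rows))
  y <- as.integer(isTRUE_vec(outcome))
  if (sum(y) < 1L || sum(1L - y) < 1L) {
    stop("need at least one positive and one negative outcome")
  }
  if ("person_id" %in% names(rows)) {
    ord <- order(rows$person_id)
    rows <- rows[ord, , drop = FALSE]
    y <- y[ord]
  }
  facility_levels <- NULL
  reference_facility <- NULL
  if (with_facility_effects) {
    tab <- sort(table(as.character(rows$facility_id)), decreasing = TRUE)
    facility_levels <- names(tab)
    reference_facility <- facility_levels[1L]
  }
  X <- .model_design(rows, covariates, facility_levels, reference_facility)
  keep <- vapply(X, function(v) stats::var(v) > 0, logical(1L))
  if (any(!keep)) {
    warning("dropping constant covariate column(s): ",
            paste(names(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  # strict separation check: a covariate whose ranges under y=0 / y=1 do
  # not overlap separates the outcome perfectly
  for (nm in names(X)) {
    x1 <- X[[nm]][y == 1L]; x0 <- X[[nm]][y == 0L]
    if (min(x1) > max(x0) || max(x1) < min(x0)) {
      stop("perfect separation on covariate: ", nm)
    }
  }
  df <- cbind(X, .y = y)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(link = link),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100L))
  if (!fit$converged) {
    stop("model did not converge after ", fit$iter, " iterations")
  }
  if (any(fit$fitted.values < 1e-12 | fit$fitted.values > 1 - 1e-12)) {
    warning("fitted probabilities numerically 0 or 1; possible quasi-separation")
  }
  cf <- stats::coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  pv <- sm$coefficients[, 4L]
  is_fac <- grepl("^facility_", names(cf))
  ll0 <- as.numeric(stats::logLik(stats::glm(y ~ 1, family = stats::binomial(link = link))))
  structure(list(
    stratum = stratum,
    link = link,
    intercept = unname(cf["(Intercept)"]),
    coefficients = cf[!is_fac & names(cf) != "(Intercept)"],
    facility_effects = stats::setNames(
      unname(cf[is_fac]), sub("^facility_", "", names(cf)[is_fac])),
    reference_facility = reference_facility,
    se = se, p_values = pv, vcov = stats::vcov(fit),
    n_obs = length(y), converged = fit$converged,
    loglik = as.numeric(stats::logLik(fit)), loglik_null = ll0,
    covariate_names = names(X)[!grepl("^facility_", names(X))]),
    class = "stratum_model")
}

#' @export
print.stratum_model <- function(x, ...) {
  cat(sprintf("<stratum_model> stratum=%s link=%s n=%d  pseudo-R2=%.3f\n",
              x$stratum, x$link, x$n_obs, pseudo_r2(x)))
  cat("coefficients:\n")
  print(round(c("(Intercept)" = x$intercept, x$coefficients), 4))
  if (length(x$facility_effects)) {
    cat(length(x$facility_effects), "facility effects (reference:",
        x$reference_facility, ")\n")
  }
  invisible(x)
}

#' McFadden pseudo-R-squared of a stratum model
#' @param model a `stratum_model`.
#' @return `1 - loglik / loglik_null`, in \[0, 1).
#' @export
pseudo_r2 <- function(model) {
  1 - model$loglik / model$loglik_null
}

# linear predictor for feature rows under a fitted model
.linear_predictor <- function(model, rows) {
  X <- .model_design(rows, model$covariate_names)
  eta <- model$intercept + as.matrix(X) %*% model$coefficients
  if (length(model$facility_effects)) {
    fac <- as.character(rows$facility_id)
    fe <- model$facility_effects[fac]
    fe[is.na(fe)] <- 0  # unseen facility levels map to effect 0
    eta <- eta + fe
  }
  as.numeric(eta)
}

#' Predict LTI risk for feature rows
#'
#' @param model a `stratum_model`.
#' @param rows feature rows covering the model's covariates; facility
#'   levels unseen at fit time contribute effect 0.
#' @return data.frame `person_id`, `stratum`, `p_lti` in \[0,1\].
#' @export
predict_risk <- function(model, rows) {
  p <- .linkinv(model$link)(.linear_predictor(model, rows))
  data.frame(person_id = if ("person_id" %in% names(rows)) rows$person_id
             else seq_len(nrow(rows)),
             stratum = model$stratum, p_lti = p,
             stringsAsFactors = FALSE)
}

#' Average marginal effect of a covariate
#'
#' For a binary covariate, the mean over rows of the counterfactual
#' difference `p(x, covariate = 1) - p(x, covariate = 0)`; for a continuous
#' covariate, the mean derivative of `p` with respect to it. The confidence
#' interval uses the delta method by default or a nonparametric bootstrap
#' (row resampling with refits) when `ci = "bootstrap"`.
#'
#' @param model a `stratum_model`.
#' @param rows feature rows over which the effect is averaged.
#' @param covariate covariate name (must be in the model).
#' @param ci `"delta"` or `"bootstrap"`.
#' @param level confidence level.
#' @param type `"auto"` treats a covariate observed at both 0 and 1 (and
#'   nothing else) as binary; override with `"binary"` or `"continuous"`.
#' @param outcome binary outcome vector, required for `ci = "bootstrap"`.
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @return list with `ame`, `lower`, `upper`, `se`, `type`.
#' @export
average_marginal_effect <- function(model, rows, covariate,
                                    ci = c("delta", "bootstrap"),
                                    level = 0.95,
                                    type = c("auto", "binary", "continuous"),
                                    outcome = NULL, B = 200L, seed = 1L) {
  ci <- match.arg(ci)
  type <- match.arg(type)
  if (!covariate %in% model$covariate_names) {
    stop("covariate not in model: ", covariate)
  }
  point <- .ame_estimate(model, rows, covariate, gradient = (ci == "delta"),
                         type = type)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (ci == "delta") {
    V <- model$vcov
    g <- point$gradient[rownames(V)]
    se <- sqrt(as.numeric(t(g) %*% V %*% g))
  } else {
    if (is.null(outcome)) stop("bootstrap CI needs the outcome vector")
    n <- nrow(rows)
    reps <- withr_seed(seed, {
      vapply(seq_len(B), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        m <- suppressWarnings(
          fit_stratum_model(rows[i, , drop = FALSE], outcome[i],
                            stratum = model$stratum, link = model$link,
                            covariates = model$covariate_names))
        .ame_estimate(m, rows[i, , drop = FALSE], covariate, type = type)$ame
      }, numeric(1L))
    })
    se <- stats::sd(reps)
  }
  list(ame = point$ame, lower = point$ame - z * se,
       upper = point$ame + z * se, se = se, type = point$type)
}

.ame_estimate <- function(model, rows, covariate, gradient = FALSE,
                          type = "auto") {
  x <- as.numeric(rows[[covariate]])
  binary <- switch(type,
                   binary = TRUE,
                   continuous = FALSE,
                   all(x %in% c(0, 1)) && any(x == 0) && any(x == 1))
  h1 <- .linkden(model$link)
  inv <- .linkinv(model$link)
  beta_names <- c("(Intercept)", model$covariate_names,
                  if (length(model$facility_effects))
                    paste0("facility_", names(model$facility_effects)))
  full_design <- function(r) {
    X <- .model_design(r, model$covariate_names)
    M <- cbind(`(Intercept)` = 1, as.matrix(X))
    if (length(model$facility_effects)) {
      fac <- as.character(r$facility_id)
      for (lev in names(model$facility_effects)) {
        M <- cbind(M, as.numeric(fac == lev))
        colnames(M)[ncol(M)] <- paste0("facility_", lev)
      }
    }
    M
  }
  if (binary) {
    r1 <- rows; r1[[covariate]] <- 1
    r0 <- rows; r0[[covariate]] <- 0
    eta1 <- .linear_predictor(model, r1)
    eta0 <- .linear_predictor(model, r0)
    ame <- mean(inv(eta1) - inv(eta0))
    out <- list(ame = ame, type = "binary")
    if (gradient) {
      M1 <- full_design(r1); M0 <- full_design(r0)
      g <- colMeans(M1 * h1(eta1)) - colMeans(M0 * h1(eta0))
      out$gradient <- g
    }
  } else {
    eta <- .linear_predictor(model, rows)
    b <- unname(model$coefficients[covariate])
    ame <- mean(h1(eta)) * b
    out <- list(ame = ame, type = "continuous")
    if (gradient) {
      # d/deta of the link density
      h2 <- if (model$link == "logit") {
        p <- inv(eta); p * (1 - p) * (1 - 2 * p)
      } else -eta * stats::dnorm(eta)
      M <- full_design(rows)
      g <- colMeans(M * h2) * b
      g[covariate] <- g[covariate] + mean(h1(eta))
      out$gradient <- g
    }
  }
  out
}

#' Variables retained at a Wald significance level
#'
#' A covariate is retained when its Wald p-value is below `alpha` in at
#' least one of the supplied stratum models; the strata are then refit on
#' the union (by the caller or [refit_retained()]). Facility fixed-effect
#' terms and the intercept are never subject to retention.
#'
#' @param models list of `stratum_model` objects.
#' @param alpha significance level (default 0.05).
#' @return character vector of retained covariate names (possibly empty,
#'   with a warning).
#' @export
variable_retention <- function(models, alpha = 0.05) {
  retained <- character(0)
  for (m in models) {
    pv <- m$p_values
    pv <- pv[names(pv) %in% m$covariate_names]
    retained <- union(retained, names(pv)[pv < alpha])
  }
  if (!length(retained)) {
    warning("no covariate significant at alpha = ", alpha,
            "; refit would be intercept-only")
  }
  retained
}

#' Refit stratum models on a retained covariate set
#'
#' @param rows_by_stratum named list of feature rows per stratum.
#' @param outcome_by_stratum named list of outcome vectors per stratum.
#' @param retained covariate names (from [variable_retention()]).
#' @param ... passed to [fit_stratum_model()].
#' @return named list of refit `stratum_model`s.
#' @export
refit_retained <- function(rows_by_stratum, outcome_by_stratum, retained, ...) {
  out <- list()
  for (s in names(rows_by_stratum)) {
    out[[s]] <- fit_stratum_model(rows_by_stratum[[s]],
                                  outcome_by_stratum[[s]], stratum = s,
                                  covariates = retained, ...)
  }
  out
}

#' Serialize / restore a stratum model as JSON
#'
#' @param model a `stratum_model`.
#' @param path file path.
#' @export
write_stratum_model <- function(model, path) {
  obj <- unclass(model)
  obj$vcov <- NULL
  # named vectors serialize as dicts so length-1 maps keep their names
  for (nm in c("coefficients", "facility_effects", "se", "p_values")) {
    obj[[nm]] <- as.list(obj[[nm]])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stratum_model
#' @export
read_stratum_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("coefficients", "facility_effects", "se", "p_values")) {
    v <- unlist(obj[[nm]])
    if (is.null(v)) v <- stats::setNames(numeric(0), character(0))
    obj[[nm]] <- v
  }
  obj$covariate_names <- as.character(unlist(obj$covariate_names))
  class(obj) <- "stratum_model"
  obj
}
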