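#' Specification of the telemedicine propensity model
#'
#' The propensity score is the conditional probability that an index visit
#' occurred via telemedicine given baseline characteristics. The default
#' model is a logistic regression with a practice-level random intercept
#' (accounting for within-practice correlation in telemedicine uptake), the
#' demographic, seasonal, specialty, complexity and prior-utilization
#' covariates, and a season-by-region interaction (added because region and
#' season balance is otherwise hard to achieve). A fixed-effects-only engine
#' is a first-class option.
#'
#' @param covariates character vector of episode-table columns.
#' @param interactions character vector of interaction terms in formula
#'   syntax (default `"season:census_region"`).
#' @param engine `"mixed"` (random-intercept logistic, Laplace approximation
#'   via lme4) or `"fixed"` (plain logistic).
#' @param group grouping column for the random intercept.
#' @return An object of class `propensity_spec`.
#' @export
propensity_spec <- function(covariates = c("race_ethnicity", "age_group",
                                           "census_division", "season",
                                           "clinician_specialty",
                                           "medical_complexity_flag",
                                           "prior_well_visits",
                                           "prior_problem_visits",
                                           "prior_telemedicine",
                                           "prior_antibiotics"),
                            interactions = "season:census_region",
                            engine = c("mixed", "fixed"),
                            group = "practice_id") {
  structure(list(covariates = covariates, interactions = interactions,
                 engine = match.arg(engine), group = group),
            class = "propensity_spec")
}

## factors with the most frequent category as reference; deterministic
## (ties broken by level name)
freq_factor <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  factor(x, levels = names(tab))
}

prep_model_frame <- function(episodes, spec) {
  vars <- unique(c(spec$covariates,
                   unlist(strsplit(spec$interactions %||% character(0),
                                   ":", fixed = TRUE))))
  absent <- setdiff(vars, names(episodes))
  if (length(absent))
    stop("propensity covariate(s) absent from episode table: ",
         paste(absent, collapse = ", "))
  df <- episodes[, unique(c(vars, spec$group, "modality")), drop = FALSE]
  for (v in vars)
    if (is.character(df[[v]])) df[[v]] <- freq_factor(df[[v]])
  df$.tele <- as.integer(df$modality == "telemedicine")
  df
}

#' Fit the telemedicine propensity model
#'
#' @param episodes complete-case episode table with a `modality` column.
#' @param spec a [propensity_spec()].
#' @return An object of class `arti_propensity` with the fitted model, the
#'   coefficient table, the estimated random-intercept standard deviation
#'   (`sigma_b`, mixed engine) and the training factor levels used for
#'   prediction. Non-convergence or apparent separation is an explicit error.
#' @examples
#' \donttest{
#' ehr <- generate_ehr(synth_config(n_practices = 20, seed = 3))
#' cohort <- build_episodes(ehr$patients, ehr$visits, ehr$prescriptions,
#'                          code_registry())
#' ep <- complete_case_filter(apply_exclusions(cohort$episodes)$episodes)
#' fit <- fit_propensity(ep$episodes, propensity_spec(engine = "fixed"))
#' summary(predict(fit))
#' }
#' @export
fit_propensity <- function(episodes, spec = propensity_spec()) {
  stopifnot(inherits(spec, "propensity_spec"))
  df <- prep_model_frame(episodes, spec)
  rhs <- paste(c(spec$covariates, spec$interactions), collapse = " + ")
  if (!nzchar(rhs)) rhs <- "1"
  if (spec$engine == "mixed") {
    if (length(unique(df[[spec$group]])) < 2)
      stop("mixed engine requires >= 2 practices")
    fml <- stats::as.formula(
      paste0(".tele ~ ", rhs, " + (1 | ", spec$group, ")"))
    fit <- lme4::glmer(fml, data = df, family = stats::binomial(),
                       control = lme4::glmerControl(
                         check.conv.singular = "ignore"))
    msgs <- fit@optinfo$conv$lme4$messages
    if (!is.null(msgs) && any(grepl("failed to converge", msgs)))
      stop("propensity model failed to converge: ",
           paste(msgs, collapse = "; "))
    beta <- lme4::fixef(fit)
    sigma_b <- sqrt(unname(lme4::VarCorr(fit)[[spec$group]][1]))
  } else {
    fml <- stats::as.formula(paste0(".tele ~ ", rhs))
    fit <- stats::glm(fml, data = df, family = stats::binomial())
    if (!fit$converged)
      stop("propensity model failed to converge (glm IRLS)")
    beta <- stats::coef(fit)
    sigma_b <- NA_real_
  }
  ## quasi-separation from empty covariate cells (all-in-person cells) is
  ## benign for weighting -- those episodes get weight ~1 -- so it is
  ## reported loudly but does not abort; non-convergence above does.
  if (any(abs(beta[!is.na(beta)]) > 15))
    warning("propensity model shows apparent separation (largest ",
            "|coefficient| ", round(max(abs(beta), na.rm = TRUE), 1),
            "); affected cells carry little or no telemedicine")
  vars <- names(df)[vapply(df, is.factor, logical(1))]
  xlevels <- lapply(df[vars], levels)
  structure(list(model = fit, spec = spec, engine = spec$engine,
                 coefficients = beta, sigma_b = sigma_b,
                 xlevels = xlevels, n = nrow(df),
                 n_tele = sum(df$.tele)),
            class = "arti_propensity")
}

#' @export
print.arti_propensity <- function(x, ...) {
  cat("Telemedicine propensity model (", x$engine, " engine)\n", sep = "")
  cat(sprintf("  episodes: %d (%d telemedicine)\n", x$n, x$n_tele))
  if (x$engine == "mixed")
    cat(sprintf("  practice intercept SD (logit): %.3f\n", x$sigma_b))
  cat("  fixed effects:\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' @export
coef.arti_propensity <- function(object, ...) object$coefficients

#' Predict per-episode propensity scores
#'
#' Mixed-engine predictions include the practice's estimated (shrunken)
#' random intercept; episodes from practices unseen at fit time receive the
#' population intercept (0). Covariate categories unseen at fit time are
#' mapped to the reference (most frequent) category. Predictions are clipped
#' to `clip` so downstream weights are finite.
#'
#' @param object an `arti_propensity` fit.
#' @param newdata episode table; defaults to the training data.
#' @param clip two-sided clipping bounds for the propensity.
#' @param ... unused.
#' @return Numeric vector of propensities in (0, 1).
#' @export
predict.arti_propensity <- function(object, newdata = NULL,
                                    clip = c(1e-6, 1 - 1e-6), ...) {
  if (is.null(newdata)) {
    e <- stats::fitted(object$model)
  } else {
    df <- prep_model_frame(newdata, object$spec)
    for (v in names(object$xlevels)) {
      lv <- object$xlevels[[v]]
      xi <- as.character(df[[v]])
      xi[!xi %in% lv] <- lv[1]
      df[[v]] <- factor(xi, levels = lv)
    }
    if (object$engine == "mixed") {
      e <- stats::predict(object$model, newdata = df, type = "response",
                          allow.new.levels = TRUE)
    } else {
      e <- stats::predict(object$model, newdata = df, type = "response")
    }
  }
  unname(clamp(e, clip[1], clip[2]))
}

#' Construct IPTW or overlap weights
#'
#' Inverse-probability-of-treatment weights target the average treatment
#' effect in the full population: `w = Z/e + (1-Z)/(1-e)`. Overlap weights
#' target the overlap population (ATO): `w = Z(1-e) + (1-Z)e`, mechanically
#' bounded in (0, 1) and hence immune to extreme propensities. Weights are
#' left unnormalized; the Hajek estimator downstream is invariant to their
#' scale.
#'
#' @param e propensity scores in (0, 1).
#' @param Z exposure indicator (1 = telemedicine), logical or 0/1.
#' @param kind `"ATE"` or `"ATO"`.
#' @return A data frame (class `arti_weights`) with columns `e`, `Z`, `w`,
#'   `kind`, carrying a `summary` attribute (min, max, effective sample size
#'   per arm).
#' @examples
#' compute_weights(c(0.2, 0.5), c(1, 0), "ATE")$w  # 5, 2
#' @export
compute_weights <- function(e, Z, kind = c("ATE", "ATO")) {
  kind <- match.arg(kind)
  Z <- as.integer(as.logical(Z))
  if (any(!is.finite(e)) || any(e <= 0) || any(e >= 1))
    stop("propensity scores must lie strictly in (0, 1) after clipping")
  w <- if (kind == "ATE") Z / e + (1 - Z) / (1 - e) else
    Z * (1 - e) + (1 - Z) * e
  out <- data.frame(e = e, Z = Z, w = w, kind = kind,
                    stringsAsFactors = FALSE)
  ess <- function(wi) sum(wi)^2 / sum(wi^2)
  attr(out, "summary") <- c(
    min = min(w), max = max(w),
    ess_inperson = ess(w[Z == 0]), ess_telemedicine = ess(w[Z == 1]))
  class(out) <- c("arti_weights", "data.frame")
  out
}
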