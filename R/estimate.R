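#' Hajek-weighted outcome percentages per arm
#'
#' Ratio (Hajek) estimator per arm: `100 * sum(w y 1[arm]) / sum(w 1[arm])`,
#' invariant to rescaling the weights within an arm.
#'
#' @param y binary outcome (0/1 or logical).
#' @param Z exposure indicator (1/TRUE = telemedicine).
#' @param w strictly positive weights.
#' @return Named vector `c(inperson =, telemedicine =)` in percent.
#' @export
weighted_arm_means <- function(y, Z, w) {
  Z <- as.logical(Z)
  y <- as.numeric(y)
  if (!any(Z) || !any(!Z)) stop("both exposure arms must be nonempty")
  if (any(w <= 0)) stop("weights must be strictly positive")
  c(inperson = 100 * sum(w[!Z] * y[!Z]) / sum(w[!Z]),
    telemedicine = 100 * sum(w[Z] * y[Z]) / sum(w[Z]))
}

#' Average treatment effect as a difference of weighted percentages
#'
#' The nonparametric marginal estimator: the ATE (or ATO, depending on the
#' weights) is the difference of Hajek-weighted outcome percentages,
#' telemedicine minus in-person. Standard errors come from a linearization
#' (sandwich) of the two ratio means with influence contributions summed
#' within practice before squaring, so the variance respects both the
#' weighting and the clustering of episodes within practices. Wald 95%
#' confidence intervals use z = 1.96; an optional small-cluster correction
#' multiplies the variance by G/(G-1).
#'
#' @param y binary outcome.
#' @param Z exposure indicator (1/TRUE = telemedicine).
#' @param w weights from [compute_weights()] (or unit weights).
#' @param cluster cluster (practice) identifiers; at least 2 distinct
#'   clusters are required for the robust variance.
#' @param outcome label carried into the printout.
#' @param estimand `"ATE"` or `"ATO"` (label only; the estimand is set by
#'   the weights).
#' @param small_cluster_correction multiply the variance by G/(G-1).
#' @return An object of class `arti_ate`: weighted percentages with
#'   cluster-robust 95% CIs per arm, the effect in percentage points, its
#'   robust SE and Wald 95% CI, and arm sizes. Methods: `print`, `summary`,
#'   `coef`, `confint`.
#' @examples
#' set.seed(1)
#' d <- data.frame(y = rbinom(60, 1, 0.4), Z = rbinom(60, 1, 0.5),
#'                 g = rep(1:6, each = 10))
#' arti_ate(d$y, d$Z, rep(1, 60), d$g)
#' @export
arti_ate <- function(y, Z, w, cluster, outcome = "outcome",
                     estimand = c("ATE", "ATO"),
                     small_cluster_correction = FALSE) {
  estimand <- match.arg(estimand)
  Z <- as.logical(Z)
  y <- as.numeric(y)
  g <- as.character(cluster)
  if (length(unique(g)) < 2)
    stop("cluster-robust SE undefined with a single cluster")
  mu <- weighted_arm_means(y, Z, w)
  s_t <- sum(w[Z])
  s_c <- sum(w[!Z])
  ## per-episode influence contributions on the percent scale
  psi_t <- ifelse(Z, 100 * w * (y - mu[["telemedicine"]] / 100) / s_t, 0)
  psi_c <- ifelse(!Z, 100 * w * (y - mu[["inperson"]] / 100) / s_c, 0)
  cl_sum <- function(v) as.numeric(rowsum(v, g))
  G <- length(unique(g))
  cf <- if (small_cluster_correction) G / (G - 1) else 1
  var_t <- cf * sum(cl_sum(psi_t)^2)
  var_c <- cf * sum(cl_sum(psi_c)^2)
  var_d <- cf * sum(cl_sum(psi_t - psi_c)^2)
  z <- stats::qnorm(0.975)
  est <- mu[["telemedicine"]] - mu[["inperson"]]
  se <- sqrt(var_d)
  structure(list(
    outcome = outcome, estimand = estimand,
    weighted_pct = mu,
    arm_se = c(inperson = sqrt(var_c), telemedicine = sqrt(var_t)),
    arm_ci = rbind(
      inperson = mu[["inperson"]] + c(-1, 1) * z * sqrt(var_c),
      telemedicine = mu[["telemedicine"]] + c(-1, 1) * z * sqrt(var_t)),
    ate = est, se_robust = se,
    ci95 = c(est - z * se, est + z * se),
    n_unweighted = c(inperson = sum(!Z), telemedicine = sum(Z)),
    n_clusters = G), class = "arti_ate")
}

#' @export
print.arti_ate <- function(x, digits = 1, ...) {
  cat(sprintf("%s of telemedicine vs in-person care: %s\n",
              x$estimand, x$outcome))
  cat(sprintf("  in-person    %s%% (95%% CI %s to %s)  [n = %d]\n",
              format(round(x$weighted_pct[["inperson"]], digits)),
              format(round(x$arm_ci["inperson", 1], digits)),
              format(round(x$arm_ci["inperson", 2], digits)),
              x$n_unweighted[["inperson"]]))
  cat(sprintf("  telemedicine %s%% (95%% CI %s to %s)  [n = %d]\n",
              format(round(x$weighted_pct[["telemedicine"]], digits)),
              format(round(x$arm_ci["telemedicine", 1], digits)),
              format(round(x$arm_ci["telemedicine", 2], digits)),
              x$n_unweighted[["telemedicine"]]))
  cat(sprintf("  %s %s percentage points (95%% CI %s to %s), %d practices\n",
              x$estimand,
              format(round(x$ate, digits)),
              format(round(x$ci95[1], digits)),
              format(round(x$ci95[2], digits)), x$n_clusters))
  invisible(x)
}

#' @export
summary.arti_ate <- function(object, ...) {
  print(object, digits = 2)
  cat(sprintf("  robust SE: %.3f percentage points\n", object$se_robust))
  invisible(object)
}

#' @export
coef.arti_ate <- function(object, ...) c(ate = object$ate)

#' @export
confint.arti_ate <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95)
    stop("only 95% Wald intervals are computed")
  m <- matrix(object$ci95, nrow = 1,
              dimnames = list("ate", c("2.5 %", "97.5 %")))
  m
}

## drop spec covariates that are constant (or that define the subgroup) and
## interactions touching a dropped covariate
restrict_spec <- function(spec, data, drop = character(0)) {
  keep <- setdiff(spec$covariates, drop)
  keep <- keep[vapply(keep, function(v) length(unique(data[[v]])) > 1,
                      logical(1))]
  ints <- spec$interactions
  if (length(ints)) {
    ok <- vapply(ints, function(tm) {
      vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
      !any(vars %in% drop) &&
        all(vapply(vars, function(v) length(unique(data[[v]])) > 1,
                   logical(1)))
    }, logical(1))
    ints <- ints[ok]
  }
  propensity_spec(covariates = keep, interactions = ints,
                  engine = spec$engine, group = spec$group)
}

## refit propensity on a subset and estimate one outcome
refit_and_estimate <- function(data, outcome, spec, estimand,
                               drop = character(0)) {
  sp <- restrict_spec(spec, data, drop)
  fit <- fit_propensity(data, sp)
  e <- predict(fit)
  wts <- compute_weights(e, data$modality == "telemedicine",
                         if (estimand == "ATO") "ATO" else "ATE")
  arti_ate(data[[outcome]], wts$Z, wts$w, data[[spec$group]],
           outcome = outcome, estimand = estimand)
}

#' Subgroup analysis with per-subgroup propensity refits
#'
#' Within each level of the subgroup variable, refits the propensity model
#' excluding the subgroup-defining covariate, reweights, and re-estimates
#' the effect; the result is a forest-plot-ready table. Levels with only one
#' exposure arm are skipped with a warning.
#'
#' @param episodes episode table with outcomes attached.
#' @param subgroup name of the subgrouping column.
#' @param outcome name of the binary outcome column.
#' @param spec a [propensity_spec()].
#' @param estimand `"ATE"` or `"ATO"`.
#' @return Data frame: one row per level with weighted arm percentages, the
#'   effect, robust SE and 95% CI.
#' @export
subgroup_analysis <- function(episodes, subgroup, outcome,
                              spec = propensity_spec(),
                              estimand = c("ATE", "ATO")) {
  estimand <- match.arg(estimand)
  lv <- sort(unique(as.character(episodes[[subgroup]])))
  rows <- list()
  for (l in lv) {
    d <- episodes[episodes[[subgroup]] == l, , drop = FALSE]
    if (length(unique(d$modality)) < 2) {
      warning("subgroup level '", l, "' has a single exposure arm; skipped")
      next
    }
    est <- refit_and_estimate(d, outcome, spec, estimand, drop = subgroup)
    rows[[l]] <- data.frame(
      subgroup = subgroup, level = l, outcome = outcome,
      n = nrow(d),
      pct_inperson = est$weighted_pct[["inperson"]],
      pct_telemedicine = est$weighted_pct[["telemedicine"]],
      ate = est$ate, se = est$se_robust,
      ci_lo = est$ci95[1], ci_hi = est$ci95[2],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diagnosis-conditional sensitivity analysis
#'
#' Restricts the sample to episodes with the given primary diagnosis and
#' repeats the full analysis (propensity refit, reweighting, estimation) for
#' both primary outcomes.
#'
#' @param episodes episode table with outcomes attached.
#' @param label a diagnosis label (see [dx_labels()]).
#' @param spec a [propensity_spec()].
#' @param estimand `"ATE"` or `"ATO"`.
#' @return Named list of `arti_ate` objects for `prescribed_antibiotic` and
#'   `concordant`.
#' @export
diagnosis_conditional <- function(episodes, label,
                                  spec = propensity_spec(),
                                  estimand = c("ATE", "ATO")) {
  estimand <- match.arg(estimand)
  d <- episodes[episodes$diagnosis == label, , drop = FALSE]
  if (!nrow(d)) stop("no episodes with diagnosis '", label, "'")
  if (length(unique(d$modality)) < 2)
    stop("diagnosis-restricted sample has a single exposure arm")
  list(
    prescribed_antibiotic = refit_and_estimate(
      d, "prescribed_antibiotic", spec, estimand),
    concordant = refit_and_estimate(d, "concordant", spec, estimand))
}

#' Weighted diagnosis mix per arm
#'
#' Weighted share of each primary diagnosis per arm plus the share of
#' bacterial diagnoses ("potentially warranting antibiotics"), with
#' differences (telemedicine minus in-person) and cluster-robust CIs.
#'
#' @param episodes episode table with `diagnosis` and `bacterial_flag`.
#' @param Z exposure indicator.
#' @param w weights.
#' @param cluster cluster identifiers.
#' @return Data frame with one row per diagnosis label plus one for the
#'   bacterial share.
#' @export
diagnosis_mix <- function(episodes, Z, w, cluster) {
  rows <- list()
  items <- c(stats::setNames(dx_labels(), dx_labels()),
             bacterial = "bacterial")
  for (nm in names(items)) {
    y <- if (nm == "bacterial") episodes$bacterial_flag else
      episodes$diagnosis == nm
    est <- arti_ate(y, Z, w, cluster, outcome = nm)
    rows[[nm]] <- data.frame(
      diagnosis = nm,
      pct_inperson = est$weighted_pct[["inperson"]],
      pct_telemedicine = est$weighted_pct[["telemedicine"]],
      difference = est$ate, ci_lo = est$ci95[1], ci_hi = est$ci95[2],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
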