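#' Standardized bias of a covariate between exposure arms
#'
#' For a binary covariate, `(p_tele - p_inperson) / sqrt((p_tele (1 -
#' p_tele) + p_inperson (1 - p_inperson)) / 2)`; for a continuous covariate
#' the analogous mean difference over the pooled standard deviation. The
#' sign convention is telemedicine minus in-person. When weights are given,
#' the arm proportions/means in the numerator are weighted but the
#' denominator keeps the unweighted dispersions, so pre- and post-weighting
#' values share a scale (the usual balance-diagnostics convention). Values
#' are signed; take absolute values for Love plots and threshold checks.
#'
#' @param x covariate (logical, 0/1, or continuous numeric).
#' @param Z exposure indicator (1/TRUE = telemedicine).
#' @param w optional strictly positive weights.
#' @return Signed standardized bias; `NA` for a degenerate covariate (zero
#'   pooled dispersion).
#' @examples
#' standardized_bias_props(0.791, 0.843)  # about -0.13
#' @export
standardized_bias <- function(x, Z, w = NULL) {
  Z <- as.logical(Z)
  x <- as.numeric(x)
  if (!is.null(w) && any(w <= 0)) stop("weights must be strictly positive")
  wm <- function(v, wt) if (is.null(wt)) mean(v) else
    sum(wt * v) / sum(wt)
  m_t <- wm(x[Z], w[Z])
  m_c <- wm(x[!Z], w[!Z])
  if (is_binary01(x)) {
    p_t <- mean(x[Z])
    p_c <- mean(x[!Z])
    denom <- sqrt((p_t * (1 - p_t) + p_c * (1 - p_c)) / 2)
  } else {
    denom <- sqrt((stats::var(x[Z]) + stats::var(x[!Z])) / 2)
  }
  if (!is.finite(denom) || denom == 0) return(NA_real_)
  (m_t - m_c) / denom
}

#' @rdname standardized_bias
#' @param p_tele,p_inperson arm proportions of a binary covariate (used to
#'   recompute standardized biases directly from reported percentages).
#' @export
standardized_bias_props <- function(p_tele, p_inperson) {
  (p_tele - p_inperson) /
    sqrt((p_tele * (1 - p_tele) + p_inperson * (1 - p_inperson)) / 2)
}

#' Covariate balance table before and after weighting
#'
#' Expands categorical covariates into one row per level and reports, for
#' each row, the unweighted and weighted arm proportions (or means for
#' continuous covariates) and the signed standardized bias before and after
#' weighting.
#'
#' @param data episode table.
#' @param covariates columns to assess.
#' @param Z exposure indicator (1/TRUE = telemedicine).
#' @param w weights (e.g. from [compute_weights()]).
#' @return A data frame of class `balance_table`.
#' @export
balance_table <- function(data, covariates, Z, w) {
  Z <- as.logical(Z)
  rows <- list()
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.null(x)) stop("covariate absent from data: ", cv)
    if (is.character(x) || is.factor(x)) {
      for (lv in sort(unique(as.character(x)))) {
        xi <- as.numeric(x == lv)
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cv, level = lv, type = "binary",
          p_inperson = mean(xi[!Z]), p_telemedicine = mean(xi[Z]),
          wp_inperson = sum(w[!Z] * xi[!Z]) / sum(w[!Z]),
          wp_telemedicine = sum(w[Z] * xi[Z]) / sum(w[Z]),
          asb_unweighted = standardized_bias(xi, Z),
          asb_weighted = standardized_bias(xi, Z, w),
          stringsAsFactors = FALSE)
      }
    } else {
      xi <- as.numeric(x)
      type <- if (is_binary01(xi)) "binary" else "continuous"
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, level = "", type = type,
        p_inperson = mean(xi[!Z]), p_telemedicine = mean(xi[Z]),
        wp_inperson = sum(w[!Z] * xi[!Z]) / sum(w[!Z]),
        wp_telemedicine = sum(w[Z] * xi[Z]) / sum(w[Z]),
        asb_unweighted = standardized_bias(xi, Z),
        asb_weighted = standardized_bias(xi, Z, w),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("balance_table", "data.frame")
  out
}

#' Love-plot data: absolute standardized biases, sorted
#'
#' @param balance a [balance_table()].
#' @return Data frame with `covariate`, `level`, `asb_pre`, `asb_post`
#'   (absolute values), sorted descending by the pre-weighting value with a
#'   stable order.
#' @export
love_plot_data <- function(balance) {
  out <- data.frame(covariate = balance$covariate, level = balance$level,
                    asb_pre = abs(balance$asb_unweighted),
                    asb_post = abs(balance$asb_weighted),
                    stringsAsFactors = FALSE)
  out[order(-out$asb_pre), , drop = FALSE]
}

#' Draw a Love plot (base graphics)
#'
#' @param love output of [love_plot_data()].
#' @param thresholds reference lines (strict 0.10, pragmatic 0.25).
#' @return Invisibly, `love`.
#' @export
plot_love <- function(love, thresholds = c(0.10, 0.25)) {
  lab <- ifelse(nzchar(love$level),
                paste(love$covariate, love$level, sep = ": "),
                love$covariate)
  n <- nrow(love)
  yy <- rev(seq_len(n))
  graphics::plot(love$asb_pre, yy, pch = 19, col = "firebrick",
                 xlim = c(0, max(love$asb_pre, 0.3, na.rm = TRUE)),
                 yaxt = "n", xlab = "|standardized bias|", ylab = "",
                 main = "Covariate balance before/after weighting")
  graphics::points(love$asb_post, yy, pch = 17, col = "steelblue")
  graphics::axis(2, at = yy, labels = lab, las = 1, cex.axis = 0.7)
  graphics::abline(v = thresholds, lty = c(2, 3), col = "grey40")
  graphics::legend("bottomright", legend = c("before", "after"),
                   pch = c(19, 17), col = c("firebrick", "steelblue"),
                   bty = "n")
  invisible(love)
}

#' Prognostic-score balance
#'
#' Fits a logistic outcome model on the in-person (comparison) arm only,
#' predicts the outcome probability (the prognostic score) for every
#' episode, and reports the continuous-covariate standardized bias of the
#' score between arms, unweighted and weighted. A well-balanced weighted
#' sample should show a small weighted score ASB.
#'
#' @param data episode table.
#' @param outcome name of a binary outcome column.
#' @param covariates predictor columns for the outcome model.
#' @param Z exposure indicator (1/TRUE = telemedicine).
#' @param w weights.
#' @return List with `score` (per-episode prognostic score),
#'   `asb_unweighted` and `asb_weighted`.
#' @export
prognostic_score_balance <- function(data, outcome, covariates, Z, w) {
  Z <- as.logical(Z)
  if (!any(!Z)) stop("comparison (in-person) arm is empty")
  df <- data[, covariates, drop = FALSE]
  for (v in covariates)
    if (is.character(df[[v]])) df[[v]] <- freq_factor(df[[v]])
  df$.y <- as.numeric(data[[outcome]])
  keep <- vapply(covariates, function(v) length(unique(df[[v]][!Z])) > 1,
                 logical(1))
  fml <- stats::as.formula(paste(".y ~",
                                 paste(covariates[keep], collapse = " + ")))
  fit <- stats::glm(fml, data = df[!Z, , drop = FALSE],
                    family = stats::binomial())
  if (!fit$converged) stop("prognostic-score model failed to converge")
  score <- stats::predict(fit, newdata = df, type = "response")
  list(score = unname(score),
       asb_unweighted = standardized_bias(score, Z),
       asb_weighted = standardized_bias(score, Z, w))
}
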