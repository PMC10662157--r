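#' Linear mixed model with sequential random-slope selection
#'
#' Fits a linear mixed-effects model by REML with a random intercept for the
#' grouping factor. Each candidate random slope is tested sequentially with a
#' boundary-aware likelihood-ratio test: the slope enters as an uncorrelated
#' variance component, the REML likelihood ratio is referred to a 50:50
#' mixture of a point mass at zero and a chi-square with 1 df (the variance
#' sits on the boundary of its parameter space under the null), and the
#' slope is kept iff p < `alpha_slope`. Fixed-effect tests use the
#' Satterthwaite degrees-of-freedom approximation; partial eta-squared is
#' derived from the F statistics.
#'
#' @param formula fixed-effects formula, e.g. `A ~ condition * relatedness`.
#' @param data long-format data frame.
#' @param group name of the grouping (random-intercept) column.
#' @param slopes character vector of candidate random-slope terms, tested in
#'   order.
#' @param alpha_slope inclusion level for slope LRTs (default 0.05).
#' @return list of class `lmm_fit`: `model` (the `lmerMod`), `coef` (tidy
#'   fixed-effect table with Satterthwaite df and eta_p2), `slope_tests`,
#'   `selected_slopes`, `converged`.
#' @export
fit_lmm <- function(formula, data, group, slopes = character(0),
                    alpha_slope = 0.05) {
  if (!group %in% names(data)) stop("grouping column not in data")
  if (length(unique(data[[group]])) < 2L) {
    stop("fewer than 2 groups: no mixed model is identifiable; ",
         "fit an ordinary regression instead")
  }
  re <- sprintf("(1 | %s)", group)
  slope_tests <- list()
  selected <- character(0)
  for (sl in slopes) {
    f_red <- stats::as.formula(paste(deparse1(formula), "+", base_re(re, selected, group)))
    f_full <- stats::as.formula(paste(deparse1(formula), "+", base_re(re, c(selected, sl), group)))
    m_red <- lme4::lmer(f_red, data = data, REML = TRUE,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
    m_full <- lme4::lmer(f_full, data = data, REML = TRUE,
                         control = lme4::lmerControl(check.conv.singular = "ignore"))
    lr <- max(0, 2 * (as.numeric(stats::logLik(m_full)) - as.numeric(stats::logLik(m_red))))
    p <- 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
    keep <- p < alpha_slope
    slope_tests[[sl]] <- data.frame(slope = sl, lr = lr, p = p, kept = keep)
    if (keep) selected <- c(selected, sl)
  }

  f_final <- stats::as.formula(paste(deparse1(formula), "+", base_re(re, selected, group)))
  model <- lmerTest::lmer(f_final, data = data, REML = TRUE,
                          control = lme4::lmerControl(check.conv.singular = "ignore"))
  sm <- summary(model)$coefficients
  an <- tryCatch(stats::anova(model, type = 3), error = function(e) NULL)
  coef_tab <- data.frame(
    term = rownames(sm), estimate = sm[, "Estimate"], se = sm[, "Std. Error"],
    df = sm[, "df"], statistic = sm[, "t value"], p = sm[, "Pr(>|t|)"],
    row.names = NULL
  )
  eta <- NULL
  if (!is.null(an) && nrow(an)) {
    eta <- data.frame(
      effect = rownames(an), F = an[, "F value"], df1 = an[, "NumDF"],
      df2 = an[, "DenDF"], p = an[, "Pr(>F)"],
      eta_p2 = (an[, "F value"] * an[, "NumDF"]) /
        (an[, "F value"] * an[, "NumDF"] + an[, "DenDF"]),
      row.names = NULL
    )
  }
  conv <- length(model@optinfo$conv$lme4$messages) == 0L
  structure(
    list(model = model, coef = coef_tab, effects = eta,
         slope_tests = if (length(slope_tests)) do.call(rbind, slope_tests) else NULL,
         selected_slopes = selected, df_method = "satterthwaite",
         converged = conv),
    class = "lmm_fit"
  )
}

base_re <- function(re, selected, group) {
  if (!length(selected)) return(re)
  paste(c(re, sprintf("(0 + %s | %s)", selected, group)), collapse = " + ")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> random slopes kept:",
      if (length(x$selected_slopes)) paste(x$selected_slopes, collapse = ", ") else "none",
      "\n")
  print(x$coef, digits = 3)
  invisible(x)
}

#' Mixed-effects logistic regression with marginal predicted probabilities
#'
#' Maximum-likelihood fit of a logit-link generalized linear mixed model with
#' a random intercept per group (BOBYQA optimizer, large iteration cap).
#' Complete separation and degenerate outcomes are detected and reported as
#' errors rather than returned as silently divergent fits. Average marginal
#' predicted probabilities are computed for a focal predictor by setting
#' every observation to each focal value in turn, predicting on the response
#' scale at the population level (random effects at zero), and averaging.
#'
#' @param formula fixed-effects formula with a binary outcome.
#' @param data data frame.
#' @param group grouping column name.
#' @param focal optional predictor name for marginal probabilities.
#' @param focal_values values of the focal predictor (defaults to the
#'   observed unique values or a 5-point grid for numeric predictors).
#' @param max_iter optimizer iteration cap (default 200000).
#' @return list of class `glmm_fit`: `model`, `coef` (Wald z tests),
#'   `marginal` (data frame of average marginal predicted probabilities),
#'   `converged`.
#' @export
fit_mixed_logistic <- function(formula, data, group, focal = NULL,
                               focal_values = NULL, max_iter = 200000L) {
  outcome <- as.character(formula[[2L]])
  y <- data[[outcome]]
  if (length(unique(stats::na.omit(as.numeric(y)))) < 2L) {
    stop("outcome is constant: complete separation")
  }
  f <- stats::as.formula(paste(deparse1(formula), "+", sprintf("(1 | %s)", group)))
  model <- lme4::glmer(
    f, data = data, family = stats::binomial(),
    control = lme4::glmerControl(optimizer = "bobyqa",
                                 optCtrl = list(maxfun = max_iter),
                                 check.conv.singular = "ignore")
  )
  sm <- summary(model)$coefficients
  if (any(abs(sm[, "Estimate"]) > 15 & sm[, "Std. Error"] > 50)) {
    stop("fitted coefficients diverged: likely complete separation")
  }
  coef_tab <- data.frame(
    term = rownames(sm), estimate = sm[, "Estimate"], se = sm[, "Std. Error"],
    z = sm[, "z value"], p = sm[, "Pr(>|z|)"], row.names = NULL
  )
  marginal <- NULL
  if (!is.null(focal)) {
    if (is.null(focal_values)) {
      fv <- data[[focal]]
      focal_values <- if (is.numeric(fv) && length(unique(fv)) > 8L) {
        seq(min(fv), max(fv), length.out = 5L)
      } else {
        sort(unique(fv))
      }
    }
    probs <- vapply(focal_values, function(v) {
      nd <- data
      nd[[focal]] <- v
      mean(stats::predict(model, newdata = nd, type = "response", re.form = NA))
    }, numeric(1))
    marginal <- data.frame(focal = focal, value = focal_values, prob = probs)
  }
  conv <- length(model@optinfo$conv$lme4$messages) == 0L
  structure(list(model = model, coef = coef_tab, marginal = marginal,
                 converged = conv),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("<glmm_fit> mixed-effects logistic regression\n")
  print(x$coef, digits = 3)
  invisible(x)
}
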