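#' Holm-Bonferroni step-down adjustment
#'
#' Thin wrapper around `stats::p.adjust(method = "holm")`, kept as a named
#' surface so every analysis corrects families the same way.
#'
#' @param pvals numeric p values in `[0, 1]`.
#' @return adjusted p values in the input order.
#' @export
holm_adjust <- function(pvals) {
  if (!length(pvals)) stop("empty p-value list")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Paired / one-sample t test with effect size
#'
#' Two-tailed t test of paired differences (or a single delta vector)
#' against `mu0`, with Cohen's d (`mean/sd` of the deltas) and the 95%
#' confidence interval of the mean.
#'
#' @param x numeric vector (deltas, or first member of the pairs).
#' @param y optional second member; deltas are `x - y`.
#' @param mu0 null value (default 0).
#' @return data frame with `statistic`, `df`, `p`, `d`, `ci_low`, `ci_high`,
#'   `mean`, `n`.
#' @export
paired_tests <- function(x, y = NULL, mu0 = 0) {
  deltas <- if (is.null(y)) x else x - y
  deltas <- deltas[is.finite(deltas)]
  if (length(deltas) < 2L) stop("need at least 2 finite deltas")
  if (stats::sd(deltas) == 0) stop("zero variance in deltas: t test undefined")
  tt <- stats::t.test(deltas, mu = mu0)
  data.frame(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, d = (mean(deltas) - mu0) / stats::sd(deltas),
    ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
    mean = mean(deltas), n = length(deltas)
  )
}

#' Fully within-subject repeated-measures ANOVA with generalized eta-squared
#'
#' Fits `aov` with the within-subject error strata
#' `Error(participant/(A*B*...))` on per-participant cell means and reports
#' F, degrees of freedom, p and generalized eta-squared per effect. For a
#' fully within design with only measured factors,
#' `eta_G^2 = SS_effect / (SS_effect + SS_subjects + sum of all error SS)`.
#'
#' @param data long data frame of cell means.
#' @param dv name of the outcome column.
#' @param within character vector of within-subject factor columns.
#' @param id participant column name (default `"participant"`).
#' @return data frame `effect`, `df1`, `df2`, `F`, `p`, `eta_G2`.
#' @export
rm_anova <- function(data, dv, within, id = "participant") {
  stopifnot_cols(data, c(dv, within, id), "data")
  df <- data.frame(
    .y = data[[dv]], .id = factor(data[[id]]),
    lapply(stats::setNames(within, within), function(w) factor(data[[w]]))
  )
  cells <- table(df$.id, interaction(df[within]))
  if (any(cells != 1L)) stop("design must have exactly one mean per participant and cell")

  rhs <- paste(within, collapse = " * ")
  form <- stats::as.formula(
    sprintf(".y ~ %s + Error(.id/(%s))", rhs, rhs)
  )
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)

  ss_subj <- NA_real_
  rows <- list()
  err_ss <- 0
  for (stratum in sm) {
    tab <- if (is.list(stratum)) stratum[[1L]] else stratum
    terms <- trimws(rownames(tab))
    for (r in seq_along(terms)) {
      if (terms[r] == "Residuals") {
        if (all(terms == "Residuals")) {
          ss_subj <- tab[r, "Sum Sq"]   # between-participant stratum
        } else {
          err_ss <- err_ss + tab[r, "Sum Sq"]
        }
      } else {
        rows[[terms[r]]] <- data.frame(
          effect = terms[r], df1 = tab[r, "Df"],
          df2 = tab[nrow(tab), "Df"], F = tab[r, "F value"],
          p = tab[r, "Pr(>F)"], ss = tab[r, "Sum Sq"]
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$eta_G2 <- out$ss / (out$ss + ss_subj + err_ss)
  rownames(out) <- NULL
  out[, c("effect", "df1", "df2", "F", "p", "eta_G2")]
}

#' Pearson item-level correlation with confidence interval
#'
#' Correlates item (pair) level mean accuracy with an item-level similarity
#' measure across pairs.
#'
#' @param x,y numeric vectors, one value per pair.
#' @return data frame `r`, `ci_low`, `ci_high`, `t`, `df`, `p`, `n`.
#' @export
item_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector: correlation undefined")
  ct <- stats::cor.test(x, y)
  data.frame(
    r = unname(ct$estimate), ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
    t = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value,
    n = length(x)
  )
}
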