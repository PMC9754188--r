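# Reservation-validation linear model.

#' OLS with an interacting binary factor
#'
#' Fits `response ~ covariate * group` by ordinary least squares and reports
#' coefficients, sequential (type-I) ANOVA F tests, and R^2. Sequential tests
#' match the single-degree-of-freedom F statistics conventionally reported
#' for this design (covariate, then group, then their interaction); users
#' wanting type-II tests should refit by hand.
#'
#' Used to validate device-derived activity density against reservation-based
#' visitor counts, with day-of-week (weekday/weekend) as the interacting
#' factor.
#'
#' @param response numeric vector.
#' @param covariate numeric vector.
#' @param group two-level factor (or coercible); first level is the baseline.
#' @return object of class `lm_interaction_result`: `coefficients` (estimate,
#'   std. error, t, p), `anova` (term, df, sum_sq, F, p), `r_squared`,
#'   `residual_df`, and the underlying `fit`.
#' @export
fit_lm_interaction <- function(response, covariate, group) {
  n <- length(response)
  if (n < 5) stop("need at least 5 observations")
  if (length(covariate) != n || length(group) != n)
    stop("response, covariate and group must have equal length")
  if (anyNA(response) || anyNA(covariate) || anyNA(group))
    stop("missing values are not allowed")
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly 2 levels")
  df <- data.frame(.y = response, .x = covariate, .g = group)
  fit <- stats::lm(.y ~ .x * .g, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient model; collinear term(s): ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  an <- stats::anova(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "std_error", "t", "p")
  rownames(coefs) <- sub("^\\.x", "covariate", sub("^\\.g", "group:", rownames(coefs)))
  aov_tab <- data.frame(term = sub("^\\.x", "covariate",
                                   sub("^\\.g", "group", rownames(an))),
                        df = an$Df, sum_sq = an$`Sum Sq`,
                        F = an$`F value`, p = an$`Pr(>F)`,
                        stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, anova = aov_tab,
                 r_squared = sm$r.squared,
                 residual_df = fit$df.residual, fit = fit),
            class = "lm_interaction_result")
}

#' @export
print.lm_interaction_result <- function(x, ...) {
  cat("OLS with interacting binary factor\n")
  cat(sprintf("R^2 = %.3f, residual df = %d\n", x$r_squared, x$residual_df))
  print(round(x$coefficients, 4))
  cat("Sequential ANOVA:\n")
  print(x$anova, row.names = FALSE)
  invisible(x)
}
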