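# Developmental expression-trajectory analysis of driver genes: week
# recoding, per-meta-locus aggregation, random-intercept mixed models with
# likelihood-ratio testing, and trajectory classification.

#' Recode ages onto a common developmental-week scale
#'
#' Gestational ages (weeks) pass through unchanged; post-natal ages map as
#' `weeks = years * 52 + 37`, so that birth is week 37 and the scale runs
#' continuously from early gestation (week 8) to late adulthood (40 years =
#' week 2117).
#'
#' @param value Numeric age values (>= 0; gestational weeks >= 8 to match
#'   the data support).
#' @param unit `"gestational_week"` or `"postnatal_year"` (recycled).
#' @return Numeric vector of developmental weeks.
#' @export
recode_weeks <- function(value, unit = c("gestational_week", "postnatal_year")) {
  if (length(unit) > 1 && length(unit) != length(value)) {
    unit <- match.arg(unit)
  }
  unit <- rep_len(unit, length(value))
  stop_if_not(all(unit %in% c("gestational_week", "postnatal_year")),
              "unit must be gestational_week or postnatal_year")
  stop_if_not(all(value >= 0), "negative age")
  gest <- unit == "gestational_week"
  stop_if_not(all(value[gest] >= 8), "gestational weeks below 8")
  out <- numeric(length(value))
  out[gest] <- value[gest]
  out[!gest] <- value[!gest] * 52 + 37
  out
}

#' Aggregate driver-gene expression per meta-locus
#'
#' Mean expression of the measured driver genes of each meta-locus, per
#' sample (donor x age x region). Unmeasured genes are ignored; meta-loci
#' with zero measured driver genes are dropped with a warning. Coverage
#' (measured / listed genes per meta-locus) is reported as an attribute.
#'
#' @param expr An `expression_dataset` (long format).
#' @param drivers Named list: meta-locus -> character vector of genes.
#' @return data.frame with `donor`, `age_weeks`, `sex`, `region`,
#'   `metalocus`, `expression`; coverage in `attr(, "coverage")`.
#' @export
aggregate_driver_expression <- function(expr, drivers) {
  stop_if_not(length(drivers) >= 1, "drivers must be nonempty")
  measured <- unique(expr$gene)
  out <- list()
  coverage <- numeric(0)
  for (ml in names(drivers)) {
    genes <- intersect(drivers[[ml]], measured)
    coverage[ml] <- length(genes) / length(drivers[[ml]])
    if (length(genes) == 0) {
      warning("meta-locus ", ml, " has no measured driver genes; dropped")
      next
    }
    sub <- expr[expr$gene %in% genes, , drop = FALSE]
    agg <- stats::aggregate(expression ~ donor + age_weeks + sex + region,
                            data = sub, FUN = mean)
    agg$metalocus <- ml
    out[[ml]] <- agg
  }
  stop_if_not(length(out) >= 1, "no meta-locus with measured driver genes")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[, c("donor", "age_weeks", "sex", "region", "metalocus",
                 "expression")]
  attr(res, "coverage") <- coverage
  res
}

#' Fit a random-intercept mixed model to aggregated expression
#'
#' Two model forms over the aggregated table. `"weeks_only"`:
#' `expression ~ weeks + sex + (1 | donor)`, used per meta-locus to
#' classify its trajectory. `"trait_interaction"`:
#' `expression ~ weeks * trait + sex + (1 | donor)` compared against the
#' weeks-only null by a likelihood-ratio test on ML fits (the trait main
#' effect and its interaction with weeks enter together, so df = 2).
#' Coefficients and variance components come from the REML fit; Wald tests
#' use the normal approximation.
#'
#' @param data data.frame with columns `expression`, `age_weeks`, `sex`,
#'   `donor`, and `trait` for the interaction model.
#' @param formula `"weeks_only"` or `"trait_interaction"`.
#' @return An `lmm_fit`: list with `coefficients` (est, se, z, p),
#'   `varcomp` (donor-intercept and residual variances), `logLik_reml`,
#'   `logLik_ml`, and for the interaction model `lrt` (chisq, df = 2, p).
#' @export
fit_lmm <- function(data, formula = c("weeks_only", "trait_interaction")) {
  formula <- match.arg(formula)
  stop_if_not(length(unique(data$donor)) >= 2,
              "at least two donors required for a random intercept")
  stop_if_not(length(unique(data$age_weeks)) >= 2, "weeks must vary")
  data$weeks <- data$age_weeks

  has_sex <- length(unique(data$sex)) >= 2
  sex_term <- if (has_sex) " + sex" else ""
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")

  if (formula == "weeks_only") {
    f_alt <- stats::as.formula(paste0("expression ~ weeks", sex_term,
                                      " + (1 | donor)"))
    fit <- suppressMessages(lme4::lmer(f_alt, data = data, REML = TRUE,
                                       control = ctrl))
    fit_ml <- suppressMessages(lme4::lmer(f_alt, data = data, REML = FALSE,
                                          control = ctrl))
    lrt <- NULL
  } else {
    stop_if_not("trait" %in% names(data),
                "trait column required for the interaction model")
    f_alt <- stats::as.formula(paste0("expression ~ weeks * trait", sex_term,
                                      " + (1 | donor)"))
    f_null <- stats::as.formula(paste0("expression ~ weeks", sex_term,
                                       " + (1 | donor)"))
    fit <- suppressMessages(lme4::lmer(f_alt, data = data, REML = TRUE,
                                       control = ctrl))
    fit_ml <- suppressMessages(lme4::lmer(f_alt, data = data, REML = FALSE,
                                          control = ctrl))
    null_ml <- suppressMessages(lme4::lmer(f_null, data = data, REML = FALSE,
                                           control = ctrl))
    chisq <- max(0, 2 * (as.numeric(stats::logLik(fit_ml)) -
                           as.numeric(stats::logLik(null_ml))))
    df <- attr(stats::logLik(fit_ml), "df") - attr(stats::logLik(null_ml), "df")
    lrt <- list(chisq = chisq, df = df,
                p = pchisq(chisq, df = df, lower.tail = FALSE))
  }

  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      z = sm[, "Estimate"] / sm[, "Std. Error"],
                      stringsAsFactors = FALSE)
  coefs$p <- 2 * pnorm(-abs(coefs$z))
  rownames(coefs) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(donor = vc$vcov[vc$grp == "donor"],
               residual = vc$vcov[vc$grp == "Residual"])
  structure(list(coefficients = coefs, varcomp = varcomp,
                 logLik_reml = as.numeric(stats::logLik(fit)),
                 logLik_ml = as.numeric(stats::logLik(fit_ml)),
                 lrt = lrt, formula = formula, n_donors = length(unique(data$donor))),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept LMM (", x$formula, "), ", x$n_donors, " donors\n",
      sep = "")
  print(x$coefficients, digits = 4)
  if (!is.null(x$lrt)) {
    cat(sprintf("LRT vs weeks-only null: chisq = %.3f, df = %d, p = %.3g\n",
                x$lrt$chisq, x$lrt$df, x$lrt$p))
  }
  invisible(x)
}

#' Classify a developmental expression trajectory
#'
#' From a weeks-only fit: a significantly positive weeks coefficient means
#' expression rises with age (`"adulthood"` trajectory), significantly
#' negative means expression is concentrated early (`"prenatal"`), and a
#' non-significant coefficient means stable expression across life
#' (`"lifetime"`).
#'
#' @param fit An `lmm_fit` from the `"weeks_only"` formula.
#' @param alpha Significance level (default 0.05).
#' @return One of `"prenatal"`, `"adulthood"`, `"lifetime"`.
#' @export
classify_trajectory <- function(fit, alpha = 0.05) {
  row <- fit$coefficients[fit$coefficients$term == "weeks", , drop = FALSE]
  stop_if_not(nrow(row) == 1, "fit has no weeks coefficient")
  if (is.finite(row$p) && row$p < alpha) {
    if (row$estimate > 0) "adulthood" else "prenatal"
  } else {
    "lifetime"
  }
}
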