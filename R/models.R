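#' Fit the individual-interest mixed model
#'
#' Linear mixed-effects model of composite investment interest with
#' crossed random intercepts for subjects and videos:
#' `interest ~ fixed effects + (1 | subject_id) + (1 | video_id)`.
#' Continuous predictors are z-scored within the estimation sample before
#' fitting (binary 0/1 predictors are left as coded), so coefficients are
#' standardized; fitting uses ML (not REML) whenever the fit will be
#' compared by likelihood ratio.
#'
#' @param table Long-format data frame: one row per subject x video with
#'   columns `subject_id`, `video_id`, the response, and the predictors.
#' @param fixed Character vector of fixed-effect column names (may be
#'   empty for the intercept-only model).
#' @param response Response column name (default "interest").
#' @param ml Fit by maximum likelihood (default `TRUE`; required for
#'   [compare_lrt()]).
#' @return Object of class `lmm_fit`: `coefficients` (data frame with
#'   `estimate`, `se`, `t`, `df`, `p`), `ranef_var` (subject, video,
#'   residual variances), `logLik`, `AIC`, `n_obs`, `fixed`, `ml`, and
#'   the underlying `lmerMod` in `$fit`.
#' @export
fit_interest_lmm <- function(table, fixed = character(), response = "interest",
                             ml = TRUE) {
  stopifnot(all(c("subject_id", "video_id", response) %in% names(table)))
  if (length(unique(table$subject_id)) < 2 || length(unique(table$video_id)) < 2) {
    stop("need >= 2 subjects and >= 2 videos", call. = FALSE)
  }
  dat <- table[complete.cases(table[, c("subject_id", "video_id", response, fixed)]), ]
  for (f in fixed) dat[[f]] <- standardize_predictor(dat[[f]])
  rhs <- paste(c(if (length(fixed)) fixed else "1",
                 "(1 | subject_id)", "(1 | video_id)"), collapse = " + ")
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- suppressMessages(lmerTest::lmer(form, data = dat, REML = !ml))
  if (length(fixed) && any(is.na(lme4::fixef(fit)))) {
    stop("rank-deficient fixed-effect matrix", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], df = sm[, "df"],
                      t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  rv <- setNames(vc$vcov, vc$grp)
  structure(list(coefficients = coefs,
                 ranef_var = c(subject = unname(rv["subject_id"]),
                               video = unname(rv["video_id"]),
                               residual = unname(rv["Residual"])),
                 logLik = as.numeric(logLik(fit)), AIC = AIC(fit),
                 n_obs = nrow(dat), fixed = fixed, ml = ml, fit = fit),
            class = "lmm_fit")
}

# z-score continuous predictors; leave binary 0/1 (and constants) as coded.
standardize_predictor <- function(x) {
  if (is.numeric(x) && !all(x %in% c(0, 1)) && sd(x) > 0) {
    as.numeric(scale(x))
  } else {
    x
  }
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s, %d obs, logLik %.2f, AIC %.2f\n",
              if (x$ml) "ML" else "REML", x$n_obs, x$logLik, x$AIC))
  print(x$coefficients, digits = 3)
  cat(sprintf("  random-intercept variances: subject %.3f, video %.3f, residual %.3f\n",
              x$ranef_var["subject"], x$ranef_var["video"],
              x$ranef_var["residual"]))
  invisible(x)
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' `chi^2 = 2 (logLik_full - logLik_nested)` on the difference in fixed
#' parameters; both fits must be ML on the same rows and the nested fixed
#' effects must be a subset of the full ones.
#'
#' @param fit_nested,fit_full `lmm_fit` objects from [fit_interest_lmm()].
#' @return List: `chisq`, `df`, `p`.
#' @export
compare_lrt <- function(fit_nested, fit_full) {
  if (!fit_nested$ml || !fit_full$ml) {
    stop("both fits must use ML for a likelihood-ratio test", call. = FALSE)
  }
  if (fit_nested$n_obs != fit_full$n_obs) {
    stop("fits must use the same response rows", call. = FALSE)
  }
  if (!all(fit_nested$fixed %in% fit_full$fixed)) {
    stop("models are not nested", call. = FALSE)
  }
  df <- length(fit_full$fixed) - length(fit_nested$fixed)
  chisq <- max(0, 2 * (fit_full$logLik - fit_nested$logLik))
  p <- if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else 1
  list(chisq = chisq, df = df, p = p)
}

#' Video-level funding-amount regression
#'
#' Ordinary least squares at the video level (`n` = videos): funding
#' amount on mean FAA, stated deal predictions, and sentiment covariates.
#' Continuous predictors are z-scored within the estimation sample, so
#' coefficients are standardized.
#'
#' @param video_table Data frame, one row per video, containing `amount`
#'   and the predictor columns.
#' @param predictors Character vector of predictor column names.
#' @param response Response column (default "amount").
#' @param funded_only Restrict to funded videos (`amount > 0`); default
#'   `FALSE` keeps unfunded videos at amount 0.
#' @return Object of class `amount_fit`: `coefficients` (`estimate`,
#'   `se`, `t`, `p`), `AIC`, `adj_r_squared`, `n`, plus the `lm` fit.
#' @export
fit_amount_regression <- function(video_table, predictors,
                                  response = "amount",
                                  funded_only = FALSE) {
  dat <- as.data.frame(video_table)
  if (funded_only) dat <- dat[dat[[response]] > 0, ]
  if (nrow(dat) < 5) stop("need >= 5 videos", call. = FALSE)
  if (nrow(dat) <= length(predictors) + 1) {
    stop("too few videos for the number of predictors", call. = FALSE)
  }
  for (f in predictors) dat[[f]] <- standardize_predictor(dat[[f]])
  form <- stats::as.formula(paste(response, "~",
                                  paste(predictors, collapse = " + ")))
  fit <- lm(form, data = dat)
  sm <- summary(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      se = sm$coefficients[, 2],
                      t = sm$coefficients[, 3],
                      p = sm$coefficients[, 4], row.names = NULL)
  structure(list(coefficients = coefs, AIC = AIC(fit),
                 adj_r_squared = sm$adj.r.squared, n = nrow(dat),
                 fit = fit),
            class = "amount_fit")
}

#' @export
print.amount_fit <- function(x, ...) {
  cat(sprintf("<amount_fit> OLS on %d videos, AIC %.2f, adj R^2 %.3f\n",
              x$n, x$AIC, x$adj_r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}
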