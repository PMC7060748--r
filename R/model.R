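#' Mixed-effects nursing-versus-baseline comparison
#'
#' Fits a linear mixed model of a per-segment response (mean ODBA or
#' fluke-stroke rate) on nursing status, dive phase and their interaction,
#' with a random intercept per individual to account for repeated
#' measures:
#'
#' `response ~ nursing * phase, random = ~ 1 | individual`
#'
#' The nursing effect is reported as a marginal (Type III) Wald F test.
#' Dive phase enters with sum-to-zero contrasts so that, in the presence
#' of the interaction, the nursing term tests the nursing effect averaged
#' over phases (the standard Type III construction) rather than the
#' effect at an arbitrary reference phase. Denominator degrees of freedom
#' follow the within-group convention of nested mixed models,
#' `N - n_individuals - p_within` (for the published calf design of 116
#' segments over 4 deployments with 5 within-group fixed terms this gives
#' 107). Satterthwaite-style corrections are deliberately not applied;
#' the convention is an approximation and is documented as such.
#'
#' If the response is essentially constant (zero variance) the mixed
#' model is degenerate; estimates then come from the corresponding
#' fixed-effects least-squares fit (all contrasts 0) with the same df
#' convention.
#'
#' @param metrics Segment metrics data.frame (needs columns
#'   `deployment_id`, `phase`, `is_nursing`, and the response).
#' @param response Column to model: `"mean_odba"` or `"fsr"` (any numeric
#'   metrics column is accepted).
#' @return An object of class `comparison_result`: a list with the
#'   response name, fixed-effect `estimates`, `nursing_estimate`,
#'   `F` / `numdf` / `dendf` / `p` for the nursing effect,
#'   `ranef_var` (random-intercept variance), `resid_var` and
#'   `n_segments`.
#' @export
fit_nursing_model <- function(metrics, response = c("mean_odba", "fsr")) {
  response <- match.arg(response, choices = c("mean_odba", "fsr",
                                              setdiff(names(metrics), "")))
  df <- data.frame(y = metrics[[response]],
                   nursing = factor(metrics$is_nursing, levels = c(FALSE, TRUE)),
                   phase = droplevels(factor(metrics$phase)),
                   individual = factor(metrics$deployment_id))
  if (any(is.na(df$y))) stop("response contains missing values", call. = FALSE)
  if (nlevels(droplevels(df$nursing)) < 2L)
    stop("both nursing and non-nursing segments are required", call. = FALSE)
  if (nlevels(df$individual) < 2L)
    stop("at least two individuals are required for a random intercept",
         call. = FALSE)
  if (nlevels(df$phase) > 1L) {
    form <- y ~ nursing * phase
    stats::contrasts(df$phase) <- stats::contr.sum(nlevels(df$phase))
  } else {
    form <- y ~ nursing
  }
  p_within <- qr(stats::model.matrix(form, df))$rank - 1L
  dendf <- nrow(df) - nlevels(df$individual) - p_within

  if (stats::var(df$y) < 1e-16) {
    est <- stats::coef(stats::lm(form, data = df))
    res <- list(response = response, estimates = est,
                nursing_estimate = unname(est[["nursingTRUE"]]),
                F = 0, numdf = 1L, dendf = dendf, p = 1,
                ranef_var = 0, resid_var = 0, n_segments = nrow(df))
    class(res) <- "comparison_result"
    return(res)
  }

  fit <- nlme::lme(form, random = ~ 1 | individual, data = df,
                   method = "REML",
                   control = nlme::lmeControl(returnObject = TRUE))
  a <- stats::anova(fit, type = "marginal")
  vc <- nlme::VarCorr(fit)
  res <- list(response = response,
              estimates = nlme::fixef(fit),
              nursing_estimate = unname(nlme::fixef(fit)[["nursingTRUE"]]),
              F = unname(a["nursing", "F-value"]),
              numdf = unname(a["nursing", "numDF"]),
              dendf = unname(a["nursing", "denDF"]),
              p = unname(a["nursing", "p-value"]),
              ranef_var = suppressWarnings(as.numeric(vc["(Intercept)", "Variance"])),
              resid_var = fit$sigma^2,
              n_segments = nrow(df))
  class(res) <- "comparison_result"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: nursing effect %+.4f, F%d,%d = %.4f, p = %s\n",
              x$response, x$nursing_estimate, x$numdf, x$dendf, x$F,
              format.pval(x$p, digits = 4)))
  invisible(x)
}
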