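# Binomial random-intercept models of switch probability, likelihood-ratio
# interaction tests, and response-scale pairwise contrasts.

#' Fit the binomial switch-probability mixed model
#'
#' Restricts the segment table to analysable segments (single-switch or
#' maintained, mixed-free, with defined congruency), codes the response as
#' 1 = switched / 0 = maintained, and fits a logistic mixed model with fixed
#' factors condition and congruency (optionally their interaction) and a
#' random intercept per participant, via Laplace-approximated maximum
#' likelihood (`lme4::glmer`).
#'
#' @param segments output of [extract_segments()]; must contain exactly two
#'   condition levels after filtering.
#' @param include_interaction include the condition x congruency interaction
#'   (the full model); `FALSE` gives the nested reduced model.
#' @param condition_levels optional explicit ordering of the two condition
#'   levels (first level is the reference).
#' @return object of class `switch_glmm`: named fixed-effect `coefficients`
#'   on the logit scale with `coef_se` and `z_values`,
#'   `random_intercept_var`, `log_likelihood`, `df`, `n_obs`, `n_groups`,
#'   a `boundary` flag (singular zero-variance random effect), a
#'   `separation` flag (implausibly large coefficients), and the underlying
#'   `lme4` fit.
#' @export
fit_switch_model <- function(segments, include_interaction = TRUE,
                             condition_levels = NULL) {
  d <- segments[segments$outcome %in% c("maintained", "switched") &
                  segments$congruency %in% c("congruent", "incongruent"), ,
                drop = FALSE]
  if (nrow(d) == 0) stop("no analysable segments")
  d$switched <- as.integer(d$outcome == "switched")
  d$condition <- if (is.null(condition_levels)) factor(d$condition)
  else factor(d$condition, levels = condition_levels)
  d$congruency <- factor(d$congruency, levels = c("congruent", "incongruent"))
  d$participant_id <- factor(d$participant_id)
  if (nlevels(d$condition) != 2)
    stop("fit_switch_model expects exactly two condition levels, got ",
         nlevels(d$condition))
  form <- if (include_interaction)
    switched ~ condition * congruency + (1 | participant_id)
  else
    switched ~ condition + congruency + (1 | participant_id)
  fit <- lme4::glmer(form, data = d, family = stats::binomial("logit"),
                     control = lme4::glmerControl(optimizer = "bobyqa"))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  ll <- stats::logLik(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    coefficients = beta,
    coef_se = se,
    z_values = beta / se,
    random_intercept_var = vc$vcov[1],
    log_likelihood = as.numeric(ll),
    df = attr(ll, "df"),
    n_obs = stats::nobs(fit),
    n_groups = nlevels(d$participant_id),
    boundary = lme4::isSingular(fit),
    separation = any(abs(beta) > 10),
    include_interaction = include_interaction,
    fit = fit,
    data = d), class = "switch_glmm")
}

#' @method print switch_glmm
#' @export
print.switch_glmm <- function(x, ...) {
  cat(sprintf("switch_glmm (%s): %d segments, %d participants, logLik %.3f\n",
              if (x$include_interaction) "full" else "reduced",
              x$n_obs, x$n_groups, x$log_likelihood))
  print(round(cbind(estimate = x$coefficients, se = x$coef_se,
                    z = x$z_values), 4))
  cat(sprintf("random intercept variance: %.4g%s\n", x$random_intercept_var,
              if (x$boundary) " (boundary fit)" else ""))
  if (x$separation) cat("warning: possible complete separation\n")
  invisible(x)
}

#' Likelihood-ratio test of the condition x congruency interaction
#'
#' Compares the full (interaction) model against its reduced version on the
#' log-likelihood ratio: `chi2 = 2 * (llf - llr)` (clipped at zero),
#' referred to a chi-square distribution with 1 degree of freedom.
#'
#' @param full,reduced `switch_glmm` fits of the full and nested reduced
#'   model on the same data.
#' @return list with `chi2`, `df` and `p`.
#' @export
lrt_interaction <- function(full, reduced) {
  stopifnot(inherits(full, "switch_glmm"), inherits(reduced, "switch_glmm"))
  if (full$n_obs != reduced$n_obs)
    stop("models were fitted to different numbers of observations")
  if (!all(names(reduced$coefficients) %in% names(full$coefficients)))
    stop("models are not nested")
  df <- full$df - reduced$df
  if (df != 1L)
    stop("reduced model must have exactly one parameter fewer than the full model")
  chi2 <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Response-scale pairwise contrasts within each level of the other factor
#'
#' Estimated marginal means are formed on the response (probability) scale,
#' i.e. after the inverse logit, at the population level (random intercept
#' at its zero mean), and the two levels of one factor are contrasted within
#' each level of the other; standard errors come from the delta method and
#' tests are two-sided z-tests. No multiplicity correction is applied.
#'
#' @param fit a full `switch_glmm` (with interaction).
#' @param by factor whose levels condition the contrasts: `"condition"`
#'   (contrast congruent vs incongruent within each condition) or
#'   `"congruency"`.
#' @return data.frame with `level_pair`, the conditioning level,
#'   `estimate_prob_scale`, `se`, `z`, `p` and a `boundary` flag copied from
#'   the fit.
#' @export
pairwise_contrasts <- function(fit, by = c("condition", "congruency")) {
  stopifnot(inherits(fit, "switch_glmm"))
  by <- match.arg(by)
  other <- if (by == "condition") "congruency" else "condition"
  emm <- emmeans::emmeans(fit$fit,
                          specs = stats::as.formula(paste0("~", other, "|", by)),
                          regrid = "response")
  ct <- summary(emmeans::contrast(emm, method = "pairwise"), adjust = "none")
  ct <- as.data.frame(ct)
  out <- data.frame(level_pair = as.character(ct$contrast),
                    by_level = as.character(ct[[by]]),
                    estimate_prob_scale = ct$estimate,
                    se = ct$SE,
                    z = ct$z.ratio,
                    p = ct$p.value,
                    boundary = fit$boundary)
  names(out)[2] <- by
  out
}
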