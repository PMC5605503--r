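# The study's statistical analysis: logistic regression on trial-by-trial
# accuracy with a participant random intercept, Wald Z tests on the fixed
# effects. Estimation is delegated to lme4::glmer (Laplace by default,
# adaptive Gauss-Hermite via `nAGQ`); this module owns the model
# parameterisation, the internal covariate scaling and its exact
# back-transform, and the Wald/CI reporting.

# terms of the reference accuracy model, in reporting order
.fit_terms <- c("(Intercept)", "group", "age", "trial_type", "subtlety",
                "social", "nonsocial", "group:subtlety")

# model frame with numeric codings: group ASD=1/TD=0, trial type present=1,
# subtlety in raw degrees, condition dummies against baseline
.model_frame <- function(responses) {
  need <- c("participant_id", "group", "age", "condition", "subtlety",
            "chase_present", "correct")
  miss <- setdiff(need, names(responses))
  if (length(miss)) stop("responses are missing columns: ", paste(miss, collapse = ", "))
  data.frame(
    correct = as.integer(responses$correct),
    group = as.integer(as.character(responses$group) == "ASD"),
    age = responses$age,
    trial_type = as.integer(responses$chase_present),
    subtlety = responses$subtlety,
    social = as.integer(responses$condition == "social"),
    nonsocial = as.integer(responses$condition == "nonsocial"),
    participant_id = factor(responses$participant_id)
  )
}

#' Fit the random-intercept logistic accuracy model
#'
#' Maximises the marginal likelihood of
#' `correct ~ group + age + trial_type + subtlety + social + nonsocial +
#' group:subtlety + (1 | participant_id)`
#' (binomial, logit link) with the participant intercept integrated out --
#' Laplace approximation by default, adaptive Gauss-Hermite quadrature when
#' `nAGQ > 1`. Wald Z statistics, two-sided normal p-values and
#' `estimate +/- 1.96 * SE` confidence intervals are reported for every
#' fixed effect.
#'
#' Internally age is centred and subtlety rescaled before optimisation (raw
#' units put the optimisation badly off-scale); estimates and their
#' covariance are transformed back exactly, so all reported coefficients are
#' in raw units: logits per year of age, per degree of subtlety.
#'
#' @param responses data frame as produced by [simulate_study()] (columns
#'   `participant_id, group, age, condition, subtlety, chase_present,
#'   correct`).
#' @param formula optional alternative `lme4` formula on the coded columns
#'   (`group, age, trial_type, subtlety, social, nonsocial,
#'   participant_id`); when supplied, covariates are used untransformed.
#' @param nAGQ integrand quadrature order passed to [lme4::glmer()]; 1 =
#'   Laplace.
#' @param age_center,subtlety_scale internal scaling constants for the
#'   default model.
#' @return An object of class `chase_glmm_fit`: `fixed_effects` data frame
#'   (`term, estimate, se, z, p, ci_lo, ci_hi`), `sigma_u` (estimated
#'   random-intercept SD), `log_likelihood`, `converged`, `separation`
#'   (large-SE flag), `n_obs`, `n_participants`, and the underlying
#'   `glmerMod` as `model`.
#' @export
fit_random_intercept_logistic <- function(responses, formula = NULL, nAGQ = 1L,
                                          age_center = 14, subtlety_scale = 30) {
  mf <- .model_frame(responses)
  if (nlevels(mf$participant_id) < 2L) stop("need at least 2 participants")

  if (is.null(formula)) {
    mf$age_c <- mf$age - age_center
    mf$subtlety_s <- mf$subtlety / subtlety_scale
    form <- correct ~ group + age_c + trial_type + subtlety_s + social +
      nonsocial + group:subtlety_s + (1 | participant_id)
  } else form <- formula

  fit <- withCallingHandlers(
    lme4::glmer(form, data = mf, family = stats::binomial(),
                nAGQ = nAGQ, control = lme4::glmerControl(optimizer = "bobyqa")),
    warning = function(w) {
      if (grepl("failed to converge|unidentifiable|Rescale", conditionMessage(w)))
        invokeRestart("muffleWarning")
    },
    message = function(m) {
      if (grepl("singular", conditionMessage(m))) invokeRestart("muffleMessage")
    }
  )
  # a singular (sigma_u = 0 boundary) fit is a valid optimum, not a failure
  msgs <- fit@optinfo$conv$lme4$messages
  msgs <- msgs[!grepl("singular", msgs)]
  conv <- length(msgs) == 0L && fit@optinfo$conv$opt == 0L

  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  if (is.null(formula)) {
    # exact linear back-transform to raw units:
    # intercept_raw = b0 - age_center * b_age; subtlety terms divided by scale
    k <- length(beta)
    Tm <- diag(k)
    nm <- names(beta)
    Tm[1, which(nm == "age_c")] <- -age_center
    Tm[which(nm == "subtlety_s"), which(nm == "subtlety_s")] <- 1 / subtlety_scale
    Tm[which(nm == "group:subtlety_s"), which(nm == "group:subtlety_s")] <- 1 / subtlety_scale
    beta <- drop(Tm %*% beta)
    V <- Tm %*% V %*% t(Tm)
    names(beta) <- .fit_terms[match(nm, c("(Intercept)", "group", "age_c",
                                          "trial_type", "subtlety_s", "social",
                                          "nonsocial", "group:subtlety_s"))]
  }
  se <- sqrt(diag(V))
  z <- beta / se
  separation <- any(se > 50)
  fe <- data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
    ci_lo = unname(beta - 1.96 * se), ci_hi = unname(beta + 1.96 * se)
  )
  vc <- lme4::VarCorr(fit)
  structure(list(
    fixed_effects = fe,
    sigma_u = unname(attr(vc$participant_id, "stddev")),
    log_likelihood = as.numeric(stats::logLik(fit)),
    converged = conv, separation = separation,
    n_obs = nrow(mf), n_participants = nlevels(mf$participant_id),
    model = fit
  ), class = "chase_glmm_fit")
}

#' @export
print.chase_glmm_fit <- function(x, ...) {
  cat(sprintf("<chase_glmm_fit> %d obs, %d participants; sigma_u = %.3f; logLik = %.1f%s\n",
              x$n_obs, x$n_participants, x$sigma_u, x$log_likelihood,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(wald_table(x, warn_only = TRUE), row.names = FALSE)
  invisible(x)
}

#' Wald test table for a fitted accuracy model
#'
#' Formats the fixed effects as estimate (SE), Wald Z, p-value and 95%
#' confidence interval; p-values below 0.001 print as "<0.001".
#'
#' @param fit a `chase_glmm_fit`.
#' @param warn_only if `TRUE`, an unconverged fit gives a warning instead of
#'   an error.
#' @return data frame `term, estimate, se, z, p, p_label, ci_lo, ci_hi`.
#' @export
wald_table <- function(fit, warn_only = FALSE) {
  stopifnot(inherits(fit, "chase_glmm_fit"))
  if (!fit$converged) {
    msg <- "fit did not converge; Wald table is unreliable"
    if (warn_only) warning(msg) else stop(msg)
  }
  fe <- fit$fixed_effects
  fe$p_label <- ifelse(fe$p < 0.001, "<0.001", sprintf("%.3f", fe$p))
  fe[, c("term", "estimate", "se", "z", "p", "p_label", "ci_lo", "ci_hi")]
}
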