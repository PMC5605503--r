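# Generative side: a synthetic cohort and Bernoulli responses whose
# statistical structure is exactly what the accuracy GLMM assumes.

#' Sample a synthetic cohort of participants
#'
#' Draws `n_per_group` ASD and `n_per_group` TD adolescents. Ages come from
#' group-specific normal distributions (defaults: ASD mean 14.08, SD 1.47;
#' TD mean 14.33, SD 1.27) truncated to `age_range`; each participant gets a
#' random intercept `u ~ N(0, sigma_u)` on the logit scale.
#'
#' @param n_per_group participants per group.
#' @param params a [glmm_params()]; supplies `sigma_u`.
#' @param age_mean,age_sd named numeric vectors (`TD`, `ASD`), years.
#' @param age_range truncation bounds, years.
#' @param seed integer seed.
#' @return data frame `participant_id, group` (factor TD/ASD), `age,
#'   random_intercept`.
#' @export
sample_cohort <- function(n_per_group = 24, params = glmm_params(),
                          age_mean = c(TD = 14.33, ASD = 14.08),
                          age_sd = c(TD = 1.27, ASD = 1.47),
                          age_range = c(12, 16.5), seed = 1L) {
  stopifnot(n_per_group >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  rtruncnorm <- function(n, mean, sd) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(2L * n, mean, sd)
      out <- c(out, x[x >= age_range[1] & x <= age_range[2]])
    }
    out[seq_len(n)]
  }
  grp <- rep(c("TD", "ASD"), each = n_per_group)
  age <- c(rtruncnorm(n_per_group, age_mean["TD"], age_sd["TD"]),
           rtruncnorm(n_per_group, age_mean["ASD"], age_sd["ASD"]))
  data.frame(
    participant_id = sprintf("P%02d", seq_len(2L * n_per_group)),
    group = factor(grp, levels = c("TD", "ASD")),
    age = age,
    random_intercept = if (params$sigma_u == 0) rep(0, 2L * n_per_group) else
      stats::rnorm(2L * n_per_group, 0, params$sigma_u)
  )
}

#' Probability of a correct response on one trial
#'
#' Inverse-logit of the generative linear predictor: intercept + group
#' (ASD = 1) + age + trial type (chase-present = 1) + subtlety (degrees) +
#' condition dummies (baseline reference) + group x subtlety + the
#' participant's random intercept.
#'
#' @param profile one row (or several) of a [sample_cohort()] data frame;
#'   needs `group`, `age`, `random_intercept`.
#' @param trial one row (or several, matching `profile`) with `condition`,
#'   `subtlety`, `chase_present`.
#' @param params a [glmm_params()].
#' @return P(correct), numeric.
#' @examples
#' pr <- data.frame(group = "TD", age = 14, random_intercept = 0)
#' tr <- data.frame(condition = "baseline", subtlety = 45, chase_present = TRUE)
#' response_probability(pr, tr)  # plogis(-0.77) under the default parameters
#' @export
response_probability <- function(profile, trial, params = glmm_params()) {
  g <- as.integer(as.character(profile$group) == "ASD")
  s <- trial$subtlety
  eta <- params$beta_intercept +
    params$beta_group * g +
    params$beta_age * profile$age +
    params$beta_trialtype * as.integer(trial$chase_present) +
    params$beta_subtlety * s +
    params$beta_social * as.integer(trial$condition == "social") +
    params$beta_nonsocial * as.integer(trial$condition == "nonsocial") +
    params$beta_group_x_subtlety * g * s +
    profile$random_intercept
  stats::plogis(eta)
}

#' Simulate trial-by-trial responses for a whole study
#'
#' For every non-practice design row, draws `correct ~
#' Bernoulli(response_probability)` and derives the present/absent response
#' from `correct` and the trial's true type. A quadrant response (1-4,
#' counterclockwise from upper-right) is sampled for bookkeeping whenever the
#' response is "present"; it is never analysed.
#'
#' @param design a [build_design()] table covering every cohort member.
#' @param cohort a [sample_cohort()] data frame.
#' @param params a [glmm_params()].
#' @param seed integer seed.
#' @return data frame `participant_id, group, age, condition, subtlety,
#'   chase_present, response_present, correct, quadrant`.
#' @export
simulate_study <- function(design, cohort, params = glmm_params(), seed = 1L) {
  test <- design[!design$is_practice, ]
  if (!all(cohort$participant_id %in% test$participant_id) ||
      !all(test$participant_id %in% cohort$participant_id))
    stop("consistency error: design and cohort cover different participants")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  ix <- match(test$participant_id, cohort$participant_id)
  prof <- cohort[ix, ]
  p <- response_probability(prof, test, params)
  correct <- stats::rbinom(length(p), 1L, p) == 1L
  response_present <- ifelse(correct, test$chase_present, !test$chase_present)
  quadrant <- ifelse(response_present, sample.int(4L, length(p), replace = TRUE),
                     NA_integer_)
  data.frame(
    participant_id = test$participant_id,
    group = prof$group, age = prof$age,
    condition = test$condition, subtlety = test$subtlety,
    chase_present = test$chase_present,
    response_present = response_present,
    correct = correct, quadrant = quadrant
  )
}
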