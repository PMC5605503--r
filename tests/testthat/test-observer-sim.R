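# Generative response model and trajectory-based heuristic observers.

test_that("sample_cohort draws matched groups with truncated-normal ages", {
  co <- sample_cohort(24, seed = 3)
  expect_equal(nrow(co), 48)
  expect_equal(as.vector(table(co$group)), c(24, 24))
  expect_true(all(co$age >= 12 & co$age <= 16.5))

  co0 <- sample_cohort(10, glmm_params(sigma_u = 0), seed = 3)
  expect_true(all(co0$random_intercept == 0))

  # Monte-Carlo age means against the truncated-normal oracle
  # (scipy.stats.truncnorm on [12, 16.5]): ASD 14.15372, TD 14.30449
  big <- sample_cohort(10000, seed = 4)
  for (g in c("ASD", "TD")) {
    a <- big$age[big$group == g]
    target <- if (g == "ASD") 14.153717 else 14.304491
    expect_lt(abs(mean(a) - target), 3 * sd(a) / sqrt(length(a)))
  }
})

test_that("response_probability evaluates the generative logistic model", {
  null <- glmm_params(0, 0, 0, 0, 0, 0, 0, 0, sigma_u = 0)
  pr <- data.frame(group = "TD", age = 14, random_intercept = 0)
  tr <- data.frame(condition = "baseline", subtlety = 45, chase_present = TRUE)
  expect_equal(response_probability(pr, tr, null), 0.5)

  # default parameters: eta = -1.13 + 0.17*14 + 0.23 - 0.05*45 = -0.77
  # (independent logistic oracle: scipy expit(-0.77) = 0.3164791)
  expect_equal(response_probability(pr, tr), 0.3164791, tolerance = 1e-6)

  # ASD - TD contrast flips sign with subtlety: positive at 75 degrees
  pa <- data.frame(group = "ASD", age = 14, random_intercept = 0)
  t75 <- data.frame(condition = "baseline", subtlety = 75, chase_present = TRUE)
  t15 <- data.frame(condition = "baseline", subtlety = 15, chase_present = TRUE)
  expect_gt(response_probability(pa, t75), response_probability(pr, t75))
  expect_lt(response_probability(pa, t15), response_probability(pr, t15))
})

test_that("simulate_study yields one record per test trial with consistent coding", {
  resp <- quick_study(4, seed = 10)
  expect_equal(nrow(resp), 8 * 225)
  expect_true(all(resp$correct == (resp$response_present == resp$chase_present)))
  expect_true(all(is.na(resp$quadrant[!resp$response_present])))
  expect_true(all(resp$quadrant[resp$response_present] %in% 1:4))
  expect_identical(resp, quick_study(4, seed = 10))
  expect_error(simulate_study(build_design(2), sample_cohort(4), seed = 1),
               "consistency")
})

test_that("empirical accuracy converges to the generative probability per cell", {
  params <- glmm_params(sigma_u = 0)
  co <- sample_cohort(1, params, seed = 5)
  pr <- co[1, ]
  # many replicate draws of one participant's baseline/45/present cell
  d <- build_design(2, seed = 6)
  reps <- do.call(rbind, lapply(1:30, function(r)
    simulate_study(d, sample_cohort(1, params, seed = 5), params, seed = 100 + r)))
  cell <- reps[reps$participant_id == "P01" & reps$condition == "baseline" &
                 reps$subtlety == 45 & reps$chase_present, ]
  p_true <- response_probability(pr, cell[1, ], params)
  ci <- binom.test(sum(cell$correct), nrow(cell))$conf.int
  expect_true(p_true >= ci[1] && p_true <= ci[2])
})

test_that("generative accuracy decreases with subtlety and social beats baseline", {
  by_subt <- matrix(NA, 20, 3)
  soc_gt_base <- logical(20)
  for (r in 1:20) {
    resp <- quick_study(6, seed = 500 + 3 * r)
    by_subt[r, ] <- tapply(resp$correct, resp$subtlety, mean)
    cm <- tapply(resp$correct, resp$condition, mean)
    soc_gt_base[r] <- cm["social"] > cm["baseline"]
  }
  avg <- colMeans(by_subt)
  expect_true(avg[1] > avg[2] && avg[2] > avg[3])
  expect_gte(sum(soc_gt_base), 19)
})

test_that("chase statistics separate true pursuit from independent motion", {
  # perfect heat-seeking at a static target: alignment exactly 1
  st <- chase_statistics(straight_chase_traj(), c(1, 2))
  expect_equal(unname(st["heading_alignment"]), 1)
  expect_error(chase_statistics(simulate_trial(trial_spec("baseline", 15, FALSE, seed = 1)),
                                c(1, 5)), "invalid pair")

  # ordered distractor pairs in absent trials: mean alignment centred on 0
  al <- c()
  for (tr in sim_batch(100, 45, present = FALSE, seed_base = 4000)) {
    di <- which(tr$roles == "distractor")[1:2]
    al <- c(al, chase_statistics(tr, di)["heading_alignment"],
            chase_statistics(tr, rev(di))["heading_alignment"])
  }
  expect_lt(abs(mean(al)), 3 * sd(al) / sqrt(length(al)))

  # true wolf-sheep alignment is higher at subtlety 15 than 75
  a15 <- sapply(sim_batch(60, 15, TRUE, seed_base = 4300),
                function(tr) chase_statistics(tr, c(tr$wolf, tr$sheep))["heading_alignment"])
  a75 <- sapply(sim_batch(60, 75, TRUE, seed_base = 4400),
                function(tr) chase_statistics(tr, c(tr$wolf, tr$sheep))["heading_alignment"])
  expect_gt(mean(a15), mean(a75))
})

test_that("wolf update-event deviations reproduce the closed-form E[cos]", {
  for (s in c(15, 75)) {
    devs <- unlist(lapply(sim_batch(100, s, TRUE, seed_base = 5000 + s),
                          wolf_update_devs))
    theory <- sin(s * pi / 180) / (s * pi / 180)
    expect_equal(mean(cospi(devs / 180)), theory, tolerance = 0.02)
  }
})

test_that("heuristic observers show the subtlety effect and a monotone ROC", {
  score_of <- function(tr) max(pair_scores(tr)$score)
  # best achievable accuracy with a criterion calibrated per subtlety level
  best_acc_at <- function(s, seed_base) {
    pres <- sapply(sim_batch(60, s, TRUE, seed_base = seed_base), score_of)
    abs_ <- sapply(sim_batch(60, s, FALSE, seed_base = seed_base + 500), score_of)
    grid <- sort(c(pres, abs_))
    max(sapply(grid, function(cr) mean(c(pres > cr, abs_ <= cr))))
  }
  expect_gt(best_acc_at(15, 6200), best_acc_at(75, 6400))

  # criterion sweep traces a monotone ROC with AUC >= 0.5 at subtlety 15
  pres <- sapply(sim_batch(40, 15, TRUE, seed_base = 6600), score_of)
  abs_ <- sapply(sim_batch(40, 15, FALSE, seed_base = 6700), score_of)
  grid <- sort(c(pres, abs_))
  hit <- sapply(grid, function(cr) mean(pres > cr))
  fa <- sapply(grid, function(cr) mean(abs_ > cr))
  expect_true(all(diff(hit) <= 0) && all(diff(fa) <= 0))
  auc <- mean(outer(pres, abs_, ">")) + 0.5 * mean(outer(pres, abs_, "=="))
  expect_gte(auc, 0.5)

  # degenerate criterion: always respond absent
  tr <- simulate_trial(trial_spec("baseline", 15, TRUE, seed = 1))
  r <- heuristic_observer_response(tr, params = observer_params(0, 0, 0, Inf))
  expect_false(r$response_present)
  expect_false(r$correct)
})

test_that("an informative gaze cue cannot hurt the observer on social trials", {
  for (s in c(15, 75)) {
    n <- 40
    base_scores_p <- numeric(n); base_scores_a <- numeric(n)
    cue_scores_p <- numeric(n); cue_scores_a <- numeric(n)
    pars <- observer_params(w_alignment = 1, w_cue = 1)
    for (k in 1:n) {
      trp <- simulate_trial(trial_spec("social", s, TRUE, seed = 8000 + s * 10 + k))
      tra <- simulate_trial(trial_spec("social", s, FALSE, seed = 8500 + s * 10 + k))
      base_scores_p[k] <- max(pair_scores(trp)$score)
      base_scores_a[k] <- max(pair_scores(tra)$score)
      cue_scores_p[k] <- max(pair_scores(trp, eye_track(trp), pars)$score)
      cue_scores_a[k] <- max(pair_scores(tra, eye_track(tra), pars)$score)
    }
    best_acc <- function(p, a) {
      grid <- sort(c(p, a))
      max(sapply(grid, function(cr) mean(c(p > cr, a <= cr))))
    }
    expect_gte(best_acc(cue_scores_p, cue_scores_a),
               best_acc(base_scores_p, base_scores_a))
  }
})
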