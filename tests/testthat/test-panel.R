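# Long-form score table with all five dimensions for the given doctor-weeks.
make_scores <- function(doctor_id, weeks, value = 0.1) {
  tidyr::crossing(doctor_id = doctor_id, week = weeks, dimension = DIMENSIONS) |>
    dplyr::mutate(score = value + seq_along(week) * 0.001)
}

test_that("panel construction aligns lagged scores with demand", {
  scores <- make_scores("d1", 1:3)
  demand <- tibble::tibble(doctor_id = "d1", week = 2:4, y = c(1, 2, 3))
  panel <- build_panel(scores, demand, lag = 1)
  expect_identical(panel$week, 2:4)
  wide <- tidyr::pivot_wider(scores, names_from = "dimension", values_from = "score")
  expect_equal(panel$expertise, wide$expertise[match(panel$week - 1L, wide$week)])

  # demand in week 4 kept only because week-3 scores exist
  scores2 <- make_scores("d1", 1:2)
  panel2 <- build_panel(scores2, demand, lag = 1)
  expect_identical(panel2$week, 2:3)

  # count control 0 -> log control 0
  controls <- tibble::tibble(doctor_id = "d1", votes = 0)
  panel3 <- build_panel(scores, demand, controls, count_controls = "votes")
  expect_equal(panel3$log_votes, rep(0, 3))

  expect_error(build_panel(scores, dplyr::bind_rows(demand, demand[1, ])),
               "duplicate")
})

test_that("panel row count equals an independent join oracle", {
  cfg <- generator_config(n_doctors = 50, n_weeks = 10, seed = 16)
  p <- generate_panel(cfg, seed = 16)
  scores <- tidyr::pivot_longer(p$truth[c("doctor_id", "week", DIMENSIONS)],
                                dplyr::all_of(DIMENSIONS),
                                names_to = "dimension", values_to = "score")
  # drop a random 10% of score rows to create missing weeks
  set.seed(17)
  scores_holey <- scores[-sample(nrow(scores), nrow(scores) %/% 10), ]
  panel <- build_panel(scores_holey, p$demand)

  # oracle: count (doctor, t) pairs where demand t exists and all 5 scores
  # exist at t - 1
  complete_keys <- names(which(table(paste(scores_holey$doctor_id, scores_holey$week)) == 5L))
  demand_keys <- paste(p$demand$doctor_id, p$demand$week - 1L)
  expect_identical(nrow(panel), sum(demand_keys %in% complete_keys))
})

test_that("two-way FE recovers exact coefficients from noiseless data", {
  cfg <- generator_config(n_doctors = 30, n_weeks = 8, noise_sd = 0, seed = 18)
  p <- generate_panel(cfg, seed = 18)
  panel <- dplyr::bind_cols(p$demand, p$truth[DIMENSIONS])
  fit <- fit_fe(panel)
  expect_equal(unname(fit$coefficients$estimate), unname(cfg$gamma[DIMENSIONS]),
               tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("estimates and clustered SEs are invariant to row permutations", {
  cfg <- generator_config(n_doctors = 20, n_weeks = 6, seed = 19)
  p <- generate_panel(cfg, seed = 19)
  panel <- dplyr::bind_cols(p$demand, p$truth[DIMENSIONS])
  set.seed(20)
  shuffled <- panel[sample(nrow(panel)), ]
  f1 <- fit_fe(panel)
  f2 <- fit_fe(shuffled)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate, tolerance = 1e-10)
  expect_equal(f1$coefficients$se, f2$coefficients$se, tolerance = 1e-10)
})

test_that("within estimator equals dummy-variable OLS with the CR1 sandwich", {
  cfg <- generator_config(n_doctors = 20, n_weeks = 6, seed = 21)
  p <- generate_panel(cfg, seed = 21)
  panel <- dplyr::bind_cols(p$demand, p$truth[DIMENSIONS])
  fit <- fit_fe(panel)
  oracle <- oracle_twfe(panel, DIMENSIONS)
  expect_equal(unname(fit$coefficients$estimate), unname(oracle$coef), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients$se), unname(oracle$se), tolerance = 1e-8)
  expect_equal(fit$r_squared, oracle$r2, tolerance = 1e-8)

  # independent covariance route via the sandwich package
  skip_if_not_installed("sandwich")
  df <- as.data.frame(panel)
  lmfit <- stats::lm(y ~ expertise + process + attitude + empathy + outcome +
                       factor(doctor_id) + factor(week), data = df)
  Vcl <- sandwich::vcovCL(lmfit, cluster = df$doctor_id, type = "HC1")
  expect_equal(unname(fit$coefficients$se),
               unname(sqrt(diag(Vcl))[DIMENSIONS]), tolerance = 1e-8)
})

test_that("pooled week-FE mode keeps time-invariant controls; twoway drops them", {
  cfg <- generator_config(n_doctors = 25, n_weeks = 6, seed = 22,
                          control_effects = c(chronic = -0.14, gender = 0.045))
  p <- generate_panel(cfg, include_controls = TRUE, seed = 22)
  panel <- dplyr::bind_cols(p$demand, p$truth[DIMENSIONS])
  panel <- dplyr::inner_join(panel, p$controls[c("doctor_id", "chronic", "gender")],
                             by = "doctor_id")
  expect_message(
    fit_tw <- fit_fe(panel, controls = c("chronic", "gender"), mode = "twoway_fe"),
    class = "hsq5d_fe_dropped"
  )
  expect_identical(sort(fit_tw$dropped), c("chronic", "gender"))
  expect_false(any(c("chronic", "gender") %in% fit_tw$coefficients$term))

  fit_pool <- fit_fe(panel, controls = c("chronic", "gender"), mode = "pooled_weekfe")
  expect_true(all(c("chronic", "gender") %in% fit_pool$coefficients$term))
  expect_true(all(fit_pool$coefficients$se > 0))
})

test_that("rank-deficient designs fail loudly, naming the collinear column", {
  cfg <- generator_config(n_doctors = 10, n_weeks = 5, seed = 23)
  p <- generate_panel(cfg, seed = 23)
  panel <- dplyr::bind_cols(p$demand, p$truth[DIMENSIONS])
  panel$dup <- panel$expertise
  expect_error(fit_fe(panel, dims = c(DIMENSIONS, "dup")), "dup")
})

test_that("one-SD marginal effects reproduce the worked arithmetic", {
  me <- marginal_effect(c(1.1189, 5.5977, 0), c(0.0252, 0.0210, 0.5))
  expect_equal(round(me$log_effect[1], 2), 0.03)
  expect_equal(round(me$pct_effect[1], 1), 2.9)
  expect_equal(round(me$log_effect[2], 2), 0.12)
  expect_equal(round(me$pct_effect[2], 1), 12.5)
  expect_equal(me$pct_effect[3], 0)
  expect_error(marginal_effect(1, -0.1))

  # small-effect limit: exp(gs) - 1 ~ gs within 1% relative error
  gs <- c(seq(-0.009, -0.001, by = 0.001), seq(0.001, 0.009, by = 0.001))
  pct <- marginal_effect(gs, 1)$pct_effect / 100
  expect_true(all(abs(pct - gs) / abs(gs) < 0.01))
})

test_that("stepwise R-squared is monotone and flat under redundancy", {
  cfg <- generator_config(n_doctors = 20, n_weeks = 8, seed = 24)
  p <- generate_panel(cfg, seed = 24)
  panel <- dplyr::bind_cols(p$demand, p$truth[DIMENSIONS])
  sw <- stepwise_r2(panel)
  expect_identical(nrow(sw), 6L)
  expect_true(all(diff(sw$r_squared) >= -1e-12))
  # the strongest generating regressor adds variance on noisy data
  expect_gt(sw$r_squared[6], sw$r_squared[1])

  # adding a duplicate of an existing regressor changes nothing
  panel$dup <- panel$process
  sw_dup <- stepwise_r2(panel, order = c("process", "dup"))
  expect_equal(sw_dup$r_squared[3], sw_dup$r_squared[2], tolerance = 1e-12)

  # monotonicity over many random small panels
  for (s in 1:100) {
    cfg_s <- generator_config(n_doctors = 8, n_weeks = 4, noise_sd = 1, seed = s)
    ps <- generate_panel(cfg_s, seed = s)
    pan <- dplyr::bind_cols(ps$demand, ps$truth[DIMENSIONS])
    expect_true(all(diff(stepwise_r2(pan)$r_squared) >= -1e-10))
  }
})

test_that("censoring trims the configured tails deterministically", {
  panel <- tibble::tibble(doctor_id = "d", week = 1:100, y = sample(1:100))
  expect_identical(censor_dependent(panel, 0), panel)
  kept <- censor_dependent(panel, 0.10)
  expect_setequal(kept$y, 11:90)
  # original row order is preserved
  expect_identical(kept$y, panel$y[panel$y %in% 11:90])

  # sort-and-slice oracle on a random panel with ties
  set.seed(25)
  rnd <- tibble::tibble(doctor_id = "d", week = 1:57, y = sample(1:20, 57, TRUE))
  f <- 0.1
  n_drop <- floor(f * nrow(rnd))
  ord <- order(rnd$y)
  keep_idx <- sort(ord[(n_drop + 1):(nrow(rnd) - n_drop)])
  expect_identical(censor_dependent(rnd, f)$y, rnd$y[keep_idx])
})

test_that("clustered SEs shrink roughly as one over root G", {
  mean_se <- function(G, reps = 6) {
    mean(sapply(seq_len(reps), function(r) {
      cfg <- generator_config(n_doctors = G, n_weeks = 8, noise_sd = 1,
                              doctor_fe_sd = 0, week_fe_sd = 0, seed = 1000 * G + r)
      p <- generate_panel(cfg, seed = 1000 * G + r)
      panel <- dplyr::bind_cols(p$demand, p$truth[DIMENSIONS])
      mean(fit_fe(panel)$coefficients$se)
    }))
  }
  ratio <- mean_se(30) / mean_se(120)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
})
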