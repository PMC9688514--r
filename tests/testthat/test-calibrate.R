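make_synthetic_record <- function(kp, days, noise_sigma = 0, seed = NULL,
                                  dose = 1e8, threshold = 2.5e6, dt = 0.01) {
  traj <- simulate_kinetics(kp, dose, t_end = max(days) + 1, dt = dt,
                            output_times = sort(unique(c(0, days))))
  value <- stats::approx(traj$time, traj$C, xout = days)$y
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    value <- value * 10^rnorm(length(days), 0, noise_sigma)
  }
  patient_record("SYN", tibble::tibble(day = days, value = value),
                 schedule = dose, detection_threshold = threshold)
}

test_that("loss is near zero for the generating parameters", {
  kp <- textbook_params()
  rec <- make_synthetic_record(kp, textbook_sampling())
  expect_lt(as.numeric(residual_loss(kp, rec, dt = 0.01)), 1e-8)
})

test_that("loss ignores censored observations entirely", {
  kp <- textbook_params()
  rec <- make_synthetic_record(kp, c(1, 3, 7, 14, 28, 60, 90, 180, 250))
  rec$observations$censored[c(2, 8)] <- TRUE
  l1 <- residual_loss(kp, rec, dt = 0.01)
  rec2 <- rec
  rec2$observations$value[c(2, 8)] <- rec2$observations$value[c(2, 8)] * 1e3
  l2 <- residual_loss(kp, rec2, dt = 0.01)
  expect_identical(as.numeric(l1), as.numeric(l2))
})

test_that("a uniform factor-10 offset costs exactly one squared decade per point", {
  kp <- textbook_params()
  days <- c(1, 3, 7, 14, 28, 60)
  rec <- make_synthetic_record(kp, days)
  rec$observations$value <- rec$observations$value * 10
  n <- sum(!rec$observations$censored)
  expect_equal(as.numeric(residual_loss(kp, rec, dt = 0.01)), n * 1.0,
               tolerance = 1e-6)
})

test_that("an underflowing model count is penalized finitely and flagged", {
  # no engraftment: the whole CAR-T population is the decaying infusion and
  # is effectively extinct by day 30
  kp <- update_params(textbook_params(), eta = 0)
  rec <- patient_record("Z", tibble::tibble(day = c(30, 60), value = c(1e7, 1e7)),
                        schedule = 1e2)
  l <- residual_loss(kp, rec, dt = 0.01)
  expect_true(is.finite(as.numeric(l)))
  expect_gt(as.numeric(l), 100)
  expect_true(attr(l, "flagged"))
})

test_that("free parameters are recovered from dense noise-free data", {
  kp <- textbook_params()
  rec <- make_synthetic_record(kp, textbook_sampling())
  init <- update_params(kp, beta = 1.2, p1 = 2.2, delta = 0.15, mu = 0.02)
  fit <- fit_patient(rec, init = init, free = c("beta", "p1", "delta", "mu"),
                     n_starts = 2, seed = 11, dt = 0.02)
  for (p in c("beta", "p1", "delta", "mu")) {
    expect_lt(abs(fit$params[[p]] - kp[[p]]) / kp[[p]], 0.05)
  }
  expect_lte(fit$loss, fit$init_loss)
})

test_that("fits are deterministic under a fixed seed", {
  kp <- textbook_params()
  rec <- make_synthetic_record(kp, c(1, 3, 7, 10, 14, 21, 28, 60, 90, 180),
                               noise_sigma = 0.2, seed = 401)
  f1 <- fit_patient(rec, free = c("beta", "delta"), n_starts = 3, seed = 5,
                    dt = 0.05)
  f2 <- fit_patient(rec, free = c("beta", "delta"), n_starts = 3, seed = 5,
                    dt = 0.05)
  expect_identical(params_vector(f1$params), params_vector(f2$params))
  expect_identical(f1$loss, f2$loss)
})

test_that("an already-optimal start is not made worse", {
  kp <- textbook_params()
  rec <- make_synthetic_record(kp, c(1, 3, 7, 14, 28, 60, 120))
  fit <- fit_patient(rec, init = kp, free = c("beta", "delta"),
                     n_starts = 2, seed = 2, dt = 0.01)
  expect_lte(fit$loss, as.numeric(residual_loss(kp, rec, dt = 0.01)) + 1e-10)
  for (p in c("beta", "delta"))
    expect_lt(abs(fit$params[[p]] - kp[[p]]) / kp[[p]], 0.02)
})

test_that("goodness of fit reports zero for a perfect fit and 1 dex for 10x", {
  kp <- textbook_params()
  rec <- make_synthetic_record(kp, c(1, 7, 28, 90))
  traj <- simulate_kinetics(kp, 1e8, t_end = 91, dt = 0.01,
                            output_times = c(0, 1, 7, 28, 90, 91))
  g0 <- goodness_of_fit(rec, traj)
  expect_lt(g0$rmse_log10, 1e-4)
  rec10 <- rec
  rec10$observations$value <- rec10$observations$value * 10
  g10 <- goodness_of_fit(rec10, traj)
  expect_equal(g10$rmse_log10, 1, tolerance = 1e-4)
  expect_equal(g10$max_abs_log10, 1, tolerance = 1e-4)
})

test_that("log-RMSE concentrates near the injected noise level", {
  kp <- textbook_params()
  days <- textbook_sampling()
  traj <- simulate_kinetics(kp, 1e8, t_end = 251, dt = 0.01, output_dt = 0.05)
  model_c <- stats::approx(traj$time, traj$C, xout = days)$y
  set.seed(402)
  ok <- 0
  n_rep <- 200
  for (i in 1:n_rep) {
    rec <- patient_record("N", tibble::tibble(
      day = days, value = model_c * 10^rnorm(length(days), 0, 0.2)),
      schedule = 1e8)
    g <- goodness_of_fit(rec, traj)
    if (g$rmse_log10 >= 0.1 && g$rmse_log10 <= 0.3) ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("tidy and glance expose the fit in broom style", {
  kp <- textbook_params()
  rec <- make_synthetic_record(kp, c(1, 3, 7, 14, 28, 60))
  fit <- fit_patient(rec, init = kp, free = c("beta", "delta"),
                     n_starts = 1, seed = 1, dt = 0.05)
  td <- tidy(fit)
  expect_equal(nrow(td), 19)
  expect_equal(sum(td$free), 2)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("loss", "converged", "rmse_log10") %in% names(gl)))
})

test_that("outcome penalty pulls unconstrained late dynamics toward the label", {
  kp <- textbook_params()
  # only early observations: late dynamics unconstrained by kinetics
  rec <- make_synthetic_record(kp, c(1, 3, 7, 10, 14))
  rec$outcome <- "CR"
  rec$followup_day <- 365
  fit <- fit_patient(rec, init = kp, free = c("p1", "delta"),
                     n_starts = 1, seed = 3, dt = 0.05, outcome_weight = 1)
  traj <- simulate_kinetics(fit$params, rec$schedule, T0 = rec$T0,
                            t_end = 365, dt = 0.01, output_dt = 1)
  t_fu <- traj$T[which.min(abs(traj$time - 365))]
  expect_equal(classify_outcome(max(t_fu, 1e-30), rec$T0,
                                rec$detection_threshold), "CR")
})
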