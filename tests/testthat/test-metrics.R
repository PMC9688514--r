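constant_traj <- function(levels = c(CD = 2, CT = 3, CM = 4, CE = 1),
                          T_level = 1e7, t_end = 100, by = 0.5) {
  tt <- seq(0, t_end, by = by)
  traj <- tibble::tibble(time = tt,
                         CD = levels[["CD"]], CT = levels[["CT"]],
                         CM = levels[["CM"]], CE = levels[["CE"]],
                         T = T_level)
  traj$C <- traj$CD + traj$CT + traj$CM + traj$CE
  traj$CF <- traj$CD + traj$CT
  class(traj) <- c("carkin_trajectory", class(tibble::tibble()))
  traj
}

test_that("AUC of constant levels is level times horizon", {
  traj <- constant_traj(c(CD = 5, CT = 0, CM = 0, CE = 0))
  a <- auc_by_phenotype(traj, 28)
  expect_equal(a$auc[a$phenotype == "CD"], 140)
  expect_equal(a$auc[a$phenotype == "total"], 140)
  expect_error(auc_by_phenotype(traj, 1000), "beyond trajectory end")
})

test_that("AUC of an exponential decay matches the closed-form integral", {
  # trapezoid error on the 0.1-day grid is ~(k h)^2/12, so a moderate decay
  # rate keeps the quadrature within 1e-4 of the closed form
  kp <- update_params(textbook_params(), gamma = 0, theta = 0, alpha = 0,
                      eta = 1e-7, beta = 0.3)
  traj <- simulate_kinetics(kp, 1e8, T0 = 0, t_end = 30, dt = 1e-3)
  a <- auc_by_phenotype(traj, 28)
  k <- kp$beta + kp$eta
  closed <- 1e8 * (1 - exp(-k * 28)) / k
  expect_equal(a$auc[a$phenotype == "CD"], closed, tolerance = 1e-4)
})

test_that("phenotype AUCs sum to the total AUC", {
  traj <- simulate_kinetics(textbook_params(), 1e8, t_end = 100, dt = 0.01)
  a <- auc_by_phenotype(traj, 90)
  expect_equal(sum(a$auc[a$phenotype != "total"]),
               a$auc[a$phenotype == "total"], tolerance = 1e-12)
})

test_that("AUCs are additive across horizons", {
  traj <- simulate_kinetics(textbook_params(), 1e8, t_end = 100, dt = 0.01)
  a28 <- auc_by_phenotype(traj, 28)
  a60 <- auc_by_phenotype(traj, 60)
  # AUC over [28, 60] computed independently on the same grid
  seg <- traj[traj$time >= 28 & traj$time <= 60, ]
  mid <- sum(diff(seg$time) * (head(seg$C, -1) + tail(seg$C, -1)) / 2)
  expect_equal(a28$auc[a28$phenotype == "total"] + mid,
               a60$auc[a60$phenotype == "total"], tolerance = 1e-12)
})

test_that("non-exhausted fraction follows its definition", {
  a <- auc_by_phenotype(constant_traj(c(CD = 1, CT = 1, CM = 1, CE = 1)), 28)
  expect_equal(non_exhausted_fraction(a), 0.75)
  a0 <- auc_by_phenotype(constant_traj(c(CD = 1, CT = 2, CM = 3, CE = 0)), 28)
  expect_equal(non_exhausted_fraction(a0), 1)
  ae <- auc_by_phenotype(constant_traj(c(CD = 0, CT = 0, CM = 0, CE = 4)), 28)
  expect_equal(non_exhausted_fraction(ae), 0)
})

test_that("peak summary reports the earliest maximum and the dose ratio", {
  traj <- constant_traj()
  traj <- traj[traj$time <= 30, ]
  traj$CT <- ifelse(traj$time >= 10 & traj$time <= 12, 5e9, 1e6)
  traj$C <- traj$CD + traj$CT + traj$CM + traj$CE
  pk <- peak_summary(traj, dose = 1e8)
  expect_equal(pk$t_peak, 10) # plateaued maximum -> earliest grid time
  expect_equal(pk$peak_dose_ratio, pk$C_peak / 1e8)
  expect_equal(pk$peak_dose_ratio, 50, tolerance = 1e-6)
  expect_equal(pk$CT, 5e9)
})

test_that("relapse is detected at the constructed up-crossing", {
  tt <- seq(0, 400, 1)
  Tv <- ifelse(tt < 30, 1e7 * exp(-0.3 * tt),
               1e3 * exp(0.052 * (tt - 30)))   # re-crosses 2.5e6 near day 180
  traj <- tibble::tibble(time = tt, CD = 0, CT = 0, CM = 1e5, CE = 0, T = Tv)
  traj$C <- traj$CM; traj$CF <- 0
  class(traj) <- c("carkin_trajectory", class(tibble::tibble()))
  res <- theoretical_relapse(traj, threshold = 2.5e6, t_max = 400)
  t_cross <- 30 + log(2.5e6 / 1e3) / 0.052
  expect_lt(abs(res$t_TR - t_cross), 1.0)
  expect_true(is.na(res$reason))
  expect_equal(res$CM, 1e5)
})

test_that("monotone tumor decay reports no recurrence", {
  tt <- seq(0, 20000, 10)
  traj <- tibble::tibble(time = tt, CD = 0, CT = 0, CM = 0, CE = 0,
                         T = 1e7 * exp(-0.01 * tt))
  traj$C <- 0; traj$CF <- 0
  class(traj) <- c("carkin_trajectory", class(tibble::tibble()))
  res <- theoretical_relapse(traj, threshold = 2.5e6, t_max = 20000)
  expect_true(is.na(res$t_TR))
  expect_equal(res$reason, "no_recurrence")
})

test_that("sustained sub-threshold oscillations report a limit cycle", {
  tt <- seq(0, 20000, 10)
  # settle below threshold, then oscillate with constant amplitude
  Tv <- ifelse(tt < 100, 1e7 * exp(-0.1 * tt),
               1e5 * (1 + 0.8 * sin(2 * pi * (tt - 100) / 700)))
  traj <- tibble::tibble(time = tt, CD = 0, CT = 0, CM = 0, CE = 0, T = Tv)
  traj$C <- 0; traj$CF <- 0
  class(traj) <- c("carkin_trajectory", class(tibble::tibble()))
  res <- theoretical_relapse(traj, threshold = 2.5e6, t_max = 20000)
  expect_true(is.na(res$t_TR))
  expect_equal(res$reason, "limit_cycle")
  # damped oscillations are a plain decay, not a cycle
  Tv2 <- ifelse(tt < 100, 1e7 * exp(-0.1 * tt),
                1e5 * exp(-(tt - 100) / 4000) *
                  (1 + 0.8 * sin(2 * pi * (tt - 100) / 700)))
  traj$T <- Tv2
  res2 <- theoretical_relapse(traj, threshold = 2.5e6, t_max = 20000)
  expect_equal(res2$reason, "no_recurrence")
})

test_that("a tumor that never remits reports no_remission with a warning", {
  tt <- seq(0, 100, 1)
  traj <- tibble::tibble(time = tt, CD = 0, CT = 0, CM = 0, CE = 0,
                         T = 1e7 * exp(0.01 * tt))
  traj$C <- 0; traj$CF <- 0
  class(traj) <- c("carkin_trajectory", class(tibble::tibble()))
  expect_warning(res <- theoretical_relapse(traj, threshold = 2.5e6,
                                            t_max = 100),
                 "no remission")
  expect_equal(res$reason, "no_remission")
})

test_that("outcome classes reproduce the printed boundaries for T0 = 1e7", {
  expect_equal(classify_outcome(1e6, 1e7, 2.5e6), "CR")
  expect_equal(classify_outcome(4e6, 1e7, 2.5e6), "PR")
  expect_equal(classify_outcome(1e7, 1e7, 2.5e6), "SD")
  expect_equal(classify_outcome(2e7, 1e7, 2.5e6), "PD")
  # boundary values: half-open convention
  expect_equal(classify_outcome(2.5e6, 1e7, 2.5e6), "PR")  # = threshold
  expect_equal(classify_outcome(5e6 - 1, 1e7, 2.5e6), "PR")
  expect_equal(classify_outcome(5e6, 1e7, 2.5e6), "SD")    # = 0.5 T0
  expect_equal(classify_outcome(1.5e7, 1e7, 2.5e6), "SD")  # = 1.5 T0
  expect_equal(classify_outcome(1.5e7 + 1, 1e7, 2.5e6), "PD")
})

test_that("every positive burden maps to exactly one outcome class", {
  set.seed(501)
  Tv <- 10^runif(200, -2, 12)
  T0 <- 10^runif(200, 5, 9)
  thr <- 10^runif(200, 4, 7)
  for (i in seq_along(Tv)) {
    lab <- classify_outcome(Tv[i], T0[i], thr[i])
    expect_true(lab %in% c("CR", "PR", "SD", "PD"))
  }
})

test_that("kinetic summary bundles AUCs, peak, engraftment and relapse", {
  kp <- textbook_params()
  traj <- simulate_kinetics(kp, 1e8, t_end = 100, dt = 0.01)
  ks <- kinetic_summary(traj, t_max = 1000)
  expect_equal(nrow(ks$auc), 15)
  expect_true(all(ks$non_exhausted$fraction >= 0 &
                  ks$non_exhausted$fraction <= 1))
  expect_equal(ks$EC, engrafted_cells(kp, 1e8))
  expect_gt(ks$peak$t_peak, 3)
  # tumor is eradicated deeply, then regrows past threshold within 1000 d
  expect_false(is.na(ks$relapse$t_TR))
})
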