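# random valid parameter set: jitters every rate log-uniformly within a
# factor `spread` of the textbook values, keeping mu < xi by construction
random_params <- function(spread = 3) {
  base <- params_vector(textbook_params())
  f <- exp(stats::runif(length(base), -log(spread), log(spread)))
  v <- as.list(base * f)
  v$mu <- min(v$mu, 0.5 * v$xi)
  do.call(carkin_params, v)
}

# the committed dense observation series of the textbook trajectory
textbook_series <- function(noise_sigma = 0, t_end = 250, dt = 1e-3) {
  kp <- textbook_params()
  tr <- simulate_kinetics(kp, 1e8, t_end = t_end, dt = dt)
  days <- textbook_sampling()
  value <- stats::approx(tr$time, tr$C, xout = days)$y
  if (noise_sigma > 0)
    value <- value * 10^stats::rnorm(length(days), 0, noise_sigma)
  tibble::tibble(day = days, value = value)
}

# exact piecewise log-linear series with the four canonical phases
piecewise_series <- function(breaks = c(5, 14, 45),
                             slopes = c(-1.0, 0.9, -0.25, -0.01),
                             days = c(seq(0, 30, 0.5), seq(31, 120, 1)),
                             start_log = log(1e8)) {
  lv <- numeric(length(days))
  for (i in seq_along(days)) {
    d <- days[i]
    seg_ends <- c(breaks, Inf)
    lv[i] <- start_log
    prev <- 0
    for (s in seq_along(seg_ends)) {
      hi <- min(d, seg_ends[s])
      if (hi > prev) lv[i] <- lv[i] + slopes[s] * (hi - prev)
      prev <- seg_ends[s]
      if (d <= prev) break
    }
  }
  tibble::tibble(day = days, value = exp(lv))
}
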