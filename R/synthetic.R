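# Log-uniform priors per archetype. Shared (archetype-independent) ranges
# first; the archetype blocks control expansion strength, exhaustion,
# expansion-plateau duration and persistence, which is what separates CR-,
# PR- and SD-like kinetics: complete responders expand strongly with little
# exhaustion (deep, durable tumor kill), stable-disease kinetics expand
# weakly and exhaust quickly (shallow, transient kill).
default_priors <- function() {
  shared <- list(
    beta = c(0.8, 2.5), eta = c(3e-4, 3e-3), p3 = c(3, 6),
    A = c(5e3, 5e4), epsilon = c(0.003, 0.01),
    theta = c(1e-11, 1e-9), alpha = c(1e-13, 1e-11)
  )
  # All archetypes expand well beyond the infused dose; they differ in
  # exhaustion (lambda), expansion strength/duration (p1, p2, xi) and in the
  # cytotoxic access of the functional cells (half-saturation a): stable
  # disease corresponds to CAR-T that expand but barely dent the tumor.
  list(
    CR = c(shared, list(p1 = c(2.5, 3.6), lambda = c(0.08, 0.25),
                        xi = c(0.6, 1.0), p2 = c(0.04, 0.08),
                        a = c(3e8, 3e9),
                        delta = c(0.12, 0.3), mu = c(0.005, 0.02))),
    PR = c(shared, list(p1 = c(2.2, 3.0), lambda = c(0.4, 0.8),
                        xi = c(0.5, 0.9), p2 = c(0.06, 0.12),
                        a = c(1e9, 8e9),
                        delta = c(0.15, 0.35), mu = c(0.01, 0.04))),
    SD = c(shared, list(p1 = c(2.2, 2.8), lambda = c(0.8, 1.2),
                        xi = c(0.4, 0.6), p2 = c(0.08, 0.2),
                        a = c(1e9, 6e9),
                        delta = c(0.2, 0.45), mu = c(0.02, 0.08)))
  )
}

#' Synthetic cohort configuration
#'
#' Describes a virtual patient cohort with the statistical structure of
#' published CAR-T time courses: sparse irregular sampling over months,
#' multiplicative lognormal measurement noise, left-censoring at the assay
#' detection threshold, single or 3-day split dosing, and per-archetype
#' parameter priors producing CR-, PR- and SD-like kinetics.
#'
#' @param n_patients Number of patients.
#' @param archetype_mix Named proportions over `CR`, `PR`, `SD`; must sum
#'   to 1. Patients are allocated by largest-remainder rounding.
#' @param sampling `"clinical_sparse"` (default: days 1, 3, 7, 10, 14, 21,
#'   28, 60, 90, 180, 270, 365, matching typical qPCR follow-up cadence) or
#'   `"dense"` (every 0.25 day to day 30, every 2 days to day 150).
#' @param sampling_days Optional explicit day vector overriding `sampling`.
#' @param noise_sigma Standard deviation of the log10 multiplicative
#'   measurement noise, dex (default 0.2).
#' @param detection_threshold Censoring threshold, cells (default 2.5e6).
#' @param dosing `"single"` (default; one dose at day 0) or `"split"`
#'   (10%/30%/60% on days 0/1/2).
#' @param dose Total dose, cells (default 1e8).
#' @param T0 Initial tumor burden, cells (default 1e7).
#' @param followup_day Outcome assessment day(s): a single day or a named
#'   per-archetype vector. The default (`CR` 365, `PR` 120, `SD` 21) mirrors
#'   the heterogeneous clinical follow-up horizons: durable complete
#'   responses are confirmed about a year out, partial responses are
#'   typically assessed a few months after infusion, and stable disease is
#'   called at the early response assessment.
#' @param priors Per-archetype parameter priors (each a named list of
#'   `c(min, max)` log-uniform ranges); defaults documented in the source.
#' @param fixed Named list of parameters held at fixed values for all
#'   patients (default `r`, `b`, `gamma`, `vartheta` and `r_min`).
#' @param seed Integer seed; every cohort draw is reproducible from it.
#' @return A list of class `carkin_cohort_config`.
#' @export
cohort_config <- function(n_patients = 20,
                          archetype_mix = c(CR = 0.5, PR = 0.25, SD = 0.25),
                          sampling = c("clinical_sparse", "dense"),
                          sampling_days = NULL,
                          noise_sigma = 0.2,
                          detection_threshold = 2.5e6,
                          dosing = c("single", "split"),
                          dose = 1e8, T0 = 1e7,
                          followup_day = c(CR = 365, PR = 120, SD = 21),
                          priors = default_priors(),
                          fixed = list(r = 0.03, b = 1e-12, gamma = 3,
                                       vartheta = 1, r_min = 0.05),
                          seed = 1L) {
  sampling <- match.arg(sampling)
  dosing <- match.arg(dosing)
  if (abs(sum(archetype_mix) - 1) > 1e-8)
    stop("archetype_mix must sum to 1")
  if (!all(names(archetype_mix) %in% names(priors)))
    stop("archetype_mix names must match priors")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(sampling_days)) {
    sampling_days <- switch(sampling,
      clinical_sparse = c(1, 3, 7, 10, 14, 21, 28, 60, 90, 180, 270, 365),
      dense = c(seq(0.25, 30, by = 0.25), seq(32, 150, by = 2))
    )
  }
  if (is.unsorted(sampling_days)) stop("sampling_days must be sorted")
  structure(list(
    n_patients = n_patients, archetype_mix = archetype_mix,
    sampling = sampling, sampling_days = sampling_days,
    noise_sigma = noise_sigma, detection_threshold = detection_threshold,
    dosing = dosing, dose = dose, T0 = T0, followup_day = followup_day,
    priors = priors, fixed = fixed, seed = as.integer(seed)
  ), class = "carkin_cohort_config")
}

#' Draw model parameters for an archetype
#'
#' Samples each free parameter log-uniformly from the archetype's prior
#' range and applies the configured fixed values; draws violating the
#' parameter invariants (notably `mu < xi`) are rejected and redrawn, up to
#' 1000 times.
#'
#' @param config A [cohort_config()].
#' @param archetype One of the archetype labels in `config` (`"CR"`,
#'   `"PR"`, `"SD"` by default).
#' @return A validated [carkin_params()] object.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 7)
#' withr::with_seed(7, sample_parameters(cfg, "CR"))
sample_parameters <- function(config, archetype) {
  pri <- config$priors[[archetype]]
  if (is.null(pri)) stop("unknown archetype: ", archetype)
  for (attempt in seq_len(1000)) {
    draw <- lapply(pri, function(rg) exp(stats::runif(1, log(rg[1]), log(rg[2]))))
    kp <- tryCatch(do.call(carkin_params, c(draw, config$fixed)),
                   error = function(e) NULL)
    if (!is.null(kp)) return(kp)
  }
  stop("priors cannot satisfy the parameter invariants after 1000 draws")
}

#' Generate one synthetic patient
#'
#' Simulates the model under `kp`, samples the total CAR-T count at the
#' configured days, perturbs each value multiplicatively by
#' `10^e, e ~ Normal(0, noise_sigma)`, and censors values at or below the
#' detection threshold. The outcome label is computed by classifying the
#' noise-free tumor burden at the follow-up day. The true parameters are
#' attached as a hidden provenance attribute (see `carkin:::true_params`)
#' for recovery scoring, invisible to the fitting interface.
#'
#' @param kp True [carkin_params()] for this patient.
#' @param config A [cohort_config()].
#' @param id Patient label.
#' @param archetype Optional archetype label used to resolve a per-archetype
#'   follow-up day from the config.
#' @param dt Integration step for the noise-free simulation, days.
#' @return A [patient_record()] with hidden truth.
#' @export
generate_patient <- function(kp, config, id = "S1", archetype = NULL,
                             dt = 0.01) {
  followup <- resolve_followup(config, archetype)
  days <- config$sampling_days
  sched <- switch(config$dosing,
    single = dose_schedule(0, config$dose),
    split = split_schedule(config$dose)
  )
  t_end <- max(c(days, followup))
  # record states exactly at the sampling and assessment days
  traj <- simulate_kinetics(kp, sched, T0 = config$T0, t_end = t_end,
                            dt = dt,
                            output_times = sort(unique(c(0, days, followup))))
  model_c <- stats::approx(traj$time, traj$C, xout = days)$y
  eps <- stats::rnorm(length(days), 0, config$noise_sigma)
  value <- model_c * 10^eps
  t_fu <- stats::approx(traj$time, traj$T, xout = followup)$y
  rec <- patient_record(
    id = id,
    observations = tibble::tibble(day = days, value = value,
                                  censored = value <= config$detection_threshold),
    schedule = sched,
    detection_threshold = config$detection_threshold,
    T0 = config$T0,
    followup_day = followup,
    outcome = classify_outcome(t_fu, config$T0, config$detection_threshold),
    disease = NA_character_
  )
  attr(rec, "true_params") <- kp
  rec
}

#' Study-design base parameters of a synthetic cohort
#'
#' Builds the parameter set a fitter would use as its fixed/base values for
#' patients of a given cohort design: the configured fixed constants plus
#' the geometric midpoint of each prior range (pooled across archetypes
#' unless one is named). Contains no patient-level truth.
#'
#' @param config A [cohort_config()].
#' @param archetype Optional archetype whose priors to use; default pools
#'   all archetypes.
#' @return A [carkin_params()] object.
#' @export
cohort_base_params <- function(config, archetype = NULL) {
  pris <- if (is.null(archetype)) config$priors else config$priors[archetype]
  nms <- unique(unlist(lapply(pris, names)))
  mid <- lapply(nms, function(nm) {
    rgs <- do.call(rbind, lapply(pris, function(p) p[[nm]]))
    exp(mean(log(rgs)))
  })
  names(mid) <- nms
  kp <- do.call(carkin_params, c(mid, config$fixed))
  kp
}

resolve_followup <- function(config, archetype) {
  fu <- config$followup_day
  if (length(fu) == 1 && is.null(names(fu))) return(unname(fu))
  if (!is.null(archetype) && archetype %in% names(fu))
    return(unname(fu[[archetype]]))
  max(fu)
}

# largest-remainder allocation of n patients to the archetype proportions
allocate_archetypes <- function(n, mix) {
  exact <- n * mix
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(mix), times = base)
}

#' Generate a synthetic cohort
#'
#' Draws `n_patients` virtual patients (archetypes allocated by
#' largest-remainder rounding of the configured mix), fully reproducible
#' from the configuration seed. The returned truth table exposes the true
#' parameters for recovery scoring, kept separate from the records' fitting
#' interface.
#'
#' @param config A [cohort_config()].
#' @return A list of class `carkin_cohort` with elements `patients` (list
#'   of [patient_record()]s), `truth` (tibble: `id`, `archetype`, `outcome`
#'   and one column per true parameter) and `config`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 4, seed = 11))
#' coh$truth[, c("id", "archetype", "outcome", "beta", "delta", "mu")]
generate_cohort <- function(config) {
  archetypes <- allocate_archetypes(config$n_patients, config$archetype_mix)
  withr::with_seed(config$seed, {
    patients <- vector("list", config$n_patients)
    rows <- vector("list", config$n_patients)
    for (i in seq_along(archetypes)) {
      kp <- sample_parameters(config, archetypes[i])
      id <- sprintf("S%02d", i)
      rec <- generate_patient(kp, config, id = id, archetype = archetypes[i])
      patients[[i]] <- rec
      rows[[i]] <- tibble::tibble(id = id, archetype = archetypes[i],
                                  outcome = rec$outcome,
                                  !!!params_vector(kp))
    }
    structure(list(patients = patients, truth = dplyr::bind_rows(rows),
                   config = config),
              class = "carkin_cohort")
  })
}

#' @export
print.carkin_cohort <- function(x, ...) {
  cat("<carkin_cohort> ", length(x$patients), " patients (seed ",
      x$config$seed, ")\n", sep = "")
  print(table(archetype = x$truth$archetype, outcome = x$truth$outcome))
  invisible(x)
}
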