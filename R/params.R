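# Canonical parameter order shared with src/rk4.cpp. Do not reorder.
par_order <- c("beta", "eta", "r_min", "p1", "p2", "p3", "A", "a", "xi",
               "epsilon", "lambda", "theta", "alpha", "mu", "delta", "r",
               "b", "gamma", "vartheta")

#' Kinetic model parameters
#'
#' Constructs the full set of rate constants of the tumor--CAR-T model.
#' All populations are absolute cell numbers; all rates are per day.
#'
#' The CAR-T population is split into distributed (`CD`), effector (`CT`),
#' memory (`CM`) and exhausted (`CE`) phenotypes interacting with a
#' logistically growing tumor (`T`). Freshly infused cells are lost at rate
#' `beta` or engraft at rate `eta`; engrafted effectors expand at the
#' antigen-modulated, time-dependent rate `kappa(t) * T/(A + T)` where
#' `kappa(t) = r_min + p1 / (1 + (p2 t)^p3)` decays from `r_min + p1` to the
#' basal rate `r_min`. Effectors die (`xi`), convert to memory (`epsilon`)
#' or exhaust (`lambda`); memory cells die slowly (`mu`, constrained
#' `mu < xi`) and reconvert to effectors on antigen contact (`theta * T`);
#' tumor cells inhibit effectors (`alpha * T`). Exhausted cells die at
#' `delta`. The tumor grows logistically (rate `r`, carrying capacity `1/b`)
#' and is killed by functional cells `CF = CD + CT` at rate
#' `gamma * CF / (vartheta T + a + CF)`.
#'
#' @param beta Loss rate of distributed (non-engrafting) cells, day^-1.
#' @param eta Engraftment rate of distributed cells, day^-1.
#' @param r_min Basal effector expansion rate, day^-1.
#' @param p1 Initial (maximum additional) expansion rate, day^-1.
#' @param p2 Rate controlling the duration of the maximal-expansion plateau,
#'   day^-1.
#' @param p3 Dimensionless exponent controlling the decay of the expansion
#'   rate; must be positive.
#' @param A Tumor burden at which antigen-driven expansion is half-maximal,
#'   cells.
#' @param a Half-saturation constant of the cytotoxicity function, cells.
#' @param xi Effector death rate, day^-1.
#' @param epsilon Effector-to-memory conversion rate, day^-1.
#' @param lambda Effector exhaustion rate, day^-1.
#' @param theta Memory-to-effector reconversion coefficient, (cell day)^-1.
#' @param alpha Tumor inhibition coefficient on effectors, (cell day)^-1.
#' @param mu Memory death rate, day^-1; must satisfy `mu < xi`.
#' @param delta Exhausted-cell death rate, day^-1.
#' @param r Tumor growth rate, day^-1.
#' @param b Inverse tumor carrying capacity, cell^-1; must be positive.
#' @param gamma Cytotoxic rate of functional cells on tumor cells, day^-1.
#' @param vartheta Dimensionless half-saturation coefficient of the
#'   cytotoxic effect.
#'
#' @return A named list of class `carkin_params`.
#' @seealso [textbook_params()] for a documented timescale-separated set,
#'   [read_params()] / [write_params()] for config-file round trips.
#' @export
#' @examples
#' kp <- carkin_params(beta = 0.5, p1 = 1.5)
#' kp$beta
carkin_params <- function(beta = 1.0, eta = 1e-3, r_min = 0.05, p1 = 1.5,
                          p2 = 0.1, p3 = 4, A = 1e6, a = 5e5, xi = 0.5,
                          epsilon = 0.01, lambda = 0.2, theta = 1e-10,
                          alpha = 1e-12, mu = 0.01, delta = 0.3, r = 0.1,
                          b = 1e-12, gamma = 1, vartheta = 1) {
  kp <- list(beta = beta, eta = eta, r_min = r_min, p1 = p1, p2 = p2,
             p3 = p3, A = A, a = a, xi = xi, epsilon = epsilon,
             lambda = lambda, theta = theta, alpha = alpha, mu = mu,
             delta = delta, r = r, b = b, gamma = gamma, vartheta = vartheta)
  validate_params(kp)
  structure(kp, class = c("carkin_params", "list"))
}

#' Validate a parameter set
#'
#' Checks non-negativity of every rate, positivity of `b` and `p3`, and the
#' memory-longevity constraint `mu < xi`.
#'
#' @param kp A named list of parameters (see [carkin_params()]).
#' @return `kp`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_params <- function(kp) {
  missing <- setdiff(par_order, names(kp))
  if (length(missing) > 0)
    stop("missing parameters: ", paste(missing, collapse = ", "))
  vals <- unlist(kp[par_order])
  if (any(!is.finite(vals)))
    stop("non-finite parameter values: ",
         paste(par_order[!is.finite(vals)], collapse = ", "))
  if (any(vals < 0))
    stop("negative parameter values: ",
         paste(par_order[vals < 0], collapse = ", "))
  if (kp$b <= 0) stop("b must be positive (finite carrying capacity)")
  if (kp$p3 <= 0) stop("p3 must be positive")
  if (kp$mu >= kp$xi)
    stop("mu must be smaller than xi (memory cells outlive effectors)")
  invisible(kp)
}

#' Modify selected parameters
#'
#' @param kp A `carkin_params` object.
#' @param ... Named scalar replacements, e.g. `beta = 0.7`.
#' @return A new validated `carkin_params` object.
#' @export
update_params <- function(kp, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), par_order)
  if (length(bad) > 0)
    stop("unknown parameters: ", paste(bad, collapse = ", "))
  kp[names(repl)] <- repl
  validate_params(kp)
  structure(kp[par_order], class = c("carkin_params", "list"))
}

#' Flatten a parameter set to a named numeric vector
#'
#' @param kp A [carkin_params()] object.
#' @return Named numeric vector in canonical parameter order.
#' @export
params_vector <- function(kp) {
  unlist(kp[par_order])
}

#' @export
print.carkin_params <- function(x, ...) {
  cat("<carkin_params>\n")
  v <- params_vector(x)
  cat(paste0("  ", format(names(v), width = 9), " ",
             format(v, digits = 4, scientific = TRUE)), sep = "\n")
  invisible(x)
}

#' Timescale-separated reference parameter set
#'
#' A documented "textbook" parameter set whose trajectory exhibits the four
#' kinetic phases with well-separated timescales: the distribution loss
#' (`beta` = 2/day) is much faster than the net expansion, and the
#' exhausted-cell death (`delta` = 0.3/day) much faster than the memory
#' death (`mu` = 0.01/day). Used throughout the test-suite and vignette as
#' the canonical multiphasic example (dose 1e8 cells, T(0) = 1e7 cells).
#'
#' @return A `carkin_params` object.
#' @export
#' @examples
#' traj <- simulate_kinetics(textbook_params(), schedule = 1e8, t_end = 60)
textbook_params <- function() {
  carkin_params(beta = 2.0, eta = 3e-4, r_min = 0.05, p1 = 3.0, p2 = 0.05,
                p3 = 5, A = 1e4, a = 1e9, xi = 0.9, epsilon = 0.005,
                lambda = 0.40, theta = 1e-10, alpha = 1e-12, mu = 0.01,
                delta = 0.3, r = 0.03, b = 1e-12, gamma = 3, vartheta = 1)
}

#' Reference dense sampling grid for the textbook trajectory
#'
#' The committed observation days used with [textbook_params()] in the
#' package's worked examples and validation: every 0.25 day over the first
#' 30 days (resolving the short distribution and expansion phases), then
#' every 2 days out to day 250 (covering contraction and persistence).
#'
#' @return Numeric vector of days.
#' @export
textbook_sampling <- function() {
  c(seq(0.25, 30, by = 0.25), seq(32, 250, by = 2))
}

#' Read / write parameter configuration files
#'
#' Parameters serialize as a flat key--value mapping using the transliterated
#' symbol names (`beta`, `eta`, `r_min`, `p1`, `p2`, `p3`, `A`, `a`, `xi`,
#' `epsilon`, `lambda`, `theta`, `alpha`, `mu`, `delta`, `r`, `b`, `gamma`,
#' `vartheta`). YAML or JSON is chosen from the file extension.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param kp A `carkin_params` object (for writing).
#' @return `read_params()` returns a validated `carkin_params`;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension: ", ext)
  )
  kp <- lapply(raw[par_order], as.numeric)
  names(kp) <- par_order
  validate_params(kp)
  structure(kp, class = c("carkin_params", "list"))
}

#' @rdname read_params
#' @export
write_params <- function(kp, path) {
  validate_params(kp)
  ext <- tolower(tools::file_ext(path))
  flat <- lapply(kp[par_order], as.numeric)
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(flat, path),
    json = jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config extension: ", ext)
  )
  invisible(path)
}
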