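#' Time-dependent expansion rate kappa(t)
#'
#' The antigen-modulated expansion rate of effector CAR-T cells,
#' `kappa(t) = r_min + p1 / (1 + (p2 t)^p3)`. At infusion the rate is at its
#' maximum `r_min + p1`; it stays near that value over a plateau whose width
#' is set by `1/p2`, then decays (sharpness set by `p3`) to the basal rate
#' `r_min`.
#'
#' @param t Time since infusion, days (vectorized, non-negative).
#' @param kp A [carkin_params()] object (only `r_min`, `p1`, `p2`, `p3`
#'   are used).
#' @return Expansion rate(s), day^-1, in `[r_min, r_min + p1]`.
#' @export
#' @examples
#' expansion_rate(0, carkin_params(r_min = 0.1, p1 = 1.5)) # 1.6
expansion_rate <- function(t, kp) {
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  kp$r_min + kp$p1 / (1 + (kp$p2 * t)^kp$p3)
}

#' Antigen saturation F(T)
#'
#' Fraction of the maximal expansion rate realized at tumor burden `T`:
#' `F(T) = T / (A + T)`. Expansion requires antigen, so `F(0) = 0`, and
#' `F(A) = 1/2`.
#'
#' @param T Tumor burden, cells (vectorized, non-negative).
#' @param A Half-saturation tumor burden, cells (positive).
#' @return Dimensionless value(s) in `[0, 1)`.
#' @export
antigen_saturation <- function(T, A) {
  if (!is.finite(A) || A <= 0) stop("A must be finite and > 0")
  if (any(!is.finite(T)) || any(T < 0)) stop("T must be finite and >= 0")
  T / (A + T)
}

#' Cytotoxicity saturation f(CF, T)
#'
#' Access of functional CAR-T cells `CF = CD + CT` to tumor cells:
#' `f(CF, T) = CF / (vartheta T + a + CF)`. When tumor cells vastly
#' outnumber functional cells the per-day tumor kill `gamma f T` approaches
#' `gamma CF / vartheta`; when functional cells dominate it saturates at
#' `gamma T`.
#'
#' @param CF Functional CAR-T cells, cells (vectorized, non-negative).
#' @param T Tumor burden, cells (non-negative).
#' @param vartheta Dimensionless half-saturation coefficient (>= 0).
#' @param a Half-saturation constant, cells (>= 0).
#' @return Dimensionless value(s) in `[0, 1]`.
#' @export
kill_saturation <- function(CF, T, vartheta, a) {
  if (any(!is.finite(CF)) || any(CF < 0)) stop("CF must be finite and >= 0")
  if (any(!is.finite(T)) || any(T < 0)) stop("T must be finite and >= 0")
  if (vartheta < 0 || a < 0) stop("vartheta and a must be >= 0")
  den <- vartheta * T + a + CF
  if (any(den == 0 & CF == 0) && a == 0 && vartheta == 0)
    stop("invalid parameters: kill saturation denominator identically zero")
  ifelse(den == 0, 0, CF / den)
}

#' Right-hand side of the kinetic model
#'
#' Evaluates the instantaneous rates of change of the five compartments:
#' distributed (`CD`), effector (`CT`), memory (`CM`), exhausted (`CE`)
#' CAR-T cells and tumor cells (`T`):
#' \deqn{dCD/dt = -(\beta+\eta) CD}
#' \deqn{dCT/dt = \eta CD + \kappa(t) F(T) CT - (\xi+\epsilon+\lambda) CT
#'   + \theta T CM - \alpha T CT}
#' \deqn{dCM/dt = \epsilon CT - \theta T CM - \mu CM}
#' \deqn{dCE/dt = \lambda CT - \delta CE}
#' \deqn{dT/dt = r T (1 - b T) - \gamma f(CF, T) T}
#'
#' This R implementation is the reference surface for the mathematics; the
#' simulator integrates an equivalent compiled version.
#'
#' @param state Named numeric vector or list with components `CD`, `CT`,
#'   `CM`, `CE`, `T` (cells, non-negative).
#' @param t Time since infusion, days.
#' @param kp A [carkin_params()] object.
#' @return Named numeric vector of derivatives, cells/day.
#' @export
#' @examples
#' kinetic_rates(c(CD = 1e8, CT = 0, CM = 0, CE = 0, T = 1e7), 0,
#'               textbook_params())
kinetic_rates <- function(state, t, kp) {
  state <- unlist(state)[c("CD", "CT", "CM", "CE", "T")]
  if (any(!is.finite(state))) stop("non-finite state components")
  if (any(state < 0)) stop("negative state components")
  if (!is.finite(t) || t < 0) stop("t must be finite and >= 0")
  CD <- state[["CD"]]; CT <- state[["CT"]]; CM <- state[["CM"]]
  CE <- state[["CE"]]; Tm <- state[["T"]]
  CF <- CD + CT
  kap <- expansion_rate(t, kp)
  Fv <- antigen_saturation(Tm, kp$A)
  fv <- kill_saturation(CF, Tm, kp$vartheta, kp$a)
  c(
    CD = -(kp$beta + kp$eta) * CD,
    CT = kp$eta * CD + kap * Fv * CT - (kp$xi + kp$epsilon + kp$lambda) * CT +
      kp$theta * Tm * CM - kp$alpha * Tm * CT,
    CM = kp$epsilon * CT - kp$theta * Tm * CM - kp$mu * CM,
    CE = kp$lambda * CT - kp$delta * CE,
    T = kp$r * Tm * (1 - kp$b * Tm) - kp$gamma * fv * Tm
  )
}

#' Expected number of engrafted CAR-T cells
#'
#' Distributed cells either die (rate `beta`) or engraft (rate `eta`), so
#' `CD(t) = dose * exp(-(beta + eta) t)` and the expected total engraftment
#' is the integral of `eta * CD(t)`:
#' \deqn{EC = \frac{\eta}{\beta + \eta} \, \mathrm{dose}.}
#'
#' @param kp A [carkin_params()] object (uses `beta`, `eta`).
#' @param dose Total infused cells (>= 0).
#' @return Engrafted cells, in `[0, dose]`.
#' @export
#' @examples
#' engrafted_cells(carkin_params(beta = 0.9, eta = 0.1), 1e8) # 1e7
engrafted_cells <- function(kp, dose) {
  if (!is.finite(dose) || dose < 0) stop("dose must be finite and >= 0")
  if (kp$beta + kp$eta == 0)
    stop("beta + eta = 0: engrafted-cell count undefined")
  kp$eta / (kp$beta + kp$eta) * dose
}
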