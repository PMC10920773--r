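#' Diel division rate
#'
#' The division rate of *Prochlorococcus* is forced by the daily light
#' cycle: `mu(t) = mu_ave * (1 + delta_mu * sin(2 * pi * (t + delta_t)))`,
#' with `t` in days and `t = 0` at 06:00 local time. The rate is 1-day
#' periodic and its mean over a day equals `mu_ave` for any amplitude and
#' phase.
#'
#' @param t Time(s) in days (vectorized).
#' @param params A [life_history()] object.
#' @return Division rate(s), day^-1.
#' @examples
#' division_rate(seq(0, 1, by = 0.25), life_history())
#' @export
division_rate <- function(t, params) {
  stopifnot(inherits(params, "pd_params"))
  params$mu_ave * (1 + params$delta_mu * sin(2 * pi * (t + params$delta_t)))
}

#' Diel adsorption multiplier
#'
#' Step-wise multiplier applied to the viral adsorption rate when the diel
#' adsorption variant is active: `low_factor` from midnight to noon and
#' `high_factor` from noon to midnight (half-open intervals, the boundary
#' instant belongs to the interval it begins). With the forcing switched off
#' the multiplier is identically 1. Times are wrapped modulo 1 day.
#'
#' @param t Time(s) in days (vectorized).
#' @param forcing A [forcing_config()] object.
#' @return Dimensionless multiplier(s).
#' @examples
#' adsorption_multiplier(c(0, 0.25, 0.5, 0.75), forcing_config(TRUE))
#' @export
adsorption_multiplier <- function(t, forcing) {
  stopifnot(inherits(forcing, "pd_forcing"))
  if (!forcing$diel_adsorption) {
    return(rep(1, length(t)))
  }
  frac <- t - floor(t)
  ifelse(frac >= 0.25 & frac < 0.75, forcing$high_factor, forcing$low_factor)
}

#' Community model right-hand side
#'
#' Time derivatives of the four compartments:
#' \deqn{dS/dt = \mu(t) S - m_P S (S+I) - \phi(t) S V - \psi S G}
#' \deqn{dI/dt = \phi(t) S V - m_P I (S+I) - \eta I - \psi I G}
#' \deqn{dV/dt = \beta \eta I - \phi(t) (S+I) V - m_V V^2}
#' \deqn{dG/dt = e_{eff} \psi (S+I) G + \gamma G - m_G G^2}
#' where `phi(t) = phi * adsorption_multiplier(t, forcing)`. The same
#' time-dependent adsorption rate is used for the infection flux and the
#' free-virion adsorption sink: both describe the one physical attachment
#' process.
#'
#' This reference implementation in R mirrors the compiled right-hand side
#' used by [simulate_community()]; the two are cross-checked in the test
#' suite.
#'
#' @param t Time in days.
#' @param state Data frame (or named list) with one row and columns
#'   `S`, `I`, `V`, `G` (per-litre abundances, all >= 0).
#' @param params A [life_history()] object.
#' @param forcing A [forcing_config()] object.
#' @return A tibble with one row and columns `dS`, `dI`, `dV`, `dG`
#'   (per litre per day).
#' @examples
#' community_rhs(0, tibble::tibble(S = 1e8, I = 1e6, V = 1e9, G = 1e3),
#'   life_history(), forcing_config())
#' @export
community_rhs <- function(t, state, params, forcing = forcing_config()) {
  stopifnot(inherits(params, "pd_params"), inherits(forcing, "pd_forcing"))
  state <- as.list(state)
  S <- state$S
  I <- state$I
  V <- state$V
  G <- state$G
  vals <- c(S, I, V, G)
  if (any(!is.finite(vals))) stop("non-finite state", call. = FALSE)
  if (any(vals < 0)) stop("state components must be >= 0", call. = FALSE)
  P <- S + I
  mu <- division_rate(t, params)
  phi_t <- params$phi * adsorption_multiplier(t, forcing)
  tibble::tibble(
    dS = mu * S - params$m_P * S * P - phi_t * S * V - params$psi * S * G,
    dI = phi_t * S * V - params$m_P * I * P - params$eta * I -
      params$psi * I * G,
    dV = params$beta * params$eta * I - phi_t * P * V - params$m_V * V^2,
    dG = params$e_eff * params$psi * P * G + params$gamma * G -
      params$m_G * G^2
  )
}

#' Fraction of grazer growth attributable to *Prochlorococcus*
#'
#' Along a trajectory, grazer gains come from consuming *Prochlorococcus*
#' (`e_eff * psi * (S+I)`) and from generalist feeding on prey outside the
#' model (`gamma`). The specialism fraction is the time-average of the
#' instantaneous share of the first source; a specialist (`gamma = 0`)
#' scores 1.
#'
#' @param trajectory Data frame with columns `S` and `I` (e.g. a
#'   [simulate_community()] result).
#' @param params A [life_history()] object.
#' @return Dimensionless fraction in `[0, 1]`.
#' @examples
#' traj <- simulate_community(life_history(), t_out = seq(0, 2, by = 0.05))
#' specialism_fraction(traj, life_history())
#' @export
specialism_fraction <- function(trajectory, params) {
  stopifnot(inherits(params, "pd_params"), nrow(trajectory) > 0)
  pro_gain <- params$e_eff * params$psi * (trajectory$S + trajectory$I)
  total <- pro_gain + params$gamma
  if (all(total == 0)) {
    stop("both grazer growth sources are zero along the whole trajectory",
      call. = FALSE
    )
  }
  mean(pro_gain / total)
}
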