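#' Cruise-like initial community state
#'
#' A state on (or near) the model's diel limit cycle at 06:00 local time for
#' the default [life_history()] parameters, in per-litre units. Used as the
#' default starting point for simulations and for the synthetic-data
#' generator.
#'
#' @return A tibble with one row and columns `S`, `I`, `V`, `G`.
#' @export
default_init <- function() {
  tibble::tibble(S = 9.807e7, I = 1.932e6, V = 9.775e8, G = 9.811e5)
}

as_state_vector <- function(init) {
  init <- as.list(init)
  need <- c("S", "I", "V", "G")
  if (!all(need %in% names(init))) {
    stop("initial state needs components S, I, V, G", call. = FALSE)
  }
  y0 <- as.numeric(unlist(init[need]))
  if (any(!is.finite(y0)) || any(y0 < 0)) {
    stop("initial state must be finite and >= 0", call. = FALSE)
  }
  y0
}

#' Integrate the community model
#'
#' Solves the four-compartment system with an adaptive embedded Runge-Kutta
#' (Dormand-Prince 5(4)) stepper, restarting the integration at the diel
#' adsorption switch points so the step discontinuity never spans an
#' accepted step. Numerical undershoot below zero within the absolute
#' tolerance is clipped to zero; larger negatives abort with an error, as
#' does any component exceeding the overflow guard.
#'
#' @param params A [life_history()] object.
#' @param init Initial state (`S`, `I`, `V`, `G` per litre); defaults to
#'   [default_init()].
#' @param t_out Strictly increasing output times, days; the first element is
#'   the initial time.
#' @param forcing A [forcing_config()] object.
#' @param rtol,atol Relative and absolute solver tolerances. The absolute
#'   tolerance is in per-litre units.
#' @param overflow_guard Abort if any component exceeds this (per litre).
#' @param max_steps Maximum number of accepted steps.
#' @return A `pd_trajectory` tibble with columns `time_days`, `S`, `I`, `V`,
#'   `G` and attributes `params`, `forcing`, `min_P` (minimum total
#'   *Prochlorococcus* over all internal steps) and `n_steps`.
#' @examples
#' traj <- simulate_community(life_history(), t_out = seq(0, 4, by = 0.02))
#' @export
simulate_community <- function(params,
                               init = default_init(),
                               t_out = seq(0, 12, by = 1 / 24),
                               forcing = forcing_config(),
                               rtol = 1e-8,
                               atol = 1e-2,
                               overflow_guard = 1e15,
                               max_steps = 5e6) {
  stopifnot(inherits(params, "pd_params"), inherits(forcing, "pd_forcing"))
  validate_params(params)
  t_out <- as.numeric(t_out)
  if (length(t_out) < 1 || any(!is.finite(t_out)) || is.unsorted(t_out, strictly = TRUE)) {
    stop("t_out must be finite and strictly increasing", call. = FALSE)
  }
  stopifnot(rtol > 0, atol > 0)
  y0 <- as_state_vector(init)
  res <- .integrate_cpp(
    t_out, y0, unclass(params), unclass(forcing),
    rtol, atol, overflow_guard, as.integer(max_steps)
  )
  states <- res$states
  out <- tibble::tibble(
    time_days = t_out,
    S = states[, 1], I = states[, 2], V = states[, 3], G = states[, 4]
  )
  structure(out,
    params = params, forcing = forcing,
    min_P = res$min_P, n_steps = res$n_steps,
    class = c("pd_trajectory", class(out))
  )
}

#' Run to diel-stationary dynamics
#'
#' Integrates the model through a long burn-in (default 1000 days) so
#' transients decay, then returns the following 1-day window. Because the
#' forcing is 1-day periodic the stationary state is a diel cycle, not a
#' fixed point; stationarity is assessed by comparing the two post-burn-in
#' days point-by-point: the criterion holds when the maximum relative
#' difference between the state at `t` and `t + 1` day stays below `tol`.
#' Extinction of *Prochlorococcus* (total abundance below `floor` anywhere
#' along the run) is reported via the `extinct` attribute, not raised; the
#' returned window is then empty.
#'
#' @inheritParams simulate_community
#' @param burn_in Burn-in length, days.
#' @param tol Relative tolerance of the diel-stationarity criterion.
#' @param floor Extinction floor, cells per litre.
#' @param n_per_day Output samples per day in the returned window.
#' @return A `pd_trajectory` tibble over one day (time restarted at the
#'   06:00 phase, i.e. `time_days` in `[0, 1]`) with attributes `stationary`
#'   (logical), `max_rel_diff`, `extinct` and `min_P`.
#' @examples
#' st <- run_to_stationary(life_history(), burn_in = 200)
#' attr(st, "stationary")
#' @export
run_to_stationary <- function(params,
                              init = default_init(),
                              forcing = forcing_config(),
                              burn_in = 1000,
                              tol = 1e-3,
                              floor = 1,
                              n_per_day = 48,
                              rtol = 1e-8,
                              atol = 1e-2) {
  stopifnot(burn_in >= 0)
  y0 <- as_state_vector(init)
  # sparse output through the burn-in, dense over the last two days
  t_dense <- burn_in + seq(0, 2, by = 1 / n_per_day)
  t_burn <- if (burn_in > 0) seq(0, burn_in, length.out = 26)[-26] else numeric(0)
  t_all <- c(t_burn, t_dense)
  traj <- simulate_community(params,
    init = init, t_out = t_all,
    forcing = forcing, rtol = rtol, atol = atol
  )
  extinct <- attr(traj, "min_P") < floor
  dense <- traj[traj$time_days >= burn_in - 1e-9, ]
  n <- n_per_day + 1
  day1 <- dense[seq_len(n), c("S", "I", "V", "G")]
  day2 <- dense[n_per_day + seq_len(n), c("S", "I", "V", "G")]
  scale <- pmax(abs(as.matrix(day2)), atol)
  max_rel_diff <- max(abs(as.matrix(day2) - as.matrix(day1)) / scale)
  stationary <- !extinct && max_rel_diff < tol

  window <- dense[n_per_day + seq_len(n), ]
  window$time_days <- window$time_days - (burn_in + 1)
  if (extinct) window <- window[0, ]
  structure(window,
    params = params, forcing = forcing,
    stationary = stationary, max_rel_diff = max_rel_diff,
    extinct = extinct, min_P = attr(traj, "min_P"),
    burn_in = burn_in,
    class = c("pd_trajectory", class(tibble::tibble()))
  )
}

#' @rdname run_to_stationary
#' @param x A `run_to_stationary()` result.
#' @param ... Unused.
#' @return `glance()` returns a one-row tibble with the stationarity and
#'   extinction diagnostics.
#' @export
glance.pd_trajectory <- function(x, ...) {
  tibble::tibble(
    stationary = attr(x, "stationary") %||% NA,
    max_rel_diff = attr(x, "max_rel_diff") %||% NA_real_,
    extinct = attr(x, "extinct") %||% NA,
    min_P = attr(x, "min_P") %||% NA_real_,
    n_steps = attr(x, "n_steps") %||% NA_real_
  )
}

#' Has *Prochlorococcus* gone extinct along a trajectory?
#'
#' `TRUE` when total *Prochlorococcus* (`S + I`) falls strictly below the
#' floor anywhere on the trajectory (a sample exactly at the floor does not
#' count). When the trajectory carries a `min_P` attribute (minimum over all
#' internal solver steps, as recorded by [simulate_community()]) that finer
#' record is used.
#'
#' @param trajectory A `pd_trajectory` (or any data frame with `S`, `I`).
#' @param floor Extinction floor, cells per litre (default 1).
#' @return Logical flag.
#' @examples
#' traj <- simulate_community(life_history(), t_out = seq(0, 2, by = 0.1))
#' extinction_check(traj)
#' @export
extinction_check <- function(trajectory, floor = 1) {
  if (nrow(trajectory) == 0) stop("empty trajectory", call. = FALSE)
  min_P <- attr(trajectory, "min_P", exact = TRUE)
  if (is.null(min_P)) min_P <- min(trajectory$S + trajectory$I)
  min_P < floor
}

#' Map model state to the observed signals
#'
#' The four field signals are total *Prochlorococcus* (`pro = S + I`), the
#' percentage of infected cells (`infected_pct = 100 I / (S + I)`, defined
#' as 0 when the population is empty), free virions (`virus = V`) and
#' grazers (`grazer = G`).
#'
#' @param trajectory A data frame with columns `time_days`, `S`, `I`, `V`,
#'   `G`.
#' @return A tibble with columns `time_days`, `pro`, `infected_pct`,
#'   `virus`, `grazer`.
#' @examples
#' observe(simulate_community(life_history(), t_out = seq(0, 1, by = 0.25)))
#' @export
observe <- function(trajectory) {
  P <- trajectory$S + trajectory$I
  tibble::tibble(
    time_days = trajectory$time_days,
    pro = P,
    infected_pct = ifelse(P > 0, 100 * trajectory$I / P, 0),
    virus = trajectory$V,
    grazer = trajectory$G
  )
}

#' Write or read a trajectory as tidy CSV
#'
#' @param trajectory A `pd_trajectory`.
#' @param path File path.
#' @return `read_trajectory()` returns a tibble with columns `time_days`,
#'   `S`, `I`, `V`, `G`.
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_csv(
    trajectory[, c("time_days", "S", "I", "V", "G")], path
  )
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      time_days = "d", S = "d", I = "d", V = "d", G = "d"
    )
  )
}
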