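#' Instantaneous mortality fluxes
#'
#' Total *Prochlorococcus* loss decomposes into three fluxes: viral lysis
#' `eta * I`, grazing `psi * (S + I) * G`, and other density-dependent loss
#' `m_P * (S + I)^2` (all cells per litre per day). In the diel-adsorption
#' model variant these definitions are unchanged: adsorption modulates the
#' infection flux, not the loss bookkeeping.
#'
#' @param states Data frame with columns `S`, `I`, `V`, `G` (rows are time
#'   points; `V` is unused but kept for a uniform state layout).
#' @param params A [life_history()] object.
#' @return A tibble with columns `m_lysis`, `m_grazing`, `m_other`.
#' @examples
#' instantaneous_rates(default_init(), life_history())
#' @export
instantaneous_rates <- function(states, params) {
  stopifnot(inherits(params, "pd_params"))
  P <- states$S + states$I
  tibble::tibble(
    m_lysis = params$eta * states$I,
    m_grazing = params$psi * P * states$G,
    m_other = params$m_P * P^2
  )
}

interp_states <- function(trajectory, time_grid) {
  tibble::tibble(
    time_days = time_grid,
    S = approx(trajectory$time_days, trajectory$S, xout = time_grid)$y,
    I = approx(trajectory$time_days, trajectory$I, xout = time_grid)$y,
    V = approx(trajectory$time_days, trajectory$V, xout = time_grid)$y,
    G = approx(trajectory$time_days, trajectory$G, xout = time_grid)$y
  )
}

#' Partition total mortality into lysis, grazing and other losses
#'
#' Fractions are computed as the time-average of the pointwise ratios of
#' each component flux to the total flux (average-of-ratios, matching the
#' reporting convention of averaging the component:total ratio over the
#' sampling window), not as the ratio of time-averaged fluxes. Grid points
#' where the total flux is exactly zero are excluded with a warning.
#'
#' @param trajectory A `pd_trajectory` (or data frame with `time_days`,
#'   `S`, `I`, `V`, `G`).
#' @param params A [life_history()] object; defaults to the trajectory's
#'   own `params` attribute.
#' @param time_grid Optional evaluation grid (days), e.g. the empirical
#'   sampling times; states are linearly interpolated onto it. Defaults to
#'   the trajectory's own rows.
#' @return A `pd_partition` one-row tibble with columns `f_lysis`,
#'   `f_grazing`, `f_other` (fractions summing to 1), `m_total_daily`
#'   (time-averaged total loss flux, cells per litre per day),
#'   `per_capita_grazing` (time-average of `psi * G`, day^-1) and
#'   `lysis_to_grazing` (time-average of the pointwise lysis:grazing ratio).
#' @examples
#' st <- run_to_stationary(life_history(), burn_in = 300)
#' partition_mortality(st)
#' @export
partition_mortality <- function(trajectory, params = attr(trajectory, "params"),
                                time_grid = NULL) {
  if (is.null(params)) stop("params must be supplied", call. = FALSE)
  stopifnot(inherits(params, "pd_params"), nrow(trajectory) > 0)
  states <- if (is.null(time_grid)) {
    trajectory
  } else {
    interp_states(trajectory, time_grid)
  }
  rates <- instantaneous_rates(states, params)
  total <- rates$m_lysis + rates$m_grazing + rates$m_other
  if (all(total == 0)) {
    stop("total mortality is zero along the whole trajectory", call. = FALSE)
  }
  keep <- total > 0
  if (any(!keep)) {
    warning(sum(!keep), " grid point(s) with zero total mortality excluded",
      call. = FALSE
    )
  }
  r <- rates[keep, ]
  tot <- total[keep]
  grazing_pos <- r$m_grazing > 0
  ltg <- if (any(grazing_pos)) {
    mean(r$m_lysis[grazing_pos] / r$m_grazing[grazing_pos])
  } else {
    Inf
  }
  out <- tibble::tibble(
    f_lysis = mean(r$m_lysis / tot),
    f_grazing = mean(r$m_grazing / tot),
    f_other = mean(r$m_other / tot),
    m_total_daily = mean(tot),
    per_capita_grazing = mean(params$psi * states$G[keep]),
    lysis_to_grazing = ltg
  )
  structure(out,
    params = params,
    class = c("pd_partition", class(out))
  )
}

#' Population residence times
#'
#' The residence time of a population is the reciprocal of its
#' time-averaged per-capita loss rate. For grazers the only loss is the
#' quadratic term, so `grazer_residence = 1 / (m_G * mean(G))`. For viruses
#' the default reported residence uses the total per-capita virion loss
#' (quadratic decay plus the adsorption sink onto cells),
#' `1 / (m_V * mean(V) + phi * mean(S + I))`; the quadratic-only variant
#' `1 / (m_V * mean(V))` is also returned because reporting conventions for
#' the adsorption sink differ.
#'
#' @param params A [life_history()] object.
#' @param trajectory Data frame with columns `S`, `I`, `V`, `G`; means are
#'   taken over its rows (the fitted window).
#' @return A one-row tibble with `grazer_residence`, `virus_residence`
#'   and `virus_residence_quadratic`, days.
#' @examples
#' st <- run_to_stationary(life_history(), burn_in = 300)
#' residence_times(life_history(), st)
#' @export
residence_times <- function(params, trajectory) {
  stopifnot(inherits(params, "pd_params"), nrow(trajectory) > 0)
  Gbar <- mean(trajectory$G)
  Vbar <- mean(trajectory$V)
  Pbar <- mean(trajectory$S + trajectory$I)
  if (Gbar <= 0 || Vbar <= 0) {
    stop("zero mean abundance: residence time undefined", call. = FALSE)
  }
  tibble::tibble(
    grazer_residence = 1 / (params$m_G * Gbar),
    virus_residence = 1 / (params$m_V * Vbar + params$phi * Pbar),
    virus_residence_quadratic = 1 / (params$m_V * Vbar)
  )
}

#' Posterior distribution of the mortality partition
#'
#' For each retained posterior draw, simulates the model over the fitted
#' observation window from the draw's initial conditions, partitions
#' mortality on the empirical time grid, and aggregates the per-draw
#' fractions into means, medians and central 95% intervals. Draws whose
#' simulation fails are excluded with a message giving the count.
#'
#' @param fit A [sample_posterior()] result.
#' @param observations The observation set the fit used (for its time
#'   grids).
#' @param n_draws Number of posterior draws to propagate (evenly thinned).
#' @return A `pd_partition_post` list with elements `draws` (per-draw
#'   partition tibble) and `summary` (component, mean, median, q2.5,
#'   q97.5); `tidy()` returns the summary.
#' @export
partition_posterior <- function(fit, observations, n_draws = 200) {
  stopifnot(inherits(fit, "pd_fit"))
  draws <- posterior_params(fit, n_draws)
  grid <- sort(unique(as_tibble(observations)$time_days))
  results <- vector("list", length(draws))
  n_fail <- 0
  for (i in seq_along(draws)) {
    d <- draws[[i]]
    res <- tryCatch(
      {
        traj <- simulate_community(d$params,
          init = d$init, t_out = grid,
          forcing = fit$forcing, rtol = 1e-6, atol = 1
        )
        part <- partition_mortality(traj, d$params)
        dplyr::bind_cols(part, residence_times(d$params, traj))
      },
      error = function(e) NULL
    )
    if (is.null(res)) n_fail <- n_fail + 1 else results[[i]] <- res
  }
  if (n_fail > 0) {
    message(n_fail, " posterior draw(s) failed to simulate and were excluded")
  }
  per_draw <- dplyr::bind_rows(results)
  if (nrow(per_draw) == 0) stop("no posterior draw simulated successfully", call. = FALSE)
  summary <- per_draw |>
    tidyr::pivot_longer(dplyr::everything(),
      names_to = "component",
      values_to = "value"
    ) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      mean = mean(.data$value),
      median = median(.data$value),
      q2.5 = quantile(.data$value, 0.025, names = FALSE),
      q97.5 = quantile(.data$value, 0.975, names = FALSE),
      .groups = "drop"
    )
  structure(list(draws = per_draw, summary = summary, gamma = fit$gamma),
    class = "pd_partition_post"
  )
}

#' @rdname partition_posterior
#' @param x A `pd_partition_post` object.
#' @param ... Unused.
#' @export
tidy.pd_partition_post <- function(x, ...) x$summary

#' @export
print.pd_partition_post <- function(x, ...) {
  cat(
    "<posterior mortality partition> gamma =", x$gamma, "(",
    nrow(x$draws), "draws )\n"
  )
  print(x$summary, n = Inf)
  invisible(x)
}

#' Write partition summaries keyed by grazing-generalism level
#'
#' @param partitions A list of `pd_partition_post` objects (one per gamma
#'   variant).
#' @param path_json,path_csv Output paths (either may be `NULL`).
#' @return The combined summary tibble, invisibly.
#' @export
write_partition_summaries <- function(partitions, path_json = NULL,
                                      path_csv = NULL) {
  tab <- purrr::map(partitions, function(p) {
    dplyr::mutate(p$summary, gamma = p$gamma, .before = 1)
  }) |> dplyr::bind_rows()
  if (!is.null(path_json)) {
    jsonlite::write_json(tab, path_json, digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(path_csv)) readr::write_csv(tab, path_csv)
  invisible(tab)
}
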