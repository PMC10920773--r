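# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the cruise-like observation generator
#'
#' Describes a synthetic sampling campaign mimicking a multi-day ocean
#' time-series study: near-continuous cell counts (shipboard flow
#' cytometry; configurable down to 3-minute cadence), 4-hourly bottle
#' sampling of infected-cell percentage, free virions and grazers, a slow
#' linear multi-day trend superimposed on the diel dynamics, and
#' multiplicative lognormal observation noise on abundances (additive
#' Gaussian, truncated to `[0, 100]`, for the infected percentage). Time 0
#' is 06:00 local on day 0.
#'
#' @param true_params Generator truth, a [life_history()] object.
#' @param forcing A [forcing_config()] object.
#' @param init Initial state at `t = 0`; defaults to the on-cycle state
#'   [default_init()].
#' @param duration Days of sampling.
#' @param pro_cadence_min Cell-count cadence, minutes.
#' @param other_cadence_hr Cadence of the other three signals, hours.
#' @param trend Named list of per-signal linear trends, each
#'   `c(intercept, slope)` (units of the signal and signal per day); the
#'   trend is added to the noiseless model observables.
#' @param noise Named list of per-signal noise scales: lognormal sigma (log
#'   scale) for `pro`, `virus`, `grazer`; additive Gaussian sd in
#'   percentage points for `infected_pct`.
#' @param seed Integer seed for reproducible generation.
#' @return A `pd_genconfig` list.
#' @export
generator_config <- function(true_params = life_history(),
                             forcing = forcing_config(),
                             init = default_init(),
                             duration = 12,
                             pro_cadence_min = 60,
                             other_cadence_hr = 4,
                             trend = list(
                               pro = c(0, -2e6),
                               infected_pct = c(0, 0.04),
                               virus = c(0, -1.5e7),
                               grazer = c(0, 8e3)
                             ),
                             noise = list(
                               pro = 0.05,
                               infected_pct = 0.5,
                               virus = 0.15,
                               grazer = 0.15
                             ),
                             seed = NULL) {
  stopifnot(
    inherits(true_params, "pd_params"), inherits(forcing, "pd_forcing"),
    duration > 0, pro_cadence_min > 0, other_cadence_hr > 0
  )
  for (s in SIGNALS) {
    if (is.null(trend[[s]])) stop("trend missing for signal ", s, call. = FALSE)
    if (is.null(noise[[s]]) || noise[[s]] < 0) {
      stop("noise sigma missing or negative for signal ", s, call. = FALSE)
    }
  }
  structure(
    list(
      true_params = true_params, forcing = forcing, init = init,
      duration = duration, pro_cadence_min = pro_cadence_min,
      other_cadence_hr = other_cadence_hr, trend = trend, noise = noise,
      seed = seed
    ),
    class = "pd_genconfig"
  )
}

signal_grids <- function(config) {
  list(
    pro = seq(0, config$duration, by = config$pro_cadence_min / (24 * 60)),
    infected_pct = seq(0, config$duration, by = config$other_cadence_hr / 24),
    virus = seq(0, config$duration, by = config$other_cadence_hr / 24),
    grazer = seq(0, config$duration, by = config$other_cadence_hr / 24)
  )
}

#' Generate a cruise-like synthetic observation set
#'
#' Simulates the community model from the configured truth, samples the
#' four observables on their cadences, adds the slow per-signal trend, then
#' applies observation noise. The returned observation set carries a
#' `truth` attribute (parameters, forcing, initial state, trend
#' coefficients and the noiseless series) for parameter-recovery scoring.
#'
#' @param config A [generator_config()].
#' @param seed Overrides `config$seed`.
#' @return A `pd_obs` tibble with attribute `truth`.
#' @examples
#' obs <- generate_observations(generator_config(seed = 42))
#' dplyr::count(obs, signal)
#' @export
generate_observations <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "pd_genconfig"))
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("a seed is required for reproducible generation", call. = FALSE)
  grids <- signal_grids(config)
  t_all <- sort(unique(c(0, unlist(grids))))
  traj <- simulate_community(config$true_params,
    init = config$init,
    t_out = t_all, forcing = config$forcing
  )
  if (extinction_check(traj)) {
    stop("Prochlorococcus goes extinct during the sampling window; ",
      "choose different generator parameters",
      call. = FALSE
    )
  }
  clean <- observe_long(traj, grids = grids)
  clean$value <- clean$value +
    purrr::map2_dbl(clean$signal, clean$time_days, function(s, t) {
      config$trend[[s]][1] + config$trend[[s]][2] * t
    })
  noisy <- with_local_seed(seed, {
    out <- clean
    for (s in SIGNALS) {
      idx <- which(out$signal == s)
      sigma <- config$noise[[s]]
      if (s == "infected_pct") {
        out$value[idx] <- pmin(
          100,
          pmax(0, out$value[idx] + rnorm(length(idx), 0, sigma))
        )
      } else {
        out$value[idx] <- out$value[idx] * exp(rnorm(length(idx), 0, sigma))
      }
    }
    out
  })
  obs <- validate_observations(noisy)
  attr(obs, "truth") <- list(
    params = config$true_params, forcing = config$forcing,
    init = config$init, trend = config$trend, noise = config$noise,
    noiseless = clean, trajectory = traj, seed = seed
  )
  obs
}

#' Parameter-recovery experiment
#'
#' The end-to-end harness for the inference stage: for each replicate,
#' generate a synthetic observation set from known truth, detrend it, fit
#' the model, and score the posterior against the generator truth. Reported
#' per free parameter: whether the central 95% credible interval covers the
#' truth and the relative error of the posterior median. Replicates whose
#' fit fails to converge are flagged and excluded from the coverage
#' aggregate with a message.
#'
#' @param config A [generator_config()].
#' @param priors A [prior_spec()]; its fixed `gamma` should match the
#'   generator truth.
#' @param n_replicates Number of generate-fit-score replicates.
#' @param seeds Integer seeds, one per replicate.
#' @param mcmc Named list of options passed to [sample_posterior()]
#'   (`n_chains`, `n_warmup`, `n_samples`, ...).
#' @param keep_fits Keep the full fit objects (memory-heavy).
#' @return A `pd_recovery` list: `scores` (per replicate x parameter),
#'   `coverage` (per parameter), `summary` (overall), and optionally
#'   `fits`.
#' @export
recovery_experiment <- function(config = generator_config(),
                                priors = prior_spec(gamma = config$true_params$gamma),
                                n_replicates = 5,
                                seeds = seq_len(n_replicates),
                                mcmc = list(),
                                keep_fits = FALSE) {
  stopifnot(n_replicates >= 1, length(seeds) == n_replicates)
  truth <- config$true_params
  free <- priors$parameters$parameter
  scores <- list()
  fits <- list()
  n_nonconv <- 0
  for (r in seq_len(n_replicates)) {
    obs <- generate_observations(config, seed = seeds[r])
    det <- detrend(obs)
    fit <- do.call(sample_posterior, c(
      list(observations = det, priors = priors, seed = seeds[r]),
      mcmc
    ))
    if (keep_fits) fits[[r]] <- fit
    conv <- fit$converged
    if (!conv) n_nonconv <- n_nonconv + 1
    sm <- tidy(fit)
    sm <- sm[sm$parameter %in% free, ]
    truth_vals <- purrr::map_dbl(sm$parameter, function(p) truth[[p]])
    scores[[r]] <- tibble::tibble(
      replicate = r, seed = seeds[r], parameter = sm$parameter,
      truth = truth_vals, median = sm$median,
      q2.5 = sm$q2.5, q97.5 = sm$q97.5,
      covered = sm$q2.5 <= truth_vals & truth_vals <= sm$q97.5,
      rel_error = abs(sm$median - truth_vals) / abs(truth_vals),
      converged = conv
    )
  }
  if (n_nonconv > 0) {
    message(
      n_nonconv, " replicate(s) flagged non-converged and excluded ",
      "from coverage"
    )
  }
  all_scores <- dplyr::bind_rows(scores)
  conv_scores <- all_scores[all_scores$converged, ]
  use <- if (nrow(conv_scores) > 0) conv_scores else all_scores
  coverage <- use |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      coverage = mean(.data$covered),
      median_rel_error = median(.data$rel_error),
      median_ci_width = median(.data$q97.5 - .data$q2.5),
      .groups = "drop"
    )
  per_rep <- use |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(n_covered = sum(.data$covered), .groups = "drop")
  summary <- tibble::tibble(
    n_replicates = n_replicates,
    n_converged = n_replicates - n_nonconv,
    n_free_parameters = length(free),
    mean_covered_per_replicate = mean(per_rep$n_covered),
    overall_coverage = mean(use$covered)
  )
  out <- list(
    scores = all_scores, coverage = coverage, summary = summary,
    truth = truth
  )
  if (keep_fits) out$fits <- fits
  structure(out, class = "pd_recovery")
}

#' @export
print.pd_recovery <- function(x, ...) {
  cat("<parameter-recovery experiment>\n")
  print(x$summary)
  print(x$coverage, n = Inf)
  invisible(x)
}

#' @rdname recovery_experiment
#' @param x A `pd_recovery` object.
#' @param ... Unused.
#' @export
tidy.pd_recovery <- function(x, ...) x$coverage

#' @rdname recovery_experiment
#' @export
glance.pd_recovery <- function(x, ...) x$summary
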