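SWEEPABLE <- c(
  "mu_ave", "delta_mu", "delta_t", "m_P", "m_V", "m_G",
  "phi", "psi", "beta", "eta"
)

#' Default multiplier grid for sensitivity sweeps
#'
#' Log-spaced multipliers spanning 0.25x to 4x the baseline, always
#' including the baseline multiplier 1 at the centre.
#'
#' @param n Number of grid points (odd, so 1 is on the grid).
#' @return Numeric vector of multipliers.
#' @export
multiplier_grid <- function(n = 33) {
  if (n %% 2 == 0) stop("n must be odd so the grid contains 1", call. = FALSE)
  2^seq(-2, 2, length.out = n)
}

stationary_metrics <- function(params, forcing, burn_in, floor, rtol, atol) {
  window <- run_to_stationary(params,
    forcing = forcing, burn_in = burn_in,
    floor = floor, rtol = rtol, atol = atol
  )
  if (attr(window, "extinct")) {
    return(tibble::tibble(
      m_total_daily = NA_real_, lysis_to_grazing = NA_real_,
      coexistence = FALSE
    ))
  }
  part <- partition_mortality(window, params)
  tibble::tibble(
    m_total_daily = part$m_total_daily,
    lysis_to_grazing = part$lysis_to_grazing,
    coexistence = TRUE
  )
}

#' Single-parameter sensitivity sweep
#'
#' Varies one life-history parameter over a multiplier grid (all others
#' fixed at baseline), runs each variant to diel-stationary dynamics after a
#' long burn-in, and records the stationary-day total daily mortality and
#' lysis:grazing ratio. Extinction of *Prochlorococcus* is recorded in the
#' `coexistence` flag rather than raised.
#'
#' @param baseline A [life_history()] object (the sweep centre).
#' @param parameter One of `r paste(SWEEPABLE, collapse = ", ")`. The phase
#'   `delta_t` is wrapped modulo 1 day after scaling.
#' @param multipliers Multiplier grid; must include 1.
#' @param forcing A [forcing_config()] object.
#' @param burn_in Burn-in, days.
#' @param floor Extinction floor, cells per litre.
#' @param rtol,atol Solver tolerances.
#' @return A `pd_sweep` tibble: `parameter`, `multiplier`, `value`,
#'   `m_total_daily`, `lysis_to_grazing`, `coexistence`.
#' @examples
#' sweep_single(life_history(), "psi", multiplier_grid(5), burn_in = 200)
#' @export
sweep_single <- function(baseline, parameter, multipliers = multiplier_grid(),
                         forcing = forcing_config(), burn_in = 1000,
                         floor = 1, rtol = 1e-8, atol = 1e-2) {
  stopifnot(inherits(baseline, "pd_params"))
  if (!parameter %in% SWEEPABLE) {
    stop("parameter must be one of: ", paste(SWEEPABLE, collapse = ", "),
      call. = FALSE
    )
  }
  if (!any(abs(multipliers - 1) < 1e-12)) {
    stop("multiplier grid must include the baseline value 1", call. = FALSE)
  }
  rows <- purrr::map(multipliers, function(m) {
    value <- baseline[[parameter]] * m
    if (parameter == "delta_t") value <- value %% 1
    if (parameter == "delta_mu") value <- min(value, 1)
    p <- do.call(update_params, c(list(baseline), setNames(list(value), parameter)))
    met <- stationary_metrics(p, forcing, burn_in, floor, rtol, atol)
    dplyr::bind_cols(
      tibble::tibble(parameter = parameter, multiplier = m, value = value),
      met
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
    baseline = baseline, burn_in = burn_in,
    class = c("pd_sweep", class(out))
  )
}

#' Adsorption-clearance covariation grid
#'
#' Full factorial sweep of the viral adsorption rate and grazer clearance
#' rate relative to baseline, recording total daily mortality, the
#' lysis:grazing ratio and an extinction mask (total *Prochlorococcus*
#' below the floor anywhere after burn-in).
#'
#' @inheritParams sweep_single
#' @param phi_multipliers,psi_multipliers Multiplier grids; each must
#'   include 1.
#' @return A `pd_grid` tibble: `phi_multiplier`, `psi_multiplier`,
#'   `m_total_daily`, `lysis_to_grazing`, `extinct`.
#' @examples
#' sweep_pair(life_history(),
#'   phi_multipliers = c(0.5, 1, 2),
#'   psi_multipliers = c(0.5, 1, 2), burn_in = 200
#' )
#' @export
sweep_pair <- function(baseline,
                       phi_multipliers = multiplier_grid(),
                       psi_multipliers = multiplier_grid(),
                       forcing = forcing_config(), burn_in = 1000,
                       floor = 1, rtol = 1e-8, atol = 1e-2) {
  stopifnot(inherits(baseline, "pd_params"))
  if (!any(abs(phi_multipliers - 1) < 1e-12) ||
    !any(abs(psi_multipliers - 1) < 1e-12)) {
    stop("multiplier grids must include the baseline value 1", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    phi_multiplier = phi_multipliers,
    psi_multiplier = psi_multipliers
  )
  rows <- purrr::pmap(grid, function(phi_multiplier, psi_multiplier) {
    p <- update_params(baseline,
      phi = baseline$phi * phi_multiplier,
      psi = baseline$psi * psi_multiplier
    )
    met <- stationary_metrics(p, forcing, burn_in, floor, rtol, atol)
    tibble::tibble(
      phi_multiplier = phi_multiplier,
      psi_multiplier = psi_multiplier,
      m_total_daily = met$m_total_daily,
      lysis_to_grazing = met$lysis_to_grazing,
      extinct = !met$coexistence
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
    baseline = baseline, burn_in = burn_in,
    class = c("pd_grid", class(out))
  )
}

#' Classify parameters into sensitivity arcs
#'
#' Computes, for each swept parameter, the local elasticity (central finite
#' difference of the log response with respect to the log multiplier at
#' multiplier 1) of total daily mortality and of the lysis:grazing ratio,
#' and groups parameters by the sign pattern: parameters whose ratio
#' elasticity is negligible relative to their mortality elasticity form the
#' growth arc; among the rest, opposite signs of the two elasticities mark
#' the viral arc (more infection pressure shifts losses toward lysis while
#' lowering total daily loss) and matching signs mark the grazer arc.
#' Parameters with negligible effect on both axes are labelled
#' `insensitive`.
#'
#' @param sweeps A `pd_sweep` tibble covering one or more parameters (rows
#'   from [sweep_single()], possibly bound together).
#' @param eps Elasticities with absolute value below `eps` count as zero.
#' @param ratio_frac Ratio elasticity below `ratio_frac` times the
#'   mortality elasticity assigns the growth arc. The default 0.5 sits in
#'   the wide gap observed between mortality-dominated parameters
#'   (division rate: ratio/mortality elasticity ~ 0.25) and
#'   ratio-dominated ones (clearance ~ 1.2, adsorption and burst size ~ 10).
#' @return A tibble: `parameter`, `elasticity_mortality`,
#'   `elasticity_ratio`, `arc`.
#' @export
arc_classification <- function(sweeps, eps = 0.02, ratio_frac = 0.5) {
  df <- as_tibble(sweeps)
  if (!all(c("parameter", "multiplier") %in% names(df))) {
    stop("expected a pd_sweep-style tibble", call. = FALSE)
  }
  one <- function(sub) {
    sub <- dplyr::arrange(sub, .data$multiplier)
    i1 <- which(abs(sub$multiplier - 1) < 1e-12)
    if (length(i1) != 1 || i1 == 1 || i1 == nrow(sub)) {
      stop("sweep for '", sub$parameter[1],
        "' lacks interior baseline point",
        call. = FALSE
      )
    }
    if (!sub$coexistence[i1]) {
      stop("baseline does not coexist for '", sub$parameter[1], "'",
        call. = FALSE
      )
    }
    lo <- i1 - 1
    hi <- i1 + 1
    if (!sub$coexistence[lo] || !sub$coexistence[hi]) {
      return(tibble::tibble(
        parameter = sub$parameter[1],
        elasticity_mortality = NA_real_, elasticity_ratio = NA_real_,
        arc = "extinction-bounded"
      ))
    }
    dlm <- log(sub$multiplier[hi]) - log(sub$multiplier[lo])
    e_mort <- (log(sub$m_total_daily[hi]) - log(sub$m_total_daily[lo])) / dlm
    e_ratio <- (log(sub$lysis_to_grazing[hi]) -
      log(sub$lysis_to_grazing[lo])) / dlm
    arc <- if (abs(e_mort) < eps && abs(e_ratio) < eps) {
      "insensitive"
    } else if (abs(e_ratio) < max(eps, ratio_frac * abs(e_mort))) {
      "growth"
    } else if (sign(e_ratio) != sign(e_mort)) {
      "viral"
    } else {
      "grazer"
    }
    tibble::tibble(
      parameter = sub$parameter[1],
      elasticity_mortality = e_mort, elasticity_ratio = e_ratio, arc = arc
    )
  }
  df |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_split() |>
    purrr::map(one) |>
    dplyr::bind_rows()
}

#' Write sweep or grid results with a JSON manifest
#'
#' @param x A `pd_sweep` or `pd_grid` tibble.
#' @param path_csv CSV output path (long format).
#' @param path_manifest Optional JSON manifest path recording the baseline
#'   parameters and burn-in.
#' @return `path_csv`, invisibly.
#' @export
write_sweep <- function(x, path_csv, path_manifest = NULL) {
  readr::write_csv(as_tibble(x), path_csv)
  if (!is.null(path_manifest)) {
    jsonlite::write_json(
      list(
        baseline = unclass(attr(x, "baseline")),
        burn_in = attr(x, "burn_in")
      ),
      path_manifest,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path_csv)
}
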