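#' Life-history parameter set for the community model
#'
#' Bundles every rate and trait entering the four-compartment model of
#' susceptible (`S`) and virally infected (`I`) *Prochlorococcus*, free
#' cyanophage (`V`) and heterotrophic nanoflagellate grazers (`G`).
#' The defaults describe a coexistence regime representative of oligotrophic
#' open-ocean surface waters (total *Prochlorococcus* near 1e8 cells per
#' litre, a few percent of cells infected, phage near 1e9 per litre and
#' grazers near 1e6 per litre) and are the generator truth used throughout
#' the package's synthetic-data experiments.
#'
#' @param mu_ave Mean division rate, day^-1.
#' @param delta_mu Fractional amplitude of the diel division oscillation,
#'   dimensionless in `[0, 1]`.
#' @param delta_t Phase offset of the division oscillation, days in `[0, 1)`.
#' @param m_P Higher-order (quadratic) *Prochlorococcus* loss coefficient,
#'   L cell^-1 day^-1; implicitly represents niche competition.
#' @param m_V Higher-order viral loss coefficient, L virion^-1 day^-1.
#' @param m_G Higher-order grazer loss coefficient, L grazer^-1 day^-1.
#' @param phi Viral adsorption rate, L day^-1.
#' @param psi Grazer clearance rate, L day^-1.
#' @param beta Burst size, virions released per lysed cell (>= 1).
#' @param eta Lysis rate (reciprocal of the mean latent period), day^-1.
#' @param e_eff Effective gross growth efficiency: grazer individuals
#'   produced per *Prochlorococcus* cell consumed. This is the product of the
#'   gross growth efficiency with the prey:grazer nitrogen-quota ratio; the
#'   three factors enter the dynamics only through this product and are not
#'   separately identifiable, so they are represented as one parameter.
#' @param gamma Net generalist grazer gain rate from non-*Prochlorococcus*
#'   prey, day^-1; `gamma = 0` is a pure specialist.
#'
#' @return A `pd_params` object (named list of validated numeric scalars).
#' @seealso [forcing_config()], [simulate_community()]
#' @examples
#' p <- life_history()
#' division_rate(0.25, p)
#' @export
life_history <- function(mu_ave = 0.5,
                         delta_mu = 0.5,
                         delta_t = 0.65,
                         m_P = 3e-10,
                         m_V = 8.6e-10,
                         m_G = 5e-08,
                         phi = 4e-11,
                         psi = 4.4e-07,
                         beta = 288,
                         eta = 1.5,
                         e_eff = 1.14e-03,
                         gamma = 0) {
  p <- list(
    mu_ave = mu_ave, delta_mu = delta_mu, delta_t = delta_t,
    m_P = m_P, m_V = m_V, m_G = m_G, phi = phi, psi = psi,
    beta = beta, eta = eta, e_eff = e_eff, gamma = gamma
  )
  validate_params(p)
  structure(p, class = "pd_params")
}

validate_params <- function(p) {
  nm <- c(
    "mu_ave", "delta_mu", "delta_t", "m_P", "m_V", "m_G",
    "phi", "psi", "beta", "eta", "e_eff", "gamma"
  )
  missing <- setdiff(nm, names(p))
  if (length(missing) > 0) {
    stop("missing life-history parameters: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  for (f in nm) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", f, "' must be a finite numeric scalar", call. = FALSE)
    }
    if (v < 0) stop("parameter '", f, "' must be >= 0", call. = FALSE)
  }
  if (p$delta_mu > 1) {
    stop("delta_mu must lie in [0, 1]: larger values give a negative ",
      "division rate",
      call. = FALSE
    )
  }
  if (p$delta_t >= 1) {
    stop("delta_t must lie in [0, 1) (it is a phase in days)", call. = FALSE)
  }
  if (p$beta < 1) stop("burst size beta must be >= 1", call. = FALSE)
  invisible(p)
}

#' Modify a life-history parameter set
#'
#' @param params A [life_history()] object.
#' @param ... Named parameter replacements.
#' @return A validated `pd_params` object.
#' @examples
#' update_params(life_history(), gamma = 0.5, m_G = 5.5e-7)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "pd_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown) > 0) {
    stop("unknown parameters: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  params[names(repl)] <- repl
  validate_params(params)
  structure(params, class = "pd_params")
}

#' @export
print.pd_params <- function(x, ...) {
  cat("<life-history parameters>\n")
  print(tidy_params(x), n = Inf)
  invisible(x)
}

tidy_params <- function(p) {
  tibble::tibble(
    parameter = names(unclass(p)),
    value = unname(unlist(unclass(p)))
  )
}

#' @rdname life_history
#' @param x A `pd_params` object.
#' @param ... Unused.
#' @export
tidy.pd_params <- function(x, ...) tidy_params(x)

#' Diel forcing configuration
#'
#' Controls the step-wise diel modulation of the viral adsorption rate. The
#' clock convention throughout the package is that `t = 0` corresponds to
#' 06:00 local time, so local noon is `t mod 1 = 0.25` and local midnight is
#' `t mod 1 = 0.75`. When active, adsorption is multiplied by `low_factor`
#' from midnight to noon (the dawn half-day) and by `high_factor` from noon
#' to midnight (the dusk half-day); the defaults (0.5, 1.5) preserve the
#' daily mean adsorption rate.
#'
#' @param diel_adsorption Logical; switch the diel adsorption step on.
#' @param low_factor Multiplier applied midnight to noon.
#' @param high_factor Multiplier applied noon to midnight.
#' @param preserve_mean Logical; when `TRUE` (default) require
#'   `(low_factor + high_factor) / 2 == 1` so the daily mean adsorption rate
#'   is unchanged.
#' @return A `pd_forcing` object.
#' @examples
#' adsorption_multiplier(c(0, 0.5), forcing_config(TRUE))
#' @export
forcing_config <- function(diel_adsorption = FALSE,
                           low_factor = 0.5,
                           high_factor = 1.5,
                           preserve_mean = TRUE) {
  stopifnot(
    is.logical(diel_adsorption), length(diel_adsorption) == 1,
    is.numeric(low_factor), low_factor >= 0,
    is.numeric(high_factor), high_factor >= 0
  )
  if (preserve_mean && abs((low_factor + high_factor) / 2 - 1) > 1e-12) {
    stop("diel factors do not preserve the mean adsorption rate: ",
      "(low_factor + high_factor) / 2 must equal 1",
      call. = FALSE
    )
  }
  structure(
    list(
      diel_adsorption = diel_adsorption,
      low_factor = low_factor,
      high_factor = high_factor,
      clock_origin = "06:00"
    ),
    class = "pd_forcing"
  )
}

#' @export
print.pd_forcing <- function(x, ...) {
  cat(
    "<diel forcing> adsorption step:",
    if (x$diel_adsorption) "on" else "off",
    sprintf(
      "(low %.3g midnight-noon, high %.3g noon-midnight; t = 0 is %s)",
      x$low_factor, x$high_factor, x$clock_origin
    ), "\n"
  )
  invisible(x)
}

#' Read or write a parameter configuration file
#'
#' Parameter sets and forcing configuration are serialized as YAML with keys
#' exactly matching the field names of [life_history()] and
#' [forcing_config()].
#'
#' @param path File path.
#' @return `read_params_config()` returns a list with elements `params`
#'   (`pd_params`) and `forcing` (`pd_forcing`).
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_params_config(life_history(), forcing_config(), path)
#' cfg <- read_params_config(path)
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$params)) stop("config has no 'params' block", call. = FALSE)
  params <- do.call(life_history, cfg$params)
  forcing <- if (is.null(cfg$forcing)) {
    forcing_config()
  } else {
    do.call(forcing_config, cfg$forcing[
      intersect(
        names(cfg$forcing),
        c("diel_adsorption", "low_factor", "high_factor", "preserve_mean")
      )
    ])
  }
  list(params = params, forcing = forcing)
}

#' @rdname read_params_config
#' @param params A [life_history()] object.
#' @param forcing A [forcing_config()] object.
#' @export
write_params_config <- function(params, forcing = forcing_config(), path) {
  stopifnot(inherits(params, "pd_params"), inherits(forcing, "pd_forcing"))
  yaml::write_yaml(
    list(
      params = unclass(params),
      forcing = unclass(forcing)[c(
        "diel_adsorption", "low_factor",
        "high_factor"
      )]
    ),
    path
  )
  invisible(path)
}
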