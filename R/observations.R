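SIGNALS <- c("pro", "infected_pct", "virus", "grazer")

new_obs <- function(df, detrended = FALSE, trend = NULL) {
  structure(df,
    detrended = detrended, trend = trend,
    class = unique(c("pd_obs", class(tibble::tibble())))
  )
}

#' Read a multi-signal observation CSV
#'
#' Observation sets are tidy long CSVs with columns `time_days`, `signal`,
#' `value` and optionally `uncertainty`. The four recognised signals are
#' `pro` (total *Prochlorococcus*, cells per litre), `infected_pct`
#' (percentage of infected cells), `virus` (free virions per litre) and
#' `grazer` (nanoflagellates per litre); each signal may sit on its own time
#' grid (in the field, cell counts are near-continuous while the other three
#' signals are sampled every few hours). Times are days since 06:00 local on
#' day 0. Rows with missing values are dropped with a message giving the
#' count.
#'
#' @param path CSV file path.
#' @return A `pd_obs` tibble with columns `time_days`, `signal`, `value`
#'   (and `uncertainty` when present in the file).
#' @export
read_observations <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  validate_observations(df)
}

#' @rdname read_observations
#' @param observations A `pd_obs` tibble (e.g. from
#'   [generate_observations()]).
#' @export
write_observations <- function(observations, path) {
  readr::write_csv(as_tibble(observations), path)
  invisible(path)
}

#' @rdname read_observations
#' @export
validate_observations <- function(observations) {
  df <- as_tibble(observations)
  allowed <- c("time_days", "signal", "value", "uncertainty")
  unknown <- setdiff(names(df), allowed)
  if (length(unknown) > 0) {
    stop("unknown observation columns: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(c("time_days", "signal", "value") %in% names(df))) {
    stop("observations need columns time_days, signal, value", call. = FALSE)
  }
  bad_sig <- setdiff(unique(df$signal), SIGNALS)
  if (length(bad_sig) > 0) {
    stop("unknown signals: ", paste(bad_sig, collapse = ", "),
      "; expected ", paste(SIGNALS, collapse = ", "),
      call. = FALSE
    )
  }
  n_na <- sum(is.na(df$value) | is.na(df$time_days))
  if (n_na > 0) {
    message("dropping ", n_na, " row(s) with missing values")
    df <- df[!(is.na(df$value) | is.na(df$time_days)), ]
  }
  for (s in unique(df$signal)) {
    ts <- df$time_days[df$signal == s]
    if (is.unsorted(ts, strictly = TRUE)) {
      stop("times for signal '", s, "' are not strictly increasing",
        call. = FALSE
      )
    }
  }
  if (any(df$value < 0)) {
    stop("negative observation values are not allowed", call. = FALSE)
  }
  pct <- df$value[df$signal == "infected_pct"]
  if (length(pct) > 0 && any(pct > 100)) {
    stop("infected_pct above 100", call. = FALSE)
  }
  new_obs(df)
}

trend_design <- function(times, family) {
  switch(family,
    constant = cbind(intercept = rep(1, length(times))),
    linear = cbind(intercept = rep(1, length(times)), slope = times),
    stop("unknown trend family: ", family, call. = FALSE)
  )
}

#' Fit a slow trend to each observed signal
#'
#' The fitting convention for this model is to remove a slow multi-day trend
#' from each signal so the dynamics are fitted to diel-scale variation, and
#' to add the trend back to model output for visualization. The default
#' family is an ordinary least-squares linear trend per signal, fitted
#' independently on each signal's own time grid; a `constant` family
#' (mean removal) and a `loess` smooth are also available.
#'
#' @param observations A `pd_obs` tibble.
#' @param family One of `"linear"` (default), `"constant"`, `"loess"`.
#' @param span Loess span (only for `family = "loess"`).
#' @return A `pd_trend` object. `tidy()` returns the per-signal
#'   coefficients.
#' @examples
#' obs <- generate_observations(generator_config(seed = 1))
#' trend <- fit_trend(obs)
#' tidy(trend)
#' @export
fit_trend <- function(observations, family = c("linear", "constant", "loess"),
                      span = 0.75) {
  family <- match.arg(family)
  df <- as_tibble(observations)
  models <- list()
  for (s in unique(df$signal)) {
    sub <- df[df$signal == s, ]
    if (nrow(sub) < 3) {
      stop("signal '", s, "' has fewer than 3 samples", call. = FALSE)
    }
    if (length(unique(sub$time_days)) < 2 && family != "constant") {
      stop("degenerate time grid for signal '", s, "'", call. = FALSE)
    }
    models[[s]] <- if (family == "loess") {
      stats::loess(value ~ time_days,
        data = sub, span = span,
        control = stats::loess.control(surface = "direct")
      )
    } else {
      X <- trend_design(sub$time_days, family)
      qr_fit <- stats::lm.fit(X, sub$value)
      list(coefficients = coef(qr_fit), family = family)
    }
  }
  structure(list(family = family, models = models, span = span),
    class = "pd_trend"
  )
}

trend_predict <- function(trend, signal, times) {
  m <- trend$models[[signal]]
  if (is.null(m)) {
    stop("trend has no fit for signal '", signal, "'", call. = FALSE)
  }
  if (trend$family == "loess") {
    as.numeric(stats::predict(m, newdata = data.frame(time_days = times)))
  } else {
    as.numeric(trend_design(times, trend$family) %*% m$coefficients)
  }
}

#' @rdname fit_trend
#' @param x A `pd_trend` object.
#' @param ... Unused.
#' @export
tidy.pd_trend <- function(x, ...) {
  if (x$family == "loess") {
    return(tibble::tibble(
      signal = names(x$models), family = "loess",
      span = x$span
    ))
  }
  purrr::imap(x$models, function(m, s) {
    co <- m$coefficients
    tibble::tibble(
      signal = s, family = x$family,
      term = names(co), estimate = unname(co)
    )
  }) |> dplyr::bind_rows()
}

#' @export
print.pd_trend <- function(x, ...) {
  cat("<per-signal trend model> family:", x$family, "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Remove or re-add the slow trend
#'
#' `detrend()` subtracts the fitted trend (evaluated on each signal's own
#' time grid) from an observation set; `retrend()` adds a trend fitted on
#' data back onto a series (typically model output sampled on the
#' observation grid) for visualization. The two are exact inverses:
#' `retrend(detrend(x, trend), trend)` reproduces `x`.
#'
#' @param observations A `pd_obs` tibble (long format).
#' @param trend A [fit_trend()] result; `detrend()` fits a linear trend
#'   itself when omitted.
#' @return A `pd_obs` tibble; `detrend()` results carry the trend in the
#'   `trend` attribute and are flagged via the `detrended` attribute.
#' @examples
#' obs <- generate_observations(generator_config(seed = 1))
#' resid <- detrend(obs)
#' back <- retrend(resid, attr(resid, "trend"))
#' all.equal(back$value, obs$value)
#' @export
detrend <- function(observations, trend = NULL) {
  df <- as_tibble(observations)
  if (is.null(trend)) trend <- fit_trend(observations)
  out <- df
  for (s in unique(df$signal)) {
    idx <- df$signal == s
    out$value[idx] <- df$value[idx] - trend_predict(trend, s, df$time_days[idx])
  }
  new_obs(out, detrended = TRUE, trend = trend)
}

#' @rdname detrend
#' @param series A long tibble with columns `time_days`, `signal`, `value`
#'   (e.g. model output via [observe_long()]).
#' @export
retrend <- function(series, trend) {
  stopifnot(inherits(trend, "pd_trend"))
  df <- as_tibble(series)
  for (s in unique(df$signal)) {
    idx <- df$signal == s
    df$value[idx] <- df$value[idx] + trend_predict(trend, s, df$time_days[idx])
  }
  new_obs(df, detrended = FALSE, trend = trend)
}

#' Model observables in long observation format
#'
#' Convenience bridge from a trajectory to the long `(time_days, signal,
#' value)` layout used by the observation tools, optionally restricted to
#' given per-signal time grids by linear interpolation.
#'
#' @param trajectory A `pd_trajectory`.
#' @param grids Optional named list of time grids per signal.
#' @return A `pd_obs` tibble.
#' @export
observe_long <- function(trajectory, grids = NULL) {
  wide <- observe(trajectory)
  out <- purrr::map(SIGNALS, function(s) {
    if (is.null(grids) || is.null(grids[[s]])) {
      tibble::tibble(time_days = wide$time_days, signal = s, value = wide[[s]])
    } else {
      tibble::tibble(
        time_days = grids[[s]], signal = s,
        value = approx(wide$time_days, wide[[s]], xout = grids[[s]])$y
      )
    }
  }) |> dplyr::bind_rows()
  new_obs(out)
}
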