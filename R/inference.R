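FREE_PARAMS <- c(
  "mu_ave", "delta_mu", "delta_t", "m_P", "m_V", "m_G",
  "phi", "psi", "beta", "eta", "e_eff"
)

#' Prior specification for Bayesian fitting
#'
#' Biologically motivated bounds for the free life-history parameters.
#' Rates and coefficients spanning orders of magnitude get log-uniform
#' priors over four decades bracketing plausible open-ocean values; bounded
#' shape parameters get uniform priors. These shipped defaults are
#' implementer choices documented here, not published values; any bound or
#' family can be replaced without code changes, and a `truncated-normal`
#' family is available for informative priors. The grazing-generalism rate
#' `gamma` is fixed per model variant, not inferred.
#'
#' Initial conditions of the four compartments are additional inferred
#' quantities with lognormal priors centred on the values implied by the
#' first observations (`sdlog = ic_sdlog`), and the per-signal Gaussian
#' noise scales of the likelihood are inferred with half-normal priors
#' whose scales default to 1.5 times the standard deviation of each
#' detrended signal.
#'
#' @param gamma Fixed generalist grazing rate for this model variant,
#'   day^-1.
#' @param parameters A tibble with columns `parameter`, `family`
#'   (`"uniform"`, `"log-uniform"` or `"truncated-normal"`), `lower`,
#'   `upper`, and (for `truncated-normal`) `mean`, `sd`. Defaults cover the
#'   11 free parameters.
#' @param fixed Named list of additional parameters to fix (removed from
#'   the free set).
#' @param ic_sdlog Lognormal sdlog of the initial-condition priors.
#' @param sigma_scale_factor Half-normal scale of each noise prior, as a
#'   multiple of the detrended signal standard deviation.
#' @return A `pd_priors` object.
#' @examples
#' prior_spec(gamma = 0.05)
#' @export
prior_spec <- function(gamma = 0,
                       parameters = default_prior_table(),
                       fixed = list(),
                       ic_sdlog = 0.1,
                       sigma_scale_factor = 1.5) {
  stopifnot(is.numeric(gamma), gamma >= 0)
  tab <- as_tibble(parameters)
  need <- c("parameter", "family", "lower", "upper")
  if (!all(need %in% names(tab))) {
    stop("prior table needs columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"mean" %in% names(tab)) tab$mean <- NA_real_
  if (!"sd" %in% names(tab)) tab$sd <- NA_real_
  bad <- !tab$family %in% c("uniform", "log-uniform", "truncated-normal")
  if (any(bad)) {
    stop("unknown prior families: ", paste(unique(tab$family[bad]),
      collapse = ", "
    ), call. = FALSE)
  }
  if (any(!is.finite(tab$lower) | !is.finite(tab$upper) |
    tab$lower >= tab$upper)) {
    stop("prior bounds must be finite with lower < upper", call. = FALSE)
  }
  if (any(tab$family == "log-uniform" & tab$lower <= 0)) {
    stop("log-uniform priors need a positive lower bound", call. = FALSE)
  }
  tn <- tab$family == "truncated-normal"
  if (any(tn & (!is.finite(tab$mean) | !is.finite(tab$sd) | tab$sd <= 0))) {
    stop("truncated-normal priors need finite mean and positive sd",
      call. = FALSE
    )
  }
  tab <- tab[!tab$parameter %in% names(fixed), ]
  structure(
    list(
      gamma = gamma, parameters = tab, fixed = fixed,
      ic_sdlog = ic_sdlog, sigma_scale_factor = sigma_scale_factor
    ),
    class = "pd_priors"
  )
}

#' @rdname prior_spec
#' @export
default_prior_table <- function() {
  tibble::tribble(
    ~parameter, ~family, ~lower, ~upper,
    "mu_ave", "uniform", 0.1, 1.5,
    "delta_mu", "uniform", 0, 1,
    "delta_t", "uniform", 0, 1,
    "m_P", "log-uniform", 1e-12, 1e-8,
    "m_V", "log-uniform", 1e-12, 1e-8,
    "m_G", "log-uniform", 1e-10, 1e-6,
    "phi", "log-uniform", 1e-13, 1e-9,
    "psi", "log-uniform", 1e-9, 1e-5,
    "beta", "log-uniform", 1, 500,
    "eta", "uniform", 0.5, 6,
    "e_eff", "log-uniform", 1e-5, 1e-1
  )
}

#' @export
print.pd_priors <- function(x, ...) {
  cat("<prior specification> gamma fixed at", x$gamma, "\n")
  print(x$parameters, n = Inf)
  if (length(x$fixed) > 0) {
    cat(
      "fixed:",
      paste(names(x$fixed), unlist(x$fixed), sep = " = ", collapse = ", "),
      "\n"
    )
  }
  invisible(x)
}

# ---- transforms between unconstrained and natural scales -------------------

sigmoid <- function(u) 1 / (1 + exp(-u))

# Per-dimension transform spec: list(type, a, b, meanlog/sdlog or scale, ...)
make_transforms <- function(priors, ic_centers, sigma_scales) {
  tr <- list()
  tab <- priors$parameters
  for (i in seq_len(nrow(tab))) {
    row <- as.list(tab[i, ])
    tr[[row$parameter]] <- row
  }
  for (s in names(ic_centers)) {
    tr[[s]] <- list(
      parameter = s, family = "lognormal",
      meanlog = log(ic_centers[[s]]), sdlog = priors$ic_sdlog
    )
  }
  for (s in names(sigma_scales)) {
    tr[[paste0("sigma_", s)]] <- list(
      parameter = paste0("sigma_", s),
      family = "half-normal", scale = sigma_scales[[s]]
    )
  }
  tr
}

# natural value for one dimension (vectorized over u)
to_natural_1 <- function(u, tr) {
  switch(tr$family,
    "uniform" = ,
    "truncated-normal" = tr$lower + (tr$upper - tr$lower) * sigmoid(u),
    "log-uniform" = exp(log(tr$lower) +
      (log(tr$upper) - log(tr$lower)) * sigmoid(u)),
    "lognormal" = ,
    "half-normal" = exp(u),
    stop("bad transform")
  )
}

from_natural_1 <- function(x, tr) {
  switch(tr$family,
    "uniform" = ,
    "truncated-normal" = {
      s <- (x - tr$lower) / (tr$upper - tr$lower)
      s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
      log(s / (1 - s))
    },
    "log-uniform" = {
      s <- (log(x) - log(tr$lower)) / (log(tr$upper) - log(tr$lower))
      s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
      log(s / (1 - s))
    },
    "lognormal" = ,
    "half-normal" = log(x)
  )
}

# log prior density of the natural value plus log |dx/du| for one dimension
logprior_jac_1 <- function(u, x, tr) {
  switch(tr$family,
    "uniform" = {
      s <- sigmoid(u)
      -log(tr$upper - tr$lower) +
        log(tr$upper - tr$lower) + log(s) + log1p(-s)
    },
    "truncated-normal" = {
      s <- sigmoid(u)
      stats::dnorm(x, tr$mean, tr$sd, log = TRUE) +
        log(tr$upper - tr$lower) + log(s) + log1p(-s)
    },
    "log-uniform" = {
      s <- sigmoid(u)
      log(s) + log1p(-s) # densities in x and Jacobian terms cancel
    },
    "lognormal" = stats::dlnorm(x, tr$meanlog, tr$sdlog, log = TRUE) + log(x),
    "half-normal" = 0.5 * log(2 / pi) - log(tr$scale) -
      0.5 * (x / tr$scale)^2 + log(x)
  )
}

# ---- likelihood machinery --------------------------------------------------

ensure_detrended <- function(observations, trend_family = "linear") {
  if (isTRUE(attr(observations, "detrended", exact = TRUE))) {
    return(observations)
  }
  message("observations are not detrended; fitting and removing a ",
    trend_family, " trend")
  detrend(observations, fit_trend(observations, family = trend_family))
}

# Precompute everything the likelihood needs: the union simulation grid,
# per-signal index maps, detrended data, and the least-squares projector of
# the trend family on each signal's grid (so model output is detrended with
# the same family at negligible cost).
likelihood_context <- function(obs_det, forcing, rtol, atol) {
  df <- as_tibble(obs_det)
  trend <- attr(obs_det, "trend", exact = TRUE)
  family <- if (is.null(trend) || trend$family == "loess") {
    "linear"
  } else {
    trend$family
  }
  t_all <- sort(unique(df$time_days))
  per_signal <- list()
  for (s in intersect(SIGNALS, unique(df$signal))) {
    sub <- df[df$signal == s, ]
    X <- trend_design(sub$time_days, family)
    A <- solve(crossprod(X), t(X)) # (X'X)^{-1} X'
    per_signal[[s]] <- list(
      idx = match(sub$time_days, t_all),
      y = sub$value,
      n = nrow(sub),
      X = X, A = A
    )
  }
  # initial-condition centres from the first (raw-scale) observations
  first_raw <- function(s, default) {
    ps <- per_signal[[s]]
    if (is.null(ps)) {
      return(default)
    }
    v <- ps$y[1]
    if (!is.null(trend)) {
      v <- v + trend_predict(trend, s, df$time_days[df$signal == s][1])
    }
    v
  }
  pro1 <- max(first_raw("pro", 1e8), 1)
  pct1 <- min(max(first_raw("infected_pct", 2), 0.01), 99.9)
  ic_centers <- list(
    S0 = pro1 * (1 - pct1 / 100),
    I0 = max(pro1 * pct1 / 100, 1e-4 * pro1),
    V0 = max(first_raw("virus", 1e9), 1),
    G0 = max(first_raw("grazer", 1e6), 1)
  )
  sigma_sd <- purrr::map(per_signal, function(ps) max(sd(ps$y), 1e-12))
  list(
    t_all = t_all, per_signal = per_signal, ic_centers = ic_centers,
    sigma_sd = sigma_sd, forcing = forcing, rtol = rtol, atol = atol,
    trend_family = family
  )
}

# core Gaussian likelihood of detrended data given natural-scale values
loglik_core <- function(ctx, params_list, init_vec, sigma_list) {
  states <- tryCatch(
    .integrate_cpp(
      ctx$t_all, init_vec, params_list, unclass(ctx$forcing),
      ctx$rtol, ctx$atol, 1e15, 2000000L
    )$states,
    error = function(e) NULL
  )
  if (is.null(states)) {
    return(-Inf)
  }
  P <- states[, 1] + states[, 2]
  ll <- 0
  for (s in names(ctx$per_signal)) {
    ps <- ctx$per_signal[[s]]
    m <- switch(s,
      pro = P[ps$idx],
      infected_pct = {
        Pi <- P[ps$idx]
        ifelse(Pi > 0, 100 * states[ps$idx, 2] / Pi, 0)
      },
      virus = states[ps$idx, 3],
      grazer = states[ps$idx, 4]
    )
    m_det <- m - ps$X %*% (ps$A %*% m)
    r <- ps$y - as.numeric(m_det)
    sg <- sigma_list[[s]]
    ll <- ll + sum(stats::dnorm(r, 0, sg, log = TRUE))
  }
  ll
}

#' Log-likelihood of an observation set
#'
#' Simulates the model from the given initial conditions over the
#' observation window, detrends the model observables with the same trend
#' family used for the data, and sums independent Gaussian log-densities of
#' the detrended residuals per signal. A failed simulation yields `-Inf`
#' (the proposal is rejected) with a message.
#'
#' @param params A [life_history()] object.
#' @param observations A detrended `pd_obs` (see [detrend()]); raw
#'   observations are detrended on the fly with a message.
#' @param sigma Named per-signal noise scales (units of each signal), e.g.
#'   `c(pro = 2e6, infected_pct = 0.5, virus = 1e8, grazer = 5e4)`.
#' @param init Initial state at the first observation time.
#' @param forcing A [forcing_config()] object.
#' @param rtol,atol Solver tolerances for the embedded simulation.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(params, observations, sigma,
                           init = default_init(),
                           forcing = forcing_config(),
                           rtol = 1e-6, atol = 1) {
  stopifnot(inherits(params, "pd_params"))
  validate_params(params)
  obs_det <- ensure_detrended(observations)
  ctx <- likelihood_context(obs_det, forcing, rtol, atol)
  missing_sigma <- setdiff(names(ctx$per_signal), names(sigma))
  if (length(missing_sigma) > 0) {
    stop("sigma missing for signals: ", paste(missing_sigma, collapse = ", "),
      call. = FALSE
    )
  }
  ll <- loglik_core(ctx, unclass(params), as_state_vector(init), as.list(sigma))
  if (!is.finite(ll)) message("simulation failed; log-likelihood set to -Inf")
  ll
}

# ---- posterior sampling ----------------------------------------------------

build_posterior <- function(obs_det, priors, gamma, forcing, rtol, atol,
                            use_likelihood = TRUE) {
  ctx <- likelihood_context(obs_det, forcing, rtol, atol)
  sigma_scales <- purrr::map(
    ctx$sigma_sd,
    function(v) priors$sigma_scale_factor * v
  )
  transforms <- make_transforms(priors, ctx$ic_centers, sigma_scales)
  dim_names <- names(transforms)
  ndim <- length(dim_names)
  free <- priors$parameters$parameter
  fixed <- priors$fixed
  template <- unclass(life_history()) # field order for the C++ layer
  template$gamma <- gamma
  for (f in names(fixed)) template[[f]] <- fixed[[f]]
  sig_names <- names(ctx$sigma_sd)

  to_natural <- function(u) {
    x <- vector("list", ndim)
    names(x) <- dim_names
    for (i in seq_len(ndim)) x[[i]] <- to_natural_1(u[i], transforms[[i]])
    x
  }

  logpost <- function(u) {
    lp <- 0
    x <- vector("list", ndim)
    names(x) <- dim_names
    for (i in seq_len(ndim)) {
      xi <- to_natural_1(u[i], transforms[[i]])
      x[[i]] <- xi
      lp <- lp + logprior_jac_1(u[i], xi, transforms[[i]])
    }
    if (!is.finite(lp)) {
      return(c(-Inf, -Inf))
    }
    ll <- 0
    if (use_likelihood) {
      pl <- template
      for (f in free) pl[[f]] <- x[[f]]
      if (pl$delta_mu > 1 || pl$delta_t >= 1) {
        return(c(-Inf, -Inf))
      }
      init_vec <- c(x$S0, x$I0, x$V0, x$G0)
      sig <- x[paste0("sigma_", sig_names)]
      names(sig) <- sig_names
      ll <- loglik_core(ctx, pl, init_vec, sig)
      if (!is.finite(ll)) {
        return(c(-Inf, -Inf))
      }
    }
    c(lp + ll, ll)
  }

  # starting point: prior centres for free parameters, observation-implied
  # initial conditions, mid-scale noise (see build_posterior callers)
  start <- numeric(ndim)
  names(start) <- dim_names
  for (i in seq_len(ndim)) {
    tr <- transforms[[i]]
    start[i] <- switch(tr$family,
      "uniform" = ,
      "truncated-normal" = 0,
      "log-uniform" = 0,
      "lognormal" = tr$meanlog,
      "half-normal" = log(tr$scale / 3)
    )
  }
  list(
    logpost = logpost, ndim = ndim, dim_names = dim_names,
    to_natural = to_natural, transforms = transforms, start = start,
    ctx = ctx, template = template, free = free, sig_names = sig_names
  )
}

#' Sample the posterior of the community model
#'
#' Bayesian estimation of the free life-history parameters (plus initial
#' conditions and per-signal noise scales) for one grazing-generalism
#' variant, using a seeded affine-invariant stretch-move ensemble sampler
#' run as several independent ensembles ("chains"). Sampling is performed
#' on transformed (unconstrained) parameters; bounded priors use a logit
#' transform and positive quantities a log transform. Walkers are
#' initialized in a small ball around a short posterior-mode search so the
#' warmup is spent exploring the posterior rather than finding it.
#'
#' Convergence is summarised by split R-hat (each walker split in half) and
#' an autocorrelation-based effective sample size; the fit is flagged
#' non-converged (but still returned) when any parameter's R-hat exceeds
#' 1.05.
#'
#' @param observations A detrended `pd_obs`; raw observations are detrended
#'   with a linear trend and a message.
#' @param priors A [prior_spec()].
#' @param gamma Generalist grazing rate of this variant; defaults to
#'   `priors$gamma`.
#' @param n_chains Independent ensembles.
#' @param n_warmup,n_samples Warmup and retained sweeps per ensemble.
#' @param seed Integer seed; fits are exactly reproducible given the seed.
#' @param n_walkers Walkers per ensemble (default `3 * ndim + 3`; larger
#'   ensembles equilibrate ridge-shaped posteriors faster per sweep).
#' @param forcing A [forcing_config()] object.
#' @param likelihood `"full"` or `"off"` (prior-only sampling, for
#'   validation).
#' @param rtol,atol Solver tolerances used inside the likelihood.
#' @param stretch Stretch-move scale parameter `a`.
#' @param optim_start Run the short mode search before sampling.
#' @return A `pd_fit` object; see [tidy.pd_fit()] and [glance.pd_fit()].
#' @export
sample_posterior <- function(observations, priors = prior_spec(),
                             gamma = NULL,
                             n_chains = 4, n_warmup = 500, n_samples = 500,
                             seed = 1, n_walkers = NULL,
                             forcing = forcing_config(),
                             likelihood = c("full", "off"),
                             rtol = 1e-6, atol = 1,
                             stretch = 1.7, optim_start = TRUE) {
  stopifnot(inherits(priors, "pd_priors"))
  likelihood <- match.arg(likelihood)
  gamma <- gamma %||% priors$gamma
  obs_det <- ensure_detrended(observations)
  post <- build_posterior(obs_det, priors, gamma, forcing, rtol, atol,
    use_likelihood = likelihood == "full"
  )
  ndim <- post$ndim
  n_walkers <- n_walkers %||% (3L * ndim + 3L)
  if (n_walkers < 2 * ndim) {
    warning("fewer than 2 * ndim walkers; stretch moves degrade",
      call. = FALSE
    )
  }

  draws_u <- array(NA_real_,
    dim = c(n_samples, n_walkers, ndim, n_chains),
    dimnames = list(NULL, NULL, post$dim_names, NULL)
  )
  ll_store <- array(NA_real_, dim = c(n_samples, n_walkers, n_chains))
  accept <- 0
  total_prop <- 0

  with_local_seed(seed, {
    start <- post$start
    scatter <- NULL # Cholesky factor of the initialization covariance
    if (optim_start) {
      negp <- function(u) {
        v <- post$logpost(u)[1]
        if (!is.finite(v)) 1e10 else -v
      }
      if (likelihood == "full") {
        opt <- optim(start, negp,
          method = "Nelder-Mead",
          control = list(maxit = 1000)
        )
        opt <- optim(opt$par, negp,
          method = "BFGS",
          control = list(maxit = 200)
        )
        start <- opt$par
      }
      # Laplace approximation at the mode: walkers are dispersed with the
      # local posterior covariance so weakly curved (ridge) directions are
      # populated from the start instead of being discovered by diffusion
      scatter <- tryCatch(
        {
          H <- numeric_hessian(negp, start)
          laplace_chol(H)
        },
        error = function(e) NULL
      )
    }
    for (chain in seq_len(n_chains)) {
      walkers <- matrix(NA_real_, n_walkers, ndim)
      lp <- numeric(n_walkers)
      ll <- numeric(n_walkers)
      for (w in seq_len(n_walkers)) {
        for (try in 1:200) {
          u <- if (is.null(scatter)) {
            start + 0.05 * rnorm(ndim)
          } else {
            start + as.numeric(scatter %*% rnorm(ndim))
          }
          v <- post$logpost(u)
          if (is.finite(v[1])) break
        }
        if (!is.finite(v[1])) {
          stop("could not initialize walkers at a finite posterior",
            call. = FALSE
          )
        }
        walkers[w, ] <- u
        lp[w] <- v[1]
        ll[w] <- v[2]
      }
      halves <- list(
        seq_len(n_walkers %/% 2),
        (n_walkers %/% 2 + 1):n_walkers
      )
      g_de <- 2.38 / sqrt(2 * ndim)
      n_total <- n_warmup + n_samples
      for (step in seq_len(n_total)) {
        for (h in 1:2) {
          active <- halves[[h]]
          other <- halves[[3 - h]]
          n_other <- length(other)
          for (w in active) {
            if (runif(1) < 0.5) {
              # affine-invariant stretch move
              j <- other[sample.int(n_other, 1)]
              z <- ((stretch - 1) * runif(1) + 1)^2 / stretch
              prop <- walkers[j, ] + z * (walkers[w, ] - walkers[j, ])
              log_hastings <- (ndim - 1) * log(z)
            } else {
              # differential-evolution move (symmetric proposal); an
              # occasional unit-gamma jump hops between ridge segments
              jj <- other[sample.int(n_other, 2)]
              g <- if (runif(1) < 0.25) 1 else g_de * exp(0.3 * rnorm(1))
              prop <- walkers[w, ] + g * (walkers[jj[1], ] - walkers[jj[2], ])
              log_hastings <- 0
            }
            v <- post$logpost(prop)
            log_acc <- log_hastings + v[1] - lp[w]
            total_prop <- total_prop + 1
            if (is.finite(v[1]) && log(runif(1)) < log_acc) {
              walkers[w, ] <- prop
              lp[w] <- v[1]
              ll[w] <- v[2]
              accept <- accept + 1
            }
          }
        }
        if (step <= n_warmup && step %% 50 == 0) {
          # warmup-only: stranded walkers (far below the ensemble bulk)
          # are recycled next to a well-placed walker; detailed balance is
          # only required after warmup
          bad <- which(lp < median(lp) - 3 * ndim)
          good <- which(lp >= median(lp))
          for (w in bad) {
            src <- good[sample.int(length(good), 1)]
            u <- walkers[src, ] + 0.01 * rnorm(ndim)
            v <- post$logpost(u)
            if (is.finite(v[1])) {
              walkers[w, ] <- u
              lp[w] <- v[1]
              ll[w] <- v[2]
            }
          }
        }
        if (step > n_warmup) {
          s <- step - n_warmup
          draws_u[s, , , chain] <- walkers
          ll_store[s, , chain] <- ll
        }
      }
    }
  })

  # natural-scale pooled draws
  flat_u <- matrix(aperm(draws_u, c(1, 2, 4, 3)), ncol = ndim)
  colnames(flat_u) <- post$dim_names
  flat_nat <- flat_u
  for (i in seq_len(ndim)) {
    flat_nat[, i] <- to_natural_1(flat_u[, i], post$transforms[[i]])
  }

  rhat <- split_rhat(draws_u)
  ess <- ensemble_ess(draws_u)
  q <- apply(flat_nat, 2, quantile,
    probs = c(0.025, 0.5, 0.975),
    names = FALSE
  )
  summary <- tibble::tibble(
    parameter = post$dim_names,
    median = unname(q[2, ]), q2.5 = unname(q[1, ]), q97.5 = unname(q[3, ]),
    rhat = unname(rhat), ess = unname(ess)
  )
  obs_df <- as_tibble(obs_det)
  structure(
    list(
      draws = flat_nat, draws_u = draws_u, log_lik = ll_store,
      summary = summary, rhat = rhat, ess = ess,
      converged = all(is.finite(rhat)) && max(rhat) < 1.05,
      accept_rate = accept / max(total_prop, 1),
      gamma = gamma, seed = seed, priors = priors, forcing = forcing,
      likelihood = likelihood,
      n_chains = n_chains, n_walkers = n_walkers,
      n_warmup = n_warmup, n_samples = n_samples,
      free = post$free, sig_names = post$sig_names,
      obs_hash = rlang::hash(list(
        obs_df$time_days, obs_df$signal,
        obs_df$value
      )),
      trend = attr(obs_det, "trend", exact = TRUE)
    ),
    class = "pd_fit"
  )
}

# central-difference Hessian of f at x
numeric_hessian <- function(f, x, h = 1e-3) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  fp <- numeric(d)
  fm <- numeric(d)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    fp[i] <- f(x + ei)
    fm[i] <- f(x - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      if (j <= i) next
      ei <- replace(numeric(d), i, h)
      ej <- replace(numeric(d), j, h)
      fpp <- f(x + ei + ej)
      fmm <- f(x - ei - ej)
      H[i, j] <- H[j, i] <-
        (fpp - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fmm) / (2 * h^2)
    }
  }
  H
}

# Cholesky factor of a regularized inverse Hessian: eigenvalues are floored
# (and capped) so flat ridge directions get wide but finite dispersion
laplace_chol <- function(H, floor_ev = 0.25, cap_ev = 1e4) {
  Hs <- (H + t(H)) / 2
  ev <- eigen(Hs, symmetric = TRUE)
  lam <- pmin(pmax(ev$values, floor_ev), cap_ev)
  cov <- ev$vectors %*% diag(1 / lam, length(lam)) %*% t(ev$vectors)
  t(chol((cov + t(cov)) / 2))
}

# Split R-hat at the ensemble level: each independent ensemble contributes
# two half-sequences (first and second half of its sweeps, all walkers
# pooled). Individual walkers are interacting, not independent chains, so
# the ensemble - not the walker - is the unit of replication; the split
# still detects within-run drift, and separate ensembles detect
# disagreement. Draws are rank-normalized first (and, in a second pass,
# folded about the median before rank-normalization, taking the larger of
# the two statistics) so heavy-tailed ridge marginals do not inflate the
# variance ratio: location and scale discrepancies are both detected on a
# Gaussian scale.
split_rhat <- function(draws_u) {
  d <- dim(draws_u) # samples, walkers, ndim, chains
  n_half <- d[1] %/% 2
  if (n_half < 2) {
    return(rep(NA_real_, d[3]))
  }
  n <- n_half * d[2] # draws per half-sequence
  basic_rhat <- function(halves) {
    means <- purrr::map_dbl(halves, mean)
    vars <- purrr::map_dbl(halves, var)
    W <- mean(vars)
    B <- n * var(means)
    if (W <= 0) NA_real_ else sqrt(((n - 1) / n * W + B / n) / W)
  }
  rank_normalize <- function(x) {
    stats::qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4))
  }
  split_halves <- function(x_flat) {
    # x_flat: vector of length n_samples*walkers*chains in array order
    xa <- array(x_flat, dim = c(d[1], d[2], d[4]))
    halves <- list()
    for (chain in seq_len(d[4])) {
      halves[[2 * chain - 1]] <- as.numeric(xa[seq_len(n_half), , chain])
      halves[[2 * chain]] <- as.numeric(xa[n_half + seq_len(n_half), , chain])
    }
    halves
  }
  out <- numeric(d[3])
  for (p in seq_len(d[3])) {
    x <- as.numeric(draws_u[, , p, ])
    z <- rank_normalize(x)
    z_fold <- rank_normalize(abs(x - median(x)))
    out[p] <- max(
      basic_rhat(split_halves(z)),
      basic_rhat(split_halves(z_fold))
    )
  }
  out
}

# effective sample size from walker-averaged autocorrelation (Geyer initial
# positive sequence), summed over ensembles
ensemble_ess <- function(draws_u, lag_max = NULL) {
  d <- dim(draws_u)
  n <- d[1]
  lag_max <- lag_max %||% min(n - 1, 200)
  out <- numeric(d[3])
  for (p in seq_len(d[3])) {
    ess_total <- 0
    for (chain in seq_len(d[4])) {
      rho <- rep(0, lag_max + 1)
      nw <- 0
      for (w in seq_len(d[2])) {
        x <- draws_u[, w, p, chain]
        if (var(x) <= 0) next
        a <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)
        rho <- rho + as.numeric(a$acf)
        nw <- nw + 1
      }
      if (nw == 0) next
      rho <- rho / nw
      # Geyer: sum consecutive pairs while positive
      tau <- 1
      k <- 2
      while (k + 1 <= length(rho)) {
        pair <- rho[k] + rho[k + 1]
        if (pair <= 0) break
        tau <- tau + 2 * pair
        k <- k + 2
      }
      ess_total <- ess_total + d[2] * n / tau
    }
    out[p] <- ess_total
  }
  out
}

#' @rdname sample_posterior
#' @param x A `pd_fit` object.
#' @param ... Unused.
#' @return `tidy()` returns the posterior summary (parameter, median, 95%
#'   interval bounds, R-hat, ESS); `glance()` a one-row fit overview.
#' @export
tidy.pd_fit <- function(x, ...) x$summary

#' @rdname sample_posterior
#' @export
glance.pd_fit <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma,
    n_draws = nrow(x$draws),
    log_lik_max = suppressWarnings(max(x$log_lik, na.rm = TRUE)),
    log_lik_median = median(x$log_lik, na.rm = TRUE),
    rhat_max = suppressWarnings(max(x$rhat, na.rm = TRUE)),
    ess_min = suppressWarnings(min(x$ess, na.rm = TRUE)),
    accept_rate = x$accept_rate,
    converged = x$converged,
    seed = x$seed
  )
}

#' @export
print.pd_fit <- function(x, ...) {
  cat(
    "<posterior fit> gamma =", x$gamma, "|", nrow(x$draws), "draws |",
    if (x$converged) "converged" else "NOT converged",
    sprintf("(max R-hat %.3f)\n", suppressWarnings(max(x$rhat, na.rm = TRUE)))
  )
  print(x$summary, n = Inf)
  invisible(x)
}

# evenly thinned posterior draws as parameter sets + initial states
posterior_params <- function(fit, n_draws = 200) {
  total <- nrow(fit$draws)
  idx <- unique(round(seq(1, total, length.out = min(n_draws, total))))
  template <- unclass(life_history())
  template$gamma <- fit$gamma
  for (f in names(fit$priors$fixed)) template[[f]] <- fit$priors$fixed[[f]]
  purrr::map(idx, function(i) {
    row <- fit$draws[i, ]
    pl <- template
    for (f in fit$free) pl[[f]] <- row[[f]]
    sig <- row[paste0("sigma_", fit$sig_names)]
    names(sig) <- fit$sig_names
    list(
      params = structure(pl, class = "pd_params"),
      init = tibble::tibble(
        S = row[["S0"]], I = row[["I0"]],
        V = row[["V0"]], G = row[["G0"]]
      ),
      sigma = as.list(sig)
    )
  })
}

#' Compare fits across the specialism-generalism gradient
#'
#' Aligns posterior fits of the same observation set obtained under
#' different fixed generalist grazing rates into one summary table, and
#' flags variants whose best log-likelihood falls more than `margin` below
#' the best overall (fits to different observation sets are an error).
#'
#' @param fits A list of [sample_posterior()] results.
#' @param margin Log-likelihood margin for flagging.
#' @return A tibble with one row per variant: `gamma`, `log_lik_max`,
#'   `log_lik_median`, `rhat_max`, `converged`, `delta_best`, `flagged`.
#' @export
compare_variants <- function(fits, margin = 10) {
  stopifnot(length(fits) >= 1)
  hashes <- purrr::map_chr(fits, "obs_hash")
  if (length(unique(hashes)) > 1) {
    stop("fits were obtained on different observation sets", call. = FALSE)
  }
  tab <- purrr::map(fits, glance) |> dplyr::bind_rows()
  best <- max(tab$log_lik_max)
  tab$delta_best <- best - tab$log_lik_max
  tab$flagged <- tab$delta_best > margin
  dplyr::arrange(tab, .data$gamma)
}

#' Persist a fit
#'
#' Writes pooled posterior draws as CSV and the summary (with convergence
#' diagnostics and fit metadata) as JSON.
#'
#' @param fit A `pd_fit`.
#' @param path_draws CSV path for the draws.
#' @param path_summary JSON path for the summary.
#' @return `path_summary`, invisibly.
#' @export
write_fit <- function(fit, path_draws, path_summary) {
  readr::write_csv(as_tibble(as.data.frame(fit$draws)), path_draws)
  jsonlite::write_json(
    list(
      gamma = fit$gamma, seed = fit$seed, converged = fit$converged,
      accept_rate = fit$accept_rate,
      summary = fit$summary
    ),
    path_summary,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path_summary)
}
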