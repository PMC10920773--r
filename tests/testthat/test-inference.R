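make_fit_fixture <- function(seed = 1) {
  cfg <- low_noise_config(seed = seed)
  obs <- generate_observations(cfg)
  list(obs = obs, det = detrend(obs), truth = attr(obs, "truth"))
}

test_that("prior specification validates families and bounds", {
  pr <- prior_spec(gamma = 0.05)
  expect_equal(pr$gamma, 0.05)
  expect_equal(nrow(pr$parameters), 11)
  expect_error(
    prior_spec(parameters = tibble::tibble(
      parameter = "mu_ave", family = "cauchy", lower = 0, upper = 1
    )),
    "unknown prior families"
  )
  expect_error(
    prior_spec(parameters = tibble::tibble(
      parameter = "mu_ave", family = "uniform", lower = 1, upper = 0
    )),
    "lower < upper"
  )
  expect_error(
    prior_spec(parameters = tibble::tibble(
      parameter = "phi", family = "log-uniform", lower = 0, upper = 1
    )),
    "positive lower bound"
  )
  # fixing a parameter removes it from the free set
  pr2 <- prior_spec(fixed = list(beta = 40))
  expect_false("beta" %in% pr2$parameters$parameter)
})

test_that("log-likelihood peaks at the generator truth along 1-D scans", {
  fx <- make_fit_fixture(seed = 2)
  truth <- fx$truth$params
  sigma <- c(pro = 2e6, infected_pct = 0.25, virus = 5e7, grazer = 5e4)
  ll_at <- function(p) {
    log_likelihood(p, fx$det, sigma, init = fx$truth$init)
  }
  for (par in c("mu_ave", "psi")) {
    grid <- truth[[par]] * c(0.6, 0.8, 1, 1.25, 1.6)
    lls <- purrr::map_dbl(grid, function(v) {
      ll_at(do.call(update_params, c(list(truth), setNames(list(v), par))))
    })
    expect_equal(which.max(lls), 3)
  }
})

test_that("Gaussian likelihood responds to the noise scale as it must", {
  fx <- make_fit_fixture(seed = 3)
  truth <- fx$truth$params
  sigma <- c(pro = 2e6, infected_pct = 0.25, virus = 5e7, grazer = 5e4)
  l1 <- log_likelihood(truth, fx$det, sigma, init = fx$truth$init)
  l2 <- log_likelihood(truth, fx$det, sigma * 2, init = fx$truth$init)
  # residuals are well below 2 sigma here, so doubling sigma costs
  # normalisation without buying quadratic relief
  expect_lt(l2, l1)

  # permuting signal blocks leaves the sum unchanged
  perm <- fx$det[order(match(fx$det$signal, c("virus", "grazer", "pro", "infected_pct"))), ]
  attr(perm, "detrended") <- TRUE
  attr(perm, "trend") <- attr(fx$det, "trend")
  l3 <- log_likelihood(truth, perm, sigma, init = fx$truth$init)
  expect_equal(l3, l1, tolerance = 1e-12)
})

test_that("impossible parameters reject with -Inf rather than aborting", {
  fx <- make_fit_fixture(seed = 4)
  sigma <- c(pro = 2e6, infected_pct = 0.25, virus = 5e7, grazer = 5e4)
  runaway <- update_params(fx$truth$params, mu_ave = 50, m_P = 0, psi = 0)
  expect_message(
    ll <- log_likelihood(runaway, fx$det, sigma,
      init = tibble::tibble(S = 1e14, I = 0, V = 0, G = 0)
    ),
    "-Inf"
  )
  expect_identical(ll, -Inf)
})

test_that("posterior sampling is exactly reproducible given a seed", {
  fx <- make_fit_fixture(seed = 5)
  pr <- prior_spec(gamma = 0)
  opts <- list(
    n_chains = 1, n_warmup = 15, n_samples = 15,
    optim_start = FALSE
  )
  f1 <- do.call(sample_posterior, c(list(fx$det, pr, seed = 99), opts))
  f2 <- do.call(sample_posterior, c(list(fx$det, pr, seed = 99), opts))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$log_lik, f2$log_lik)
  f3 <- do.call(sample_posterior, c(list(fx$det, pr, seed = 100), opts))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("prior-only sampling reproduces the prior (Bayes identity)", {
  fx <- make_fit_fixture(seed = 6)
  pr <- prior_spec(gamma = 0)
  fit <- sample_posterior(fx$det, pr,
    likelihood = "off",
    n_chains = 2, n_warmup = 300, n_samples = 600, seed = 11
  )
  sm <- tidy(fit)
  # uniform prior on mu_ave over [0.1, 1.5]: median 0.8
  mu <- sm[sm$parameter == "mu_ave", ]
  expect_equal(mu$median, 0.8, tolerance = 0.08)
  # log-uniform prior on phi over [1e-13, 1e-9]: log-median at 1e-11
  phi <- sm[sm$parameter == "phi", ]
  expect_equal(log10(phi$median), -11, tolerance = 0.35)
  # central 95% interval of a uniform spans ~95% of the support
  expect_equal(mu$q2.5, 0.1 + 0.025 * 1.4, tolerance = 0.12)
  expect_equal(mu$q97.5, 1.5 - 0.025 * 1.4, tolerance = 0.12)
})

test_that("variant comparison aligns fits and rejects mixed data", {
  fx <- make_fit_fixture(seed = 7)
  opts <- list(n_chains = 1, n_warmup = 15, n_samples = 15, optim_start = FALSE)
  f0 <- do.call(sample_posterior, c(
    list(fx$det, prior_spec(gamma = 0), seed = 1), opts
  ))
  f5 <- do.call(sample_posterior, c(
    list(fx$det, prior_spec(gamma = 0.5), seed = 1), opts
  ))
  tab <- compare_variants(list(f0, f5))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$gamma, c(0, 0.5))
  expect_true(all(c("log_lik_max", "delta_best", "flagged") %in% names(tab)))

  tab1 <- compare_variants(list(f0))
  expect_equal(nrow(tab1), 1)

  fx2 <- make_fit_fixture(seed = 8)
  f_other <- do.call(sample_posterior, c(
    list(fx2$det, prior_spec(gamma = 0), seed = 1), opts
  ))
  expect_error(compare_variants(list(f0, f_other)), "different observation")
})

test_that("fits persist to draws CSV and summary JSON", {
  fx <- make_fit_fixture(seed = 9)
  fit <- sample_posterior(fx$det, prior_spec(gamma = 0),
    n_chains = 1, n_warmup = 10, n_samples = 10, seed = 2,
    optim_start = FALSE
  )
  d <- withr::local_tempfile(fileext = ".csv")
  s <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, d, s)
  back <- jsonlite::read_json(s)
  expect_equal(back$gamma, 0)
  expect_equal(length(back$summary), nrow(fit$summary))
  draws <- readr::read_csv(d, show_col_types = FALSE)
  expect_equal(nrow(draws), nrow(fit$draws))
})
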