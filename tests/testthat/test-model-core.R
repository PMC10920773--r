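test_that("division rate follows the diel sinusoid and its identities", {
  p0 <- life_history(mu_ave = 0.5, delta_mu = 0)
  expect_equal(division_rate(c(0, 0.3, 0.77), p0), rep(0.5, 3))

  p <- life_history(mu_ave = 0.5, delta_mu = 0.2, delta_t = 0)
  expect_equal(division_rate(0.25, p), 0.6) # sine maximum

  # day-mean equals mu_ave for any amplitude/phase (zero-mean sine)
  set.seed(11)
  for (i in 1:5) {
    pr <- life_history(
      mu_ave = runif(1, 0.2, 1),
      delta_mu = runif(1), delta_t = runif(1, 0, 0.999)
    )
    m <- integrate(function(t) division_rate(t, pr), 0, 1,
      rel.tol = 1e-12
    )$value
    expect_equal(m, pr$mu_ave, tolerance = 1e-10)
    # 1-day periodicity
    ts <- runif(3, 0, 1)
    expect_equal(division_rate(ts, pr), division_rate(ts + 1, pr))
  }

  expect_error(life_history(delta_mu = 1.2), "delta_mu")
  expect_error(life_history(delta_t = 1), "delta_t")
  expect_error(life_history(beta = 0.5), "beta")
  expect_error(life_history(phi = -1e-11), ">= 0")
})

test_that("diel adsorption multiplier is a mean-preserving step on the clock", {
  off <- forcing_config(FALSE)
  expect_equal(adsorption_multiplier(c(0, 0.25, 0.6, 3.99), off), rep(1, 4))

  on <- forcing_config(TRUE)
  # 06:00 (t = 0) is inside midnight->noon; 18:00 (t = 0.5) inside
  # noon->midnight
  expect_equal(adsorption_multiplier(0, on), 0.5)
  expect_equal(adsorption_multiplier(0.5, on), 1.5)
  # half-open boundaries: the switch instant belongs to the new interval
  expect_equal(adsorption_multiplier(0.25, on), 1.5)
  expect_equal(adsorption_multiplier(0.75, on), 0.5)
  # wrapping
  expect_equal(adsorption_multiplier(5.5, on), 1.5)
  # exact time average over one day (step spends half a day at each level)
  mids <- seq(1 / 2000, 1 - 1 / 2000, by = 1 / 1000)
  expect_equal(mean(adsorption_multiplier(mids, on)), 1)

  expect_error(forcing_config(TRUE, 0.4, 1.5), "preserve")
  expect_silent(forcing_config(TRUE, 0.4, 1.5, preserve_mean = FALSE))
})

test_that("rhs matches term-by-term arithmetic on randomized states", {
  set.seed(42)
  for (i in 1:1000) {
    p <- random_params()
    st <- random_state()
    t <- runif(1, 0, 3)
    got <- community_rhs(t, st, p)
    want <- oracle_rhs(t, st$S, st$I, st$V, st$G, p)
    expect_equal(as.numeric(got), unname(want), tolerance = 1e-12)
  }
})

test_that("rhs honours the diel adsorption step in both flux and sink", {
  p <- life_history()
  f <- forcing_config(TRUE)
  st <- tibble::tibble(S = 1e8, I = 1e6, V = 1e9, G = 1e3)
  for (t in c(0.1, 0.6)) {
    got <- community_rhs(t, st, p, f)
    want <- oracle_rhs(t, st$S, st$I, st$V, st$G, p,
      mult = adsorption_multiplier(t, f)
    )
    expect_equal(as.numeric(got), unname(want), tolerance = 1e-12)
  }
})

test_that("rhs limits: exponential growth, flux bookkeeping, positivity", {
  p <- update_params(life_history(), m_P = 0)
  st <- tibble::tibble(S = 1e7, I = 0, V = 0, G = 0)
  d <- community_rhs(0.3, st, p)
  expect_equal(d$dS, division_rate(0.3, p) * 1e7)
  expect_equal(c(d$dI, d$dV, d$dG), c(0, 0, 0))

  # the infection flux leaves S and enters I with equal magnitude:
  # derivatives with phi = 0 differ only by +/- phi*S*V
  set.seed(7)
  for (i in 1:20) {
    pr <- random_params()
    st <- random_state()
    pr0 <- update_params(pr, phi = 0)
    d1 <- community_rhs(0.2, st, pr)
    d0 <- community_rhs(0.2, st, pr0)
    flux <- pr$phi * st$S * st$V
    expect_equal(d1$dS - d0$dS, -flux, tolerance = 1e-10)
    expect_equal(d1$dI - d0$dI, flux, tolerance = 1e-10)
  }

  # no term can push a zero component negative
  for (i in 1:20) {
    pr <- random_params()
    st <- random_state()
    for (comp in c("S", "I", "V", "G")) {
      st0 <- st
      st0[[comp]] <- 0
      d <- community_rhs(0.4, st0, pr)
      expect_gte(d[[paste0("d", comp)]], 0)
    }
  }

  expect_error(community_rhs(0, tibble::tibble(S = -1, I = 0, V = 0, G = 0),
    life_history()), ">= 0")
  expect_error(community_rhs(0, tibble::tibble(S = NaN, I = 0, V = 0, G = 0),
    life_history()), "non-finite")
})

test_that("specialism fraction reflects the grazer diet split", {
  traj <- tibble::tibble(
    time_days = 0:2,
    S = c(1e8, 9e7, 1.1e8), I = c(1e6, 2e6, 1e6),
    V = 1e9, G = 1e6
  )
  expect_equal(specialism_fraction(traj, life_history(gamma = 0)), 1)
  p0 <- life_history(e_eff = 0, gamma = 0.1)
  expect_equal(specialism_fraction(traj, p0), 0)
  # constant state with matched sources -> exactly one half
  p <- life_history()
  g_equal <- p$e_eff * p$psi * (1e8 + 1e6)
  traj_const <- tibble::tibble(
    time_days = 0:3, S = 1e8, I = 1e6,
    V = 1e9, G = 1e6
  )
  expect_equal(
    specialism_fraction(traj_const, update_params(p, gamma = g_equal)),
    0.5
  )
  expect_error(
    specialism_fraction(
      tibble::tibble(time_days = 0, S = 0, I = 0, V = 0, G = 0),
      life_history(gamma = 0)
    ),
    "zero"
  )
})

test_that("parameter configs round-trip through YAML", {
  p <- life_history(mu_ave = 0.61, phi = 3.3e-11, gamma = 0.05)
  f <- forcing_config(TRUE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params_config(p, f, path)
  cfg <- read_params_config(path)
  expect_equal(unclass(cfg$params), unclass(p))
  expect_true(cfg$forcing$diel_adsorption)
  expect_equal(cfg$forcing$high_factor, 1.5)
})
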