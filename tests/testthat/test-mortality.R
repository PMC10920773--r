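test_that("instantaneous mortality fluxes match single-term arithmetic", {
  p <- life_history(psi = 1e-6, m_P = 0)
  st <- tibble::tibble(S = 1e8, I = 0, V = 1e9, G = 1e3)
  r <- instantaneous_rates(st, p)
  expect_equal(r$m_lysis, 0) # no infected cells
  expect_equal(r$m_grazing, 1e-6 * 1e8 * 1e3)
  expect_equal(r$m_other, 0)

  p0 <- life_history(eta = 0)
  expect_equal(instantaneous_rates(random_state(), p0)$m_lysis, 0)

  set.seed(13)
  for (i in 1:50) {
    pr <- random_params()
    st <- random_state()
    r <- instantaneous_rates(st, pr)
    P <- st$S + st$I
    expect_equal(r$m_lysis, pr$eta * st$I, tolerance = 1e-14)
    expect_equal(r$m_grazing, pr$psi * P * st$G, tolerance = 1e-14)
    expect_equal(r$m_other, pr$m_P * P^2, tolerance = 1e-14)
  }
})

test_that("partition uses the average-of-ratios convention", {
  # two hand-chosen states where average-of-ratios and ratio-of-averages
  # differ measurably; expected values computed by scalar arithmetic
  p <- life_history(eta = 1, psi = 1e-6, m_P = 0)
  traj <- tibble::tibble(
    time_days = c(0, 1),
    S = c(9e7, 4e7), I = c(1e6, 9e6), V = 0, G = c(1e3, 1e6)
  )
  # point 1: lysis 1e6, grazing 1e-6*9.1e7*1e3 = 9.1e4 -> total 1.091e6
  # point 2: lysis 9e6, grazing 1e-6*4.9e7*1e6 = 4.9e7 -> total 5.8e7
  f1_l <- 1e6 / 1.091e6
  f2_l <- 9e6 / 58e6
  part <- partition_mortality(traj, p)
  expect_equal(part$f_lysis, (f1_l + f2_l) / 2, tolerance = 1e-12)
  expect_equal(part$f_grazing, 1 - (f1_l + f2_l) / 2, tolerance = 1e-12)
  expect_equal(part$m_total_daily, (1.091e6 + 58e6) / 2, tolerance = 1e-12)
  expect_equal(part$per_capita_grazing, 1e-6 * (1e3 + 1e6) / 2)
  expect_equal(part$lysis_to_grazing,
    (1e6 / 9.1e4 + 9e6 / 4.9e7) / 2,
    tolerance = 1e-12
  )
  # and it differs measurably from the ratio-of-averages convention
  roa <- (1e6 + 9e6) / (1.091e6 + 58e6)
  expect_gt(abs(part$f_lysis - roa), 0.05)

  # fractions always sum to 1
  set.seed(17)
  for (i in 1:25) {
    pr <- random_params()
    traj <- dplyr::bind_rows(purrr::map(1:4, ~random_state()))
    traj$time_days <- 1:4
    pt <- partition_mortality(traj, pr)
    expect_equal(pt$f_lysis + pt$f_grazing + pt$f_other, 1, tolerance = 1e-9)
    expect_true(all(c(pt$f_lysis, pt$f_grazing, pt$f_other) >= 0))
  }
})

test_that("degenerate partitions behave by convention", {
  # only lysis active
  p <- life_history(psi = 0, m_P = 0, eta = 2)
  traj <- tibble::tibble(time_days = 0:2, S = 1e8, I = 1e6, V = 1e9, G = 1e6)
  part <- partition_mortality(traj, p)
  expect_equal(part$f_lysis, 1)
  expect_equal(part$f_grazing, 0)
  expect_equal(part$lysis_to_grazing, Inf)

  # constant state: fractions equal the single-point ratios
  p2 <- life_history()
  r <- instantaneous_rates(traj[1, ], p2)
  tot <- r$m_lysis + r$m_grazing + r$m_other
  part2 <- partition_mortality(traj, p2)
  expect_equal(part2$f_lysis, r$m_lysis / tot)
  expect_equal(part2$f_grazing, r$m_grazing / tot)

  # zero-mortality points are excluded with a warning
  p3 <- life_history(m_P = 0)
  traj3 <- tibble::tibble(
    time_days = 0:1, S = c(1e8, 1e8), I = c(0, 1e6),
    V = 0, G = c(0, 1e6)
  )
  expect_warning(part3 <- partition_mortality(traj3, p3), "excluded")
  r2 <- instantaneous_rates(traj3[2, ], p3)
  expect_equal(part3$f_lysis, r2$m_lysis / (r2$m_lysis + r2$m_grazing))

  # all-zero mortality errors
  expect_error(
    partition_mortality(traj3[1, ], p3),
    "zero along the whole trajectory"
  )
})

test_that("lysis fraction is nondecreasing in the lysis rate", {
  traj <- run_to_stationary(life_history(), burn_in = 200)
  etas <- c(0.5, 1, 1.5, 3, 6)
  f <- purrr::map_dbl(etas, function(e) {
    partition_mortality(traj, update_params(life_history(), eta = e))$f_lysis
  })
  expect_true(all(diff(f) > 0))
  expect_equal(
    partition_mortality(traj, update_params(life_history(), eta = 0))$f_lysis,
    0
  )
})

test_that("partition is stable under time-grid refinement", {
  traj <- run_to_stationary(life_history(), burn_in = 200, n_per_day = 96)
  coarse <- partition_mortality(traj,
    time_grid = seq(0, 1, length.out = 49)
  )
  fine <- partition_mortality(traj, time_grid = seq(0, 1, length.out = 97))
  expect_lt(abs(coarse$f_lysis - fine$f_lysis), 1e-3)
  expect_lt(abs(coarse$f_grazing - fine$f_grazing), 1e-3)
})

test_that("residence times are reciprocal per-capita quadratic losses", {
  p <- life_history(m_G = 1e-5, m_V = 1e-9, phi = 0)
  traj <- tibble::tibble(time_days = 0:1, S = 1e8, I = 0, V = 1e9, G = 5e3)
  rt <- residence_times(p, traj)
  expect_equal(rt$grazer_residence, 20) # 1 / (1e-5 * 5e3)
  expect_equal(rt$virus_residence_quadratic, 1)
  expect_equal(rt$virus_residence, 1) # phi = 0: sink-free equals quadratic

  # doubling mean grazer abundance halves the residence time
  traj2 <- dplyr::mutate(traj, G = 1e4)
  expect_equal(residence_times(p, traj2)$grazer_residence, 10)

  # with adsorption, the total virion residence is shorter
  p2 <- update_params(p, phi = 4e-11)
  rt2 <- residence_times(p2, traj)
  expect_lt(rt2$virus_residence, rt2$virus_residence_quadratic)
  expect_equal(rt2$virus_residence, 1 / (1e-9 * 1e9 + 4e-11 * 1e8))

  expect_error(
    residence_times(p, dplyr::mutate(traj, G = 0)),
    "zero mean abundance"
  )
})

test_that("default parameters partition mortality like the study system", {
  # grazing-dominated regime: most losses to grazers, a few percent each to
  # lysis and niche competition; residence times near 20 d (grazers) and
  # ~1 d (virions)
  st <- run_to_stationary(life_history(), burn_in = 400)
  part <- partition_mortality(st)
  expect_gt(part$f_grazing, 0.75)
  expect_lt(part$f_lysis, 0.15)
  expect_lt(part$f_other, 0.15)
  rt <- residence_times(life_history(), st)
  expect_gt(rt$grazer_residence, 10)
  expect_lt(rt$grazer_residence, 30)
  expect_gt(rt$virus_residence, 0.5)
  expect_lt(rt$virus_residence, 2.5)
})
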