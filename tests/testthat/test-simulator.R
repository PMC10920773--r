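test_that("integration reproduces closed forms", {
  # pure exponential growth: no viruses, no grazers, no self-limitation,
  # constant division rate
  p <- life_history(delta_mu = 0, m_P = 0, mu_ave = 0.7)
  init <- tibble::tibble(S = 1e6, I = 0, V = 0, G = 0)
  tt <- seq(0, 5, by = 0.25)
  traj <- simulate_community(p, init, tt)
  expect_equal(traj$S, 1e6 * exp(0.7 * tt), tolerance = 1e-6)
  expect_equal(max(abs(traj$I)), 0)

  # grazers alone with quadratic self-limitation decay hyperbolically
  p2 <- life_history(e_eff = 0, gamma = 0, m_G = 5e-8)
  init2 <- tibble::tibble(S = 0, I = 0, V = 0, G = 2e6)
  traj2 <- simulate_community(p2, init2, tt)
  expect_equal(traj2$G, 2e6 / (1 + 5e-8 * 2e6 * tt), tolerance = 1e-6)
})

test_that("tightening tolerances is self-consistent (step control works)", {
  p <- life_history()
  tt <- seq(0, 6, by = 0.25)
  a <- simulate_community(p, t_out = tt, rtol = 1e-6, atol = 1)
  b <- simulate_community(p, t_out = tt, rtol = 1e-9, atol = 1e-3)
  for (cc in c("S", "I", "V", "G")) {
    expect_equal(a[[cc]], b[[cc]], tolerance = 1e-5)
  }
  expect_lt(attr(a, "n_steps"), attr(b, "n_steps"))
})

test_that("trajectories agree with an independent solver", {
  p <- life_history()
  f_off <- forcing_config(FALSE)
  de_rhs <- function(t, y, parms) {
    d <- community_rhs(t, as.list(setNames(y, c("S", "I", "V", "G"))),
      parms$p, parms$f)
    list(c(d$dS, d$dI, d$dV, d$dG))
  }
  tt <- seq(0, 3, by = 0.1)
  y0 <- c(S = 9.8e7, I = 2e6, V = 1e9, G = 1e6)
  ref <- deSolve::lsoda(y0, tt, de_rhs, parms = list(p = p, f = f_off),
    rtol = 1e-10, atol = 1e-4)
  got <- simulate_community(p, as.list(y0), tt)
  for (i in 1:4) {
    expect_equal(got[[i + 1]], unname(ref[, i + 1]), tolerance = 1e-6)
  }

  # diel step variant: integrate the reference piecewise between switches
  f_on <- forcing_config(TRUE)
  breaks <- sort(unique(c(tt, 0.25 + 0:2, 0.75 + 0:2)))
  breaks <- breaks[breaks <= 3]
  y <- y0
  ref2 <- matrix(NA_real_, length(tt), 4)
  ref2[1, ] <- y0
  for (k in 2:length(breaks)) {
    seg <- deSolve::lsoda(y, c(breaks[k - 1], breaks[k]), de_rhs,
      parms = list(p = p, f = f_on), rtol = 1e-10, atol = 1e-4)
    y <- seg[nrow(seg), -1]
    hit <- which(abs(tt - breaks[k]) < 1e-12)
    if (length(hit) == 1) ref2[hit, ] <- y
  }
  got2 <- simulate_community(p, as.list(y0), tt, forcing = f_on)
  for (i in 1:4) {
    expect_equal(got2[[i + 1]], unname(ref2[, i]), tolerance = 1e-6)
  }
})

test_that("observe maps states to signals and inverts algebraically", {
  traj <- tibble::tibble(
    time_days = c(0, 1), S = c(9e7, 0), I = c(1e7, 0),
    V = c(1e9, 1e8), G = c(1e6, 1e5)
  )
  o <- observe(traj)
  expect_equal(o$pro[1], 1e8)
  expect_equal(o$infected_pct[1], 10)
  expect_equal(o$infected_pct[2], 0) # empty population convention

  set.seed(3)
  for (i in 1:20) {
    st <- random_state()
    o <- observe(tibble::tibble(time_days = 0, !!!st))
    expect_equal(o$pro * (1 - o$infected_pct / 100), st$S)
    expect_equal(o$pro * o$infected_pct / 100, st$I)
  }
})

test_that("extinction check uses a strict floor", {
  mk <- function(P) tibble::tibble(
    time_days = seq_along(P), S = P / 2, I = P / 2, V = 1, G = 1
  )
  expect_false(extinction_check(mk(c(1e7, 2e7))))
  expect_true(extinction_check(mk(c(1e7, 0.5))))
  expect_false(extinction_check(mk(c(10, 1)))) # boundary: strictly less than
  expect_error(extinction_check(mk(numeric(0))), "empty")
})

test_that("default parameters reach a diel-stationary coexistence cycle", {
  st <- run_to_stationary(life_history(), burn_in = 300)
  g <- glance(st)
  expect_true(g$stationary)
  expect_false(g$extinct)
  expect_lt(g$max_rel_diff, 1e-3)
  # the stationary window is a genuine diel cycle, not a fixed point
  P <- st$S + st$I
  expect_gt((max(P) - min(P)) / mean(P), 0.01)
  # doubling the burn-in changes the window by less than the tolerance
  st2 <- run_to_stationary(life_history(), burn_in = 600)
  expect_equal(st$S, st2$S, tolerance = 1e-3)
})

test_that("burn_in = 0 returns the first simulated day", {
  st <- run_to_stationary(life_history(), burn_in = 0, n_per_day = 24)
  direct <- simulate_community(life_history(),
    t_out = seq(0, 2, by = 1 / 24))
  expect_equal(st$S, direct$S[25:49], tolerance = 1e-9)
  expect_equal(st$time_days, seq(0, 1, by = 1 / 24) - 0)
})

test_that("trajectories round-trip through CSV", {
  traj <- simulate_community(life_history(), t_out = seq(0, 1, by = 0.25))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$S, traj$S)
  expect_equal(back$time_days, traj$time_days)
})

test_that("runaway dynamics trip the overflow guard", {
  p <- life_history(mu_ave = 1.4, delta_mu = 0, m_P = 0)
  init <- tibble::tibble(S = 1e12, I = 0, V = 0, G = 0)
  expect_error(
    simulate_community(p, init, seq(0, 20, by = 1), overflow_guard = 1e13),
    "overflow"
  )
})
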