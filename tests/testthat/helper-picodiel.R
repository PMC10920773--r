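# Independent scalar-arithmetic oracle for the model right-hand side:
# evaluates each labelled flux term separately and sums, sharing no code
# with the package implementation.
oracle_rhs <- function(t, S, I, V, G, p, mult = 1) {
  mu <- p$mu_ave * (1 + p$delta_mu * sin(2 * pi * (t + p$delta_t)))
  phi_t <- p$phi * mult
  division <- mu * S
  ho_S <- p$m_P * S * (S + I)
  infection <- phi_t * S * V
  grazing_S <- p$psi * S * G
  ho_I <- p$m_P * I * (S + I)
  lysis <- p$eta * I
  grazing_I <- p$psi * I * G
  production <- p$beta * p$eta * I
  adsorption <- phi_t * (S + I) * V
  ho_V <- p$m_V * V * V
  gain <- p$e_eff * p$psi * (S + I) * G
  generalist <- p$gamma * G
  ho_G <- p$m_G * G * G
  c(
    dS = division - ho_S - infection - grazing_S,
    dI = infection - ho_I - lysis - grazing_I,
    dV = production - adsorption - ho_V,
    dG = gain + generalist - ho_G
  )
}

random_params <- function() {
  life_history(
    mu_ave = runif(1, 0.1, 1.5),
    delta_mu = runif(1, 0, 1),
    delta_t = runif(1, 0, 0.999),
    m_P = 10^runif(1, -12, -9),
    m_V = 10^runif(1, -12, -9),
    m_G = 10^runif(1, -9, -7),
    phi = 10^runif(1, -13, -10),
    psi = 10^runif(1, -8, -6),
    beta = runif(1, 1, 500),
    eta = runif(1, 0.5, 6),
    e_eff = 10^runif(1, -4, -2),
    gamma = runif(1, 0, 0.5)
  )
}

random_state <- function() {
  tibble::tibble(
    S = 10^runif(1, 5, 9), I = 10^runif(1, 3, 7),
    V = 10^runif(1, 7, 10), G = 10^runif(1, 3, 7)
  )
}

# generalist companion baseline: larger grazer self-limitation balances the
# extra gamma growth so grazers settle near the same abundance
generalist_baseline <- function() {
  update_params(life_history(), gamma = 0.5, m_G = 5.5e-7)
}

low_noise_config <- function(seed = NULL) {
  generator_config(
    noise = list(
      pro = 0.02, infected_pct = 0.25,
      virus = 0.05, grazer = 0.05
    ),
    seed = seed
  )
}
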