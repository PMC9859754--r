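test_that("identical parameters and seed reproduce a byte-identical series", {
  pars <- tiny_params(enable_cap = TRUE, enable_trains = TRUE)
  sch <- run_schedule(50, 20, 5)
  s1 <- run_simulation(pars, sch)
  s2 <- run_simulation(pars, sch)
  expect_identical(s1$states, s2$states)
  expect_identical(s1$counts, s2$counts)
  s3 <- run_simulation(model_params(L0 = 100L, gamma = 0.5, seed = 43L), sch)
  expect_false(identical(s1$states, s3$states))
})

test_that("without attachment the lattice stays empty while still growing", {
  pars <- model_params(L0 = 50, c_motor = 0, gamma = 2, seed = 5)
  ser <- run_simulation(pars, run_schedule(20, 10, 5))
  expect_true(all(vapply(ser$states, function(st) sum(st$motor) == 0L,
                         logical(1))))
  expect_gt(ser$final_length, 50)
})

test_that("growth-only dynamics adds Poisson-distributed length", {
  # mean added length gamma * T, checked within 4 sd of the Poisson count
  pars <- model_params(L0 = 10, c_motor = 0, gamma = 4, k_c_on = 0, seed = 21)
  T_end <- 500
  ser <- run_simulation(pars, run_schedule(T_end, 1, 1))
  added <- ser$states[[1]]$length - 10
  expect_lt(abs(added - 4 * T_end), 4 * sqrt(4 * T_end))
})

test_that("attach/detach occupancy matches the two-state closed form", {
  pars <- model_params(L0 = 2, p = 0, gamma = 0, omega_a = 0.3, omega_d = 0.7,
                       k_c_on = 0, seed = 31)
  ser <- run_simulation(pars, run_schedule(20, 2000, 2))
  occ <- mean(vapply(ser$states, function(st) mean(st$motor), numeric(1)))
  expect_equal(occ, 0.3 / (0.3 + 0.7), tolerance = 0.08)
})

test_that("time-averaged density matches the exact master-equation solution", {
  # brute-force oracle: null vector of the 2^4-state generator
  L <- 4L
  p <- 4; wa <- 0.4; wd <- 0.6
  exact <- exact_motor_density(L, p, wa, wd)
  pars <- model_params(L0 = L, p = p, omega_a = wa, omega_d = wd,
                       gamma = 0, k_c_on = 0, seed = 17)
  ser <- run_simulation(pars, run_schedule(20, 3000, 1))
  dens <- snapshot_density(ser)
  expect_true(all(abs(dens$mean - exact) < 3.5 * pmax(dens$se, 1e-3)))
})

test_that("the pure-R stepper agrees with the exact solution on a tiny lattice", {
  # dual route: step_gillespie() over the propensity catalogue is an
  # independent implementation of the same Markov process
  L <- 3L
  p <- 2; wa <- 0.4; wd <- 0.6
  exact <- exact_motor_density(L, p, wa, wd)
  pars <- model_params(L0 = L, p = p, omega_a = wa, omega_d = wd,
                       gamma = 0, k_c_on = 0, seed = 13)
  set.seed(13)
  st <- lattice_state(L)
  tocc <- numeric(L); total_t <- 0
  for (k in 1:12000) {
    out <- step_gillespie(st, pars)
    tocc <- tocc + st$motor * out$dt  # state held during the waiting time
    total_t <- total_t + out$dt
    st <- out$state
  }
  expect_true(all(abs(tocc / total_t - exact) < 0.04))
})

test_that("event accounting balances arrivals, departures and standing motors", {
  pars <- tiny_params(c_motor = 200, enable_cap = TRUE, enable_trains = TRUE,
                      enable_stabilization = TRUE)
  ser <- run_simulation(pars, run_schedule(100, 50, 5))
  cts <- ser$counts
  expect_equal(unname(cts["attach"] - cts["detach"] - cts["end_exit"]),
               ser$final_motor_count)
  expect_equal(unname(cts["grow"]), ser$final_length - pars$L0)
})

test_that("exclusion and cargo-on-motor invariants hold in every snapshot", {
  pars <- tiny_params(c_motor = 300, enable_cap = TRUE, enable_trains = TRUE,
                      enable_stabilization = TRUE)
  ser <- run_simulation(pars, run_schedule(100, 100, 2))
  for (st in ser$states) expect_silent(validate_lattice_state(st))
  # nucleotide ages with distance from the growing tip: the region beyond the
  # cap must be fully hydrolysed
  last <- ser$states[[100]]
  expect_true(all(last$nucleotide[seq_len(last$length - 200)] == "GDP"))
})

test_that("a cap without rate contrast is statistically indistinguishable from no cap", {
  sch <- run_schedule(200, 300, 2)
  base <- model_params(L0 = 200, gamma = 1, c_motor = 100, seed = 55)
  p_cap <- base; p_cap$enable_cap <- TRUE; p_cap$p_slow <- p_cap$p
  d_off <- tip_window_density(run_simulation(base, sch), 150L)
  d_on <- tip_window_density(run_simulation(p_cap, sch), 150L)
  se <- sqrt(d_off$se^2 + d_on$se^2)
  expect_lt(abs(d_on$mean - d_off$mean), 5 * se + 0.003)
})

test_that("first-layer cargo equilibrates to its stationary carrying fraction", {
  carrying <- function(omega_d, seed) {
    # p = 0 isolates the Langmuir + cargo kinetics from transport
    pars <- model_params(L0 = 200, p = 0, gamma = 0, k_m_on = 0, k_m_off = 0,
                         k_c_on = 1, k_c_off = 2, omega_d = omega_d,
                         omega_a = 0.05 * omega_d / 0.95, seed = seed)
    ser <- run_simulation(pars, run_schedule(100, 500, 2))
    frac <- vapply(ser$states, function(st) {
      m <- st$motor == 1L
      if (!any(m)) return(NA_real_)
      mean(st$cargo[m] > 0L)
    }, numeric(1))
    mean(frac, na.rm = TRUE)
  }
  # motor turnover renews the population cargo-free, so the exact stationary
  # fraction is k_c_on / (k_c_on + k_c_off + omega_d) ...
  expect_equal(carrying(0.25, 77), 1 / 3.25, tolerance = 0.05)
  # ... which approaches the detailed-balance value k_c_on/(k_c_on+k_c_off)
  # once binding kinetics are much faster than turnover
  expect_equal(carrying(0.02, 78), 1 / 3, tolerance = 0.05)
})

test_that("motor-free cap yields the exponential GTP profile with decay k_h1/gamma", {
  pars <- model_params(c_motor = 0, gamma = 3, k_h1 = 0.35, k_h2 = 0.35,
                       L0 = 200, enable_cap = TRUE, seed = 91)
  ser <- run_simulation(pars, run_schedule(300, 200, 5))
  W <- 80L
  gtp <- rowMeans(vapply(ser$states, function(st) {
    idx <- seq.int(st$length, by = -1L, length.out = W)
    as.numeric(st$nucleotide[idx] == "GTP")
  }, numeric(W)))
  x <- 0:(W - 1L)
  keep <- gtp > 0.1
  fit <- lm(log(gtp[keep]) ~ x[keep])
  expect_equal(unname(-coef(fit)[2]), pars$k_h1 / pars$gamma, tolerance = 0.1)
})

test_that("degenerate schedules and absorbing states are refused", {
  expect_error(run_schedule(100, 0), "at least one sample")
  dead <- model_params(L0 = 5, p = 0, omega_a = 0, omega_d = 0, gamma = 0,
                       k_c_on = 0, seed = 1)
  expect_error(run_simulation(dead, run_schedule(1, 1, 1)), "absorbing")
  st <- lattice_state(3)
  expect_error(step_gillespie(st, dead), "absorbing")
})

test_that("snapshot series round-trip through their tabular serialization", {
  pars <- tiny_params(enable_cap = TRUE)
  ser <- run_simulation(pars, run_schedule(30, 5, 5))
  dir <- withr::local_tempdir()
  write_snapshots(ser, dir)
  back <- read_snapshots(dir)
  for (i in seq_along(ser$states)) {
    expect_identical(back$states[[i]]$motor, ser$states[[i]]$motor)
    expect_identical(back$states[[i]]$cargo, ser$states[[i]]$cargo)
    expect_identical(back$states[[i]]$nucleotide, ser$states[[i]]$nucleotide)
  }
  expect_equal(back$seed, ser$seed)
})
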