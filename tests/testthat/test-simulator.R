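test_that("RK4 reproduces closed forms and converges at fourth order", {
  # linear decay against its closed form
  a <- 0.011
  out <- integrate_rk4(function(t, y) -a * y, 25, c(0, 24), step = 0.01)
  expect_lt(rel_err(out[2, 1], 25 * exp(-a * 24)), 1e-9)

  # zero dynamics: constant trajectory
  outc <- integrate_rk4(function(t, y) 0 * y, c(3, 7), c(0, 10, 20),
                        step = 0.5)
  expect_equal(outc, matrix(c(3, 3, 3, 7, 7, 7), ncol = 2),
               ignore_attr = TRUE)

  # halving the step shrinks the error ~16x (order 4); a faster decay
  # keeps the truncation error well above round-off
  b <- 2
  exact <- 25 * exp(-b * 5)
  e1 <- abs(integrate_rk4(function(t, y) -b * y, 25, c(0, 5),
                          step = 0.2)[2, 1] - exact)
  e2 <- abs(integrate_rk4(function(t, y) -b * y, 25, c(0, 5),
                          step = 0.1)[2, 1] - exact)
  expect_gt(e1 / e2, 12)
  expect_lt(e1 / e2, 20)
})

test_that("closed-form ZA subsystem solution matches its triangular special case", {
  za <- za_params(kZY = 0.02, kXY = 0.01, kYZ = 0, rhoZY = 10, kXZ = 0)
  t <- c(0, 5, 30)
  cf <- za_subsystem_closed_form(za, 25, t)
  a <- za$kZY + za$kXY
  expect_equal(cf[, "Y"], 25 * exp(-a * t))
  expect_equal(cf[, "Z"], 25 * za$rhoZY * za$kZY * (1 - exp(-a * t)) / a)
  expect_equal(unname(cf[1, ]), c(25, 0))

  # confluent (repeated-eigenvalue) branch: kZY=kXY=kYZ=kXZ=0 gives A = 0
  za0 <- za_params(0, 0, 0, rhoZY = 1)
  cf0 <- za_subsystem_closed_form(za0, 25, c(0, 10))
  expect_equal(unname(cf0[2, ]), c(25, 0))
})

test_that("compiled integrator agrees with the matrix-exponential oracle on random kinetics", {
  set.seed(7)
  design <- experiment_design("continuous", sample_times = c(1, 6, 24, 48),
                              Y0 = 25)
  ag <- ag1_cont()
  for (i in 1:100) {
    za <- random_za()
    traj <- simulate_experiment(1, za, ag, design, step = 0.01)
    sim <- trajectory_at(traj, design$sample_times)
    cf <- za_subsystem_closed_form(za, 25, design$sample_times)
    scale <- pmax(abs(cf), 1e-8)
    expect_lt(max(abs(cbind(sim$Y, sim$Z) - cf) / scale), 1e-6)
  }
})

test_that("pulse medium replacement resets Y instantaneously and leaves cells untouched", {
  za <- za_params(0.607, 0.029, 18.06, 14.91, Ystar_plus = 0)
  st <- c(Y = 18.3, Z = 4.4, G = 2.7)
  post <- apply_medium_replacement(st, za)
  expect_equal(unname(post), c(0, 4.4, 2.7))
  # identity when the replacement concentration equals the current one
  za_id <- za_params(0.607, 0.029, 18.06, 14.91, Ystar_plus = 18.3)
  expect_equal(apply_medium_replacement(st, za_id), st)
  # usage error outside pulse mode
  cont <- experiment_design("continuous", c(1, 24))
  expect_error(apply_medium_replacement(st, za, design = cont),
               "pulse-mode event")

  sc <- scenario_truth("model1_pulse")
  traj <- simulate_experiment(1, sc$za, sc$ag, sc$design)
  at_star <- trajectory_at(traj, sc$design$t_star)
  expect_identical(at_star$Y, 0)          # post-event value is stored
  expect_gt(traj$y_pre, 20)               # pre-event medium ZA retrievable
  # intracellular ZA is continuous across the event: the pulse run is
  # identical to a continuous run with the same kinetics up to t_star
  cont_design <- experiment_design("continuous",
                                   sample_times = sc$design$sample_times,
                                   Y0 = sc$design$Y0)
  traj_c <- simulate_experiment(1, sc$za, sc$ag, cont_design)
  tt <- c(0.5, 1)
  expect_equal(trajectory_at(traj, tt)$Z, trajectory_at(traj_c, tt)$Z,
               tolerance = 1e-12)
  expect_equal(traj$y_pre, trajectory_at(traj_c, 1)$Y, tolerance = 1e-12)
})

test_that("halving the default step leaves reported states unchanged to 1e-7", {
  sc <- scenario_truth("model1_continuous")
  s1 <- trajectory_at(simulate_experiment(1, sc$za, sc$ag, sc$design,
                                          step = 0.01),
                      sc$design$sample_times)
  s2 <- trajectory_at(simulate_experiment(1, sc$za, sc$ag, sc$design,
                                          step = 0.005),
                      sc$design$sample_times)
  expect_lt(max(abs(s1[-1] - s2[-1]) / pmax(abs(s2[-1]), 1e-8)), 1e-7)
})

test_that("pulse dosing never yields more intracellular ZA than continuous dosing", {
  za <- za_cont(); ag <- ag1_cont()
  times <- c(1, 3, 6, 12, 18, 24, 48)
  cont <- simulate_experiment(1, za, ag,
                              experiment_design("continuous", times))
  puls <- simulate_experiment(1, za, ag,
                              experiment_design("pulse", times, t_star = 1))
  zc <- trajectory_at(cont, times)$Z
  zp <- trajectory_at(puls, times)$Z
  expect_true(all(zp <= zc + 1e-12))
})

test_that("without drug both models hold the antigen pool at G0", {
  d0 <- experiment_design("continuous", c(1, 12, 48), Y0 = 0)
  tr1 <- simulate_experiment(1, za_cont(), ag1_cont(), d0)
  expect_lt(max(abs(tr1$states[, "G"] - ag1_cont()$G0)), 1e-9)
  expect_equal(max(tr1$states[, "Z"]), 0)
  tr2 <- simulate_experiment(2, za_cont(), ag2_cont(), d0)
  expect_lt(max(abs(tr2$states[, "G"] - ag2_cont()$G0)), 1e-9)
  expect_equal(max(tr2$states[, "B"]), 0)
})

test_that("bound and unbound enzyme percentages always sum to exactly U0", {
  sc <- scenario_truth("model2_continuous")
  tr <- simulate_experiment(2, sc$za, sc$ag, sc$design)
  expect_identical(max(abs(tr$states[, "U"] + tr$states[, "B"] - 100)), 0)
  expect_true(all(tr$states[, "B"] <= 100))
})

test_that("fixed-step trajectories agree with an adaptive reference solver", {
  sc <- scenario_truth("model1_continuous")
  ours <- trajectory_at(simulate_experiment(1, sc$za, sc$ag, sc$design),
                        sc$design$sample_times)
  f <- function(t, y, parms) {
    list(unname(model1_rhs(c(Y = y[1], Z = y[2], G = y[3]), sc$za, sc$ag)))
  }
  ref <- deSolve::lsoda(c(25, 0, sc$ag$G0),
                        c(0, sc$design$sample_times), f, NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(as.matrix(ours[c("Y", "Z", "G")]) - ref[-1, -1]) /
                  pmax(abs(ref[-1, -1]), 1e-8)), 1e-6)
})

test_that("integration failures carry the failure time", {
  # explosive artificial dynamics through the generic integrator
  expect_error(integrate_rk4(function(t, y) y^2, 1, c(0, 10), step = 0.1),
               "non-finite state at t")
})
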