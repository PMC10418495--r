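test_that("the equilibrium state is the rest configuration", {
  st <- equilibrium_state(4)
  expect_equal(st$phi2, rep(pi, 4))
  expect_equal(st$phi1, rep(0, 4))
  expect_equal(st$delta, rep(1L, 4))
  expect_error(equilibrium_state(1), ">= 2")

  mech <- toy_mechanics("ATGC")
  a <- rhs(st, mech, forcing_spec(F0 = 0), 0)
  # torque residual relative to the single-angle coupling torque scale
  scale <- mech$k12 * mech$R1 * (mech$R1 + mech$R2) / mech$I1
  expect_lt(max(abs(c(a$a1, a$a2))) / max(scale), 1e-12)
})

test_that("conservative-mode torques are minus the potential gradient", {
  set.seed(21)
  mech <- toy_mechanics("ATGCGA")
  st <- equilibrium_state(6)
  st$phi1 <- st$phi1 + runif(6, -0.4, 0.4)
  st$phi2 <- st$phi2 + runif(6, -0.4, 0.4)
  st$delta <- c(1L, 1L, 0L, 1L, 0L, 1L)   # mix of intact and broken bonds
  a <- rhs(st, mech, forcing_spec(F0 = 0), 0, mode = "conservative")
  h <- 1e-7
  for (i in seq_len(6)) {
    for (chain in 1:2) {
      sp <- st; sm <- st
      fld <- if (chain == 1) "phi1" else "phi2"
      sp[[fld]][i] <- sp[[fld]][i] + h
      sm[[fld]][i] <- sm[[fld]][i] - h
      grad <- (total_energy(sp, mech) - total_energy(sm, mech)) / (2 * h)
      tq <- if (chain == 1) a$a1[i] * mech$I1[i] else a$a2[i] * mech$I2[i]
      expect_equal(tq, -grad, tolerance = 1e-6)
    }
  }
})

test_that("mirrored perturbations give mirrored accelerations on a uniform chain", {
  mech <- toy_mechanics("AAAAAA")    # both chains uniform
  st <- equilibrium_state(6)
  st$phi1 <- c(0.1, -0.2, 0.3, 0.05, -0.1, 0.2)
  st$phi2 <- pi + c(-0.1, 0.2, 0.1, -0.3, 0.2, 0.0)
  a <- rhs(st, mech, forcing_spec(F0 = 0), 0)
  str <- st
  str$phi1 <- rev(st$phi1); str$phi2 <- rev(st$phi2)
  ar <- rhs(str, mech, forcing_spec(F0 = 0), 0)
  expect_equal(ar$a1, rev(a$a1), tolerance = 1e-12)
  expect_equal(ar$a2, rev(a$a2), tolerance = 1e-12)
})

test_that("pair stretch energy is anchored at the rest state and maximal at alignment", {
  mech <- toy_mechanics("ATGC")
  st <- equilibrium_state(4)
  expect_equal(pair_potential_energy(st, mech), rep(0, 4), tolerance = 1e-25)
  st$phi2 <- st$phi1   # aligned bases
  expect_equal(pair_potential_energy(st, mech),
               2 * mech$k12 * mech$R1 * mech$R2)
  # strictly increasing in the deviation from the rest separation
  devs <- seq(0.1, 3.1, by = 0.2)
  e <- vapply(devs, function(x) {
    s <- equilibrium_state(4); s$phi1[2] <- x
    pair_potential_energy(s, mech, 2)
  }, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("bonds break above and restore below the critical energy, ties frozen", {
  mech <- toy_mechanics("ATGC", Ecr = 0.250e-22)
  st <- equilibrium_state(4)
  expect_equal(update_bonds(st, mech)$delta, rep(1L, 4))

  # drive one pair past its threshold
  st2 <- st
  st2$phi1[3] <- pi / 2
  expect_gt(pair_potential_energy(st2, mech, 3), mech$Ecr[3])
  st2 <- update_bonds(st2, mech)
  expect_equal(st2$delta, c(1L, 1L, 0L, 1L))

  # relax it back below the threshold: restored
  st2$phi1[3] <- 0
  expect_equal(update_bonds(st2, mech)$delta, rep(1L, 4))

  # exact tie leaves the indicator unchanged in both directions
  st3 <- st
  st3$phi1[2] <- 0.5
  mech3 <- mech
  mech3$Ecr[2] <- pair_potential_energy(st3, mech3, 2)
  expect_equal(update_bonds(st3, mech3)$delta[2], 1L)
  st3$delta[2] <- 0L
  expect_equal(update_bonds(st3, mech3)$delta[2], 0L)
})

test_that("an undisturbed equilibrium does not move", {
  mech <- toy_mechanics("ATGCATGC")
  st <- equilibrium_state(8)
  s1 <- rk4_step(st, mech, forcing_spec(F0 = 0), 1e-14)
  expect_equal(s1$phi1, st$phi1, tolerance = 1e-13)
  expect_equal(s1$phi2, st$phi2, tolerance = 1e-13)

  traj <- simulate(mech, forcing_spec(F0 = 0),
                   integration_spec(T = 5e-12, tau = 1e-14), record_mask = TRUE)
  expect_equal(max(abs(traj$final_state$phi1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(traj$final_state$phi2 - pi)), 0, tolerance = 1e-9)
  expect_false(any(traj$mask))
})

test_that("the integrator converges at fourth order on a smooth problem", {
  mech <- toy_mechanics("AT", Ecr = 1)   # unreachable threshold: no events
  mech$beta1[] <- 0; mech$beta2[] <- 0
  f <- forcing_spec(F0 = 0)
  st0 <- equilibrium_state(2)
  st0$phi1 <- c(0.3, -0.2)
  st0$phi2 <- pi + c(0.1, 0.25)
  run <- function(tau, nsteps) {
    s <- st0
    for (k in seq_len(nsteps)) s <- rk4_step(s, mech, f, tau)
    c(s$phi1, s$phi2, s$v1, s$v2)
  }
  # base step well inside the asymptotic regime (~275 steps per natural
  # period of the stiff backbone mode)
  tau0 <- 4e-15; n0 <- 250L
  ref <- run(tau0 / 16, n0 * 16L)
  errs <- vapply(0:2, function(k) {
    max(abs(run(tau0 / 2^k, n0 * 2L^k) - ref))
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(abs(orders - 4) < 0.2))
})

test_that("energy is conserved without damping and dissipated with it", {
  mech <- toy_mechanics("ATGCAT", Ecr = 1)
  f <- forcing_spec(F0 = 0)
  st <- equilibrium_state(6)
  st$phi1 <- st$phi1 + c(0.2, -0.1, 0.15, 0.0, -0.2, 0.1)

  cons <- mech; cons$beta1[] <- 0; cons$beta2[] <- 0
  e0 <- total_energy(st, cons)
  s <- st
  for (k in 1:200) s <- rk4_step(s, cons, f, 1e-14)
  expect_equal(total_energy(s, cons), e0, tolerance = 1e-8)

  s <- st
  e_prev <- total_energy(s, mech)
  for (k in 1:100) {
    s <- rk4_step(s, mech, f, 1e-14)
    e_now <- total_energy(s, mech)
    expect_lte(e_now, e_prev * (1 + 1e-12))
    e_prev <- e_now
  }
})

test_that("the compiled stepping loop matches the R reference stepper", {
  mech <- toy_mechanics("ATGCAT", Ecr = 0.250e-22)
  f <- toy_forcing(2e-19)   # strong drive so bonds break within the short run
  nsteps <- 100L
  traj <- simulate(mech, f, integration_spec(T = nsteps * 1e-14, tau = 1e-14),
                   record_mask = TRUE)
  s <- equilibrium_state(6)
  masks <- matrix(NA, nsteps, 6)
  for (k in seq_len(nsteps)) {
    s <- rk4_step(s, mech, f, 1e-14)
    s <- update_bonds(s, mech)
    masks[k, ] <- s$delta == 0L
  }
  expect_true(any(masks))            # the toy drive does break bonds
  expect_equal(unname(traj$mask), masks)
  expect_equal(traj$final_state$phi1, s$phi1, tolerance = 1e-12)
  expect_equal(traj$final_state$v2, s$v2, tolerance = 1e-12)
  expect_identical(traj$final_state$delta, s$delta)
})

test_that("simulation is deterministic and honours the recording stride", {
  mech <- toy_mechanics("ATGCATGC", Ecr = 0.250e-22)
  integ <- integration_spec(T = 1e-12, tau = 1e-14, record_stride = 7L)
  t1 <- simulate(mech, toy_forcing(), integ)
  t2 <- simulate(mech, toy_forcing(), integ)
  expect_identical(t1$q, t2$q)
  expect_identical(t1$mask, t2$mask)
  expect_equal(nrow(t1$q), 100L %/% 7L)
  expect_equal(t1$times, (1:nrow(t1$q)) * 7 * 1e-14)
})

test_that("threshold limits behave as expected", {
  mech_hi <- toy_mechanics("ATGCAT", Ecr = 1)
  t_hi <- simulate(mech_hi, toy_forcing(), integration_spec(T = 5e-13, tau = 1e-14))
  expect_false(any(t_hi$mask))
  expect_equal(unname(occupancy_probability(t_hi)), rep(0, 5))

  mech_lo <- toy_mechanics("ATGCAT", Ecr = 1e-40)
  t_lo <- simulate(mech_lo, toy_forcing(), integration_spec(T = 5e-13, tau = 1e-14))
  expect_true(all(t_lo$mask))
  expect_equal(occupancy_probability(t_lo)[["g2"]], 1)
})
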