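#' Periodic forcing specification
#'
#' External influence per base: \code{-beta * dphi/dt + F0 * cos(omega * t)},
#' applied identically to every base on both chains. The dissipation
#' coefficient lives in the mechanics table; here only the periodic drive is
#' specified.
#'
#' @param F0 Torque amplitude (N m). Default 0.526e-22.
#' @param omega Angular frequency (1/s). Default 0.4e12.
#' @return Object of class \code{forcing_spec}.
#' @export
forcing_spec <- function(F0 = 0.526e-22, omega = 0.4e12) {
  stopifnot(is.numeric(F0), length(F0) == 1L, is.finite(F0),
            is.numeric(omega), length(omega) == 1L, omega > 0)
  structure(list(F0 = F0, omega = omega), class = "forcing_spec")
}

#' Integration specification
#'
#' @param T Time horizon (s). Default 3.0e-10.
#' @param tau Step size (s). Default 1.0e-14, so the default run takes
#'   m = 30,000 steps.
#' @param record_stride Record the bond state every this many steps
#'   (default 1: sample points coincide with t_j = j*tau).
#' @return Object of class \code{integration_spec} with element \code{m},
#'   the step count \code{round(T/tau)}.
#' @export
integration_spec <- function(T = 3.0e-10, tau = 1.0e-14, record_stride = 1L) {
  stopifnot(is.numeric(T), T > 0, is.numeric(tau), tau > 0)
  record_stride <- as.integer(record_stride)
  stopifnot(record_stride >= 1L)
  m <- as.integer(round(T / tau))
  if (m < 1L) stop("integration horizon shorter than one step")
  structure(list(T = T, tau = tau, record_stride = record_stride, m = m),
            class = "integration_spec")
}

#' Equilibrium initial state
#'
#' The duplex at rest: chain-1 angles 0, chain-2 angles pi (bases facing
#' each other), zero angular velocities, every bond intact, t = 0.
#'
#' @param n Pair count (>= 2).
#' @return Object of class \code{dynamic_state} with elements \code{phi1},
#'   \code{phi2}, \code{v1}, \code{v2} (numeric length n), \code{delta}
#'   (integer 0/1 length n), \code{t}.
#' @export
equilibrium_state <- function(n) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2: the chain-end equations need distinct ends")
  structure(
    list(phi1 = numeric(n), phi2 = rep(pi, n), v1 = numeric(n), v2 = numeric(n),
         delta = rep(1L, n), t = 0),
    class = "dynamic_state"
  )
}

dynamic_state <- function(phi1, phi2, v1, v2, delta = rep(1L, length(phi1)), t = 0) {
  n <- length(phi1)
  stopifnot(length(phi2) == n, length(v1) == n, length(v2) == n, length(delta) == n,
            all(delta %in% c(0L, 1L)))
  structure(list(phi1 = as.numeric(phi1), phi2 = as.numeric(phi2),
                 v1 = as.numeric(v1), v2 = as.numeric(v2),
                 delta = as.integer(delta), t = as.numeric(t)),
            class = "dynamic_state")
}

# Backbone torques. "conservative" derives them from segment springs
# K_seg(i) between neighbours i and i+1 (K_seg(i) = K of base i), so the
# force is exactly minus the gradient of the backbone potential even when K
# varies along the chain; with uniform K this coincides with the printed
# second-difference form used by "literal".
backbone_torque <- function(phi, K, mode) {
  n <- length(phi)
  out <- numeric(n)
  if (mode == "conservative") {
    kseg <- K[-n]
    d <- diff(phi)                     # phi[i+1] - phi[i]
    out[1L] <- kseg[1L] * d[1L]
    out[n] <- -kseg[n - 1L] * d[n - 1L]
    if (n > 2L) {
      i <- 2:(n - 1L)
      out[i] <- kseg[i - 1L] * (-d[i - 1L]) + kseg[i] * d[i]
    }
  } else {
    out[1L] <- K[1L] * (phi[2L] - phi[1L])
    out[n] <- K[n] * (phi[n - 1L] - phi[n])
    if (n > 2L) {
      i <- 2:(n - 1L)
      out[i] <- K[i] * (phi[i - 1L] - 2 * phi[i] + phi[i + 1L])
    }
  }
  out
}

#' Angular accelerations of both chains
#'
#' The right-hand side of the coupled second-order system. Per interior base
#' the torque has three parts: the backbone (sugar-phosphate) coupling to
#' the two neighbours, the hydrogen-bond coupling to the complementary base,
#' and the external term \code{-beta*v + F0*cos(omega*t)}. End bases couple
#' to their single neighbour.
#'
#' @param state A \code{dynamic_state}.
#' @param mech A \code{\link{build_pair_mechanics}} result.
#' @param forcing A \code{\link{forcing_spec}}.
#' @param t Time (s) at which to evaluate the periodic drive.
#' @param mode \code{"conservative"} (default) derives both chains' bond
#'   torques from one interaction potential so the rest state (0, pi) is a
#'   true minimum; \code{"literal"} flips the sign of the chain-2
#'   relative-angle term (the printed form of the model).
#' @param delta_gates_both Should a broken bond (delta = 0) switch off both
#'   bond-coupling terms (default for conservative mode) or only the
#'   single-angle term (the literal placement)?
#' @return List with numeric vectors \code{a1}, \code{a2} (rad/s^2).
#' @export
rhs <- function(state, mech, forcing, t = state$t,
                mode = c("conservative", "literal"), delta_gates_both = NULL) {
  mode <- match.arg(mode)
  if (is.null(delta_gates_both)) delta_gates_both <- (mode == "conservative")
  if (!all(is.finite(state$phi1)) || !all(is.finite(state$phi2)) ||
      !all(is.finite(state$v1)) || !all(is.finite(state$v2)))
    stop("non-finite state passed to rhs()")
  d <- as.numeric(state$delta)
  dg <- if (delta_gates_both) d else rep(1, mech$n)
  s1 <- sin(state$phi1)
  s2 <- sin(state$phi2)
  srel <- sin(state$phi1 - state$phi2)
  kRR <- mech$k12 * mech$R1 * mech$R2
  drive <- forcing$F0 * cos(forcing$omega * t)
  rel2 <- if (mode == "conservative") -dg * kRR * srel else dg * kRR * srel
  tq1 <- backbone_torque(state$phi1, mech$K1, mode) -
    d * mech$k12 * mech$R1 * (mech$R1 + mech$R2) * s1 +
    dg * kRR * srel - mech$beta1 * state$v1 + drive
  tq2 <- backbone_torque(state$phi2, mech$K2, mode) +
    d * mech$k12 * mech$R2 * (mech$R1 + mech$R2) * s2 +
    rel2 - mech$beta2 * state$v2 + drive
  list(a1 = tq1 / mech$I1, a2 = tq2 / mech$I2)
}

#' Hydrogen-bond stretch energy of each pair
#'
#' The break-test energy: \code{k12*R1*R2*(1 + cos(phi1 - phi2))}. It is
#' anchored at zero in the rest state (phi1 - phi2 = -pi) and reaches its
#' maximum \code{2*k12*R1*R2} when the bases align. It is evaluated
#' regardless of the current bond indicator, since the same quantity decides
#' both breaking and restoring.
#'
#' @param state A \code{dynamic_state}.
#' @param mech Pair mechanics.
#' @param i Optional position (1-based); default all positions.
#' @param include_backbone_terms Also add the delta-gated single-angle parts
#'   of the interaction potential (off by default: the relative-rotation
#'   term is the part that directly measures bond stretch).
#' @return Numeric vector of energies (N m).
#' @export
pair_potential_energy <- function(state, mech, i = NULL,
                                  include_backbone_terms = FALSE) {
  e <- mech$k12 * mech$R1 * mech$R2 * (1 + cos(state$phi1 - state$phi2))
  if (include_backbone_terms) {
    e <- e + as.numeric(state$delta) * mech$k12 * (mech$R1 + mech$R2) *
      (mech$R1 * (1 - cos(state$phi1)) + mech$R2 * (1 + cos(state$phi2)))
  }
  if (!is.null(i)) {
    stopifnot(all(i >= 1L), all(i <= mech$n))
    e <- e[i]
  }
  e
}

#' Total mechanical energy (conservative mode)
#'
#' Kinetic energy plus backbone segment-spring potential plus the bond
#' interaction potential. Useful for energy-audit checks: with beta = 0,
#' F0 = 0 and no bond events the quantity is conserved up to the
#' integrator's truncation error; with beta > 0 it is non-increasing.
#'
#' @inheritParams rhs
#' @return Scalar energy (N m).
#' @export
total_energy <- function(state, mech, delta_gates_both = TRUE) {
  d <- as.numeric(state$delta)
  dg <- if (delta_gates_both) d else rep(1, mech$n)
  kin <- 0.5 * sum(mech$I1 * state$v1^2 + mech$I2 * state$v2^2)
  bb <- function(phi, K) {
    kseg <- K[-length(K)]
    sum(0.5 * kseg * diff(phi)^2)
  }
  vint <- sum(d * mech$k12 * (mech$R1 + mech$R2) *
                (mech$R1 * (1 - cos(state$phi1)) + mech$R2 * (1 + cos(state$phi2))) +
              dg * mech$k12 * mech$R1 * mech$R2 * (1 + cos(state$phi1 - state$phi2)))
  kin + bb(state$phi1, mech$K1) + bb(state$phi2, mech$K2) + vint
}

#' Apply the break/restore rule to the bond indicators
#'
#' A bond breaks (delta 1 -> 0) when its stretch energy exceeds the pair's
#' critical energy, and a broken bond is restored (0 -> 1) when the energy
#' falls back below it. Exact equality leaves the indicator unchanged
#' (strict inequalities prevent chatter at the threshold).
#'
#' @param state A \code{dynamic_state}.
#' @param mech Pair mechanics (supplies \code{Ecr}).
#' @return The state with updated \code{delta}.
#' @export
update_bonds <- function(state, mech) {
  e <- pair_potential_energy(state, mech)
  delta <- state$delta
  delta[e > mech$Ecr] <- 0L
  delta[delta == 0L & e < mech$Ecr] <- 1L
  state$delta <- delta
  state
}

#' One classic fourth-order Runge-Kutta step
#'
#' Advances angles and angular velocities by one step of size \code{tau}.
#' The bond indicators are held fixed within the step; apply
#' \code{\link{update_bonds}} afterwards (as \code{\link{simulate}} does).
#'
#' @inheritParams rhs
#' @param tau Step size (s).
#' @return The advanced \code{dynamic_state} (with \code{t} incremented).
#' @export
rk4_step <- function(state, mech, forcing, tau,
                     mode = c("conservative", "literal"), delta_gates_both = NULL) {
  mode <- match.arg(mode)
  deriv <- function(phi1, phi2, v1, v2, t) {
    s <- state
    s$phi1 <- phi1; s$phi2 <- phi2; s$v1 <- v1; s$v2 <- v2
    a <- rhs(s, mech, forcing, t, mode = mode, delta_gates_both = delta_gates_both)
    list(dphi1 = v1, dphi2 = v2, dv1 = a$a1, dv2 = a$a2)
  }
  t0 <- state$t
  k1 <- deriv(state$phi1, state$phi2, state$v1, state$v2, t0)
  k2 <- deriv(state$phi1 + tau / 2 * k1$dphi1, state$phi2 + tau / 2 * k1$dphi2,
              state$v1 + tau / 2 * k1$dv1, state$v2 + tau / 2 * k1$dv2, t0 + tau / 2)
  k3 <- deriv(state$phi1 + tau / 2 * k2$dphi1, state$phi2 + tau / 2 * k2$dphi2,
              state$v1 + tau / 2 * k2$dv1, state$v2 + tau / 2 * k2$dv2, t0 + tau / 2)
  k4 <- deriv(state$phi1 + tau * k3$dphi1, state$phi2 + tau * k3$dphi2,
              state$v1 + tau * k3$dv1, state$v2 + tau * k3$dv2, t0 + tau)
  comb <- function(f) tau / 6 * (k1[[f]] + 2 * k2[[f]] + 2 * k3[[f]] + k4[[f]])
  state$phi1 <- state$phi1 + comb("dphi1")
  state$phi2 <- state$phi2 + comb("dphi2")
  state$v1 <- state$v1 + comb("dv1")
  state$v2 <- state$v2 + comb("dv2")
  state$t <- t0 + tau
  if (!all(is.finite(state$phi1)) || !all(is.finite(state$phi2)) ||
      !all(is.finite(state$v1)) || !all(is.finite(state$v2))) {
    bad <- which(!is.finite(state$phi1) | !is.finite(state$phi2) |
                   !is.finite(state$v1) | !is.finite(state$v2))[1L]
    stop(sprintf("integration diverged at t = %.4g s, position %d", state$t, bad))
  }
  state
}

#' Integrate the duplex and record the bond trajectory
#'
#' Runs \code{m = round(T/tau)} Runge-Kutta steps from the given initial
#' state, applying the break/restore rule after every completed step, and
#' records the broken-bond mask (and the per-group occupancy fractions)
#' every \code{record_stride} steps. Sampling starts at t = tau: the initial
#' state does not enter the occupancy average. The computation is fully
#' deterministic. The stepping loop runs in compiled code; it agrees with
#' repeated \code{\link{rk4_step}} + \code{\link{update_bonds}} to machine
#' precision.
#'
#' @inheritParams rhs
#' @param integ An \code{\link{integration_spec}}.
#' @param state Initial state; default \code{\link{equilibrium_state}}.
#' @param record_mask Keep the full 0/1 mask matrix (samples x positions)?
#'   Occupancy fractions per size group are always recorded; the mask matrix
#'   is only needed for run-level inspection.
#' @param record_energy Keep the pair stretch-energy matrix at each sample
#'   (needed for re-thresholding experiments)?
#' @return Object of class \code{bond_trajectory}: \code{times}, \code{q}
#'   (samples x 5 occupancy-fraction matrix with columns
#'   \code{OS, g1, g2, g3, g4}), optional \code{mask} and \code{energy}
#'   matrices, \code{final_state}, \code{n}, \code{m}, \code{record_stride}.
#' @export
simulate <- function(mech, forcing = forcing_spec(), integ = integration_spec(),
                     state = equilibrium_state(mech$n),
                     mode = c("conservative", "literal"), delta_gates_both = NULL,
                     record_mask = TRUE, record_energy = FALSE) {
  mode <- match.arg(mode)
  if (is.null(delta_gates_both)) delta_gates_both <- (mode == "conservative")
  stopifnot(inherits(mech, "pair_mechanics"), inherits(forcing, "forcing_spec"),
            inherits(integ, "integration_spec"), inherits(state, "dynamic_state"))
  if (length(state$phi1) != mech$n)
    stop("state and mechanics disagree on the pair count")
  groups <- bubble_size_groups()
  res <- simulate_core(
    state$phi1, state$phi2, state$v1, state$v2, state$delta,
    mech$I1, mech$I2, mech$R1, mech$R2, mech$K1, mech$K2,
    mech$k12, mech$beta1, mech$beta2, mech$Ecr,
    forcing$F0, forcing$omega, state$t, integ$tau, integ$m, integ$record_stride,
    mode == "conservative", delta_gates_both,
    as.integer(groups$min), as.integer(ifelse(is.finite(groups$max), groups$max, .Machine$integer.max)),
    record_mask, record_energy
  )
  colnames(res$q) <- groups$group
  traj <- list(
    times = res$times,
    q = res$q,
    mask = if (record_mask) res$mask else NULL,
    energy = if (record_energy) res$energy else NULL,
    final_state = dynamic_state(res$phi1, res$phi2, res$v1, res$v2, res$delta,
                                t = res$t),
    n = mech$n, m = integ$m, record_stride = integ$record_stride
  )
  class(traj) <- "bond_trajectory"
  traj
}

#' Re-threshold a recorded energy trajectory at a new critical energy
#'
#' Turns the stretch-energy snapshots of a simulation run with
#' \code{record_energy = TRUE} into the bond masks that a (hypothetical)
#' threshold \code{Ecr} would declare broken at each sample, without
#' re-running the dynamics. Because raising \code{Ecr} can only shrink the
#' broken set, occupancy in runs of length >= L is non-increasing in
#' \code{Ecr} for every L on such a fixed trajectory.
#'
#' @param traj A \code{bond_trajectory} carrying an \code{energy} matrix.
#' @param Ecr Critical energy (N m).
#' @return A \code{bond_trajectory} with the re-thresholded \code{mask} and
#'   recomputed \code{q}.
#' @export
threshold_trajectory <- function(traj, Ecr) {
  stopifnot(inherits(traj, "bond_trajectory"))
  if (is.null(traj$energy))
    stop("trajectory has no energy snapshots; run simulate(record_energy = TRUE)")
  mask <- traj$energy > Ecr
  q <- t(apply(mask, 1L, occupancy_fraction))
  colnames(q) <- bubble_size_groups()$group
  out <- traj
  out$mask <- mask
  out$q <- q
  out$energy <- traj$energy
  out
}
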