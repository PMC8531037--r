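p_unit <- hydro_params() # a = 1, 6 pi eta a = 1

test_that("pair blocks match symbolic substitution into the printed tensor", {
  # self block is the identity over the drag coefficient
  expect_equal(pair_block(NULL, p_unit), diag(2))
  # contact separation x = 2a: parallel coefficient (3/4 - 1/8) = 5/8,
  # perpendicular 3/8 + 1/16 = 7/16
  B <- pair_block(c(2, 0), p_unit)
  expect_equal(B[1, 1], 5 / 8, tolerance = 1e-14)
  expect_equal(B[2, 2], 7 / 16, tolerance = 1e-14)
  expect_equal(B[1, 2], 0)
  # general direction against direct formula evaluation
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(2); x <- x / sqrt(sum(x^2)) * runif(1, 2, 10)
    xn <- sqrt(sum(x^2)); xh <- x / xn
    ref <- (3 / (4 * xn)) * (diag(2) + outer(xh, xh)) +
      0.5 * (1 / xn)^3 * (diag(2) - 3 * outer(xh, xh))
    expect_equal(pair_block(x, p_unit), ref, tolerance = 1e-14)
  }
  # far-field decay like 1/x
  b10 <- pair_block(c(10, 0), p_unit)[1, 1]
  b100 <- pair_block(c(100, 0), p_unit)[1, 1]
  expect_equal(b10 / b100, 10, tolerance = 0.01)
  expect_warning(pair_block(c(1, 0), p_unit), "2a")
  expect_error(pair_block(c(0, 0), p_unit))
  # physical scaling: drag prefactor enters inversely
  p2 <- hydro_params(a = 1, eta_fluid = 2 / (6 * pi))
  expect_equal(pair_block(c(3, 1), p2), pair_block(c(3, 1), p_unit) / 2)
})

test_that("assembled mobility matrix is symmetric SPD on random configs", {
  set.seed(7)
  for (i in 1:100) {
    N <- sample(2:5, 1)
    repeat {
      P <- matrix(runif(2 * N, 0, 10 + 2 * N), N, 2)
      dmin <- min(dist(P))
      if (dmin >= 2) break
    }
    Z <- mobility_matrix(P, p_unit)
    expect_lt(max(abs(Z - t(Z))), 1e-12)
    expect_no_error(chol(Z)) # positive definite
  }
})

test_that("common-velocity solve matches Stokes limits and the dense oracle", {
  # N = 1: Stokes drag, specific power exactly 1
  s1 <- solve_common_velocity(matrix(c(0, 0), 1, 2), c(1, 0), p_unit)
  expect_equal(s1$forces, matrix(c(1, 0), 1, 2))
  expect_equal(s1$power, 1)
  expect_equal(s1$specific, 1)
  expect_equal(solo_power(p_unit, c(1, 0)), 1)
  # two agents far apart decouple toward solo power (1/x convergence)
  s2 <- solve_common_velocity(rbind(c(0, 0), c(100, 0)), c(1, 0), p_unit)
  expect_equal(s2$specific, 1, tolerance = 0.03)
  s3 <- solve_common_velocity(rbind(c(0, 0), c(1000, 0)), c(1, 0), p_unit)
  expect_equal(s3$specific, 1, tolerance = 0.004)
  expect_gt(s3$specific, s2$specific)
  # drafting: in-line beats side-by-side at the same separation
  expect_lt(formation_specific_power(rbind(c(0, 0), c(2, 0))),
            formation_specific_power(rbind(c(0, 0), c(0, 2))))
  # random configurations against the independent dense oracle
  set.seed(11)
  for (i in 1:20) {
    N <- sample(2:5, 1)
    repeat {
      P <- matrix(runif(2 * N, 0, 8 + 2 * N), N, 2)
      if (min(dist(P)) >= 2) break
    }
    v <- rnorm(2)
    got <- solve_common_velocity(P, v, p_unit)
    orc <- oracle_common_velocity(P, v, p_unit)
    expect_equal(got$forces, orc$forces, tolerance = 1e-10)
    expect_equal(got$power, orc$power, tolerance = 1e-10)
  }
})

test_that("power is translation invariant and rotation equivariant", {
  P <- rbind(c(0, 0), c(2.5, 0.5), c(1, 2.2))
  v <- c(1, 0.3)
  base <- solve_common_velocity(P, v, p_unit)$power
  # translation
  expect_equal(solve_common_velocity(P + 7, v, p_unit)$power, base,
               tolerance = 1e-12)
  # simultaneous rotation of positions and velocity
  th <- 0.83
  Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(solve_common_velocity(P %*% t(Rm), as.numeric(Rm %*% v),
                                     p_unit)$power, base, tolerance = 1e-10)
})

test_that("N=2 optimum is the in-line pair at contact (grid-search oracle)", {
  opt <- optimize_configuration(2, p_unit, restarts = 12, seed = 2)
  sep <- opt$best[2, ] - opt$best[1, ]
  expect_equal(sqrt(sum(sep^2)), 2, tolerance = 1e-3)  # minimum separation
  expect_lt(abs(sep[2] / sep[1]), 0.05)                # aligned with v = x
  expect_equal(opt$n_global, 1L)
  # brute-force grid over (separation, orientation)
  grid <- expand.grid(d = seq(2, 6, by = 0.1),
                      th = seq(0, pi / 2, length.out = 19))
  gp <- mapply(function(d, th)
    formation_specific_power(rbind(c(0, 0), d * c(cos(th), sin(th))),
                             p_unit), grid$d, grid$th)
  expect_equal(opt$specific, min(gp), tolerance = 1e-3)
  gbest <- grid[which.min(gp), ]
  expect_equal(gbest$d, 2, tolerance = 1e-9)
  expect_equal(gbest$th, 0, tolerance = 1e-9)
})

test_that("locomotion step honours the leader constraint and Stokes limits", {
  p <- hydro_params(v_lead = c(0.5, 0))
  # far-separated followers move at F / drag independent of the leader
  P <- rbind(c(0, 0), c(5000, 0), c(-5000, 3000))
  st <- locomotion_env_step(P, rbind(c(0.3, 0), c(0, -0.2)), p, dt = 0.1)
  expect_equal(st$velocities[1, ], c(0.5, 0), tolerance = 1e-10)
  expect_equal(st$velocities[2, ], c(0.3, 0), tolerance = 1e-3)
  expect_equal(st$velocities[3, ], c(0, -0.2), tolerance = 1e-3)
  # passive follower near the leader is advected by the leader's flow
  P2 <- rbind(c(0, 0), c(-3, 0))
  st2 <- locomotion_env_step(P2, matrix(c(0, 0), 1, 2), p, dt = 0.1)
  expect_gt(st2$velocities[2, 1], 0.05) # dragged along +x
  # independent check: v_follower = zeta_21 F_leader with F solved so that
  # zeta_11 F = v_lead (single force in the system)
  Fl <- solve(pair_block(NULL, p), p$v_lead)
  vf <- pair_block(P2[2, ] - P2[1, ], p, warn = FALSE) %*% Fl
  expect_equal(st2$velocities[2, ], as.numeric(vf), tolerance = 1e-10)
  # energy bookkeeping: sum of per-agent powers equals the printed total
  st3 <- locomotion_env_step(rbind(c(0, 0), c(-2.5, 0.5), c(-2.5, -2)),
                             rbind(c(0.4, 0.1), c(-0.1, 0.2)), p, dt = 0.1)
  Fa <- rbind(st3$leader_force, c(0.4, 0.1), c(-0.1, 0.2))
  expect_equal(sum(st3$powers), sum(Fa^2) / p$drag, tolerance = 1e-12)
})
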