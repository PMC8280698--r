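test_that("shxf auxiliary spawning follows the energy-partition rule", {
  # below threshold: nothing spawns, so the decoherence term stays off
  m <- flat_model(0, 0.01)
  st <- trajectory_state(R = 0, V = sqrt(2 * 0.01 / 2000), active = 1,
                         C = c(sqrt(1 - 1e-6) + 0i, sqrt(1e-6) + 0i))
  st$adiab <- adiabatic_point(m, 0)
  aux <- shxf_update_aux(st, NULL, m, dt = 0.4, spawn_threshold = 0.01)
  expect_false(aux$alive)
  xi <- shxf_xi(st$C, Q = 0, f = aux$f, masses = m$masses)
  expect_identical(xi, as.complex(c(0, 0)))

  # flat lower aux surface, active 0.01 Ha above, parent KE = 0.01:
  # KE_aux = 0.02, aux speed = parent speed * sqrt(2)
  st2 <- trajectory_state(R = 0, V = sqrt(2 * 0.01 / 2000), active = 2,
                          C = c(sqrt(0.2) + 0i, sqrt(0.8) + 0i))
  st2$adiab <- adiabatic_point(m, 0)
  aux2 <- shxf_update_aux(st2, NULL, m, dt = 0.4)
  expect_true(aux2$alive)
  expect_equal(as.numeric(aux2$V / st2$V), sqrt(2), tolerance = 1e-12)

  # classically forbidden spawn freezes the aux and counts it
  m3 <- flat_model(0, 0.5)
  st3 <- trajectory_state(R = 0, V = sqrt(2 * 0.01 / 2000), active = 1,
                          C = c(sqrt(0.8) + 0i, sqrt(0.2) + 0i))
  st3$adiab <- adiabatic_point(m3, 0)
  aux3 <- shxf_update_aux(st3, NULL, m3, dt = 0.4)
  expect_true(aux3$alive); expect_true(aux3$frozen)
  expect_identical(aux3$n_frozen, 1L)
  expect_identical(as.numeric(aux3$V), 0)
})

test_that("shxf auxiliary coincides with the parent on parallel surfaces", {
  # degenerate parallel flat surfaces: identical dynamics, aux tracks parent
  m <- flat_model(0.1, 0.1)
  st <- trajectory_state(R = 1, V = 0.004, active = 1,
                         C = c(sqrt(0.7) + 0i, sqrt(0.3) + 0i))
  st$adiab <- structure(list(energies = c(0.1, 0.1),
                             gradients = matrix(0, 2, 1),
                             nacv = array(0, dim = c(2, 2, 1)),
                             eigvecs = diag(2)), class = "adiabatic_point")
  aux <- shxf_update_aux(st, NULL, m, dt = 0.5)
  expect_equal(as.numeric(aux$V), 0.004, tolerance = 1e-14)
  for (i in 1:20) {
    st$R <- st$R + st$V * 0.5
    aux <- shxf_update_aux(st, aux, m, dt = 0.5)
    expect_equal(as.numeric(aux$R), as.numeric(st$R), tolerance = 1e-12)
  }
  expect_true(all(aux$f == 0))
})

test_that("quantum momentum: weighted-center formula and sigma scaling", {
  # coincident auxiliary positions give zero quantum momentum
  Q <- quantum_momentum(R = 1.2, aux_positions = rbind(1.2, 1.2),
                        populations = c(0.4, 0.6), sigma = 0.3)
  expect_identical(as.numeric(Q), 0)

  # equal populations displaced by Delta: Q = Delta / (4 sigma^2)
  Dlt <- 0.8
  Q <- quantum_momentum(R = 0, aux_positions = rbind(0, -Dlt),
                        populations = c(0.5, 0.5), sigma = 0.25)
  expect_equal(as.numeric(Q), Dlt / (4 * 0.25^2), tolerance = 1e-14)

  # 1/sigma^2 scaling: shrinking sigma by sqrt(2) doubles Q
  Q2 <- quantum_momentum(R = 0, aux_positions = rbind(0, -Dlt),
                         populations = c(0.5, 0.5), sigma = 0.25 / sqrt(2))
  expect_equal(as.numeric(Q2), 2 * as.numeric(Q), tolerance = 1e-14)

  expect_error(quantum_momentum(0, rbind(0, 1), c(0.5, 0.5), sigma = 0),
               "positive")
})

test_that("shxf_xi: zero limits and exact norm neutrality", {
  masses <- 2000
  # unit population: the correction vanishes
  xi <- shxf_xi(c(1 + 0i, 0i), Q = 0.5, f = rbind(1, -2), masses)
  expect_equal(xi, as.complex(c(0, 0)), tolerance = 1e-15)

  # identical accumulated forces: force-difference structure gives zero
  C <- random_unit_C()
  xi <- shxf_xi(C, Q = 0.5, f = rbind(1.7, 1.7), masses)
  expect_equal(xi, as.complex(c(0, 0)), tolerance = 1e-15)

  # the term redistributes population without creating it:
  # d/dt sum |C|^2 from xi alone vanishes identically
  set.seed(5)
  for (rep in 1:20) {
    C <- random_unit_C()
    f <- rbind(stats::rnorm(1, 0, 3), stats::rnorm(1, 0, 3))
    xi <- shxf_xi(C, Q = stats::rnorm(1), f = f, masses)
    ddt_norm <- sum(2 * Re(Conj(C) * xi))
    expect_lt(abs(ddt_norm), 1e-14)
  }

  # population flows toward the state whose accumulated force aligns with Q
  C <- c(sqrt(0.6) + 0i, sqrt(0.4) + 0i)
  xi <- shxf_xi(C, Q = 1, f = rbind(2, -1), masses)  # state 1 aligned with Q
  expect_gt(2 * Re(Conj(C[1]) * xi[1]), 0)
  expect_lt(2 * Re(Conj(C[2]) * xi[2]), 0)
})

test_that("edc_apply: closed-form tau, alpha = 0 limit, renormalization", {
  # tau = (1/|deps|)(1 + alpha/T) = 20 a.u. for deps = T = alpha = 0.1
  C <- c(sqrt(0.5) + 0i, sqrt(0.5) + 0i)
  out <- edc_apply(C, active = 1, eps = c(0, 0.1), T = 0.1, alpha = 0.1, dt = 1)
  expect_equal(Mod(out[2]) / Mod(C[2]), exp(-1 / 20), tolerance = 1e-12)
  expect_lt(abs(sum(Mod(out)^2) - 1), 1e-14)

  # alpha = 0: tau = 1/|deps| independent of the kinetic energy
  o1 <- edc_apply(C, 1, c(0, 0.05), T = 0.02, alpha = 0, dt = 2)
  o2 <- edc_apply(C, 1, c(0, 0.05), T = 0.9, alpha = 0, dt = 2)
  expect_equal(o1, o2, tolerance = 1e-14)
  expect_equal(Mod(o1[2]) / Mod(C[2]), exp(-2 * 0.05), tolerance = 1e-12)

  # zero gap: explicit no-damping branch, no division by zero
  o3 <- edc_apply(C, 1, c(0.2, 0.2), T = 0.1, alpha = 0.1, dt = 5)
  expect_equal(o3, C, tolerance = 1e-14)

  # damping acts on coefficients: phases of nonactive states are preserved
  Cph <- c(sqrt(0.5) + 0i, sqrt(0.5) * exp(0.77i))
  o4 <- edc_apply(Cph, 1, c(0, 0.1), T = 0.1, alpha = 0.1, dt = 1)
  expect_equal(Arg(o4[2]), 0.77, tolerance = 1e-12)

  expect_error(edc_apply(C, 1, c(0, 0.1), T = 0, alpha = 0.1, dt = 1), "positive")
})

test_that("afssh moments: driven kinematics and linearity", {
  mom0 <- list(dR = matrix(0, 2, 1), dP = matrix(0, 2, 1), dF = matrix(0, 2, 1))
  masses <- 2000; dt <- 0.5

  # parallel surfaces: no driving force, moments stay exactly zero
  ad_par <- fake_adiab(c(0, 0.01), c(0.002, 0.002))
  mom <- mom0
  for (i in 1:50) mom <- afssh_step_moments(mom, ad_par, active = 1, masses, dt)
  expect_true(all(mom$dR == 0) && all(mom$dP == 0))

  # constant force difference: dR follows dF t^2 / (2M) exactly
  # (velocity-Verlet is exact for constant acceleration)
  dF <- -(0.004 - 0.001)
  ad_c <- fake_adiab(c(0, 0.01), c(0.001, 0.004))
  mom <- list(dR = matrix(0, 2, 1), dP = matrix(0, 2, 1),
              dF = matrix(c(0, dF), 2, 1))
  nsteps <- 40
  for (i in 1:nsteps) mom <- afssh_step_moments(mom, ad_c, 1, masses, dt)
  tt <- nsteps * dt
  expect_equal(mom$dR[2, 1], dF * tt^2 / (2 * masses), tolerance = 1e-12)
  expect_equal(mom$dP[2, 1], dF * tt, tolerance = 1e-12)

  # sign flip of the force difference flips the moments
  ad_f <- fake_adiab(c(0, 0.01), c(0.004, 0.001))
  momf <- list(dR = matrix(0, 2, 1), dP = matrix(0, 2, 1),
               dF = matrix(c(0, -dF), 2, 1))
  for (i in 1:nsteps) momf <- afssh_step_moments(momf, ad_f, 1, masses, dt)
  expect_equal(momf$dR[2, 1], -mom$dR[2, 1], tolerance = 1e-14)
})

test_that("afssh rates: zero-moment and perpendicular limits, monotone growth", {
  # dR = 0: no positive growth term, no collapse possible
  mom <- list(dR = matrix(0, 2, 1), dP = matrix(0, 2, 1), dF = matrix(0, 2, 1))
  ad <- fake_adiab(c(0, 0.02), c(0.001, 0.004), nacv01 = 0.3)
  r <- afssh_rate(mom, ad, active = 1)
  expect_identical(r$collapse[2], 0)
  expect_identical(r$reset[2], 0)

  # growth term is a dot product: orthogonal dF and dR kill it (2-DOF)
  ad2 <- structure(list(energies = c(0, 0.02),
                        gradients = matrix(c(0, 0.003, 0, 0), 2, 2),
                        nacv = array(0, dim = c(2, 2, 2)),
                        eigvecs = diag(2)), class = "adiabatic_point")
  mom2 <- list(dR = matrix(c(0, 0, 0, 0.4), 2, 2), dP = matrix(0, 2, 2),
               dF = matrix(0, 2, 2))
  r2 <- afssh_rate(mom2, ad2, active = 1)   # dF along DOF 1, dR along DOF 2
  expect_equal(r2$collapse[2], 0, tolerance = 1e-15)

  # increasing |dR| along a fixed dF direction increases the growth term
  ad3 <- fake_adiab(c(0, 0.02), c(0.004, 0.001), nacv01 = 0)
  rates <- vapply(c(0.1, 0.2, 0.4, 0.8), function(s) {
    m <- list(dR = matrix(c(0, s), 2, 1), dP = matrix(0, 2, 1),
              dF = matrix(0, 2, 1))
    afssh_rate(m, ad3, 1)$collapse[2]
  }, 0)
  expect_true(all(diff(rates) > 0))

  # reset rate is the negated growth term
  m <- list(dR = matrix(c(0, -0.3), 2, 1), dP = matrix(0, 2, 1),
            dF = matrix(0, 2, 1))
  r3 <- afssh_rate(m, ad3, 1)
  expect_lt(r3$collapse[2], 0)
  expect_equal(r3$reset[2], -r3$collapse[2] - 2 * abs((0.02) * 0 * -0.3),
               tolerance = 1e-15)
})

test_that("afssh collapse: threshold rule and renormalization", {
  C <- c(sqrt(0.7) + 0i, sqrt(0.3) + 0i)
  rates <- list(collapse = c(0, 0.5), reset = c(0, 0))

  # dt_c/tau = 0.5: r = 0.4 collapses, r = 0.6 does not
  out <- afssh_collapse(C, active = 1, rates, dt_c = 1,
                        r_collapse = c(0, 0.4), r_reset = c(0, 1))
  expect_true(out$collapsed[2])
  expect_identical(out$C[2], 0 + 0i)
  expect_equal(Mod(out$C[1])^2, 1, tolerance = 1e-14)

  out2 <- afssh_collapse(C, 1, rates, 1, r_collapse = c(0, 0.6), r_reset = c(0, 1))
  expect_false(out2$collapsed[2])
  expect_identical(out2$C, C)

  # nonpositive rate never collapses, whatever the draw
  rates0 <- list(collapse = c(0, -2), reset = c(0, 0.4))
  out3 <- afssh_collapse(C, 1, rates0, 1, r_collapse = c(0, 0), r_reset = c(0, 0.2))
  expect_false(out3$collapsed[2])
  expect_true(out3$reset[2])   # reset event fires without touching C
  expect_identical(out3$C, C)
})

test_that("decoherence schemes produce distinct per-trajectory traces on one seed", {
  # recrossing dynamics engages all three corrections on a single trajectory
  m <- get_model("extended_coupling")
  st <- trajectory_state(R = -13, V = 10 / 2000, active = 1)
  traces <- lapply(c("none", "shxf", "edc", "afssh"), function(sch) {
    cfg <- sh_config(dt = 0.4, n_steps = 12000, decoherence = sch, sigma = 0.35,
                     seed = 31, record_every = 20)
    run_trajectory(m, st, cfg, traj_id = 2)$record$pop1
  })
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(identical(traces[[i]], traces[[j]]))
})

test_that("engine norm is preserved through every scheme's plugin step", {
  m <- get_model("single_crossing")
  ics <- tully1_ics(12)
  for (sch in c("none", "shxf", "edc", "afssh")) {
    cfg <- sh_config(dt = 0.4, n_steps = 4000, decoherence = sch, sigma = 0.35,
                     seed = 9)
    ens <- run_ensemble(m, ics, cfg, active = 1)
    expect_lt(max(ens$drift$norm), 1e-10, label = sch)
  }
})
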