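test_that("nuclear_step: free particle, harmonic closed form, reversibility", {
  # flat surface: uniform motion
  m <- flat_model(0.1, 0.4)
  st <- trajectory_state(R = -1, V = 0.01, active = 1)
  st$adiab <- adiabatic_point(m, st$R)
  s2 <- nuclear_step(st, m, 2.5)
  expect_equal(s2$R, -1 + 0.01 * 2.5, tolerance = 1e-14)
  expect_equal(s2$V, 0.01, tolerance = 1e-14)

  # harmonic surface: tiny energy drift, trajectory matches the closed form
  k <- 0.002; mass <- 2000; w <- sqrt(k / mass)
  hm <- harmonic_model(k, mass)
  st <- trajectory_state(R = 0.7, V = 0, active = 1)
  st$adiab <- adiabatic_point(hm, st$R)
  E0 <- 0.5 * mass * st$V^2 + st$adiab$energies[1]
  for (i in 1:1000) st <- nuclear_step(st, hm, 0.1)
  E1 <- 0.5 * mass * st$V^2 + st$adiab$energies[1]
  expect_lt(abs(E1 - E0), 1e-8)
  expect_equal(st$R, 0.7 * cos(w * 100), tolerance = 1e-6)

  # symplectic time reversal on an anharmonic surface
  m1 <- get_model("single_crossing")
  st <- trajectory_state(R = -4, V = 0.0075, active = 1)
  st$adiab <- adiabatic_point(m1, st$R)
  for (i in 1:400) st <- nuclear_step(st, m1, 0.4)
  st$V <- -st$V
  for (i in 1:400) st <- nuclear_step(st, m1, 0.4)
  expect_equal(st$R, -4, tolerance = 1e-9)
  expect_equal(-st$V, 0.0075, tolerance = 1e-9)
})

test_that("electronic_step: phase evolution, Rabi form, norm conservation", {
  zero_vd <- matrix(0, 2, 2)
  # decoupled states: pure phase factors
  C0 <- c(sqrt(0.7) + 0i, sqrt(0.3) * 1i)
  eps <- c(-0.01, 0.02)
  C <- electronic_step(C0, eps, eps, zero_vd, zero_vd, dt = 37, n_substeps = 200)
  expect_equal(C, C0 * exp(-1i * eps * 37), tolerance = 1e-10)

  # degenerate energies with constant coupling: Rabi cos^2/sin^2 populations
  kap <- 0.01
  vd <- matrix(c(0, -kap, kap, 0), 2, 2)
  C <- electronic_step(c(1 + 0i, 0i), c(0, 0), c(0, 0), vd, vd,
                       dt = 50, n_substeps = 500)
  expect_equal(Mod(C[1])^2, cos(kap * 50)^2, tolerance = 1e-8)
  expect_equal(Mod(C[2])^2, sin(kap * 50)^2, tolerance = 1e-8)

  # unitarity with no decoherence term over 1e4 substeps
  vd2 <- matrix(c(0, -0.004, 0.004, 0), 2, 2)
  C <- electronic_step(random_unit_C(), c(-0.01, 0.01), c(-0.008, 0.012),
                       vd, vd2, dt = 100, n_substeps = 10000)
  expect_lt(abs(sum(Mod(C)^2) - 1), 1e-10)
})

test_that("hop_probability: no coherence, clamping, dt linearity, low-population guard", {
  st <- trajectory_state(R = 0, V = 0.01, active = 1,
                         C = c(sqrt(0.6) + 0i, sqrt(0.4) + 0i))
  st$adiab <- fake_adiab(c(-0.005, 0.005), c(0, 0), nacv01 = 1.2)

  # positive coherence times positive v.d -> finite probability, linear in dt
  z1 <- hop_probability(st, 0.2)
  z2 <- hop_probability(st, 0.1)
  expect_gt(z1[2], 0)
  expect_equal(z1[2], 2 * z2[2], tolerance = 1e-12)

  # raw negative expression is clamped to zero
  st$C <- c(sqrt(0.6) + 0i, -sqrt(0.4) + 0i)
  expect_identical(hop_probability(st, 0.2), c(0, 0))

  # no coherence, no hops
  st$C <- c(1 + 0i, 0i)
  expect_identical(hop_probability(st, 0.2), c(0, 0))

  # active population underflow falls back to zero probability with a warning
  st$C <- c(1e-8 + 0i, sqrt(1 - 1e-16) + 0i)
  expect_warning(z <- hop_probability(st, 0.2), "below 1e-12")
  expect_identical(z, c(0, 0))
})

test_that("attempt_hop selects by cumulative windows over ascending targets", {
  expect_identical(attempt_hop(c(0.3), 0.2), 1L)
  expect_identical(attempt_hop(c(0.3), 0.9), NA_integer_)
  expect_identical(attempt_hop(c(0.2, 0.3), 0.4), 2L)   # windows (0,0.2], (0.2,0.5]
  expect_identical(attempt_hop(c(0.2, 0.3), 0.15), 1L)
  expect_identical(attempt_hop(c(0.2, 0.3), 0.6), NA_integer_)
  expect_error(attempt_hop(c(0.7, 0.6), 0.5))           # sum > 1 violates the contract
})

test_that("isotropic rescaling: closed-form kappa and frustration", {
  # KE = 0.02, deps = -0.01 (downhill): kappa = sqrt(1 - deps/KE) = sqrt(1.5)
  v0 <- sqrt(2 * 0.02 / 2000)
  r <- rescale_isotropic(V = v0, masses = 2000, deps = -0.01)
  expect_true(r$accepted)
  expect_equal(r$V / v0, sqrt(1.5), tolerance = 1e-12)

  # deps = 0: identity
  r <- rescale_isotropic(0.01, 2000, 0)
  expect_true(r$accepted); expect_identical(r$V, 0.01)

  # potential-energy gain exceeding KE: frustrated, V untouched
  v <- sqrt(2 * 0.005 / 2000)
  r <- rescale_isotropic(v, 2000, 0.01)
  expect_false(r$accepted); expect_identical(r$V, v)

  # zero KE with a downhill hop: direction undefined, rejected with warning
  expect_warning(r <- rescale_isotropic(0, 2000, -0.01), "undefined")
  expect_false(r$accepted)
})

test_that("NACV rescaling: minimal-|gamma| root, exact energy conservation", {
  # deps = 0 and V perpendicular to d: gamma = 0, velocities unchanged
  r <- rescale_nacv(V = c(0.01, 0), masses = c(2000, 2000), d = c(0, 1), deps = 0)
  expect_true(r$accepted)
  expect_equal(r$V, c(0.01, 0), tolerance = 1e-15)

  # randomized 3-DOF cases: quadratic residual at the chosen root, energy exact
  set.seed(8)
  for (rep in 1:10) {
    masses <- stats::runif(3, 1500, 2500)
    V <- stats::rnorm(3, 0, 0.01); d <- stats::rnorm(3)
    deps <- stats::runif(1, -0.01, 0.5 * sum(masses * V^2))
    r <- rescale_nacv(V, masses, d, deps)
    if (!r$accepted) next
    gam <- sum(masses * (r$V - V) * d) / sum(d^2)  # recover gamma from the update
    a <- sum(d^2 / (2 * masses)); b <- sum(V * d)
    expect_lt(abs(a * gam^2 + b * gam + deps), 1e-12)
    E_pre <- 0.5 * sum(masses * V^2)
    E_post <- 0.5 * sum(masses * r$V^2) + deps
    expect_lt(abs(E_post - E_pre), 1e-12)
    # minimal-|gamma| root selection
    disc <- sqrt(b^2 - 4 * a * deps)
    gmin <- min(abs((-b + disc) / (2 * a)), abs((-b - disc) / (2 * a)))
    expect_equal(abs(gam), gmin, tolerance = 1e-9)
  }

  # zero NACV is a distinct frustration from energy forbiddenness
  r <- rescale_nacv(0.01, 2000, 0, 0.001)
  expect_false(r$accepted); expect_identical(r$reason, "zero_nacv")
  r <- rescale_nacv(1e-5, 2000, 1, 0.01)
  expect_false(r$accepted); expect_identical(r$reason, "energy")
})

test_that("rescale_dispatch: NACV-first with isotropic fallback", {
  masses <- c(2000, 2000)
  # feasible NACV: nacv+iso result identical to nacv
  V <- c(0.01, 0.005); d <- c(1, 0.2); deps <- 1e-4
  rn <- rescale_dispatch("nacv", V, masses, d, deps)
  rb <- rescale_dispatch("nacv+iso", V, masses, d, deps)
  expect_true(rn$accepted && rb$accepted)
  expect_identical(rb$V, rn$V)
  expect_identical(rb$branch, "nacv")

  # tiny velocity along d but large total KE: frustrated under nacv,
  # accepted via the isotropic fallback under nacv+iso
  V <- c(0.02, 1e-6); d <- c(0, 1); deps <- 5e-4
  rn <- rescale_dispatch("nacv", V, masses, d, deps)
  rb <- rescale_dispatch("nacv+iso", V, masses, d, deps)
  expect_false(rn$accepted)
  expect_true(rb$accepted)
  expect_identical(rb$branch, "iso_fallback")

  # both infeasible: frustrated under every mode
  V <- c(1e-6, 1e-6); deps <- 0.01
  for (mode in c("iso", "nacv", "nacv+iso"))
    expect_false(rescale_dispatch(mode, V, masses, d, deps)$accepted)
})

test_that("run_trajectory: zero coupling is inert; records audit energy", {
  m0 <- get_model("extended_coupling", params = list(B = 0))  # no coupling anywhere
  st <- trajectory_state(R = -5, V = 0.005, active = 1)
  cfg <- sh_config(dt = 0.4, n_steps = 500, seed = 3)
  tr <- run_trajectory(m0, st, cfg)
  expect_true(all(tr$record$active == 1))
  expect_true(all(abs(tr$record$pop1 - 1) < 1e-12))
  expect_identical(nrow(tr$hops), 0L)

  # energy audit across rescaling modes on the single-crossing model
  for (mode in c("iso", "nacv", "nacv+iso")) {
    cfg <- sh_config(dt = 0.4, n_steps = 4000, rescale = mode, seed = 11)
    ics <- tully1_ics(10)
    for (i in 1:10) {
      sti <- trajectory_state(R = ics$R[i, 1], V = ics$P[i, 1] / 2000, active = 1)
      tr <- run_trajectory(m = get_model("single_crossing"), sti, cfg, traj_id = i)
      expect_lt(tr$diagnostics$max_seg_drift, 1e-6)
      expect_lt(tr$diagnostics$max_hop_jump, 1e-10)
      expect_lt(tr$diagnostics$max_norm_dev, 1e-8)
    }
  }
})

test_that("identical seeds replay bitwise-identical hop logs", {
  m <- get_model("single_crossing")
  st <- trajectory_state(R = -6, V = 0.0075, active = 1)
  cfg <- sh_config(dt = 0.4, n_steps = 3000, seed = 21)
  t1 <- run_trajectory(m, st, cfg, traj_id = 4)
  t2 <- run_trajectory(m, st, cfg, traj_id = 4)
  expect_identical(t1$hops, t2$hops)
  expect_identical(t1$record, t2$record)
  # a different trajectory id gives an independent draw stream
  d4 <- run_trajectory(m, st, cfg, traj_id = 4, collect_full = TRUE)$draws
  d5 <- run_trajectory(m, st, cfg, traj_id = 5, collect_full = TRUE)$draws
  expect_false(identical(d4, d5))
})

test_that("compiled engine reproduces the step-level operations exactly", {
  m <- get_model("single_crossing")
  dt <- 0.4; nst <- 60
  cfg <- sh_config(dt = dt, n_steps = nst, seed = 5, record_every = 1)
  st0 <- trajectory_state(R = -2.5, V = 15 / 2000, active = 1)
  tr <- run_trajectory(m, st0, cfg, traj_id = 1, collect_full = TRUE)
  expect_identical(sum(tr$hops$accepted), 0L)  # hop-free segment by construction

  st <- st0; st$adiab <- adiabatic_point(m, st$R)
  C <- st$C
  vdmat <- function(v, ap) {
    d <- ap$nacv[1, 2, 1]
    matrix(c(0, -v * d, v * d, 0), 2, 2)
  }
  for (i in 1:nst) {
    ad_old <- st$adiab; v_old <- st$V
    st <- nuclear_step(st, m, dt)
    C <- electronic_step(C, ad_old$energies, st$adiab$energies,
                         vdmat(v_old, ad_old), vdmat(st$V, st$adiab), dt, 20)
  }
  expect_equal(st$R, tr$record$R[nst + 1], tolerance = 1e-12)
  expect_equal(st$V, tr$record$V[nst + 1], tolerance = 1e-12)
  Ceng <- complex(real = c(tr$C_record$re0[nst + 1], tr$C_record$re1[nst + 1]),
                  imaginary = c(tr$C_record$im0[nst + 1], tr$C_record$im1[nst + 1]))
  expect_equal(C, Ceng, tolerance = 1e-10)

  # per-step hopping probabilities in the record match Eq-3 recomputation
  for (j in c(20, 40, 60)) {
    stj <- trajectory_state(R = tr$record$R[j + 1], V = tr$record$V[j + 1],
                            active = tr$record$active[j + 1],
                            C = complex(real = c(tr$C_record$re0[j + 1], tr$C_record$re1[j + 1]),
                                        imaginary = c(tr$C_record$im0[j + 1], tr$C_record$im1[j + 1])))
    stj$adiab <- adiabatic_point(m, stj$R)
    expect_equal(sum(hop_probability(stj, dt)), tr$zeta_record[j + 1],
                 tolerance = 1e-9)
  }
})

test_that("fewest-switches stays minimal on a single-passage model", {
  m <- get_model("single_crossing")
  ics <- tully1_ics(40)
  cfg <- sh_config(dt = 0.4, n_steps = 4500, seed = 13)
  ens <- run_ensemble(m, ics, cfg, active = 1)
  expect_lte(ens$hops$mean_accepted_per_traj, 2)
})
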