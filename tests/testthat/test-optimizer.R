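test_that("restraint energy/gradient follow the harmonic closed form", {
  g <- system_geometry(c("C", "C"), coords_ang = rbind(c(0, 0, 0),
                                                       c(1.6, 0, 0)))
  ## at the target: zero energy, zero gradient
  r0 <- restraint(1L, 2L, target = 1.6)
  res0 <- restraint_energy_gradient(g, r0)
  expect_equal(res0$energy, 0, tolerance = 1e-14)
  expect_equal(max(abs(res0$gradient)), 0, tolerance = 1e-14)
  ## k = 500 kcal/mol/A^2, displacement 0.1 A -> 2.5 kcal/mol
  r1 <- restraint(1L, 2L, target = 1.5, force_constant = 500)
  res1 <- restraint_energy_gradient(g, r1)
  expect_equal(res1$energy * KCAL_PER_HARTREE, 2.5, tolerance = 1e-10)
  ## restraints on disjoint pairs are additive
  g4 <- system_geometry(rep("C", 4),
                        coords_ang = rbind(c(0, 0, 0), c(1.6, 0, 0),
                                           c(0, 5, 0), c(1.4, 5, 0)))
  r2 <- restraint(3L, 4L, target = 1.5, force_constant = 500)
  both <- restraint_energy_gradient(g4, rbind(r1, r2))
  e_sep <- restraint_energy_gradient(g4, r1)$energy +
    restraint_energy_gradient(g4, r2)$energy
  expect_equal(both$energy, e_sep, tolerance = 1e-15)
  ## gradient matches finite differences
  num <- numerical_gradient(function(gg)
    restraint_energy_gradient(gg, rbind(r1, r2))$energy, g4, step = 1e-5)
  expect_lt(max(abs(num - both$gradient)), 1e-9)
  expect_error(restraint(1L, 1L, 1.0), class = "fragopt_argument_error")
  expect_error(restraint(1L, 2L, -1), class = "fragopt_argument_error")
})

test_that("optimization from a minimum returns immediately and unchanged", {
  w <- make_water_chain(1)
  part <- all_active_partition(w$fragments)
  ## the reference water is the minimum of the RHF-level mock surface
  pt <- optimize_active(w$geometry, w$fragments, part, NULL,
                        run_config(hybrid_enabled = FALSE))
  expect_true(pt$converged)
  expect_lte(pt$n_steps, 1L)
  expect_lt(max(abs(pt$geometry$coords - w$geometry$coords)), 1e-8)
})

test_that("a restrained harmonic bond converges to the weighted mean length", {
  ## single C-C fragment: mock bond k_b (Hartree/Bohr^2) at L, restraint k_r
  ## toward T; stationary point at (k_b L + k_r T) / (k_b + k_r)
  g <- system_geometry(c("C", "C"), coords_ang = rbind(c(0, 0, 0),
                                                       c(1.5, 0, 0)))
  fs <- build_fragments(g, list(1:2))
  part <- all_active_partition(fs)
  target_ang <- 1.8
  cfg <- run_config(gradient_tolerance = 1e-8, hybrid_enabled = FALSE)
  pt <- optimize_active(g, fs, part, restraint(1L, 2L, target_ang), cfg)
  expect_true(pt$converged)
  r_fin <- ANG_PER_BOHR * sqrt(sum((pt$geometry$coords[1, ] -
                                    pt$geometry$coords[2, ])^2))
  k_b <- 0.25                                  # Hartree/Bohr^2
  k_r <- (500 / KCAL_PER_HARTREE) * ANG_PER_BOHR^2  # -> Hartree/Bohr^2
  L <- 1.5; T <- target_ang
  expect_equal(r_fin, (k_b * L + k_r * T) / (k_b + k_r), tolerance = 1e-6)
  ## residual displacement from the target is bounded by |grad_unres| / k_r
  dV <- k_b * abs(r_fin - L) / ANG_PER_BOHR       # Hartree/Bohr
  expect_lte(abs(r_fin - T) / ANG_PER_BOHR, dV / k_r + 1e-6)
})

test_that("frozen-domain atoms are bitwise unchanged by optimization", {
  toy <- make_toy_reaction()
  cfg <- run_config(max_opt_steps = 8L)
  pt <- optimize_active(toy$geometry, toy$fragments, toy$partition,
                        restraint(1L, 2L, 1.6), cfg, NULL, toy$backend)
  frozen_atoms <- 5:7
  expect_identical(pt$geometry$coords[frozen_atoms, ],
                   toy$geometry$coords[frozen_atoms, ])
  ## accepted-step energies are non-increasing for the line-search minimizer
  expect_true(all(diff(pt$energy_trace) <= 0))
})

test_that("optimization is deterministic and flags non-convergence", {
  toy <- make_toy_reaction()
  cfg <- run_config(max_opt_steps = 3L)
  p1 <- optimize_active(toy$geometry, toy$fragments, toy$partition,
                        restraint(1L, 2L, 2.0), cfg, NULL, toy$backend)
  p2 <- optimize_active(toy$geometry, toy$fragments, toy$partition,
                        restraint(1L, 2L, 2.0), cfg, NULL, toy$backend)
  expect_identical(p1$geometry$coords, p2$geometry$coords)
  expect_identical(p1$energy_trace, p2$energy_trace)
  expect_false(p1$converged)   # 3 steps cannot converge this displacement
})

test_that("a single-target scan equals one restrained optimization", {
  toy <- make_toy_reaction()
  cfg <- run_config()
  tg <- toy_scan_targets(1, from = -1.2, to = -1.2)
  path <- scan_reaction_path(toy$geometry, toy$fragments, toy$partition,
                             toy$breaking_pair, toy$forming_pair, tg, cfg,
                             NULL, toy$backend)
  expect_length(path$points, 1L)
  pt <- optimize_active(toy$geometry, toy$fragments, toy$partition,
                        rbind(restraint(1L, 2L, tg$r1_target[1]),
                              restraint(3L, 4L, tg$r2_target[1])),
                        cfg, NULL, toy$backend,
                        coordinate_pairs = list(breaking = c(1L, 2L),
                                                forming = c(3L, 4L)))
  expect_equal(path$points[[1]]$energy_report$total, pt$energy_report$total,
               tolerance = 1e-12)
})

test_that("the adiabatic scan recovers the analytic double-well profile", {
  toy <- make_toy_reaction()
  cfg <- run_config()
  path <- scan_reaction_path(toy$geometry, toy$fragments, toy$partition,
                             toy$breaking_pair, toy$forming_pair,
                             toy_scan_targets(21), cfg, NULL, toy$backend)
  tab <- tidy(path)
  expect_true(all(tab$converged))
  ## sign convention: product well positive, reactant negative
  expect_lt(tab$reaction_coordinate[1], 0)
  expect_gt(tab$reaction_coordinate[nrow(tab)], 0)
  b <- barrier_and_reaction_energy(path)
  ## documented restraint-stiffness bias bound: the effective restraint on
  ## R = r1 - r2 is k_r/2; with k_well the largest curvature of the profile
  ## over the scanned range, the recovered barrier deviates by at most
  ## barrier * k_well / (k_well + k_r/2)   (conservative; discretization of
  ## the 21-point grid is far below it)
  Rgrid <- seq(-1.2, 1.2, length.out = 2001)
  V <- toy$analytic$profile(Rgrid)
  k_well <- max(abs(diff(V, differences = 2)) / diff(Rgrid)[1]^2)
  k_eff <- 500 / 2
  bias_bound <- toy$analytic$barrier_kcal * k_well / (k_well + k_eff)
  expect_lt(abs(b$barrier_kcal - toy$analytic$barrier_kcal), bias_bound)
  expect_lt(abs(b$reaction_energy_kcal - toy$analytic$reaction_energy_kcal),
            bias_bound)
  ## TS estimate sits near the analytic barrier top
  expect_lt(abs(b$ts_coordinate - toy$analytic$ts), 0.15)
})

test_that("forward and backward scans agree on the convex toy system", {
  toy <- make_toy_reaction(kind = "convex")
  cfg <- run_config(gradient_tolerance = 1e-6)
  tg_fwd <- toy_scan_targets(7, from = -0.9, to = 0.9)
  tg_bwd <- tg_fwd[rev(seq_len(nrow(tg_fwd))), ]
  fwd <- scan_reaction_path(toy$geometry, toy$fragments, toy$partition,
                            toy$breaking_pair, toy$forming_pair, tg_fwd,
                            cfg, NULL, toy$backend)
  bwd <- scan_reaction_path(toy$geometry, toy$fragments, toy$partition,
                            toy$breaking_pair, toy$forming_pair, tg_bwd,
                            cfg, NULL, toy$backend)
  e_fwd <- vapply(fwd$points, function(p) p$energy_report$total, 1.0)
  e_bwd <- rev(vapply(bwd$points, function(p) p$energy_report$total, 1.0))
  expect_lt(max(abs(e_fwd - e_bwd)), 1e-6)
})

test_that("barrier arithmetic is exact on hand-written paths", {
  ## monotonically decreasing path: zero barrier, negative reaction energy
  mono <- data.frame(energy_kcal = c(0, -2, -5),
                     reaction_coordinate = c(-1, 0, 1))
  b1 <- barrier_and_reaction_energy(mono)
  expect_identical(b1$barrier_kcal, 0)
  expect_identical(b1$reaction_energy_kcal, -5)
  ## (0, 5, 3) kcal/mol -> barrier 5, reaction energy +3
  b2 <- barrier_and_reaction_energy(
    data.frame(energy_kcal = c(0, 5, 3), reaction_coordinate = c(-1, 0, 1)))
  expect_identical(b2$barrier_kcal, 5)
  expect_identical(b2$reaction_energy_kcal, 3)
  expect_identical(b2$ts_coordinate, 0)
  ## Hartree input converts through the documented constant
  b3 <- barrier_and_reaction_energy(
    data.frame(energy_hartree = c(0, 5 / KCAL_PER_HARTREE)))
  expect_equal(b3$barrier_kcal, 5, tolerance = 1e-12)
  expect_error(barrier_and_reaction_energy(
    data.frame(energy_kcal = 1)), class = "fragopt_argument_error")
})
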