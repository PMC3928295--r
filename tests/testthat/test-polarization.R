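## Helpers to build bare site sets without going through backend records.
bare_sites <- function(coords, q, alpha, frag) {
  structure(list(coords = coords, q = q, alpha = alpha, frag = frag,
                 atom = seq_len(nrow(coords))), class = "pol_sites")
}

test_that("static field follows Coulomb's law and cancels by symmetry", {
  ## one unit charge at distance d on the x axis
  s <- bare_sites(rbind(c(0, 0, 0), c(4, 0, 0)), q = c(0, 1),
                  alpha = c(1, 0), frag = c(1L, 2L))
  f <- static_field(s)
  expect_equal(f[1, ], c(-1 / 16, 0, 0), tolerance = 1e-14)
  ## mirror charges: transverse components cancel at the midpoint site
  s2 <- bare_sites(rbind(c(0, 0, 0), c(3, 4, 0), c(3, -4, 0)),
                   q = c(0, 1, 1), alpha = c(1, 0, 0), frag = c(1L, 2L, 2L))
  f2 <- static_field(s2)
  expect_equal(f2[1, 2], 0, tolerance = 1e-14)
  expect_lt(abs(f2[1, 1] - 2 * (-3) / 125), 1e-14)
})

test_that("random site configurations match the brute-force field sum", {
  set.seed(9)
  coords <- matrix(runif(18, 0, 8), 6, 3)
  q <- round(runif(6, -1, 1), 3)
  frag <- c(1L, 1L, 2L, 2L, 3L, 3L)
  s <- bare_sites(coords, q, alpha = rep(1, 6), frag = frag)
  f <- static_field(s)
  f_oracle <- matrix(0, 6, 3)
  for (i in 1:6) for (j in 1:6) {
    if (frag[j] == frag[i]) next
    d <- coords[i, ] - coords[j, ]
    f_oracle[i, ] <- f_oracle[i, ] + q[j] * d / sum(d^2)^1.5
  }
  expect_equal(f, f_oracle, tolerance = 1e-13)
})

test_that("a single site in a uniform field gives mu = aF, E = -aF^2/2", {
  s <- bare_sites(rbind(c(0, 0, 0)), q = 0, alpha = 2.5, frag = 1L)
  F0 <- matrix(c(0.03, -0.01, 0.02), 1, 3)
  st <- solve_induced_dipoles(s, field = F0)
  expect_equal(st$induced_dipoles, 2.5 * F0, tolerance = 1e-14)
  expect_equal(st$energy, -0.5 * 2.5 * sum(F0^2), tolerance = 1e-15)
})

test_that("zero polarizability means zero energy without iterations", {
  s <- bare_sites(rbind(c(0, 0, 0), c(5, 0, 0)), q = c(1, -1),
                  alpha = c(0, 0), frag = c(1L, 2L))
  st <- solve_induced_dipoles(s)
  expect_identical(st$energy, 0)
  expect_identical(st$iterations, 0L)
})

test_that("two coupled axial sites agree with the dense linear solve", {
  s <- bare_sites(rbind(c(0, 0, 0), c(5, 0, 0)), q = c(0, 0),
                  alpha = c(1, 1), frag = c(1L, 2L))
  F0 <- rbind(c(0.05, 0, 0), c(0.05, 0, 0))
  it <- solve_induced_dipoles(s, field = F0)
  de <- solve_induced_dipoles(s, field = F0, method = "dense")
  expect_lt(abs(it$energy - de$energy), 1e-10)
  ## closed form for two axial sites: mu = alpha(F + 2 mu / r^3)
  mu_exact <- 0.05 / (1 - 2 / 125)
  expect_equal(it$induced_dipoles[1, 1], mu_exact, tolerance = 1e-10)
})

test_that("iterative and dense solvers agree to 1e-10 on 12-site systems", {
  w <- make_water_cluster(4, seed = 13)
  recs <- lapply(w$fragments$id, function(id)
    compute_monomer(w$geometry, w$fragments, id))
  names(recs) <- as.character(w$fragments$id)
  s <- pol_sites(w$geometry, w$fragments, recs)
  it <- solve_induced_dipoles(s)
  de <- solve_induced_dipoles(s, method = "dense")
  expect_lt(abs(it$energy - de$energy), 1e-10)
  expect_lt(abs(it$energy - oracle_pol_energy(s$coords, s$q, s$alpha, s$frag)),
            1e-10)
  expect_lt(it$energy, 0)  # induction lowers the energy
})

test_that("pair polarization is symmetric and vanishes at long range", {
  cfg <- run_config()
  near <- make_water_chain(2, spacing = 3.0)
  recs <- lapply(near$fragments$id, function(id)
    compute_monomer(near$geometry, near$fragments, id))
  names(recs) <- as.character(near$fragments$id)
  eij <- pol_energy_pair(near$geometry, near$fragments, recs, 1L, 2L, cfg)
  eji <- pol_energy_pair(near$geometry, near$fragments, recs, 2L, 1L, cfg)
  expect_equal(as.numeric(eij), as.numeric(eji), tolerance = 1e-14)
  expect_lt(abs(as.numeric(eij) -
                oracle_pol_energy(attr(eij, "sites")$coords,
                                  attr(eij, "sites")$q,
                                  attr(eij, "sites")$alpha,
                                  attr(eij, "sites")$frag)), 1e-10)
  far <- make_water_chain(2, spacing = 100)
  recs_f <- lapply(far$fragments$id, function(id)
    compute_monomer(far$geometry, far$fragments, id))
  names(recs_f) <- as.character(far$fragments$id)
  expect_lt(abs(as.numeric(
    pol_energy_pair(far$geometry, far$fragments, recs_f, 1L, 2L, cfg))),
    1e-12)
})

test_that("polarization is many-body: pair sum differs unless coupling is off", {
  ## three fragments: two lone polarizable neutral sites (1, 2) plus one
  ## charged, non-polarizable source fragment (3).  Each site then feels a
  ## static field from fragment 3 only, so if the dipole-dipole coupling T
  ## were zero the total would equal the sum over pairs exactly.
  coords <- rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3, 0))
  q <- c(0, 0, 0.8); alpha <- c(3, 3, 0); frag <- c(1L, 2L, 3L)
  s_all <- bare_sites(coords, q, alpha, frag)
  e_tot <- solve_induced_dipoles(s_all, method = "dense")$energy
  pair_energy <- function(keep) {
    sp <- bare_sites(coords[keep, , drop = FALSE], q[keep], alpha[keep],
                     frag[keep])
    solve_induced_dipoles(sp, method = "dense")$energy
  }
  pair_sum <- pair_energy(c(1, 3)) + pair_energy(c(2, 3)) +
    pair_energy(c(1, 2))
  expect_gt(abs(e_tot - pair_sum), 1e-8)         # coupling is many-body
  ## with T zeroed, mu_i = alpha_i F_i directly and the pair sum is exact
  f <- static_field(s_all)
  e_uncoupled_tot <- -0.5 * sum(alpha * rowSums(f^2))
  uncoupled_pair <- function(keep) {
    sp <- bare_sites(coords[keep, , drop = FALSE], q[keep], alpha[keep],
                     frag[keep])
    fp <- static_field(sp)
    -0.5 * sum(alpha[keep] * rowSums(fp^2))
  }
  e_uncoupled_pairs <- uncoupled_pair(c(1, 3)) + uncoupled_pair(c(2, 3)) +
    uncoupled_pair(c(1, 2))
  expect_equal(e_uncoupled_tot, e_uncoupled_pairs, tolerance = 1e-14)
})

test_that("induction lowers the energy on seeded random systems", {
  for (seed in c(3, 17, 29)) {
    w <- make_water_cluster(3, seed = seed)
    recs <- lapply(w$fragments$id, function(id)
      compute_monomer(w$geometry, w$fragments, id))
    names(recs) <- as.character(w$fragments$id)
    e <- as.numeric(pol_energy_total(w$geometry, w$fragments, recs,
                                     run_config()))
    expect_lte(e, 0)
  }
})

test_that("far-pair electrostatics equals the brute-force charge sum", {
  ## two unit point charges 10 Bohr apart in different fragments -> 0.1 Ha
  g <- system_geometry(c("H", "H"),
                      coords_bohr = rbind(c(0, 0, 0), c(10, 0, 0)))
  fs <- build_fragments(g, list(1L, 2L), charges = c(1L, 1L))
  recs <- list("1" = list(charges = 1), "2" = list(charges = 1))
  expect_equal(far_pair_electrostatics(g, fs, recs, 1L, 2L), 0.1,
               tolerance = 1e-14)
  ## all-zero charges on either side -> exactly 0
  recs0 <- list("1" = list(charges = 0), "2" = list(charges = 1))
  expect_identical(far_pair_electrostatics(g, fs, recs0, 1L, 2L), 0)
  ## 3x3 charge fragments vs 9-term enumeration
  set.seed(4)
  coords <- rbind(matrix(runif(9, 0, 2), 3), matrix(runif(9, 10, 12), 3))
  g2 <- system_geometry(rep("H", 6), coords_bohr = coords)
  fs2 <- build_fragments(g2, list(1:3, 4:6))
  qa <- c(0.3, -0.1, 0.2); qb <- c(-0.4, 0.25, 0.15)
  recs2 <- list("1" = list(charges = qa), "2" = list(charges = qb))
  e_or <- 0
  for (a in 1:3) for (b in 1:3)
    e_or <- e_or + qa[a] * qb[b] /
      sqrt(sum((coords[a, ] - coords[3 + b, ])^2))
  expect_equal(far_pair_electrostatics(g2, fs2, recs2, 1L, 2L), e_or,
               tolerance = 1e-13)
})

test_that("non-convergence raises a polarization error with the residual", {
  s <- bare_sites(rbind(c(0, 0, 0), c(5, 0, 0)), q = c(0, 0),
                  alpha = c(1, 1), frag = c(1L, 2L))
  F0 <- rbind(c(0.05, 0, 0), c(0.05, 0, 0))
  expect_error(solve_induced_dipoles(s, field = F0, max_iter = 1L),
               "residual", class = "fragopt_polarization_error")
})
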