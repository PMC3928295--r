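test_that("pair selection applies the vdW relative distance and FDD rules", {
  w <- make_water_chain(2, spacing = 2.8)
  part <- all_active_partition(w$fragments)
  pairs <- select_qm_pairs(w$fragments, w$geometry, part, 1.5)
  ## oracle: minimum over atom pairs of r / (vdW sums) with the Bondi table
  rel_oracle <- Inf
  for (a in 1:3) for (b in 4:6) {
    r <- oracle_min_dist_ang(w$geometry, a, b)
    rel_oracle <- min(rel_oracle,
                      r / (vdw_radius(w$geometry$elements[a]) +
                           vdw_radius(w$geometry$elements[b])))
  }
  expect_equal(pairs$rel_distance[1], rel_oracle, tolerance = 1e-12)
  expect_true(pairs$qm[1])
  ## vanishing cutoff excludes the pair
  pairs0 <- select_qm_pairs(w$fragments, w$geometry, part, 1e-9)
  expect_false(pairs0$qm[1])
  ## pairs wholly inside F are never recomputed under FDD
  toy <- make_toy_reaction()
  pt <- select_qm_pairs(toy$fragments, toy$geometry, toy$partition, 1.5)
  ff <- pt$domain_i == "F" & pt$domain_j == "F"
  expect_true(all(pt$recompute[ff] == "once"))
  expect_true(all(pt$recompute[pt$domain_i == "A" | pt$domain_j == "A"] ==
                    "always"))
  pt_nofdd <- select_qm_pairs(toy$fragments, toy$geometry, toy$partition,
                              1.5, fdd = FALSE)
  expect_true(all(pt_nofdd$recompute == "always"))
})

test_that("a one-fragment system reduces to its monomer energy", {
  w <- make_water_chain(1)
  part <- all_active_partition(w$fragments)
  rep1 <- efmo_total_energy(w$geometry, w$fragments, part, run_config())
  rec <- compute_monomer(w$geometry, w$fragments, 1L)
  expect_identical(rep1$total, rec$energy)
  expect_identical(rep1$qm_dimer_sum, 0)
  expect_identical(rep1$total_classical_pol, 0)
})

test_that("the two-body expansion is exact for 2 and 3 fragments (mock)", {
  cfg <- run_config(dimer_cutoff = Inf, polarization_enabled = FALSE)
  for (n in 2:3) {
    w <- make_water_chain(n, spacing = 3.0, seed = n, perturbation = 0.05)
    part <- all_active_partition(w$fragments)
    rep_n <- efmo_total_energy(w$geometry, w$fragments, part, cfg)
    super <- as.numeric(mock_backend_energy(
      w$geometry, groups = split(seq_len(3 * n), rep(seq_len(n), each = 3))))
    expect_lt(abs(rep_n$total - super), 1e-12)
  }
})

test_that("energy report terms sum exactly to the stored total", {
  w <- make_water_chain(4, spacing = 3.0, seed = 8, perturbation = 0.05)
  part <- assign_domains(w$fragments, w$geometry, 1L, 3.5, 6.5)
  rep4 <- efmo_hybrid_energy(w$geometry, w$fragments, part, run_config())
  expect_identical(rep4$total,
                   rep4$monomer_sum + rep4$qm_dimer_sum +
                     rep4$pair_pol_correction + rep4$far_pair_sum +
                     rep4$total_classical_pol + rep4$mp2_correction)
  expect_lte(rep4$mp2_correction, 0)
  ## tidy/glance surface
  td <- tidy(rep4)
  expect_true(all(c("term", "fragments", "hartree", "kcal_mol") %in%
                    names(td)))
  expect_equal(glance(rep4)$total, rep4$total)
})

test_that("hybrid total differs from RHF by exactly E_corr(H)", {
  cfg <- run_config(mp2_basis = "cc-pVDZ")
  for (fixture in list(make_water_chain(3, seed = 1, perturbation = 0.08),
                       make_water_cluster(3, seed = 2))) {
    for (h in fixture$fragments$id) {
      part <- all_active_partition(fixture$fragments, h)
      r_rhf <- efmo_total_energy(fixture$geometry, fixture$fragments, part, cfg)
      r_hyb <- efmo_hybrid_energy(fixture$geometry, fixture$fragments, part, cfg)
      rec_h <- compute_monomer(fixture$geometry, fixture$fragments, h,
                               "MP2", "cc-pVDZ")
      ## strictly additive: bitwise identity of the difference
      expect_identical(r_hyb$total, r_rhf$total + rec_h$correlation_energy)
      expect_identical(r_hyb$mp2_correction, rec_h$correlation_energy)
    }
  }
})

test_that("choosing each fragment as H shifts the total by its own E_corr", {
  w <- make_water_chain(3, seed = 6, perturbation = 0.1)
  cfg <- run_config(mp2_basis = "cc-pVTZ")
  totals <- numeric(3); corrs <- numeric(3)
  for (h in 1:3) {
    part <- all_active_partition(w$fragments, h)
    totals[h] <- efmo_hybrid_energy(w$geometry, w$fragments, part, cfg)$total
    corrs[h] <- compute_monomer(w$geometry, w$fragments, h, "MP2",
                                "cc-pVTZ")$correlation_energy
  }
  expect_equal(totals - corrs, rep(totals[1] - corrs[1], 3),
               tolerance = 1e-14)
})

test_that("FDD caching computes frozen records once and is energy-neutral", {
  toy <- make_toy_reaction()
  cfg_fdd <- run_config(hybrid_enabled = FALSE)
  cache <- new_fdd_cache()
  e1 <- efmo_total_energy(toy$geometry, toy$fragments, toy$partition,
                          cfg_fdd, cache, toy$backend)
  ## displace an active atom and evaluate twice more
  g2 <- toy$geometry
  g2$coords[1, 1] <- g2$coords[1, 1] + 0.05
  for (k in 1:2)
    efmo_total_energy(g2, toy$fragments, toy$partition, cfg_fdd, cache,
                      toy$backend)
  audit <- fdd_cache_audit(cache)
  f_mono <- audit[audit$kind == "monomer" & audit$domain == "F", ]
  expect_true(all(f_mono$count == 1L))
  a_mono <- audit[audit$kind == "monomer" & audit$domain == "A", ]
  expect_true(all(a_mono$count >= 2L))
  ff_dimer <- audit[audit$kind == "dimer" & audit$domain == "F-F", ]
  expect_true(all(ff_dimer$count <= 1L))

  ## control: with FDD off every monomer is recomputed on every evaluation
  cfg_off <- run_config(hybrid_enabled = FALSE, fdd_enabled = FALSE)
  cache2 <- new_fdd_cache()
  for (k in 1:3)
    efmo_total_energy(toy$geometry, toy$fragments, toy$partition, cfg_off,
                      cache2, toy$backend)
  audit2 <- fdd_cache_audit(cache2)
  expect_true(all(audit2$count[audit2$kind == "monomer"] == 3L))

  ## FDD on/off gives bitwise identical totals on a fixed geometry
  e_fdd <- efmo_total_energy(toy$geometry, toy$fragments, toy$partition,
                             cfg_fdd, new_fdd_cache(), toy$backend)
  e_off <- efmo_total_energy(toy$geometry, toy$fragments, toy$partition,
                             cfg_off, new_fdd_cache(), toy$backend)
  expect_identical(e_fdd$total, e_off$total)
})

test_that("moving an active atom invalidates only that fragment's records", {
  toy <- make_toy_reaction()
  cfg <- run_config(hybrid_enabled = FALSE)
  cache <- new_fdd_cache()
  efmo_total_energy(toy$geometry, toy$fragments, toy$partition, cfg, cache,
                    toy$backend)
  keys_before <- ls(cache$store)
  g2 <- toy$geometry
  g2$coords[2, 2] <- g2$coords[2, 2] + 0.02   # substrate (fragment 1) atom
  efmo_total_energy(g2, toy$fragments, toy$partition, cfg, cache,
                    toy$backend)
  keys_after <- ls(cache$store)
  fresh <- setdiff(keys_after, keys_before)
  ## new records only for fragment 1's monomer and its dimers
  expect_true(all(grepl("^monomer\\|1\\|", fresh) |
                    grepl("^dimer\\|1,", fresh)))
  audit <- fdd_cache_audit(cache)
  expect_equal(audit$count[audit$kind == "monomer" & audit$label == "1"], 2L)
  expect_true(all(audit$count[audit$kind == "monomer" &
                                audit$label != "1"] == 1L))
})

test_that("duplicating a system at 1000 A doubles the total energy", {
  w <- make_water_chain(2, spacing = 3.0, seed = 3, perturbation = 0.05)
  cfg <- run_config()
  part <- all_active_partition(w$fragments)
  e1 <- efmo_total_energy(w$geometry, w$fragments, part, cfg)$total
  g2 <- system_geometry(rep(w$geometry$elements, 2),
                        coords_bohr = rbind(w$geometry$coords,
                                            sweep(w$geometry$coords, 2,
                                                  c(1000 / ANG_PER_BOHR, 0, 0),
                                                  "+")))
  fs2 <- build_fragments(g2, list(1:3, 4:6, 7:9, 10:12))
  part2 <- all_active_partition(fs2)
  e2 <- efmo_total_energy(g2, fs2, part2, cfg)$total
  expect_lt(abs(e2 - 2 * e1), 1e-8)
})

test_that("the far-pair sum vanishes member-by-member as the cutoff grows", {
  w <- make_water_chain(4, spacing = 3.0, seed = 9, perturbation = 0.05)
  part <- all_active_partition(w$fragments)
  cuts <- c(1.0, 1.5, 2.5, 5, Inf)
  fars <- vapply(cuts, function(ct) {
    efmo_total_energy(w$geometry, w$fragments, part,
                      run_config(dimer_cutoff = ct))$far_pair_sum
  }, 1.0)
  expect_identical(fars[length(fars)], 0)
  totals <- vapply(cuts, function(ct) {
    efmo_total_energy(w$geometry, w$fragments, part,
                      run_config(dimer_cutoff = ct))$total
  }, 1.0)
  ## migration jumps shrink with distance: successive totals approach the
  ## all-QM limit monotonically in magnitude of change
  jumps <- abs(diff(totals))
  expect_lt(jumps[length(jumps)], jumps[1] + 1e-15)
})

test_that("polarization span switch restricts E_pol to the chosen domains", {
  toy <- make_toy_reaction()
  cfg_all <- run_config(hybrid_enabled = FALSE, pol_domain = "all")
  cfg_ab <- run_config(hybrid_enabled = FALSE, pol_domain = "active_buffer")
  e_all <- efmo_total_energy(toy$geometry, toy$fragments, toy$partition,
                             cfg_all, NULL, toy$backend)
  e_ab <- efmo_total_energy(toy$geometry, toy$fragments, toy$partition,
                            cfg_ab, NULL, toy$backend)
  ## the restricted span drops the frozen spectators' induction
  expect_false(identical(e_all$total_classical_pol, e_ab$total_classical_pol))
  ## oracle for the restricted span: dense solve over A+b sites only
  recs <- lapply(toy$fragments$id, function(id)
    compute_monomer(toy$geometry, toy$fragments, id, backend = toy$backend))
  names(recs) <- as.character(toy$fragments$id)
  s_ab <- pol_sites(toy$geometry, toy$fragments, recs, c(1L, 2L))
  expect_lt(abs(e_ab$total_classical_pol -
                  solve_induced_dipoles(s_ab, method = "dense")$energy),
            1e-10)
})
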