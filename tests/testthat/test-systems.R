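# Ligand templates, anchor geometries and system construction.

test_that("ligand templates carry the prescribed charges and satisfy their invariants", {
  tpl <- build_ligand_template("formaldehyde_like")
  expect_equal(tpl$atoms$charge, c(0.5, -0.5, 0, 0))
  expect_equal(tpl$net_charge, 0)
  expect_length(tpl$coordinating, 1)
  expect_identical(tpl$atoms$element[tpl$coordinating], "O")

  for (kind in c("formaldehyde_like", "backbone_carbonyl", "hydroxyl",
                 "carboxylate")) {
    t2 <- build_ligand_template(kind)
    expect_equal(sum(t2$atoms$charge), t2$net_charge, tolerance = 1e-12)
    idx <- c(t2$bonds$i, t2$bonds$j, t2$angles$i, t2$angles$j, t2$angles$k)
    expect_true(all(idx >= 1 & idx <= nrow(t2$atoms)))
  }

  carb <- build_ligand_template("carboxylate")
  expect_length(carb$coordinating, 2)   # bidentate: both oxygens
  expect_equal(carb$net_charge, -1)

  expect_error(build_ligand_template("ether"), "unsupported")
})

test_that("anchor geometries hit the known packing optima", {
  g4 <- anchor_geometry(4, 2.3)
  expect_equal(g4$min_angle, 109.4712, tolerance = 1e-3)
  g6 <- anchor_geometry(6, 2.3)
  expect_equal(g6$min_angle, 90, tolerance = 1e-3)
  g8 <- anchor_geometry(8, 2.3)
  expect_equal(g8$min_angle, 74.8585, tolerance = 1e-3)
  expect_gt(g8$min_angle, anchor_geometry(8, 2.3, n8 = "cube")$min_angle)

  g5 <- anchor_geometry(5, 1.0)
  expect_equal(sqrt(rowSums(g5$points^2)), rep(1, 5), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(g4$points^2)), rep(2.3, 4), tolerance = 1e-9)

  expect_error(anchor_geometry(3, 2.3), "unsupported coordination")
  expect_error(anchor_geometry(9, 2.3), "unsupported coordination")

  expect_identical(anchor_geometry(7, 1.5)$points, anchor_geometry(7, 1.5)$points)
})

test_that("the sphere-packing optimiser reproduces the closed-form polyhedra", {
  for (n in c(4, 6)) {
    pts <- pack_points_sphere(n, seed = 0)
    expect_equal(min_pair_angle(pts), anchor_geometry(n, 1)$min_angle,
                 tolerance = 1e-3)
  }
})

test_that("abstract cages have the right composition, charge and restraints", {
  sys <- build_abstract_system("Na", 6)
  expect_equal(nrow(sys$atoms), 25)          # 1 ion + 6 x 4 atoms
  expect_null(sys$anchors)                   # kf = 0 means no anchors
  expect_equal(system_charge(sys), 1)
  expect_length(sys$wall$atoms, 6)

  dual <- build_abstract_system("K", 8, r_opt = 2.8, kf = 50, dual_sets = TRUE)
  expect_equal(sum(dual$atoms$set == 1L), 32)
  expect_equal(sum(dual$atoms$set == 2L), 32)
  expect_true(all(dual$anchors$idx %in% which(dual$atoms$set == 1L)))
  expect_equal(system_charge(dual), 1)

  expect_error(build_abstract_system("Na", 6, kf = 100),
               "r_opt")
})

test_that("identical inputs give bit-identical systems", {
  s1 <- build_abstract_system("Li", 5, r_opt = 2.0, kf = 10, dual_sets = TRUE)
  s2 <- build_abstract_system("Li", 5, r_opt = 2.0, kf = 10, dual_sets = TRUE)
  expect_identical(s1$coords, s2$coords)
  expect_identical(s1$anchors$pos, s2$anchors$pos)
})

test_that("minimisation finds the isolated-pair optimum and orders ions by size", {
  # single anchored atom already at its minimum: coordinates unchanged
  toy <- build_toy_oracle(1, kf = 10)
  out <- minimise(toy, max_steps = 100, tol = 1e-6)
  expect_equal(out$coords, toy$coords, tolerance = 1e-10)

  # ion + one ligand relaxes to the 1-D scan minimum
  dmin <- list()
  for (ion in c("Li", "Na", "K")) {
    sys <- build_abstract_system(ion, 4)
    keep <- which(sys$atoms$ligand %in% c(0L, 1L))
    # single-ligand system built directly
    tpl <- build_ligand_template("formaldehyde_like")
    one <- rlfep:::new_particle_system(ion, list(list(
      template = tpl,
      coords = rlfep:::place_ligand(tpl, c(0, 0, 1), 2.6), set = 1L)))
    one <- minimise(one, max_steps = 5000, tol = 1e-3)
    d <- sqrt(sum(one$coords[1 + tpl$coordinating, ]^2))
    expect_equal(d, pair_minimum_scan(ion), tolerance = 0.02)
    dmin[[ion]] <- d
  }
  expect_lt(dmin$Li, dmin$Na)   # smaller LJ radius pulls the pair minimum in
  expect_lt(dmin$Na, dmin$K)
})

test_that("site models match the published compositions and charges", {
  na2 <- build_site_model("LeuT_Na2", "Na")
  frag <- table(na2$atoms$fragment[na2$atoms$set == 1L &
                                   !duplicated(na2$atoms$ligand)])
  ligs <- na2$atoms[na2$atoms$set == 1L, ]
  per_lig <- tapply(ligs$fragment, ligs$ligand, `[`, 1)
  expect_equal(sum(per_lig == "backbone_carbonyl"), 3)  # GLY20, VAL23, ALA351
  expect_equal(sum(per_lig == "hydroxyl"), 2)           # THR354, SER355
  expect_equal(system_charge(na2), 1)                   # all-neutral ligands

  glt1 <- build_site_model("Glt_Na1", "Na")
  per_lig <- tapply(glt1$atoms$fragment[glt1$atoms$set == 1L],
                    glt1$atoms$ligand[glt1$atoms$set == 1L], `[`, 1)
  expect_true("carboxylate" %in% per_lig)               # ASP405, bidentate
  expect_length(glt1$wall$atoms, 5)                     # 3 C=O + 2 carboxylate O

  na1 <- build_site_model("LeuT_Na1", "Na")
  expect_equal(system_charge(na1), 0)                   # carboxylate + cation

  expect_error(build_site_model("KcsA_S2", "K"), "unknown site")
})

test_that("per-ion minimised anchors are strain-free: Li sits closer than K", {
  dli <- build_site_model("LeuT_Na2", "Li", kf = 100)
  dk <- build_site_model("LeuT_Na2", "K", kf = 100)
  oli <- mean(sqrt(rowSums(dli$coords[dli$wall$atoms, ]^2)))
  ok <- mean(sqrt(rowSums(dk$coords[dk$wall$atoms, ]^2)))
  expect_lt(oli, ok)
})
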