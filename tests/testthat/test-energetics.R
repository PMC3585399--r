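# Pair energies, switching, softcore, restraints, totals and forces.

test_that("pair energy reproduces the 12-6 minimum, Coulomb's law and the cutoff", {
  p <- nonbonded_params()
  eps <- 0.15; sig <- 3.0
  # LJ-only minimum at 2^(1/6) sigma is exactly -eps
  expect_equal(pair_energy(0, 0, eps, sig, 2^(1 / 6) * sig, p), -eps,
               tolerance = 1e-12)
  # Coulomb's law with the standard kcal A / (mol e^2) constant
  expect_equal(pair_energy(1, -0.5, 0, 1, 3, p),
               332.0637 * (-0.5) / 3, tolerance = 1e-10)
  # identically zero at and beyond the cutoff
  for (r in c(12, 12.5, 20))
    expect_identical(pair_energy(1, 1, eps, sig, r, p), 0)
  expect_error(pair_energy(1, 1, eps, sig, 0, p), "singular")
})

test_that("pair energy is continuous through the switching region", {
  p <- nonbonded_params()
  u <- function(r) pair_energy(0.3, -0.4, 0.1, 3.2, r, p)
  for (r0 in c(10, 12)) {
    expect_lt(abs(u(r0 - 1e-9) - u(r0 + 1e-9)), 1e-8)
    # slopes match across the joins (the switch is C1)
    s_in <- (u(r0 - 1e-5) - u(r0 - 3e-5)) / 2e-5
    s_out <- (u(r0 + 3e-5) - u(r0 + 1e-5)) / 2e-5
    expect_equal(s_in, s_out, tolerance = 1e-3)
  }
})

test_that("softcore is finite when decoupled and exact at full coupling", {
  p <- nonbonded_params()
  rs <- seq(0.5, 11.5, by = 0.25)
  plain <- vapply(rs, function(r) pair_energy(0, 0, 0.2, 3, r, p), numeric(1))
  soft1 <- vapply(rs, function(r) pair_energy(0, 0, 0.2, 3, r, p,
                                              lambda_vdw = 1), numeric(1))
  expect_equal(soft1, plain, tolerance = 1e-12)
  # decoupled-state energies stay finite down to near-zero separation
  for (lam in c(0.01, 0.5, 0.99))
    expect_true(is.finite(pair_energy(0, 0, 5, 3, 1e-3, p, lambda_vdw = lam)))
})

test_that("restraint terms follow the half-k convention and flat bottom", {
  spec <- list(sphere = list(center = c(0, 0, 0), radius = 3.5, k = 100))
  expect_equal(restraint_energy(c(3.4, 0, 0), spec)[["wall"]], 0)
  expect_equal(restraint_energy(c(3.6, 0, 0), spec)[["wall"]], 0.5)
  spec$anchor <- list(pos = c(1, 2, 3), kf = 250)
  expect_equal(restraint_energy(c(1, 2, 3), spec)[["anchor"]], 0)
  expect_equal(restraint_energy(c(1, 2, 4), spec)[["anchor"]], 125)
})

test_that("total energy is additive and zero for an isolated ion", {
  lone <- build_toy_oracle(0)
  expect_equal(total_energy(lone)[["total"]], 0)

  sys <- build_abstract_system("Na", 5)
  e <- total_energy(sys)
  expect_equal(e[["total"]],
               e[["coulomb"]] + e[["lj"]] + e[["bonded"]] +
                 e[["wall_restraint"]] + e[["anchor_restraint"]],
               tolerance = 1e-9)
  expect_gte(e[["wall_restraint"]], 0)
  expect_gte(e[["anchor_restraint"]], 0)
})

test_that("analytic forces match central differences", {
  sys <- build_abstract_system("K", 4, r_opt = 2.7, kf = 25, dual_sets = TRUE)
  sys$alchemy$mode <- "dual_set"
  sys <- set_lambda(sys, 0.3)
  f <- forces(sys)
  x <- sys$coords
  h <- 1e-5
  set.seed(11)
  for (probe in sample(seq_len(nrow(x)), 6)) {
    for (d in 1:3) {
      xp <- x; xp[probe, d] <- xp[probe, d] + h
      xm <- x; xm[probe, d] <- xm[probe, d] - h
      num <- -(total_energy(sys, xp)[["total"]] -
                 total_energy(sys, xm)[["total"]]) / (2 * h)
      expect_equal(f[probe, d], num, tolerance = 1e-5)
    }
  }
})

test_that("non-restraint terms are translation invariant", {
  sys <- build_abstract_system("Na", 4)
  sys$wall$atoms <- integer(0)
  e0 <- total_energy(sys)
  shifted <- sweep(sys$coords, 2, c(1.7, -2.1, 0.4), "+")
  e1 <- total_energy(sys, shifted)
  for (cmp in c("coulomb", "lj", "bonded"))
    expect_equal(e1[[cmp]], e0[[cmp]], tolerance = 1e-9)
})

test_that("dual ligand sets do not interact with each other", {
  sys <- build_abstract_system("Na", 4, r_opt = 2.3, kf = 10, dual_sets = TRUE)
  sys$alchemy$mode <- "dual_set"
  single <- build_abstract_system("Na", 4, r_opt = 2.3, kf = 10)
  # at lambda = 0 the ghost set is fully decoupled: nonbonded terms equal the
  # single-set system's even though the ghosts sit right on top of it
  e_dual <- total_energy(set_lambda(sys, 0))
  e_single <- total_energy(single)
  expect_equal(e_dual[["coulomb"]], e_single[["coulomb"]], tolerance = 1e-9)
  expect_equal(e_dual[["lj"]], e_single[["lj"]], tolerance = 1e-9)
  expect_true(is.finite(total_energy(set_lambda(sys, 0.5))[["total"]]))
})
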