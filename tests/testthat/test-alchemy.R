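# Lambda schedules, estimators against closed forms, morph legs and cycle
# arithmetic.

test_that("lambda schedules are monotone, complete and mirrored in reverse", {
  s <- lambda_schedule("dense_endpoints")
  expect_equal(s$values[1], 0)
  expect_equal(s$values[length(s$values)], 1)
  expect_false(is.unsorted(s$values, strictly = TRUE))
  r <- lambda_schedule("uniform", 11, direction = "reverse")
  expect_identical(schedule_traversal(r), rev(r$values))
  expect_error(lambda_schedule(values = c(0, 0.5, 0.4, 1)), "increasing")
  expect_error(lambda_schedule(values = c(0.1, 0.5, 1)), "endpoints")
})

test_that("EXP handles degenerate perturbations exactly", {
  lams <- seq(0, 1, 0.25)
  zero <- estimate_exp(fake_samples(lams, rep(0, 4)))
  expect_equal(zero$total_dG, 0, tolerance = 1e-12)
  const <- estimate_exp(fake_samples(lams, rep(1.7, 4)))
  expect_equal(const$per_window$dG, rep(1.7, 4), tolerance = 1e-12)
  expect_equal(const$total_dG, 4 * 1.7, tolerance = 1e-12)
})

test_that("BAR is exact for a symmetric two-state toy", {
  s <- fake_samples(c(0, 1), 0)
  expect_equal(estimate_bar(s)$total_dG, 0, tolerance = 1e-9)
})

test_that("per-window totals add up (leg invariant)", {
  s <- fake_samples(seq(0, 1, 0.2), c(0.3, -1.1, 2.0, 0.7, -0.2))
  est <- estimate_exp(s)
  expect_equal(est$total_dG, sum(est$per_window$dG), tolerance = 1e-9)
})

test_that("the single-atom anchor morph matches the harmonic closed form", {
  kB <- rlf_constants()$kB
  closed <- 1.5 * kB * 310 * log(10)
  # the quadrature oracle agrees with the closed form
  expect_equal(harmonic_dG_quadrature(1, 10), closed, tolerance = 1e-6)

  sys <- build_toy_oracle(1, kf = 1, kf_target = 10)
  sam <- collect_fep_samples(sys, lambda_schedule("uniform", 11), 20000,
                             seed = 7)
  ex <- estimate_exp(sam)
  br <- estimate_bar(sam)
  expect_lt(abs(ex$total_dG - closed), 2 * ex$total_se)
  expect_lt(abs(br$total_dG - closed), 2 * br$total_se)
  # estimator consistency on the same data
  expect_lt(abs(ex$total_dG - br$total_dG),
            2 * sqrt(ex$total_se^2 + br$total_se^2) + 0.05)
})

test_that("forward and reverse runs agree within hysteresis tolerance", {
  fw <- collect_fep_samples(build_toy_oracle(2, kf = 1, kf_target = 10),
                            lambda_schedule("uniform", 11), 15000, seed = 3)
  rv <- collect_fep_samples(build_toy_oracle(2, kf = 1, kf_target = 10),
                            lambda_schedule("uniform", 11,
                                            direction = "reverse"),
                            15000, seed = 4)
  efw <- estimate_exp(fw); erv <- estimate_exp(rv)
  expect_lt(hysteresis(efw, erv),
            2 * sqrt(efw$total_se^2 + erv$total_se^2) + 0.05)
  expect_identical(hysteresis(efw, structure(list(total_dG = -efw$total_dG),
                                             class = "fep_leg")), 0)
  agg <- hysteresis_summary(c(0.1, 0.5, 0.2))
  expect_equal(agg, c(max = 0.5, mean = 0.8 / 3))
})

test_that("restraint morphs respect the no-strain guard and the kf = 0 identity", {
  z <- run_restraint_morph("Na", 5, kf_target = 0, seed = 1)
  expect_identical(z$total_dG, 0)
  expect_identical(sum(z$per_window$dG), 0)

  anchors_k <- cage_anchors("K", 4, 2.7)
  expect_error(run_restraint_morph("Na", 4, 100, anchors_k, seed = 1),
               "strain contamination")
  # deliberate strained-cavity mode is allowed and runs
  leg <- run_restraint_morph("Na", 4, 100, anchors_k, seed = 1,
                             schedule = lambda_schedule(values = c(0, 0.3, 0.7, 1)),
                             nsteps_per_window = 2000, allow_strain = TRUE)
  expect_true(is.finite(leg$total_dG))
})

test_that("ion morphs refuse anchored systems and are trivial for identical species", {
  id <- run_ion_morph(4, "Na", "Na", seed = 1)
  expect_identical(id$total_dG, 0)
  empty <- run_ion_morph(0, "Na", "K", seed = 1)
  expect_identical(empty$total_dG, 0)
  anchored <- build_abstract_system("Na", 4, r_opt = 2.3, kf = 10)
  expect_error(run_ion_morph(ion_from = "Na", ion_to = "K", system = anchored),
               "protocol error")
})

test_that("ion morphs are reversible within statistical error", {
  fw <- run_ion_morph(4, "Na", "K", seed = 11, nsteps_per_window = 10000,
                      schedule = lambda_schedule("uniform", 11))
  bw <- run_ion_morph(4, "K", "Na", seed = 12, nsteps_per_window = 10000,
                      schedule = lambda_schedule("uniform", 11))
  expect_lt(abs(fw$total_dG + bw$total_dG),
            2 * sqrt(fw$total_se^2 + bw$total_se^2) + 0.2)
})

test_that("cycle assembly is pure arithmetic with the documented sign pattern", {
  cA <- fake_leg(1.0, ions = "Na", kf = 100)
  cB <- fake_leg(-2.0, ions = "K", kf = 100)
  site <- fake_leg(0.5, kind = "ion_morph", ions = c("K", "Na"))
  cy <- assemble_cycle(cA, cB, site, ddG_hydr = 3.0)
  # ddG = dG_B + dG_site - ddG_hydr - dG_A
  expect_equal(cy$ddG_exchange, -2.0 + 0.5 - 3.0 - 1.0, tolerance = 1e-12)
  expect_equal(cy$ddG_rlf, -3.0, tolerance = 1e-12)

  # kf = 0: both constraint legs vanish and ddG_RLF is exactly zero
  zA <- fake_leg(0, ions = "Na", kf = 0); zB <- fake_leg(0, ions = "K", kf = 0)
  cy0 <- assemble_cycle(zA, zB, site, ddG_hydr = 3.0)
  expect_identical(cy0$ddG_rlf, 0)

  expect_error(assemble_cycle(fake_leg(1, kf = 10), cB, site, 0),
               "different kf")
  bad_site <- fake_leg(0.5, kind = "ion_morph", ions = c("Na", "K"))
  expect_error(assemble_cycle(cA, cB, bad_site, 0), "site exchange")
  # hydration constant defaults to the packaged table
  cy2 <- assemble_cycle(cA, cB, site)
  expect_equal(cy2$ddG_hydr, hydration_ddG("K", "Na"), tolerance = 1e-12)
})

test_that("thermo decomposition is an exact arithmetic identity", {
  cA <- fake_leg(2.0, ions = "Na", kf = 100, endpoint_u = c(-10, -9))
  cB <- fake_leg(5.0, ions = "K", kf = 100, endpoint_u = c(-20, -15))
  site <- fake_leg(0, kind = "ion_morph", ions = c("K", "Na"))
  cy <- assemble_cycle(cA, cB, site, ddG_hydr = 0)
  dec <- decompose_thermo(list(cy))
  expect_equal(dec$dG, dec$dH + dec$minus_TdS, tolerance = 1e-9)
  expect_equal(dec$dH, ((-15) - (-20)) - ((-9) - (-10)), tolerance = 1e-9)
})
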