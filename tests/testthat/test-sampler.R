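# Langevin sampling: determinism, frame bookkeeping, thermostat calibration,
# containment, and cross-energy re-evaluation.

test_that("trajectories are deterministic and frames are counted correctly", {
  sys <- build_abstract_system("Na", 4)
  t1 <- run_dynamics(sys, 3000, seed = 42, save_interval = 100)
  t2 <- run_dynamics(sys, 3000, seed = 42, save_interval = 100)
  t3 <- run_dynamics(sys, 3000, seed = 43, save_interval = 100)
  expect_identical(t1$frames, t2$frames)
  expect_false(identical(t1$frames, t3$frames))
  expect_equal(dim(t1$frames)[1], 31)  # floor(nsteps/save) + initial frame
  expect_true(all(is.finite(t1$frames)))
  # the ion never moves
  expect_true(all(t1$frames[, 1, ] == 0))
})

test_that("zero temperature from a minimum leaves atoms stationary", {
  toy <- build_toy_oracle(3, kf = 10)
  tr <- run_dynamics(toy, 2000, seed = 1, temperature = 0)
  nf <- dim(tr$frames)[1]
  expect_equal(tr$frames[nf, , ], tr$frames[1, , ], tolerance = 1e-12)
})

test_that("the thermostat samples the target temperature (equipartition)", {
  toy <- build_toy_oracle(5, kf = 10)
  tr <- run_dynamics(toy, 100000, seed = 7)          # 100 ps
  tk <- tr$energies$tkin[-(1:100)]
  blocks <- split(tk, cut(seq_along(tk), 10, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(tk) - 310), 3 * se + 1e-9)
})

test_that("anchored-atom fluctuations follow the equipartition closed form", {
  kB <- rlf_constants()$kB
  for (kf in c(1, 10, 100)) {
    toy <- build_toy_oracle(1, kf = kf)
    tr <- run_dynamics(toy, 120000, seed = 21 + kf)
    r <- rms_fluctuation(tr, atoms = 2)
    expect_equal(r$pooled, sqrt(3 * kB * 310 / kf), tolerance = 0.05)
  }
})

test_that("the spherical wall contains the coordinating oxygens", {
  sys <- build_abstract_system("K", 6)
  sys <- minimise(sys, 1000, 1)
  tr <- run_dynamics(sys, 50000, seed = 3, save_interval = 10)
  viol <- 0
  for (a in sys$wall$atoms) {
    d <- sqrt(rowSums(tr$frames[, a, ]^2))
    viol <- viol + sum(d > 3.6)
  }
  expect_lt(viol / (dim(tr$frames)[1] * length(sys$wall$atoms)), 1e-3)
})

test_that("cross energies reproduce the trajectory's own series and are flat for a lambda-independent Hamiltonian", {
  sys <- build_abstract_system("Na", 4)
  sys$alchemy$mode <- "ion_morph"; sys$alchemy$ion_to <- "K"
  sys <- set_lambda(sys, 0.4)
  tr <- run_dynamics(sys, 2000, seed = 5)
  x <- sample_cross_energies(sys, tr, c(0.2, 0.4, 0.9))
  expect_equal(unname(x[, 2]), tr$energies$total, tolerance = 1e-9)
  expect_error(sample_cross_energies(sys, tr, c(0, 1.2)), "lambda")

  plain <- build_toy_oracle(2, kf = 5)   # no alchemical dependence
  tp <- run_dynamics(plain, 1000, seed = 6)
  xp <- sample_cross_energies(plain, tp, c(0, 0.5, 1))
  expect_equal(xp[, 1], xp[, 2], tolerance = 1e-12)
  expect_equal(xp[, 1], xp[, 3], tolerance = 1e-12)
})

test_that("fluctuation analysis rejects degenerate input and reports zero for frozen atoms", {
  toy <- build_toy_oracle(2, kf = 10)
  tr <- run_dynamics(toy, 1000, seed = 2, temperature = 0)
  r <- rms_fluctuation(tr)
  expect_equal(unname(r$pooled), 0, tolerance = 1e-12)
  tr1 <- tr
  tr1$frames <- tr$frames[1, , , drop = FALSE]
  expect_error(rms_fluctuation(tr1), "single frame")
})
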