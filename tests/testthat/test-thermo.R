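# RDF and optimal radii, occupancy volumes.

make_static_traj <- function(sys, nframes = 150) {
  nat <- nrow(sys$coords)
  frames <- array(0, c(nframes, nat, 3))
  for (f in seq_len(nframes)) frames[f, , ] <- sys$coords
  structure(list(frames = frames, natom = nat, system = sys,
                 temperature = sys$temperature, timestep = 1, seed = 0),
            class = "trajectory")
}

test_that("the RDF first peak recovers a frozen shell radius", {
  sys <- build_abstract_system("Na", 6, r_opt = 2.3)
  tr <- make_static_traj(sys)
  rdf <- compute_rdf(tr, bin_width = 0.05)
  expect_lt(abs(rdf$first_peak_r - 2.3), 0.05 / 2 + 1e-9)
  expect_true(all(rdf$g >= 0))
  expect_error(compute_rdf(tr, atoms = integer(0)), "empty")
  tr$frames <- tr$frames[1:10, , , drop = FALSE]
  expect_error(compute_rdf(tr), "100 frames")
})

test_that("optimal radii order with ion size and converge with sampling", {
  ro <- lapply(c("Li", "Na", "K"), function(ion)
    find_r_opt(ion, 4, nsteps = 40000, seed = 2))
  r <- vapply(ro, `[[`, numeric(1), "r_opt")
  expect_lt(r[1], r[2])  # Li < Na
  expect_lt(r[2], r[3])  # Na < K

  # doubling the frames of a converged run moves the peak less than one bin
  sys <- build_abstract_system("Na", 4)
  sys <- minimise(sys, 1000, 1)
  tr <- run_dynamics(sys, 80000, seed = 9)
  half <- tr; half$frames <- tr$frames[1:400, , , drop = FALSE]
  expect_lte(abs(compute_rdf(tr)$first_peak_r - compute_rdf(half)$first_peak_r),
             0.05 + 1e-9)
})

test_that("occupancy volume reproduces a static sphere and behaves monotonically", {
  toy <- build_toy_oracle(1, kf = 10)
  tr <- make_static_traj(toy, nframes = 3)
  v <- occupancy_volume(tr, atoms = 2, spacing = 0.1, radii = 1.52)
  expect_equal(as.numeric(v), 4 / 3 * pi * 1.52^3, tolerance = 0.02)

  # empty trajectory: zero volume
  tr0 <- tr; tr0$frames <- tr$frames[0, , , drop = FALSE]
  expect_equal(as.numeric(occupancy_volume(tr0, atoms = 2, radii = 1.52)), 0)
  expect_error(occupancy_volume(tr, atoms = integer(0)), "empty")

  # a moving atom: volume is non-increasing in the isovalue and cumulative
  # volume non-decreasing with added frames
  toy2 <- build_toy_oracle(1, kf = 5)
  trm <- run_dynamics(toy2, 20000, seed = 4)
  vs <- vapply(c(0.1, 0.5, 1.0), function(iso)
    as.numeric(occupancy_volume(trm, atoms = 2, spacing = 0.2, isovalue = iso,
                                mode = "frame_fraction", radii = 1.52)),
    numeric(1))
  expect_true(all(diff(vs) <= 0))
  part <- trm; part$frames <- trm$frames[1:50, , , drop = FALSE]
  expect_lte(as.numeric(occupancy_volume(part, atoms = 2, spacing = 0.2,
                                         radii = 1.52)),
             as.numeric(occupancy_volume(trm, atoms = 2, spacing = 0.2,
                                         radii = 1.52)))
})

test_that("anchored fluctuations shrink monotonically with kf across the grid", {
  pooled <- vapply(c(1, 10, 100), function(kf) {
    toy <- build_toy_oracle(2, kf = kf)
    tr <- run_dynamics(toy, 30000, seed = 5)
    rms_fluctuation(tr)$pooled
  }, numeric(1))
  expect_true(all(diff(pooled) < 0))
})
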